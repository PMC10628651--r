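#' PAM fluorometry trace
#'
#' A rapid-light-curve protocol trace from a pulse-amplitude-modulation
#' fluorometer: dark-adapted minimum (`F0`) and maximum (`Fm`)
#' fluorescence, followed by stepwise actinic illumination with steady
#' (`F`) and saturating-pulse (`Fm_prime`) fluorescence at each PAR step.
#'
#' @param F0 minimum fluorescence after dark adaptation (> 0).
#' @param Fm maximal fluorescence after a saturating pulse (> F0).
#' @param steps data.frame with columns `PAR` (non-negative,
#'   non-decreasing), `F` (> 0) and `Fm_prime` (>= F).
#' @return an object of class `"pam_trace"`.
#' @export
pam_trace <- function(F0, Fm, steps) {
  if (!(Fm > F0 && F0 > 0))
    stop("need Fm > F0 > 0 (implausible dark-adapted fluorescence)",
         call. = FALSE)
  stopifnot(is.data.frame(steps),
            all(c("PAR", "F", "Fm_prime") %in% names(steps)))
  if (any(steps$PAR < 0) || is.unsorted(steps$PAR))
    stop("'PAR' must be non-negative and non-decreasing", call. = FALSE)
  if (any(steps$F <= 0) || any(steps$Fm_prime < steps$F))
    stop("each step needs Fm_prime >= F > 0", call. = FALSE)
  structure(list(F0 = F0, Fm = Fm, steps = steps), class = "pam_trace")
}

#' @export
print.pam_trace <- function(x, ...) {
  cat(sprintf("PAM trace: Fv/Fm = %.3f, %d light steps (PAR %g..%g)\n",
              fv_fm(x$F0, x$Fm), nrow(x$steps),
              min(x$steps$PAR), max(x$steps$PAR)))
  invisible(x)
}

#' Maximum quantum yield of PSII, Fv/Fm
#'
#' \eqn{F_v/F_m = (F_m - F_0)/F_m} after dark adaptation. Healthy
#' microalgal cultures typically fall in 0.7-0.8; lower values indicate
#' stress on PSII.
#'
#' @param F0,Fm dark-adapted minimum and maximal fluorescence.
#' @return the yield (dimensionless); values with `Fm <= F0` produce a
#'   warning (physically implausible).
#' @examples
#' fv_fm(0.2, 1.0)  # 0.8
#' @export
fv_fm <- function(F0, Fm) {
  if (any(Fm <= 0)) stop("'Fm' must be positive", call. = FALSE)
  if (any(Fm <= F0))
    warning("Fm <= F0: physically implausible trace", call. = FALSE)
  (Fm - F0) / Fm
}

#' Effective quantum yield in light
#'
#' \eqn{\Delta F/F_m' = (F_m' - F)/F_m'} at one actinic light step.
#'
#' @param F steady fluorescence in light.
#' @param Fm_prime maximal fluorescence after a saturating pulse in light.
#' @return the effective yield (dimensionless); `Fm_prime < F` warns.
#' @examples
#' effective_yield(0.5, 1.0)  # 0.5
#' @export
effective_yield <- function(F, Fm_prime) {
  if (any(Fm_prime <= 0)) stop("'Fm_prime' must be positive", call. = FALSE)
  if (any(Fm_prime < F))
    warning("Fm_prime < F: implausible step flagged", call. = FALSE)
  (Fm_prime - F) / Fm_prime
}

#' Relative electron transport rate
#'
#' \eqn{rETR = \Delta F/F_m' \times PAR \times 0.5}; the factor 0.5
#' assumes two photons per electron transported linearly (photons split
#' between the two photosystems).
#'
#' @param delta_yield effective quantum yield \eqn{\Delta F/F_m'}.
#' @param PAR photosynthetically active radiation, umol m^-2 s^-1 (>= 0).
#' @return rETR (dimensionless).
#' @examples
#' retr(0.5, 100)  # 25
#' @export
retr <- function(delta_yield, PAR) {
  if (any(PAR < 0)) stop("'PAR' must be non-negative", call. = FALSE)
  delta_yield * PAR * 0.5
}

#' rETR light-curve points from a PAM trace
#'
#' @param trace a [pam_trace()].
#' @return data.frame with `PAR`, `yield` and `rETR` per step.
#' @export
rlc_points <- function(trace) {
  stopifnot(inherits(trace, "pam_trace"))
  y <- effective_yield(trace$steps$F, trace$steps$Fm_prime)
  data.frame(PAR = trace$steps$PAR, yield = y,
             rETR = retr(y, trace$steps$PAR))
}

#' Fit the rectangular-hyperbola rapid light curve
#'
#' Least-squares fit of the saturating exponential ("rectangular
#' hyperbola") model
#' \deqn{rETR(PAR) = rETR_{max}\,(1 - e^{-\alpha PAR / rETR_{max}})}
#' by Nelder-Mead simplex on log-parameters. Returns the maximum relative
#' electron transport rate, the initial slope \eqn{\alpha} (maximum light
#' utilization coefficient) and the saturation irradiance
#' \eqn{E_k = rETR_{max}/\alpha}.
#'
#' @param PAR light levels; either a numeric vector (with `rETR`) or a
#'   [pam_trace()] (rETR computed via [rlc_points()]).
#' @param rETR observed rETR at each `PAR` (ignored when `PAR` is a
#'   trace).
#' @param include_zero keep the PAR = 0 point (rETR = 0) in the fit
#'   (default TRUE; it anchors the curve at the origin).
#' @param weights optional per-point weights for the squared residuals.
#' @param reltol,maxit simplex settings, as in [fit_haldane()].
#' @return an object of class `"rlc_fit"` with elements `rETR_max`,
#'   `alpha`, `E_k`, `data`, `fitted`, `residuals`, `rss`, `convergence`.
#' @examples
#' p <- c(0, 50, 100, 250, 500, 750, 1000)
#' y <- 60 * (1 - exp(-0.3 * p / 60))
#' coef(fit_rlc(p, y))
#' @export
fit_rlc <- function(PAR, rETR = NULL, include_zero = TRUE, weights = NULL,
                    reltol = 1e-8, maxit = 5000) {
  if (inherits(PAR, "pam_trace")) {
    pts <- rlc_points(PAR)
    PAR <- pts$PAR; rETR <- pts$rETR
  }
  stopifnot(length(PAR) == length(rETR))
  keep <- is.finite(PAR) & is.finite(rETR)
  if (!include_zero) keep <- keep & PAR > 0
  PAR <- PAR[keep]; rETR <- rETR[keep]
  w <- if (is.null(weights)) rep(1, length(PAR)) else weights[keep]
  if (sum(PAR > 0) < 3L)
    stop("need at least 3 points with PAR > 0 to fit the light curve",
         call. = FALSE)
  pos <- which(PAR > 0)
  rmax0 <- max(rETR[pos])
  a0 <- rETR[pos[1]] / PAR[pos[1]]
  if (!is.finite(a0) || a0 <= 0) a0 <- rmax0 / stats::median(PAR[pos])
  model <- function(p, par) p[1] * (1 - exp(-p[2] * par / p[1]))
  obj <- function(lp) sum(w * (rETR - model(exp(lp), PAR))^2)
  ctl <- list(reltol = reltol, maxit = maxit)
  opt <- stats::optim(log(c(rmax0, a0)), obj, method = "Nelder-Mead",
                      control = ctl)
  opt2 <- stats::optim(opt$par, obj, method = "Nelder-Mead", control = ctl)
  if (opt2$value <= opt$value) opt <- opt2
  if (opt$convergence != 0)
    warning("Nelder-Mead did not converge within 'maxit' iterations",
            call. = FALSE)
  p <- exp(opt$par)
  fitted <- model(p, PAR)
  structure(
    list(rETR_max = p[1], alpha = p[2], E_k = p[1] / p[2],
         data = data.frame(PAR = PAR, rETR = rETR),
         fitted = fitted, residuals = rETR - fitted,
         rss = opt$value, convergence = opt$convergence == 0),
    class = "rlc_fit"
  )
}

#' @export
coef.rlc_fit <- function(object, ...) {
  c(rETR_max = object$rETR_max, alpha = object$alpha, E_k = object$E_k)
}

#' @export
print.rlc_fit <- function(x, ...) {
  cat("Rapid light curve fit (rectangular hyperbola)\n")
  cat(sprintf(
    "  rETR_max = %.4g, alpha = %.4g, E_k = rETR_max/alpha = %.4g umol m^-2 s^-1\n",
    x$rETR_max, x$alpha, x$E_k))
  cat(sprintf("  n = %d, RSS = %.4g, converged: %s\n",
              nrow(x$data), x$rss, x$convergence))
  invisible(x)
}

#' @export
predict.rlc_fit <- function(object, newdata = NULL, ...) {
  par <- if (is.null(newdata)) object$data$PAR
         else if (is.data.frame(newdata)) newdata$PAR
         else newdata
  object$rETR_max * (1 - exp(-object$alpha * par / object$rETR_max))
}

#' @export
residuals.rlc_fit <- function(object, ...) object$residuals

#' @export
plot.rlc_fit <- function(x, n_grid = 200, ...) {
  grid <- seq(0, max(x$data$PAR) * 1.05, length.out = n_grid)
  plot(x$data$PAR, x$data$rETR,
       xlab = "PAR (umol m^-2 s^-1)", ylab = "rETR", ...)
  graphics::lines(grid, predict(x, grid))
  graphics::abline(v = x$E_k, lty = 3)
  invisible(x)
}
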