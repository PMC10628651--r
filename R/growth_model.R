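#' Haldane growth-irradiance parameters
#'
#' Parameter set of the Haldane (substrate-inhibition) model of gross
#' growth rate versus irradiance:
#' \deqn{\mu_L(I) = \frac{\mu_{max} I}{I + \frac{\mu_{max}}{\alpha}
#'   \left(\frac{I}{I_{opt}} - 1\right)^2}}
#' where `mu_max` is the maximal gross growth rate reached at the optimal
#' PPFD `I_opt`, and `alpha` is the initial slope of the curve (growth rate
#' gained per unit PPFD at low light).
#'
#' @param mu_max maximal gross growth rate, d^-1 (> 0).
#' @param alpha initial slope, d^-1 per umol m^-2 s^-1 (> 0).
#' @param I_opt optimal PPFD, umol m^-2 s^-1 (> 0).
#' @return an object of class `"haldane_params"`.
#' @examples
#' p <- haldane_params(mu_max = 1, alpha = 0.01, I_opt = 150)
#' haldane_mu(150, p)  # mu_max
#' haldane_mu(300, p)  # 0.75
#' @export
haldane_params <- function(mu_max, alpha, I_opt) {
  if (any(c(mu_max, alpha, I_opt) <= 0))
    stop("all Haldane parameters must be positive", call. = FALSE)
  structure(list(mu_max = mu_max, alpha = alpha, I_opt = I_opt),
            class = "haldane_params")
}

#' @export
print.haldane_params <- function(x, ...) {
  cat(sprintf(
    "Haldane parameters: mu_max = %.4g d^-1, alpha = %.4g d^-1/PPFD, I_opt = %.4g umol m^-2 s^-1\n",
    x$mu_max, x$alpha, x$I_opt))
  invisible(x)
}

#' Haldane gross growth rate at a given irradiance
#'
#' @param I PPFD, umol m^-2 s^-1 (vectorized, >= 0).
#' @param params a [haldane_params()] object.
#' @return gross light-phase growth rate \eqn{\mu_L(I)}, d^-1.
#' @export
haldane_mu <- function(I, params) {
  stopifnot(inherits(params, "haldane_params"))
  if (any(I < 0)) stop("'I' must be non-negative", call. = FALSE)
  with(params, mu_max * I / (I + (mu_max / alpha) * (I / I_opt - 1)^2))
}

#' Net growth rate under intermittent light (no mitigation)
#'
#' The net specific growth rate predicted when photosynthesis proceeds at
#' the continuous-light Haldane rate of the *peak* irradiance during light
#' phases and respiration runs constantly:
#' \eqn{\mu(I) = \mu_L(I_{peak})\,\epsilon - R}. This is the
#' "no-photoinhibition-mitigation" prediction; measured rates exceeding it
#' indicate mitigation by the light/dark cycling.
#'
#' @param I_peak peak PPFD (vectorized).
#' @param params a [haldane_params()] object.
#' @param epsilon duty cycle in (0, 1].
#' @param R respiration rate, d^-1.
#' @return net specific growth rate, d^-1.
#' @examples
#' p <- haldane_params(1, 0.01, 150)
#' net_growth(300, p, epsilon = 1/3, R = 0.05)  # 0.20
#' @export
net_growth <- function(I_peak, params, epsilon = 1, R = 0) {
  if (any(epsilon <= 0) || any(epsilon > 1))
    stop("'epsilon' must be in (0, 1]", call. = FALSE)
  haldane_mu(I_peak, params) * epsilon - R
}

#' Fit the Haldane growth-irradiance model
#'
#' Least-squares fit of the Haldane model to gross light-phase growth rates
#' measured at several irradiances, using the derivative-free Nelder-Mead
#' simplex. Positivity of the three parameters is enforced by optimizing on
#' the log scale. Initial values follow the conventional heuristic:
#' `mu_max` from the largest observed rate, `I_opt` from its light level,
#' `alpha` from the slope of the two lowest-light points (overridable via
#' `start`).
#'
#' @param I PPFD levels, umol m^-2 s^-1.
#' @param mu_L gross light-phase growth rates at `I`, d^-1. If net rates
#'   were measured under intermittent light, convert first with
#'   [gross_light_rate()].
#' @param start optional [haldane_params()] or named list of starting
#'   values.
#' @param reltol convergence tolerance on parameters and objective
#'   (default 1e-8).
#' @param maxit maximum simplex iterations (default 5000).
#' @return an object of class `"haldane_fit"`: the fitted
#'   [haldane_params()] in `$params`, plus `$data`, `$fitted`,
#'   `$residuals`, `$rss` and `$convergence` (TRUE when the simplex
#'   converged).
#' @examples
#' p <- haldane_params(0.6, 0.008, 130)
#' I <- c(25, 50, 100, 150, 300, 600)
#' fit <- fit_haldane(I, haldane_mu(I, p))
#' coef(fit)
#' @export
fit_haldane <- function(I, mu_L, start = NULL, reltol = 1e-8, maxit = 5000) {
  stopifnot(length(I) == length(mu_L))
  keep <- is.finite(I) & is.finite(mu_L)
  I <- I[keep]; mu_L <- mu_L[keep]
  if (length(unique(I)) < 3L)
    stop("Haldane fit is unidentifiable with fewer than 3 distinct light levels",
         call. = FALSE)
  if (is.null(start)) {
    i_max <- which.max(mu_L)
    mu0 <- max(mu_L[i_max], 1e-6)
    iopt0 <- max(I[i_max], 1e-6)
    ord <- order(I)
    lo <- ord[I[ord] > 0][1:2]
    a0 <- if (length(lo) == 2L && diff(I[lo]) != 0)
      abs(diff(mu_L[lo]) / diff(I[lo])) else mu0 / iopt0
    if (!is.finite(a0) || a0 <= 0) a0 <- mu0 / iopt0
    start <- list(mu_max = mu0, alpha = a0, I_opt = iopt0)
  }
  obj <- function(lp) {
    p <- haldane_params(exp(lp[1]), exp(lp[2]), exp(lp[3]))
    sum((mu_L - haldane_mu(I, p))^2)
  }
  lp0 <- log(c(start$mu_max, start$alpha, start$I_opt))
  ctl <- list(reltol = reltol, maxit = maxit)
  opt <- stats::optim(lp0, obj, method = "Nelder-Mead", control = ctl)
  # restart from the optimum: standard Nelder-Mead polish
  opt2 <- stats::optim(opt$par, obj, method = "Nelder-Mead", control = ctl)
  if (opt2$value <= opt$value) opt <- opt2
  if (opt$convergence != 0)
    warning("Nelder-Mead did not converge within 'maxit' iterations",
            call. = FALSE)
  params <- haldane_params(exp(opt$par[1]), exp(opt$par[2]), exp(opt$par[3]))
  fitted <- haldane_mu(I, params)
  structure(
    list(params = params, data = data.frame(I = I, mu_L = mu_L),
         fitted = fitted, residuals = mu_L - fitted, rss = opt$value,
         convergence = opt$convergence == 0),
    class = "haldane_fit"
  )
}

#' @export
coef.haldane_fit <- function(object, ...) {
  with(object$params, c(mu_max = mu_max, alpha = alpha, I_opt = I_opt))
}

#' @export
print.haldane_fit <- function(x, ...) {
  cat("Haldane growth-irradiance fit (Nelder-Mead least squares)\n")
  print(x$params)
  cat(sprintf("  n = %d, RSS = %.4g, converged: %s\n",
              nrow(x$data), x$rss, x$convergence))
  invisible(x)
}

#' @export
summary.haldane_fit <- function(object, ...) {
  n <- nrow(object$data)
  out <- list(params = coef(object), n = n, rss = object$rss,
              sigma = sqrt(object$rss / max(n - 3, 1)),
              convergence = object$convergence)
  class(out) <- "summary.haldane_fit"
  out
}

#' @export
print.summary.haldane_fit <- function(x, ...) {
  cat("Haldane growth-irradiance fit\n  parameters:\n")
  print(x$params)
  cat(sprintf("  n = %d, RSS = %.4g, residual sd = %.4g, converged: %s\n",
              x$n, x$rss, x$sigma, x$convergence))
  invisible(x)
}

#' @export
predict.haldane_fit <- function(object, newdata = NULL, ...) {
  I <- if (is.null(newdata)) object$data$I
       else if (is.data.frame(newdata)) newdata$I
       else newdata
  haldane_mu(I, object$params)
}

#' @export
residuals.haldane_fit <- function(object, ...) object$residuals

#' @export
plot.haldane_fit <- function(x, n_grid = 200, ...) {
  I <- x$data$I
  grid <- seq(0, max(I) * 1.1, length.out = n_grid)
  plot(I, x$data$mu_L, xlab = "PPFD (umol m^-2 s^-1)",
       ylab = expression(mu[L] ~ (d^-1)), ...)
  graphics::lines(grid, haldane_mu(grid, x$params))
  graphics::abline(v = x$params$I_opt, lty = 3)
  invisible(x)
}

#' @export
simulate.haldane_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  sigma <- sqrt(object$rss / max(nrow(object$data) - 3, 1))
  as.data.frame(replicate(
    nsim, object$fitted + stats::rnorm(length(object$fitted), 0, sigma)))
}

#' Growth yield on the time-averaged light input
#'
#' \eqn{Yield = \mu / (I_{peak}\,\epsilon) = \mu / I_{ave}}: net growth per
#' unit of average light dose.
#'
#' @param mu net specific growth rate, d^-1.
#' @param I_ave time-averaged PPFD (> 0).
#' @return yield, d^-1 umol^-1 m^2 s.
#' @examples
#' growth_yield(0.5, 100)  # 0.005
#' @export
growth_yield <- function(mu, I_ave) {
  if (any(I_ave <= 0)) stop("'I_ave' must be positive", call. = FALSE)
  mu / I_ave
}

#' Rotating-reactor specification
#'
#' Parameters of a revolving biofilm reactor in which a fraction `epsilon`
#' of the total biofilm-carrying surface is illuminated at any instant, so
#' the total-to-footprint area ratio is \eqn{S_T/S_f = 1/\epsilon}.
#'
#' @param epsilon duty cycle in (0, 1].
#' @param rho dry-weight volumetric biomass density, g m^-3
#'   (default 1.40e5).
#' @param h biofilm thickness, m (default 1e-4, i.e. 100 um).
#' @return an object of class `"reactor_spec"` (includes the enforced
#'   `area_ratio` = 1/epsilon).
#' @export
reactor_spec <- function(epsilon, rho = 1.40e5, h = 1e-4) {
  if (epsilon <= 0 || epsilon > 1)
    stop("'epsilon' must be in (0, 1]", call. = FALSE)
  if (rho <= 0 || h <= 0)
    stop("'rho' and 'h' must be positive", call. = FALSE)
  structure(list(epsilon = epsilon, rho = rho, h = h,
                 area_ratio = 1 / epsilon),
            class = "reactor_spec")
}

#' Net footprint productivity of a rotating biofilm system
#'
#' \eqn{P_f = \mu\,(S_T/S_f)\,\rho\,h} with \eqn{S_T/S_f = 1/\epsilon}:
#' the biomass produced per unit ground area and per day, accounting for
#' the fact that a reactor running at duty cycle \eqn{\epsilon} carries
#' \eqn{1/\epsilon} times more biofilm than its illuminated footprint.
#'
#' @param mu net specific growth rate, d^-1 (vectorized).
#' @param spec a [reactor_spec()].
#' @return footprint productivity, g m^-2 d^-1.
#' @examples
#' footprint_productivity(0.5, reactor_spec(1/3))  # 21
#' @export
footprint_productivity <- function(mu, spec) {
  stopifnot(inherits(spec, "reactor_spec"))
  mu * spec$area_ratio * spec$rho * spec$h
}

#' Scan net growth, yield and footprint productivity over regimes
#'
#' Evaluates the intermittent-light predictions (net growth without
#' mitigation, growth yield and footprint productivity) over a grid of
#' (peak PPFD, duty cycle) combinations; optionally joins measured net
#' rates for comparison.
#'
#' @param params a [haldane_params()] object.
#' @param R respiration rate, d^-1.
#' @param I_peak vector of peak PPFD values.
#' @param epsilon vector of duty cycles (crossed with `I_peak`).
#' @param rho,h reactor biomass density (g m^-3) and thickness (m), as in
#'   [reactor_spec()].
#' @param measured optional data.frame with columns `I_peak`, `epsilon`,
#'   `mu` of observed net rates to append (matched by grid row where
#'   present).
#' @return a data.frame with columns `I_peak`, `epsilon`, `I_ave`, `mu_L`,
#'   `mu` (predicted net), `yield`, `P_f` and, when supplied,
#'   `mu_observed`.
#' @export
productivity_scan <- function(params, R, I_peak, epsilon,
                              rho = 1.40e5, h = 1e-4, measured = NULL) {
  stopifnot(inherits(params, "haldane_params"))
  if (length(I_peak) == 0L || length(epsilon) == 0L)
    stop("empty scan grid", call. = FALSE)
  grid <- expand.grid(I_peak = I_peak, epsilon = epsilon,
                      KEEP.OUT.ATTRS = FALSE)
  grid$I_ave <- grid$I_peak * grid$epsilon
  grid$mu_L <- haldane_mu(grid$I_peak, params)
  grid$mu <- grid$mu_L * grid$epsilon - R
  grid$yield <- ifelse(grid$I_ave > 0, grid$mu / grid$I_ave, NA_real_)
  grid$P_f <- vapply(seq_len(nrow(grid)), function(i)
    footprint_productivity(grid$mu[i],
                           reactor_spec(grid$epsilon[i], rho, h)), 0)
  if (!is.null(measured)) {
    key <- paste(grid$I_peak, signif(grid$epsilon, 12))
    mkey <- paste(measured$I_peak, signif(measured$epsilon, 12))
    grid$mu_observed <- measured$mu[match(key, mkey)]
  }
  grid
}

# RNG-state helpers shared by seeded simulators: save/restore .Random.seed
# so seeded calls do not disturb the caller's stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
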