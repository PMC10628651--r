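#' Paired incident/transmitted light time series
#'
#' Container for daily light-transmittance measurements through a biofilm:
#' incident PPFD above the flow-cell (`I_in`) and transmitted PPFD below it
#' (`I_out`), possibly at several positions along the channel.
#'
#' @param times observation times in days, strictly increasing, length >= 2.
#' @param I_in incident PPFD per time point (scalar recycled, or vector).
#' @param I_out transmitted PPFD: a vector (one position) or a matrix with
#'   one column per position.
#' @param regime_label optional character tag.
#' @return an object of class `"transmittance_series"`.
#' @export
transmittance_series <- function(times, I_in, I_out, regime_label = "") {
  times <- as.numeric(times)
  if (length(times) < 2L) stop("need at least two time points", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly increasing", call. = FALSE)
  I_out <- as.matrix(I_out)
  if (nrow(I_out) != length(times))
    stop("'I_out' must have one row per time point", call. = FALSE)
  I_in <- rep_len(as.numeric(I_in), length(times))
  if (any(I_in <= 0)) stop("'I_in' must be positive", call. = FALSE)
  if (any(I_out < 0)) stop("'I_out' must be non-negative", call. = FALSE)
  structure(
    list(times = times, I_in = I_in, I_out = I_out,
         regime_label = regime_label),
    class = "transmittance_series"
  )
}

#' @export
print.transmittance_series <- function(x, ...) {
  cat(sprintf("Transmittance series '%s': %d time points, %d position(s)\n",
              x$regime_label, length(x$times), ncol(x$I_out)))
  cat(sprintf("  t = %.3g .. %.3g d; final attenuation %.1f%%\n",
              min(x$times), max(x$times),
              attenuation(x$I_in[length(x$I_in)],
                          x$I_out[nrow(x$I_out), ])))
  invisible(x)
}

#' Light attenuation by the biofilm
#'
#' Percent of incident light removed by the biofilm:
#' \eqn{(I_{in} - I_{out})/I_{in} \times 100}. When `I_out` holds several
#' positions (vector or matrix columns) they are averaged first.
#'
#' @param I_in incident PPFD (scalar or vector over time).
#' @param I_out transmitted PPFD; a vector of positions for scalar `I_in`,
#'   or a matrix (time x position) for vector `I_in`.
#' @return attenuation in percent.
#' @examples
#' attenuation(100, 50)            # 50
#' attenuation(106, 10.6)          # 90
#' @export
attenuation <- function(I_in, I_out) {
  if (any(I_in <= 0)) stop("'I_in' must be positive", call. = FALSE)
  if (any(I_out < 0)) stop("'I_out' must be non-negative", call. = FALSE)
  if (length(I_in) == 1L) {
    out <- mean(I_out)
  } else {
    I_out <- as.matrix(I_out)
    stopifnot(nrow(I_out) == length(I_in))
    out <- rowMeans(I_out)
  }
  (I_in - out) / I_in * 100
}

#' Lambert-Beer biomass proxy: ln(ln(I_in/I_out))
#'
#' Under the Lambert-Beer law \eqn{I_{out} = I_{in} e^{-kX}}, the quantity
#' \eqn{\ln\ln(I_{in}/I_{out}) = \ln(kX)} is linear in time during
#' exponential growth with slope equal to the net specific growth rate,
#' independently of the extinction coefficient k. Positions are averaged on
#' `I_out` before the transform. Points where `I_out >= I_in` (no
#' attenuation, e.g. a clean cell) leave the double log undefined; they are
#' excluded with a warning and marked `usable = FALSE`.
#'
#' @param series a [transmittance_series()].
#' @return a data.frame with columns `time`, `proxy` (`NA` where
#'   undefined) and `usable`.
#' @export
biomass_proxy <- function(series) {
  stopifnot(inherits(series, "transmittance_series"))
  out <- rowMeans(series$I_out)
  ratio <- series$I_in / out
  usable <- is.finite(ratio) & ratio > 1
  if (any(!usable))
    warning(sprintf(
      "%d point(s) with I_out >= I_in excluded from the biomass proxy",
      sum(!usable)), call. = FALSE)
  proxy <- rep(NA_real_, length(ratio))
  proxy[usable] <- log(log(ratio[usable]))
  data.frame(time = series$times, proxy = proxy, usable = usable)
}

#' Net specific growth rate from light transmittance
#'
#' Fits the Lambert-Beer double-log proxy \eqn{\ln\ln(I_{in}/I_{out})}
#' against time by ordinary least squares over every contiguous window of
#' at least `min_points` usable observations and returns the window with the
#' maximum slope; that slope is the net specific growth rate \eqn{\mu}
#' (d^-1). Ties on slope are broken in favour of the longer window, then
#' the earlier start.
#'
#' @param series a [transmittance_series()] with times in days.
#' @param min_points minimum regression window length (default 4).
#' @param per_position if `TRUE`, additionally estimate a rate per sensor
#'   position (for dispersion assessment).
#' @return an object of class `"growth_fit"`: list with `mu` (d^-1),
#'   `window` (start/end indices into the usable-point set), `r_squared`,
#'   `n_points`, `proxy` (the transformed data) and, optionally,
#'   `per_position` rates.
#' @examples
#' t <- 0:9
#' Iout <- 300 * exp(-0.2 * exp(0.5 * t))
#' fit <- fit_growth_rate(transmittance_series(t, 300, Iout))
#' coef(fit)  # mu = 0.5
#' @export
fit_growth_rate <- function(series, min_points = 4, per_position = FALSE) {
  stopifnot(inherits(series, "transmittance_series"))
  pr <- biomass_proxy(series)
  best <- .max_slope_window(pr$time[pr$usable], pr$proxy[pr$usable],
                            min_points)
  pp <- NULL
  if (per_position && ncol(series$I_out) > 1L) {
    pp <- apply(series$I_out, 2L, function(col) {
      ratio <- series$I_in / col
      ok <- is.finite(ratio) & ratio > 1
      if (sum(ok) < min_points) return(NA_real_)
      .max_slope_window(series$times[ok], log(log(ratio[ok])),
                        min_points)$slope
    })
  }
  structure(
    list(mu = best$slope, window = c(start = best$start, end = best$end),
         r_squared = best$r2, n_points = best$n, proxy = pr,
         per_position = pp, regime_label = series$regime_label),
    class = "growth_fit"
  )
}

# Max-slope contiguous-window OLS scan. x strictly increasing.
.max_slope_window <- function(x, y, min_points) {
  n <- length(x)
  if (n < min_points)
    stop(sprintf("insufficient points: %d usable, %d required",
                 n, min_points), call. = FALSE)
  best <- NULL
  for (len in min_points:n) {
    for (s in 1:(n - len + 1L)) {
      e <- s + len - 1L
      xi <- x[s:e]; yi <- y[s:e]
      sxx <- sum((xi - mean(xi))^2)
      if (sxx == 0) next
      slope <- sum((xi - mean(xi)) * (yi - mean(yi))) / sxx
      ssy <- sum((yi - mean(yi))^2)
      r2 <- if (ssy == 0) 1 else slope^2 * sxx / ssy
      # ties: prefer larger window, then earlier start; iterate in an order
      # where later candidates win only on strictly larger slope
      if (is.null(best) || slope > best$slope ||
          (slope == best$slope && (len > best$n ||
                                   (len == best$n && s < best$start)))) {
        best <- list(slope = slope, start = s, end = e, n = len, r2 = r2)
      }
    }
  }
  best
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Transmittance growth-rate estimate")
  if (nzchar(x$regime_label)) cat(" [", x$regime_label, "]", sep = "")
  cat("\n")
  cat(sprintf("  mu = %.4g d^-1 (window %d..%d, n = %d, R^2 = %.3f)\n",
              x$mu, x$window["start"], x$window["end"],
              x$n_points, x$r_squared))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) c(mu = object$mu)

#' @export
plot.growth_fit <- function(x, ...) {
  ok <- x$proxy$usable
  plot(x$proxy$time[ok], x$proxy$proxy[ok],
       xlab = "time (d)", ylab = "ln(ln(I_in/I_out))", ...)
  tt <- x$proxy$time[ok][x$window["start"]:x$window["end"]]
  yy <- x$proxy$proxy[ok][x$window["start"]:x$window["end"]]
  fit <- stats::lm(yy ~ tt)
  graphics::abline(fit, lty = 2)
  invisible(x)
}

#' Gross growth rate during light phases
#'
#' Converts a net specific growth rate into the gross rate sustained during
#' the light phase of an intermittent regime, assuming respiration at a
#' constant rate R in light and darkness:
#' \eqn{\mu_L = (\mu + R)/\epsilon}. This is the algebraic inverse of the
#' intermittent-light net-growth relation
#' \eqn{\mu = \mu_L \epsilon - R} (see [net_growth()]).
#'
#' @param mu net specific growth rate, d^-1.
#' @param R respiration rate, d^-1 (>= 0).
#' @param epsilon duty cycle in (0, 1].
#' @return gross light-phase growth rate, d^-1.
#' @examples
#' gross_light_rate(0.2, 0.1, 1/3)  # 0.9
#' @export
gross_light_rate <- function(mu, R, epsilon) {
  if (any(epsilon <= 0) || any(epsilon > 1))
    stop("'epsilon' must be in (0, 1]", call. = FALSE)
  if (any(R < 0)) stop("'R' must be non-negative", call. = FALSE)
  (mu + R) / epsilon
}
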