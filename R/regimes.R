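#' Square-wave light/dark illumination program
#'
#' Constructs a light regime: a periodic square wave that delivers a peak
#' photosynthetic photon flux density (PPFD) `I_peak` for `T_L` seconds
#' followed by `T_D` seconds of darkness. Derived quantities are the duty
#' cycle (light fraction) \eqn{\epsilon = T_L/(T_L+T_D)}, the cycle time
#' \eqn{T = T_L + T_D} and the time-averaged PPFD
#' \eqn{I_{ave} = I_{peak}\,\epsilon}. Continuous light is the special case
#' `T_D = 0` (\eqn{\epsilon = 1}).
#'
#' @param label character tag for the regime (e.g. `"300-5s-0-10s"`).
#' @param I_peak peak PPFD during the light phase, umol m^-2 s^-1.
#' @param T_L light-phase duration, seconds. Must be positive.
#' @param T_D dark-phase duration, seconds. Zero means continuous light.
#'
#' @return An object of class `"light_regime"`: a list with fields
#'   `label`, `I_peak`, `T_L`, `T_D`, `epsilon`, `period` and `I_ave`.
#' @examples
#' r <- light_regime("300-5s-0-10s", I_peak = 310, T_L = 5, T_D = 10)
#' r$epsilon   # 1/3
#' r$I_ave     # 103.33
#' @export
light_regime <- function(label, I_peak, T_L, T_D = 0) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!is.numeric(I_peak) || length(I_peak) != 1L || I_peak < 0)
    stop("'I_peak' must be a single non-negative PPFD", call. = FALSE)
  if (!is.numeric(T_L) || length(T_L) != 1L || T_L <= 0)
    stop("'T_L' must be a single positive duration (s)", call. = FALSE)
  if (!is.numeric(T_D) || length(T_D) != 1L || T_D < 0)
    stop("'T_D' must be a single non-negative duration (s)", call. = FALSE)
  period <- T_L + T_D
  epsilon <- T_L / period
  structure(
    list(label = label, I_peak = I_peak, T_L = T_L, T_D = T_D,
         epsilon = epsilon, period = period, I_ave = I_peak * epsilon),
    class = "light_regime"
  )
}

#' @export
print.light_regime <- function(x, ...) {
  cat("Light regime:", x$label, "\n")
  if (x$T_D == 0) {
    cat(sprintf("  continuous light at %.4g umol m^-2 s^-1\n", x$I_peak))
  } else {
    cat(sprintf("  peak %.4g umol m^-2 s^-1, L/D %g s / %g s (T = %g s)\n",
                x$I_peak, x$T_L, x$T_D, x$period))
    cat(sprintf("  duty cycle epsilon = %.4g; average PPFD = %.4g (~%d)\n",
                x$epsilon, x$I_ave, round(x$I_ave)))
  }
  invisible(x)
}

#' Time-averaged PPFD of a light regime
#'
#' The light dose received per unit time over one full cycle,
#' \eqn{I_{ave} = I_{peak} T_L / (T_L + T_D)}.
#'
#' @param regime a [light_regime()].
#' @return average PPFD, umol m^-2 s^-1.
#' @examples
#' average_ppfd(light_regime("demo", 310, 5, 10))  # 103.33
#' @export
average_ppfd <- function(regime) {
  stopifnot(inherits(regime, "light_regime"))
  regime$I_peak * regime$T_L / (regime$T_L + regime$T_D)
}

#' Instantaneous PPFD of a square-wave regime
#'
#' Evaluates the square wave at times `t` (seconds). Cycles start with the
#' light phase at `t = 0`; the signal is periodic with period
#' `T_L + T_D`.
#'
#' @param regime a [light_regime()].
#' @param t numeric vector of times in seconds, all non-negative.
#' @return PPFD at each `t`.
#' @examples
#' waveform(light_regime("demo", 310, 5, 10), c(2, 7))  # 310, 0
#' @export
waveform <- function(regime, t) {
  stopifnot(inherits(regime, "light_regime"))
  if (any(t < 0)) stop("times must be non-negative", call. = FALSE)
  ifelse((t %% regime$period) < regime$T_L, regime$I_peak, 0)
}

#' The five reference illumination programs
#'
#' The standard flow-cell experiment set: continuous light at ~100
#' umol m^-2 s^-1 and four intermittent regimes with cycle times from 15 s
#' to 3 min, all delivering an average PPFD of ~100 umol m^-2 s^-1
#' (duty cycles 1/3 and 1/5 at peaks of ~300 and ~500).
#'
#' @return a named list of [light_regime()] objects.
#' @export
default_regimes <- function() {
  regs <- list(
    light_regime("100 cont",        106, T_L = 1,  T_D = 0),
    light_regime("300-5s-0-10s",    310, T_L = 5,  T_D = 10),
    light_regime("300-30s-0-60s",   310, T_L = 30, T_D = 60),
    light_regime("300-1min-0-2min", 310, T_L = 60, T_D = 120),
    light_regime("500-5s-0-20s",    496, T_L = 5,  T_D = 20)
  )
  names(regs) <- vapply(regs, `[[`, "", "label")
  regs
}

#' Tabulate derived photometric quantities for a set of regimes
#'
#' @param regimes a list of [light_regime()] objects
#'   (default [default_regimes()]).
#' @return a data.frame with one row per regime: label, peak PPFD, duty
#'   cycle, cycle time (s), exact average PPFD and the average rounded to
#'   the nearest integer (display convention).
#' @export
describe_regimes <- function(regimes = default_regimes()) {
  stopifnot(all(vapply(regimes, inherits, TRUE, "light_regime")))
  data.frame(
    label     = vapply(regimes, `[[`, "", "label"),
    I_peak    = vapply(regimes, `[[`, 0, "I_peak"),
    epsilon   = vapply(regimes, `[[`, 0, "epsilon"),
    period_s  = vapply(regimes, `[[`, 0, "period"),
    I_ave     = vapply(regimes, `[[`, 0, "I_ave"),
    I_ave_int = round(vapply(regimes, `[[`, 0, "I_ave")),
    row.names = NULL
  )
}

#' Rectangular flow-cell channel
#'
#' Geometry and operating conditions of a millifluidic flow-cell channel.
#' Fluid defaults are water near room temperature.
#'
#' @param length,width,height channel dimensions, mm.
#' @param flow_rate volumetric medium flow, mL min^-1.
#' @param fluid_density kg m^-3 (default 1000).
#' @param fluid_viscosity mPa s (default 1.0).
#' @return an object of class `"flow_cell"`.
#' @examples
#' fc <- flow_cell(length = 40, width = 6, height = 3, flow_rate = 0.1)
#' mean_velocity(fc)  # ~0.093 mm/s
#' reynolds(fc)       # ~0.37
#' @export
flow_cell <- function(length, width, height, flow_rate,
                      fluid_density = 1000, fluid_viscosity = 1.0) {
  if (any(c(length, width, height) <= 0))
    stop("all channel dimensions must be positive", call. = FALSE)
  if (flow_rate < 0) stop("'flow_rate' must be non-negative", call. = FALSE)
  if (fluid_viscosity <= 0) stop("'fluid_viscosity' must be positive", call. = FALSE)
  area <- width * height                       # mm^2
  perim <- 2 * (width + height)                # mm
  structure(
    list(length = length, width = width, height = height,
         flow_rate = flow_rate, fluid_density = fluid_density,
         fluid_viscosity = fluid_viscosity,
         area = area, hydraulic_diameter = 4 * area / perim),
    class = "flow_cell"
  )
}

#' @export
print.flow_cell <- function(x, ...) {
  cat(sprintf("Flow-cell channel %g x %g x %g mm, flow %g mL/min\n",
              x$length, x$width, x$height, x$flow_rate))
  cat(sprintf("  mean velocity %.3g mm/s, Re %.3g, wall shear %.3g mPa\n",
              mean_velocity(x), reynolds(x), wall_shear(x)))
  invisible(x)
}

#' Mean flow velocity in the channel
#'
#' Volumetric flow divided by cross-section area.
#'
#' @param fc a [flow_cell()].
#' @return mean velocity, mm s^-1.
#' @export
mean_velocity <- function(fc) {
  stopifnot(inherits(fc, "flow_cell"))
  q_mm3_s <- fc$flow_rate * 1000 / 60          # mL/min -> mm^3/s
  q_mm3_s / fc$area
}

#' Reynolds number of the channel flow
#'
#' \eqn{Re = \rho v D_h / \mu} with the hydraulic diameter
#' \eqn{D_h = 4A/P} of the rectangular duct.
#'
#' @param fc a [flow_cell()].
#' @return dimensionless Reynolds number.
#' @export
reynolds <- function(fc) {
  stopifnot(inherits(fc, "flow_cell"))
  v <- mean_velocity(fc) / 1000                # m/s
  dh <- fc$hydraulic_diameter / 1000           # m
  mu <- fc$fluid_viscosity / 1000              # Pa s
  fc$fluid_density * v * dh / mu
}

#' Wall shear stress (parallel-plate approximation)
#'
#' \eqn{\tau = 6 \mu Q / (w h^2)} for fully developed laminar flow between
#' parallel plates. Note: published flow-cell shear values are sometimes an
#' order of magnitude larger than this formula yields for the same geometry
#' and flow; the approximation used there is rarely stated. This function
#' always reports the standard parallel-plate value.
#'
#' @param fc a [flow_cell()].
#' @return wall shear stress, mPa.
#' @export
wall_shear <- function(fc) {
  stopifnot(inherits(fc, "flow_cell"))
  q <- fc$flow_rate * 1e-6 / 60                # m^3/s
  w <- fc$width / 1000                         # m
  h <- fc$height / 1000                        # m
  mu <- fc$fluid_viscosity / 1000              # Pa s
  tau_pa <- 6 * mu * q / (w * h^2)
  tau_pa * 1000                                # mPa
}
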