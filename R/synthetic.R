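#' Synthetic study scenario configuration
#'
#' Ground truth and noise settings for the synthetic-data generators. The
#' defaults emulate the reference flow-cell experiment: the five standard
#' illumination programs ([default_regimes()]), 15 days of daily sampling,
#' transmitted light read at three positions along the channel, and a
#' Haldane ground truth whose optimum sits at the experiment's ~100
#' umol m^-2 s^-1 average PPFD so that peaks of 300-500 are strongly
#' photoinhibiting.
#'
#' Photoinhibition mitigation by fast cycling is emulated with a
#' light-integration weight \eqn{m = e^{-T/\tau_I}} (cycle time T,
#' integration time scale `tau_I`): the "observed" gross rate is
#' \eqn{m\,\mu_L(I_{ave}) + (1-m)\,\mu_L(I_{peak})}, recovering full light
#' integration for fast cycles and the unmitigated Haldane rate at the
#' peak for slow ones.
#'
#' @param regimes named list of [light_regime()]s.
#' @param params ground-truth [haldane_params()].
#' @param R respiration rate, d^-1.
#' @param k light extinction coefficient, m^2 g^-1.
#' @param X0 initial areal biomass, g m^-2.
#' @param days experiment duration, days (daily sampling).
#' @param n_positions transmitted-light sensor positions per channel.
#' @param sigma_I multiplicative (lognormal sdlog) noise on transmitted
#'   light.
#' @param sigma_pam additive Gaussian noise on PAM quantum yields.
#' @param jitter_um lateral thickness jitter for layered stacks, um.
#' @param tau_I light-integration time scale, seconds.
#' @return an object of class `"scenario_config"`.
#' @export
scenario_config <- function(regimes = default_regimes(),
                            params = haldane_params(mu_max = 0.55,
                                                    alpha = 0.005,
                                                    I_opt = 100),
                            R = 0.05, k = 0.15, X0 = 1, days = 15,
                            n_positions = 3, sigma_I = 0.02,
                            sigma_pam = 0.01, jitter_um = 2,
                            tau_I = 60) {
  stopifnot(inherits(params, "haldane_params"),
            all(vapply(regimes, inherits, TRUE, "light_regime")))
  if (any(c(R, sigma_I, sigma_pam, jitter_um) < 0) ||
      any(c(k, X0, days, n_positions, tau_I) <= 0))
    stop("invalid scenario parameter", call. = FALSE)
  structure(list(regimes = regimes, params = params, R = R, k = k,
                 X0 = X0, days = days, n_positions = n_positions,
                 sigma_I = sigma_I, sigma_pam = sigma_pam,
                 jitter_um = jitter_um, tau_I = tau_I),
            class = "scenario_config")
}

#' Ground-truth net growth rate of a regime under a scenario
#'
#' With `mitigated = FALSE` this is the plain intermittent-light
#' prediction \eqn{\mu_L(I_{peak})\epsilon - R}; with `mitigated = TRUE`
#' the gross rate is the light-integration blend described in
#' [scenario_config()].
#'
#' @param cfg a [scenario_config()].
#' @param regime a [light_regime()].
#' @param mitigated emulate photoinhibition mitigation by fast cycling.
#' @return net specific growth rate, d^-1.
#' @export
scenario_mu <- function(cfg, regime, mitigated = FALSE) {
  stopifnot(inherits(cfg, "scenario_config"),
            inherits(regime, "light_regime"))
  if (!mitigated || regime$T_D == 0)
    return(net_growth(regime$I_peak, cfg$params, regime$epsilon, cfg$R))
  m <- exp(-regime$period / cfg$tau_I)
  mu_L <- m * haldane_mu(regime$I_ave, cfg$params) +
    (1 - m) * haldane_mu(regime$I_peak, cfg$params)
  mu_L * regime$epsilon - cfg$R
}

#' Simulate a daily biomass trajectory
#'
#' Net exponential growth \eqn{X(t) = X_0 e^{\mu t}} at the scenario's
#' ground-truth net rate for the regime.
#'
#' @param cfg a [scenario_config()].
#' @param regime a [light_regime()].
#' @param days duration (default `cfg$days`); sampling is daily from 0.
#' @param mitigated passed to [scenario_mu()].
#' @return data.frame with `time_d`, `X` (g m^-2) and attribute `"mu"`
#'   (the generating rate).
#' @export
gen_growth_trajectory <- function(cfg, regime, days = cfg$days,
                                  mitigated = FALSE) {
  if (days < 2) stop("'days' must be at least 2", call. = FALSE)
  mu <- scenario_mu(cfg, regime, mitigated)
  t <- seq(0, days - 1)
  structure(data.frame(time_d = t, X = cfg$X0 * exp(mu * t)), mu = mu)
}

#' Simulate a transmittance series from a biomass trajectory
#'
#' Lambert-Beer forward model with multiplicative lognormal sensor noise:
#' \eqn{I_{out} = I_{in} e^{-kX} \eta}, \eqn{\log\eta \sim N(0,
#' \sigma_I)}, independently per sensor position. The incident reading is
#' the regime's peak PPFD.
#'
#' @param cfg a [scenario_config()].
#' @param trajectory output of [gen_growth_trajectory()].
#' @param regime the [light_regime()] the trajectory was generated under.
#' @param seed integer seed (mandatory when `cfg$sigma_I > 0`).
#' @return a [transmittance_series()].
#' @export
gen_transmittance <- function(cfg, trajectory, regime, seed = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (cfg$sigma_I > 0 && is.null(seed))
    stop("a seed is required for noisy transmittance", call. = FALSE)
  n <- nrow(trajectory)
  clean <- regime$I_peak * exp(-cfg$k * trajectory$X)
  I_out <- matrix(rep(clean, cfg$n_positions), n, cfg$n_positions)
  if (cfg$sigma_I > 0) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
    I_out <- I_out * exp(matrix(stats::rnorm(n * cfg$n_positions, 0,
                                             cfg$sigma_I),
                                n, cfg$n_positions))
  }
  transmittance_series(trajectory$time_d, regime$I_peak, I_out,
                       regime$label)
}

#' Simulate a PAM rapid-light-curve trace
#'
#' Seven actinic steps from 0 to 1000 umol m^-2 s^-1 (the standard
#' protocol). Effective yields are implied by the rectangular hyperbola at
#' the given parameters, perturbed by truncated Gaussian noise, and
#' converted back to (F, Fm') pairs with an Fm' that declines with PAR.
#' Fv/Fm is drawn uniformly in the healthy 0.7-0.8 range.
#'
#' @param cfg a [scenario_config()].
#' @param rETR_max,alpha ground-truth light-curve parameters.
#' @param seed integer seed (mandatory when `cfg$sigma_pam > 0`).
#' @return a [pam_trace()] with attribute `"truth"` holding the
#'   generating parameters.
#' @export
gen_pam_trace <- function(cfg, rETR_max, alpha, seed = NULL) {
  stopifnot(inherits(cfg, "scenario_config"),
            rETR_max > 0, alpha > 0)
  if (cfg$sigma_pam > 0 && is.null(seed))
    stop("a seed is required for noisy PAM traces", call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(if (is.null(seed)) 0L else seed)
  PAR <- c(0, 50, 100, 250, 500, 750, 1000)
  phi0 <- stats::runif(1, 0.7, 0.8)              # Fv/Fm, healthy range
  r <- rETR_max * (1 - exp(-alpha * PAR / rETR_max))
  yield <- ifelse(PAR > 0, r / (0.5 * PAR), phi0)
  if (cfg$sigma_pam > 0)
    yield <- pmin(pmax(yield + stats::rnorm(length(PAR), 0, cfg$sigma_pam),
                       0), 0.85)
  Fm <- 1
  F0 <- Fm * (1 - phi0)
  Fm_prime <- Fm * (1 - 0.3 * PAR / max(PAR))    # NPQ-like decline
  F <- Fm_prime * (1 - yield)
  pam_trace(F0, Fm,
            data.frame(PAR = PAR, F = F, Fm_prime = Fm_prime)) |>
    structure(truth = c(rETR_max = rETR_max, alpha = alpha,
                        fv_fm = phi0))
}

#' Simulate a binary biofilm stack
#'
#' Two contrasting morphologies at a matched biovolume target:
#' \describe{
#'   \item{layered}{a uniform slab; per-column height is the target
#'     thickness plus Gaussian jitter (`cfg$jitter_um`).}
#'   \item{clustered}{a few hemispherical colonies seeded at random (x, y)
#'     positions on the substratum, radii chosen so the total colony
#'     volume matches the same biovolume target.}
#' }
#'
#' @param cfg a [scenario_config()].
#' @param mode `"layered"` or `"clustered"`.
#' @param target_biovolume target biovolume, um^3 um^-2.
#' @param nx,ny,nz grid dimensions (defaults sized for desk-scale demos).
#' @param voxel_xy,voxel_z voxel dimensions, um (defaults match the
#'   reference confocal setting).
#' @param n_colonies number of colonies in clustered mode.
#' @param seed integer seed (mandatory; placement and jitter are random).
#' @return a [biofilm_stack()].
#' @export
gen_stack <- function(cfg, mode = c("layered", "clustered"),
                      target_biovolume = 10, nx = 64, ny = 64, nz = 16,
                      voxel_xy = 1.25, voxel_z = 3.94, n_colonies = 4,
                      seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(cfg, "scenario_config"), target_biovolume >= 0)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  v <- array(0L, c(nx, ny, nz))
  if (mode == "layered") {
    h <- target_biovolume +
      stats::rnorm(nx * ny, 0, cfg$jitter_um)       # um per column
    n_sl <- pmin(pmax(round(h / voxel_z), 0L), nz)
    n_sl <- matrix(n_sl, nx, ny)
    for (z in seq_len(nz)) v[, , z] <- (n_sl >= z) + 0L
  } else {
    # hemisphere volume (2/3) pi r^3 per colony; match total volume
    total_um3 <- target_biovolume * nx * ny * voxel_xy^2
    r_um <- (3 * total_um3 / (2 * pi * n_colonies))^(1 / 3)
    cx <- stats::runif(n_colonies, 1, nx)
    cy <- stats::runif(n_colonies, 1, ny)
    xs <- (seq_len(nx) - 0.5) * voxel_xy
    ys <- (seq_len(ny) - 0.5) * voxel_xy
    zs <- (seq_len(nz) - 0.5) * voxel_z
    for (i in seq_len(n_colonies)) {
      dx2 <- (xs - cx[i] * voxel_xy)^2
      dy2 <- (ys - cy[i] * voxel_xy)^2
      for (z in seq_len(nz)) {
        d2 <- outer(dx2, dy2, `+`) + zs[z]^2
        v[, , z] <- v[, , z] | (d2 <= r_um^2)
      }
    }
    mode(v) <- "integer"
  }
  biofilm_stack(v, voxel_xy, voxel_z)
}

#' Simulate a binary cell-mask micrograph
#'
#' Places non-overlapping rasterized disks with lognormal-ish radius
#' variation by rejection sampling. Ground-truth centers, radii and exact
#' disk areas are attached as attribute `"truth"`.
#'
#' @param cfg a [scenario_config()].
#' @param n_cells number of disks requested (>= 0). If the packing is
#'   infeasible, fewer are placed with a warning.
#' @param radius_mean,radius_sd disk radius distribution, um (Gaussian,
#'   truncated at 1 px).
#' @param dim_px image edge, pixels (square image).
#' @param pixel_size um per pixel.
#' @param seed integer seed (mandatory).
#' @param max_tries rejection-sampling budget per remaining cell.
#' @return a [cell_mask()] with attribute `"truth"`
#'   (data.frame `x`, `y`, `r_um`, `area_um2`).
#' @export
gen_cell_image <- function(cfg, n_cells, radius_mean = 2, radius_sd = 0.3,
                           dim_px = 256, pixel_size = 0.32, seed = 1,
                           max_tries = 200) {
  stopifnot(inherits(cfg, "scenario_config"), n_cells >= 0)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  img <- matrix(0L, dim_px, dim_px)
  placed <- data.frame(x = numeric(0), y = numeric(0), r_um = numeric(0),
                       area_um2 = numeric(0))
  if (n_cells > 0) {
    xs <- (seq_len(dim_px) - 0.5) * pixel_size
    for (i in seq_len(n_cells)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        r <- max(stats::rnorm(1, radius_mean, radius_sd), pixel_size)
        cx <- stats::runif(1, r, dim_px * pixel_size - r)
        cy <- stats::runif(1, r, dim_px * pixel_size - r)
        # reject overlap (small gap so 8-connected components stay apart)
        if (nrow(placed) == 0 ||
            all(sqrt((placed$x - cx)^2 + (placed$y - cy)^2) >
                placed$r_um + r + 2 * pixel_size)) {
          ok <- TRUE; break
        }
      }
      if (!ok) {
        warning(sprintf("packing infeasible: placed %d of %d cells",
                        nrow(placed), n_cells), call. = FALSE)
        break
      }
      d2 <- outer((xs - cx)^2, (xs - cy)^2, `+`)
      img[d2 <= r^2] <- 1L
      placed <- rbind(placed,
                      data.frame(x = cx, y = cy, r_um = r,
                                 area_um2 = pi * r^2))
    }
  }
  structure(cell_mask(img, pixel_size), truth = placed)
}
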