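# Independent brute-force oracles used across test files.

# Time-average of a square wave by midpoint sampling over k whole periods;
# dt must divide both phase durations so the mean is exact.
midpoint_mean <- function(regime, k = 3, dt = 0.25) {
  t <- seq(dt / 2, k * regime$period - dt / 2, by = dt)
  mean(waveform(regime, t))
}

# Direct voxel-count biovolume, bypassing the package accessor internals.
brute_biovolume <- function(arr, voxel_xy, voxel_z) {
  sum(arr != 0) * voxel_xy^2 * voxel_z / (dim(arr)[1] * dim(arr)[2] * voxel_xy^2)
}

# Column-top thickness by explicit per-column scan.
brute_thickness <- function(arr, voxel_z) {
  apply(arr, c(1, 2), function(col) {
    occ <- which(col != 0)
    if (length(occ) == 0) 0 else max(occ) * voxel_z
  })
}

# COMSTAT roughness coefficient from a thickness vector.
brute_roughness <- function(L) mean(abs(L - mean(L))) / mean(L)

# A stack with prescribed per-column slice counts (nx x ny matrix).
stack_from_heights <- function(n_slices, nz, voxel_xy = 1, voxel_z = 1) {
  nx <- nrow(n_slices); ny <- ncol(n_slices)
  v <- array(0L, c(nx, ny, nz))
  for (z in seq_len(nz)) v[, , z] <- (n_slices >= z) + 0L
  biofilm_stack(v, voxel_xy, voxel_z)
}

# Noiseless Lambert-Beer series from exponential growth.
beer_lambert_series <- function(mu, k = 0.2, X0 = 1, I_in = 300,
                                days = 0:14, label = "synthetic") {
  transmittance_series(days, I_in, I_in * exp(-k * X0 * exp(mu * days)),
                       label)
}
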