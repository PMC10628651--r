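#' Binary 3D biofilm stack
#'
#' A confocal z-stack reduced to a binary voxel grid. Dimension order is
#' (x, y, z) with slice `z = 1` at the substratum and slices counting
#' upward. Default voxel dimensions follow the common confocal setting of
#' 1.25 um lateral pixels and 3.94 um z-steps.
#'
#' @param voxels logical or 0/1 3D array, dim = (nx, ny, nz).
#' @param voxel_xy lateral voxel edge, um (> 0).
#' @param voxel_z axial voxel edge (z-step), um (> 0).
#' @return an object of class `"biofilm_stack"`.
#' @export
biofilm_stack <- function(voxels, voxel_xy = 1.25, voxel_z = 3.94) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  if (voxel_xy <= 0 || voxel_z <= 0)
    stop("voxel dimensions must be positive", call. = FALSE)
  mode(voxels) <- "integer"
  if (any(!voxels %in% c(0L, 1L)))
    stop("'voxels' must be binary (0/1)", call. = FALSE)
  structure(list(voxels = voxels, voxel_xy = voxel_xy, voxel_z = voxel_z),
            class = "biofilm_stack")
}

#' @export
print.biofilm_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "Biofilm stack %d x %d x %d voxels (%.3g um xy, %.3g um z)\n",
    d[1], d[2], d[3], x$voxel_xy, x$voxel_z))
  cat(sprintf("  biovolume %.3g um^3/um^2, max thickness %.3g um\n",
              biovolume(x), max(thickness_map(x))))
  invisible(x)
}

#' Read a binary stack from a multi-page TIFF
#'
#' One page per z-slice, first page at the substratum; nonzero pixels
#' become foreground.
#'
#' @param path TIFF file path.
#' @param voxel_xy,voxel_z voxel dimensions, um.
#' @return a [biofilm_stack()].
#' @export
read_stack <- function(path, voxel_xy = 1.25, voxel_z = 3.94) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- vapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]
    (p > 0) + 0L
  }, matrix(0L, nrow(pages[[1]]), ncol(pages[[1]])))
  biofilm_stack(arr, voxel_xy, voxel_z)
}

#' Biovolume per substratum area
#'
#' Total foreground volume divided by the substratum area imaged:
#' occupied voxels x voxel volume / (nx ny voxel_xy^2), in um^3 um^-2.
#' Numerically equal to mean column thickness only for void-free
#' solid-from-substratum columns.
#'
#' @param stack a [biofilm_stack()].
#' @return biovolume, um^3 um^-2.
#' @export
biovolume <- function(stack) {
  stopifnot(inherits(stack, "biofilm_stack"))
  sum(stack$voxels) * stack$voxel_z / prod(dim(stack$voxels)[1:2])
}

#' Per-column biofilm thickness map
#'
#' For each (x, y) column, the height of the highest occupied voxel
#' (counted from the substratum, internal voids included):
#' `(index of highest occupied slice) * voxel_z`; 0 for empty columns.
#'
#' @param stack a [biofilm_stack()].
#' @return numeric matrix (nx x ny) of thicknesses, um.
#' @export
thickness_map <- function(stack) {
  stopifnot(inherits(stack, "biofilm_stack"))
  v <- stack$voxels
  nz <- dim(v)[3]
  top <- matrix(0L, dim(v)[1], dim(v)[2])
  for (z in seq_len(nz)) {
    occ <- v[, , z] != 0L
    top[occ] <- z
  }
  top * stack$voxel_z
}

#' Roughness coefficient of the biofilm surface
#'
#' The COMSTAT roughness coefficient: the mean absolute relative deviation
#' of column thickness,
#' \deqn{R_a^* = \frac{1}{N} \sum_i \frac{|L_i - \bar L|}{\bar L},}
#' 0 for a perfectly flat film and approaching 2 for maximal heterogeneity
#' (the supremum is \eqn{2(N-1)/N}). By default all columns over the
#' substratum enter the sum, empty columns with L = 0; set
#' `occupied_only = TRUE` to restrict to occupied columns.
#'
#' @param stack a [biofilm_stack()].
#' @param occupied_only drop empty columns from the column set.
#' @return dimensionless roughness in [0, 2).
#' @export
roughness <- function(stack, occupied_only = FALSE) {
  tm <- thickness_map(stack)
  L <- as.vector(tm)
  if (occupied_only) L <- L[L > 0]
  if (length(L) == 0L || all(L == 0))
    stop("roughness undefined: no occupied columns", call. = FALSE)
  Lbar <- mean(L)
  mean(abs(L - Lbar)) / Lbar
}

#' Full structural metric set for one stack
#'
#' @param stack a [biofilm_stack()].
#' @param occupied_only column convention passed to [roughness()].
#' @return a one-row data.frame: `biovolume` (um^3 um^-2),
#'   `mean_thickness`, `max_thickness` (um), `roughness` (A.U.).
#' @export
structure_metrics <- function(stack, occupied_only = FALSE) {
  tm <- thickness_map(stack)
  data.frame(
    biovolume = biovolume(stack),
    mean_thickness = mean(tm),
    max_thickness = max(tm),
    roughness = if (any(tm > 0)) roughness(stack, occupied_only)
                else NA_real_
  )
}

#' Max-thickness-versus-biovolume slope diagnostic
#'
#' Ordinary least-squares slope of maximum thickness against biovolume
#' over early development, with adjusted R^2. A steep slope indicates
#' clustered (vertical colony) growth; a near-zero or negative slope
#' indicates conformal layer-by-layer growth.
#'
#' @param biovolume biovolumes over time (um^3 um^-2), length >= 3, not
#'   constant.
#' @param max_thickness matching maximum thicknesses, um.
#' @return a list with `slope`, `adj_r_squared`, `n` and the underlying
#'   `lm` fit.
#' @export
cluster_slope <- function(biovolume, max_thickness) {
  stopifnot(length(biovolume) == length(max_thickness))
  if (length(biovolume) < 3L)
    stop("need at least 3 time points", call. = FALSE)
  if (stats::var(biovolume) == 0)
    stop("degenerate series: biovolume is constant", call. = FALSE)
  fit <- stats::lm(max_thickness ~ biovolume)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       adj_r_squared = s$adj.r.squared,
       n = length(biovolume), fit = fit)
}

#' Structural metrics for a batch of stacks
#'
#' Computes [structure_metrics()] per stack and position-averaged values
#' (mean and standard deviation) per group, emulating measurement at
#' several positions along a channel.
#'
#' @param stacks a list of [biofilm_stack()] objects.
#' @param group grouping factor (e.g. timepoint), one value per stack;
#'   default puts all stacks in one group.
#' @return a data.frame with one row per stack (`kind = "stack"`) and one
#'   summary row per group (`kind = "group_mean"`, with `*_sd` columns).
#'   All stacks within a group must share voxel dimensions.
#' @export
batch_metrics <- function(stacks, group = rep("all", length(stacks))) {
  stopifnot(length(stacks) == length(group),
            all(vapply(stacks, inherits, TRUE, "biofilm_stack")))
  per <- do.call(rbind, lapply(stacks, structure_metrics))
  per <- cbind(data.frame(kind = "stack", group = as.character(group),
                          stringsAsFactors = FALSE), per)
  metr <- c("biovolume", "mean_thickness", "max_thickness", "roughness")
  rows <- lapply(split(seq_along(stacks), as.character(group)), function(idx) {
    dims <- unique(t(vapply(stacks[idx], function(s)
      c(s$voxel_xy, s$voxel_z), c(0, 0))))
    if (nrow(dims) > 1L)
      stop("mixed voxel dimensions within a group", call. = FALSE)
    m <- per[idx, metr, drop = FALSE]
    out <- data.frame(kind = "group_mean", group = per$group[idx[1]],
                      stringsAsFactors = FALSE)
    for (v in metr) {
      out[[v]] <- mean(m[[v]])
      out[[paste0(v, "_sd")]] <- stats::sd(m[[v]])
    }
    out
  })
  summ <- do.call(rbind, rows)
  for (v in paste0(metr, "_sd")) per[[v]] <- NA_real_
  rbind(per, summ[names(per)])
}
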