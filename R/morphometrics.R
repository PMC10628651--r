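#' Binary cell-mask image
#'
#' A 2D binary micrograph mask (foreground = cells) with a physical pixel
#' size. Thresholding of raw grayscale micrographs is out of scope: masks
#' are the input boundary.
#'
#' @param pixels logical or 0/1 matrix; `TRUE`/1 marks cell pixels.
#' @param pixel_size physical pixel edge, um per pixel (> 0).
#' @return an object of class `"cell_mask"`.
#' @export
cell_mask <- function(pixels, pixel_size) {
  stopifnot(is.matrix(pixels))
  if (pixel_size <= 0) stop("'pixel_size' must be positive", call. = FALSE)
  mode(pixels) <- "integer"
  if (any(!pixels %in% c(0L, 1L)))
    stop("'pixels' must be binary (0/1)", call. = FALSE)
  structure(list(pixels = pixels, pixel_size = pixel_size),
            class = "cell_mask")
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf("Binary cell mask %d x %d px (%.3g um/px), %d foreground px\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              sum(x$pixels)))
  invisible(x)
}

#' Read a binary mask from a single-plane TIFF
#'
#' Nonzero pixels become foreground.
#'
#' @param path TIFF file path.
#' @param pixel_size um per pixel.
#' @return a [cell_mask()].
#' @export
read_cell_mask <- function(path, pixel_size) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  cell_mask((img > 0) + 0L, pixel_size)
}

# 8-connected component labelling by iterative minimum-label propagation:
# every foreground pixel starts with a unique label; each sweep replaces a
# pixel's label by the minimum over its 3x3 neighbourhood (foreground
# only) until a fixed point. Converges in O(component diameter) sweeps.
.label8 <- function(m) {
  fg <- m != 0L
  lab <- matrix(0L, nrow(m), ncol(m))
  lab[fg] <- seq_len(sum(fg))
  nr <- nrow(m); nc <- ncol(m)
  shift <- function(x, dr, dc) {
    out <- matrix(0L, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- x[rs - dr, cs - dc]
    out
  }
  repeat {
    nb <- lab
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      s <- shift(lab, dr, dc)
      take <- fg & s > 0L & (nb == 0L | s < nb)
      nb[take] <- s[take]
    }
    if (all(nb[fg] >= lab[fg])) break
    lab[fg] <- pmin(lab[fg], nb[fg])
  }
  # compact labels to 1..n
  ids <- sort(unique(lab[fg]))
  lab[fg] <- match(lab[fg], ids)
  lab
}

#' Particle areas from a binary mask
#'
#' Labels 8-connected foreground components (the particle-analysis
#' convention of ImageJ) and returns the physical area of each particle.
#' Touching cells merge into one particle; no watershed splitting is
#' attempted. Border-touching particles are retained.
#'
#' @param mask a [cell_mask()].
#' @param min_area drop particles smaller than this area (um^2,
#'   default 0 = keep all).
#' @return numeric vector of particle areas in um^2 (empty for an empty
#'   mask).
#' @examples
#' m <- matrix(0L, 10, 10); m[2:6, 2:6] <- 1L
#' particle_areas(cell_mask(m, 1))  # 25
#' @export
particle_areas <- function(mask, min_area = 0) {
  stopifnot(inherits(mask, "cell_mask"))
  if (!any(mask$pixels != 0L)) return(numeric(0))
  lab <- .label8(mask$pixels)
  counts <- tabulate(lab[lab > 0L])
  areas <- counts * mask$pixel_size^2
  areas[areas >= min_area]
}

#' Sphere-equivalent cell volume from projected area
#'
#' Assuming spherical cells, the volume of the sphere whose great-circle
#' cross-section has area A:
#' \eqn{V = \frac{4}{3} A \sqrt{A/\pi}} (equivalently
#' \eqn{\frac{4}{3}\pi r^3} with \eqn{r = \sqrt{A/\pi}}).
#'
#' @param A projected cell area, um^2 (vectorized, >= 0).
#' @return cell volume, um^3.
#' @examples
#' cell_volume(pi)  # 4*pi/3, the unit sphere
#' @export
cell_volume <- function(A) {
  if (any(A < 0)) stop("'A' must be non-negative", call. = FALSE)
  (4 / 3) * A * sqrt(A / pi)
}

#' Chlorophyll-a concentration from DMSO-extract absorbances
#'
#' Spectrophotometric two-wavelength equation for DMSO extracts:
#' \eqn{chl_a = 12.19\,A_{665} - 3.45\,A_{649}} (ug mL^-1). Negative
#' results are returned as-is with a below-detection warning.
#'
#' @param abs665,abs649 absorbances at 665 and 649 nm (>= 0, vectorized).
#' @return chlorophyll-a concentration, ug mL^-1.
#' @examples
#' chlorophyll_a(1, 0)      # 12.19
#' chlorophyll_a(0.5, 0.2)  # 5.405
#' @export
chlorophyll_a <- function(abs665, abs649) {
  if (any(abs665 < 0) || any(abs649 < 0))
    stop("absorbances must be non-negative", call. = FALSE)
  out <- 12.19 * abs665 - 3.45 * abs649
  if (any(out < 0))
    warning("negative chlorophyll-a: below detection limit", call. = FALSE)
  out
}

#' Normalize chlorophyll-a per cell and per cell volume
#'
#' Converts an extract concentration to per-cell (pg cell^-1) and
#' per-cell-volume (fg um^-3) contents.
#'
#' @param chl extract concentration, ug mL^-1.
#' @param extract_volume extract volume, mL.
#' @param n_cells number of cells in the extract (> 0).
#' @param mean_cell_volume mean cell volume, um^3 (> 0).
#' @return named list with `per_cell` (pg cell^-1) and `per_volume`
#'   (fg um^-3).
#' @examples
#' normalize_chl(1, 1, 1e6, 50)  # 1 pg/cell, 20 fg/um^3
#' @export
normalize_chl <- function(chl, extract_volume, n_cells, mean_cell_volume) {
  if (n_cells <= 0) stop("'n_cells' must be positive", call. = FALSE)
  if (mean_cell_volume <= 0)
    stop("'mean_cell_volume' must be positive", call. = FALSE)
  per_cell <- chl * extract_volume * 1e6 / n_cells      # ug -> pg
  per_volume <- per_cell * 1e3 / mean_cell_volume       # pg -> fg
  list(per_cell = per_cell, per_volume = per_volume)
}

#' Areal cell density
#'
#' Total cell count divided by the substratum surface. Note that channel
#' substratum areas are configuration-dependent (a 40 x 6 mm channel has
#' 2.4 cm^2; smaller effective sampling areas are sometimes used), so the
#' area is always an explicit argument.
#'
#' @param n_cells total cell count (>= 0).
#' @param substratum_area substratum surface, cm^2 (> 0).
#' @return areal density, cells cm^-2.
#' @examples
#' areal_density(2.4e6, 0.24)  # 1e7
#' @export
areal_density <- function(n_cells, substratum_area) {
  if (any(substratum_area <= 0))
    stop("'substratum_area' must be positive", call. = FALSE)
  if (any(n_cells < 0)) stop("'n_cells' must be non-negative", call. = FALSE)
  n_cells / substratum_area
}

#' Summary statistics for a cell population
#'
#' Convenience wrapper composing the particle, volume and chlorophyll
#' operations into the per-population summary.
#'
#' @param areas particle areas, um^2 (e.g. from [particle_areas()]).
#' @param chl optional extract concentration, ug mL^-1.
#' @param extract_volume extract volume, mL (with `chl`).
#' @param n_cells cell count used for normalization (default
#'   `length(areas)`).
#' @param substratum_area optional substratum surface, cm^2, for areal
#'   density.
#' @return a list with `areas`, `volumes`, `mean_volume`, `n_cells` and,
#'   when inputs allow, `chl_per_cell`, `chl_per_volume`,
#'   `areal_density`.
#' @export
cell_population_stats <- function(areas, chl = NULL, extract_volume = 1,
                                  n_cells = length(areas),
                                  substratum_area = NULL) {
  vols <- cell_volume(areas)
  out <- list(areas = areas, volumes = vols,
              mean_volume = if (length(vols)) mean(vols) else NA_real_,
              n_cells = n_cells)
  if (!is.null(chl) && length(vols)) {
    nc <- normalize_chl(chl, extract_volume, n_cells, out$mean_volume)
    out$chl_per_cell <- nc$per_cell
    out$chl_per_volume <- nc$per_volume
  }
  if (!is.null(substratum_area))
    out$areal_density <- areal_density(n_cells, substratum_area)
  out
}
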