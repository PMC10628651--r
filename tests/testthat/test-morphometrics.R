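test_that("particle areas count 8-connected components in physical units", {
  m <- matrix(0L, 20, 20)
  m[2:6, 2:6] <- 1L; m[10:14, 2:6] <- 1L; m[2:6, 12:16] <- 1L
  expect_equal(particle_areas(cell_mask(m, 1)), c(25, 25, 25))
  expect_equal(particle_areas(cell_mask(matrix(0L, 5, 5), 1)), numeric(0))
  # pixel size squared scales areas
  expect_equal(particle_areas(cell_mask(m, 0.5)), c(25, 25, 25) * 0.25)
  # diagonal touching merges (8-connectivity, particle-analysis default)
  d <- matrix(0L, 5, 5); d[2, 2] <- 1L; d[3, 3] <- 1L
  expect_equal(particle_areas(cell_mask(d, 1)), 2)
  # min_area filter
  s <- matrix(0L, 10, 10); s[1, 1] <- 1L; s[5:8, 5:8] <- 1L
  expect_equal(particle_areas(cell_mask(s, 1), min_area = 2), 16)
})

test_that("total particle area conserves the foreground pixel count", {
  set.seed(5)
  for (i in 1:5) {
    m <- matrix(rbinom(400, 1, 0.3), 20, 20)
    px <- runif(1, 0.1, 2)
    expect_equal(sum(particle_areas(cell_mask(m, px))), sum(m) * px^2)
  }
})

test_that("rasterized disks have near-pi-r-squared areas", {
  cfg <- scenario_config()
  img <- gen_cell_image(cfg, n_cells = 12, radius_mean = 2.5,
                        radius_sd = 0.2, seed = 8)
  truth <- attr(img, "truth")
  areas <- particle_areas(img)
  expect_equal(length(areas), nrow(truth))
  # each particle within one pixel-ring of its generating disk area
  px <- img$pixel_size
  ring <- (2 * pi * truth$r_um / px + 4) * px^2
  expect_true(all(abs(sort(areas) - sort(truth$area_um2)) < sort(ring) + 1))
})

test_that("sphere-equivalent volume follows the A^(3/2) law", {
  expect_equal(cell_volume(pi), 4 * pi / 3)
  expect_equal(cell_volume(0), 0)
  expect_equal(cell_volume(pi * 25), 4 / 3 * pi * 125, tolerance = 1e-12)
  expect_equal(cell_volume(78.5398), 523.599, tolerance = 1e-5)
  A <- c(1, 4, 9)
  expect_equal(cell_volume(4 * A) / cell_volume(A), rep(8, 3))
  expect_error(cell_volume(-1), "non-negative")
})

test_that("disk-image ground-truth volumes are recovered within 5%", {
  cfg <- scenario_config()
  # radii >= 4 px: rasterization error per disk stays under 5% in volume
  img <- gen_cell_image(cfg, n_cells = 8, radius_mean = 5 * 0.32,
                        radius_sd = 0.05, dim_px = 200, seed = 21)
  truth <- attr(img, "truth")
  vols <- cell_volume(sort(particle_areas(img)))
  vols_true <- cell_volume(sort(truth$area_um2))
  expect_true(all(abs(vols / vols_true - 1) <= 0.05))
})

test_that("chlorophyll-a equation and normalizations are exact", {
  expect_equal(chlorophyll_a(1, 0), 12.19)
  expect_equal(chlorophyll_a(0, 0), 0)
  expect_equal(chlorophyll_a(0.5, 0.2), 5.405)
  expect_warning(chlorophyll_a(0, 0.5), "below detection")
  nc <- normalize_chl(1, 1, 1e6, 50)
  expect_equal(nc$per_cell, 1)
  expect_equal(nc$per_volume, 20)
  # doubling the cell count halves per-cell content
  expect_equal(normalize_chl(1, 1, 2e6, 50)$per_cell, 0.5)
  expect_error(normalize_chl(1, 1, 0, 50), "n_cells")
})

test_that("areal density divides counts by substratum area additively", {
  expect_equal(areal_density(2.4e6, 0.24), 1e7)
  expect_equal(areal_density(0, 1), 0)
  # pooling replicate channels leaves the density unchanged
  n <- c(1.2e6, 1.2e6); a <- c(0.12, 0.12)
  expect_equal(areal_density(sum(n), sum(a)), areal_density(n[1], a[1]))
  expect_error(areal_density(10, 0), "positive")
})

test_that("population summary composes areas, volumes and chlorophyll", {
  areas <- c(pi, 4 * pi)
  st <- cell_population_stats(areas, chl = 1, extract_volume = 1,
                              n_cells = 1e6, substratum_area = 0.24)
  expect_equal(st$volumes, cell_volume(areas))
  expect_equal(st$mean_volume, mean(cell_volume(areas)))
  expect_equal(st$chl_per_cell, 1)
  expect_equal(st$areal_density, 1e6 / 0.24)
})
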