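test_that("biovolume equals slab height for a full slab and 0 when empty", {
  slab <- biofilm_stack(array(1L, c(8, 8, 10)), voxel_xy = 1, voxel_z = 1)
  expect_equal(biovolume(slab), 10)
  empty <- biofilm_stack(array(0L, c(8, 8, 10)), 1, 1)
  expect_equal(biovolume(empty), 0)
})

test_that("metrics on random stacks match brute-force voxel oracles", {
  set.seed(33)
  for (i in 1:5) {
    arr <- array(rbinom(30 * 30 * 10, 1, 0.4), c(30, 30, 10))
    st <- biofilm_stack(arr, voxel_xy = 1.25, voxel_z = 3.94)
    expect_equal(biovolume(st), brute_biovolume(arr, 1.25, 3.94))
    tm <- thickness_map(st)
    expect_equal(tm, brute_thickness(arr, 3.94))
    m <- structure_metrics(st)
    expect_equal(m$max_thickness, max(tm))
    expect_equal(m$mean_thickness, mean(tm))
    expect_equal(m$roughness, brute_roughness(as.vector(tm)))
  }
})

test_that("thickness counts voxels from the substratum to the highest top", {
  arr <- array(0L, c(3, 3, 8))
  arr[1, 1, 5] <- 1L                  # top at slice 5, voids below
  st <- biofilm_stack(arr, voxel_xy = 1, voxel_z = 3.94)
  tm <- thickness_map(st)
  expect_equal(tm[1, 1], 19.7)
  expect_equal(tm[2, 2], 0)
  # porous column: biovolume diverges from mean thickness
  expect_lt(biovolume(st), mean(tm) + 1e-9)
})

test_that("solid-from-substratum morphologies have biovolume == mean thickness", {
  set.seed(12)
  h <- matrix(sample(0:6, 25, replace = TRUE), 5, 5)
  st <- stack_from_heights(h, nz = 7, voxel_xy = 2, voxel_z = 1.5)
  expect_equal(biovolume(st), mean(thickness_map(st)))
})

test_that("roughness follows the COMSTAT coefficient", {
  flat <- stack_from_heights(matrix(4L, 6, 6), nz = 6)
  expect_equal(roughness(flat), 0)
  # two columns (0, 2t): mean t, each deviation t -> Ra* = 1
  two <- stack_from_heights(matrix(c(0L, 4L), 1, 2), nz = 4, voxel_z = 2)
  expect_equal(roughness(two), 1)
  expect_equal(roughness(two), brute_roughness(c(0, 8)))
  # single occupied column among N: Ra* = 2(N-1)/N, the supremum case
  N <- 25
  h <- matrix(0L, 5, 5); h[1, 1] <- 3L
  one <- stack_from_heights(h, nz = 3)
  expect_equal(roughness(one), 2 * (N - 1) / N)
  expect_lt(roughness(one), 2)
  # scale invariance: same height field, scaled voxel_z
  set.seed(4)
  hh <- matrix(sample(1:5, 16, replace = TRUE), 4, 4)
  expect_equal(roughness(stack_from_heights(hh, 5, voxel_z = 1)),
               roughness(stack_from_heights(hh, 5, voxel_z = 7.3)))
  expect_error(roughness(biofilm_stack(array(0L, c(2, 2, 2)), 1, 1)),
               "undefined")
})

test_that("metrics are invariant to translation and 90-degree rotation", {
  set.seed(9)
  arr <- array(0L, c(12, 12, 6))
  arr[3:6, 3:7, 1:3] <- rbinom(4 * 5 * 3, 1, 0.7)
  st <- biofilm_stack(arr, 1.25, 3.94)
  shifted <- array(0L, dim(arr)); shifted[6:9, 5:9, ] <- arr[3:6, 3:7, ]
  rot <- array(0L, c(12, 12, 6))
  for (z in 1:6) rot[, , z] <- t(arr[12:1, , z])
  for (other in list(shifted, rot)) {
    st2 <- biofilm_stack(other, 1.25, 3.94)
    expect_equal(biovolume(st2), biovolume(st))
    expect_equal(structure_metrics(st2)[-1], structure_metrics(st)[-1])
  }
})

test_that("cluster slope separates clustered from layered growth", {
  cfg <- scenario_config()
  targets <- 2.5 * (1:5)
  series <- function(mode, off) {
    met <- do.call(rbind, lapply(seq_along(targets), function(i)
      structure_metrics(gen_stack(cfg, mode, targets[i],
                                  seed = 400 + off + i))))
    cluster_slope(met$biovolume, met$max_thickness)
  }
  lay <- series("layered", 0)
  clu <- series("clustered", 50)
  expect_gt(clu$slope, lay$slope)
  # layered slabs thicken about one um per um^3/um^2 of biovolume
  expect_equal(lay$slope, 1, tolerance = 0.5)
  expect_error(cluster_slope(c(1, 2), c(1, 2)), "at least 3")
  expect_error(cluster_slope(rep(2, 4), 1:4), "degenerate")
})

test_that("batch metrics aggregate positions with stack + group rows", {
  slab <- stack_from_heights(matrix(3L, 4, 4), nz = 4)
  five <- rep(list(slab), 5)
  tab <- batch_metrics(five, group = rep("day1", 5))
  expect_equal(nrow(tab), 6)            # stacks + groups
  gm <- tab[tab$kind == "group_mean", ]
  expect_equal(gm$biovolume, biovolume(slab))
  expect_equal(gm$biovolume_sd, 0)
  expect_equal(gm$roughness, 0)
  mixed <- list(slab, stack_from_heights(matrix(3L, 4, 4), 4, voxel_z = 2))
  expect_error(batch_metrics(mixed, group = c("a", "a")), "mixed voxel")
})

test_that("masks and stacks round-trip through TIFF files", {
  m <- matrix(0L, 12, 12); m[3:7, 4:8] <- 1L
  f1 <- tempfile(fileext = ".tif")
  tiff::writeTIFF(m * 1.0, f1)
  back <- read_cell_mask(f1, pixel_size = 0.32)
  expect_identical(back$pixels, m)
  expect_equal(particle_areas(back), 25 * 0.32^2)

  arr <- array(0L, c(6, 6, 4)); arr[2:4, 2:4, 1:2] <- 1L
  f2 <- tempfile(fileext = ".tif")
  tiff::writeTIFF(lapply(1:4, function(z) arr[, , z] * 1.0), f2)
  st <- read_stack(f2, voxel_xy = 1, voxel_z = 2)
  expect_identical(st$voxels, arr)
  expect_equal(max(thickness_map(st)), 4)
  unlink(c(f1, f2))
})
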