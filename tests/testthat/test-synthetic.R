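test_that("generators are deterministic functions of (config, seed)", {
  cfg <- scenario_config()
  reg <- cfg$regimes[["300-5s-0-10s"]]
  traj <- gen_growth_trajectory(cfg, reg)
  expect_identical(gen_transmittance(cfg, traj, reg, seed = 3),
                   gen_transmittance(cfg, traj, reg, seed = 3))
  expect_identical(gen_pam_trace(cfg, 60, 0.3, seed = 4),
                   gen_pam_trace(cfg, 60, 0.3, seed = 4))
  expect_identical(gen_stack(cfg, "clustered", 8, seed = 5),
                   gen_stack(cfg, "clustered", 8, seed = 5))
  expect_identical(gen_cell_image(cfg, 10, seed = 6),
                   gen_cell_image(cfg, 10, seed = 6))
  # different seeds give different noise
  expect_false(identical(gen_transmittance(cfg, traj, reg, seed = 3),
                         gen_transmittance(cfg, traj, reg, seed = 4)))
})

test_that("seeded generators do not disturb the caller's RNG stream", {
  cfg <- scenario_config()
  set.seed(99); before <- .Random.seed
  invisible(gen_pam_trace(cfg, 60, 0.3, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("trajectory log-slope equals the scenario net growth rate", {
  cfg <- scenario_config()
  for (lab in names(cfg$regimes)) {
    reg <- cfg$regimes[[lab]]
    traj <- gen_growth_trajectory(cfg, reg)
    slope <- unname(coef(lm(log(traj$X) ~ traj$time_d))[2])
    expect_equal(slope, scenario_mu(cfg, reg), tolerance = 1e-10)
    expect_equal(slope, attr(traj, "mu"), tolerance = 1e-10)
  }
  expect_error(gen_growth_trajectory(cfg, cfg$regimes[[1]], days = 1),
               "at least 2")
})

test_that("mitigated rates exceed unmitigated ones for photoinhibiting peaks", {
  cfg <- scenario_config()
  for (lab in c("300-5s-0-10s", "500-5s-0-20s")) {
    reg <- cfg$regimes[[lab]]
    expect_gt(scenario_mu(cfg, reg, mitigated = TRUE),
              scenario_mu(cfg, reg, mitigated = FALSE))
  }
  # continuous light: mitigation has nothing to act on
  cont <- cfg$regimes[["100 cont"]]
  expect_equal(scenario_mu(cfg, cont, TRUE), scenario_mu(cfg, cont, FALSE))
})

test_that("noise-free transmittance closes the growth-estimation loop", {
  cfg <- scenario_config(sigma_I = 0)
  for (lab in c("100 cont", "300-5s-0-10s")) {
    reg <- cfg$regimes[[lab]]
    traj <- gen_growth_trajectory(cfg, reg)
    fit <- fit_growth_rate(gen_transmittance(cfg, traj, reg))
    expect_equal(fit$mu, attr(traj, "mu"), tolerance = 1e-9)
  }
})

test_that("noisy transmittance requires a seed", {
  cfg <- scenario_config()
  reg <- cfg$regimes[[1]]
  traj <- gen_growth_trajectory(cfg, reg)
  expect_error(gen_transmittance(cfg, traj, reg), "seed")
})

test_that("layered stacks become flat as jitter vanishes", {
  cfg <- scenario_config(jitter_um = 0)
  st <- gen_stack(cfg, "layered", target_biovolume = 10, seed = 1)
  expect_equal(roughness(st), 0)
  cfg2 <- scenario_config(jitter_um = 3)
  expect_gt(roughness(gen_stack(cfg2, "layered", 10, seed = 1)), 0)
})

test_that("empty cell images and infeasible packings are handled", {
  cfg <- scenario_config()
  img0 <- gen_cell_image(cfg, 0, seed = 1)
  expect_equal(sum(img0$pixels), 0)
  expect_equal(particle_areas(img0), numeric(0))
  expect_warning(
    crowded <- gen_cell_image(cfg, 500, radius_mean = 4, dim_px = 64,
                              seed = 2, max_tries = 20),
    "packing infeasible")
  expect_lt(nrow(attr(crowded, "truth")), 500)
})
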