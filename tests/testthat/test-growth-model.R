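test_that("Haldane curve hits its landmarks", {
  p <- haldane_params(1, 0.01, 150)
  expect_equal(haldane_mu(150, p), 1)          # maximum at I_opt
  expect_equal(haldane_mu(0, p), 0)
  expect_equal(haldane_mu(300, p), 0.75)       # denominator 300 + 100
  expect_error(haldane_params(0, 0.01, 150), "positive")
})

test_that("Haldane curve has the unimodal photoinhibition shape", {
  p <- haldane_params(0.55, 0.005, 100)
  grid <- seq(0, 1000, by = 1)
  mu <- haldane_mu(grid, p)
  below <- grid < p$I_opt & grid > 0
  above <- grid > p$I_opt
  expect_true(all(diff(mu[below]) > 0))
  expect_true(all(diff(mu[above]) < 0))
  expect_equal(max(mu), p$mu_max, tolerance = 1e-6)
  # initial slope approaches alpha
  I0 <- p$I_opt / 1000
  expect_equal(haldane_mu(I0, p) / I0, p$alpha, tolerance = 0.01)
})

test_that("net growth under intermittent light follows mu_L * eps - R", {
  p <- haldane_params(1, 0.01, 150)
  expect_equal(net_growth(300, p, epsilon = 1, R = 0.1),
               haldane_mu(300, p) - 0.1)
  expect_equal(net_growth(0, p, epsilon = 1/3, R = 0.08), -0.08)
  expect_equal(net_growth(300, p, epsilon = 1/3, R = 0.05), 0.20)
})

test_that("Haldane fit recovers noiseless parameters at 6 light levels", {
  truth <- haldane_params(0.55, 0.005, 100)
  I <- c(25, 50, 100, 200, 400, 800)
  fit <- fit_haldane(I, haldane_mu(I, truth))
  expect_true(fit$convergence)
  expect_equal(unname(coef(fit)), c(0.55, 0.005, 100), tolerance = 1e-3)
  expect_lt(fit$rss, 1e-10)
})

test_that("Haldane fit is invariant to point order and light-unit rescaling", {
  truth <- haldane_params(0.8, 0.012, 180)
  I <- c(20, 60, 120, 180, 350, 700)
  y <- haldane_mu(I, truth)
  ord <- c(4, 1, 6, 3, 5, 2)
  expect_equal(coef(fit_haldane(I[ord], y[ord])), coef(fit_haldane(I, y)),
               tolerance = 1e-6)
  # I -> c*I maps (mu_max, alpha, I_opt) -> (mu_max, alpha/c, c*I_opt)
  cc <- 3.7
  sc <- coef(fit_haldane(cc * I, y))
  expect_equal(unname(sc), c(0.8, 0.012 / cc, 180 * cc), tolerance = 1e-3)
})

test_that("Haldane fit fails loudly when unidentifiable", {
  expect_error(fit_haldane(c(100, 100, 100), c(0.4, 0.41, 0.39)),
               "unidentifiable")
})

test_that("noisy Haldane fits have median parameter error under 15%", {
  truth <- haldane_params(0.55, 0.005, 100)
  I <- c(10, 25, 50, 100, 150, 300, 600, 1000)
  clean <- haldane_mu(I, truth)
  errs <- vapply(1:50, function(i) {
    set.seed(7000 + i)
    fit <- fit_haldane(I, clean + rnorm(length(I), 0, 0.02))
    abs(unname(coef(fit)) / c(0.55, 0.005, 100) - 1)
  }, numeric(3))
  expect_true(all(apply(errs, 1, stats::median) < 0.15))
})

test_that("growth yield is net rate per unit average light", {
  expect_equal(growth_yield(0.5, 100), 0.005)
  expect_equal(growth_yield(0, 250), 0)
  expect_error(growth_yield(0.5, 0), "positive")
  # yield depends only on mu and I_ave, not how the dose is delivered
  expect_equal(growth_yield(0.3, 300 * (1/3)), growth_yield(0.3, 100 * 1))
})

test_that("footprint productivity follows mu * (1/eps) * rho * h", {
  expect_equal(footprint_productivity(0.5, reactor_spec(1/3)), 21)
  expect_equal(reactor_spec(1/3)$area_ratio, 3)
  spec1 <- reactor_spec(1, rho = 2e5, h = 5e-5)
  expect_equal(footprint_productivity(0.4, spec1), 0.4 * 2e5 * 5e-5)
  expect_error(reactor_spec(0), "epsilon")
})

test_that("productivity scan matches the scalar operations elementwise", {
  p <- haldane_params(0.55, 0.005, 100)
  scan <- productivity_scan(p, R = 0.05, I_peak = c(50, 100, 300, 500),
                            epsilon = c(1, 1/3))
  for (i in seq_len(nrow(scan))) {
    expect_equal(scan$mu[i],
                 net_growth(scan$I_peak[i], p, scan$epsilon[i], 0.05))
    expect_equal(scan$yield[i], scan$mu[i] / scan$I_ave[i])
    expect_equal(scan$P_f[i],
                 footprint_productivity(scan$mu[i],
                                        reactor_spec(scan$epsilon[i])))
  }
  # eps = 1 rows reproduce the continuous-light Haldane curve minus R
  e1 <- scan[scan$epsilon == 1, ]
  expect_equal(e1$mu, haldane_mu(e1$I_peak, p) - 0.05)
  # P_f at fixed mu strictly increases as eps decreases
  expect_true(all(footprint_productivity(0.3, reactor_spec(1/5)) >
                  footprint_productivity(0.3, reactor_spec(1/3))))
  expect_error(productivity_scan(p, 0.05, numeric(0), 1), "empty")
})

test_that("haldane_fit methods behave as a standard model object", {
  truth <- haldane_params(0.55, 0.005, 100)
  I <- c(25, 50, 100, 200, 400, 800)
  fit <- fit_haldane(I, haldane_mu(I, truth))
  expect_equal(predict(fit, 100), haldane_mu(100, fit$params))
  expect_equal(unname(residuals(fit)), unname(fit$data$mu_L - fit$fitted))
  expect_output(print(fit), "Haldane")
  expect_output(print(summary(fit)), "RSS")
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_identical(dim(sims), c(6L, 2L))
  expect_identical(sims, simulate(fit, nsim = 2, seed = 9))
})
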