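test_that("exponential model matches its closed form at anchor points", {
  p <- kinetic_params("exponential", g_i = 0.1, g_f = 0.3, tau = 600)
  expect_identical(predict_gs(p, 0), 0.1)
  expect_equal(predict_gs(p, 1e9), 0.3, tolerance = 1e-12)
  # direct substitution: g_f + (g_i - g_f)/e
  expect_equal(predict_gs(p, 600), 0.3 + (0.1 - 0.3) * exp(-1), tolerance = 1e-15)
  expect_equal(predict_gs(p, 600), 0.2264241, tolerance = 1e-7)
  expect_error(kinetic_params("exponential", 0.1, 0.3, 600, lam = 1))
  expect_error(predict_gs(p, c(0, NaN)))
  expect_error(predict_gs(p, -5))
})

test_that("sigmoidal model anchors: 37% at t = tau with no lag, lag shifts onset", {
  # with lam = 0 the double exponential at t = tau is exp(-exp(0)) = 1/e
  p <- kinetic_params("sigmoidal", g_i = 0, g_f = 1, tau = 300, lam = 0)
  expect_equal(predict_gs(p, 300), exp(-1), tolerance = 1e-12)
  expect_equal(predict_gs(p, 1e7), 1, tolerance = 1e-12)
  # at t = lam the response is exp(-e) ~ 6.6% complete: lam acts as a lag
  p2 <- kinetic_params("sigmoidal", g_i = 0, g_f = 1, tau = 300, lam = 200)
  expect_equal(predict_gs(p2, 200), exp(-exp(1)), tolerance = 1e-12)
  expect_error(kinetic_params("sigmoidal", 0, 1, 300, lam = -5))
})

test_that("CDWeibull collapses to the exponential model at lam = 1", {
  tt <- seq(0, 7200, length.out = 2001)
  pc <- kinetic_params("cdweibull", g_i = 0.1, g_f = 0.3, tau = 600, lam = 1)
  pe <- kinetic_params("exponential", g_i = 0.1, g_f = 0.3, tau = 600)
  expect_lt(max(abs(predict_gs(pc, tt) - predict_gs(pe, tt))), 1e-12)
  expect_equal(slmax(pc), slmax(pe), tolerance = 1e-15, ignore_attr = TRUE)
})

test_that("t = tau is a static point of the CDWeibull independent of shape", {
  for (lam in c(0.5, 0.8, 1, 1.7, 2.5, 4)) {
    p <- kinetic_params("cdweibull", g_i = 0.1, g_f = 0.3, tau = 600, lam = lam)
    expect_equal(predict_gs(p, 600), 0.3 + (0.1 - 0.3) * exp(-1), tolerance = 1e-14)
    expect_equal(t63(p), 600)
  }
  p2 <- kinetic_params("cdweibull", g_i = 0.1, g_f = 0.3, tau = 600, lam = 2)
  expect_equal(predict_gs(p2, 300), 0.3 + (0.1 - 0.3) * exp(-0.25), tolerance = 1e-14)
  expect_error(kinetic_params("cdweibull", 0.1, 0.3, 600, lam = 0))
})

test_that("closed-form slmax matches dense numerical differentiation", {
  expect_equal(as.numeric(slmax(kinetic_params("exponential", 0.1, 0.3, 600))),
               0.2 / 600, tolerance = 1e-15)
  for (lam in c(1.3, 2, 2.5)) {
    p <- kinetic_params("cdweibull", g_i = 0.1, g_f = 0.3, tau = 600, lam = lam)
    expect_equal(as.numeric(slmax(p)), oracle_slmax_grid(p), tolerance = 1e-6)
  }
  ps <- kinetic_params("sigmoidal", g_i = 0.1, g_f = 0.3, tau = 300, lam = 100)
  expect_equal(as.numeric(slmax(ps)), 0.2 / (exp(1) * 300), tolerance = 1e-15)
  expect_equal(as.numeric(slmax(ps)), oracle_slmax_grid(ps), tolerance = 1e-6)
})

test_that("slmax for lam < 1 is flagged as a boundary evaluation", {
  p <- kinetic_params("cdweibull", g_i = 0.1, g_f = 0.3, tau = 600, lam = 0.7)
  s1 <- slmax(p, eps = 1)
  s2 <- slmax(p, eps = 0.1)
  expect_true(isTRUE(attr(s1, "boundary")))
  expect_gt(as.numeric(s2), as.numeric(s1))  # supremum is at t -> 0+
  # matches the finite-difference slope at eps
  num <- (predict_gs(p, 1 + 1e-6) - predict_gs(p, 1 - 1e-6)) / 2e-6
  expect_equal(as.numeric(s1), abs(num), tolerance = 1e-6)
})

test_that("sigmoidal t63 matches bisection and shifts additively with the lag", {
  p0 <- kinetic_params("sigmoidal", g_i = 0, g_f = 1, tau = 200, lam = 0)
  expect_equal(t63(p0), oracle_t63_bisect(p0), tolerance = 1e-9)
  expect_equal(t63(p0) / 200, 1.7793, tolerance = 1e-4)
  p100 <- kinetic_params("sigmoidal", g_i = 0, g_f = 1, tau = 200, lam = 100)
  expect_equal(t63(p100), t63(p0) + 100, tolerance = 1e-12)
  expect_error(t63(kinetic_params("exponential", 0.2, 0.2, 600)))
})

test_that("every model completes exactly 1 - 1/e of dgs at its t63", {
  set.seed(11)
  for (i in 1:25) {
    g_i <- runif(1, 0, 0.3); g_f <- runif(1, 0, 0.5)
    if (abs(g_f - g_i) < 1e-3) g_f <- g_i + 0.1
    tau <- runif(1, 30, 5000)
    ps <- list(
      kinetic_params("exponential", g_i, g_f, tau),
      kinetic_params("sigmoidal", g_i, g_f, tau, lam = runif(1, 0, 500)),
      kinetic_params("cdweibull", g_i, g_f, tau, lam = runif(1, 0.5, 3.5))
    )
    for (p in ps) {
      comp <- abs(predict_gs(p, t63(p)) - p$g_i) / abs(p$g_f - p$g_i)
      expect_equal(comp, 1 - exp(-1), tolerance = 1e-9)
    }
  }
})

test_that("predictions are monotone and bounded between the endpoints", {
  set.seed(12)
  tt <- seq(0, 20000, length.out = 800)
  for (i in 1:20) {
    g_i <- runif(1, 0, 0.4); g_f <- runif(1, 0, 0.4)
    tau <- runif(1, 50, 4000)
    ps <- list(
      kinetic_params("exponential", g_i, g_f, tau),
      kinetic_params("sigmoidal", g_i, g_f, tau, lam = runif(1, 0, 400)),
      kinetic_params("cdweibull", g_i, g_f, tau, lam = runif(1, 0.6, 3))
    )
    for (p in ps) {
      y <- predict_gs(p, tt)
      s <- sign(p$g_f - p$g_i)
      expect_true(all(s * diff(y) >= -1e-15))
      expect_true(all(y >= min(g_i, g_f) - 1e-12 & y <= max(g_i, g_f) + 1e-12))
    }
  }
})

test_that("empirical t63 recovers the generating time constant", {
  # noiseless exponential, pre-step plateau included, sampled every 30 s
  tc <- make_step_series(tau = 600, lam = 1)
  est <- t63_empirical(tc$time, tc$gs, switch_time = 0)
  expect_lt(abs(est - 600), 30)

  # constant series: no response signal
  flat <- gs_timecourse(seq(0, 3600, 30), rep(1000, 121), rep(0.2, 121))
  expect_error(t63_empirical(flat$time, flat$gs), class = "stomkin_no_response")

  # non-monotone series: first crossing returned, multi-crossing flagged
  tt <- seq(-300, 3600, 30)
  gs <- approx(c(-300, 0, 500, 800, 1200, 3600),
               c(0.10, 0.10, 0.35, 0.20, 0.30, 0.30), xout = tt)$y
  est3 <- t63_empirical(tt, gs, switch_time = 0)
  expect_true(isTRUE(attr(est3, "multi_crossing")))
  expect_lt(as.numeric(est3), 500)
})

test_that("empirical t63 is robust to measurement noise on average", {
  ests <- vapply(1:50, function(s) {
    tc <- make_step_series(tau = 600, lam = 1, noise_sd = 0.002, seed = 100 + s)
    as.numeric(t63_empirical(tc$time, tc$gs, switch_time = 0))
  }, 0.0)
  expect_lt(abs(mean(ests) - 600) / 600, 0.10)
})
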