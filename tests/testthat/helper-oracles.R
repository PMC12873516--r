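# Independent numerical oracles used across test files. These deliberately
# avoid the closed forms under test: bisection on the predict functions and
# dense finite differences.

# Bisection for the 63.2% completion time of any kinetic_params object.
oracle_t63_bisect <- function(p, upper = 50 * p$tau, tol = 1e-9) {
  target <- (1 - exp(-1)) * abs(p$g_f - p$g_i)
  f <- function(t) abs(predict_gs(p, t) - p$g_i) - target
  lo <- 0
  hi <- upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Maximum of the finite-difference gradient of predict_gs on a dense grid.
oracle_slmax_grid <- function(p, n = 1e6, t_max = 6 * p$tau) {
  tt <- seq(0, t_max, length.out = n)
  g <- predict_gs(p, tt)
  max(abs(diff(g)) / diff(tt)[1L])
}

# Hat-matrix closed-form exact LOO for OLS with ML variance: the
# independent oracle for the case-deletion implementation (identity V).
oracle_loo_hat <- function(X, y) {
  n <- length(y)
  XtX_inv <- solve(crossprod(X))
  H <- X %*% XtX_inv %*% t(X)
  beta <- XtX_inv %*% crossprod(X, y)
  e <- drop(y - X %*% beta)
  h <- diag(H)
  rss <- sum(e^2)
  vapply(seq_len(n), function(i) {
    e_loo <- e[i] / (1 - h[i])                    # deleted residual
    rss_m <- rss - e[i]^2 / (1 - h[i])            # RSS without i
    s2_m <- rss_m / (n - 1)                       # ML variance of the refit
    pred_var <- s2_m * (1 + h[i] / (1 - h[i]))    # x_i'(X_-i'X_-i)^-1 x_i = h/(1-h)
    stats::dnorm(y[i], y[i] - e_loo, sqrt(pred_var), log = TRUE)
  }, 0.0)
}

# Small curated-series builder: pre-step plateau + one CDWeibull response.
make_step_series <- function(g_i = 0.1, g_f = 0.3, tau = 600, lam = 1,
                             dt = 30, t_pre = 300, t_post = 3600,
                             noise_sd = 0, seed = NULL,
                             ppfd = c(100, 1000)) {
  if (!is.null(seed)) set.seed(seed)
  tt <- seq(-t_pre, t_post, by = dt)
  p <- kinetic_params("cdweibull", g_i = g_i, g_f = g_f, tau = tau, lam = lam)
  gs <- ifelse(tt < 0, g_i, predict_gs(p, pmax(tt, 0)))
  if (noise_sd > 0) gs <- pmax(gs + stats::rnorm(length(tt), 0, noise_sd), 0)
  light <- ifelse(tt < 0, ppfd[1L], ppfd[2L])
  gs_timecourse(tt, light, gs, source_id = "fixture")
}
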