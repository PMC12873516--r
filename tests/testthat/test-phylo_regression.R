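# Synthetic trait table with a known generating model for recovery checks.
make_phylo_table <- function(n, seed, b_sd = 0, sd_resid = 0.3,
                             phylo = NULL, sd_phylo = 0) {
  set.seed(seed)
  sp <- if (!is.null(phylo)) phylo$tree$tip.label else sprintf("sp%02d", 1:n)
  lsd <- rnorm(n, log(220), 0.6)
  lssl <- rnorm(n, log(29), 0.35)
  rsd <- ifelse(runif(n) < 0.3, 0, runif(n, 0.05, 2))
  gc <- sample(c("K", "DB"), n, replace = TRUE)
  dev <- if (sd_phylo > 0) {
    drop(MASS::mvrnorm(1, rep(0, n), sd_phylo^2 * phylo$corr[sp, sp]))
  } else 0
  tau <- exp(log(20) + b_sd * (lsd - log(220)) + dev + rnorm(n, 0, sd_resid))
  data.frame(species = sp, sd_total = exp(lsd), ssl = exp(lssl),
             rsd = rsd, rsd_class = classify_rsd(rsd), gc_type = gc,
             tau_open = tau, stringsAsFactors = FALSE)
}

test_that("candidate enumeration is complete and duplicate-free", {
  cands <- enumerate_candidates()
  expect_identical(length(cands), 2047L)
  keys <- vapply(cands, function(x) paste(sort(x), collapse = "|"), "")
  expect_identical(anyDuplicated(keys), 0L)
  expect_identical(sum(lengths(cands) == 1L), 11L)
  expect_identical(sum(vapply(cands, function(x) "lineage" %in% x, TRUE)), 1024L)
})

test_that("tree preparation repairs zero branches and prunes with warning", {
  # star phylogeny: no shared history, identity correlation
  star <- prepare_tree("(A:1,B:1,C:1,D:1);")
  expect_equal(unname(star$corr), diag(4), tolerance = 1e-12)

  # hand-computed 4-tip tree: A's zero stem is raised to the minimum
  # nonzero length (1), making depths 2 everywhere; corr(A,B) = shared/depth
  tr <- prepare_tree("((A:0,B:1):1,(C:1,D:1):1);")
  expect_true(all(tr$tree$edge.length > 0))
  expect_equal(tr$corr["A", "B"], 0.5, tolerance = 1e-12)
  expect_equal(tr$corr["A", "C"], 0, tolerance = 1e-12)
  expect_equal(unname(diag(tr$corr)), rep(1, 4))

  expect_warning(pr <- prepare_tree("((A:1,B:1):1,C:2);", c("A", "B", "X")),
                 "X")
  expect_identical(pr$dropped, "X")
  expect_identical(sort(pr$tree$tip.label), c("A", "B"))
})

test_that("identity-correlation GLS collapses to ordinary least squares", {
  tab <- make_phylo_table(40, seed = 50, b_sd = -0.4)
  f <- fit_candidate(c("SD", "SSl"), tab, "tau_open")
  ols <- lm(log(tau_open) ~ log(sd_total) + log(ssl), data = tab)
  expect_equal(unname(f$beta), unname(coef(ols)), tolerance = 1e-8)
})

test_that("case-deletion LOO equals the hat-matrix closed form", {
  tab <- make_phylo_table(25, seed = 51, b_sd = -0.4)
  f <- fit_candidate(c("SD",  "GC"), tab, "tau_open")
  X <- cbind(1, log(tab$sd_total), as.numeric(tab$gc_type == "DB"))
  expect_equal(f$elpd_i, oracle_loo_hat(X, log(tab$tau_open)), tolerance = 1e-6)
})

test_that("generating coefficients are recovered within 2 SE", {
  tab <- make_phylo_table(80, seed = 52, b_sd = -0.5, sd_resid = 0.2)
  f <- fit_candidate("SD", tab, "tau_open")
  X <- cbind(1, log(tab$sd_total))
  se_b <- sqrt(f$sigma2 * diag(solve(crossprod(X))) * f$n / (f$n - 2))
  expect_lt(abs(f$beta[2] - (-0.5)), 2 * se_b[2])
})

test_that("pseudo-R2 is bounded, near zero under the null, monotone with signal", {
  r2_null <- vapply(1:20, function(s) {
    fit_candidate("SD", make_phylo_table(40, seed = 600 + s), "tau_open")$pseudo_r2
  }, 0.0)
  expect_true(all(r2_null >= 0 & r2_null <= 1))
  expect_lt(median(r2_null), 0.1)

  # noiseless signal in SD and SSl: nested candidates increase R2
  set.seed(53)
  tab <- make_phylo_table(40, seed = 53, sd_resid = 0)
  tab$tau_open <- exp(1 - 0.5 * log(tab$sd_total) + 0.4 * log(tab$ssl))
  r2_1 <- fit_candidate("SD", tab, "tau_open")$pseudo_r2
  r2_2 <- fit_candidate(c("SD", "SSl"), tab, "tau_open")$pseudo_r2
  expect_gt(r2_2, r2_1)
  expect_equal(r2_2, 1, tolerance = 1e-9)
})

test_that("rank table flags equivalence by the 2-SE rule", {
  tab <- make_phylo_table(40, seed = 54, b_sd = -0.5)
  f1 <- fit_candidate("SD", tab, "tau_open")
  f2 <- fit_candidate(c("SD", "SSl"), tab, "tau_open")
  rk <- loo_rank(list(f1, f2, f1))   # duplicate candidate ties exactly
  expect_identical(nrow(rk), 3L)
  dup <- rk[rk$terms == "SD", ]
  expect_equal(diff(dup$looic), 0)
  expect_true(all(dup$equivalent))
  expect_true(all(rk$d_looic >= 0))
})

test_that("singular designs are dropped with a reason", {
  tab <- make_phylo_table(30, seed = 55)
  tab$ssl <- tab$sd_total   # SSl:SD becomes SD^2-collinear set
  f <- fit_candidate(c("SD", "SSl"), tab, "tau_open")
  expect_true(is_dropped(f))
  expect_match(f$reason, "singular")
})

test_that("lineage models win under strong phylogenetic signal", {
  wins <- 0L
  n_sim <- 30L
  for (s in seq_len(n_sim)) {
    ph <- gen_phylogeny(30, seed = 700 + s)
    tab <- make_phylo_table(30, seed = 800 + s, phylo = ph,
                            sd_phylo = 0.8, sd_resid = 0.1)
    f_lin <- fit_candidate(c("SD", "lineage"), tab, "tau_open", phylo = ph)
    f_iid <- fit_candidate("SD", tab, "tau_open")
    if (f_lin$looic < f_iid$looic) wins <- wins + 1L
  }
  expect_gt(wins / n_sim, 0.5)
})

test_that("model selection reports best and parsimonious rows", {
  ph <- gen_phylogeny(40, seed = 77)
  tab <- make_phylo_table(40, seed = 78, phylo = ph, b_sd = -0.5,
                          sd_phylo = 0.4, sd_resid = 0.2)
  cands <- list("SD", c("SD", "SSl"), c("SD", "lineage"),
                c("SD", "SSl", "lineage"), "SSl")
  fits <- lapply(cands, fit_candidate, table = tab, response = "tau_open",
                 phylo = ph)
  sel <- select_models(loo_rank(fits))
  expect_true("best" %in% sel$type)
  expect_true(all(sel$type %in% c("best", "w_phylogeny", "wo_phylogeny")))
  f <- tempfile(fileext = ".csv")
  write_ranking_csv(sel, f)
  out <- read.csv(f, check.names = FALSE)
  expect_true(all(candidate_terms() %in% names(out)))
  expect_identical(out$lineage[out$type == "w_phylogeny"], 1L)
})
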