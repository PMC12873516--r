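test_that("tree generation is seeded, ultrametric and the right shape", {
  t1 <- gen_phylogeny(12, seed = 1)
  t2 <- gen_phylogeny(12, seed = 1)
  expect_identical(ape::write.tree(t1$tree), ape::write.tree(t2$tree))
  t3 <- gen_phylogeny(12, seed = 2)
  expect_false(identical(ape::write.tree(t1$tree), ape::write.tree(t3$tree)))

  expect_identical(gen_phylogeny(2, seed = 3)$tree$Nnode, 1L)   # single cherry
  expect_identical(gen_phylogeny(50, seed = 4)$tree$Nnode, 49L)
  expect_true(ape::is.ultrametric(t1$tree, tol = 1e-8))
})

test_that("trait generation hits its statistical structure targets", {
  cfg <- synth_config(n_species = 500, seed = 42)
  ph <- gen_phylogeny(500, seed = 42)
  tab <- gen_traits(ph, cfg)

  lcor <- cor(log(tab$ssl), log(tab$sd_total))
  expect_lt(abs(lcor - (-0.6)), 0.1)

  zero_frac <- mean(tab$rsd == 0, na.rm = TRUE)
  ci <- 1.96 * sqrt(0.29 * 0.71 / 500)
  expect_lt(abs(zero_frac - 0.29), ci + 0.01)

  expect_true(all(tab$rsd >= 0 & tab$rsd <= 2.2, na.rm = TRUE))
  expect_true(all(tab$tau_open * 60 >= 60 & tab$tau_open * 60 <= 3600))
  expect_true(all(c("K", "DB") %in% tab$gc_type))
  expect_false(is.null(attr(tab, "truth")))
})

test_that("dumbbell species are faster and clustered in one clade", {
  cfg <- synth_config(n_species = 120, seed = 7)
  ph <- gen_phylogeny(120, seed = 7)
  tab <- gen_traits(ph, cfg)
  expect_lt(mean(tab$tau_open[tab$gc_type == "DB"]),
            mean(tab$tau_open[tab$gc_type == "K"]))
  # clade clustering: DB tips form a connected subtree
  db_tips <- tab$species[tab$gc_type == "DB"]
  sub <- ape::keep.tip(ph$tree, db_tips)
  mrca_clade <- ape::extract.clade(ph$tree, ape::getMRCA(ph$tree, db_tips))
  expect_identical(sort(mrca_clade$tip.label), sort(db_tips))
})

test_that("zero phylogenetic signal leaves species deviations tree-independent", {
  cfg0 <- synth_config(n_species = 150, seed = 12,
                       effects = list(tau_open_intercept = log(28 * 60),
                                      b_sd = 0, b_ssl = 0, b_gc_open = 0,
                                      tau_close_intercept = log(20 * 60),
                                      b_gc_close = 0, sd_resid = 0.05,
                                      sd_phylo = 0.5, pagel_lambda = 0))
  ph <- gen_phylogeny(150, seed = 12)
  tab <- gen_traits(ph, cfg0)
  # Abouheif/Moran-style check via distance correlation: deviations vs
  # phylogenetic correlation should be near zero at lambda = 0
  dev <- log(tab$tau_open * 60)
  C <- ph$corr[tab$species, tab$species]
  off <- upper.tri(C)
  prod_dev <- tcrossprod(dev - mean(dev))
  expect_lt(abs(cor(C[off], prod_dev[off])), 0.05)
})

test_that("noiseless, artifact-free time courses equal the model exactly", {
  cfg <- synth_config(n_species = 1, n_replicates = 2, noise_sd = 0, seed = 5)
  truth <- list(g_low = 0.1, g_high = 0.3, tau_open = 600, tau_close = 900,
                lambda_open = 1.5, lambda_close = 2)
  tcs <- gen_timecourse_set(truth, cfg)
  expect_length(tcs, 2L)
  tc <- tcs[[1]]
  tr <- attr(tc, "truth")
  mid <- tc$time >= tr$switch_times[1] & tc$time < tr$switch_times[2]
  expect_equal(tc$gs[mid],
               predict_gs(tr$p_open, tc$time[mid] - tr$switch_times[1]),
               tolerance = 1e-12)
  post <- tc$time >= tr$switch_times[2]
  expect_equal(tc$gs[post],
               predict_gs(tr$p_close, tc$time[post] - tr$switch_times[2]),
               tolerance = 1e-12)
  # asymmetric directions present
  steps <- detect_light_steps(tc)
  expect_identical(steps$direction, c("INCREASE", "DECREASE"))
})

test_that("injected artifacts are recovered exactly by transient stripping", {
  cfg <- synth_config(n_species = 1, n_replicates = 1, noise_sd = 0.002,
                      artifact = list(amplitude = 0.05, n_points = 2L),
                      seed = 6)
  truth <- list(g_low = 0.1, g_high = 0.3, tau_open = 600, tau_close = 900,
                lambda_open = 1.2, lambda_close = 1.8)
  tc <- gen_timecourse_set(truth, cfg)[[1]]
  tr <- attr(tc, "truth")
  segs <- curate_timecourse(tc)
  excl <- unlist(lapply(segs, function(s) {
    which(tc$time %in% s$data$time[s$data$point_label == "EXCLUDED_TRANSIENT"])
  }))
  expect_setequal(excl, tr$artifact_indices)
})

test_that("generator output round-trips through the curation readers", {
  cfg <- synth_config(n_species = 1, n_replicates = 1, seed = 8)
  truth <- list(g_low = 0.1, g_high = 0.25, tau_open = 400, tau_close = 700,
                lambda_open = 1.4, lambda_close = 2.2)
  tc <- gen_timecourse_set(truth, cfg)[[1]]
  f <- tempfile(fileext = ".csv")
  write_timecourse_csv(tc, f)
  back <- read_timecourse_csv(f)
  expect_equal(back$gs, tc$gs)
  expect_identical(nrow(detect_light_steps(back)), 2L)
})

test_that("full round trip recovers asymmetric time constants", {
  # generate -> curate -> fit both directions -> derive
  cfg <- synth_config(n_species = 1, n_replicates = 3, noise_sd = 0.004,
                      schedule = list(levels = c(100, 1000, 100),
                                      durations = c(600, 3000, 3600),
                                      dt = 60),
                      seed = 9)
  truth <- list(g_low = 0.1, g_high = 0.3, tau_open = 600, tau_close = 1200,
                lambda_open = 1.5, lambda_close = 2)
  tcs <- gen_timecourse_set(truth, cfg)
  segs <- lapply(tcs, curate_timecourse)
  opens <- lapply(segs, `[[`, 1L)
  closes <- lapply(segs, `[[`, 2L)
  f_open <- fit_set(opens, "cdweibull", fit_config(seed = 91))
  f_close <- fit_set(closes, "cdweibull", fit_config(seed = 92))
  m <- derive_metrics(f_open, f_close, id = "roundtrip")
  expect_lt(abs(m$tau_open - 10) / 10, 0.10)
  expect_lt(abs(m$tau_close - 20) / 20, 0.10)
  expect_lt(abs(m$tau_ratio - 0.5), 0.1)
})
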