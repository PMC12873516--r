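test_that("light steps are detected with direction and merged ramps", {
  tt <- seq(0, 3600, 30)
  flat <- gs_timecourse(tt, rep(1000, length(tt)), rep(0.2, length(tt)))
  expect_identical(nrow(detect_light_steps(flat)), 0L)

  one <- gs_timecourse(tt, ifelse(tt < 600, 100, 1000), rep(0.2, length(tt)))
  st <- detect_light_steps(one)
  expect_identical(nrow(st), 1L)
  expect_identical(st$direction, "INCREASE")
  expect_equal(st$switch_time, 600)

  two <- gs_timecourse(tt, ifelse(tt < 600, 100, ifelse(tt < 2400, 1000, 100)),
                       rep(0.2, length(tt)))
  st2 <- detect_light_steps(two)
  expect_identical(st2$direction, c("INCREASE", "DECREASE"))

  # sub-threshold fluctuation is not a step
  small <- gs_timecourse(tt, 1000 + 20 * sin(tt / 500), rep(0.2, length(tt)))
  expect_identical(nrow(detect_light_steps(small, min_delta = 50)), 0L)
})

test_that("segments end at the next switch or the series end", {
  # slow response: steady state is not reached, so the segment runs to the
  # series end (and is flagged accordingly)
  slow <- make_step_series(tau = 1500, lam = 1, t_post = 3600)
  st_s <- detect_light_steps(slow)
  seg_s <- extract_segment(slow, st_s[1, ], st_s)
  expect_equal(max(seg_s$data$time), 3600)
  expect_true("no_steady_state" %in% seg_s$flags)

  # fast response: steady state reached early; tail trimmed to ~5 min of
  # steady-state data
  tc <- make_step_series(tau = 300, lam = 1.5, t_post = 3600)
  steps <- detect_light_steps(tc)
  seg <- extract_segment(tc, steps[1, ], steps)
  expect_true(seg$usable)
  expect_gte(seg$steady_tail_duration, 300)
  expect_lte(max(seg$data$time), 3600)

  # two-step series: first segment must stop at the second switch
  tt <- seq(0, 7200, 30)
  ppfd <- ifelse(tt < 600, 100, ifelse(tt < 3600, 1000, 100))
  p_open <- kinetic_params("cdweibull", 0.1, 0.3, 300, lam = 1.5)
  gs <- ifelse(tt < 600, 0.1,
        ifelse(tt < 3600, predict_gs(p_open, pmax(tt - 600, 0)),
               0.3 * exp(-(tt - 3600) / 400) + 0.1 * (1 - exp(-(tt - 3600) / 400))))
  tc2 <- gs_timecourse(tt, ppfd, gs)
  steps2 <- detect_light_steps(tc2)
  seg1 <- extract_segment(tc2, steps2[1, ], steps2)
  expect_lt(max(seg1$data$time), 3600)

  # too-short segment is flagged
  short <- gs_timecourse(seq(0, 3600, 30), ifelse(seq(0, 3600, 30) < 3450, 100, 1000),
                         rep(0.1, 121))
  st3 <- detect_light_steps(short)
  seg3 <- extract_segment(short, st3[1, ], st3)
  expect_false(seg3$usable)
  expect_true("too_short" %in% seg3$flags)
})

test_that("secondary drift after a reached steady state is cut", {
  tt <- seq(-300, 5400, 30)
  # fast response (tau = 200) reaches plateau, then a linear drift begins
  p <- kinetic_params("cdweibull", 0.1, 0.3, 200, lam = 1)
  gs <- ifelse(tt < 0, 0.1, predict_gs(p, pmax(tt, 0)))
  drift <- tt > 3600
  gs[drift] <- gs[drift] + 3e-5 * (tt[drift] - 3600)
  tc <- gs_timecourse(tt, ifelse(tt < 0, 100, 1000), gs)
  steps <- detect_light_steps(tc)
  seg <- extract_segment(tc, steps[1, ], steps)
  expect_true("secondary_drift_cut" %in% seg$flags ||
              max(seg$data$time) < max(tt))
  expect_lt(max(seg$data$time), 4500)
  expect_gte(seg$steady_tail_duration, 300)
})

test_that("post-switch spike artifacts are stripped exactly", {
  tc <- make_step_series(tau = 600, lam = 1.5)
  # inject a 2-sample spike right after the switch
  post <- which(tc$time >= 0)
  spike_ids <- post[1:2]
  tc$gs[spike_ids] <- tc$gs[spike_ids] + 0.05
  steps <- detect_light_steps(tc)
  seg <- strip_transients(extract_segment(tc, steps[1, ], steps))
  excl <- which(seg$data$point_label == "EXCLUDED_TRANSIENT")
  expect_identical(seg$data$time[excl], tc$time[spike_ids])

  # clean series: nothing excluded
  tc0 <- make_step_series(tau = 600, lam = 1.5)
  seg0 <- strip_transients(extract_segment(tc0, steps[1, ], steps))
  expect_identical(sum(seg0$data$point_label == "EXCLUDED_TRANSIENT"), 0L)

  # artifact that never returns near the pre-step level: unusable
  tc_bad <- make_step_series(tau = 600, lam = 1.5)
  postb <- which(tc_bad$time >= 0)
  tc_bad$gs[postb] <- tc_bad$gs[postb] + 0.2   # offset the whole response
  segb <- strip_transients(extract_segment(tc_bad, steps[1, ], steps))
  expect_false(segb$usable)
  expect_true("transient_never_recovered" %in% segb$flags)
})

test_that("transient exclusion is a prefix and curation is idempotent", {
  tc <- make_step_series(tau = 600, lam = 1.5, noise_sd = 0.002, seed = 5)
  post <- which(tc$time >= 0)
  tc$gs[post[1:3]] <- tc$gs[post[1:3]] + c(0.06, 0.04, 0.02)
  steps <- detect_light_steps(tc)
  seg1 <- strip_transients(extract_segment(tc, steps[1, ], steps))
  lab1 <- seg1$data$point_label
  post_lab <- lab1[seg1$data$time >= 0]
  excl <- post_lab == "EXCLUDED_TRANSIENT"
  if (any(excl)) {
    expect_identical(which(excl), seq_len(sum(excl)))  # prefix property
  }
  seg2 <- strip_transients(seg1)
  expect_identical(seg2$data$point_label, lab1)
})

test_that("time-course CSVs round-trip through alias-aware reading", {
  tc <- make_step_series(tau = 600, lam = 1.5, noise_sd = 0.001, seed = 9)
  f <- tempfile(fileext = ".csv")
  write_timecourse_csv(tc, f)
  back <- read_timecourse_csv(f)
  expect_equal(back$time, tc$time)
  expect_equal(back$gs, tc$gs)

  # foreign column spellings
  f2 <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(Time = tc$time, Qin = tc$ppfd, gsw = tc$gs),
                   f2, row.names = FALSE)
  back2 <- read_timecourse_csv(f2)
  expect_equal(back2$gs, tc$gs)

  # corrupt numeric cell fails with a row-level message
  lines <- readLines(f2)
  lines[10] <- sub("^[^,]*", "oops", lines[10])
  writeLines(lines, f2)
  expect_error(read_timecourse_csv(f2), "row")
})
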