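# Synthetic study generator: trees, anatomy, kinetic traits and noisy gs
# time courses with the statistical structure the cross-species analysis
# assumes, carrying full ground truth for every stage.

#' Synthetic study configuration
#'
#' Defaults emulate the conditions of the cross-species compilation this
#' package analyses: a step light schedule of 30 min low light
#' (100 umol m-2 s-1), 60 min high (1000), 60 min low again, sampled every
#' 30 s (long enough to reach steady state at the slowest default time
#' constants); CDWeibull-shaped responses with asymmetric opening/closing
#' time constants; Gaussian measurement noise (sd 0.005 mol m-2 s-1);
#' optional post-switch transient spike artifacts; species anatomy with a
#' negative log SD - log SSl correlation (-0.6), zero-inflated rSD (29%
#' hypostomatous) with positive part up to about 2.2, a kidney/dumbbell
#' guard-cell mixture clustered by clade; anatomy-to-kinetics effects on
#' the log scale with kidney-type opening time constants averaging tens of
#' minutes and dumbbell types several-fold faster; and Brownian
#' phylogenetic signal scaled by Pagel's lambda.
#'
#' @param n_species number of species.
#' @param n_replicates curves per set.
#' @param schedule list: `levels` (PPFD), `durations` (s), `dt` (s).
#' @param tau_open_range,tau_close_range time-constant ranges (s) used when
#'   drawing species kinetics (draws are clamped into these).
#' @param lambda_range CDWeibull shape range.
#' @param noise_sd residual gs noise sd (mol m-2 s-1).
#' @param artifact list: `amplitude` (mol m-2 s-1), `n_points` (samples
#'   after each switch); amplitude 0 disables.
#' @param anatomy list: `ssl_meanlog`, `ssl_sdlog`, `sd_meanlog`,
#'   `sd_sdlog`, `log_cor` (SD-SSl log correlation), `rsd_zero_frac`,
#'   `rsd_max`, `db_frac` (dumbbell fraction).
#' @param effects list of log-scale coefficients linking anatomy to
#'   kinetics: `tau_open_intercept` (log s, kidney), `b_sd`, `b_ssl`,
#'   `b_gc_open`, `tau_close_intercept`, `b_gc_close`, `sd_resid` (iid log
#'   sd), `sd_phylo` (Brownian sd), `pagel_lambda`.
#' @param seed mandatory integer seed.
#' @return list of class `"synth_config"`.
#' @export
synth_config <- function(n_species = 24L, n_replicates = 3L,
                         schedule = list(levels = c(100, 1000, 100),
                                         durations = c(1800, 3600, 3600),
                                         dt = 30),
                         tau_open_range = c(60, 3600),
                         tau_close_range = c(40, 3600),
                         lambda_range = c(0.8, 3),
                         noise_sd = 0.005,
                         artifact = list(amplitude = 0, n_points = 2L),
                         anatomy = list(ssl_meanlog = log(29), ssl_sdlog = 0.35,
                                        sd_meanlog = log(220), sd_sdlog = 0.6,
                                        log_cor = -0.6, rsd_zero_frac = 0.29,
                                        rsd_max = 2.16, db_frac = 0.3),
                         effects = list(tau_open_intercept = log(28 * 60),
                                        b_sd = -0.15, b_ssl = 0.3,
                                        b_gc_open = log(7 / 28),
                                        tau_close_intercept = log(20 * 60),
                                        b_gc_close = log(8.9 / 20),
                                        sd_resid = 0.25, sd_phylo = 0.3,
                                        pagel_lambda = 1),
                         seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(abs(anatomy$log_cor) < 1,
            anatomy$rsd_zero_frac >= 0, anatomy$rsd_zero_frac <= 1,
            effects$pagel_lambda >= 0, effects$pagel_lambda <= 1)
  structure(list(
    n_species = as.integer(n_species), n_replicates = as.integer(n_replicates),
    schedule = schedule, tau_open_range = tau_open_range,
    tau_close_range = tau_close_range, lambda_range = lambda_range,
    noise_sd = noise_sd, artifact = artifact, anatomy = anatomy,
    effects = effects, seed = as.integer(seed)
  ), class = "synth_config")
}

#' Simulate a pure-birth ultrametric phylogeny
#'
#' @param n_species number of tips (>= 2); tips are labelled `sp01`,
#'   `sp02`, ...
#' @param seed integer seed (same seed, same Newick string).
#' @return a [prepare_tree()] result.
#' @export
gen_phylogeny <- function(n_species, seed) {
  stopifnot(n_species >= 2L)
  set.seed(as.integer(seed))
  tree <- ape::rphylo(n_species, birth = 1, death = 0)
  tree$tip.label <- sprintf("sp%02d", seq_len(n_species))
  prepare_tree(tree)
}

#' Generate a species trait table with hidden truth
#'
#' Draws log-SSl and log-SD jointly normal with the configured negative
#' correlation; assigns dumbbell guard cells to one clade (mimicking the
#' lineage clustering of grasses); draws zero-inflated rSD; and sets
#' kinetic traits as a linear function of log anatomy plus a Brownian
#' phylogenetic deviation (Pagel-lambda scaled) and iid noise. The full
#' generating record is attached as attribute `"truth"`.
#'
#' @param phylo a [prepare_tree()] result (e.g. from [gen_phylogeny()]).
#' @param cfg a [synth_config()].
#' @return trait table (one row per species): anatomy columns as in
#'   [anatomy_record()] plus `tau_open`, `tau_close` (min), `slmax_open`,
#'   `slmax_close`, `lambda_open`, `lambda_close`, `dgs_open`.
#' @export
gen_traits <- function(phylo, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 1L)
  sp <- phylo$tree$tip.label
  n <- length(sp)
  an <- cfg$anatomy
  ef <- cfg$effects

  Sig <- matrix(c(an$ssl_sdlog^2,
                  an$log_cor * an$ssl_sdlog * an$sd_sdlog,
                  an$log_cor * an$ssl_sdlog * an$sd_sdlog,
                  an$sd_sdlog^2), 2)
  lx <- MASS::mvrnorm(n, mu = c(an$ssl_meanlog, an$sd_meanlog), Sigma = Sig)
  ssl <- exp(lx[, 1L])
  sd_total <- exp(lx[, 2L])

  # dumbbell guard cells cluster in one clade: take the subtree closest to
  # the target fraction
  target <- round(an$db_frac * n)
  gc_type <- rep("K", n)
  if (target >= 1L) {
    subs <- ape::subtrees(phylo$tree)
    sizes <- vapply(subs, function(s) length(s$tip.label), 0L)
    cand <- which(sizes < n)
    best <- cand[which.min(abs(sizes[cand] - target))]
    gc_type[sp %in% subs[[best]]$tip.label] <- "DB"
  }

  is_zero <- stats::runif(n) < an$rsd_zero_frac
  rsd <- ifelse(is_zero, 0, stats::runif(n, 0.02, an$rsd_max))
  sd_adaxial <- sd_total * rsd / (1 + rsd)
  sd_abaxial <- sd_total - sd_adaxial

  # Brownian deviations with Pagel-lambda scaled correlation
  lam_p <- ef$pagel_lambda
  C <- phylo$corr[sp, sp]
  Cl <- lam_p * C + (1 - lam_p) * diag(n)
  bm_open <- drop(MASS::mvrnorm(1, rep(0, n), ef$sd_phylo^2 * Cl))
  bm_close <- drop(MASS::mvrnorm(1, rep(0, n), ef$sd_phylo^2 * Cl))

  db <- as.numeric(gc_type == "DB")
  zs <- function(v) v - mean(v)
  ltau_open <- ef$tau_open_intercept + ef$b_sd * zs(lx[, 2L]) +
    ef$b_ssl * zs(lx[, 1L]) + ef$b_gc_open * db + bm_open +
    stats::rnorm(n, 0, ef$sd_resid)
  ltau_close <- ef$tau_close_intercept + ef$b_sd * zs(lx[, 2L]) +
    ef$b_ssl * zs(lx[, 1L]) + ef$b_gc_close * db + bm_close +
    stats::rnorm(n, 0, ef$sd_resid)
  tau_open <- pmin(pmax(exp(ltau_open), cfg$tau_open_range[1L]), cfg$tau_open_range[2L])
  tau_close <- pmin(pmax(exp(ltau_close), cfg$tau_close_range[1L]), cfg$tau_close_range[2L])
  lambda_open <- stats::runif(n, cfg$lambda_range[1L], cfg$lambda_range[2L])
  lambda_close <- stats::runif(n, cfg$lambda_range[1L], cfg$lambda_range[2L])
  dgs_open <- exp(stats::rnorm(n, log(0.15), 0.3))

  slm <- function(tau, lam, dg) {
    vapply(seq_len(n), function(i) {
      as.numeric(slmax(kinetic_params("cdweibull", g_i = 0, g_f = dg[i],
                                      tau = tau[i], lam = lam[i])))
    }, 0.0)
  }
  tab <- anatomy_record(data.frame(
    species = sp, genotype = sp, gc_type = gc_type,
    ssl = ssl, ssw = ssl * 0.55,
    sd_abaxial = sd_abaxial, sd_adaxial = sd_adaxial,
    stringsAsFactors = FALSE
  ))
  tab$tau_open <- tau_open / 60
  tab$tau_close <- tau_close / 60
  tab$lambda_open <- lambda_open
  tab$lambda_close <- lambda_close
  tab$dgs_open <- dgs_open
  tab$slmax_open <- slm(tau_open, lambda_open, dgs_open)
  tab$slmax_close <- slm(tau_close, lambda_close, dgs_open)
  attr(tab, "truth") <- list(
    log_anatomy = lx, bm_open = bm_open, bm_close = bm_close,
    tau_open_s = tau_open, tau_close_s = tau_close,
    is_zero = is_zero, config = cfg
  )
  tab
}

#' Generate a set of noisy gs time courses for one genotype
#'
#' CDWeibull trajectories following the configured step light schedule
#' (opening at the first switch, closing at the second), with Gaussian
#' noise and an optional post-switch spike artifact. The generating
#' parameters and artifact indices are attached as attribute `"truth"` of
#' each series.
#'
#' @param truth list with `g_low`, `g_high`, `tau_open`, `tau_close` (s),
#'   `lambda_open`, `lambda_close`; scalar fields are shared across
#'   replicates, vectors (length `n_replicates`) give per-curve values.
#' @param cfg a [synth_config()]; `n_replicates`, `schedule`, `noise_sd`
#'   and `artifact` are used.
#' @param seed overrides `cfg$seed` when given.
#' @return list of [gs_timecourse()] objects, one per replicate.
#' @export
gen_timecourse_set <- function(truth, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(as.integer(seed %||% (cfg$seed + 2L)))
  sch <- cfg$schedule
  t_switch1 <- sch$durations[1L]
  t_switch2 <- sch$durations[1L] + sch$durations[2L]
  t_end <- sum(sch$durations)
  tt <- seq(0, t_end, by = sch$dt)
  ppfd <- ifelse(tt < t_switch1, sch$levels[1L],
          ifelse(tt < t_switch2, sch$levels[2L], sch$levels[3L]))
  rep_field <- function(v, k) if (length(v) >= k) v[k] else v[1L]

  lapply(seq_len(cfg$n_replicates), function(k) {
    g_lo <- rep_field(truth$g_low, k)
    g_hi <- rep_field(truth$g_high, k)
    p_open <- kinetic_params("cdweibull", g_i = g_lo, g_f = g_hi,
                             tau = rep_field(truth$tau_open, k),
                             lam = rep_field(truth$lambda_open, k))
    p_close <- kinetic_params("cdweibull", g_i = g_hi, g_f = g_lo,
                              tau = rep_field(truth$tau_close, k),
                              lam = rep_field(truth$lambda_close, k))
    gs <- numeric(length(tt))
    pre <- tt < t_switch1
    mid <- tt >= t_switch1 & tt < t_switch2
    post <- tt >= t_switch2
    gs[pre] <- g_lo
    gs[mid] <- predict_gs(p_open, tt[mid] - t_switch1)
    # closing starts from wherever opening got to
    g_reached <- predict_gs(p_open, t_switch2 - t_switch1)
    p_close2 <- kinetic_params("cdweibull", g_i = g_reached, g_f = g_lo,
                               tau = p_close$tau, lam = p_close$lam)
    gs[post] <- predict_gs(p_close2, tt[post] - t_switch2)

    art_idx <- integer(0)
    if (cfg$artifact$amplitude != 0 && cfg$artifact$n_points > 0L) {
      for (ts in c(t_switch1, t_switch2)) {
        first <- which(tt >= ts)[1L]
        ids <- first:min(length(tt), first + cfg$artifact$n_points - 1L)
        gs[ids] <- gs[ids] + cfg$artifact$amplitude
        art_idx <- c(art_idx, ids)
      }
    }
    gs <- pmax(gs + stats::rnorm(length(gs), 0, cfg$noise_sd), 0)
    tc <- gs_timecourse(tt, ppfd, gs, source_id = sprintf("rep%02d", k))
    attr(tc, "truth") <- list(p_open = p_open, p_close = p_close2,
                              artifact_indices = art_idx,
                              switch_times = c(t_switch1, t_switch2))
    tc
  })
}

#' Generate plain fitting segments (time since switch, gs)
#'
#' Lightweight generator for fitting tests: `n_curves` CDWeibull responses
#' on a shared time grid with iid Gaussian noise; no schedule, no
#' artifacts.
#'
#' @param n_curves curves in the set.
#' @param tau,lam shared truth (s, dimensionless).
#' @param g_i,g_f endpoints; vectors recycle over curves.
#' @param times sampling times (s since switch).
#' @param noise_sd Gaussian noise sd.
#' @param seed integer seed.
#' @param model generating model (default `"cdweibull"`).
#' @return list of data frames `(time, gs)`.
#' @export
gen_segments <- function(n_curves = 3L, tau = 600, lam = 1.5,
                         g_i = 0.1, g_f = 0.3,
                         times = seq(0, 3600, by = 30),
                         noise_sd = 0.005, seed = 1L,
                         model = c("cdweibull", "exponential", "sigmoidal")) {
  model <- match.arg(model)
  set.seed(as.integer(seed))
  g_i <- rep_len(g_i, n_curves)
  g_f <- rep_len(g_f, n_curves)
  lapply(seq_len(n_curves), function(k) {
    p <- kinetic_params(model, g_i = g_i[k], g_f = g_f[k], tau = tau,
                        lam = if (model == "exponential") NULL else lam)
    data.frame(time = times,
               gs = pmax(predict_gs(p, times) + stats::rnorm(length(times), 0, noise_sd), 0))
  })
}
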