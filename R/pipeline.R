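# Pipeline orchestration: simulate -> curate -> fit -> metrics -> stats ->
# phylo, with a JSON manifest recording config, seeds and output hashes.

#' Default pipeline configuration
#'
#' @param out_dir output directory.
#' @param seed master seed; every stage derives its own from it.
#' @param stages stages to run, in order; `"all"` expands to the full
#'   sequence `simulate, curate, fit, metrics, stats, phylo`.
#' @param n_species species in the simulated study.
#' @param n_replicates curves per set.
#' @param model response model fitted to the curated sets.
#' @param fit sampler settings passed to [fit_config()] (list).
#' @param synth overrides passed to [synth_config()] (list).
#' @param phylo_responses response columns ranked in the phylo stage.
#' @param phylo_max_candidates cap on the number of candidates fitted per
#'   response (the full 2047 by default).
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir = "stomkin_out", seed = 1L,
                            stages = "all", n_species = 8L,
                            n_replicates = 3L, model = "cdweibull",
                            fit = list(), synth = list(),
                            phylo_responses = "tau_open",
                            phylo_max_candidates = 2047L) {
  all_stages <- c("simulate", "curate", "fit", "metrics", "stats", "phylo")
  if (identical(stages, "all")) stages <- all_stages
  if (!all(stages %in% all_stages)) {
    stop("unknown stage(s): ", paste(setdiff(stages, all_stages), collapse = ", "),
         call. = FALSE)
  }
  structure(list(
    out_dir = out_dir, seed = as.integer(seed), stages = stages,
    n_species = as.integer(n_species), n_replicates = as.integer(n_replicates),
    model = model, fit = fit, synth = synth,
    phylo_responses = phylo_responses,
    phylo_max_candidates = as.integer(phylo_max_candidates)
  ), class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

.md5_of <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, force = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in order. Each stage writes its outputs
#' under `cfg$out_dir` and later stages re-read them from disk when the
#' in-memory state is absent, so a run is resumable stage by stage. A
#' `manifest.json` records the package version, config hash, per-stage
#' seeds and the MD5 of every output file.
#'
#' @param cfg a [pipeline_config()] or a YAML path.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- new.env(parent = emptyenv())
  manifest <- list(
    package = "stomkin",
    version = as.character(utils::packageVersion("stomkin")),
    seed = cfg$seed, config_hash = .md5_of(unclass(cfg)),
    stages = list()
  )
  t_all <- Sys.time()
  for (stage in cfg$stages) {
    t0 <- Sys.time()
    files <- switch(stage,
      simulate = .stage_simulate(cfg, st),
      curate   = .stage_curate(cfg, st),
      fit      = .stage_fit(cfg, st),
      metrics  = .stage_metrics(cfg, st),
      stats    = .stage_stats(cfg, st),
      phylo    = .stage_phylo(cfg, st)
    )
    manifest$stages[[stage]] <- list(
      files = as.list(tools::md5sum(files)),
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
    )
    message(sprintf("[stomkin] stage %-8s done (%.1fs, %d file(s))",
                    stage, manifest$stages[[stage]]$seconds, length(files)))
  }
  manifest$total_seconds <- round(as.numeric(difftime(Sys.time(), t_all, units = "secs")), 2)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(state = as.list(st), manifest = manifest))
}

.synth_cfg <- function(cfg) {
  do.call(synth_config, utils::modifyList(
    list(n_species = cfg$n_species, n_replicates = cfg$n_replicates,
         seed = cfg$seed),
    cfg$synth
  ))
}

.stage_simulate <- function(cfg, st) {
  sc <- .synth_cfg(cfg)
  st$phylo <- gen_phylogeny(sc$n_species, seed = cfg$seed)
  st$traits <- gen_traits(st$phylo, sc)
  tc_dir <- file.path(cfg$out_dir, "timecourses")
  dir.create(tc_dir, showWarnings = FALSE)
  files <- character(0)
  st$timecourses <- list()
  for (i in seq_len(nrow(st$traits))) {
    sp <- st$traits$species[i]
    truth <- list(
      g_low = 0.08, g_high = 0.08 + st$traits$dgs_open[i],
      tau_open = st$traits$tau_open[i] * 60,
      tau_close = st$traits$tau_close[i] * 60,
      lambda_open = st$traits$lambda_open[i],
      lambda_close = st$traits$lambda_close[i]
    )
    tcs <- gen_timecourse_set(truth, sc, seed = cfg$seed + 100L + i)
    st$timecourses[[sp]] <- tcs
    for (k in seq_along(tcs)) {
      f <- file.path(tc_dir, sprintf("%s_rep%02d.csv", sp, k))
      write_timecourse_csv(tcs[[k]], f)
      files <- c(files, f)
    }
  }
  tree_f <- file.path(cfg$out_dir, "tree.nwk")
  ape::write.tree(st$phylo$tree, tree_f)
  traits_f <- file.path(cfg$out_dir, "traits_true.csv")
  utils::write.csv(st$traits, traits_f, row.names = FALSE)
  c(files, tree_f, traits_f)
}

.load_timecourses <- function(cfg, st) {
  if (!is.null(st$timecourses)) return()
  tc_dir <- file.path(cfg$out_dir, "timecourses")
  fs <- list.files(tc_dir, pattern = "\\.csv$", full.names = TRUE)
  if (!length(fs)) stop("stage 'curate': no time courses found; run 'simulate' or provide inputs",
                        call. = FALSE)
  st$timecourses <- list()
  for (f in fs) {
    sp <- sub("_rep[0-9]+\\.csv$", "", basename(f))
    st$timecourses[[sp]] <- c(st$timecourses[[sp]], list(read_timecourse_csv(f)))
  }
}

.stage_curate <- function(cfg, st) {
  .load_timecourses(cfg, st)
  st$segments <- lapply(st$timecourses, function(tcs) {
    lapply(tcs, curate_timecourse)
  })
  cur_dir <- file.path(cfg$out_dir, "curated")
  dir.create(cur_dir, showWarnings = FALSE)
  files <- character(0)
  for (sp in names(st$segments)) {
    for (k in seq_along(st$segments[[sp]])) {
      for (s in seq_along(st$segments[[sp]][[k]])) {
        seg <- st$segments[[sp]][[k]][[s]]
        f <- file.path(cur_dir, sprintf("%s_rep%02d_seg%d.csv", sp, k, s))
        write_timecourse_csv(seg$data, f)
        files <- c(files, f)
      }
    }
  }
  files
}

.stage_fit <- function(cfg, st) {
  if (is.null(st$segments)) .stage_curate(cfg, st)
  fc_base <- utils::modifyList(list(seed = cfg$seed), cfg$fit)
  st$fits <- list()
  for (sp in names(st$segments)) {
    by_dir <- list(INCREASE = list(), DECREASE = list())
    for (k in seq_along(st$segments[[sp]])) {
      for (seg in st$segments[[sp]][[k]]) {
        if (isTRUE(seg$usable)) {
          by_dir[[seg$step$direction]] <- c(by_dir[[seg$step$direction]], list(seg))
        }
      }
    }
    for (dr in names(by_dir)) {
      if (length(by_dir[[dr]]) >= 3L) {
        fc <- do.call(fit_config, utils::modifyList(
          fc_base, list(seed = cfg$seed + 10L * match(sp, names(st$segments)) +
                          match(dr, names(by_dir)))))
        st$fits[[paste(sp, dr, sep = ".")]] <-
          fit_set(by_dir[[dr]], model = cfg$model, cfg = fc,
                  set_id = paste(sp, dr, sep = "."))
      }
    }
  }
  f <- file.path(cfg$out_dir, "fit_results.csv")
  write_fit_results(st$fits, f)
  c(f, sub("\\.csv$", ".json", f))
}

.stage_metrics <- function(cfg, st) {
  if (is.null(st$fits)) stop("stage 'metrics': no fits in state; run 'fit' first",
                             call. = FALSE)
  sps <- unique(sub("\\.(INCREASE|DECREASE)$", "", names(st$fits)))
  st$metrics <- do.call(rbind, lapply(sps, function(sp) {
    fo <- st$fits[[paste0(sp, ".INCREASE")]]
    fc_ <- st$fits[[paste0(sp, ".DECREASE")]]
    ok <- function(f) !is.null(f) && f$converged
    derive_metrics(if (ok(fo)) fo, if (ok(fc_)) fc_, id = sp)
  }))
  if (is.null(st$traits)) {
    tf <- file.path(cfg$out_dir, "traits_true.csv")
    if (file.exists(tf)) st$traits <- utils::read.csv(tf)
  }
  tab <- st$metrics
  names(tab)[names(tab) == "id"] <- "species"
  if (!is.null(st$traits)) {
    anat <- st$traits[, intersect(c("species", "gc_type", "ssl", "ssw", "sd_abaxial",
                                    "sd_adaxial", "sd_total", "rsd", "rsd_class"),
                                  names(st$traits))]
    tab <- merge(anat, tab, by = "species", suffixes = c("_true", ""))
  }
  st$trait_table <- tab
  f <- file.path(cfg$out_dir, "trait_table.csv")
  utils::write.csv(tab, f, row.names = FALSE)
  f
}

.stage_stats <- function(cfg, st) {
  if (is.null(st$trait_table)) {
    f <- file.path(cfg$out_dir, "trait_table.csv")
    if (!file.exists(f)) stop("stage 'stats': no trait table; run 'metrics' first",
                              call. = FALSE)
    st$trait_table <- utils::read.csv(f)
  }
  tab <- st$trait_table
  files <- character(0)
  kin <- intersect(c("tau_open", "tau_close", "slmax_open", "slmax_close"), names(tab))
  summ <- summarize_traits(tab, traits = c("ssl", "sd_total", kin))
  f1 <- file.path(cfg$out_dir, "group_summaries.csv")
  utils::write.csv(summ, f1, row.names = FALSE)
  files <- c(files, f1)

  sma <- tryCatch(sma_fit(tab$sd_total, tab$ssl, log_transform = TRUE),
                  error = function(e) NULL)
  if (!is.null(sma)) {
    f2 <- file.path(cfg$out_dir, "sma_sd_ssl.csv")
    utils::write.csv(data.frame(slope = sma$slope, intercept = sma$intercept,
                                r2 = sma$r2, p = sma$p, n = sma$n), f2,
                     row.names = FALSE)
    files <- c(files, f2)
  }
  if ("tau_open" %in% names(tab) && "rsd_class" %in% names(tab) &&
      length(unique(stats::na.omit(tab$rsd_class))) >= 2) {
    kd <- kruskal_dunn(tab$tau_open, tab$rsd_class)
    f3 <- file.path(cfg$out_dir, "kruskal_dunn_tau_open.txt")
    writeLines(c(
      sprintf("Kruskal-Wallis H = %.3f, df = %d, p = %.4g", kd$H, kd$df, kd$p),
      "", "Compact letters (groups sharing a letter do not differ):",
      sprintf("  %-8s %s", names(kd$letters), kd$letters)
    ), f3)
    files <- c(files, f3)
  }
  files
}

.stage_phylo <- function(cfg, st) {
  if (is.null(st$trait_table)) .stage_stats(cfg, st)
  if (is.null(st$phylo)) {
    tf <- file.path(cfg$out_dir, "tree.nwk")
    if (!file.exists(tf)) stop("stage 'phylo': no tree; run 'simulate' or provide one",
                               call. = FALSE)
    st$phylo <- prepare_tree(tf, st$trait_table$species)
  }
  cands <- enumerate_candidates()
  if (cfg$phylo_max_candidates < length(cands)) {
    cands <- cands[seq_len(cfg$phylo_max_candidates)]
  }
  files <- character(0)
  for (resp in cfg$phylo_responses) {
    fits <- lapply(cands, fit_candidate, table = st$trait_table,
                   response = resp, phylo = st$phylo)
    ok <- !vapply(fits, is.null, TRUE)
    rk <- loo_rank(fits[ok])
    sel <- select_models(rk)
    f <- file.path(cfg$out_dir, sprintf("model_selection_%s.csv", resp))
    write_ranking_csv(sel, f)
    files <- c(files, f)
  }
  files
}
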