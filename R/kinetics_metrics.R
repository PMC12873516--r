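#' Derive species/genotype speed traits from directional fits
#'
#' Combines a converged opening fit and a converged closing fit into the
#' derived kinetic traits used in cross-species analysis: `tau` (min),
#' `slmax` (mol m-2 s-2), `t63` (min) and `dgs` (mol m-2 s-1) per
#' direction, plus the asymmetry ratio `tau_open / tau_close`. Values come
#' from posterior means via the closed-form metrics of the response model;
#' `dgs` is averaged over the set's curves. A missing direction yields a
#' partial record with `NA` fields.
#'
#' @param fit_open,fit_close [fit_set()] results (either may be `NULL`).
#' @param id identifier copied into the record.
#' @return one-row data frame: `id`, `tau_open`, `tau_close` (min),
#'   `slmax_open`, `slmax_close`, `t63_open`, `t63_close` (min),
#'   `tau_ratio`, `dgs_open`, `dgs_close`.
#' @export
derive_metrics <- function(fit_open = NULL, fit_close = NULL, id = "sp") {
  one <- function(fit) {
    if (is.null(fit)) return(list(tau = NA_real_, slmax = NA_real_,
                                  t63 = NA_real_, dgs = NA_real_))
    if (!fit$converged) warning("deriving metrics from a non-converged fit", call. = FALSE)
    ps <- lapply(seq_len(fit$n_curves), fit_params, fit = fit)
    dgs <- mean(vapply(ps, function(p) abs(p$g_f - p$g_i), 0.0))
    # tau/lam are shared; t63/slmax magnitudes use the set-mean endpoints
    p0 <- ps[[1L]]
    p_mean <- kinetic_params(fit$model, g_i = 0, g_f = dgs, tau = p0$tau, lam = p0$lam)
    list(tau = p0$tau / 60, slmax = as.numeric(slmax(p_mean)),
         t63 = t63(p_mean) / 60, dgs = dgs)
  }
  o <- one(fit_open); c_ <- one(fit_close)
  data.frame(
    id = id,
    tau_open = o$tau, tau_close = c_$tau,
    slmax_open = o$slmax, slmax_close = c_$slmax,
    t63_open = o$t63, t63_close = c_$t63,
    tau_ratio = o$tau / c_$tau,
    dgs_open = o$dgs, dgs_close = c_$dgs,
    stringsAsFactors = FALSE
  )
}

#' Classify the adaxial/abaxial stomatal density ratio
#'
#' The four functional rSD classes: `R0` (`rSD = 0`, hypostomatous),
#' `R_0_05` (`0 < rSD <= 0.5`), `R_05_1` (`0.5 < rSD <= 1`) and `R_GT1`
#' (`rSD > 1`), as an ordered factor. The binning converts the
#' zero-inflated ratio into ordered categorical data usable in regressions.
#'
#' @param rsd numeric vector of density ratios, `>= 0`.
#' @return ordered factor with levels `R0 < R_0_05 < R_05_1 < R_GT1`.
#' @export
classify_rsd <- function(rsd) {
  if (any(rsd < 0, na.rm = TRUE)) stop("rSD must be >= 0", call. = FALSE)
  cls <- ifelse(is.na(rsd), NA_character_,
         ifelse(rsd == 0, "R0",
         ifelse(rsd <= 0.5, "R_0_05",
         ifelse(rsd <= 1, "R_05_1", "R_GT1"))))
  factor(cls, levels = c("R0", "R_0_05", "R_05_1", "R_GT1"), ordered = TRUE)
}

#' Simulate composite two-surface leaf kinetics
#'
#' Amphistomatous leaves carry independent stomatal populations on the
#' adaxial and abaxial surfaces, with potentially distinct kinetics. The
#' leaf-level response is the stomatal-count-weighted average of the two
#' surface responses, with weights set by the density ratio rSD:
#' `w_ad = rSD / (1 + rSD)`, `w_ab = 1 / (1 + rSD)` (so `w_ad + w_ab = 1`
#' exactly and `rSD = 0` reproduces the abaxial curve). The composite t63
#' is located numerically on the weighted curve.
#'
#' @param ad,ab [kinetic_params()] for the adaxial and abaxial surfaces
#'   (CDWeibull).
#' @param rsd adaxial/abaxial stomatal density ratio, `>= 0`.
#' @param t_grid evaluation times (s); defaults to a dense grid over
#'   5 * max(tau).
#' @return list: `time`, `gs` (composite curve), `gs_ad`, `gs_ab`,
#'   `w_ad`, `w_ab`, `t63` (s, composite).
#' @export
simulate_composite_leaf <- function(ad, ab, rsd, t_grid = NULL) {
  stopifnot(inherits(ad, "kinetic_params"), inherits(ab, "kinetic_params"))
  if (rsd < 0) stop("rSD must be >= 0", call. = FALSE)
  if (is.null(t_grid)) {
    t_grid <- seq(0, 5 * max(ad$tau, ab$tau), length.out = 4000L)
  }
  w_ad <- rsd / (1 + rsd)
  w_ab <- 1 / (1 + rsd)
  gs_ad <- predict_gs(ad, t_grid)
  gs_ab <- predict_gs(ab, t_grid)
  gs <- w_ad * gs_ad + w_ab * gs_ab
  g_i <- gs[1L]
  g_f <- w_ad * ad$g_f + w_ab * ab$g_f
  dg <- g_f - g_i
  t63_comp <- NA_real_
  if (abs(dg) > 0) {
    comp <- (gs - g_i) / dg
    hit <- which(comp >= 1 - exp(-1))
    if (length(hit)) {
      i <- hit[1L]
      t63_comp <- if (i == 1L) t_grid[1L] else {
        t0 <- t_grid[i - 1L]; t1 <- t_grid[i]
        t0 + (t1 - t0) * ((1 - exp(-1)) - comp[i - 1L]) / (comp[i] - comp[i - 1L])
      }
    }
  }
  list(time = t_grid, gs = gs, gs_ad = gs_ad, gs_ab = gs_ab,
       w_ad = w_ad, w_ab = w_ab, t63 = t63_comp)
}

# column alias map for anatomy tables
.anat_aliases <- list(
  species = c("species", "sp"),
  genotype = c("genotype", "cultivar", "accession"),
  gc_type = c("gc_type", "gc", "guard_cell_type", "stomatal_type"),
  ssl = c("ssl", "stomatal_length", "length"),
  ssw = c("ssw", "stomatal_width", "width"),
  sd_abaxial = c("sd_abaxial", "sd_ab", "abaxial_density"),
  sd_adaxial = c("sd_adaxial", "sd_ad", "adaxial_density")
)

#' Read an anatomy table from CSV
#'
#' Expects per-surface stomatal densities (mm-2), guard-cell length/width
#' (um) and guard-cell type (K/DB), with configurable column aliases.
#' Derives `sd_total` (surfaces summed), `rsd` (adaxial/abaxial, 0 when the
#' adaxial surface is bare) and the ordered `rsd_class`.
#'
#' @param path CSV path.
#' @param aliases named list extending the built-in alias map.
#' @return data frame with standardized columns.
#' @export
read_anatomy_csv <- function(path, aliases = list()) {
  raw <- utils::read.csv(path, check.names = FALSE)
  amap <- .anat_aliases
  for (nm in names(aliases)) amap[[nm]] <- unique(c(amap[[nm]], tolower(aliases[[nm]])))
  out <- list()
  for (field in names(amap)) {
    hit <- which(tolower(names(raw)) %in% amap[[field]])
    out[[field]] <- if (length(hit)) raw[[hit[1L]]] else NA
  }
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  if (all(is.na(out$sd_abaxial))) stop("no abaxial density column found", call. = FALSE)
  out$sd_adaxial[is.na(out$sd_adaxial)] <- 0
  anatomy_record(out)
}

#' Standardize an anatomy table
#'
#' Validates densities and derives `sd_total = sd_abaxial + sd_adaxial`,
#' `rsd = sd_adaxial / sd_abaxial` and [classify_rsd()] classes.
#'
#' @param df data frame with at least `species`, `gc_type`, `ssl`,
#'   `sd_abaxial`, `sd_adaxial`.
#' @return the augmented data frame.
#' @export
anatomy_record <- function(df) {
  stopifnot(all(c("species", "sd_abaxial", "sd_adaxial") %in% names(df)))
  if (any(df$sd_abaxial < 0 | df$sd_adaxial < 0, na.rm = TRUE)) {
    stop("stomatal densities must be >= 0", call. = FALSE)
  }
  df$sd_total <- df$sd_abaxial + df$sd_adaxial
  df$rsd <- ifelse(df$sd_abaxial > 0, df$sd_adaxial / df$sd_abaxial,
                   ifelse(df$sd_adaxial == 0, NA_real_, Inf))
  df$rsd_class <- classify_rsd(ifelse(is.finite(df$rsd), df$rsd, NA))
  df
}

#' Species-level trait summaries
#'
#' Mean and SD of selected trait columns per grouping variable (default:
#' guard-cell type), averaging across species means (each species
#' contributes once regardless of its number of genotypes); set
#' `across = "observations"` to average raw rows instead.
#'
#' @param table trait table (one row per species or genotype).
#' @param traits character vector of numeric columns to summarize.
#' @param group grouping column (default `"gc_type"`).
#' @param across `"species"` (default) or `"observations"`.
#' @return data frame: group, trait, mean, sd, n.
#' @export
summarize_traits <- function(table, traits, group = "gc_type",
                             across = c("species", "observations")) {
  across <- match.arg(across)
  if (across == "species" && "species" %in% names(table)) {
    sp_means <- stats::aggregate(table[traits],
                                 by = table[c("species", group)],
                                 FUN = mean, na.rm = TRUE)
    table <- sp_means
  }
  out <- do.call(rbind, lapply(traits, function(tr) {
    agg_m <- stats::aggregate(table[[tr]], by = table[group],
                              FUN = mean, na.rm = TRUE)
    agg_s <- stats::aggregate(table[[tr]], by = table[group],
                              FUN = stats::sd, na.rm = TRUE)
    agg_n <- stats::aggregate(table[[tr]], by = table[group],
                              FUN = function(v) sum(!is.na(v)))
    data.frame(group = agg_m[[1L]], trait = tr, mean = agg_m$x,
               sd = agg_s$x, n = agg_n$x, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
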