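# Exhaustive anatomy -> kinetics regression model selection with optional
# phylogenetically structured species effects.

#' The eleven candidate regression terms
#'
#' Main effects of stomatal density (SD), stomatal length (SSl), the
#' ordered density-ratio class (rSD), guard-cell type (GC); all their
#' two-way interactions; and `lineage`, which toggles the Brownian-motion
#' phylogenetic covariance on the species effect.
#'
#' @return character vector of length 11.
#' @export
candidate_terms <- function() {
  c("SD", "SSl", "rSD", "GC",
    "SD:GC", "SSl:GC", "rSD:GC", "SD:rSD", "SSl:rSD", "SSl:SD",
    "lineage")
}

#' Enumerate all candidate models
#'
#' All non-empty subsets of the eleven terms of [candidate_terms()]:
#' exactly `2^11 - 1 = 2047` candidates. Non-hierarchical subsets
#' (interactions without their main effects) are deliberately included.
#'
#' @return list of character vectors, one per candidate.
#' @export
enumerate_candidates <- function() {
  terms <- candidate_terms()
  n <- length(terms)
  out <- vector("list", 2^n - 1L)
  for (i in seq_len(2^n - 1L)) {
    out[[i]] <- terms[bitwAnd(i, bitwShiftL(1L, 0:(n - 1L))) != 0L]
  }
  out
}

#' Prepare a phylogeny and its Brownian correlation
#'
#' Reads (or accepts) a rooted tree, sets zero-length branches to the
#' minimum nonzero branch length, prunes to the modelled species, and
#' computes the Brownian-motion correlation matrix (shared root-to-MRCA
#' path length over total depth, `ape::vcv(corr = TRUE)`).
#'
#' @param tree a Newick file path, Newick string, or `phylo` object.
#' @param species_list species to retain; members missing from the tips
#'   are reported in a warning and dropped from the result.
#' @return list of class `"stomkin_phylo"`: `tree` (repaired, pruned),
#'   `corr` (correlation matrix, species in row/col names), `dropped`.
#' @export
prepare_tree <- function(tree, species_list = NULL) {
  if (is.character(tree)) {
    tree <- if (file.exists(tree)) ape::read.tree(tree) else ape::read.tree(text = tree)
  }
  stopifnot(inherits(tree, "phylo"))
  bl <- tree$edge.length
  if (is.null(bl)) stop("tree has no branch lengths", call. = FALSE)
  nz <- bl[bl > 0]
  if (length(nz) == 0L) stop("tree has no nonzero branch lengths", call. = FALSE)
  tree$edge.length[bl <= 0] <- min(nz)
  dropped <- character(0)
  if (!is.null(species_list)) {
    dropped <- setdiff(species_list, tree$tip.label)
    if (length(dropped)) {
      warning(sprintf("species missing from tree tips (dropped): %s",
                      paste(dropped, collapse = ", ")), call. = FALSE)
    }
    keep <- intersect(species_list, tree$tip.label)
    tree <- ape::keep.tip(tree, keep)
  }
  corr <- ape::vcv(tree, corr = TRUE)
  structure(list(tree = tree, corr = corr, dropped = dropped),
            class = "stomkin_phylo")
}

# Design-matrix columns for a candidate term set. Continuous predictors are
# natural-log transformed; the ordered rSD class uses orthogonal polynomial
# contrasts (linear/quadratic/cubic); GC is treatment-coded (DB vs K).
.design_cols <- function(table, terms) {
  need <- unique(unlist(strsplit(setdiff(terms, "lineage"), ":", fixed = TRUE)))
  base <- list()
  if ("SD" %in% need) base$SD <- log(table$sd_total)
  if ("SSl" %in% need) base$SSl <- log(table$ssl)
  if ("GC" %in% need) base$GC <- as.numeric(table$gc_type == "DB")
  if ("rSD" %in% need) {
    cls <- table$rsd_class
    if (!is.ordered(cls)) cls <- classify_rsd(table$rsd)
    cp <- stats::contr.poly(4)
    m <- cp[as.integer(cls), , drop = FALSE]
    colnames(m) <- paste0("rSD", c(".L", ".Q", ".C"))
    base$rSD <- m
  }
  cols <- list()
  for (tm in setdiff(terms, "lineage")) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1L]]
    if (length(parts) == 1L) {
      v <- base[[parts]]
      cols[[tm]] <- if (is.matrix(v)) v else matrix(v, ncol = 1, dimnames = list(NULL, tm))
    } else {
      a <- base[[parts[1L]]]; b <- base[[parts[2L]]]
      am <- if (is.matrix(a)) a else matrix(a, ncol = 1, dimnames = list(NULL, parts[1L]))
      bm <- if (is.matrix(b)) b else matrix(b, ncol = 1, dimnames = list(NULL, parts[2L]))
      prod <- do.call(cbind, lapply(seq_len(ncol(am)), function(i) {
        out <- am[, i] * bm
        colnames(out) <- paste(colnames(am)[i], colnames(bm), sep = ":")
        out
      }))
      cols[[tm]] <- prod
    }
  }
  if (length(cols)) do.call(cbind, cols) else NULL
}

# ML generalized least squares with a fixed correlation matrix.
.gls_ml <- function(X, y, V = NULL) {
  n <- length(y)
  if (is.null(V)) {
    Xw <- X; yw <- y; ldetV <- 0
  } else {
    U <- chol(V)
    Xw <- backsolve(U, X, transpose = TRUE)
    yw <- backsolve(U, y, transpose = TRUE)
    ldetV <- 2 * sum(log(diag(U)))
  }
  if (qr(Xw)$rank < ncol(Xw)) return(NULL)
  XtX_inv <- solve(crossprod(Xw))
  beta <- drop(XtX_inv %*% crossprod(Xw, yw))
  rw <- yw - Xw %*% beta
  rss <- sum(rw^2)
  sigma2 <- rss / n
  list(beta = beta, sigma2 = sigma2,
       fitted = drop(X %*% beta), resid = drop(y - X %*% beta),
       loglik = -0.5 * (n * log(2 * pi * sigma2) + n + ldetV),
       XtVinvX_inv = XtX_inv)
}

#' Fit one candidate anatomy-kinetics model
#'
#' Gaussian linear model of a natural-log response on the candidate's
#' design columns (continuous predictors log-transformed, ordered rSD via
#' polynomial contrasts, GC treatment-coded), estimated by maximum
#' likelihood GLS. When `lineage` is in the term set the species effect is
#' phylogenetically structured: the residual correlation is the
#' Brownian-motion matrix of `phylo`; otherwise species effects are iid
#' (identity correlation). The pseudo (Psi) R-squared is
#' `var(fitted) / (var(fitted) + var(residual))`.
#'
#' @param cand character vector of terms (one element of
#'   [enumerate_candidates()]).
#' @param table trait table with `species`, `sd_total`, `ssl`, `rsd` (or
#'   `rsd_class`), `gc_type` and the response column.
#' @param response response column name (e.g. `"tau_open"`); log
#'   transformed internally (set `log_response = FALSE` for a pre-logged
#'   column).
#' @param phylo a [prepare_tree()] result (required when `"lineage"` is in
#'   `cand`).
#' @param log_response log-transform the response (default TRUE).
#' @return list of class `"candidate_fit"`: `terms`, `beta`, `sigma2`,
#'   `loglik`, `pseudo_r2`, `elpd_i` (exact case-deletion pointwise LOO log
#'   densities), `looic`, `se_looic`, `n`, `rows` (row indices used); or a
#'   `"candidate_dropped"` marker (see [is_dropped()]) carrying the reason
#'   when the design is singular or the data insufficient.
#' @export
fit_candidate <- function(cand, table, response, phylo = NULL,
                          log_response = TRUE) {
  if ("lineage" %in% cand && is.null(phylo)) {
    stop("candidate includes 'lineage' but no phylogeny supplied", call. = FALSE)
  }
  y_raw <- table[[response]]
  Xc <- .design_cols(table, cand)
  ok <- is.finite(y_raw) & (!log_response | y_raw > 0)
  if (!is.null(Xc)) ok <- ok & stats::complete.cases(Xc) & apply(is.finite(as.matrix(Xc)), 1L, all)
  rows <- which(ok)
  y <- if (log_response) log(y_raw[rows]) else y_raw[rows]
  X <- cbind(`(Intercept)` = 1, if (!is.null(Xc)) Xc[rows, , drop = FALSE])
  n <- length(y)
  if (n <= ncol(X) + 1L) return(.candidate_dropped("too few complete cases"))
  V <- NULL
  if ("lineage" %in% cand) {
    sp <- as.character(table$species[rows])
    miss <- setdiff(sp, rownames(phylo$corr))
    if (length(miss)) return(.candidate_dropped("species missing from phylogeny"))
    V <- phylo$corr[sp, sp]
  }
  fit <- .gls_ml(X, y, V)
  if (is.null(fit)) return(.candidate_dropped("singular design"))
  elpd_i <- .exact_loo(X, y, V)
  psi_r2 <- stats::var(fit$fitted) /
    (stats::var(fit$fitted) + stats::var(fit$resid))
  structure(list(
    terms = cand, response = response, beta = fit$beta, sigma2 = fit$sigma2,
    loglik = fit$loglik, pseudo_r2 = psi_r2,
    elpd_i = elpd_i, looic = -2 * sum(elpd_i),
    se_looic = 2 * sqrt(length(elpd_i) * stats::var(elpd_i)),
    n = n, rows = rows, has_lineage = "lineage" %in% cand
  ), class = "candidate_fit")
}

# Exact case-deletion LOO for the Gaussian GLS model: for each i, refit on
# the remaining rows and evaluate the log predictive density of y_i under
# the conditional Gaussian given y_{-i} (accounting for the correlation V
# and for the uncertainty of the refitted coefficients).
.exact_loo <- function(X, y, V = NULL) {
  n <- length(y)
  vapply(seq_len(n), function(i) {
    Xm <- X[-i, , drop = FALSE]; ym <- y[-i]
    if (is.null(V)) {
      f <- .gls_ml(Xm, ym, NULL)
      mu <- drop(X[i, ] %*% f$beta)
      s2 <- f$sigma2 * (1 + drop(X[i, ] %*% f$XtVinvX_inv %*% X[i, ]))
    } else {
      Vm <- V[-i, -i, drop = FALSE]
      v <- V[-i, i]
      f <- .gls_ml(Xm, ym, Vm)
      Um <- chol(Vm)
      a <- backsolve(Um, backsolve(Um, v, transpose = TRUE))  # Vm^-1 v
      mu <- drop(X[i, ] %*% f$beta) + sum(a * (ym - Xm %*% f$beta))
      cond_var <- V[i, i] - sum(v * a)
      g <- X[i, ] - drop(crossprod(Xm, a))   # effective covariate
      s2 <- f$sigma2 * (cond_var + drop(g %*% f$XtVinvX_inv %*% g))
    }
    stats::dnorm(y[i], mu, sqrt(s2), log = TRUE)
  }, 0.0)
}

# Marker for candidates that could not be fitted (singular design, too few
# complete cases); carries the reason for the ranking report.
.candidate_dropped <- function(reason) {
  structure(list(dropped = TRUE, reason = reason), class = "candidate_dropped")
}

#' Is a candidate fit a dropped placeholder?
#' @param x a [fit_candidate()] result.
#' @return `TRUE` for dropped candidates; the reason is in `x$reason`.
#' @export
is_dropped <- function(x) inherits(x, "candidate_dropped") || is.null(x)

#' Rank candidate fits by leave-one-out criterion
#'
#' Ranks fitted candidates by LOOIC (lower is better out-of-sample).
#' Models whose LOOIC difference with the best is below twice the standard
#' error of the pointwise difference are flagged equivalent. Mirroring the
#' reporting convention of the meta-analysis, [select_models()] extracts
#' the best model and the most parsimonious equivalent models with and
#' without phylogeny.
#'
#' @param fits list of [fit_candidate()] results (NULL entries allowed and
#'   skipped); all must use identical rows.
#' @return data frame of class `"candidate_ranking"`, one row per fit:
#'   `rank`, `terms`, `n_terms`, `has_lineage`, `pseudo_r2`, `looic`,
#'   `se_looic`, `d_looic`, `se_diff`, `equivalent`.
#' @export
loo_rank <- function(fits) {
  fits <- Filter(Negate(is_dropped), fits)
  if (!length(fits)) stop("no successful fits", call. = FALSE)
  rows <- lapply(fits, `[[`, "rows")
  if (length(unique(vapply(rows, paste, "", collapse = ","))) != 1L) {
    stop("fits use different rows; refit on common complete cases", call. = FALSE)
  }
  looic <- vapply(fits, `[[`, 0.0, "looic")
  ord <- order(looic)
  best <- fits[[ord[1L]]]
  out <- do.call(rbind, lapply(seq_along(ord), function(r) {
    f <- fits[[ord[r]]]
    di <- f$elpd_i - best$elpd_i
    se_diff <- sqrt(length(di) * stats::var(di))
    data.frame(
      rank = r,
      terms = paste(f$terms, collapse = "+"),
      n_terms = length(f$terms),
      has_lineage = f$has_lineage,
      pseudo_r2 = f$pseudo_r2,
      looic = f$looic, se_looic = f$se_looic,
      d_looic = f$looic - best$looic, se_diff = se_diff,
      equivalent = (f$looic - best$looic) < max(2 * se_diff, 1e-9),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  class(out) <- c("candidate_ranking", "data.frame")
  out
}

#' Select best and parsimonious candidate models
#'
#' From a [loo_rank()] table: the global best model, the most parsimonious
#' (fewest-term) equivalent model containing `lineage`, and the most
#' parsimonious equivalent model without it.
#'
#' @param ranking a [loo_rank()] result.
#' @return data frame with rows `best`, `w_phylogeny`, `wo_phylogeny`
#'   (rows absent when no candidate qualifies).
#' @export
select_models <- function(ranking) {
  eq <- ranking[ranking$equivalent | ranking$rank == 1L, , drop = FALSE]
  pick <- function(df) df[order(df$n_terms, df$looic), , drop = FALSE][1, , drop = FALSE]
  out <- list(best = ranking[ranking$rank == 1L, , drop = FALSE])
  w <- eq[eq$has_lineage, , drop = FALSE]
  wo <- eq[!eq$has_lineage, , drop = FALSE]
  if (nrow(w)) out$w_phylogeny <- pick(w)
  if (nrow(wo)) out$wo_phylogeny <- pick(wo)
  res <- do.call(rbind, out)
  res$type <- rownames(res)
  rownames(res) <- NULL
  res[, c("type", setdiff(names(res), "type"))]
}

#' Write a candidate ranking shaped like a model-selection table
#'
#' One row per selected model with per-term inclusion flags, pseudo-R2,
#' LOOIC and its SE.
#'
#' @param selection a [select_models()] result (or any ranking rows).
#' @param path CSV output path.
#' @export
write_ranking_csv <- function(selection, path) {
  flags <- t(vapply(strsplit(selection$terms, "+", fixed = TRUE), function(tm) {
    as.integer(candidate_terms() %in% tm)
  }, integer(length(candidate_terms()))))
  colnames(flags) <- candidate_terms()
  utils::write.csv(cbind(selection, flags), path, row.names = FALSE)
  invisible(path)
}
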