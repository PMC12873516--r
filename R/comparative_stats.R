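#' Standardized major axis (SMA) regression
#'
#' Symmetric line fit for bivariate allometry: slope
#' `b = sign(r) * s_y / s_x`, intercept `ybar - b * xbar`. The slope
#' confidence interval uses the standard SMA construction
#' `b * (sqrt(B + 1) +/- sqrt(B))` with
#' `B = F(1, n-2; 1-alpha) * (1 - r^2) / (n - 2)`, and the test of the
#' fit is the test of the Pearson correlation (the SMA slope is never zero,
#' so "no relationship" is assessed through r).
#'
#' @param x,y numeric vectors.
#' @param log_transform natural-log both axes before fitting (default
#'   `FALSE`).
#' @param alpha CI level complement (default 0.05).
#' @return list of class `"sma_fit"`: `slope`, `intercept`, `r2`, `p`,
#'   `ci` (slope CI), `n`.
#' @export
sma_fit <- function(x, y, log_transform = FALSE, alpha = 0.05) {
  keep <- is.finite(x) & is.finite(y)
  if (log_transform) keep <- keep & x > 0 & y > 0
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 finite pairs", call. = FALSE)
  if (log_transform) { x <- log(x); y <- log(y) }
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) {
    stop(structure(class = c("stomkin_degenerate", "error", "condition"),
                   list(message = "zero variance in x or y", call = NULL)))
  }
  r <- stats::cor(x, y)
  b <- sign(r + (r == 0)) * sy / sx
  a <- mean(y) - b * mean(x)
  B <- stats::qf(1 - alpha, 1, n - 2) * (1 - r^2) / (n - 2)
  ci <- b * c(sqrt(B + 1) - sqrt(B), sqrt(B + 1) + sqrt(B))
  if (b < 0) ci <- rev(ci)
  p <- stats::cor.test(x, y)$p.value
  structure(list(slope = b, intercept = a, r2 = r^2, p = p,
                 ci = ci, n = n, log_transform = log_transform),
            class = "sma_fit")
}

#' @export
print.sma_fit <- function(x, ...) {
  cat(sprintf("SMA: slope %.4g [%.4g, %.4g], intercept %.4g, r2 = %.3f, p = %.3g, n = %d\n",
              x$slope, x$ci[1], x$ci[2], x$intercept, x$r2, x$p, x$n))
  invisible(x)
}

# Dunn pairwise z statistic between groups i and j on pooled ranks,
# with the Kruskal-Wallis tie correction.
.dunn_z <- function(rbar_i, rbar_j, n_i, n_j, N, tie_term) {
  (rbar_i - rbar_j) / sqrt((N * (N + 1) / 12 - tie_term) * (1 / n_i + 1 / n_j))
}

#' Kruskal-Wallis test with Dunn post hoc and compact letters
#'
#' Rank-based comparison of a trait across groups: the Kruskal-Wallis H
#' test (base [stats::kruskal.test()], tie-corrected), followed by Dunn's
#' pairwise z tests on the pooled ranks and a compact letter display in
#' which groups sharing a letter are not significantly different.
#'
#' @param values numeric trait values.
#' @param groups group labels (same length).
#' @param p_adjust multiple-testing adjustment for the Dunn p values:
#'   `"none"` (default, the common Dunn-test default) or any
#'   [stats::p.adjust()] method such as `"BH"`.
#' @param alpha significance level for the letter display.
#' @return list of class `"kruskal_dunn"`: `H`, `df`, `p` (global),
#'   `pairwise` (group1, group2, z, p, p_adj), `letters` (named character),
#'   `group_stats`.
#' @export
kruskal_dunn <- function(values, groups, p_adjust = "none", alpha = 0.05) {
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)

  kw <- stats::kruskal.test(values, groups)
  H <- unname(kw$statistic)
  p_glob <- kw$p.value
  if (!is.finite(H)) { H <- 0; p_glob <- 1 }  # all values tied
  N <- length(values)
  rk <- rank(values)
  tie_counts <- table(values)
  tie_term <- sum(tie_counts^3 - tie_counts) / (12 * (N - 1))
  rbar <- tapply(rk, groups, mean)
  nn <- tapply(rk, groups, length)
  lev <- levels(groups)

  pairs <- utils::combn(lev, 2L)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1L, k]; g2 <- pairs[2L, k]
    z <- .dunn_z(rbar[[g1]], rbar[[g2]], nn[[g1]], nn[[g2]], N, tie_term)
    data.frame(group1 = g1, group2 = g2, z = z,
               p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  }))
  pw$p[is.nan(pw$z)] <- 1
  pw$z[is.nan(pw$z)] <- 0
  pw$p_adj <- stats::p.adjust(pw$p, method = p_adjust)

  letters <- .compact_letters(lev, pw, rbar, alpha,
                              global_sig = p_glob < alpha)
  list(H = H, df = unname(kw$parameter), p = p_glob,
       pairwise = pw, letters = letters,
       group_stats = data.frame(group = lev, n = as.integer(nn),
                                mean_rank = as.numeric(rbar),
                                stringsAsFactors = FALSE))
}

# Insert-absorb compact letter display: walk groups in mean-rank order,
# grow maximal sets of mutually non-different groups, assign one letter per
# set. When the global test is not significant all groups share one letter.
.compact_letters <- function(lev, pw, rbar, alpha, global_sig = TRUE) {
  if (!global_sig) return(stats::setNames(rep("a", length(lev)), lev))
  differ <- matrix(FALSE, length(lev), length(lev), dimnames = list(lev, lev))
  for (k in seq_len(nrow(pw))) {
    if (pw$p_adj[k] < alpha) {
      differ[pw$group1[k], pw$group2[k]] <- TRUE
      differ[pw$group2[k], pw$group1[k]] <- TRUE
    }
  }
  ord <- lev[order(rbar)]
  sets <- list()
  for (g in ord) {
    placed <- FALSE
    for (s in seq_along(sets)) {
      if (!any(differ[g, sets[[s]]])) {
        sets[[s]] <- c(sets[[s]], g)
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1L]] <- g
  }
  # drop sets fully contained in another
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) for (j in seq_along(sets)) {
    if (i != j && keep[j] && all(sets[[i]] %in% sets[[j]]) &&
        length(sets[[i]]) < length(sets[[j]])) keep[i] <- FALSE
  }
  sets <- sets[keep]
  out <- stats::setNames(rep("", length(lev)), lev)
  for (s in seq_along(sets)) {
    for (g in sets[[s]]) out[g] <- paste0(out[g], letters[s])
  }
  out
}

#' PCA on standardized traits
#'
#' Principal component analysis on z-scored complete cases of the selected
#' columns, optionally split by a grouping column (the cross-species
#' analyses are run separately per guard-cell type). Loadings are
#' sign-fixed so the largest-magnitude loading of each component is
#' positive.
#'
#' @param table trait table.
#' @param columns numeric columns to include.
#' @param by optional grouping column; when given, one PCA per group level.
#' @return for a single PCA: list of class `"trait_pca"` with `loadings`,
#'   `scores`, `explained` (variance fractions), `n`, `flagged_n_lt_p`;
#'   with `by`, a named list of such objects.
#' @export
pca_traits <- function(table, columns, by = NULL) {
  if (!is.null(by)) {
    lv <- unique(as.character(table[[by]]))
    out <- lapply(lv, function(l) {
      pca_traits(table[table[[by]] == l, , drop = FALSE], columns)
    })
    names(out) <- lv
    return(out)
  }
  m <- as.matrix(table[columns])
  cc <- stats::complete.cases(m)
  m <- m[cc, , drop = FALSE]
  if (nrow(m) < 2L) stop("need at least 2 complete cases", call. = FALSE)
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  # determinism: largest |loading| positive per component
  for (j in seq_len(ncol(pc$rotation))) {
    i_max <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i_max, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  structure(list(
    loadings = pc$rotation, scores = pc$x,
    explained = pc$sdev^2 / sum(pc$sdev^2),
    sdev = pc$sdev, center = pc$center, scale = pc$scale,
    n = nrow(m), flagged_n_lt_p = nrow(m) < ncol(m)
  ), class = "trait_pca")
}

#' Leave-one-out Procrustes stability of a trait PCA
#'
#' Drops each row in turn, refits the PCA, Procrustes-aligns the retained
#' scores to the full-data scores (symmetric `vegan::procrustes`) and
#' reports the mean Procrustes correlation across deletions.
#'
#' @param table,columns as in [pca_traits()].
#' @param k number of components compared (default 2).
#' @param n_max cap on the number of deletions evaluated.
#' @return list: `mean_correlation`, `correlations`.
#' @export
pca_stability <- function(table, columns, k = 2L, n_max = 50L) {
  if (!requireNamespace("vegan", quietly = TRUE)) {
    stop("pca_stability requires the vegan package", call. = FALSE)
  }
  m <- as.matrix(table[columns])
  m <- m[stats::complete.cases(m), , drop = FALSE]
  full <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  idx <- seq_len(min(nrow(m), n_max))
  cors <- vapply(idx, function(i) {
    sub <- stats::prcomp(m[-i, , drop = FALSE], center = TRUE, scale. = TRUE)
    pr <- vegan::procrustes(full$x[-i, seq_len(k)], sub$x[, seq_len(k)],
                            symmetric = TRUE)
    sqrt(1 - pr$ss)
  }, 0.0)
  list(mean_correlation = mean(cors), correlations = cors)
}
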