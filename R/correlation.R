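#' @title Pearson correlation engine
#' @description
#' Pearson correlation over arbitrary feature-set pairs — expression vs
#' expression, expression vs methylation, expression vs protein — pooled
#' over all samples or per cohort, with pairwise-complete missing handling
#' (RPPA panels differ by cohort, so listwise deletion would discard data).
#' Two-sided p-values come from the t transform `t = r * sqrt((n-2)/(1-r^2))`
#' with n - 2 degrees of freedom. Correlation profiles can be grouped by
#' average-linkage hierarchical clustering on Euclidean distances.
#' @name correlation
NULL

#' Pearson correlation with a t-transform p-value
#'
#' @param x,y Numeric vectors; pairs with a missing member are dropped.
#' @return List with `r`, `p_value`, `n` (complete pairs). When fewer than
#'   3 complete pairs remain or either vector is constant, `r` and
#'   `p_value` are `NA` and a message states the reason.
#' @examples
#' pearson(c(1, 2, 3, 4), c(1, 3, 2, 4))$r  # 0.8
#' @export
pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3L) {
    message("pearson: fewer than 3 complete pairs")
    return(list(r = NA_real_, p_value = NA_real_, n = n))
  }
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    message("pearson: constant input")
    return(list(r = NA_real_, p_value = NA_real_, n = n))
  }
  r <- stats::cor(x, y)
  list(r = r, p_value = .r_to_p(r, n), n = n)
}

.r_to_p <- function(r, n) {
  # two-sided p from t = r * sqrt((n-2)/(1-r^2)), df = n - 2;
  # |r| = 1 maps to p = 0
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r) & n >= 3
  t <- abs(r[ok]) * sqrt((n[ok] - 2) / pmax(1 - r[ok]^2, 0))
  p[ok] <- 2 * stats::pt(t, df = n[ok] - 2, lower.tail = FALSE)
  p
}

.cor_block <- function(a, b) {
  # features x samples in; long data frame of r/p/n per feature pair out
  ta <- t(unclass(a)); tb <- t(unclass(b))
  r <- suppressWarnings(stats::cor(ta, tb, use = "pairwise.complete.obs"))
  n <- crossprod(!is.na(ta), !is.na(tb))
  # pairwise r of a constant-overlap pair is NA (sd zero) -> keep NA
  data.frame(feature_a = rep(rownames(a), times = nrow(b)),
             feature_b = rep(rownames(b), each = nrow(a)),
             r = as.vector(r), n = as.vector(n),
             p_value = as.vector(.r_to_p(as.vector(r), as.vector(n))),
             stringsAsFactors = FALSE)
}

#' Correlate every feature of one matrix with every feature of another
#'
#' Restricts both matrices to their shared samples, then computes Pearson
#' r, p and the complete-pair count for all (feature of `a`) x (feature of
#' `b`) pairs — over all shared samples (`pooled`) or within each cohort
#' (`per_cohort`). Pairs with fewer than 3 complete pairs are dropped (a
#' message reports how many). `significant` marks pairs with
#' `|r| >= r_min` and `p <= p_max`.
#'
#' @param a,b [omics_matrix()] objects with overlapping samples.
#' @param metadata Sample metadata; required for `per_cohort`.
#' @param mode `"pooled"` or `"per_cohort"`.
#' @param r_min,p_max Significance thresholds (defaults 0.3 and 0.05; the
#'   per-cohort methylation-expression analyses conventionally use
#'   `p_max = 0.01`).
#' @return Long data frame: `feature_a`, `feature_b`, `cohort`, `r`,
#'   `p_value`, `n`, `significant`.
#' @export
correlate_sets <- function(a, b, metadata = NULL,
                           mode = c("pooled", "per_cohort"),
                           r_min = 0.3, p_max = 0.05) {
  mode <- match.arg(mode)
  aligned <- align_samples(list(a, b))
  a <- aligned[[1]]; b <- aligned[[2]]
  groups <- if (mode == "pooled") list(pooled = colnames(a))
  else {
    if (is.null(metadata)) stop("per_cohort mode requires metadata")
    validate_metadata(metadata)
    md <- metadata[match(colnames(a), metadata$sample_id), ]
    split(colnames(a), md$cohort)
  }
  rows <- lapply(names(groups), function(g) {
    ids <- groups[[g]]
    block <- .cor_block(a[, ids, drop = FALSE], b[, ids, drop = FALSE])
    block$cohort <- g
    block
  })
  tab <- do.call(rbind, rows)
  too_few <- tab$n < 3L
  if (any(too_few))
    message("correlate_sets: dropped ", sum(too_few),
            " pair(s) with fewer than 3 complete observations")
  tab <- tab[!too_few, , drop = FALSE]
  tab$significant <- !is.na(tab$r) & abs(tab$r) >= r_min &
    !is.na(tab$p_value) & tab$p_value <= p_max
  tab <- tab[, c("feature_a", "feature_b", "cohort", "r", "p_value", "n",
                 "significant")]
  rownames(tab) <- NULL
  tab
}

#' Wide feature x feature r-grid from a correlation table
#'
#' @param correlations Output of [correlate_sets()] (one cohort level).
#' @return Numeric matrix of r values (rows = `feature_a`, columns =
#'   `feature_b`).
#' @export
correlation_grid <- function(correlations) {
  fa <- unique(correlations$feature_a)
  fb <- unique(correlations$feature_b)
  grid <- matrix(NA_real_, length(fa), length(fb),
                 dimnames = list(fa, fb))
  grid[cbind(match(correlations$feature_a, fa),
             match(correlations$feature_b, fb))] <- correlations$r
  grid
}

#' Cluster correlation profiles
#'
#' Agglomerative clustering of the rows of an r-grid with average linkage
#' and Euclidean distance, cut to exactly `k` clusters. Rows are sorted by
#' feature id before clustering so ties in merge order resolve
#' deterministically, and cluster labels are renumbered by first appearance
#' in lexicographic feature order. Missing r values are treated as 0 (a
#' message reports how many).
#'
#' @param grid Numeric feature x feature (or feature x profile) matrix.
#' @param k Number of clusters (1 <= k <= nrow(grid)).
#' @return Named integer vector of cluster labels in 1..k.
#' @export
cluster_profiles <- function(grid, k) {
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(grid)) stop("k exceeds the number of rows")
  grid <- grid[order(rownames(grid)), , drop = FALSE]
  n_missing <- sum(is.na(grid))
  if (n_missing) {
    message("cluster_profiles: ", n_missing, " missing r value(s) set to 0")
    grid[is.na(grid)] <- 0
  }
  hc <- stats::hclust(stats::dist(grid, method = "euclidean"),
                      method = "average")
  raw <- stats::cutree(hc, k = k)
  relabel <- match(raw, unique(raw))
  stats::setNames(relabel, rownames(grid))
}
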