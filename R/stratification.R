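#' @title Four-group methylation stratification
#' @description
#' Stratifies tumor samples by the methylation of one promoter probeset and
#' one gene-body probeset, each split at its central value (median by
#' default, mean optionally) over all included samples: Group 1 = promoter
#' low / body high, Group 2 = promoter low / body low, Group 3 = promoter
#' high / body high, Group 4 = promoter high / body low. When promoter
#' methylation represses and body methylation accompanies expression,
#' Group 1 is expected to show the highest and Group 4 the lowest
#' expression of the target gene. Expression differences between all six
#' group pairs are then tested with the signed fold change and Welch t.
#' @name stratification
NULL

#' Stratify samples into four methylation groups
#'
#' `low` means probe beta <= the split value, `high` means above it
#' (boundary samples go to `low`; deterministic and documented).
#'
#' @param methylation An [omics_matrix()] of beta values.
#' @param promoter_probe,body_probe Probeset ids; an absent probe is an
#'   error naming it.
#' @param center `"median"` (default) or `"mean"` — the split statistic,
#'   computed over all samples with both probes non-missing.
#' @param samples Optional sample subset to stratify (default: all columns).
#' @return A `stratified_groups` object: list with `assignment` (named
#'   integer vector in 1..4), `split_value_promoter`, `split_value_body`,
#'   `promoter_probe`, `body_probe`, `center`, `n_unassigned` (samples
#'   missing either probe).
#' @export
stratify <- function(methylation, promoter_probe, body_probe,
                     center = c("median", "mean"), samples = NULL) {
  center <- match.arg(center)
  for (p in c(promoter_probe, body_probe))
    if (!p %in% rownames(methylation))
      stop("probe not present in methylation matrix: ", p)
  if (is.null(samples)) samples <- colnames(methylation)
  pm <- unclass(methylation)[promoter_probe, samples]
  bd <- unclass(methylation)[body_probe, samples]
  ok <- !is.na(pm) & !is.na(bd)
  if (sum(ok) < 4L)
    stop("fewer than 4 samples with both probes measured")
  cfun <- if (center == "median") stats::median else mean
  split_p <- cfun(pm[ok])
  split_b <- cfun(bd[ok])
  p_low <- pm[ok] <= split_p
  b_low <- bd[ok] <= split_b
  # 1 = prom low / body high, 2 = low/low, 3 = high/high, 4 = high/low
  grp <- ifelse(p_low & !b_low, 1L,
                ifelse(p_low & b_low, 2L,
                       ifelse(!p_low & !b_low, 3L, 4L)))
  names(grp) <- samples[ok]
  structure(list(assignment = grp,
                 split_value_promoter = split_p,
                 split_value_body = split_b,
                 promoter_probe = promoter_probe, body_probe = body_probe,
                 center = center, n_unassigned = sum(!ok)),
            class = "stratified_groups")
}

#' @export
print.stratified_groups <- function(x, ...) {
  cat("<stratified_groups> ", x$promoter_probe, " (split ",
      signif(x$split_value_promoter, 4), ") x ", x$body_probe, " (split ",
      signif(x$split_value_body, 4), "), center = ", x$center, "\n", sep = "")
  print(table(group = x$assignment))
  if (x$n_unassigned)
    cat(x$n_unassigned, "sample(s) unassigned (missing a probe)\n")
  invisible(x)
}

#' Pairwise expression differences between methylation groups
#'
#' For each of the six unordered group pairs (i, j) with i < j, computes
#' the signed fold change (group i as group 1, group j as group 2 — so a
#' positive fc means the higher-numbered group is higher) and the Welch
#' two-tailed p for `target_feature`. Pairs where either group has fewer
#' than 2 samples with expression are skipped with a message.
#'
#' @param expression An [omics_matrix()] of log2 expression.
#' @param groups A [stratify()] result.
#' @param target_feature Feature id to test.
#' @return Data frame with `group1`, `group2`, `n1`, `n2`, `mean1`,
#'   `mean2`, `fc`, `t_stat`, `p_value`.
#' @seealso [group_summary()] for per-group medians and IQ ranges.
#' @export
group_differential <- function(expression, groups, target_feature) {
  if (!target_feature %in% rownames(expression))
    stop("feature not present in expression matrix: ", target_feature)
  vals <- unclass(expression)[target_feature, ]
  rows <- list()
  for (i in 1:3) for (j in (i + 1):4) {
    vi <- vals[names(groups$assignment)[groups$assignment == i]]
    vj <- vals[names(groups$assignment)[groups$assignment == j]]
    vi <- vi[!is.na(vi)]; vj <- vj[!is.na(vj)]
    if (length(vi) < 2L || length(vj) < 2L) {
      message("group_differential: pair (", i, ", ", j,
              ") skipped (fewer than 2 samples in a group)")
      next
    }
    tt <- suppressWarnings(welch_test(vi, vj))
    rows[[length(rows) + 1L]] <- data.frame(
      group1 = i, group2 = j, n1 = length(vi), n2 = length(vj),
      mean1 = mean(vi), mean2 = mean(vj), fc = fold_change(vi, vj),
      t_stat = tt$t_stat, p_value = tt$p_value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(group1 = integer(), group2 = integer(),
                      n1 = integer(), n2 = integer(), mean1 = numeric(),
                      mean2 = numeric(), fc = numeric(), t_stat = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Descriptive statistics of expression per methylation group
#'
#' @inheritParams group_differential
#' @return Data frame with `group`, `n`, `median`, `q1`, `q3` (type-7
#'   quartiles of the group's expression).
#' @export
group_summary <- function(expression, groups, target_feature) {
  if (!target_feature %in% rownames(expression))
    stop("feature not present in expression matrix: ", target_feature)
  vals <- unclass(expression)[target_feature, ]
  out <- lapply(1:4, function(g) {
    v <- vals[names(groups$assignment)[groups$assignment == g]]
    v <- v[!is.na(v)]
    if (!length(v))
      return(data.frame(group = g, n = 0L, median = NA_real_,
                        q1 = NA_real_, q3 = NA_real_))
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(group = g, n = length(v), median = q[2], q1 = q[1], q3 = q[3])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
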