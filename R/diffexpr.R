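#' @title Differential expression with a signed fold change
#' @description
#' Two-group differential analysis on log2 expression values: the fold
#' change is `+/- 2^|mean2 - mean1|` on the linear scale, positive when
#' group 2 has the higher mean, and significance comes from a two-tailed
#' unpaired Welch t-test. Analyses run pooled (all tumors vs all normals)
#' or per cohort (each tumor type against its matched normal tissue).
#' @name diffexpr
NULL

#' Signed fold change between two groups of log2 values
#'
#' Computes `sign * 2^|mean(group2) - mean(group1)|` where the sign is
#' positive when group 2 has the higher mean and negative when group 1
#' does. Equal means give `+1` (a tie is never called either way, so its
#' sign is immaterial). Consequently `|fc| >= 1` always, and swapping the
#' groups flips the sign while preserving the magnitude.
#'
#' @param group1,group2 Numeric vectors of log2 expression values; `NA`s
#'   are dropped.
#' @return The signed fold change on the linear scale.
#' @examples
#' fold_change(c(1, 1), c(3, 3))  # +4
#' fold_change(c(3, 3), c(1, 1))  # -4
#' @export
fold_change <- function(group1, group2) {
  group1 <- group1[!is.na(group1)]
  group2 <- group2[!is.na(group2)]
  if (length(group1) == 0L) stop("group1 has no non-missing values")
  if (length(group2) == 0L) stop("group2 has no non-missing values")
  d <- mean(group2) - mean(group1)
  if (d == 0) return(1)
  sign(d) * 2^abs(d)
}

#' Two-tailed unpaired Welch t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom, computed as group1 minus group2 (so group2 larger gives a
#' negative t). Features too sparse to test (< 2 non-missing values in a
#' group, or no variance in either group) yield a missing p-value with a
#' warning rather than an error, so pipelines survive sparse features.
#'
#' @param group1,group2 Numeric vectors; `NA`s dropped.
#' @param var_equal Use the pooled-variance Student test instead of Welch.
#' @return List with `t_stat`, `p_value`, `df` (all `NA` when untestable).
#' @export
welch_test <- function(group1, group2, var_equal = FALSE) {
  group1 <- group1[!is.na(group1)]
  group2 <- group2[!is.na(group2)]
  untestable <- function(reason) {
    warning("t-test skipped: ", reason, call. = FALSE)
    list(t_stat = NA_real_, p_value = NA_real_, df = NA_real_)
  }
  if (length(group1) < 2L || length(group2) < 2L)
    return(untestable("fewer than 2 values in a group"))
  if (stats::var(group1) + stats::var(group2) == 0)
    return(untestable("zero variance in both groups"))
  fit <- stats::t.test(group1, group2, var.equal = var_equal)
  list(t_stat = unname(fit$statistic), p_value = fit$p.value,
       df = unname(fit$parameter))
}

.call_direction <- function(mean1, mean2, fc, p, fc_min, p_max) {
  ifelse(!is.na(p) & p <= p_max & !is.na(fc) &
           fc >= fc_min & mean2 > mean1, "up",
         ifelse(!is.na(p) & p <= p_max & !is.na(fc) &
                  fc <= -fc_min & mean2 < mean1, "down", "none"))
}

#' Differential table over an expression matrix
#'
#' One row per feature per comparison. In `pooled` mode all normal samples
#' form group 1 and all tumor samples group 2; in `per_cohort` mode each
#' cohort's normals are compared with its tumors, and cohorts lacking
#' either group are skipped with a message. A feature is called `up` when
#' `fc >= fc_min` and `p <= p_max`, `down` when `fc <= -fc_min` and
#' `p <= p_max`, else `none`. A Benjamini-Hochberg column (`p_adj`, per
#' comparison) is emitted for reference but never used for the calls.
#'
#' @param expression An [omics_matrix()] of log2 expression.
#' @param metadata Sample metadata covering its samples (see
#'   [validate_metadata()]).
#' @param mode `"per_cohort"` or `"pooled"`.
#' @param fc_min,p_max Call thresholds (defaults 1.4 and 0.05).
#' @param var_equal Passed to [welch_test()].
#' @return Data frame with columns `feature_id`, `cohort`, `n1`, `n2`,
#'   `mean1`, `mean2`, `fc`, `t_stat`, `p_value`, `p_adj`, `call`.
#' @seealso [differential_summary()] for the percentage of cohorts up/down
#'   per feature.
#' @export
differential_table <- function(expression, metadata,
                               mode = c("per_cohort", "pooled"),
                               fc_min = 1.4, p_max = 0.05,
                               var_equal = FALSE) {
  mode <- match.arg(mode)
  validate_metadata(metadata)
  missing_md <- setdiff(colnames(expression), metadata$sample_id)
  if (length(missing_md))
    stop("samples without metadata: ",
         paste(utils::head(missing_md, 5), collapse = ", "))
  md <- metadata[match(colnames(expression), metadata$sample_id), ]

  comparisons <- if (mode == "pooled") list(pooled = seq_len(ncol(expression)))
  else {
    cohorts <- unique(md$cohort)
    out <- list()
    for (co in cohorts) {
      idx <- which(md$cohort == co)
      if (!any(md$source[idx] == "normal") || !any(md$source[idx] == "tumor")) {
        message("differential_table: skipping cohort ", co,
                " (missing tumor or normal group)")
        next
      }
      out[[co]] <- idx
    }
    out
  }

  rows <- list()
  for (label in names(comparisons)) {
    idx <- comparisons[[label]]
    g1 <- idx[md$source[idx] == "normal"]
    g2 <- idx[md$source[idx] == "tumor"]
    for (f in rownames(expression)) {
      v1 <- expression[f, g1]
      v2 <- expression[f, g2]
      n1 <- sum(!is.na(v1)); n2 <- sum(!is.na(v2))
      if (n1 == 0L || n2 == 0L) {
        message("differential_table: ", f, " in ", label,
                " has an all-missing group; skipped")
        next
      }
      m1 <- mean(v1, na.rm = TRUE); m2 <- mean(v2, na.rm = TRUE)
      tt <- suppressWarnings(welch_test(v1, v2, var_equal = var_equal))
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = f, cohort = label, n1 = n1, n2 = n2,
        mean1 = m1, mean2 = m2, fc = fold_change(v1, v2),
        t_stat = tt$t_stat, p_value = tt$p_value, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) return(.empty_diff_table())
  tab$p_adj <- stats::ave(tab$p_value, tab$cohort,
                          FUN = function(p) stats::p.adjust(p, "BH"))
  tab$call <- .call_direction(tab$mean1, tab$mean2, tab$fc, tab$p_value,
                              fc_min, p_max)
  rownames(tab) <- NULL
  tab
}

.empty_diff_table <- function() {
  data.frame(feature_id = character(), cohort = character(),
             n1 = integer(), n2 = integer(), mean1 = numeric(),
             mean2 = numeric(), fc = numeric(), t_stat = numeric(),
             p_value = numeric(), p_adj = numeric(), call = character(),
             stringsAsFactors = FALSE)
}

#' Percentage of cohorts up- or down-regulated per feature
#'
#' Summarizes a per-cohort differential table into, for each feature, the
#' number and percentage of cohorts called up and down.
#'
#' @param table Output of [differential_table()] in `per_cohort` mode.
#' @return Data frame with `feature_id`, `n_cohorts`, `n_up`, `n_down`,
#'   `pct_up`, `pct_down`.
#' @export
differential_summary <- function(table) {
  if (any(table$cohort == "pooled"))
    stop("differential_summary expects a per-cohort table")
  feats <- unique(table$feature_id)
  out <- lapply(feats, function(f) {
    sub <- table[table$feature_id == f, ]
    n <- nrow(sub)
    data.frame(feature_id = f, n_cohorts = n,
               n_up = sum(sub$call == "up"),
               n_down = sum(sub$call == "down"),
               pct_up = 100 * sum(sub$call == "up") / n,
               pct_down = 100 * sum(sub$call == "down") / n,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Volcano-ready table from a differential table
#'
#' @param table Output of [differential_table()].
#' @return Data frame with `feature_id`, `cohort`, `fc`, `neglog10_p`,
#'   `call`, ordered by feature then cohort.
#' @export
volcano_table <- function(table) {
  out <- data.frame(feature_id = table$feature_id, cohort = table$cohort,
                    fc = table$fc,
                    neglog10_p = -log10(table$p_value),
                    call = table$call, stringsAsFactors = FALSE)
  out[order(out$feature_id, out$cohort), , drop = FALSE]
}
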