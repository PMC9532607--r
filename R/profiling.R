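#' @title Expression and methylation profiling
#' @description
#' Cohort-level profiling against reference distributions: per-cohort tumor
#' medians are called against the interquartile range of the matched normal
#' tissue (above the 3rd or below the 1st quartile), medians that are
#' extreme across cohorts are flagged with Tukey 1.5 x IQR fences, and
#' per-probe methylation medians are categorized as methylated
#' (median beta >= 0.6), unmethylated (median beta <= 0.2) or partially
#' methylated in between. Quantiles use linear interpolation
#' (type 7, the R default).
#' @name profiling
NULL

#' Quartile call of a tumor median against the normal-tissue IQR
#'
#' Computes type-7 quartiles of the reference (normal) values and calls the
#' tumor median `above_q3` when it exceeds the 3rd quartile, `below_q1`
#' when it falls under the 1st, else `none`.
#'
#' @param tumor_values Numeric vector (>= 1 non-missing value).
#' @param normal_values Reference vector (>= 4 non-missing values; with
#'   fewer the call is skipped with a warning and `NULL` is returned).
#' @param feature_id,cohort Optional labels carried into the result.
#' @param type Quantile estimator (see [stats::quantile()]); default 7.
#' @return One-row data frame with `feature_id`, `cohort`, `median`
#'   (tumor), `ref_median`, `q1`, `q3`, `iqr`, `quartile_call`,
#'   `outlier_flag` (`"none"` here; filled by [profile_features()]), or
#'   `NULL` when skipped.
#' @export
quartile_call <- function(tumor_values, normal_values,
                          feature_id = NA_character_,
                          cohort = NA_character_, type = 7) {
  tumor_values <- tumor_values[!is.na(tumor_values)]
  normal_values <- normal_values[!is.na(normal_values)]
  if (length(tumor_values) < 1L) stop("no non-missing tumor values")
  if (length(normal_values) < 4L) {
    warning("quartile_call skipped for ", feature_id, "/", cohort,
            ": fewer than 4 normal values", call. = FALSE)
    return(NULL)
  }
  q <- stats::quantile(normal_values, c(0.25, 0.5, 0.75), type = type,
                       names = FALSE)
  med <- stats::median(tumor_values)
  call <- if (med > q[3]) "above_q3" else if (med < q[1]) "below_q1" else "none"
  data.frame(feature_id = feature_id, cohort = cohort, median = med,
             ref_median = q[2], q1 = q[1], q3 = q[3], iqr = q[3] - q[1],
             quartile_call = call, outlier_flag = "none",
             stringsAsFactors = FALSE)
}

#' Tukey-fence outlier flag for a cohort median
#'
#' Flags `candidate` as an `upper` or `lower` outlier when it lies beyond
#' the Tukey fences `q3 + 1.5 * iqr` / `q1 - 1.5 * iqr` computed over the
#' per-cohort medians (type-7 quartiles).
#'
#' @param cohort_medians Numeric vector of per-cohort medians (>= 4
#'   non-missing).
#' @param candidate The median to flag.
#' @param k Fence multiplier (1.5, the standard boxplot rule).
#' @param type Quantile estimator; default 7.
#' @return `"upper"`, `"lower"` or `"none"`.
#' @examples
#' outlier_flag(1:10, 30)   # "upper" (fence 7.75 + 1.5 * 4.5 = 14.5)
#' outlier_flag(1:10, -10)  # "lower" (fence 3.25 - 6.75 = -3.5)
#' @export
outlier_flag <- function(cohort_medians, candidate, k = 1.5, type = 7) {
  cohort_medians <- cohort_medians[!is.na(cohort_medians)]
  if (length(cohort_medians) < 4L)
    stop("need at least 4 cohort medians")
  q <- stats::quantile(cohort_medians, c(0.25, 0.75), type = type,
                       names = FALSE)
  iqr <- q[2] - q[1]
  if (candidate > q[2] + k * iqr) "upper"
  else if (candidate < q[1] - k * iqr) "lower"
  else "none"
}

#' Methylation state of one probeset in one cohort
#'
#' The median beta value is categorized as `methylated` when >= 0.6,
#' `unmethylated` when <= 0.2, and `partial` in between.
#'
#' @param beta_values Beta values for one probeset in one cohort (>= 1
#'   non-missing; all-missing input is skipped with a warning and `NULL`).
#' @param probeset_id,cohort Optional labels carried into the result.
#' @param methylated_min,unmethylated_max State boundaries (0.6 and 0.2).
#' @return One-row data frame with `probeset_id`, `cohort`, `median_beta`,
#'   `state`, or `NULL` when skipped.
#' @export
methylation_state <- function(beta_values, probeset_id = NA_character_,
                              cohort = NA_character_,
                              methylated_min = 0.6, unmethylated_max = 0.2) {
  beta_values <- beta_values[!is.na(beta_values)]
  if (length(beta_values) == 0L) {
    warning("methylation_state skipped for ", probeset_id, "/", cohort,
            ": all values missing", call. = FALSE)
    return(NULL)
  }
  med <- stats::median(beta_values)
  state <- if (med >= methylated_min) "methylated"
  else if (med <= unmethylated_max) "unmethylated"
  else "partial"
  data.frame(probeset_id = probeset_id, cohort = cohort, median_beta = med,
             state = state, stringsAsFactors = FALSE)
}

#' Profile every feature in every cohort
#'
#' Runs [quartile_call()] for each (feature, cohort) pair — tumor values of
#' the cohort against that cohort's normal values — then flags each
#' cohort's median with [outlier_flag()] against the medians of all cohorts
#' for the same feature.
#'
#' @param expression An [omics_matrix()] of log2 expression.
#' @param metadata Sample metadata (see [validate_metadata()]).
#' @param type Quantile estimator; default 7.
#' @return A long `ProfileSummary` data frame (see [quartile_call()]).
#' @export
profile_features <- function(expression, metadata, type = 7) {
  validate_metadata(metadata)
  md <- metadata[match(colnames(expression), metadata$sample_id), ]
  cohorts <- unique(md$cohort)
  rows <- list()
  for (f in rownames(expression)) {
    per_cohort <- list()
    for (co in cohorts) {
      tum <- expression[f, md$cohort == co & md$source == "tumor"]
      nrm <- expression[f, md$cohort == co & md$source == "normal"]
      if (sum(!is.na(tum)) < 1L) next
      res <- suppressWarnings(
        quartile_call(tum, nrm, feature_id = f, cohort = co, type = type))
      if (is.null(res)) {
        message("profile_features: ", f, "/", co,
                " skipped (fewer than 4 normal values)")
        next
      }
      per_cohort[[co]] <- res
    }
    if (!length(per_cohort)) next
    tab <- do.call(rbind, per_cohort)
    if (nrow(tab) >= 4L)
      tab$outlier_flag <- vapply(seq_len(nrow(tab)), function(i)
        outlier_flag(tab$median, tab$median[i], type = type), character(1))
    rows[[f]] <- tab
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Methylation states for every probeset in every cohort
#'
#' Applies [methylation_state()] to the tumor samples of each cohort, then
#' flags cross-cohort outliers of the median beta with [outlier_flag()].
#'
#' @param methylation An [omics_matrix()] of beta values.
#' @param metadata Sample metadata.
#' @param methylated_min,unmethylated_max State boundaries.
#' @return Long data frame with `probeset_id`, `cohort`, `median_beta`,
#'   `state`, `outlier_flag`.
#' @export
methylation_profile <- function(methylation, metadata,
                                methylated_min = 0.6,
                                unmethylated_max = 0.2) {
  validate_metadata(metadata)
  md <- metadata[match(colnames(methylation), metadata$sample_id), ]
  cohorts <- unique(md$cohort[md$source == "tumor"])
  rows <- list()
  for (f in rownames(methylation)) {
    per_cohort <- list()
    for (co in cohorts) {
      vals <- methylation[f, md$cohort == co & md$source == "tumor"]
      res <- suppressWarnings(
        methylation_state(vals, probeset_id = f, cohort = co,
                          methylated_min = methylated_min,
                          unmethylated_max = unmethylated_max))
      if (is.null(res)) {
        message("methylation_profile: ", f, "/", co, " skipped (all missing)")
        next
      }
      per_cohort[[co]] <- res
    }
    if (!length(per_cohort)) next
    tab <- do.call(rbind, per_cohort)
    tab$outlier_flag <- if (nrow(tab) >= 4L)
      vapply(seq_len(nrow(tab)), function(i)
        outlier_flag(tab$median_beta, tab$median_beta[i]), character(1))
    else "none"
    rows[[f]] <- tab
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Wide cohort x feature call grid
#'
#' Pivots a long profile table ([profile_features()] or
#' [methylation_profile()]) into a cohort x feature character grid of calls
#' (quartile calls or methylation states), with a parallel grid of outlier
#' flags as the `"outliers"` attribute. Both grids export cleanly to TSV
#' for heatmap tools.
#'
#' @param profiles Long profile table.
#' @return Character matrix (cohorts x features) with attribute
#'   `"outliers"`.
#' @export
call_matrix <- function(profiles) {
  if (!nrow(profiles)) stop("empty profile table")
  feat_col <- if ("feature_id" %in% names(profiles)) "feature_id" else "probeset_id"
  val_col <- if ("quartile_call" %in% names(profiles)) "quartile_call" else "state"
  cohorts <- unique(profiles$cohort)
  feats <- unique(profiles[[feat_col]])
  grid <- matrix(NA_character_, length(cohorts), length(feats),
                 dimnames = list(cohorts, feats))
  flags <- grid
  idx <- cbind(match(profiles$cohort, cohorts),
               match(profiles[[feat_col]], feats))
  grid[idx] <- profiles[[val_col]]
  flags[idx] <- profiles$outlier_flag
  attr(grid, "outliers") <- flags
  grid
}

#' Write a call grid (and its outlier flags) to TSV
#'
#' @param grid Output of [call_matrix()].
#' @param path Output path; outlier flags go to `<path>.outliers.tsv` when
#'   present.
#' @return Invisibly, `path`.
#' @export
write_call_matrix <- function(grid, path) {
  df <- data.frame(cohort = rownames(grid),
                   as.data.frame(unclass(grid)[, , drop = FALSE]),
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path)
  fl <- attr(grid, "outliers")
  if (!is.null(fl)) {
    df2 <- data.frame(cohort = rownames(fl),
                      as.data.frame(unclass(fl)[, , drop = FALSE]),
                      check.names = FALSE, stringsAsFactors = FALSE)
    .write_tsv(df2, paste0(path, ".outliers.tsv"))
  }
  invisible(path)
}
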