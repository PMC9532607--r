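#' @title Log-rank survival annotation
#' @description
#' Kaplan-Meier / log-rank annotation of features against overall survival
#' (OS) and progression-free interval (PFI): samples are dichotomized at
#' the median of the feature (ties to the low group), the two-group
#' log-rank chi-square (1 df) is computed, and significant features are
#' called `favorable` when the high-feature group has the better survival
#' curve — operationalized as the higher restricted-mean survival over the
#' observed horizon — or `unfavorable` otherwise.
#' @name survival_annotation
NULL

#' Two-group log-rank test
#'
#' Standard log-rank chi-square with 1 degree of freedom (hypergeometric
#' variance at each distinct event time), two-sided p from the chi-square
#' distribution. With zero events overall the statistic is 0 and p is 1
#' (with a message), not an error.
#'
#' @param times_1,events_1 Times and 0/1 event indicators for group 1.
#' @param times_2,events_2 Same for group 2.
#' @return List with `statistic` and `p_value`.
#' @export
logrank_test <- function(times_1, events_1, times_2, events_2) {
  stopifnot(length(times_1) == length(events_1),
            length(times_2) == length(events_2),
            length(times_1) >= 1, length(times_2) >= 1)
  if (sum(events_1) + sum(events_2) == 0) {
    message("logrank_test: no events; statistic 0")
    return(list(statistic = 0, p_value = 1))
  }
  d <- data.frame(time = c(times_1, times_2),
                  event = c(events_1, events_2),
                  group = rep(1:2, c(length(times_1), length(times_2))))
  fit <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  stat <- fit$chisq
  list(statistic = unname(stat),
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# restricted mean survival: area under the Kaplan-Meier curve up to tmax
.km_rmst <- function(time, event, tmax) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  t <- c(0, fit$time[fit$time <= tmax], tmax)
  s <- c(1, fit$surv[fit$time <= tmax])
  sum(diff(t) * s)
}

#' Annotate one feature against one survival endpoint
#'
#' Samples with both a feature value and a record for `endpoint` are split
#' at the median of the feature (values <= median form the low group).
#' Direction is called only when `p <= p_max`: `favorable` when the high
#' group has the larger restricted-mean survival over the common observed
#' horizon, `unfavorable` otherwise, else `none`. The underlying
#' high-vs-low comparison is always reported in `high_better` so
#' non-significant rows still carry a sign for volcano plots.
#'
#' @param values Named numeric vector (names = sample ids).
#' @param survival Long-format survival table (see [read_survival()]).
#' @param endpoint `"OS"` or `"PFI"`.
#' @param feature_id,cohort Labels carried into the result.
#' @param p_max Significance threshold for the direction call.
#' @return One-row data frame with `feature_id`, `cohort`, `endpoint`,
#'   `logrank_stat`, `p_value`, `direction`, `high_better`, `n_high`,
#'   `n_low`, or `NULL` when the annotation is skipped (fewer than 4
#'   usable samples, or a degenerate split such as a constant feature).
#' @export
annotate_feature <- function(values, survival, endpoint = c("OS", "PFI"),
                             feature_id = NA_character_,
                             cohort = NA_character_, p_max = 0.05) {
  endpoint <- match.arg(endpoint)
  sub <- survival[survival$endpoint == endpoint, , drop = FALSE]
  common <- intersect(names(values)[!is.na(values)], sub$sample_id)
  if (length(common) < 4L) {
    message("annotate_feature: ", feature_id, "/", cohort,
            " skipped (fewer than 4 samples with value and record)")
    return(NULL)
  }
  v <- values[common]
  rec <- sub[match(common, sub$sample_id), ]
  low <- v <= stats::median(v)
  if (all(low) || !any(low)) {
    message("annotate_feature: ", feature_id, "/", cohort,
            " skipped (degenerate median split)")
    return(NULL)
  }
  lr <- suppressMessages(
    logrank_test(rec$time[!low], rec$event[!low],
                 rec$time[low], rec$event[low]))
  horizon <- max(rec$time)
  rm_high <- .km_rmst(rec$time[!low], rec$event[!low], horizon)
  rm_low <- .km_rmst(rec$time[low], rec$event[low], horizon)
  high_better <- rm_high > rm_low
  direction <- if (!is.na(lr$p_value) && lr$p_value <= p_max)
    if (high_better) "favorable" else "unfavorable"
  else "none"
  data.frame(feature_id = feature_id, cohort = cohort, endpoint = endpoint,
             logrank_stat = lr$statistic, p_value = lr$p_value,
             direction = direction, high_better = high_better,
             n_high = sum(!low), n_low = sum(low),
             stringsAsFactors = FALSE)
}

#' Annotate every feature of a matrix, per cohort and endpoint
#'
#' Convenience wrapper running [annotate_feature()] for each feature of
#' `values` within each cohort's tumor samples, for one endpoint.
#'
#' @param values An [omics_matrix()] (expression or methylation).
#' @param survival Long-format survival table.
#' @param metadata Sample metadata.
#' @param endpoint `"OS"` or `"PFI"`.
#' @param p_max Significance threshold for direction calls.
#' @return Data frame of annotations (zero rows if all skipped).
#' @export
annotate_matrix <- function(values, survival, metadata,
                            endpoint = c("OS", "PFI"), p_max = 0.05) {
  endpoint <- match.arg(endpoint)
  validate_metadata(metadata)
  md <- metadata[match(colnames(values), metadata$sample_id), ]
  cohorts <- unique(md$cohort[md$source == "tumor"])
  rows <- list()
  for (co in cohorts) {
    ids <- colnames(values)[md$cohort == co & md$source == "tumor"]
    for (f in rownames(values)) {
      v <- unclass(values)[f, ids]
      ann <- suppressMessages(
        annotate_feature(v, survival, endpoint, feature_id = f,
                         cohort = co, p_max = p_max))
      if (!is.null(ann)) rows[[length(rows) + 1L]] <- ann
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(feature_id = character(), cohort = character(),
                      endpoint = character(), logrank_stat = numeric(),
                      p_value = numeric(), direction = character(),
                      high_better = logical(), n_high = integer(),
                      n_low = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Volcano-ready table from survival annotations
#'
#' The signed statistic encodes direction: negative when the high-feature
#' group fares better (favorable), positive when it fares worse. `p = 1`
#' maps to 0 on the `-log10(p)` axis. Rows are ordered deterministically by
#' (feature, cohort, endpoint).
#'
#' @param annotations Output of [annotate_feature()]/[annotate_matrix()]
#'   (non-empty).
#' @return Data frame with `feature_id`, `cohort`, `endpoint`,
#'   `signed_stat`, `neglog10_p`, `direction`.
#' @export
survival_volcano <- function(annotations) {
  if (!nrow(annotations)) stop("empty annotation table")
  out <- data.frame(
    feature_id = annotations$feature_id, cohort = annotations$cohort,
    endpoint = annotations$endpoint,
    signed_stat = ifelse(annotations$high_better, -1, 1) *
      annotations$logrank_stat,
    neglog10_p = -log10(annotations$p_value),
    direction = annotations$direction, stringsAsFactors = FALSE)
  out <- out[order(out$feature_id, out$cohort, out$endpoint), , drop = FALSE]
  rownames(out) <- NULL
  out
}
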