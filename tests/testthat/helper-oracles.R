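# Independent reference implementations used as oracles. Each is written
# from the textbook definition and never calls the code path it checks.

# Welch unequal-variance t from first principles
welch_oracle <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  v1 <- var(g1) / length(g1)
  v2 <- var(g2) / length(g2)
  t <- (mean(g1) - mean(g2)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(g1) - 1) + v2^2 / (length(g2) - 1))
  list(t_stat = t, p_value = 2 * pt(-abs(t), df), df = df)
}

# Pearson r from raw sums, p via the t transform
pearson_oracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- abs(r) * sqrt((n - 2) / (1 - r^2))
  list(r = r, p_value = 2 * pt(t, df = n - 2, lower.tail = FALSE), n = n)
}

# Two-group log-rank chi-square from the observed-minus-expected table
logrank_oracle <- function(t1, e1, t2, e2) {
  times <- sort(unique(c(t1[e1 == 1], t2[e2 == 1])))
  O1 <- 0; E1 <- 0; V <- 0
  for (tt in times) {
    n1 <- sum(t1 >= tt); n2 <- sum(t2 >= tt); n <- n1 + n2
    d1 <- sum(t1 == tt & e1 == 1); d2 <- sum(t2 == tt & e2 == 1)
    d <- d1 + d2
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- (O1 - E1)^2 / V
  list(statistic = stat, p_value = pchisq(stat, 1, lower.tail = FALSE))
}

# Sort-based type-7 quantile: h = (n-1)p + 1, linear interpolation
quantile_oracle <- function(x, p) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# brute-force quartile call / Tukey fence using quantile_oracle only
quartile_call_oracle <- function(tumor, normal) {
  q1 <- quantile_oracle(normal, 0.25)
  q3 <- quantile_oracle(normal, 0.75)
  med <- quantile_oracle(tumor, 0.5)
  if (med > q3) "above_q3" else if (med < q1) "below_q1" else "none"
}

outlier_flag_oracle <- function(medians, candidate) {
  q1 <- quantile_oracle(medians, 0.25)
  q3 <- quantile_oracle(medians, 0.75)
  iqr <- q3 - q1
  if (candidate > q3 + 1.5 * iqr) "upper"
  else if (candidate < q1 - 1.5 * iqr) "lower"
  else "none"
}

# --- shared tiny fixtures -------------------------------------------------

# minimal single-cohort, single-gene simulation for recovery loops
one_gene_config <- function(seed, tumor_shift = 0, promoter_coupling = 0,
                            body_coupling = 0, survival_effect = 0,
                            noise_sd = 1, n_tumor = 200, n_normal = 200) {
  simulation_config(
    n_cohorts = 1,
    samples_per_cohort_tumor = n_tumor,
    samples_per_cohort_normal = n_normal,
    genes = list(gene_spec("G1", base_mean = 2, tumor_shift = tumor_shift,
                           promoter_coupling = promoter_coupling,
                           body_coupling = body_coupling,
                           survival_effect = survival_effect,
                           isoform_biotypes = character(0),
                           probes_per_region = c(promoter = 1, body = 1))),
    proteins = NULL, noise_sd = noise_sd, seed = seed)
}

make_matrix <- function(values, kind = "expression_log2fpkm",
                        features = rownames(values) %||%
                          sprintf("f%d", seq_len(nrow(values))),
                        samples = colnames(values) %||%
                          sprintf("s%d", seq_len(ncol(values)))) {
  omics_matrix(values, kind, feature_ids = features, sample_ids = samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
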