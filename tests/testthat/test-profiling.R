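test_that("quartile calls against the normal IQR match the stated examples", {
  nrm <- c(1, 2, 3, 4, 5)  # type-7 q1 = 2, q3 = 4
  expect_identical(quartile_call(4.5, nrm)$quartile_call, "above_q3")
  expect_identical(quartile_call(3, nrm)$quartile_call, "none")
  expect_identical(quartile_call(1.5, nrm)$quartile_call, "below_q1")
  res <- quartile_call(c(4, 5), nrm, feature_id = "f", cohort = "ACC")
  expect_identical(res[, c("q1", "q3", "iqr")],
                   data.frame(q1 = 2, q3 = 4, iqr = 2))
  expect_warning(expect_null(quartile_call(1, c(1, 2, 3))), "fewer than 4")
})

test_that("Tukey fences flag extreme cohort medians", {
  expect_identical(outlier_flag(1:10, 30), "upper")   # fence 14.5
  expect_identical(outlier_flag(1:10, -10), "lower")  # fence -3.5
  expect_identical(outlier_flag(1:10, median(1:10)), "none")
  expect_identical(outlier_flag(1:10, 14.5), "none")  # on the fence
  expect_error(outlier_flag(1:3, 5), "at least 4")
})

test_that("methylation states honor the closed 0.6 / 0.2 boundaries", {
  state <- function(...) methylation_state(...)$state
  expect_identical(state(0.65), "methylated")
  expect_identical(state(0.15), "unmethylated")
  expect_identical(state(0.40), "partial")
  expect_identical(state(0.6), "methylated")     # >= 0.6 inclusive
  expect_identical(state(0.2), "unmethylated")   # <= 0.2 inclusive
  expect_identical(state(c(0.1, 0.3, NA)), state(0.2))
  expect_warning(expect_null(methylation_state(NA_real_)), "missing")
})

test_that("quartile and fence logic agree with a sort-based oracle", {
  set.seed(101)
  for (i in 1:500) {
    nrm <- round(rnorm(sample(4:50, 1)), 3)
    tum <- round(rnorm(sample(1:50, 1), mean = runif(1, -2, 2)), 3)
    expect_identical(quartile_call(tum, nrm)$quartile_call,
                     quartile_call_oracle(tum, nrm))
    med <- round(rnorm(sample(4:50, 1)), 3)
    cand <- rnorm(1, sd = 4)
    expect_identical(outlier_flag(med, cand),
                     outlier_flag_oracle(med, cand))
  }
})

test_that("raising the tumor median never downgrades a call", {
  rank_call <- function(x) match(x, c("below_q1", "none", "above_q3"))
  set.seed(11)
  for (i in 1:50) {
    nrm <- rnorm(12)
    med <- rnorm(1)
    c1 <- quartile_call(med, nrm)$quartile_call
    c2 <- quartile_call(med + abs(rnorm(1)), nrm)$quartile_call
    expect_gte(rank_call(c2), rank_call(c1))
  }
})

profile_fixture <- function() {
  # 5 cohorts x (3 tumor + 4 normal); f1 planted extreme in cohort C5
  set.seed(21)
  cohorts <- paste0("C", 1:5)
  md <- data.frame(
    sample_id = sprintf("%s-%s%d", rep(cohorts, each = 7),
                        rep(c(rep("T", 3), rep("N", 4)), 5),
                        rep(c(1:3, 1:4), 5)),
    cohort = rep(cohorts, each = 7),
    source = rep(c(rep("tumor", 3), rep("normal", 4)), 5),
    stringsAsFactors = FALSE)
  vals <- matrix(rnorm(2 * 35, sd = 0.1), 2, 35,
                 dimnames = list(c("f1", "f2"), md$sample_id))
  vals["f1", md$cohort == "C5" & md$source == "tumor"] <- 50
  list(m = omics_matrix(vals, "expression_log2fpkm"), md = md)
}

test_that("profile_features flags a planted extreme cohort as upper outlier", {
  fx <- profile_fixture()
  prof <- profile_features(fx$m, fx$md)
  expect_identical(nrow(prof), 10L)  # 2 features x 5 cohorts
  hit <- prof[prof$feature_id == "f1" & prof$cohort == "C5", ]
  expect_identical(hit$outlier_flag, "upper")
  expect_identical(hit$quartile_call, "above_q3")
  expect_true(all(prof$outlier_flag[prof$feature_id == "f2"] == "none"))
})

test_that("call_matrix pivots long profiles into a complete grid", {
  fx <- profile_fixture()
  prof <- profile_features(fx$m, fx$md)
  grid <- call_matrix(prof)
  expect_identical(dim(grid), c(5L, 2L))
  expect_identical(length(grid), length(unique(prof$cohort)) *
                     length(unique(prof$feature_id)))
  expect_identical(grid["C5", "f1"], "above_q3")
  expect_identical(attr(grid, "outliers")["C5", "f1"], "upper")
  # single-cell grid matches its input call
  one <- call_matrix(prof[1, ])
  expect_identical(dim(one), c(1L, 1L))
  expect_identical(unname(one[1, 1]), prof$quartile_call[1])
  expect_error(call_matrix(prof[0, ]), "empty")
})

test_that("methylation_profile categorizes per-cohort tumor medians", {
  set.seed(31)
  cohorts <- paste0("C", 1:4)
  md <- data.frame(sample_id = sprintf("%s-T%d", rep(cohorts, each = 5), 1:5),
                   cohort = rep(cohorts, each = 5), source = "tumor",
                   stringsAsFactors = FALSE)
  vals <- matrix(runif(20, 0.25, 0.55), 1, 20,
                 dimnames = list("cg1", md$sample_id))
  vals[1, md$cohort == "C1"] <- runif(5, 0.8, 0.95)
  vals[1, md$cohort == "C2"] <- runif(5, 0.01, 0.1)
  m <- omics_matrix(vals, "methylation_beta")
  prof <- methylation_profile(m, md)
  states <- setNames(prof$state, prof$cohort)
  expect_identical(unname(states[c("C1", "C2", "C3", "C4")]),
                   c("methylated", "unmethylated", "partial", "partial"))
})
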