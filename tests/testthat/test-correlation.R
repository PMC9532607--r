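test_that("pearson matches the closed form and cor.test", {
  expect_equal(pearson(1:5, 1:5)$r, 1)
  expect_equal(pearson(1:5, -(1:5))$r, -1)
  expect_equal(pearson(c(1, 2, 3, 4), c(1, 3, 2, 4))$r, 0.8)
  set.seed(13)
  for (i in 1:300) {
    n <- sample(4:30, 1)
    x <- rnorm(n); y <- 0.4 * x + rnorm(n)
    if (i %% 3 == 0) x[sample(n, 1)] <- NA
    got <- pearson(x, y)
    want <- pearson_oracle(x, y)
    ref <- cor.test(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-10)
    expect_equal(got$r, unname(ref$estimate), tolerance = 1e-10)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-8)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-8)
    expect_identical(got$n, sum(!is.na(x) & !is.na(y)))
  }
})

test_that("degenerate correlation inputs return NA with a reason", {
  expect_message(res <- pearson(1:2, 2:3), "fewer than 3")
  expect_true(is.na(res$r))
  expect_message(res2 <- pearson(c(1, 1, 1), rnorm(3)), "constant")
  expect_true(is.na(res2$r))
})

cor_fixture <- function(seed = 17) {
  set.seed(seed)
  n <- 40
  cohorts <- rep(c("ACC", "BLCA"), each = n / 2)
  x <- rnorm(n); y <- 0.8 * x + 0.3 * rnorm(n); z <- rnorm(n)
  samples <- sprintf("s%02d", 1:n)
  a <- make_matrix(rbind(fx = x, fy = y), samples = samples)
  b <- make_matrix(rbind(fz = z, fx2 = x), samples = samples)
  md <- data.frame(sample_id = samples, cohort = cohorts, source = "tumor",
                   stringsAsFactors = FALSE)
  list(a = a, b = b, md = md)
}

test_that("correlate_sets covers all pairs and is symmetric in its inputs", {
  fx <- cor_fixture()
  ab <- correlate_sets(fx$a, fx$b, mode = "pooled")
  ba <- correlate_sets(fx$b, fx$a, mode = "pooled")
  expect_identical(nrow(ab), 4L)
  for (i in seq_len(nrow(ab))) {
    j <- which(ba$feature_a == ab$feature_b[i] &
                 ba$feature_b == ab$feature_a[i])
    expect_equal(ab$r[i], ba$r[j])
  }
  # self-correlation r = 1 on the diagonal
  aa <- correlate_sets(fx$a, fx$a, mode = "pooled")
  diag_rows <- aa[aa$feature_a == aa$feature_b, ]
  expect_equal(diag_rows$r, c(1, 1))
})

test_that("per-cohort r is invariant to sample shuffling within cohorts", {
  fx <- cor_fixture()
  base <- correlate_sets(fx$a, fx$b, fx$md, mode = "per_cohort")
  perm <- c(sample(1:20), sample(21:40))
  a2 <- fx$a[, perm]
  shuf <- correlate_sets(a2, fx$b, fx$md, mode = "per_cohort")
  key <- function(d) d[order(d$feature_a, d$feature_b, d$cohort), ]
  expect_equal(key(base)$r, key(shuf)$r)
  # and to cohort ordering
  md_rev <- fx$md[rev(seq_len(nrow(fx$md))), ]
  rev_tab <- correlate_sets(fx$a, fx$b, md_rev, mode = "per_cohort")
  expect_equal(sort(rev_tab$r), sort(base$r))
})

test_that("pairs with fewer than 3 complete observations are dropped", {
  a <- make_matrix(matrix(c(1, 2, 3, 4), 1), features = "fa",
                   samples = sprintf("s%d", 1:4))
  bvals <- matrix(c(1, NA, NA, NA), 1)
  b <- make_matrix(bvals, features = "fb", samples = sprintf("s%d", 1:4))
  expect_message(tab <- correlate_sets(a, b, mode = "pooled"), "dropped 1")
  expect_identical(nrow(tab), 0L)
})

test_that("significance combines the r and p thresholds", {
  fx <- cor_fixture()
  tab <- correlate_sets(fx$a, fx$b, mode = "pooled", r_min = 0.3,
                        p_max = 0.05)
  strong <- tab[tab$feature_a == "fx" & tab$feature_b == "fx2", ]
  expect_true(strong$significant)
  expect_identical(tab$significant,
                   abs(tab$r) >= 0.3 & tab$p_value <= 0.05)
})

test_that("planted negative promoter coupling is significant per cohort", {
  b <- generate_bundle(one_gene_config(3, promoter_coupling = -0.5,
                                       n_normal = 2))
  md <- b$metadata[b$metadata$source == "tumor", ]
  expr <- b$expression[, md$sample_id, drop = FALSE]
  tab <- suppressMessages(correlate_sets(expr, b$methylation, md,
                                         mode = "per_cohort"))
  hit <- tab[tab$feature_a == "G1" & grepl("000001$", tab$feature_b), ]
  expect_true(hit$significant)
  expect_lt(hit$r, 0)
})

test_that("cluster_profiles recovers a planted block structure", {
  block <- rbind(a1 = c(1, 1, 0, 0), a2 = c(1, 1, 0, 0),
                 b1 = c(0, 0, 1, 1), b2 = c(0, 0, 1, 1))
  labels <- cluster_profiles(block * 10, k = 2)
  expect_identical(labels[["a1"]], labels[["a2"]])
  expect_identical(labels[["b1"]], labels[["b2"]])
  expect_false(labels[["a1"]] == labels[["b1"]])
  # k = n rows: every row its own cluster
  all_own <- cluster_profiles(block * 10, k = 4)
  expect_identical(sort(unique(all_own)), 1:4)
  # labels renumbered by lexicographic first appearance
  expect_identical(labels[["a1"]], 1L)
  expect_error(cluster_profiles(block, k = 0), "k")
  expect_error(cluster_profiles(block, k = 5), "k")
})

test_that("missing r values cluster as zero with a message", {
  grid <- rbind(a = c(1, NA), b = c(1, 0), c = c(-5, 4))
  expect_message(labels <- cluster_profiles(grid, k = 2), "1 missing")
  expect_identical(labels[["a"]], labels[["b"]])
})
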