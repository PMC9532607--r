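cor_rows <- function(pair_sign_by_cohort, a = "gA", b = "pB") {
  # build a per-cohort correlation table for one pair from a signed vector
  n <- length(pair_sign_by_cohort)
  data.frame(feature_a = a, feature_b = b,
             cohort = sprintf("C%02d", seq_len(n)),
             r = 0.5 * pair_sign_by_cohort, p_value = 0.001, n = 50,
             significant = pair_sign_by_cohort != 0,
             stringsAsFactors = FALSE)
}

test_that("concordance classification matches the exhaustive truth table", {
  for (np in 0:6) for (nn in 0:(6 - np)) {
    if (np + nn == 0) {
      expect_error(classify_concordance(np, nn), "at least one")
      next
    }
    want <- if (nn == 0) "total_positive"
    else if (np == 0) "total_negative"
    else "partial"
    expect_identical(classify_concordance(np, nn), want)
  }
  expect_error(classify_concordance(-1, 2), "non-negative")
})

test_that("edges tally significant cohorts with their signs", {
  # positive in 8 cohorts -> total_positive, n = 8
  e1 <- aggregate_edges(cor_rows(rep(1, 8)), min_cohorts = 5)
  expect_identical(e1$n_significant, 8L)
  expect_identical(e1$concordance, "total_positive")
  # negative in 7, positive in 3 -> partial, n = 10
  e2 <- aggregate_edges(cor_rows(c(rep(-1, 7), rep(1, 3))), min_cohorts = 5)
  expect_identical(e2$n_significant, 10L)
  expect_identical(e2$n_negative, 7L)
  expect_identical(e2$n_positive, 3L)
  expect_identical(e2$concordance, "partial")
  # below the cohort filter -> no edge
  e3 <- aggregate_edges(cor_rows(c(rep(1, 4), rep(0, 4))), min_cohorts = 5)
  expect_identical(nrow(e3), 0L)
})

test_that("aggregation rejects pooled rows and ignores row order", {
  rows <- cor_rows(rep(1, 6))
  pooled <- rows; pooled$cohort[1] <- "pooled"
  expect_error(aggregate_edges(pooled), "pooled")
  shuffled <- rows[sample(nrow(rows)), ]
  expect_identical(aggregate_edges(rows, 5), aggregate_edges(shuffled, 5))
})

test_that("raising min_cohorts never adds edges", {
  set.seed(23)
  rows <- do.call(rbind, lapply(1:10, function(i)
    cor_rows(sample(c(-1, 0, 1), 12, replace = TRUE),
             a = paste0("g", i %% 3), b = paste0("p", i))))
  prev <- nrow(aggregate_edges(rows, 1))
  for (k in 2:6) {
    cur <- nrow(aggregate_edges(rows, k))
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("mean_r covers significant cohorts only and self-pairs drop", {
  rows <- rbind(cor_rows(c(1, 1, 0, 0)), cor_rows(rep(1, 4), a = "x", b = "x"))
  rows$r[3:4] <- 0.9  # non-significant cohorts must not contribute
  e <- aggregate_edges(rows, min_cohorts = 1)
  expect_identical(nrow(e), 1L)   # self-pair excluded
  expect_equal(e$mean_r, 0.5)
})

edge_fixture <- function() {
  aggregate_edges(rbind(
    cor_rows(rep(1, 6), "gA", "p1"), cor_rows(rep(-1, 6), "gB", "p1"),
    cor_rows(rep(1, 6), "gA", "p2"), cor_rows(rep(1, 6), "gB", "p2"),
    cor_rows(rep(1, 6), "gC", "p2"), cor_rows(rep(1, 6), "gC", "p3")),
    min_cohorts = 5)
}

test_that("exports carry the edge multiset in every format", {
  edges <- edge_fixture()
  dir <- withr::local_tempdir()
  sif <- file.path(dir, "net.sif")
  export_network(edges, "sif", sif)
  lines <- readLines(sif)
  expect_length(lines, nrow(edges))
  expect_match(lines[1], "^gA\ttotal_positive\tp1$")
  tsv <- file.path(dir, "net.tsv")
  export_network(edges, "tsv", tsv)
  expect_identical(nrow(read.delim(tsv)), nrow(edges))
  gml <- file.path(dir, "net.graphml")
  export_network(edges, "graphml", gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_identical(igraph::ecount(g), as.double(nrow(edges)))
  expect_setequal(igraph::edge_attr(g, "concordance"), edges$concordance)
  expect_equal(sort(igraph::edge_attr(g, "n_significant")),
               sort(edges$n_significant))
})

test_that("an empty edge table exports valid empty files", {
  empty <- aggregate_edges(cor_rows(rep(0, 4)), min_cohorts = 1)
  dir <- withr::local_tempdir()
  export_network(empty, "sif", file.path(dir, "e.sif"))
  expect_identical(readLines(file.path(dir, "e.sif")), character(0))
  export_network(empty, "tsv", file.path(dir, "e.tsv"))
  expect_identical(nrow(read.delim(file.path(dir, "e.tsv"))), 0L)
})

test_that("multi-anchor nodes are partitioned by anchor degree", {
  edges <- edge_fixture()
  anchors <- c("gA", "gB", "gC")
  shared <- multi_degree_nodes(edges, anchors)
  expect_identical(shared$feature_id, c("p2", "p1"))
  expect_identical(shared$anchor_degree, c(3L, 2L))
  expect_identical(shared$anchors[shared$feature_id == "p1"], "gA,gB")
  # p3 touches a single anchor and is excluded
  expect_false("p3" %in% shared$feature_id)
  # no edges -> empty table
  none <- aggregate_edges(cor_rows(rep(0, 4)), 1)
  expect_identical(nrow(multi_degree_nodes(none, anchors)), 0L)
  # absent anchors contribute degree 0
  expect_identical(nrow(multi_degree_nodes(edges, c("gZ", "gY"))), 0L)
})
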