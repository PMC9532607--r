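test_that("reading a matrix preserves shape, order and missingness", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature\tsB\tsA",
               "g2\t1.5\tNA",
               "g1\t-9.966\t0.25",
               "g3\t\t3"), path)
  m <- read_matrix(path, "expression_log2fpkm")
  expect_identical(dim(m), c(3L, 2L))
  expect_identical(feature_ids(m), c("g2", "g1", "g3"))
  expect_identical(sample_ids(m), c("sB", "sA"))
  expect_true(is.na(m["g2", "sA"]))
  expect_true(is.na(m["g3", "sB"]))
  expect_identical(m["g3", "sA"], 3)
  expect_identical(value_kind(m), "expression_log2fpkm")
})

test_that("write(read(f)) reproduces a canonical fixture byte-for-byte", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature\ts1\ts2",
               "g1\t0.5\tNA",
               "g2\t-2.25\t3"), path)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(read_matrix(path, "expression_log2fpkm"), out)
  expect_identical(readLines(out), readLines(path))
  # and two writes of the same matrix are byte-identical
  out2 <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(read_matrix(path, "expression_log2fpkm"), out2)
  expect_identical(readBin(out, "raw", file.size(out)),
                   readBin(out2, "raw", file.size(out2)))
})

test_that("read/write round-trip is the cell-level identity on random data", {
  set.seed(42)
  vals <- matrix(round(rnorm(60), 6), 10, 6)
  vals[sample(60, 12)] <- NA
  m <- make_matrix(vals)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(m, path)
  m2 <- read_matrix(path, "expression_log2fpkm")
  expect_equal(unclass(m2), unclass(m), ignore_attr = TRUE)
  expect_identical(feature_ids(m2), feature_ids(m))
  expect_identical(sample_ids(m2), sample_ids(m))
})

test_that("an empty feature registry writes a header-only file", {
  m <- make_matrix(matrix(numeric(0), 0, 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(m, path)
  expect_identical(readLines(path), "feature\ts1\ts2")
})

test_that("duplicate identifiers are a hard error naming the duplicate", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature\ts1\ts2", "g1\t1\t2", "g1\t3\t4"), path)
  expect_error(read_matrix(path, "expression_log2fpkm"), "g1")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature\tsX\tsX", "g1\t1\t2"), path2)
  expect_error(read_matrix(path2, "expression_log2fpkm"), "sX")
})

test_that("a beta value outside [0, 1] is rejected with its cell named", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature\ts1\ts2", "cg1\t0.5\t0.7", "cg2\t1.2\t0.1"), path)
  err <- expect_error(read_matrix(path, "methylation_beta"))
  expect_match(conditionMessage(err), "cg2")
  expect_match(conditionMessage(err), "s1")
  # the same values are fine as expression
  expect_silent(read_matrix(path, "expression_log2fpkm"))
})

test_that("align_samples intersects in first-matrix order and is idempotent", {
  m1 <- make_matrix(matrix(1:6, 2, 3), samples = c("A", "B", "C"))
  m2 <- make_matrix(matrix(1:6, 2, 3), samples = c("B", "C", "D"))
  out <- suppressMessages(align_samples(list(m1, m2)))
  expect_identical(sample_ids(out[[1]]), c("B", "C"))
  expect_identical(sample_ids(out[[2]]), c("B", "C"))
  # identical sample sets pass through unchanged
  same <- align_samples(list(m1, m1))
  expect_identical(sample_ids(same[[1]]), c("A", "B", "C"))
  # idempotence
  twice <- suppressMessages(align_samples(out))
  expect_identical(lapply(twice, unclass), lapply(out, unclass))
})

test_that("an empty triple intersection is an error despite pairwise overlap", {
  m1 <- make_matrix(matrix(1:4, 2, 2), samples = c("A", "B"))
  m2 <- make_matrix(matrix(1:4, 2, 2), samples = c("B", "C"))
  m3 <- make_matrix(matrix(1:4, 2, 2), samples = c("C", "A"))
  # every pair overlaps ...
  expect_length(suppressMessages(align_samples(list(m1, m2)))[[1]] |> colnames(), 1L)
  # ... but the triple intersection is empty
  expect_error(suppressMessages(align_samples(list(m1, m2, m3))), "no samples")
})

test_that("annotation invariants enforce the probeset region rule", {
  ann <- data.frame(feature_id = c("g", "cg1"), gene_symbol = "g",
                    feature_class = c("gene", "probeset"),
                    biotype = c("coding", "not_applicable"),
                    gene_region = c("not_applicable", "promoter"),
                    stringsAsFactors = FALSE)
  expect_silent(validate_annotation(ann))
  bad <- ann; bad$gene_region <- c("not_applicable", "not_applicable")
  expect_error(validate_annotation(bad), "cg1")
  bad2 <- ann; bad2$gene_region <- c("body", "promoter")
  expect_error(validate_annotation(bad2), "g")
})

test_that("survival tables round-trip through the wide on-disk dialect", {
  surv <- data.frame(sample_id = rep(c("s1", "s2"), each = 2),
                     endpoint = rep(c("OS", "PFI"), 2),
                     time = c(100.5, 40, 250, 60),
                     event = c(1L, 0L, 0L, 1L), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_survival(surv, path)
  back <- read_survival(path)
  key <- function(d) d[order(d$sample_id, d$endpoint), ]
  expect_equal(key(back), key(surv), ignore_attr = TRUE)
  # invariant violations are rejected
  expect_error(validate_survival(transform(surv, time = -1)), "negative")
  expect_error(validate_survival(transform(surv, event = 2L)), "event")
  expect_error(validate_survival(rbind(surv, surv[1, ])), "duplicate")
})

test_that("metadata validation catches unknown sources and bad tumor groups", {
  md <- data.frame(sample_id = c("a", "b"), cohort = "ACC",
                   source = c("tumor", "normal"), tumor_group = c(1L, 9L),
                   stringsAsFactors = FALSE)
  expect_silent(validate_metadata(md))
  expect_error(validate_metadata(transform(md, source = "cell_line")),
               "source")
  expect_error(validate_metadata(transform(md, tumor_group = c(0L, 5L))),
               "tumor_group")
})
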