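#' @title Omics matrix container
#' @description
#' An `omics_matrix` is a features x samples numeric matrix with a declared
#' value kind: `expression_log2fpkm` (log2(fpkm + 0.001) units),
#' `methylation_beta` (beta values in \[0, 1\]) or `protein_rppa`
#' (normalized RPPA protein levels). Feature and sample identifiers are
#' carried as dimnames and must be unique; missing values are `NA`, never 0.
#' @name omics_matrix-class
NULL

VALUE_KINDS <- c("expression_log2fpkm", "methylation_beta", "protein_rppa")

#' Minimum attainable log2(fpkm + 0.001) expression value
#'
#' Expression matrices are on the log2(fpkm + 0.001) scale, so an fpkm of 0
#' maps to `log2(0.001)`, approximately -9.966.
#' @export
EXPRESSION_FLOOR <- log2(0.001)

#' Construct an omics matrix
#'
#' @param values Numeric matrix, rows = features, columns = samples. Row and
#'   column names are used as feature/sample identifiers unless overridden.
#' @param value_kind One of `"expression_log2fpkm"`, `"methylation_beta"`,
#'   `"protein_rppa"`.
#' @param feature_ids,sample_ids Optional identifier vectors overriding the
#'   dimnames of `values`.
#' @return An object of class `omics_matrix`.
#' @examples
#' m <- omics_matrix(matrix(rnorm(6), 3, 2,
#'                          dimnames = list(c("g1", "g2", "g3"), c("s1", "s2"))),
#'                   "expression_log2fpkm")
#' dim(m)
#' @export
omics_matrix <- function(values, value_kind,
                         feature_ids = rownames(values),
                         sample_ids = colnames(values)) {
  value_kind <- match.arg(value_kind, VALUE_KINDS)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(feature_ids) && nrow(values) == 0L) feature_ids <- character(0)
  if (is.null(sample_ids) && ncol(values) == 0L) sample_ids <- character(0)
  if (is.null(feature_ids) || is.null(sample_ids))
    stop("feature and sample identifiers are required")
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(values))
    stop("length of feature_ids (", length(feature_ids),
         ") does not match nrow(values) (", nrow(values), ")")
  if (length(sample_ids) != ncol(values))
    stop("length of sample_ids (", length(sample_ids),
         ") does not match ncol(values) (", ncol(values), ")")
  .check_unique(feature_ids, "feature id")
  .check_unique(sample_ids, "sample id")
  dimnames(values) <- list(feature_ids, sample_ids)
  if (value_kind == "methylation_beta") .check_beta_range(values)
  structure(values, value_kind = value_kind, class = c("omics_matrix", "matrix"))
}

.check_unique <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate ", what, "(s): ", paste(utils::head(dup, 5), collapse = ", "))
  invisible(ids)
}

.check_beta_range <- function(values) {
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    r <- bad[1, 1]; c <- bad[1, 2]
    stop("beta value out of [0, 1] at feature '", rownames(values)[r],
         "', sample '", colnames(values)[c], "': ", values[r, c])
  }
  invisible(values)
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat("<omics_matrix> ", nrow(x), " features x ", ncol(x), " samples [",
      attr(x, "value_kind"), "], ", sum(is.na(x)), " missing\n", sep = "")
  invisible(x)
}

#' Value kind of an omics matrix
#' @param x An `omics_matrix`.
#' @return The value-kind string.
#' @export
value_kind <- function(x) attr(x, "value_kind")

#' Feature and sample identifiers
#' @param x An `omics_matrix`.
#' @return Character vector of identifiers in matrix order.
#' @export
feature_ids <- function(x) rownames(x)

#' @rdname feature_ids
#' @export
sample_ids <- function(x) colnames(x)

# ---------------------------------------------------------------------------
# Xena genomicMatrix dialect: tab-separated, first column = feature id,
# header row = sample ids. "" and "NA" (any case) read as missing; written
# missing is always "NA". Row/column order is preserved exactly.

.NA_TOKENS <- c("", "NA", "na", "Na", "nA")

#' Read a Xena-style genomic matrix
#'
#' Reads a tab-separated features x samples matrix whose first column holds
#' feature identifiers and whose header row holds sample identifiers (the
#' UCSC Xena genomicMatrix dialect). Empty cells and `"NA"` (case
#' insensitive) are missing; no cell is ever coerced to zero.
#'
#' @param path Path to the TSV file.
#' @param value_kind Declared kind of the values; beta matrices are
#'   range-checked on read.
#' @return An [omics_matrix()] with feature and sample registries in file
#'   order.
#' @seealso [write_matrix()]
#' @export
read_matrix <- function(path, value_kind) {
  value_kind <- match.arg(value_kind, VALUE_KINDS)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 1L) stop("empty header in ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, na.strings = .NA_TOKENS,
                           colClasses = c("character",
                                          rep("numeric", length(header) - 1L)),
                           stringsAsFactors = FALSE)
  ids <- tab[[1]]
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  m <- omics_matrix(vals, value_kind,
                    feature_ids = ids, sample_ids = header[-1])
  attr(m, "id_column") <- header[1]
  m
}

#' Write a Xena-style genomic matrix
#'
#' Emits exactly the dialect [read_matrix()] accepts; missing values are
#' written as `"NA"`. Two writes of the same matrix are byte-identical, and
#' read/write round-trips preserve every cell.
#'
#' @param matrix An [omics_matrix()].
#' @param path Output path.
#' @param id_column Header label for the feature-id column (defaults to the
#'   label remembered from [read_matrix()], else `"feature"`).
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(matrix, path, id_column = NULL) {
  stopifnot(inherits(matrix, "omics_matrix"))
  if (is.null(id_column))
    id_column <- attr(matrix, "id_column") %||% "feature"
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c(id_column, colnames(matrix)), collapse = "\t"), con)
  if (nrow(matrix)) {
    body <- apply(unclass(matrix), 1, function(row) {
      cells <- ifelse(is.na(row), "NA", vapply(row, .num_str, character(1)))
      paste(cells, collapse = "\t")
    })
    writeLines(paste(rownames(matrix), body, sep = "\t"), con)
  }
  invisible(path)
}

.num_str <- function(x) {
  # full-precision decimal form, stable across writes
  format(x, trim = TRUE, scientific = FALSE, digits = 15)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Restrict matrices to their shared samples
#'
#' Cross-assay analyses (expression vs methylation vs protein) need a common
#' sample set. All returned matrices carry identical sample ordering: the
#' intersection of all sample registries, in first-matrix order. The number
#' of samples dropped from each matrix is reported via `message()`.
#'
#' @param matrices A list of [omics_matrix()] objects.
#' @return A list of matrices of the same length, restricted to the shared
#'   samples.
#' @export
align_samples <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 1L)
  shared <- Reduce(intersect, lapply(matrices, colnames))
  shared <- colnames(matrices[[1]])[colnames(matrices[[1]]) %in% shared]
  if (length(shared) == 0L)
    stop("no samples shared by all matrices")
  lapply(seq_along(matrices), function(i) {
    m <- matrices[[i]]
    dropped <- ncol(m) - length(shared)
    if (dropped > 0)
      message("align_samples: dropped ", dropped, " sample(s) from matrix ", i)
    out <- m[, shared, drop = FALSE]
    attr(out, "value_kind") <- attr(m, "value_kind")
    class(out) <- class(m)
    out
  })
}

#' @export
`[.omics_matrix` <- function(x, i, j, ..., drop = TRUE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    attr(out, "value_kind") <- attr(x, "value_kind")
    class(out) <- class(x)
  }
  out
}

# ---------------------------------------------------------------------------
# Companion TSV dialects: feature annotation, sample phenotype, survival.

FEATURE_CLASSES <- c("gene", "isoform", "probeset", "protein")
BIOTYPES <- c("coding", "non_coding", "retained_intron", "not_applicable")
GENE_REGIONS <- c("promoter", "first_exon", "body", "utr3", "not_applicable")

#' Validate a feature annotation table
#'
#' Checks the structural invariants of per-feature metadata: unique feature
#' ids, known feature classes/biotypes/regions, and the region rule — every
#' probeset maps to a gene region while genes, isoforms and proteins carry
#' `gene_region = "not_applicable"`.
#'
#' @param annotation Data frame with columns `feature_id`, `gene_symbol`,
#'   `feature_class`, `biotype`, `gene_region` and optionally `chrom`,
#'   `chromStart`, `chromEnd`, `strand` (0-based half-open intervals, carried
#'   as metadata only).
#' @return The annotation, invisibly, or an error describing the violation.
#' @export
validate_annotation <- function(annotation) {
  req <- c("feature_id", "gene_symbol", "feature_class", "biotype", "gene_region")
  miss <- setdiff(req, names(annotation))
  if (length(miss)) stop("annotation lacks column(s): ", paste(miss, collapse = ", "))
  .check_unique(annotation$feature_id, "feature id")
  bad <- setdiff(annotation$feature_class, FEATURE_CLASSES)
  if (length(bad)) stop("unknown feature_class: ", paste(bad, collapse = ", "))
  bad <- setdiff(annotation$biotype, BIOTYPES)
  if (length(bad)) stop("unknown biotype: ", paste(bad, collapse = ", "))
  bad <- setdiff(annotation$gene_region, GENE_REGIONS)
  if (length(bad)) stop("unknown gene_region: ", paste(bad, collapse = ", "))
  probe <- annotation$feature_class == "probeset"
  if (any(probe & annotation$gene_region == "not_applicable"))
    stop("probeset(s) without a gene region: ",
         paste(utils::head(annotation$feature_id[probe & annotation$gene_region ==
                                                   "not_applicable"], 5),
               collapse = ", "))
  if (any(!probe & annotation$gene_region != "not_applicable"))
    stop("non-probeset feature(s) with a gene region: ",
         paste(utils::head(annotation$feature_id[!probe & annotation$gene_region !=
                                                   "not_applicable"], 5),
               collapse = ", "))
  invisible(annotation)
}

#' Read / write the feature annotation TSV
#'
#' probeMap-style dialect with columns `feature_id`, `gene_symbol`,
#' `feature_class`, `biotype`, `gene_region`, `chrom`, `chromStart`,
#' `chromEnd`, `strand`.
#'
#' @param path File path.
#' @return `read_annotation` returns a validated data frame.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, sep = "\t", quote = "", check.names = FALSE,
                           na.strings = .NA_TOKENS, stringsAsFactors = FALSE,
                           colClasses = "character")
  for (col in intersect(c("chromStart", "chromEnd"), names(ann)))
    ann[[col]] <- as.integer(ann[[col]])
  validate_annotation(ann)
  ann
}

#' @rdname read_annotation
#' @param annotation Data frame as returned by [read_annotation()].
#' @export
write_annotation <- function(annotation, path) {
  validate_annotation(annotation)
  .write_tsv(annotation, path)
}

#' Validate a sample metadata table
#'
#' Each sample carries a cohort code (e.g. `"READ"`, `"LGG"`), a source
#' (`tumor` or `normal`) and optionally a `tumor_group` in 1..9 used to
#' encode RPPA protein-panel availability.
#'
#' @param metadata Data frame with columns `sample_id`, `cohort`, `source`
#'   and optionally `tumor_group`.
#' @return The metadata, invisibly.
#' @export
validate_metadata <- function(metadata) {
  req <- c("sample_id", "cohort", "source")
  miss <- setdiff(req, names(metadata))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  .check_unique(metadata$sample_id, "sample id")
  bad <- setdiff(metadata$source, c("tumor", "normal"))
  if (length(bad)) stop("unknown source: ", paste(bad, collapse = ", "))
  if (!is.null(metadata$tumor_group)) {
    tg <- metadata$tumor_group[!is.na(metadata$tumor_group)]
    if (length(tg) && (any(tg < 1) || any(tg > 9)))
      stop("tumor_group out of 1..9")
  }
  invisible(metadata)
}

#' Read / write the sample phenotype TSV
#'
#' Columns: `sample_id`, `cohort`, `source`, `tumor_group`.
#' @param path File path.
#' @return `read_metadata` returns a validated data frame.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, sep = "\t", quote = "", check.names = FALSE,
                          na.strings = .NA_TOKENS, stringsAsFactors = FALSE)
  md$sample_id <- as.character(md$sample_id)
  validate_metadata(md)
  md
}

#' @rdname read_metadata
#' @param metadata Data frame as returned by [read_metadata()].
#' @export
write_metadata <- function(metadata, path) {
  validate_metadata(metadata)
  .write_tsv(metadata, path)
}

#' Read / write the survival TSV
#'
#' On disk the dialect is wide — one row per sample with columns `sample`,
#' `OS`, `OS.time`, `PFI`, `PFI.time` (event indicator and time in days).
#' In memory survival records are long: one row per (sample, endpoint) with
#' columns `sample_id`, `endpoint`, `time`, `event`.
#'
#' @param path File path.
#' @return `read_survival` returns the long-format data frame.
#' @export
read_survival <- function(path) {
  wide <- utils::read.delim(path, sep = "\t", quote = "", check.names = FALSE,
                            na.strings = .NA_TOKENS, stringsAsFactors = FALSE)
  .check_unique(wide$sample, "survival sample")
  out <- list()
  for (ep in c("OS", "PFI")) {
    tcol <- paste0(ep, ".time")
    if (!all(c(ep, tcol) %in% names(wide))) next
    keep <- !is.na(wide[[ep]]) & !is.na(wide[[tcol]])
    out[[ep]] <- data.frame(sample_id = as.character(wide$sample[keep]),
                            endpoint = ep,
                            time = as.numeric(wide[[tcol]][keep]),
                            event = as.integer(wide[[ep]][keep]),
                            stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, out)
  rownames(long) <- NULL
  validate_survival(long)
  long
}

#' @rdname read_survival
#' @param survival Long-format data frame as returned by [read_survival()].
#' @export
write_survival <- function(survival, path) {
  validate_survival(survival)
  samples <- unique(survival$sample_id)
  wide <- data.frame(sample = samples, stringsAsFactors = FALSE)
  for (ep in c("OS", "PFI")) {
    sub <- survival[survival$endpoint == ep, , drop = FALSE]
    idx <- match(samples, sub$sample_id)
    wide[[ep]] <- sub$event[idx]
    wide[[paste0(ep, ".time")]] <- sub$time[idx]
  }
  .write_tsv(wide, path)
}

#' Validate a long-format survival table
#' @param survival Data frame with columns `sample_id`, `endpoint`, `time`,
#'   `event`.
#' @return The table, invisibly.
#' @export
validate_survival <- function(survival) {
  req <- c("sample_id", "endpoint", "time", "event")
  miss <- setdiff(req, names(survival))
  if (length(miss)) stop("survival lacks column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(survival$endpoint, c("OS", "PFI"))
  if (length(bad)) stop("unknown endpoint: ", paste(bad, collapse = ", "))
  if (any(survival$time < 0, na.rm = TRUE)) stop("negative survival time")
  if (!all(survival$event %in% c(0L, 1L))) stop("event must be 0 or 1")
  key <- paste(survival$sample_id, survival$endpoint)
  if (anyDuplicated(key))
    stop("duplicate (sample, endpoint) record: ", key[duplicated(key)][1])
  invisible(survival)
}

.write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    cells <- vapply(df, function(col) {
      if (is.numeric(col) && !is.integer(col))
        ifelse(is.na(col), "NA", vapply(col, .num_str, character(1)))
      else ifelse(is.na(col), "NA", as.character(col))
    }, character(nrow(df)))
    if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
    writeLines(apply(cells, 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", quote = "", check.names = FALSE,
                    na.strings = .NA_TOKENS, stringsAsFactors = FALSE)
}
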