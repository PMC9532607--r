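#' @title Cross-cohort concordance networks
#' @description
#' Aggregates per-cohort significant correlations into an undirected edge
#' list: an edge joins a feature pair that is significantly correlated in
#' at least `min_cohorts` cohorts (conventionally 5 for gene-protein and 20
#' for protein-protein networks), and its concordance records whether the
#' correlation sign agrees across those cohorts — `total_positive` /
#' `total_negative` when every significant cohort has the same sign,
#' `partial` when signs disagree. Networks export as SIF, GraphML or TSV
#' for Cytoscape-class tools.
#' @name network
NULL

#' Concordance class from sign counts
#'
#' @param n_positive,n_negative Counts of significant cohorts with positive
#'   / negative correlation (each >= 0, sum >= 1). Vectorized.
#' @return `"total_positive"`, `"total_negative"` or `"partial"`.
#' @export
classify_concordance <- function(n_positive, n_negative) {
  if (any(n_positive < 0) || any(n_negative < 0))
    stop("sign counts must be non-negative")
  if (any(n_positive + n_negative < 1))
    stop("at least one significant cohort is required")
  ifelse(n_negative == 0, "total_positive",
         ifelse(n_positive == 0, "total_negative", "partial"))
}

#' Aggregate per-cohort correlations into concordance edges
#'
#' Tallies, for every unordered feature pair, the cohorts in which the pair
#' is significantly correlated and the sign of each such correlation;
#' pairs reaching `min_cohorts` significant cohorts become edges. Sign
#' counts and `mean_r` cover significant cohorts only — non-significant
#' cohorts are ignored entirely. Self-pairs are excluded.
#'
#' @param correlations Per-cohort output of [correlate_sets()]; pooled rows
#'   are an error (aggregation over cohorts is meaningless on pooled
#'   input).
#' @param min_cohorts Minimum number of significant cohorts for an edge.
#' @return Data frame with `feature_a`, `feature_b` (lexicographic order
#'   within the pair), `n_significant`, `n_positive`, `n_negative`,
#'   `concordance`, `mean_r`, sorted by pair.
#' @export
aggregate_edges <- function(correlations, min_cohorts = 5) {
  if (any(correlations$cohort == "pooled"))
    stop("aggregate_edges requires per-cohort correlations, not pooled rows")
  sig <- correlations[correlations$significant &
                        correlations$feature_a != correlations$feature_b, ,
                      drop = FALSE]
  if (!nrow(sig)) return(.empty_edges())
  a <- pmin(sig$feature_a, sig$feature_b)
  b <- pmax(sig$feature_a, sig$feature_b)
  key <- paste(a, b, sep = "\r")
  # a pair can appear in both orientations within a cohort (e.g. a = b
  # matrices); count each (pair, cohort) once
  dedup <- !duplicated(paste(key, sig$cohort))
  sig <- sig[dedup, , drop = FALSE]
  a <- a[dedup]; b <- b[dedup]; key <- key[dedup]
  pos <- tapply(sig$r > 0, key, sum)
  neg <- tapply(sig$r < 0, key, sum)
  mean_r <- tapply(sig$r, key, mean)
  keys <- names(pos)
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  edges <- data.frame(feature_a = parts[, 1], feature_b = parts[, 2],
                      n_significant = as.integer(pos + neg),
                      n_positive = as.integer(pos),
                      n_negative = as.integer(neg),
                      mean_r = as.numeric(mean_r),
                      stringsAsFactors = FALSE)
  edges <- edges[edges$n_significant >= min_cohorts, , drop = FALSE]
  if (!nrow(edges)) return(.empty_edges())
  edges$concordance <- classify_concordance(edges$n_positive, edges$n_negative)
  edges <- edges[order(edges$feature_a, edges$feature_b),
                 c("feature_a", "feature_b", "n_significant", "n_positive",
                   "n_negative", "concordance", "mean_r")]
  rownames(edges) <- NULL
  edges
}

.empty_edges <- function() {
  data.frame(feature_a = character(), feature_b = character(),
             n_significant = integer(), n_positive = integer(),
             n_negative = integer(), concordance = character(),
             mean_r = numeric(), stringsAsFactors = FALSE)
}

#' Export a concordance network
#'
#' SIF rows are `feature_a <tab> concordance <tab> feature_b`; GraphML
#' (written via igraph) carries every edge field as an attribute; TSV is
#' the full edge table. Row order is deterministic (lexicographic pair).
#'
#' @param edges Output of [aggregate_edges()].
#' @param format `"tsv"`, `"sif"` or `"graphml"`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
export_network <- function(edges, format = c("tsv", "sif", "graphml"), path) {
  format <- match.arg(format)
  edges <- edges[order(edges$feature_a, edges$feature_b), , drop = FALSE]
  if (format == "tsv") {
    .write_tsv(edges, path)
  } else if (format == "sif") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    if (nrow(edges))
      writeLines(paste(edges$feature_a, edges$concordance, edges$feature_b,
                       sep = "\t"), con)
    else writeLines(character(0), con)
  } else {
    g <- igraph::graph_from_data_frame(
      edges, directed = FALSE,
      vertices = data.frame(name = sort(unique(c(edges$feature_a,
                                                 edges$feature_b)))))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Features connected to two or more anchor features
#'
#' Given an edge table and a set of anchor features (e.g. the network's
#' genes), reports every other feature connected to at least two anchors,
#' with the anchor count and identities — the "shared neighbor" summary of
#' a gene-protein network.
#'
#' @param edges Output of [aggregate_edges()].
#' @param anchor_features Character vector of anchor ids (absent anchors
#'   simply contribute degree 0).
#' @return Data frame with `feature_id`, `anchor_degree`, `anchors`
#'   (comma-separated), sorted by decreasing degree then id.
#' @export
multi_degree_nodes <- function(edges, anchor_features) {
  if (!nrow(edges))
    return(data.frame(feature_id = character(), anchor_degree = integer(),
                      anchors = character(), stringsAsFactors = FALSE))
  touching <- edges[edges$feature_a %in% anchor_features |
                      edges$feature_b %in% anchor_features, , drop = FALSE]
  other <- ifelse(touching$feature_a %in% anchor_features,
                  touching$feature_b, touching$feature_a)
  anchor <- ifelse(touching$feature_a %in% anchor_features,
                   touching$feature_a, touching$feature_b)
  keep <- !(other %in% anchor_features)
  other <- other[keep]; anchor <- anchor[keep]
  if (!length(other))
    return(data.frame(feature_id = character(), anchor_degree = integer(),
                      anchors = character(), stringsAsFactors = FALSE))
  by_node <- split(anchor, other)
  out <- data.frame(
    feature_id = names(by_node),
    anchor_degree = vapply(by_node, function(x) length(unique(x)), integer(1)),
    anchors = vapply(by_node, function(x)
      paste(sort(unique(x)), collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  out <- out[out$anchor_degree >= 2L, , drop = FALSE]
  out <- out[order(-out$anchor_degree, out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
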