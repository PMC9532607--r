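#' @title End-to-end pipeline
#' @description
#' Orchestrates the full workflow — simulate (or load) a multi-cohort
#' bundle, differential expression, expression and methylation profiling,
#' pooled and per-cohort correlations, concordance networks, four-group
#' methylation stratification, and survival annotation — under a single
#' configuration whose defaults reproduce the conventional thresholds:
#' fold-change 1.4 at p <= 0.05, |r| >= 0.3 at p <= 0.05 for
#' expression/protein correlations and p <= 0.01 for per-cohort
#' methylation-expression correlations, edges in >= 5 (gene-protein) or
#' >= 20 (protein-protein) cohorts, 7 correlation-profile clusters. A run
#' manifest records every artifact with its MD5 hash; identical
#' configuration and seed give identical hashes.
#' @name pipeline
NULL

#' Build a pipeline configuration
#'
#' @param sim A [simulation_config()] (used when `input_dir` is `NULL`).
#' @param input_dir Optional directory holding a bundle written by
#'   [write_bundle()]; when given, data are loaded instead of simulated.
#' @param out_dir Output directory for all stage artifacts.
#' @param seed Integer seed; overrides `sim$seed` so one flag controls all
#'   randomness.
#' @param fc_min,p_max Differential call thresholds.
#' @param r_min Correlation magnitude threshold.
#' @param p_cor_expression Correlation p threshold for expression /
#'   protein analyses.
#' @param p_cor_methylation Correlation p threshold for per-cohort
#'   methylation-expression analyses.
#' @param min_cohorts_gene_protein,min_cohorts_protein_protein Cohort
#'   filters for the two concordance networks.
#' @param n_clusters Number of correlation-profile clusters.
#' @param center Stratification split statistic (`"median"` or `"mean"`).
#' @param stratify_gene,promoter_probe,body_probe Stratification target;
#'   when `NULL`, the second gene of the annotation (or the first, if only
#'   one) and its first promoter / first body probeset are used.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            input_dir = NULL,
                            out_dir = tempfile("panmethnet_run_"),
                            seed = 1L,
                            fc_min = 1.4, p_max = 0.05,
                            r_min = 0.3,
                            p_cor_expression = 0.05,
                            p_cor_methylation = 0.01,
                            min_cohorts_gene_protein = 5,
                            min_cohorts_protein_protein = 20,
                            n_clusters = 7,
                            center = "median",
                            stratify_gene = NULL,
                            promoter_probe = NULL,
                            body_probe = NULL) {
  structure(list(sim = sim, input_dir = input_dir, out_dir = out_dir,
                 seed = as.integer(seed), fc_min = fc_min, p_max = p_max,
                 r_min = r_min, p_cor_expression = p_cor_expression,
                 p_cor_methylation = p_cor_methylation,
                 min_cohorts_gene_protein = min_cohorts_gene_protein,
                 min_cohorts_protein_protein = min_cohorts_protein_protein,
                 n_clusters = n_clusters, center = center,
                 stratify_gene = stratify_gene,
                 promoter_probe = promoter_probe, body_probe = body_probe),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar keys map onto [pipeline_config()] arguments; an optional `sim`
#' block maps onto [simulation_config()].
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$sim)) {
    if (!is.null(raw$sim$genes))
      raw$sim$genes <- lapply(raw$sim$genes, function(g) do.call(gene_spec, g))
    raw$sim <- do.call(simulation_config, raw$sim)
  }
  do.call(pipeline_config, raw)
}

#' Validate a pipeline configuration
#'
#' Checks threshold ranges, file existence and probe/gene references;
#' returns the problems instead of erroring so callers can report them all
#' at once.
#'
#' @param config A [pipeline_config()].
#' @return Character vector of problems; empty when valid.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  add <- function(msg) problems <<- c(problems, msg)
  pos <- c("fc_min", "p_max", "r_min", "p_cor_expression",
           "p_cor_methylation", "min_cohorts_gene_protein",
           "min_cohorts_protein_protein", "n_clusters")
  for (k in pos) {
    v <- config[[k]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      add(paste0(k, " must be a positive number (got ",
                 deparse(config[[k]]), ")"))
  }
  if (is.numeric(config$fc_min) && length(config$fc_min) == 1L &&
      !is.na(config$fc_min) && config$fc_min > 0 && config$fc_min < 1)
    add("fc_min below 1 is meaningless for a signed fold change")
  for (k in c("p_max", "p_cor_expression", "p_cor_methylation"))
    if (is.numeric(config[[k]]) && length(config[[k]]) == 1L &&
        !is.na(config[[k]]) && config[[k]] > 1)
      add(paste0(k, " must not exceed 1"))
  if (!config$center %in% c("median", "mean"))
    add("center must be 'median' or 'mean'")
  if (!is.null(config$input_dir)) {
    if (!dir.exists(config$input_dir))
      add(paste0("input_dir does not exist: ", config$input_dir))
    else for (f in c("expression.tsv", "methylation.tsv", "phenotype.tsv",
                     "annotation.tsv", "survival.tsv"))
      if (!file.exists(file.path(config$input_dir, f)))
        add(paste0("input_dir lacks ", f))
  } else if (!inherits(config$sim, "simulation_config")) {
    add("either input_dir or a simulation_config is required")
  }
  if (!is.null(config$promoter_probe) || !is.null(config$body_probe)) {
    ann <- tryCatch(.pipeline_annotation(config), error = function(e) NULL)
    if (!is.null(ann)) {
      for (p in c(config$promoter_probe, config$body_probe))
        if (!p %in% ann$feature_id[ann$feature_class == "probeset"])
          add(paste0("stratification probe not in annotation: ", p))
    }
  }
  if (!is.null(config$stratify_gene)) {
    ann <- tryCatch(.pipeline_annotation(config), error = function(e) NULL)
    if (!is.null(ann) &&
        !config$stratify_gene %in% ann$feature_id[ann$feature_class == "gene"])
      add(paste0("stratify_gene not in annotation: ", config$stratify_gene))
  }
  problems
}

.pipeline_annotation <- function(config) {
  if (!is.null(config$input_dir))
    read_annotation(file.path(config$input_dir, "annotation.tsv"))
  else simulated_annotation(config$sim)
}

.resolve_stratification <- function(config, annotation) {
  genes <- annotation$feature_id[annotation$feature_class == "gene"]
  gene <- config$stratify_gene %||%
    (if (length(genes) >= 2) genes[2] else genes[1])
  probes <- annotation[annotation$feature_class == "probeset" &
                         annotation$gene_symbol == gene, , drop = FALSE]
  pick <- function(region, configured) {
    if (!is.null(configured)) return(configured)
    hit <- probes$feature_id[probes$gene_region == region]
    if (!length(hit)) stop("no ", region, " probeset annotated for ", gene)
    hit[1]
  }
  list(gene = gene,
       promoter_probe = pick("promoter", config$promoter_probe),
       body_probe = pick("body", config$body_probe))
}

.stage_log <- function(stage, t0) {
  message(sprintf("[%s] done in %.1fs", stage,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full pipeline
#'
#' Executes every stage in order, writes each stage's TSV / network
#' artifacts under `config$out_dir`, and returns the in-memory results plus
#' a manifest (stage, file, MD5 hash, bytes). Any stage error aborts with
#' the stage name; a `FAILED` marker naming the stage is left in the
#' manifest file.
#'
#' @param config A [pipeline_config()]; validated first — any problem is an
#'   error.
#' @return Invisibly, a `pipeline_result` list: `bundle`, `diff_pooled`,
#'   `diff_per_cohort`, `diff_summary`, `expression_profile`,
#'   `methylation_profile`, `cor_expr_meth_pooled`,
#'   `cor_expr_meth_cohort`, `cor_expr_protein`, `cor_protein_protein`,
#'   `protein_clusters`, `gene_protein_edges`, `protein_protein_edges`,
#'   `shared_proteins`, `stratification`, `strat_pairs`, `strat_groups`,
#'   `survival_expression`, `survival_methylation`, `manifest`.
#' @export
run_pipeline <- function(config) {
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  manifest_path <- file.path(config$out_dir, "manifest.tsv")
  emit <- function(stage, name, writer) {
    path <- file.path(config$out_dir, name)
    writer(path)
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, file = name,
      md5 = unname(tools::md5sum(path)),
      bytes = file.size(path), stringsAsFactors = FALSE)
  }
  stage <- "simulate"
  res <- list()
  tryCatch({
    t0 <- as.numeric(Sys.time())
    bundle <- if (!is.null(config$input_dir)) read_bundle(config$input_dir)
    else {
      cfg <- config$sim
      cfg$seed <- config$seed
      generate_bundle(cfg)
    }
    res$bundle <- bundle
    emit(stage, "expression.tsv", function(p) write_matrix(bundle$expression, p))
    emit(stage, "methylation.tsv", function(p) write_matrix(bundle$methylation, p))
    if (!is.null(bundle$protein))
      emit(stage, "protein.tsv", function(p) write_matrix(bundle$protein, p))
    emit(stage, "phenotype.tsv", function(p) write_metadata(bundle$metadata, p))
    .stage_log(stage, t0)

    stage <- "diffexpr"; t0 <- as.numeric(Sys.time())
    res$diff_pooled <- suppressMessages(differential_table(
      bundle$expression, bundle$metadata, "pooled",
      fc_min = config$fc_min, p_max = config$p_max))
    res$diff_per_cohort <- suppressMessages(differential_table(
      bundle$expression, bundle$metadata, "per_cohort",
      fc_min = config$fc_min, p_max = config$p_max))
    res$diff_summary <- differential_summary(res$diff_per_cohort)
    emit(stage, "differential_pooled.tsv",
         function(p) .write_tsv(res$diff_pooled, p))
    emit(stage, "differential_per_cohort.tsv",
         function(p) .write_tsv(res$diff_per_cohort, p))
    emit(stage, "differential_summary.tsv",
         function(p) .write_tsv(res$diff_summary, p))
    emit(stage, "volcano_expression.tsv",
         function(p) .write_tsv(volcano_table(res$diff_per_cohort), p))
    .stage_log(stage, t0)

    stage <- "profile"; t0 <- as.numeric(Sys.time())
    res$expression_profile <- suppressMessages(
      profile_features(bundle$expression, bundle$metadata))
    res$methylation_profile <- suppressMessages(
      methylation_profile(bundle$methylation, bundle$metadata))
    emit(stage, "expression_profile.tsv",
         function(p) .write_tsv(res$expression_profile, p))
    emit(stage, "expression_calls.tsv", function(p)
      write_call_matrix(call_matrix(res$expression_profile), p))
    emit(stage, "methylation_states.tsv",
         function(p) .write_tsv(res$methylation_profile, p))
    emit(stage, "methylation_calls.tsv", function(p)
      write_call_matrix(call_matrix(res$methylation_profile), p))
    .stage_log(stage, t0)

    stage <- "correlate"; t0 <- as.numeric(Sys.time())
    md <- bundle$metadata
    tumor_ids <- md$sample_id[md$source == "tumor"]
    expr_t <- bundle$expression[, colnames(bundle$expression) %in% tumor_ids,
                                drop = FALSE]
    res$cor_expr_meth_pooled <- suppressMessages(correlate_sets(
      expr_t, bundle$methylation, mode = "pooled",
      r_min = config$r_min, p_max = config$p_cor_expression))
    res$cor_expr_meth_cohort <- suppressMessages(correlate_sets(
      expr_t, bundle$methylation, md, mode = "per_cohort",
      r_min = config$r_min, p_max = config$p_cor_methylation))
    emit(stage, "cor_expression_methylation_pooled.tsv",
         function(p) .write_tsv(res$cor_expr_meth_pooled, p))
    emit(stage, "cor_expression_methylation_per_cohort.tsv",
         function(p) .write_tsv(res$cor_expr_meth_cohort, p))
    if (!is.null(bundle$protein)) {
      res$cor_expr_protein <- suppressMessages(correlate_sets(
        expr_t, bundle$protein, md, mode = "per_cohort",
        r_min = config$r_min, p_max = config$p_cor_expression))
      res$cor_protein_protein <- suppressMessages(correlate_sets(
        bundle$protein, bundle$protein, md, mode = "per_cohort",
        r_min = config$r_min, p_max = config$p_cor_expression))
      cor_ep_pooled <- suppressMessages(correlate_sets(
        expr_t, bundle$protein, mode = "pooled",
        r_min = config$r_min, p_max = config$p_cor_expression))
      grid <- t(correlation_grid(cor_ep_pooled))
      k <- min(config$n_clusters, nrow(grid))
      res$protein_clusters <- suppressMessages(cluster_profiles(grid, k))
      emit(stage, "cor_expression_protein_per_cohort.tsv",
           function(p) .write_tsv(res$cor_expr_protein, p))
      emit(stage, "protein_clusters.tsv", function(p) .write_tsv(
        data.frame(protein_id = names(res$protein_clusters),
                   cluster = unname(res$protein_clusters),
                   stringsAsFactors = FALSE), p))
    }
    .stage_log(stage, t0)

    stage <- "network"; t0 <- as.numeric(Sys.time())
    if (!is.null(bundle$protein)) {
      res$gene_protein_edges <- aggregate_edges(
        res$cor_expr_protein, min_cohorts = config$min_cohorts_gene_protein)
      res$protein_protein_edges <- aggregate_edges(
        res$cor_protein_protein,
        min_cohorts = config$min_cohorts_protein_protein)
      anchors <- bundle$annotation$feature_id[
        bundle$annotation$feature_class == "gene"]
      res$shared_proteins <- multi_degree_nodes(res$gene_protein_edges,
                                                anchors)
      emit(stage, "gene_protein_edges.tsv", function(p)
        export_network(res$gene_protein_edges, "tsv", p))
      emit(stage, "gene_protein_network.sif", function(p)
        export_network(res$gene_protein_edges, "sif", p))
      if (nrow(res$gene_protein_edges))
        emit(stage, "gene_protein_network.graphml", function(p)
          export_network(res$gene_protein_edges, "graphml", p))
      emit(stage, "protein_protein_edges.tsv", function(p)
        export_network(res$protein_protein_edges, "tsv", p))
      emit(stage, "shared_proteins.tsv",
           function(p) .write_tsv(res$shared_proteins, p))
    }
    .stage_log(stage, t0)

    stage <- "stratify"; t0 <- as.numeric(Sys.time())
    strat_cfg <- .resolve_stratification(config, bundle$annotation)
    res$stratification <- stratify(
      bundle$methylation, strat_cfg$promoter_probe, strat_cfg$body_probe,
      center = config$center)
    res$strat_pairs <- suppressMessages(group_differential(
      bundle$expression, res$stratification, strat_cfg$gene))
    res$strat_groups <- group_summary(bundle$expression, res$stratification,
                                      strat_cfg$gene)
    emit(stage, "stratification_assignment.tsv", function(p) .write_tsv(
      data.frame(sample_id = names(res$stratification$assignment),
                 group = unname(res$stratification$assignment),
                 stringsAsFactors = FALSE), p))
    emit(stage, "stratification_pairs.tsv",
         function(p) .write_tsv(res$strat_pairs, p))
    emit(stage, "stratification_groups.tsv",
         function(p) .write_tsv(res$strat_groups, p))
    .stage_log(stage, t0)

    stage <- "survive"; t0 <- as.numeric(Sys.time())
    genes <- bundle$annotation$feature_id[
      bundle$annotation$feature_class == "gene"]
    expr_g <- bundle$expression[rownames(bundle$expression) %in% genes, ,
                                drop = FALSE]
    res$survival_expression <- do.call(rbind, lapply(c("OS", "PFI"),
      function(ep) annotate_matrix(expr_g, bundle$survival, md, ep,
                                   p_max = config$p_max)))
    res$survival_methylation <- do.call(rbind, lapply(c("OS", "PFI"),
      function(ep) annotate_matrix(bundle$methylation, bundle$survival, md,
                                   ep, p_max = config$p_max)))
    emit(stage, "survival_expression.tsv",
         function(p) .write_tsv(res$survival_expression, p))
    emit(stage, "survival_expression_volcano.tsv", function(p)
      .write_tsv(survival_volcano(res$survival_expression), p))
    emit(stage, "survival_methylation.tsv",
         function(p) .write_tsv(res$survival_methylation, p))
    emit(stage, "survival_methylation_volcano.tsv", function(p)
      .write_tsv(survival_volcano(res$survival_methylation), p))
    .stage_log(stage, t0)
  }, error = function(e) {
    mf <- do.call(rbind, manifest)
    mf <- rbind(mf, data.frame(stage = stage, file = "FAILED",
                               md5 = NA_character_, bytes = NA_real_,
                               stringsAsFactors = FALSE))
    .write_tsv(mf, manifest_path)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  res$manifest <- do.call(rbind, manifest)
  .write_tsv(res$manifest, manifest_path)
  class(res) <- "pipeline_result"
  invisible(res)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", nrow(x$manifest), " artifact(s) over ",
      length(unique(x$manifest$stage)), " stage(s)\n", sep = "")
  print(x$manifest[, c("stage", "file")])
  invisible(x)
}
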