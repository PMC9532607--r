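#' @title Synthetic multi-cohort generator
#' @description
#' Generates linked expression / methylation / protein / survival data with
#' the statistical structure the pan-cancer analyses assume: per-cohort
#' Gaussian expression in log2(fpkm + 0.001) space with planted tumor
#' shifts, isoforms as noisy biotype-offset copies of their gene, 450K-style
#' beta values coupled to expression through a latent Gaussian copula
#' (promoter probes low and typically negatively coupled, gene-body probes
#' high and typically positively coupled), RPPA-style protein levels
#' available only in cohort subsets, and exponential survival times whose
#' log-hazard is linear in standardized expression. Every planted parameter
#' is recorded in a truth table so downstream stages can be validated.
#' @name synthetic_cohort
NULL

#' The 33 TCGA tumor-type codes used to name synthetic cohorts
#' @export
TCGA_COHORTS <- c("ACC", "BLCA", "BRCA", "CESC", "CHOL", "COAD", "DLBC",
                  "ESCA", "GBM", "HNSC", "KICH", "KIRC", "KIRP", "LAML",
                  "LGG", "LIHC", "LUAD", "LUSC", "MESO", "OV", "PAAD",
                  "PCPG", "PRAD", "READ", "SARC", "SKCM", "STAD", "TGCT",
                  "THCA", "THYM", "UCEC", "UCS", "UVM")

# logistic location per gene region: promoters sit hypomethylated, gene
# bodies hypermethylated, 1st exon / 3'UTR intermediate
.REGION_LOC <- c(promoter = -2, first_exon = -0.5, body = 2, utr3 = 0.5)
.REGION_SCALE <- 1

#' Specify one synthetic gene
#'
#' @param gene_id Gene identifier.
#' @param base_mean Normal-tissue mean expression, log2(fpkm + 0.001) units.
#' @param tumor_shift Log2-units added to the tumor mean (the planted
#'   differential effect; `2^|tumor_shift|` is the expected fold change).
#' @param promoter_coupling Target Pearson correlation between promoter (and
#'   1st-exon) probe beta values and expression, in (-1, 1); typically
#'   negative.
#' @param body_coupling Target correlation for gene-body (and 3'UTR) probes;
#'   typically positive.
#' @param survival_effect Log hazard ratio per standard deviation of
#'   expression (positive = higher expression, worse survival).
#' @param isoform_biotypes Character vector of biotypes, one isoform each.
#' @param probes_per_region Named integer vector over
#'   `promoter`, `first_exon`, `body`, `utr3`.
#' @return A `gene_spec` list.
#' @export
gene_spec <- function(gene_id,
                      base_mean = 2,
                      tumor_shift = 0,
                      promoter_coupling = 0,
                      body_coupling = 0,
                      survival_effect = 0,
                      isoform_biotypes = c(rep("coding", 4),
                                           rep("non_coding", 2),
                                           rep("retained_intron", 2)),
                      probes_per_region = c(promoter = 6, first_exon = 4,
                                            body = 8, utr3 = 2)) {
  for (r in c(promoter_coupling, body_coupling))
    if (abs(r) >= 1) stop("infeasible coupling for ", gene_id, ": |r| >= 1")
  stopifnot(all(isoform_biotypes %in% BIOTYPES))
  stopifnot(all(names(probes_per_region) %in% names(.REGION_LOC)))
  structure(list(gene_id = gene_id, base_mean = base_mean,
                 tumor_shift = tumor_shift,
                 promoter_coupling = promoter_coupling,
                 body_coupling = body_coupling,
                 survival_effect = survival_effect,
                 isoform_biotypes = isoform_biotypes,
                 probes_per_region = probes_per_region),
            class = "gene_spec")
}

#' Default three-gene network specification
#'
#' Emulates the shape of a small tumor-microenvironment network: one gene
#' broadly upregulated with uniformly negative methylation coupling, one
#' broadly downregulated with opposed promoter (negative) and gene-body
#' (positive) couplings, and one upregulated gene with body-dominant
#' positive coupling.
#' @return List of three [gene_spec()] objects.
#' @export
default_genes <- function() {
  list(
    gene_spec("simLCN2", base_mean = 2, tumor_shift = 2,
              promoter_coupling = -0.5, body_coupling = -0.3,
              survival_effect = 0.7),
    gene_spec("simSLC22A17", base_mean = 4, tumor_shift = -1.5,
              promoter_coupling = -0.5, body_coupling = 0.3,
              survival_effect = -0.7),
    gene_spec("simMMP9", base_mean = 1, tumor_shift = 2,
              promoter_coupling = -0.3, body_coupling = 0.3,
              survival_effect = 0.7)
  )
}

#' Default synthetic RPPA panel
#'
#' Twelve proteins, each coupled to one network gene at a signed target
#' correlation. Six form a core panel measured in all nine tumor groups
#' with strong couplings (|r| = 0.7), so pairs of core proteins attached to
#' the same gene inherit a pairwise correlation of about 0.49 and can form
#' protein-protein edges across many cohorts; the other six are measured
#' only in a 5-of-9 window of tumor groups at |r| = 0.5, so panel
#' availability differs across cohorts as it does for real RPPA data.
#' @param genes List of [gene_spec()] objects the proteins attach to.
#' @return Data frame with columns `protein_id`, `gene_id`, `target_r`,
#'   `groups` (comma-separated tumor groups where measured).
#' @export
default_proteins <- function(genes = default_genes()) {
  n <- 12L
  core <- 6L
  gene_ids <- vapply(genes, `[[`, character(1), "gene_id")
  protein_id <- sprintf("PROT%02d", seq_len(n))
  gene_id <- gene_ids[((seq_len(n) - 1L) %% length(gene_ids)) + 1L]
  target_r <- ifelse(seq_len(n) <= core, 0.7, 0.5) *
    ifelse(seq_len(n) %% 2 == 0, -1, 1)
  groups <- vapply(seq_len(n), function(j) {
    if (j <= core) return(paste(1:9, collapse = ","))
    w <- ((j - 1L + 0:4) %% 9L) + 1L
    paste(sort(w), collapse = ",")
  }, character(1))
  data.frame(protein_id = protein_id, gene_id = gene_id,
             target_r = target_r, groups = groups,
             stringsAsFactors = FALSE)
}

#' Build a simulation configuration
#'
#' The defaults are the study conditions the generator emulates: 33 cohorts
#' named with TCGA codes, 200 tumor and 50 matched normal samples per
#' cohort, a three-gene network with eight isoforms and twenty probesets per
#' gene, noise of 1 log2-unit, and administrative censoring targeting
#' roughly 30% censored at null.
#'
#' @param n_cohorts Number of tumor cohorts.
#' @param samples_per_cohort_tumor,samples_per_cohort_normal Per-cohort
#'   sample counts (each >= 2).
#' @param genes List of [gene_spec()]s.
#' @param proteins Protein panel data frame (see [default_proteins()]), or
#'   `NULL` for no protein data.
#' @param noise_sd Residual sd of gene expression, log2-units.
#' @param isoform_noise_sd Extra sd of isoforms around their gene.
#' @param cohort_sd Sd of per-cohort baseline shifts around `base_mean`.
#' @param os_rate,pfi_rate Baseline exponential hazards (per day) for
#'   overall survival and progression-free interval.
#' @param censor_quantile Administrative horizon is the baseline survival
#'   quantile at this probability (0.7 leaves ~30% censored at null).
#' @param seed Integer; fully determines the generated bundle.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_cohorts = 33,
                              samples_per_cohort_tumor = 200,
                              samples_per_cohort_normal = 50,
                              genes = default_genes(),
                              proteins = default_proteins(genes),
                              noise_sd = 1,
                              isoform_noise_sd = 0.3,
                              cohort_sd = 0.5,
                              os_rate = 1 / 1000,
                              pfi_rate = 1 / 600,
                              censor_quantile = 0.7,
                              seed = 1L) {
  stopifnot(n_cohorts >= 1, samples_per_cohort_tumor >= 2,
            samples_per_cohort_normal >= 2, noise_sd > 0,
            censor_quantile > 0, censor_quantile < 1)
  structure(list(n_cohorts = n_cohorts,
                 samples_per_cohort_tumor = samples_per_cohort_tumor,
                 samples_per_cohort_normal = samples_per_cohort_normal,
                 genes = genes, proteins = proteins,
                 noise_sd = noise_sd, isoform_noise_sd = isoform_noise_sd,
                 cohort_sd = cohort_sd, os_rate = os_rate,
                 pfi_rate = pfi_rate, censor_quantile = censor_quantile,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Read a simulation configuration from YAML
#'
#' Scalar keys map directly onto [simulation_config()] arguments; an
#' optional `genes` block is a list of [gene_spec()] argument sets.
#' @param path Path to the YAML file.
#' @return A `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$genes))
    raw$genes <- lapply(raw$genes, function(g) do.call(gene_spec, g))
  if (!is.null(raw$proteins))
    raw$proteins <- do.call(data.frame,
                            c(raw$proteins, stringsAsFactors = FALSE))
  do.call(simulation_config, raw)
}

# attenuation of Pearson correlation induced by the logistic transform:
# for Z ~ N(0,1), a = cor(plogis(loc + s*Z), Z), evaluated by quadrature.
# Planting latent coupling r/a yields observed beta-expression correlation r.
.logistic_attenuation <- function(loc, s = .REGION_SCALE) {
  g <- function(z) stats::plogis(loc + s * z)
  phi <- function(z) stats::dnorm(z)
  m <- stats::integrate(function(z) g(z) * phi(z), -8, 8)$value
  v <- stats::integrate(function(z) (g(z) - m)^2 * phi(z), -8, 8)$value
  cz <- stats::integrate(function(z) g(z) * z * phi(z), -8, 8)$value
  cz / sqrt(v)
}

.region_coupling <- function(spec, region) {
  switch(region,
         promoter = spec$promoter_coupling,
         first_exon = spec$promoter_coupling,
         body = spec$body_coupling,
         utr3 = spec$body_coupling)
}

.probe_ids <- function(gene_index, spec) {
  n <- sum(spec$probes_per_region)
  sprintf("cg%02d%06d", gene_index, seq_len(n))
}

#' Feature annotation implied by a simulation configuration
#' @param config A [simulation_config()].
#' @return A validated annotation data frame covering genes, isoforms,
#'   probesets and proteins.
#' @export
simulated_annotation <- function(config) {
  rows <- list()
  for (gi in seq_along(config$genes)) {
    spec <- config$genes[[gi]]
    g <- spec$gene_id
    rows[[length(rows) + 1L]] <-
      data.frame(feature_id = g, gene_symbol = g, feature_class = "gene",
                 biotype = "coding", gene_region = "not_applicable",
                 stringsAsFactors = FALSE)
    n_iso <- length(spec$isoform_biotypes)
    if (n_iso)
      rows[[length(rows) + 1L]] <-
        data.frame(feature_id = sprintf("%s.iso%02d", g, seq_len(n_iso)),
                   gene_symbol = g, feature_class = "isoform",
                   biotype = spec$isoform_biotypes,
                   gene_region = "not_applicable", stringsAsFactors = FALSE)
    regions <- rep(names(spec$probes_per_region), spec$probes_per_region)
    rows[[length(rows) + 1L]] <-
      data.frame(feature_id = .probe_ids(gi, spec), gene_symbol = g,
                 feature_class = "probeset", biotype = "not_applicable",
                 gene_region = regions, stringsAsFactors = FALSE)
  }
  if (!is.null(config$proteins))
    rows[[length(rows) + 1L]] <-
      data.frame(feature_id = config$proteins$protein_id,
                 gene_symbol = config$proteins$gene_id,
                 feature_class = "protein", biotype = "not_applicable",
                 gene_region = "not_applicable", stringsAsFactors = FALSE)
  ann <- do.call(rbind, rows)
  rownames(ann) <- NULL
  validate_annotation(ann)
  ann
}

.biotype_offset <- c(coding = -0.5, non_coding = -3, retained_intron = -4,
                     not_applicable = 0)

#' Generate a synthetic multi-cohort bundle
#'
#' Draws the full linked data set described in [simulation_config()]. The
#' same configuration (including its seed) always produces a byte-identical
#' bundle. Methylation, protein and survival data cover tumor samples only,
#' mirroring the pan-cancer sources these shapes emulate.
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_bundle`: list with elements `expression`,
#'   `methylation`, `protein` ([omics_matrix()]s), `annotation`, `metadata`,
#'   `survival`, `truth` (data frames) and `config`.
#' @examples
#' cfg <- simulation_config(n_cohorts = 2, samples_per_cohort_tumor = 20,
#'                          samples_per_cohort_normal = 10, seed = 7)
#' b <- generate_bundle(cfg)
#' dim(b$expression)
#' @export
generate_bundle <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  cohorts <- if (config$n_cohorts <= length(TCGA_COHORTS))
    TCGA_COHORTS[seq_len(config$n_cohorts)]
  else c(TCGA_COHORTS, sprintf("SIM%02d", seq_len(config$n_cohorts -
                                                    length(TCGA_COHORTS))))
  nt <- config$samples_per_cohort_tumor
  nn <- config$samples_per_cohort_normal
  ann <- simulated_annotation(config)
  expr_features <- ann$feature_id[ann$feature_class %in% c("gene", "isoform")]
  meth_features <- ann$feature_id[ann$feature_class == "probeset"]
  prot_features <- ann$feature_id[ann$feature_class == "protein"]

  tumor_ids <- unlist(lapply(cohorts, function(co)
    sprintf("%s-T%03d", co, seq_len(nt))))
  normal_ids <- unlist(lapply(cohorts, function(co)
    sprintf("%s-N%03d", co, seq_len(nn))))
  all_ids <- c(tumor_ids, normal_ids)

  metadata <- data.frame(
    sample_id = all_ids,
    cohort = c(rep(cohorts, each = nt), rep(cohorts, each = nn)),
    source = c(rep("tumor", length(tumor_ids)),
               rep("normal", length(normal_ids))),
    tumor_group = ((match(c(rep(cohorts, each = nt), rep(cohorts, each = nn)),
                          cohorts) - 1L) %% 9L) + 1L,
    stringsAsFactors = FALSE)

  expr <- matrix(NA_real_, length(expr_features), length(all_ids),
                 dimnames = list(expr_features, all_ids))
  meth <- matrix(NA_real_, length(meth_features), length(tumor_ids),
                 dimnames = list(meth_features, tumor_ids))
  prot <- if (length(prot_features))
    matrix(NA_real_, length(prot_features), length(tumor_ids),
           dimnames = list(prot_features, tumor_ids)) else NULL

  atten <- vapply(names(.REGION_LOC), function(r)
    .logistic_attenuation(.REGION_LOC[[r]]), numeric(1))

  truth <- list()
  surv_rows <- list()
  os_h <- stats::qexp(config$censor_quantile, rate = config$os_rate)
  pfi_h <- stats::qexp(config$censor_quantile, rate = config$pfi_rate)

  for (ci in seq_along(cohorts)) {
    co <- cohorts[ci]
    t_ids <- sprintf("%s-T%03d", co, seq_len(nt))
    n_ids <- sprintf("%s-N%03d", co, seq_len(nn))
    loghaz_os <- rep(0, nt)
    loghaz_pfi <- rep(0, nt)

    for (gi in seq_along(config$genes)) {
      spec <- config$genes[[gi]]
      baseline <- spec$base_mean + stats::rnorm(1, 0, config$cohort_sd)
      x_t <- baseline + spec$tumor_shift + stats::rnorm(nt, 0, config$noise_sd)
      x_n <- baseline + stats::rnorm(nn, 0, config$noise_sd)
      x_t <- pmax(x_t, EXPRESSION_FLOOR)
      x_n <- pmax(x_n, EXPRESSION_FLOOR)
      expr[spec$gene_id, t_ids] <- x_t
      expr[spec$gene_id, n_ids] <- x_n

      n_iso <- length(spec$isoform_biotypes)
      if (n_iso) for (ii in seq_len(n_iso)) {
        off <- .biotype_offset[[spec$isoform_biotypes[ii]]]
        iso_id <- sprintf("%s.iso%02d", spec$gene_id, ii)
        expr[iso_id, t_ids] <- pmax(x_t + off +
          stats::rnorm(nt, 0, config$isoform_noise_sd), EXPRESSION_FLOOR)
        expr[iso_id, n_ids] <- pmax(x_n + off +
          stats::rnorm(nn, 0, config$isoform_noise_sd), EXPRESSION_FLOOR)
      }

      x_std <- as.numeric(scale(x_t))
      if (stats::sd(x_t) == 0) x_std <- rep(0, nt)

      pids <- .probe_ids(gi, spec)
      regions <- rep(names(spec$probes_per_region), spec$probes_per_region)
      for (pi in seq_along(pids)) {
        region <- regions[pi]
        r_target <- .region_coupling(spec, region)
        r_lat <- r_target / atten[[region]]
        if (abs(r_lat) >= 1)
          stop("infeasible coupling for ", spec$gene_id, " ", region,
               ": target ", r_target, " needs latent |r| >= 1")
        z <- r_lat * x_std + sqrt(1 - r_lat^2) * stats::rnorm(nt)
        meth[pids[pi], t_ids] <-
          stats::plogis(.REGION_LOC[[region]] + .REGION_SCALE * z)
      }

      loghaz_os <- loghaz_os + spec$survival_effect * x_std
      loghaz_pfi <- loghaz_pfi + spec$survival_effect * x_std

      truth[[length(truth) + 1L]] <- data.frame(
        cohort = co, gene_id = spec$gene_id, baseline = baseline,
        tumor_shift = spec$tumor_shift,
        promoter_coupling = spec$promoter_coupling,
        body_coupling = spec$body_coupling,
        survival_effect = spec$survival_effect, stringsAsFactors = FALSE)
    }

    if (!is.null(config$proteins) && nrow(config$proteins)) {
      grp <- ((ci - 1L) %% 9L) + 1L
      for (pj in seq_len(nrow(config$proteins))) {
        p <- config$proteins[pj, ]
        measured <- grp %in% as.integer(strsplit(p$groups, ",")[[1]])
        if (!measured) next
        xg <- expr[p$gene_id, t_ids]
        xs <- if (stats::sd(xg) > 0) as.numeric(scale(xg)) else rep(0, nt)
        prot[p$protein_id, t_ids] <-
          p$target_r * xs + sqrt(1 - p$target_r^2) * stats::rnorm(nt)
      }
    }

    t_os <- stats::rexp(nt, rate = config$os_rate * exp(loghaz_os))
    t_pfi <- stats::rexp(nt, rate = config$pfi_rate * exp(loghaz_pfi))
    surv_rows[[length(surv_rows) + 1L]] <- data.frame(
      sample_id = rep(t_ids, 2L),
      endpoint = rep(c("OS", "PFI"), each = nt),
      time = c(pmin(t_os, os_h), pmin(t_pfi, pfi_h)),
      event = as.integer(c(t_os <= os_h, t_pfi <= pfi_h)),
      stringsAsFactors = FALSE)
  }

  bundle <- list(
    expression = omics_matrix(expr, "expression_log2fpkm"),
    methylation = omics_matrix(meth, "methylation_beta"),
    protein = if (!is.null(prot)) omics_matrix(prot, "protein_rppa") else NULL,
    annotation = ann,
    metadata = metadata,
    survival = do.call(rbind, surv_rows),
    truth = do.call(rbind, truth),
    config = config)
  rownames(bundle$survival) <- NULL
  rownames(bundle$truth) <- NULL
  validate_metadata(bundle$metadata)
  validate_survival(bundle$survival)
  class(bundle) <- "synthetic_bundle"
  bundle
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("<synthetic_bundle> ", length(unique(x$metadata$cohort)), " cohorts, ",
      nrow(x$metadata), " samples; expression ", nrow(x$expression),
      " x ", ncol(x$expression), ", methylation ", nrow(x$methylation),
      " x ", ncol(x$methylation),
      if (!is.null(x$protein)) paste0(", protein ", nrow(x$protein),
                                      " x ", ncol(x$protein)),
      "\n", sep = "")
  invisible(x)
}

#' Write / read a synthetic bundle on disk
#'
#' All components are written in the package's TSV dialects
#' (`expression.tsv`, `methylation.tsv`, `protein.tsv`, `annotation.tsv`,
#' `phenotype.tsv`, `survival.tsv`, `truth.tsv`); re-reading reproduces the
#' in-memory data.
#'
#' @param bundle A `synthetic_bundle`.
#' @param directory Output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_bundle <- function(bundle, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(directory, f)
  write_matrix(bundle$expression, p("expression.tsv"))
  write_matrix(bundle$methylation, p("methylation.tsv"))
  if (!is.null(bundle$protein)) write_matrix(bundle$protein, p("protein.tsv"))
  write_annotation(bundle$annotation, p("annotation.tsv"))
  write_metadata(bundle$metadata, p("phenotype.tsv"))
  write_survival(bundle$survival, p("survival.tsv"))
  .write_tsv(bundle$truth, p("truth.tsv"))
  invisible(directory)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(directory) {
  p <- function(f) file.path(directory, f)
  bundle <- list(
    expression = read_matrix(p("expression.tsv"), "expression_log2fpkm"),
    methylation = read_matrix(p("methylation.tsv"), "methylation_beta"),
    protein = if (file.exists(p("protein.tsv")))
      read_matrix(p("protein.tsv"), "protein_rppa") else NULL,
    annotation = read_annotation(p("annotation.tsv")),
    metadata = read_metadata(p("phenotype.tsv")),
    survival = read_survival(p("survival.tsv")),
    truth = if (file.exists(p("truth.tsv"))) .read_tsv(p("truth.tsv")) else NULL,
    config = NULL)
  class(bundle) <- "synthetic_bundle"
  bundle
}
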