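#' Pipeline configuration
#'
#' Validates paths and merges user settings over the default parameters
#' (MAF > 0.05, r2 < 0.05, window 1000 / step 50, geno 0.1, mind 0.2,
#' k = 10 PCs, CPM > 0.05 in at least 20% of samples).
#'
#' @param vcf_a primary (RNA-seq-derived) VCF path.
#' @param vcf_b optional paired (array) VCF path; enables the concordance
#'   and PC-comparison stages.
#' @param panel optional reference SNP panel TSV; enables panel intersection.
#' @param counts,meta optional expression count TSV (genes x samples, first
#'   column gene id) and sample metadata TSV (columns `sample`, `sex`, and
#'   any covariates); enable the DGE/inflation stage.
#' @param out_dir output directory (created if absent).
#' @param thresholds a [qc_thresholds()] object.
#' @param k_pcs number of principal components.
#' @param covariate_cols metadata columns used as nuisance covariates.
#' @param stages character vector of optional stage toggles; subset of
#'   `c("panel", "concordance", "compare", "dge")`. Stages missing their
#'   inputs are skipped.
#' @return a validated list of class `PipelineConfig`.
#' @export
pipeline_config <- function(vcf_a, vcf_b = NULL, panel = NULL,
                            counts = NULL, meta = NULL,
                            out_dir = "rnapopstruct_out",
                            thresholds = qc_thresholds(), k_pcs = 10L,
                            covariate_cols = NULL,
                            stages = c("panel", "concordance", "compare", "dge")) {
  for (f in c(vcf_a, vcf_b, panel, counts, meta)) {
    if (!is.null(f) && !file.exists(f)) stop("input file not found: ", f)
  }
  structure(list(vcf_a = vcf_a, vcf_b = vcf_b, panel = panel,
                 counts = counts, meta = meta, out_dir = out_dir,
                 thresholds = thresholds, k_pcs = as.integer(k_pcs),
                 covariate_cols = covariate_cols, stages = stages),
            class = "PipelineConfig")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' QC (sample then variant filters) -> optional panel intersection -> LD
#' pruning -> PCA, then optionally harmonization/concordance against the
#' paired VCF, PC-set comparison (Spearman + CCA/Wilks/shared variance) and
#' the DGE inflation stage. Every stage writes a TSV under the output
#' directory, and a JSON run log records the effective parameters, input
#' file hashes and row counts (kept + removed equals input at every
#' filter). Rerunning with identical inputs reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return named list (manifest) of output file paths, invisibly also
#'   written to the run log.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$out_dir, name)
  manifest <- list()
  log <- list(parameters = unclass(config$thresholds),
              k_pcs = config$k_pcs,
              inputs = list(), counts = list())
  log$parameters$excluded_regions <- NULL
  for (f in c(vcf_a = config$vcf_a, vcf_b = config$vcf_b,
              panel = config$panel, counts = config$counts,
              meta = config$meta)) {
    log$inputs[[basename(f)]] <- unname(tools::md5sum(f))
  }
  message("[qc] reading ", config$vcf_a)
  a <- read_vcf(config$vcf_a)
  log$counts$input_variants <- n_variants(a)
  log$counts$input_samples <- n_samples(a)

  sf <- filter_samples(a, config$thresholds$mind_max)
  a <- sf$data
  log$counts$samples_removed <- length(sf$removed)
  fv <- filter_variants(a, th = config$thresholds)
  a <- fv$data
  log$counts$variant_removed <- as.list(fv$removed)
  log$counts$variants_after_qc <- n_variants(a)
  manifest$qc_summary <- write_tsv(
    data.frame(rule = c(names(fv$removed), "kept"),
               count = c(unname(fv$removed), fv$kept)),
    out("qc_summary.tsv"))

  if ("panel" %in% config$stages && !is.null(config$panel)) {
    message("[panel] intersecting with ", config$panel)
    pan <- read_panel(config$panel)
    a <- intersect_with_panel(a, pan)
    log$counts$variants_after_panel <- n_variants(a)
  }

  message("[prune] LD pruning ", n_variants(a), " variants")
  kept <- ld_prune(a, config$thresholds)
  a <- subset_variants(a, kept)
  log$counts$variants_after_prune <- n_variants(a)

  message("[pca] computing ", config$k_pcs, " PCs")
  pca_a <- compute_pcs(standardize(a), config$k_pcs)
  manifest$eigenvec <- write_pcs(pca_a, out("rgpc.eigenvec"))
  writeLines(format(pca_a$eigenvalues, digits = 10), out("rgpc.eigenval"))
  manifest$eigenval <- out("rgpc.eigenval")

  b_qc <- NULL
  if (!is.null(config$vcf_b) &&
      any(c("concordance", "compare") %in% config$stages)) {
    b <- read_vcf(config$vcf_b)
    fb <- filter_variants(b, th = config$thresholds)
    b_qc <- fb$data
    log$counts$vcf_b_variants_after_qc <- n_variants(b_qc)
  }

  if (!is.null(b_qc) && "concordance" %in% config$stages) {
    message("[concord] paired concordance")
    mt <- match_variants(a, b_qc)
    b_al <- align_genotypes(b_qc, mt)
    a_sub <- subset_variants(a, mt$index_a[mt$action %in% matched_actions])
    rep_c <- sample_concordance(a_sub, b_al)
    manifest$concordance <- write_tsv(rep_c$pairs, out("concordance.tsv"))
    log$counts$concordance_pairs <- nrow(rep_c$pairs)
    log$mean_concordance <- rep_c$mean_concordance
  }

  if (!is.null(b_qc) && "compare" %in% config$stages) {
    message("[compare] PC-set comparison")
    kept_b <- ld_prune(b_qc, config$thresholds)
    b_pr <- subset_variants(b_qc, kept_b)
    pca_b <- compute_pcs(standardize(b_pr), config$k_pcs)
    manifest$eigenvec_b <- write_pcs(pca_b, out("array.eigenvec"))
    shared <- intersect(pca_a$samples, pca_b$samples)
    cmp <- compare_pc_sets(pca_a$scores[shared, , drop = FALSE],
                           pca_b$scores[shared, , drop = FALSE])
    cca_tab <- cbind(cmp$wilks,
                     rd = cmp$shared$rd_y, cum_rd = cmp$shared$cum_rd_y)
    manifest$cca <- write_tsv(cca_tab, out("cca.tsv"))
    sp <- as.data.frame(cmp$spearman$rho)
    sp <- cbind(rgpc = rownames(sp), sp)
    manifest$spearman <- write_tsv(sp, out("spearman.tsv"))
  }

  if ("dge" %in% config$stages && !is.null(config$counts) &&
      !is.null(config$meta)) {
    message("[dge] differential expression with inflation control")
    counts <- as.matrix(utils::read.table(config$counts, header = TRUE,
                                          row.names = 1L, sep = "\t",
                                          check.names = FALSE))
    meta <- utils::read.table(config$meta, header = TRUE, sep = "\t",
                              stringsAsFactors = TRUE)
    shared <- intersect(intersect(colnames(counts), meta$sample),
                        rownames(pca_a$scores))
    counts <- counts[, shared, drop = FALSE]
    meta <- meta[match(shared, meta$sample), , drop = FALSE]
    covars <- if (!is.null(config$covariate_cols)) {
      meta[, config$covariate_cols, drop = FALSE]
    }
    expr <- cpm_filter(counts)
    log$counts$genes_after_cpm_filter <- nrow(expr)
    pcs_used <- pca_a$scores[shared, , drop = FALSE]
    with_pcs <- dge_lm(expr, meta$sex, covars, pcs_used)
    without_pcs <- dge_lm(expr, meta$sex, covars)
    infl <- inflation_m(with_pcs, without_pcs)
    manifest$dge_with_pcs <- write_tsv(with_pcs, out("dge_with_pcs.tsv"))
    manifest$dge_without_pcs <- write_tsv(without_pcs,
                                          out("dge_without_pcs.tsv"))
    manifest$inflation <- write_tsv(
      data.frame(median_with = infl$median_chisq_with_pcs,
                 median_without = infl$median_chisq_without_pcs,
                 m = infl$m), out("inflation.tsv"))
    log$inflation_m <- infl$m
  }

  log$manifest <- lapply(manifest, identity)
  jsonlite::write_json(log, out("run_log.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest$run_log <- out("run_log.json")
  manifest
}

#' Write a simulated study to disk
#'
#' Runs the generators and writes the truth VCF, both ascertained views,
#' population labels, counts, metadata and the gene truth table — the file
#' set the pipeline stages consume.
#'
#' @param out_dir output directory.
#' @param k_pops,fst,n_per_pop,n_variants see [simulate_genotypes()].
#' @param n_genes,sex_imbalance see [simulate_counts()] / [simulate_sex()].
#' @param seed integer seed driving all generators.
#' @return named list of written paths.
#' @export
simulate_study <- function(out_dir, k_pops = 3L, fst = 0.1, n_per_pop = 100L,
                           n_variants = 5000L, n_genes = 2000L,
                           sex_imbalance = 0.6, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genotypes(k_pops, fst, n_per_pop, n_variants, seed = seed)
  views <- derive_paired_views(sim$data, seed = seed + 1L)
  sex <- simulate_sex(sim$labels, imbalance = sex_imbalance, seed = seed + 2L)
  expr <- simulate_counts(sim$labels, sex, n_genes = n_genes, seed = seed + 3L)
  colnames(expr$counts) <- sim$data$samples
  out <- function(name) file.path(out_dir, name)
  paths <- list(
    full_vcf = write_vcf(sim$data, out("full.vcf")),
    array_vcf = write_vcf(views$array, out("array.vcf")),
    rnaseq_vcf = write_vcf(views$rnaseq, out("rnaseq.vcf")),
    labels = write_tsv(data.frame(sample = sim$data$samples,
                                  population = sim$labels),
                       out("labels.tsv")),
    meta = write_tsv(data.frame(sample = sim$data$samples, sex = sex,
                                population = sim$labels),
                     out("meta.tsv")),
    truth = write_tsv(expr$truth, out("truth.tsv"))
  )
  counts_df <- data.frame(gene = rownames(expr$counts), expr$counts,
                          check.names = FALSE)
  paths$counts <- write_tsv(counts_df, out("counts.tsv"))
  paths
}
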