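#' End-to-end pipeline orchestration
#'
#' @description
#' [run_pipeline()] drives the full analysis from a single
#' configuration: harmonize the per-disease summary statistics, load (or
#' simulate) the reference panel, LD-prune, assign SNPs to genes,
#' estimate the global phenotype correlation, scan SNPs and genes by
#' canonical correlation, run the per-disease gene-based tests, refine
#' into pleiotropic calls, and emit report files plus a run manifest.
#' Bonferroni thresholds default to `alpha/m` computed from the run's
#' own SNP and gene counts. Stages cache their outputs under
#' `<out_dir>/cache/` and are resumable.
#'
#' @name pipeline_cli
NULL

default_pipeline_params <- function() {
  list(ambiguous_policy = "drop",
       prune = list(window_snps = 50, step_snps = 5, r2_max = 0.2),
       n_eff_rule = "min",
       shrink = list(factor = 0.999, tol = 1e-8),
       gene_test = list(n_sims = 1e6, seed = 1, adaptive = TRUE),
       refine = list(alpha = 0.05, gene_p_threshold = 1e-6))
}

merge_params <- function(base, override) {
  for (nm in names(override)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(override[[nm]]))
      merge_params(base[[nm]], override[[nm]]) else override[[nm]]
  }
  base
}

load_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config$params <- merge_params(default_pipeline_params(), config$params %||% list())
  if (is.null(config$simulate) && is.null(config$inputs))
    stopf("pipeline config needs either a 'simulate' block or an 'inputs' block")
  config
}

#' Run the full pleiotropy pipeline
#'
#' @param config a list or YAML file path. Either a `simulate` block
#'   ([sim_config()] fields) or an `inputs` block (`sumstats`: vector of
#'   summary-statistic files; `reference`: VCF/dosage path;
#'   `gene_list`: glist path), plus an optional `params` block
#'   (`ambiguous_policy`, `prune`, `n_eff_rule`, `shrink`, `gene_test`,
#'   `refine`) and optional `novelty_map` path.
#' @param out_dir output directory for stage outputs, reports, cache and
#'   manifest.
#' @param resume reuse cached stage outputs when present (default FALSE).
#' @return Invisibly, a `run_manifest` list: config digest, input
#'   digests, seeds, per-stage counts and wall times, and the refined
#'   calls under `$calls`.
#' @export
run_pipeline <- function(config, out_dir, resume = FALSE) {
  config <- load_pipeline_config(config)
  pars <- config$params
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cache_dir <- file.path(out_dir, "cache")
  dir.create(cache_dir, showWarnings = FALSE)

  manifest <- list(config_digest = digest_object(config),
                   stage_versions = list(pipeline = "1"),
                   seeds = list(), counts = list(), wall_time = list(),
                   input_digests = list())
  timer <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    cache <- file.path(cache_dir, paste0(name, ".rds"))
    res <- if (resume && file.exists(cache)) readRDS(cache) else {
      v <- expr
      saveRDS(v, cache)
      v
    }
    manifest$wall_time[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  # --- inputs: simulated or from files ------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$causal_genes <- sim_args$causal %||% sim_args$causal_genes %||% list()
    sim_args$causal <- NULL
    sc <- do.call(sim_config, sim_args)
    manifest$seeds$simulate <- sc$seed
    sim <- timer("simulate", simulate_gwas(sc, joint_cohort = FALSE))
    studies <- sim$studies
    reference <- timer("reference", simulate_reference(sc))
    gene_table <- sim_gene_regions(sc)
    manifest$truth <- list(causal_genes = sim$truth$causal_genes)
  } else {
    studies <- timer("read_sumstats",
                     lapply(config$inputs$sumstats, read_sumstats))
    reference <- timer("reference", load_reference(config$inputs$reference))
    gene_table <- read_gene_list(config$inputs$gene_list)
    manifest$input_digests <- as.list(tools::md5sum(
      c(unlist(config$inputs$sumstats), config$inputs$reference,
        config$inputs$gene_list)))
  }

  # --- harmonize -----------------------------------------------------------
  panel <- timer("harmonize", harmonize(studies, pars$ambiguous_policy))
  manifest$counts$snps_harmonized <- nrow(panel$B)

  # restrict the reference panel to harmonized SNPs (and vice versa)
  shared <- intersect(panel$snps$id, reference$snps$id)
  if (!length(shared)) stopf("run_pipeline: no overlap between panel and reference")
  ridx <- which(reference$snps$id %in% shared)
  reference$snps <- reference$snps[ridx]
  reference$G <- reference$G[, ridx, drop = FALSE]
  reference$maf <- reference$maf[ridx]
  keep_rows <- panel$snps$id %in% shared
  panel$snps <- panel$snps[keep_rows]
  panel$B <- panel$B[keep_rows, , drop = FALSE]
  panel$SE <- panel$SE[keep_rows, , drop = FALSE]

  # --- phenotype correlation on ALL harmonized SNPs (pre-pruning) ----------
  std <- standardize_beta(panel)
  sigma_yy <- timer("sigma_yy", estimate_sigma_yy(std))

  # --- prune + annotate ----------------------------------------------------
  kept <- timer("prune", do.call(prune, c(list(reference), pars$prune)))
  manifest$counts$snps_pruned <- length(kept)
  genes <- timer("annotate", assign_snps_to_genes(reference, gene_table))
  genes_tested <- Filter(function(g) length(intersect(g$member_snps, kept)) > 0, genes)
  manifest$counts$genes_tested <- length(genes_tested)

  n_eff <- effective_n(panel$N, pars$n_eff_rule)
  manifest$seeds$gene_test <- pars$gene_test$seed

  # --- scans ---------------------------------------------------------------
  snp_res <- timer("snp_scan",
    snp_scan(std, sigma_yy, kept = match(reference$snps$id[kept], std$snps$id),
             n_eff = n_eff, shrink_factor = pars$shrink$factor,
             shrink_tol = pars$shrink$tol))
  gene_res <- timer("gene_scan",
    gene_scan(std, reference, genes_tested, sigma_yy, kept = kept,
              n_eff = n_eff, shrink_factor = pars$shrink$factor,
              shrink_tol = pars$shrink$tol))
  assoc_res <- timer("gene_test_scan",
    gene_test_scan(panel, reference, genes_tested, kept = kept,
                   n_sims = pars$gene_test$n_sims, seed = pars$gene_test$seed,
                   adaptive = pars$gene_test$adaptive))

  # --- refine + report -----------------------------------------------------
  cfg <- refine_config(alpha = pars$refine$alpha,
                       m_snps = max(length(kept), 1L),
                       m_genes = max(length(genes_tested), 1L),
                       gene_p_threshold = pars$refine$gene_p_threshold)
  calls <- timer("refine",
    refine_pleiotropic(gene_res[, c("unit_id", "pvalue")], assoc_res, cfg,
                       novelty_map = config$novelty_map))
  manifest$counts$genes_selected <- attr(calls, "counts")$selected
  manifest$counts$multi_disease <- attr(calls, "counts")$multi_disease

  gene_meta <- data.table::rbindlist(lapply(genes_tested, function(g)
    data.table::data.table(gene = g$name, chrom = g$chrom)))
  meta <- list(thresholds = cfg[c("snp_threshold", "metacca_threshold",
                                  "gene_p_threshold")],
               n_eff = n_eff, n_eff_rule = pars$n_eff_rule,
               shrink = pars$shrink, gene_test = pars$gene_test)
  write_scan(snp_res, file.path(out_dir, "snp_scan.tsv"), meta)
  write_scan(gene_res, file.path(out_dir, "gene_scan.tsv"), meta)
  data.table::fwrite(assoc_res, file.path(out_dir, "gene_assoc.tsv"), sep = "\t")
  emit_report(calls, cfg, out_dir, scan_results = gene_res, gene_meta = gene_meta)

  outputs <- file.path(out_dir, c("snp_scan.tsv", "gene_scan.tsv",
                                  "gene_assoc.tsv", "pleiotropy_calls.tsv",
                                  "refine_summary.json"))
  manifest$output_digests <- as.list(tools::md5sum(outputs[file.exists(outputs)]))
  manifest$calls <- calls
  manifest$scans <- list(snp = snp_res, gene = gene_res, assoc = assoc_res)
  class(manifest) <- "run_manifest"
  manifest_json <- manifest[setdiff(names(manifest), c("calls", "scans"))]
  write_json_sidecar(manifest_json, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

# Stable digest of an R object via md5 of its canonical serialization.
digest_object <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>\n")
  cat(sprintf("  config digest: %s\n", x$config_digest))
  for (nm in names(x$counts)) cat(sprintf("  %s: %s\n", nm, x$counts[[nm]]))
  invisible(x)
}
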