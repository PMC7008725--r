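#' Built-in validation experiments
#'
#' @description
#' Two simulation experiments used to validate the engine end to end:
#' a null calibration of the SNP-level scan, and a recovery study that
#' plants pleiotropic genes and measures how reliably the full pipeline
#' finds them. Both are deterministic in their seeds and are exercised
#' by the test suite.
#'
#' @name validation
NULL

#' Null calibration of the SNP-level scan
#'
#' Simulates a GWAS with no causal effects, runs the SNP-level
#' multivariate scan, and summarizes how uniform the resulting p-values
#' are.
#'
#' @param seed integer seed.
#' @param n_snps SNPs simulated (default 2000).
#' @param n_traits traits/cohorts (default 3).
#' @param n_per_cohort individuals per cohort (default 2000).
#' @return List: `pvalues`, `ks_p` (Kolmogorov-Smirnov test against
#'   uniform), `type1` (empirical rejection rate at alpha = 0.05) and
#'   `n` (number of SNPs tested).
#' @export
null_calibration <- function(seed = 1, n_snps = 2000, n_traits = 3,
                             n_per_cohort = 2000) {
  cfg <- sim_config(seed = seed, n_reference = 100,
                    n_cohorts = rep(as.integer(n_per_cohort), n_traits),
                    n_snps = n_snps, n_genes = max(1, n_snps %/% 10),
                    block_rho = 0)
  sim <- simulate_gwas(cfg, joint_cohort = FALSE)
  panel <- harmonize(sim$studies)
  std <- standardize_beta(panel)
  res <- snp_scan(std, estimate_sigma_yy(std))
  ks <- suppressWarnings(stats::ks.test(res$pvalue, "punif"))
  list(pvalues = res$pvalue, ks_p = unname(ks$p.value),
       type1 = mean(res$pvalue < 0.05), n = nrow(res))
}

#' Recovery study: planted pleiotropic genes through the full pipeline
#'
#' For each seed, simulates `n_genes` gene regions of which three carry
#' a shared standardized effect across three of the five traits
#' (genes 5, 20 and 40 affecting traits 1-3, 2-4 and 3-5), runs
#' harmonization, pruning, the gene-level canonical-correlation scan,
#' the per-disease Monte-Carlo gene tests and the intersection filter at
#' the run's own Bonferroni threshold, then scores the selected gene set
#' against the truth.
#'
#' @param seeds integer seeds, one replicate each (default 1:20).
#' @param n_per_cohort cohort size per trait (default 5000).
#' @param n_genes simulated genes (default 60).
#' @param effect per-SNP standardized effect in causal genes
#'   (default 0.05).
#' @param n_sims Monte-Carlo draws for the gene-based tests
#'   (default 1e6, matching the 1e-6 association gate).
#' @return List: `per_seed` (data.table seed/tp/fp/fn/selected),
#'   `sensitivity` (mean over seeds), `fdp` (pooled false-discovery
#'   proportion), `n_seeds`.
#' @export
recovery_study <- function(seeds = 1:20, n_per_cohort = 5000, n_genes = 60,
                           effect = 0.05, n_sims = 1e6) {
  causal <- list(list(gene = 5, traits = 1:3, effect = effect),
                 list(gene = 20, traits = 2:4, effect = effect),
                 list(gene = 40, traits = 3:5, effect = effect))
  truth <- sprintf("GENE%03d", c(5, 20, 40))
  rows <- lapply(seeds, function(sd) {
    cfg <- sim_config(seed = sd, n_reference = 500,
                      n_cohorts = rep(as.integer(n_per_cohort), 5),
                      n_snps = n_genes * 5, n_genes = n_genes,
                      block_rho = 0.7, causal_genes = causal)
    sim <- simulate_gwas(cfg, joint_cohort = FALSE)
    panel <- harmonize(sim$studies)
    ref <- simulate_reference(cfg)
    std <- standardize_beta(panel)
    syy <- estimate_sigma_yy(std)
    kept <- prune(ref)
    genes <- assign_snps_to_genes(ref, sim_gene_regions(cfg))
    genes <- Filter(function(g) length(intersect(g$member_snps, kept)) > 0, genes)
    gres <- gene_scan(std, ref, genes, syy, kept = kept)
    assoc <- gene_test_scan(panel, ref, genes, kept = kept,
                            n_sims = n_sims, seed = sd)
    cfgr <- refine_config(m_snps = length(kept), m_genes = length(genes))
    calls <- refine_pleiotropic(gres[, c("unit_id", "pvalue")], assoc, cfgr)
    sel <- calls$gene[calls$selected]
    data.table::data.table(seed = sd,
                           tp = length(intersect(sel, truth)),
                           fp = length(setdiff(sel, truth)),
                           fn = length(setdiff(truth, sel)),
                           selected = length(sel))
  })
  per_seed <- data.table::rbindlist(rows)
  list(per_seed = per_seed,
       sensitivity = mean(per_seed$tp / length(truth)),
       fdp = if (sum(per_seed$selected) == 0) 0
             else sum(per_seed$fp) / sum(per_seed$selected),
       n_seeds = length(seeds))
}
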