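#' Published seven-disease autoimmune pleiotropy screen
#'
#' Bundled result tables from a published multivariate pleiotropy screen
#' of seven autoimmune/autoinflammatory diseases (celiac disease,
#' inflammatory bowel disease, multiple sclerosis, primary biliary
#' cirrhosis, rheumatoid arthritis, systemic lupus erythematosus, type 1
#' diabetes): 67 genes with their multivariate canonical-correlation
#' p-value, seven per-disease gene-based p-values (floored at 1e-6 by
#' that analysis's 1e6-draw Monte-Carlo), per-gene features (chromosome,
#' member-SNP count, canonical r), and the curated confirmed/novel
#' annotation. These serve as a real-scale demonstration input for
#' [refine_pleiotropic()]: the screen tested 41,274 pruned SNPs in
#' 11,516 gene regions, giving Bonferroni thresholds 0.05/41,274 and
#' 0.05/11,516.
#'
#' @return List with `pvalues` (gene, metacca_p, seven disease columns),
#'   `features` (gene, chrom, n_snps, r, metacca_p, gene_type),
#'   `novelty_map` (named vector gene -> confirmed/novel), and the
#'   screen's test counts `m_snps` (41274) and `m_genes` (11516).
#' @export
published_screen <- function() {
  pv <- data.table::fread(system.file("extdata", "autoimmune67_gene_pvalues.tsv",
                                      package = "pleiocca"), sep = "\t")
  ft <- data.table::fread(system.file("extdata", "autoimmune67_features.tsv",
                                      package = "pleiocca"), sep = "\t",
                          colClasses = list(character = "chrom"))
  list(pvalues = pv, features = ft,
       novelty_map = setNames(tolower(ft$gene_type), ft$gene),
       m_snps = 41274L, m_genes = 11516L)
}
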