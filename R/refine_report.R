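#' Bonferroni thresholds, intersection filter and reporting
#'
#' @description
#' A gene is called pleiotropic when it passes two independent gates:
#' its multivariate (all-trait) canonical-correlation p-value falls
#' below the Bonferroni gene threshold (strict `<`), and its gene-based
#' p-value reaches the per-disease cutoff (`<=`, default 1e-6 — the
#' Monte-Carlo floor, which counts as an association) for at least one
#' disease. Genes reaching the cutoff for two or more diseases are
#' flagged multi-disease. Novelty (confirmed vs novel pleiotropic gene)
#' is an externally curated annotation, applied but never inferred.
#'
#' @name refine_report
NULL

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate, in (0,1).
#' @param m number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha < 1))
    stopf("bonferroni_threshold: alpha must be in (0,1)")
  if (!is_count(m)) stopf("bonferroni_threshold: m must be a positive integer")
  alpha / m
}

#' Refinement configuration
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param m_snps count of tested SNPs (for the SNP-level threshold).
#' @param m_genes count of tested genes (for the gene-level threshold).
#' @param gene_p_threshold per-disease gene-based cutoff (default 1e-6,
#'   the Monte-Carlo floor at 1e6 draws).
#' @param metacca_threshold override for the multivariate gene gate;
#'   default `alpha / m_genes`.
#' @return A `refine_config` list.
#' @export
refine_config <- function(alpha = 0.05, m_snps = 1L, m_genes = 1L,
                          gene_p_threshold = 1e-6, metacca_threshold = NULL) {
  stopifnot(is_count(m_snps), is_count(m_genes))
  structure(list(alpha = alpha, m_snps = m_snps, m_genes = m_genes,
                 gene_p_threshold = gene_p_threshold,
                 snp_threshold = bonferroni_threshold(alpha, m_snps),
                 metacca_threshold = metacca_threshold %||%
                   bonferroni_threshold(alpha, m_genes)),
            class = "refine_config")
}

#' Intersection filter producing pleiotropic gene calls
#'
#' @param gene_cca data.frame of multivariate gene results: columns
#'   `gene` (or `unit_id`) and `metacca_p` (or `pvalue`).
#' @param gene_assoc per-disease gene-based p-values, either long
#'   (`gene, disease, pvalue`) or wide (`gene` plus one column per
#'   disease).
#' @param config a `refine_config`.
#' @param novelty_map optional annotation, see [classify_novelty()].
#' @return A `pleiotropy_calls` data.table sorted by gene: `gene,
#'   metacca_p`, one `p_<disease>` column per disease, `n_assoc,
#'   selected, multi_disease, novelty`; attribute `"counts"` tallies
#'   selected / multi-disease / novelty classes, and `"excluded"` lists
#'   genes present in only one input.
#' @export
refine_pleiotropic <- function(gene_cca, gene_assoc, config,
                               novelty_map = NULL) {
  stopifnot(inherits(config, "refine_config"))
  cca <- data.table::as.data.table(gene_cca)
  if (!"gene" %in% names(cca) && "unit_id" %in% names(cca))
    data.table::setnames(cca, "unit_id", "gene")
  if (!"metacca_p" %in% names(cca) && "pvalue" %in% names(cca))
    data.table::setnames(cca, "pvalue", "metacca_p")
  if (!all(c("gene", "metacca_p") %in% names(cca)))
    stopf("refine_pleiotropic: gene_cca needs columns gene/unit_id and metacca_p/pvalue")
  if (anyDuplicated(cca$gene))
    stopf("refine_pleiotropic: duplicate gene rows in gene_cca: %s",
          paste(unique(cca$gene[duplicated(cca$gene)]), collapse = ", "))

  assoc <- data.table::as.data.table(gene_assoc)
  if (all(c("gene", "disease", "pvalue") %in% names(assoc))) {
    if (anyDuplicated(assoc[, c("gene", "disease")]))
      stopf("refine_pleiotropic: duplicate (gene, disease) rows in gene_assoc")
    assoc <- data.table::dcast(assoc, gene ~ disease, value.var = "pvalue")
  } else if (!"gene" %in% names(assoc)) {
    stopf("refine_pleiotropic: gene_assoc needs a gene column")
  }
  if (anyDuplicated(assoc$gene))
    stopf("refine_pleiotropic: duplicate gene rows in gene_assoc")
  diseases <- setdiff(names(assoc), "gene")

  shared <- intersect(cca$gene, assoc$gene)
  excluded <- list(cca_only = setdiff(cca$gene, shared),
                   assoc_only = setdiff(assoc$gene, shared))

  calls <- merge(cca[, c("gene", "metacca_p"), with = FALSE], assoc, by = "gene")
  pm <- as.matrix(calls[, diseases, with = FALSE])
  calls[, n_assoc := rowSums(pm <= config$gene_p_threshold, na.rm = TRUE)]
  calls[, selected := metacca_p < config$metacca_threshold & n_assoc >= 1L]
  calls[, multi_disease := selected & n_assoc >= 2L]
  calls[, novelty := "unknown"]
  data.table::setnames(calls, diseases, paste0("p_", diseases))
  data.table::setorder(calls, gene)
  out <- structure(calls[], class = c("pleiotropy_calls", class(calls)),
                   diseases = diseases, excluded = excluded,
                   config = config)
  out <- classify_novelty(out, novelty_map)
  out
}

#' Apply a confirmed/novel annotation to pleiotropy calls
#'
#' @param calls a `pleiotropy_calls` table.
#' @param novelty_map `NULL` (all unknown), a named character vector
#'   `gene -> confirmed|novel`, a two-column data.frame
#'   (`gene, novelty`), or a path to two-column delimited text. The map
#'   may be partial; unmapped genes stay `unknown`.
#' @return The calls with `novelty` set and attribute `"counts"`
#'   refreshed (`selected, multi_disease, confirmed, novel, unknown`).
#' @export
classify_novelty <- function(calls, novelty_map = NULL) {
  stopifnot(inherits(calls, "pleiotropy_calls"))
  map <- normalize_novelty_map(novelty_map)
  if (length(map)) {
    hit <- match(calls$gene, names(map))
    calls[!is.na(hit), novelty := unname(map[hit[!is.na(hit)]])]
  }
  counts <- list(genes = nrow(calls),
                 selected = sum(calls$selected),
                 multi_disease = sum(calls$multi_disease),
                 confirmed = sum(calls$novelty == "confirmed" & calls$selected),
                 novel = sum(calls$novelty == "novel" & calls$selected),
                 unknown = sum(calls$novelty == "unknown" & calls$selected))
  data.table::setattr(calls, "counts", counts)
  calls
}

normalize_novelty_map <- function(novelty_map) {
  if (is.null(novelty_map)) return(character(0))
  if (is.character(novelty_map) && is.null(names(novelty_map)) &&
      length(novelty_map) == 1L && file.exists(novelty_map)) {
    dt <- data.table::fread(novelty_map, header = TRUE)
    novelty_map <- setNames(as.character(dt[[2]]), dt[[1]])
  }
  if (is.data.frame(novelty_map))
    novelty_map <- setNames(as.character(novelty_map[[2]]), novelty_map[[1]])
  map <- tolower(novelty_map)
  bad <- !map %in% c("confirmed", "novel")
  if (any(bad))
    stopf("classify_novelty: labels must be confirmed/novel, got %s",
          paste(unique(novelty_map[bad]), collapse = ", "))
  map
}

#' Emit the final pleiotropy report
#'
#' Writes a calls table (gene, multivariate p, per-disease p's, flags),
#' a gene-feature table (chromosome, member-SNP count, canonical r) when
#' the multivariate gene scan is supplied, and a JSON summary of counts
#' and thresholds.
#'
#' @param calls a `pleiotropy_calls` table.
#' @param config the `refine_config` used.
#' @param path output directory (created if needed).
#' @param scan_results optional [gene_scan()] output supplying `g` and
#'   `r` per gene.
#' @param gene_meta optional data.frame `gene, chrom` for the feature
#'   table.
#' @return Invisibly, the written paths.
#' @export
emit_report <- function(calls, config, path, scan_results = NULL,
                        gene_meta = NULL) {
  stopifnot(inherits(calls, "pleiotropy_calls"), inherits(config, "refine_config"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  sel <- calls[calls$selected]
  calls_path <- file.path(path, "pleiotropy_calls.tsv")
  data.table::fwrite(sel, calls_path, sep = "\t")
  paths <- calls_path

  if (!is.null(scan_results)) {
    sc <- data.table::as.data.table(scan_results)
    feat <- merge(sel[, c("gene", "metacca_p", "novelty"), with = FALSE],
                  sc[, c("unit_id", "g", "r")],
                  by.x = "gene", by.y = "unit_id", all.x = TRUE)
    if (!is.null(gene_meta))
      feat <- merge(feat, data.table::as.data.table(gene_meta)[, c("gene", "chrom")],
                    by = "gene", all.x = TRUE)
    else feat[, chrom := NA_character_]
    data.table::setcolorder(feat, c("gene", "chrom", "g", "r", "metacca_p", "novelty"))
    data.table::setnames(feat, "g", "n_snps")
    data.table::setorder(feat, gene)
    feat_path <- file.path(path, "gene_features.tsv")
    data.table::fwrite(feat, feat_path, sep = "\t")
    paths <- c(paths, feat_path)
  }

  summary_path <- file.path(path, "refine_summary.json")
  write_json_sidecar(list(
    thresholds = list(alpha = config$alpha, m_snps = config$m_snps,
                      m_genes = config$m_genes,
                      snp_threshold = config$snp_threshold,
                      metacca_threshold = config$metacca_threshold,
                      gene_p_threshold = config$gene_p_threshold),
    counts = attr(calls, "counts"),
    excluded = lapply(attr(calls, "excluded"), length)), summary_path)
  invisible(c(paths, summary_path))
}

#' Re-read an emitted calls table
#'
#' @param path the `pleiotropy_calls.tsv` written by [emit_report()].
#' @return data.table in the [refine_pleiotropic()] input shape (wide
#'   per-disease p columns renamed back to disease labels).
#' @export
read_pleiotropy_calls <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  pcols <- grep("^p_", names(dt), value = TRUE)
  data.table::setnames(dt, pcols, sub("^p_", "", pcols))
  dt
}
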