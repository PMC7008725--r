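#' GWAS summary-statistic input, validation and cross-study harmonization
#'
#' @description
#' One GWAS (or GWAS meta-analysis) contributes per-SNP regression
#' coefficients (`beta`), standard errors (`se`), p-values and sample
#' sizes for a single disease. [read_sumstats()] loads and validates one
#' such file; [harmonize()] aligns several studies to a shared effect
#' allele convention and intersects their SNPs into a [`beta_panel`];
#' [write_sumstats()] round-trips a panel back to per-disease files.
#'
#' @name sumstats_io
NULL

SUMSTATS_COLS <- c("SNP", "CHR", "POS", "A1", "A2", "BETA", "SE", "P", "N")
VALID_ALLELES <- c("A", "C", "G", "T")

new_summary_stats <- function(disease_label, data) {
  structure(list(disease = disease_label, data = data), class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("<summary_stats> disease=%s, %d SNPs, n=%d\n",
              x$disease, nrow(x$data), x$data$N[1]))
  invisible(x)
}

#' Read one GWAS summary-statistics file
#'
#' Expects delimited text (gzip transparently handled) with a header row
#' naming columns `SNP, CHR, POS, A1, A2, BETA, SE, P, N` (A1 is the
#' effect allele). Other header names can be mapped via `column_map`.
#' A missing `P` column (or missing entries) is recomputed from the
#' two-sided normal tail of `beta/se`; missing `beta` or `se` is an error.
#' Per-SNP sample sizes are reduced to the study's median with a warning,
#' since downstream standardization treats `n` as a per-study scalar.
#' Duplicate SNP ids keep the first occurrence (logged).
#'
#' @param path file path.
#' @param column_map optional named character vector mapping standard
#'   names to the file's header names, e.g.
#'   `c(SNP = "rsid", BETA = "effect")`.
#' @param disease_label label for the trait; defaults to the file base name.
#' @return A `summary_stats` object with fields `disease` and `data`
#'   (columns `SNP, CHR, POS, A1, A2, BETA, SE, P, N`). Attribute
#'   `"log"` records dropped duplicate counts.
#' @export
read_sumstats <- function(path, column_map = NULL, disease_label = NULL) {
  if (!file.exists(path)) stopf("summary-statistics file not found: %s", path)
  dt <- data.table::fread(path, header = TRUE, colClasses = list(character = "CHR"))
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), SUMSTATS_COLS)
    if (length(bad)) stopf("column_map has unknown standard names: %s", paste(bad, collapse = ", "))
    for (std in names(column_map)) {
      if (!column_map[[std]] %in% names(dt))
        stopf("column_map: file has no column '%s'", column_map[[std]])
      data.table::setnames(dt, column_map[[std]], std)
    }
  }
  required <- setdiff(SUMSTATS_COLS, "P")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols))
    stopf("format error in %s: missing required column(s) %s",
          path, paste(missing_cols, collapse = ", "))
  if (!"P" %in% names(dt)) dt[, P := NA_real_]
  dt <- dt[, SUMSTATS_COLS, with = FALSE]
  dt[, `:=`(SNP = as.character(SNP), CHR = as.character(CHR),
            A1 = toupper(as.character(A1)), A2 = toupper(as.character(A2)))]

  validate_sumstats(dt, path)

  log <- list(n_read = nrow(dt), n_duplicate_dropped = 0L, n_p_recomputed = 0L)
  dup <- duplicated(dt$SNP)
  if (any(dup)) {
    log$n_duplicate_dropped <- sum(dup)
    warnf("%s: %d duplicate snp_id rows dropped (first occurrence kept): %s",
          path, sum(dup), paste(head(unique(dt$SNP[dup]), 5), collapse = ", "))
    dt <- dt[!dup]
  }

  nmiss <- is.na(dt$P)
  if (any(nmiss)) {
    log$n_p_recomputed <- sum(nmiss)
    dt[nmiss, P := 2 * pnorm(-abs(BETA / SE))]
  }

  if (length(unique(dt$N)) > 1L) {
    med <- as.integer(round(stats::median(dt$N)))
    warnf("%s: per-SNP N varies; reduced to study median %d", path, med)
    dt[, N := med]
  }
  dt[, N := as.integer(N)]

  out <- new_summary_stats(disease_label %||% sub("\\.(tsv|txt|sumstats)(\\.gz)?$", "",
                                                 basename(path)), dt)
  attr(out, "log") <- log
  out
}

validate_sumstats <- function(dt, path) {
  line <- seq_len(nrow(dt)) + 1L  # header is line 1
  bad_allele <- !(dt$A1 %in% VALID_ALLELES) | !(dt$A2 %in% VALID_ALLELES) | dt$A1 == dt$A2
  bad_se <- !is.finite(dt$SE) | dt$SE <= 0
  bad_p <- !is.na(dt$P) & (!is.finite(dt$P) | dt$P <= 0 | dt$P > 1)
  bad_beta <- !is.finite(dt$BETA)
  bad_n <- !is.finite(dt$N) | dt$N <= 0
  bad_pos <- !is.finite(dt$POS) | dt$POS < 1 | dt$POS != round(dt$POS)
  bad <- bad_allele | bad_se | bad_p | bad_beta | bad_n | bad_pos
  if (any(bad)) {
    what <- character(0)
    if (any(bad_se)) what <- c(what, sprintf("se <= 0 or non-finite [%s]",
      paste(dt$SNP[bad_se], collapse = ", ")))
    if (any(bad_p)) what <- c(what, sprintf("p outside (0,1] [%s]",
      paste(dt$SNP[bad_p], collapse = ", ")))
    if (any(bad_allele)) what <- c(what, sprintf("invalid allele pair [%s]",
      paste(dt$SNP[bad_allele], collapse = ", ")))
    if (any(bad_beta)) what <- c(what, sprintf("non-finite beta [%s]",
      paste(dt$SNP[bad_beta], collapse = ", ")))
    if (any(bad_n)) what <- c(what, sprintf("non-positive n [%s]",
      paste(dt$SNP[bad_n], collapse = ", ")))
    if (any(bad_pos)) what <- c(what, sprintf("invalid position [%s]",
      paste(dt$SNP[bad_pos], collapse = ", ")))
    stopf("validation error in %s (lines %s): %s", path,
          paste(head(line[bad], 10), collapse = ", "), paste(what, collapse = "; "))
  }
  invisible(TRUE)
}

is_ambiguous_pair <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize several studies into an aligned multi-trait beta panel
#'
#' Keeps the SNPs present in every study, aligns all effect estimates to
#' the allele convention of the first study (beta signs are flipped for
#' studies whose effect/other alleles are swapped relative to it), drops
#' strand-ambiguous A/T and C/G SNPs under the default policy, and drops
#' (with a log) SNPs whose allele pairs cannot be reconciled. Rows come
#' out sorted by (chromosome, position).
#'
#' @param studies list of `summary_stats` objects (distinct diseases).
#' @param ambiguous_policy `"drop"` (default) removes strand-ambiguous
#'   A/T and C/G SNPs; `"keep"` retains them (all input cohorts assumed
#'   strand-consistent).
#' @return A `beta_panel`: list with `snps` (data.table id/chrom/pos/a1/a2),
#'   `diseases`, matrices `B` and `SE` (SNP x disease), per-study sizes
#'   `N`, and a harmonization `log`.
#' @export
harmonize <- function(studies, ambiguous_policy = c("drop", "keep")) {
  ambiguous_policy <- match.arg(ambiguous_policy)
  if (!length(studies)) stopf("harmonize: need at least one study")
  if (!all(vapply(studies, inherits, TRUE, "summary_stats")))
    stopf("harmonize: inputs must be summary_stats objects")
  labels <- vapply(studies, `[[`, "", "disease")
  if (anyDuplicated(labels)) stopf("harmonize: duplicate disease labels")

  common <- Reduce(intersect, lapply(studies, function(s) s$data$SNP))
  if (!length(common)) stopf("no common SNPs across the %d studies", length(studies))

  ref <- studies[[1]]$data[match(common, SNP)]
  log <- list(n_common = length(common), n_ambiguous_dropped = 0L,
              n_allele_mismatch_dropped = 0L, mismatch_ids = character(0))

  keep <- rep(TRUE, length(common))
  if (ambiguous_policy == "drop") {
    amb <- is_ambiguous_pair(ref$A1, ref$A2)
    log$n_ambiguous_dropped <- sum(amb)
    keep <- keep & !amb
  }

  p <- length(studies)
  B <- SE <- matrix(NA_real_, length(common), p,
                    dimnames = list(common, labels))
  for (k in seq_len(p)) {
    d <- studies[[k]]$data[match(common, SNP)]
    same <- d$A1 == ref$A1 & d$A2 == ref$A2
    swap <- d$A1 == ref$A2 & d$A2 == ref$A1
    mismatch <- !(same | swap)
    if (any(mismatch)) {
      log$n_allele_mismatch_dropped <- log$n_allele_mismatch_dropped + sum(mismatch & keep)
      log$mismatch_ids <- union(log$mismatch_ids, common[mismatch])
      keep <- keep & !mismatch
    }
    B[, k] <- ifelse(swap, -d$BETA, d$BETA)
    SE[, k] <- d$SE
  }
  if (!any(keep))
    stopf("no common SNPs survive allele harmonization across the %d studies", p)

  snps <- data.table::data.table(id = ref$SNP, chrom = ref$CHR, pos = ref$POS,
                                 a1 = ref$A1, a2 = ref$A2)[keep]
  B <- B[keep, , drop = FALSE]
  SE <- SE[keep, , drop = FALSE]
  ord <- snp_order(snps$chrom, snps$pos, snps$id)
  snps <- snps[ord]
  structure(list(snps = snps,
                 diseases = labels,
                 B = B[ord, , drop = FALSE],
                 SE = SE[ord, , drop = FALSE],
                 N = setNames(vapply(studies, function(s) s$data$N[1], 1L), labels),
                 log = log),
            class = "beta_panel")
}

#' @export
print.beta_panel <- function(x, ...) {
  cat(sprintf("<beta_panel> %d SNPs x %d diseases (%s)\n",
              nrow(x$B), ncol(x$B), paste(x$diseases, collapse = ", ")))
  invisible(x)
}

#' Write a harmonized panel back to per-disease summary-statistic files
#'
#' Emits one `read_sumstats`-compatible tab-delimited file per disease
#' (p-values recomputed from `beta/se`), plus a JSON sidecar recording
#' disease order, sample sizes and harmonization log counts. Row order
#' follows the panel, so output bytes are stable.
#'
#' @param panel a `beta_panel`.
#' @param directory output directory (created if needed).
#' @return Invisibly, the written file paths (sidecar last).
#' @export
write_sumstats <- function(panel, directory) {
  stopifnot(inherits(panel, "beta_panel"))
  if (nrow(panel$B) == 0L) stopf("refusing to write a panel with zero SNPs")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (k in seq_along(panel$diseases)) {
    d <- panel$diseases[k]
    dt <- data.table::data.table(
      SNP = panel$snps$id, CHR = panel$snps$chrom, POS = panel$snps$pos,
      A1 = panel$snps$a1, A2 = panel$snps$a2,
      BETA = panel$B[, k], SE = panel$SE[, k],
      P = 2 * pnorm(-abs(panel$B[, k] / panel$SE[, k])),
      N = panel$N[[k]])
    f <- file.path(directory, paste0(d, ".sumstats.tsv"))
    data.table::fwrite(dt, f, sep = "\t")
    paths <- c(paths, f)
  }
  sidecar <- file.path(directory, "panel_meta.json")
  write_json_sidecar(list(diseases = as.list(panel$diseases),
                          N = as.list(panel$N),
                          log = panel$log[c("n_common", "n_ambiguous_dropped",
                                            "n_allele_mismatch_dropped")]),
                     sidecar)
  invisible(c(paths, sidecar))
}
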