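#' Reference-panel handling: dosages, MAF, LD and gene regions
#'
#' The LD structure entering the covariance assembly is estimated from a
#' reference genotype panel of matched ancestry, never from the summary
#' statistics themselves. This file loads such a panel (VCF or dosage
#' matrix), computes pairwise LD, performs PLINK-style window pruning
#' (50-SNP window, 5-SNP step, r^2 > 0.2, smaller-MAF removal), and
#' assigns SNPs to gene regions.
#'
#' @name panel_prep
NULL

new_reference_panel <- function(snps, G, log = list()) {
  maf <- colMeans(G) / 2
  maf <- pmin(maf, 1 - maf)
  structure(list(individuals = nrow(G), snps = snps, G = G, maf = maf, log = log),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("<reference_panel> %d individuals x %d SNPs\n",
              x$individuals, ncol(x$G)))
  invisible(x)
}

#' Load a reference genotype panel
#'
#' Accepts a VCF (biallelic SNP records with a GT field) or a
#' tab-delimited dosage matrix whose header is
#' `SNP CHR POS A1 A2 <sample1> <sample2> ...` with dosages in {0,1,2}
#' counting A1 alleles. Multiallelic sites, sites with any missing or
#' half-missing call, and monomorphic sites (MAF 0) are dropped with
#' counts in the result's `log`. SNPs come out sorted by
#' (chromosome, position).
#'
#' @param path input file.
#' @param format `"auto"` (default, by extension), `"vcf"`, or `"dosage"`.
#' @return A `reference_panel`: `individuals`, `snps`
#'   (data.table id/chrom/pos/a1/a2), dosage matrix `G`
#'   (individuals x SNPs, A1-counted), `maf`, `log`.
#' @export
load_reference <- function(path, format = c("auto", "vcf", "dosage")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
  if (format == "vcf") load_reference_vcf(path) else load_reference_dosage(path)
}

load_reference_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  biallelic <- ref %in% VALID_ALLELES & alt %in% VALID_ALLELES
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  dos <- gt_to_dosage(gt)          # SNP x individual, NA on missing calls
  complete <- rowSums(is.na(dos)) == 0L
  keep <- biallelic & complete
  log <- list(n_sites = nrow(fix),
              n_multiallelic_dropped = sum(!biallelic),
              n_missing_dropped = sum(biallelic & !complete))
  if (!any(keep)) stopf("no usable biallelic, fully-called sites in %s", path)
  snps <- data.table::data.table(
    id = ifelse(is.na(fix[keep, "ID"]) | fix[keep, "ID"] == ".",
                paste0(fix[keep, "CHROM"], ":", fix[keep, "POS"]), fix[keep, "ID"]),
    chrom = as.character(fix[keep, "CHROM"]),
    pos = as.integer(fix[keep, "POS"]),
    a1 = alt[keep], a2 = ref[keep])   # dosage counts ALT alleles
  finalize_reference(snps, t(dos[keep, , drop = FALSE]), log)
}

gt_to_dosage <- function(gt) {
  d <- matrix(NA_real_, nrow(gt), ncol(gt))
  clean <- gsub("\\|", "/", gt)
  d[clean %in% c("0/0")] <- 0
  d[clean %in% c("0/1", "1/0")] <- 1
  d[clean %in% c("1/1")] <- 2
  d
}

load_reference_dosage <- function(path) {
  dt <- data.table::fread(path, header = TRUE, colClasses = list(character = "CHR"))
  meta_cols <- c("SNP", "CHR", "POS", "A1", "A2")
  missing_cols <- setdiff(meta_cols, names(dt))
  if (length(missing_cols))
    stopf("dosage matrix %s lacks column(s) %s", path, paste(missing_cols, collapse = ", "))
  samp_cols <- setdiff(names(dt), meta_cols)
  if (!length(samp_cols)) stopf("dosage matrix %s has no sample columns", path)
  G <- t(as.matrix(dt[, samp_cols, with = FALSE]))  # individuals x SNPs
  ok <- matrix(G %in% c(0, 1, 2), nrow = nrow(G))   # NA calls come out FALSE
  complete <- colSums(!ok) == 0L
  log <- list(n_sites = ncol(G), n_multiallelic_dropped = 0L,
              n_missing_dropped = sum(!complete))
  if (!any(complete)) stopf("no fully-called sites in %s", path)
  snps <- data.table::data.table(id = as.character(dt$SNP), chrom = dt$CHR,
                                 pos = as.integer(dt$POS),
                                 a1 = toupper(dt$A1), a2 = toupper(dt$A2))[complete]
  finalize_reference(snps, G[, complete, drop = FALSE], log)
}

finalize_reference <- function(snps, G, log) {
  ord <- snp_order(snps$chrom, snps$pos, snps$id)
  snps <- snps[ord]
  G <- G[, ord, drop = FALSE]
  maf <- colMeans(G) / 2
  maf <- pmin(maf, 1 - maf)
  mono <- maf <= 0
  log$n_monomorphic_dropped <- sum(mono)
  if (all(mono)) stopf("all sites monomorphic in the reference panel")
  snps <- snps[!mono]
  G <- G[, !mono, drop = FALSE]
  colnames(G) <- snps$id
  rownames(G) <- NULL
  new_reference_panel(snps, G, log)
}

#' Pairwise LD between two panel SNPs
#'
#' Squared Pearson correlation of the two dosage columns.
#'
#' @param panel a `reference_panel`.
#' @param i,j distinct SNP column indices.
#' @return r^2 in \[0, 1\].
#' @export
ld_r2 <- function(panel, i, j) {
  stopifnot(inherits(panel, "reference_panel"))
  s <- ncol(panel$G)
  if (!is_count(i) || !is_count(j) || i > s || j > s || i == j)
    stopf("ld_r2: i, j must be distinct valid SNP indices")
  cor(panel$G[, i], panel$G[, j])^2
}

#' LD-based SNP pruning (window / step / r^2)
#'
#' Within each chromosome, windows of `window_snps` SNPs advance by
#' `step_snps`; inside a window, for any pair with r^2 > `r2_max` the
#' SNP with the smaller MAF is removed (equal MAFs: the later-positioned
#' SNP goes). Passes repeat until no window contains an offending pair,
#' so the result is a fixed point. Deterministic.
#'
#' @param panel a `reference_panel`.
#' @param window_snps window size in SNPs (default 50).
#' @param step_snps window advance in SNPs (default 5).
#' @param r2_max LD threshold (default 0.2).
#' @return Sorted indices (into `panel$snps`) of the surviving SNPs.
#' @export
prune <- function(panel, window_snps = 50, step_snps = 5, r2_max = 0.2) {
  stopifnot(inherits(panel, "reference_panel"))
  if (!is_count(window_snps) || !is_count(step_snps) ||
      step_snps > window_snps)
    stopf("prune: need window_snps >= step_snps >= 1")
  kept <- logical(ncol(panel$G))
  for (ch in unique(panel$snps$chrom)) {
    idx <- which(panel$snps$chrom == ch)       # already position-sorted
    kept[prune_chrom(panel, idx, window_snps, step_snps, r2_max)] <- TRUE
  }
  which(kept)
}

prune_chrom <- function(panel, idx, window_snps, step_snps, r2_max) {
  alive <- rep(TRUE, length(idx))
  repeat {
    changed <- FALSE
    live <- idx[alive]
    if (length(live) < 2L) break
    starts <- seq(1L, length(live), by = step_snps)
    for (s in starts) {
      win <- live[s:min(s + window_snps - 1L, length(live))]
      win <- win[alive[match(win, idx)]]       # may shrink within this pass
      if (length(win) < 2L) next
      removed <- prune_window(panel, win, r2_max)
      if (length(removed)) {
        alive[match(removed, idx)] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  idx[alive]
}

# Greedy within-window removal; returns removed panel indices.
prune_window <- function(panel, win, r2_max) {
  R2 <- cor(panel$G[, win, drop = FALSE])^2
  maf <- panel$maf[win]
  alive <- rep(TRUE, length(win))
  repeat {
    R2a <- R2
    R2a[!alive, ] <- 0; R2a[, !alive] <- 0
    R2a[lower.tri(R2a, diag = TRUE)] <- 0
    hit <- which(R2a > r2_max, arr.ind = TRUE)
    if (!nrow(hit)) break
    # first offending pair in scan order (column-major upper triangle)
    i <- hit[1, 1]; j <- hit[1, 2]
    drop <- if (maf[i] < maf[j]) i else if (maf[j] < maf[i]) j else max(i, j)
    alive[drop] <- FALSE
  }
  win[!alive]
}

#' Read a gene-region list (glist dialect)
#'
#' Whitespace-delimited rows `chrom start end name`, positions 1-based
#' inclusive.
#'
#' @param path file path.
#' @return data.table with columns `chrom, start, end, name`.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(parts) != 4L)
  if (length(bad))
    stopf("format error in gene list %s: line(s) %s do not have 4 fields",
          path, paste(head(bad, 10), collapse = ", "))
  g <- data.table::data.table(
    chrom = vapply(parts, `[`, "", 1L),
    start = suppressWarnings(as.integer(vapply(parts, `[`, "", 2L))),
    end = suppressWarnings(as.integer(vapply(parts, `[`, "", 3L))),
    name = vapply(parts, `[`, "", 4L))
  bad <- which(is.na(g$start) | is.na(g$end) | g$start > g$end)
  if (length(bad))
    stopf("format error in gene list %s: line(s) %s have invalid coordinates",
          path, paste(head(bad, 10), collapse = ", "))
  g
}

#' Assign panel SNPs to gene regions
#'
#' Intervals are 1-based and inclusive at both ends; a SNP inside k
#' overlapping genes belongs to all k; genes with no member SNPs are
#' omitted. SNPs falling in no gene are reported via the
#' `"out_of_gene"` attribute.
#'
#' @param panel a `reference_panel`.
#' @param gene_list a file path (glist dialect) or a data.frame with
#'   columns `chrom, start, end, name`.
#' @return List of `gene_region` objects (`name, chrom, start, end,
#'   member_snps` as panel indices), ordered by (chrom, start, name).
#' @export
assign_snps_to_genes <- function(panel, gene_list) {
  stopifnot(inherits(panel, "reference_panel"))
  g <- if (is.character(gene_list)) read_gene_list(gene_list)
       else data.table::as.data.table(gene_list)
  stopifnot(all(c("chrom", "start", "end", "name") %in% names(g)))
  g <- g[order(chrom_rank(g$chrom), g$start, g$name)]
  regions <- list()
  in_gene <- logical(ncol(panel$G))
  for (ch in unique(g$chrom)) {
    gi <- which(g$chrom == ch)
    si <- which(panel$snps$chrom == ch)
    if (!length(si)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = g$start[gi], end = g$end[gi]),
      IRanges::IRanges(start = panel$snps$pos[si], width = 1L))
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    for (k in seq_along(gi)) {
      members <- si[sh[qh == k]]
      if (!length(members)) next
      in_gene[members] <- TRUE
      regions[[length(regions) + 1L]] <- structure(
        list(name = g$name[gi[k]], chrom = ch,
             start = g$start[gi[k]], end = g$end[gi[k]],
             member_snps = sort(members)),
        class = "gene_region")
    }
  }
  structure(regions, out_of_gene = which(!in_gene))
}
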