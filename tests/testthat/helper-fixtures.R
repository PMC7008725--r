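# Fixtures built in code: small summary-stat tables, studies and panels.

make_sumstats_dt <- function(n = 3, seed = 1, chrom = "1") {
  set.seed(seed)
  pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"))
  pick <- sample.int(nrow(pairs), n, replace = TRUE)
  data.table::data.table(
    SNP = sprintf("rs%04d", seq_len(n)), CHR = chrom, POS = seq_len(n) * 100L,
    A1 = pairs[pick, 1], A2 = pairs[pick, 2],
    BETA = rnorm(n, sd = 0.05), SE = runif(n, 0.01, 0.05),
    P = runif(n), N = 1000L)
}

write_sumstats_file <- function(dt, path = tempfile(fileext = ".tsv")) {
  data.table::fwrite(dt, path, sep = "\t")
  path
}

make_study <- function(dt, disease = "d1") {
  read_sumstats(write_sumstats_file(dt), disease_label = disease)
}

# A reference panel built directly from a dosage matrix (individuals x SNPs).
make_panel_from_G <- function(G, chrom = "1", ids = NULL) {
  s <- ncol(G)
  ids <- ids %||% sprintf("rs%04d", seq_len(s))
  dt <- data.table::data.table(
    SNP = ids, CHR = chrom, POS = seq_len(s) * 100L, A1 = "A", A2 = "G")
  dos <- data.table::as.data.table(t(G))
  data.table::setnames(dos, sprintf("S%03d", seq_len(nrow(G))))
  path <- tempfile(fileext = ".dosage.tsv")
  data.table::fwrite(cbind(dt, dos), path, sep = "\t")
  load_reference(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

expect_no_offending_pair <- function(panel, kept, window_snps = 50,
                                     step_snps = 5, r2_max = 0.2) {
  # brute-force oracle: enumerate the sliding windows over the survivors
  # exactly as the pruner defines them and check every pair exhaustively
  worst <- 0
  for (ch in unique(panel$snps$chrom)) {
    live <- kept[panel$snps$chrom[kept] == ch]
    if (length(live) < 2) next
    for (s in seq(1, length(live), by = step_snps)) {
      win <- live[s:min(s + window_snps - 1, length(live))]
      if (length(win) < 2) next
      R2 <- stats::cor(panel$G[, win])^2
      worst <- max(worst, max(R2[upper.tri(R2)]))
    }
  }
  expect_lte(worst, r2_max)
}
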