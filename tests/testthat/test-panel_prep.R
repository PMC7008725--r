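test_that("VCF loading computes MAF from genotype calls", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
               "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1"), vcf)
  p <- load_reference(vcf)
  expect_equal(ncol(p$G), 1L)
  expect_equal(p$maf, 0.5, ignore_attr = TRUE)
  expect_equal(unname(p$G[, 1]), c(0, 1, 2))
})

test_that("sites with missing calls are dropped under the default policy", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
               "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t./.\t1/1",
               "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1"), vcf)
  p <- load_reference(vcf)
  expect_equal(p$snps$id, "rs2")
  expect_equal(p$log$n_missing_dropped, 1L)
})

test_that("a synthetic panel written as VCF reloads with an identical dosage matrix", {
  cfg <- sim_config(seed = 2, n_reference = 50, n_cohorts = 500L,
                    n_snps = 30, n_genes = 6, maf_range = c(0.2, 0.5))
  ref <- simulate_reference(cfg)
  vcf <- tempfile(fileext = ".vcf")
  write_reference_vcf(ref, vcf)
  back <- load_reference(vcf)
  expect_equal(back$snps$id, ref$snps$id)
  expect_equal(unname(back$G), unname(ref$G))
  expect_equal(back$maf, ref$maf, ignore_attr = TRUE)
})

test_that("ld_r2 is 1 for identical and complementary columns", {
  G <- cbind(a = c(0, 1, 2, 1, 0, 2), b = c(0, 1, 2, 1, 0, 2))
  G <- cbind(G, c = 2 - G[, 1])
  p <- make_panel_from_G(G)
  expect_equal(ld_r2(p, 1, 2), 1)
  expect_equal(ld_r2(p, 1, 3), 1)   # r = -1 squares to 1
  expect_error(ld_r2(p, 2, 2), "distinct")
})

test_that("independent columns have near-zero r2 (Monte-Carlo)", {
  set.seed(42)
  G <- matrix(rbinom(1000 * 40, 2, 0.3), 1000, 40)
  p <- make_panel_from_G(G)
  r2 <- stats::cor(p$G)^2
  off <- r2[upper.tri(r2)]
  expect_gte(mean(off < 0.01), 0.95)
})

test_that("pruning keeps mutually independent SNPs and resolves duplicates by MAF", {
  set.seed(7)
  G <- matrix(rbinom(400 * 20, 2, 0.4), 400, 20)
  p <- make_panel_from_G(G)
  expect_equal(prune(p), seq_len(ncol(p$G)))

  # duplicate pair with different MAFs: the smaller-MAF copy is removed
  x <- rbinom(500, 2, 0.3)                      # maf ~0.3
  y <- ifelse(x > 0 & rbinom(500, 1, 0.35) == 1, x - 1, x)  # correlated, lower maf
  while (stats::cor(x, y)^2 <= 0.2 || mean(y) / 2 >= mean(x) / 2)
    y <- ifelse(x > 0 & rbinom(500, 1, 0.35) == 1, x - 1, x)
  p2 <- make_panel_from_G(cbind(x, y))
  expect_equal(prune(p2), 1L)

  # exact duplicates (equal MAF): the later-positioned SNP is removed
  p3 <- make_panel_from_G(cbind(x, x))
  expect_equal(prune(p3), 1L)
})

test_that("pruning a blocky panel leaves no offending pair (brute-force oracle)", {
  cfg <- sim_config(seed = 11, n_reference = 250, n_cohorts = 500L,
                    n_snps = 200, n_genes = 20, block_rho = 0.9,
                    maf_range = c(0.1, 0.5))
  ref <- simulate_reference(cfg)
  kept <- prune(ref)
  expect_true(length(kept) < ncol(ref$G))   # the blocks force removals
  expect_no_offending_pair(ref, kept)
  # fixed point: pruning the pruned set changes nothing
  sub <- ref
  sub$snps <- sub$snps[kept]
  sub$G <- sub$G[, kept, drop = FALSE]
  sub$maf <- sub$maf[kept]
  expect_equal(prune(sub), seq_along(kept))
})

test_that("pruning is invariant to individual ordering", {
  cfg <- sim_config(seed = 13, n_reference = 150, n_cohorts = 500L,
                    n_snps = 80, n_genes = 8, block_rho = 0.8)
  ref <- simulate_reference(cfg)
  shuffled <- ref
  set.seed(1)
  shuffled$G <- ref$G[sample(nrow(ref$G)), , drop = FALSE]
  expect_equal(prune(shuffled), prune(ref))
})

test_that("gene assignment respects inclusive interval bounds and overlaps", {
  G <- matrix(rbinom(50 * 3, 2, 0.4), 50, 3)
  p <- make_panel_from_G(G)          # positions 100, 200, 300
  genes <- data.frame(chrom = "1", start = c(100L, 150L), end = c(200L, 200L),
                      name = c("gA", "gB"))
  regions <- assign_snps_to_genes(p, genes)
  expect_equal(vapply(regions, `[[`, "", "name"), c("gA", "gB"))
  expect_equal(regions[[1]]$member_snps, c(1L, 2L))   # 100 and 200 inside [100,200]
  expect_equal(regions[[2]]$member_snps, 2L)          # 201 would be outside
  expect_equal(attr(regions, "out_of_gene"), 3L)
})

test_that("gene membership equals brute-force interval containment at scale", {
  set.seed(3)
  n_snps <- 1000
  G <- matrix(rbinom(30 * n_snps, 2, 0.4), 30, n_snps)
  pos <- sort(sample.int(5e5, n_snps))
  dt <- data.table::data.table(SNP = sprintf("rs%05d", seq_len(n_snps)),
                               CHR = "1", POS = pos, A1 = "A", A2 = "G")
  dos <- data.table::as.data.table(t(G))
  data.table::setnames(dos, sprintf("S%03d", 1:30))
  path <- tempfile(fileext = ".tsv")
  data.table::fwrite(cbind(dt, dos), path, sep = "\t")
  panel <- load_reference(path)

  starts <- sample.int(5e5, 50)
  genes <- data.frame(chrom = "1", start = starts,
                      end = starts + sample.int(2e4, 50),
                      name = sprintf("g%02d", 1:50))
  regions <- assign_snps_to_genes(panel, genes)
  got <- lapply(regions, `[[`, "member_snps")
  names(got) <- vapply(regions, `[[`, "", "name")
  for (k in seq_len(nrow(genes))) {
    expected <- which(panel$snps$pos >= genes$start[k] &
                      panel$snps$pos <= genes$end[k])
    if (!length(expected)) expect_false(genes$name[k] %in% names(got))
    else expect_equal(got[[genes$name[k]]], expected)
  }
  # overlap duplication only increases total membership
  expect_gte(sum(lengths(got)),
             n_snps - length(attr(regions, "out_of_gene")))
})

test_that("malformed gene list rows are reported with line numbers", {
  f <- tempfile()
  writeLines(c("1 100 200 gA", "1 300 gB"), f)
  expect_error(read_gene_list(f), "line\\(s\\) 2")
  writeLines(c("1 500 400 gC"), f)
  expect_error(read_gene_list(f), "invalid coordinates")
})
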