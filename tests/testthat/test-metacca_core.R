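make_beta_panel <- function(B, SE, N, ids = NULL) {
  s <- nrow(B); p <- ncol(B)
  ids <- ids %||% sprintf("rs%04d", seq_len(s))
  structure(list(
    snps = data.table::data.table(id = ids, chrom = "1",
                                  pos = seq_len(s) * 100L, a1 = "A", a2 = "G"),
    diseases = sprintf("d%d", seq_len(p)), B = B, SE = SE,
    N = stats::setNames(N, sprintf("d%d", seq_len(p))),
    log = list()), class = "beta_panel")
}

test_that("standardization is beta / (se * sqrt(n))", {
  panel <- make_beta_panel(B = matrix(c(0.05, 0), 2, 1),
                           SE = matrix(0.025, 2, 1), N = 400L)
  std <- standardize_beta(panel)
  expect_equal(std$Bstd[1, 1], 0.1)        # 0.05 / (0.025 * 20)
  expect_equal(std$Bstd[2, 1], 0)          # zero beta stays zero
  bad <- make_beta_panel(matrix(0.1, 1, 1), matrix(-1, 1, 1), 100L)
  expect_error(standardize_beta(bad), "rs0001/d1")
})

test_that("standardized betas approximate genotype-phenotype correlations", {
  # regression identity: for standardized x and y, beta_hat / (se sqrt(n)) ~ cor(x, y)
  set.seed(21)
  n <- 2000
  x <- scale(rbinom(n, 2, 0.3))
  y <- drop(0.15 * x + rnorm(n) * sqrt(1 - 0.15^2))
  fit <- summary(lm(y ~ x))$coefficients
  std <- fit["x", "Estimate"] / (fit["x", "Std. Error"] * sqrt(n))
  expect_lt(abs(std - cor(x, y)), 2 / sqrt(n))
})

test_that("scale invariance: rescaling a study's betas and SEs changes nothing", {
  set.seed(4)
  B <- matrix(rnorm(20 * 3, sd = 0.03), 20, 3)
  SE <- matrix(runif(20 * 3, 0.01, 0.02), 20, 3)
  panel <- make_beta_panel(B, SE, c(900L, 1000L, 1100L))
  scaled <- panel
  scaled$B[, 2] <- scaled$B[, 2] * 7.3
  scaled$SE[, 2] <- scaled$SE[, 2] * 7.3
  s1 <- standardize_beta(panel); s2 <- standardize_beta(scaled)
  expect_equal(s2$Bstd, s1$Bstd)
  r1 <- snp_scan(s1, estimate_sigma_yy(s1))
  r2 <- snp_scan(s2, estimate_sigma_yy(s2))
  expect_equal(r2, r1)
})

test_that("sigma_yy is a correlation matrix of the beta columns", {
  set.seed(5)
  b <- rnorm(10, sd = 0.02)
  panel <- make_beta_panel(cbind(b, b), matrix(0.01, 10, 2), c(1000L, 1000L))
  syy <- estimate_sigma_yy(standardize_beta(panel))
  expect_equal(syy[1, 2], 1)
  one <- make_beta_panel(matrix(b, 10, 1), matrix(0.01, 10, 1), 1000L)
  expect_equal(estimate_sigma_yy(standardize_beta(one)), matrix(1, 1, 1))
})

test_that("null studies give near-zero phenotype correlations", {
  set.seed(6)
  S <- 10000
  B <- matrix(rnorm(S * 3), S, 3) * 0.01
  panel <- make_beta_panel(B, matrix(0.01, S, 3), rep(1000L, 3))
  syy <- estimate_sigma_yy(standardize_beta(panel))
  off <- syy[upper.tri(syy)]
  expect_true(all(abs(off) < 3 / sqrt(S)))
})

test_that("sigma_xx recovers the generating AR(1) LD decay", {
  cfg <- sim_config(seed = 8, n_reference = 2000, n_cohorts = 500L,
                    n_snps = 10, n_genes = 1, block_rho = 0.6,
                    maf_range = c(0.3, 0.5))
  ref <- simulate_reference(cfg)
  sxx <- estimate_sigma_xx(ref, 1:10)
  expect_equal(diag(sxx), rep(1, 10), ignore_attr = TRUE)
  expect_equal(sxx, t(sxx), ignore_attr = TRUE)
  # dosage correlation decays with distance like the latent AR(1),
  # attenuated by thresholding: adjacent > 2-apart > 4-apart
  adj <- mean(sxx[cbind(1:9, 2:10)])
  two <- mean(sxx[cbind(1:8, 3:10)])
  four <- mean(sxx[cbind(1:6, 5:10)])
  expect_gt(adj, two); expect_gt(two, four)
  one_snp <- estimate_sigma_xx(ref, 3)
  expect_equal(one_snp, matrix(1, 1, 1), ignore_attr = TRUE)
})

test_that("assemble_full_cov builds the block matrix and flags PSD status", {
  b <- assemble_full_cov(matrix(1), matrix(0.1), matrix(1), "u")
  expect_equal(b$full, matrix(c(1, 0.1, 0.1, 1), 2))
  expect_true(b$psd)
  b2 <- assemble_full_cov(matrix(1), matrix(1.2), matrix(1), "u")
  expect_false(b2$psd)
  expect_equal(b2$min_eigenvalue, -0.2)     # eigenvalues 1 +/- 1.2
  set.seed(9)
  sxx <- as_corr <- stats::cov2cor(crossprod(matrix(rnorm(40), 10, 4)))
  sxy <- matrix(rnorm(8, sd = 0.1), 4, 2)
  syy <- stats::cov2cor(crossprod(matrix(rnorm(20), 10, 2)))
  full <- assemble_full_cov(sxx, sxy, syy, "u")$full
  expect_equal(full[1:4, 1:4], sxx)
  expect_equal(full[1:4, 5:6], sxy)
  expect_equal(full[5:6, 5:6], syy)
  expect_equal(full[5:6, 1:4], t(sxy))
  expect_error(assemble_full_cov(sxx, matrix(0, 3, 2), syy, "u"), "conformable")
})

test_that("shrinkage converges in the closed-form iteration count and damps only off-diagonals", {
  b <- assemble_full_cov(matrix(1), matrix(1.2), matrix(1), "u")
  shrunk <- shrink_to_psd(b, factor = 0.999, tol = 1e-8)
  k_expected <- ceiling(log((1 - 1e-8) / 1.2) / log(0.999))
  expect_equal(shrunk$shrink_iterations, k_expected)
  expect_true(shrunk$psd)
  expect_equal(diag(shrunk$full), c(1, 1))
  expect_equal(abs(shrunk$sigma_xy[1, 1]), 1.2 * 0.999^k_expected)

  ident <- assemble_full_cov(diag(3), matrix(0, 3, 2), diag(2), "i")
  expect_identical(shrink_to_psd(ident), ident)   # 0 iterations, unchanged

  # property: diagonal untouched, off-diagonal magnitudes never increase
  set.seed(10)
  for (i in 1:5) {
    sxy <- matrix(rnorm(6, sd = 1), 3, 2)      # large enough to break PSD often
    bb <- assemble_full_cov(diag(3), sxy, diag(2), "p")
    ss <- shrink_to_psd(bb)
    expect_equal(diag(ss$full), diag(bb$full))
    expect_true(all(abs(ss$full) <= abs(bb$full) + 1e-12))
    expect_gte(ss$min_eigenvalue, 1e-8 - 1e-12)
  }
})

test_that("cca_from_cov handles the whitened 1x1 case and the null exactly", {
  b <- assemble_full_cov(matrix(1), matrix(0.1), matrix(1), "u")
  res <- cca_from_cov(b, 1000)
  expect_equal(res$r, 0.1)
  expect_equal(res$df, 1L)
  null <- cca_from_cov(assemble_full_cov(matrix(1), matrix(0, 1, 3), diag(3), "z"), 1000)
  expect_equal(null$r, 0)
  expect_equal(null$pvalue, 1)
  expect_error(cca_from_cov(assemble_full_cov(matrix(1), matrix(1.2), matrix(1), "u"), 1000),
               "PSD")
  expect_error(cca_from_cov(b, 3), "n_eff")
})

test_that("summary-statistic CCA equals individual-level CCA on sample moments", {
  set.seed(12)
  for (i in 1:10) {
    g <- sample(1:5, 1); p <- sample(1:5, 1); n <- 500
    G <- matrix(rbinom(n * g, 2, runif(g, 0.2, 0.5)), n, g, byrow = FALSE)
    while (qr(G)$rank < g) G <- matrix(rbinom(n * g, 2, 0.4), n, g)
    Y <- matrix(rnorm(n * p), n, p) + G[, 1] %o% runif(p, 0, 0.2)
    X <- scale(G); Ys <- scale(Y)
    bundle <- assemble_full_cov(cor(X), cor(X, Ys), cor(Ys), "eq")
    res <- cca_from_cov(bundle, n)
    ora <- oracle_cca(G, Y)
    expect_lt(abs(res$r - ora$r), 1e-8)
    expect_lt(abs(res$statistic - ora$statistic), 1e-6)
  }
})

test_that("scaling sigma_xy toward zero never increases r", {
  set.seed(13)
  sxx <- stats::cov2cor(crossprod(matrix(rnorm(60), 20, 3)))
  syy <- stats::cov2cor(crossprod(matrix(rnorm(40), 20, 2)))
  sxy <- matrix(rnorm(6, sd = 0.1), 3, 2)
  rs <- vapply(c(1, 0.8, 0.5, 0.2, 0.05), function(c) {
    cca_from_cov(assemble_full_cov(sxx, c * sxy, syy, "m"), 5000)$r
  }, 0)
  expect_true(all(diff(rs) <= 1e-12))
})

test_that("snp_scan reduces to the univariate z-test when p = 1", {
  set.seed(14)
  B <- matrix(rnorm(50, sd = 0.03), 50, 1)
  SE <- matrix(runif(50, 0.01, 0.02), 50, 1)
  panel <- make_beta_panel(B, SE, 10000L)
  std <- standardize_beta(panel)
  res <- snp_scan(std, matrix(1, 1, 1))
  z2 <- (B / SE)^2
  # Bartlett statistic is a fixed monotone transform of z^2/n
  expect_equal(order(res$pvalue), order(-z2))
  lam <- 1 - std$Bstd[, 1]^2
  expect_equal(res$statistic, -(10000 - 1 - 1.5) * log(lam), ignore_attr = TRUE)
  zero <- make_beta_panel(matrix(0, 3, 1), matrix(0.01, 3, 1), 1000L)
  rz <- snp_scan(standardize_beta(zero), matrix(1, 1, 1))
  expect_true(all(rz$pvalue == 1))
})

test_that("gene_scan: a single-member gene equals the SNP-level result", {
  cfg <- sim_config(seed = 15, n_reference = 300, n_cohorts = rep(1500L, 3),
                    n_snps = 30, n_genes = 30)   # one SNP per gene
  sim <- simulate_gwas(cfg, joint_cohort = FALSE)
  panel <- harmonize(sim$studies)
  ref <- simulate_reference(cfg)
  std <- standardize_beta(panel)
  syy <- estimate_sigma_yy(std)
  genes <- assign_snps_to_genes(ref, sim_gene_regions(cfg))
  sres <- snp_scan(std, syy)
  gres <- gene_scan(std, ref, genes[1:5], syy)
  for (k in 1:5) {
    srow <- sres[sres$unit_id == ref$snps$id[genes[[k]]$member_snps[1]], ]
    expect_equal(gres$r[k], srow$r)
    expect_equal(gres$pvalue[k], srow$pvalue)
  }
})

test_that("with exact covariances a gene's r is at least its best member SNP's", {
  # identity LD, orthogonal effects: adding SNPs can only add canonical signal
  syy <- diag(3)
  sxy <- rbind(c(0.1, 0, 0), c(0, 0.08, 0))
  gene <- cca_from_cov(assemble_full_cov(diag(2), sxy, syy, "g"), 5000)
  snp1 <- cca_from_cov(assemble_full_cov(matrix(1), sxy[1, , drop = FALSE], syy, "s1"), 5000)
  snp2 <- cca_from_cov(assemble_full_cov(matrix(1), sxy[2, , drop = FALSE], syy, "s2"), 5000)
  expect_gte(gene$r, max(snp1$r, snp2$r) - 1e-12)
})
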