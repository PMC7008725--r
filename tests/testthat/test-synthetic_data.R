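test_that("generators are pure functions of (config, seed)", {
  cfg <- sim_config(seed = 17, n_reference = 80, n_cohorts = c(400L, 600L),
                    n_snps = 40, n_genes = 8)
  expect_identical(simulate_reference(cfg), simulate_reference(cfg))
  s1 <- simulate_gwas(cfg); s2 <- simulate_gwas(cfg)
  expect_identical(s1$studies[[1]]$data, s2$studies[[1]]$data)
  expect_identical(s1$joint$Y, s2$joint$Y)
  cfg2 <- sim_config(seed = 18, n_reference = 80, n_cohorts = c(400L, 600L),
                     n_snps = 40, n_genes = 8)
  expect_false(identical(simulate_reference(cfg2)$G, simulate_reference(cfg)$G))
})

test_that("block_rho controls LD: zero gives independence, larger rho more LD", {
  base <- list(seed = 23, n_reference = 2000, n_cohorts = 500L,
               n_snps = 40, n_genes = 4, maf_range = c(0.2, 0.5))
  r2_adjacent <- function(rho) {
    ref <- simulate_reference(do.call(sim_config, c(base, block_rho = rho)))
    idx <- cbind(1:(ncol(ref$G) - 1), 2:ncol(ref$G))
    same_block <- (idx[, 1] - 1) %/% 10 == (idx[, 2] - 1) %/% 10
    mean(vapply(which(same_block), function(k)
      cor(ref$G[, idx[k, 1]], ref$G[, idx[k, 2]])^2, 0))
  }
  ref0 <- simulate_reference(do.call(sim_config, c(base, block_rho = 0)))
  r2 <- cor(ref0$G)^2
  expect_lt(quantile(r2[upper.tri(r2)], 0.95), 0.01)
  expect_gt(r2_adjacent(0.8), r2_adjacent(0.2))
})

test_that("realized MAFs track the configured range", {
  cfg <- sim_config(seed = 29, n_reference = 1500, n_cohorts = 500L,
                    n_snps = 60, n_genes = 6, maf_range = c(0.1, 0.4))
  ref <- simulate_reference(cfg)
  expect_true(all(ref$maf > 0.05 & ref$maf <= 0.5))
  expect_gt(mean(ref$maf), 0.1)
})

test_that("null GWAS z-scores are standard normal", {
  cfg <- sim_config(seed = 37, n_reference = 100, n_cohorts = 2000L,
                    n_snps = 400, n_genes = 40, block_rho = 0)
  sim <- simulate_gwas(cfg, joint_cohort = FALSE)
  z <- sim$studies[[1]]$data[, BETA / SE]
  # mean |z| for N(0,1) is sqrt(2/pi); SE of the mean ~ sqrt(1 - 2/pi)/sqrt(S)
  expect_lt(abs(mean(abs(z)) - sqrt(2 / pi)),
            3 * sqrt(1 - 2 / pi) / sqrt(length(z)))
  expect_lt(abs(var(z) - 1), 3 * sqrt(2 / length(z)))
})

test_that("estimated standardized betas are consistent for causal SNPs", {
  reps <- 50
  est <- numeric(reps)
  for (i in seq_len(reps)) {
    cfg <- sim_config(seed = 1000 + i, n_reference = 50, n_cohorts = 5000L,
                      n_snps = 10, n_genes = 10, block_rho = 0,
                      causal_genes = list(list(gene = 1, traits = 1, effect = 0.1)))
    sim <- simulate_gwas(cfg, joint_cohort = FALSE)
    d <- sim$studies[[1]]$data
    est[i] <- (d$BETA / (d$SE * sqrt(d$N)))[1]
  }
  expect_lt(abs(mean(est) - 0.1), 0.01)
})

test_that("per-trait cohorts are disjoint with the configured sizes", {
  cfg <- sim_config(seed = 41, n_reference = 60, n_cohorts = c(500L, 800L, 300L),
                    n_snps = 20, n_genes = 4)
  sim <- simulate_gwas(cfg, joint_cohort = FALSE)
  expect_equal(vapply(sim$studies, function(s) s$data$N[1], 1L), c(500L, 800L, 300L))
  # different cohorts see different sampling noise
  expect_false(identical(sim$studies[[1]]$data$BETA, sim$studies[[2]]$data$BETA))
})

test_that("implied heritability above 1 is rejected", {
  expect_error(simulate_gwas(sim_config(
    seed = 43, n_cohorts = 500L, n_snps = 20, n_genes = 2, block_rho = 0.9,
    causal_genes = list(list(gene = 1, traits = 1, effect = 0.5)))),
    "heritability")
})

test_that("truth records causal SNPs inside the declared genes", {
  cfg <- sim_config(seed = 47, n_reference = 60, n_cohorts = rep(500L, 2),
                    n_snps = 50, n_genes = 10,
                    causal_genes = list(list(gene = 3, traits = 2, effect = 0.05)))
  sim <- simulate_gwas(cfg, joint_cohort = FALSE)
  pop_genes <- sim_gene_regions(cfg)
  expect_equal(sim$truth$causal_genes, "GENE003")
  expect_length(sim$truth$causal_snps[[1]], 0)
  snp_pos <- sim$studies[[1]]$data$POS[sim$truth$causal_snps[[2]]]
  g3 <- pop_genes[pop_genes$name == "GENE003"]
  expect_true(all(snp_pos >= g3$start & snp_pos <= g3$end))
})

test_that("the oracle reduces to |cor| for one SNP and one trait", {
  set.seed(51)
  g <- rbinom(300, 2, 0.3)
  y <- 0.1 * scale(g) + rnorm(300)
  res <- oracle_cca(matrix(g), matrix(y))
  expect_equal(res$r, abs(cor(g, y)), ignore_attr = TRUE)
})

test_that("permuting phenotype rows destroys the canonical correlation", {
  cfg <- sim_config(seed = 53, n_reference = 50, n_cohorts = rep(2000L, 3),
                    n_snps = 20, n_genes = 4, n_joint = 2000,
                    causal_genes = list(list(gene = 1, traits = 1:2, effect = 0.08)))
  sim <- simulate_gwas(cfg)
  G <- sim$joint$G[, 1:5]; Y <- sim$joint$Y
  set.seed(1)
  perm <- oracle_cca(G, Y[sample(nrow(Y)), ])
  real <- oracle_cca(G, Y)
  expect_lt(perm$r, 0.12)
  expect_gt(real$r, perm$r)
  expect_gt(perm$pvalue, 1e-3)
})

test_that("rank-deficient genotype blocks are rejected by the oracle", {
  set.seed(55)
  g <- rbinom(100, 2, 0.4)
  expect_error(oracle_cca(cbind(g, g), matrix(rnorm(100))), "rank-deficient")
  expect_error(oracle_cca(matrix(1, 100, 1), matrix(rnorm(100))), "constant")
})

test_that("glist and truth writers emit the documented dialects", {
  cfg <- sim_config(seed = 57, n_reference = 50, n_cohorts = 500L,
                    n_snps = 20, n_genes = 4)
  f <- tempfile()
  write_gene_list(sim_gene_regions(cfg), f)
  back <- read_gene_list(f)
  expect_equal(back$name, sprintf("GENE%03d", 1:4))
  sim <- simulate_gwas(cfg, joint_cohort = FALSE)
  tf <- tempfile(fileext = ".json")
  write_sim_truth(sim$truth, tf)
  expect_equal(jsonlite::read_json(tf)$generator_version, "1")
})
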