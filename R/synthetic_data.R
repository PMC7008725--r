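#' Synthetic multi-cohort GWAS generator and individual-level oracle
#'
#' @description
#' Emulates the real inputs of a cross-disease pleiotropy analysis: a
#' reference genotype panel with blockwise LD, several disjoint cohorts
#' of different sizes each measuring one trait, and per-trait univariate
#' regression summary statistics (beta, se, p, n). Genotypes arise from
#' latent block-AR(1) Gaussians thresholded at per-SNP MAF quantiles
#' (two haplotypes per individual summed to a dosage), which induces
#' controllable LD without coalescent machinery. Effects are specified
#' on the standardized-genotype scale, so the simulated truth is
#' directly comparable to standardized betas. Everything is a pure
#' function of (config, seed).
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' @param seed integer master seed; all stage seeds derive from it.
#' @param n_reference reference-panel individuals (default 500).
#' @param n_cohorts per-trait cohort sizes; length sets the trait count
#'   p (default five cohorts of 5000).
#' @param n_snps total SNPs (default 300).
#' @param n_genes gene regions; SNPs are split into contiguous
#'   equal-as-possible gene blocks which are also the LD blocks
#'   (default 60).
#' @param block_rho within-block AR(1) latent correlation in \[0,1)
#'   (default 0.7).
#' @param maf_range per-SNP MAF drawn uniformly from this interval
#'   (default c(0.05, 0.5)).
#' @param causal_genes list of `list(gene =, traits =, effect =)`
#'   entries: every SNP of that gene gets `effect` (standardized scale)
#'   on each listed trait.
#' @param resid_trait_corr p x p residual correlation among traits for
#'   the joint cohort (default identity; irrelevant for disjoint
#'   cohorts).
#' @param n_joint individuals in the optional joint cohort measuring
#'   all traits at once (default 1000).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_reference = 500, n_cohorts = rep(5000L, 5),
                       n_snps = 300, n_genes = 60, block_rho = 0.7,
                       maf_range = c(0.05, 0.5), causal_genes = list(),
                       resid_trait_corr = NULL, n_joint = 1000) {
  p <- length(n_cohorts)
  stopifnot(is_count(seed + 1), is_count(n_reference), p >= 1,
            all(vapply(n_cohorts, is_count, TRUE)),
            is_count(n_snps), is_count(n_genes), n_genes <= n_snps,
            block_rho >= 0, block_rho < 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  resid_trait_corr <- resid_trait_corr %||% diag(p)
  if (!isTRUE(all.equal(resid_trait_corr, t(resid_trait_corr))) ||
      any(abs(diag(resid_trait_corr) - 1) > 1e-10) ||
      min(eigen(resid_trait_corr, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stopf("sim_config: resid_trait_corr must be a PSD correlation matrix")
  for (cg in causal_genes) {
    stopifnot(is_count(cg$gene), cg$gene <= n_genes,
              all(cg$traits >= 1 & cg$traits <= p), is.numeric(cg$effect))
  }
  structure(list(seed = as.integer(seed), n_reference = n_reference,
                 n_cohorts = as.integer(n_cohorts), n_snps = n_snps,
                 n_genes = n_genes, block_rho = block_rho,
                 maf_range = maf_range, causal_genes = causal_genes,
                 resid_trait_corr = resid_trait_corr, n_joint = n_joint,
                 p = p),
            class = "sim_config")
}

# Deterministic population model: SNP metadata, MAFs, allele pairs, gene
# and LD block layout. Seeded from config$seed alone.
build_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    s <- config$n_snps
    sizes <- rep(s %/% config$n_genes, config$n_genes)
    extra <- s - sum(sizes)
    if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    gene_of <- rep(seq_len(config$n_genes), times = sizes)
    pos <- seq_len(s) * 1000L
    # non-complementary allele pairs: post-QC GWAS inputs have the
    # strand-ambiguous A/T and C/G SNPs already excluded
    pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                   c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
    pick <- sample.int(nrow(pairs), s, replace = TRUE)
    snps <- data.table::data.table(
      id = sprintf("rs%06d", seq_len(s)),
      chrom = "1",
      pos = pos,
      a1 = pairs[pick, 1], a2 = pairs[pick, 2],
      maf = stats::runif(s, config$maf_range[1], config$maf_range[2]),
      gene = gene_of)
    genes <- snps[, list(chrom = chrom[1], start = min(pos) - 100L,
                         end = max(pos) + 100L), by = "gene"]
    genes[, name := sprintf("GENE%03d", gene)]
    blocks <- split(seq_len(s), gene_of)
    list(snps = snps, genes = genes[, c("chrom", "start", "end", "name")],
         blocks = blocks, rho = config$block_rho)
  })
}

ar1_corr <- function(size, rho) rho^abs(outer(seq_len(size), seq_len(size), "-"))

# Draw an n x S dosage matrix from the population model (two thresholded
# latent-Gaussian haplotypes per individual). Uses the current RNG stream.
draw_dosages <- function(n, pop) {
  s <- nrow(pop$snps)
  G <- matrix(0L, n, s)
  thresh <- qnorm(pop$snps$maf)
  for (b in pop$blocks) {
    size <- length(b)
    latent <- matrix(rnorm(2L * n * size), 2L * n, size)
    if (size > 1L && pop$rho > 0)
      latent <- latent %*% chol(ar1_corr(size, pop$rho))
    al <- latent < rep(thresh[b], each = 2L * n)
    G[, b] <- al[seq_len(n), , drop = FALSE] + al[n + seq_len(n), , drop = FALSE]
  }
  G
}

#' Simulate a reference genotype panel
#'
#' @param config a `sim_config`.
#' @return A `reference_panel` with `config$n_reference` individuals;
#'   deterministic in `config$seed`.
#' @export
simulate_reference <- function(config) {
  pop <- build_population(config)
  G <- with_seed(config$seed + 11L, draw_dosages(config$n_reference, pop))
  if (any(apply(G, 2, function(x) length(unique(x))) == 1L))
    stopf("simulate_reference: monomorphic column drawn; increase n_reference or maf_range")
  snps <- pop$snps[, c("id", "chrom", "pos", "a1", "a2")]
  G <- matrix(as.numeric(G), nrow(G), ncol(G))
  colnames(G) <- snps$id
  new_reference_panel(data.table::copy(snps), G,
                      log = list(simulated = TRUE, seed = config$seed))
}

# True effect matrix (n_snps x p) on the standardized-genotype scale.
effect_matrix <- function(config, pop) {
  E <- matrix(0, config$n_snps, config$p)
  for (cg in config$causal_genes) {
    rows <- which(pop$snps$gene == cg$gene)
    E[rows, cg$traits] <- cg$effect
  }
  E
}

# Theoretical genetic variance per trait for standardized genotypes with
# the block LD structure (approximating dosage correlation by the latent
# AR(1); adequate for heritability guarding).
genetic_variance <- function(config, pop, E) {
  vapply(seq_len(config$p), function(t) {
    v <- 0
    for (b in pop$blocks) {
      e <- E[b, t]
      if (any(e != 0)) v <- v + drop(e %*% ar1_corr(length(b), pop$rho) %*% e)
    }
    v
  }, 0)
}

#' Simulate per-disease GWAS summary statistics with known architecture
#'
#' Each trait is measured in its own disjoint cohort drawn from the same
#' population model (mirroring independent disease consortia). The
#' phenotype is `standardized genotypes %*% effects + Gaussian noise`
#' with total variance about 1; per-SNP univariate regression on the raw
#' dosage yields beta, se and p. Optionally a joint cohort measures all
#' traits on one sample for individual-level validation.
#'
#' @param config a `sim_config`.
#' @param joint_cohort also draw the joint cohort (default TRUE).
#' @return List with `studies` (one `summary_stats` per trait), `truth`
#'   (a `sim_truth`: per-trait causal SNP indices, effect matrix,
#'   generator version), and `joint` (`list(G, Y)` or NULL).
#' @export
simulate_gwas <- function(config, joint_cohort = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  pop <- build_population(config)
  E <- effect_matrix(config, pop)
  h2 <- genetic_variance(config, pop, E)
  if (any(h2 >= 1))
    stopf("simulate_gwas: implied heritability >= 1 for trait(s) %s",
          paste(which(h2 >= 1), collapse = ", "))

  studies <- vector("list", config$p)
  for (t in seq_len(config$p)) {
    n <- config$n_cohorts[t]
    studies[[t]] <- with_seed(config$seed + 100L + t, {
      G <- draw_dosages(n, pop)
      sds <- apply(G, 2, sd)
      if (any(sds == 0))
        stopf("simulate_gwas: monomorphic column in cohort %d; increase n or maf_range", t)
      X <- scale(G)
      y <- drop(X %*% E[, t]) + rnorm(n) * sqrt(1 - h2[t])
      reg <- univariate_regression(G, y)
      new_summary_stats(sprintf("trait%d", t), data.table::data.table(
        SNP = pop$snps$id, CHR = pop$snps$chrom, POS = pop$snps$pos,
        A1 = pop$snps$a1, A2 = pop$snps$a2,
        BETA = reg$beta, SE = reg$se, P = reg$p, N = n))
    })
  }

  joint <- NULL
  if (joint_cohort) {
    joint <- with_seed(config$seed + 57L, {
      G <- draw_dosages(config$n_joint, pop)
      X <- scale(G)
      noise <- matrix(rnorm(config$n_joint * config$p), config$n_joint) %*%
        chol(config$resid_trait_corr)
      Y <- X %*% E + sweep(noise, 2, sqrt(1 - h2), "*")
      colnames(G) <- pop$snps$id
      colnames(Y) <- sprintf("trait%d", seq_len(config$p))
      list(G = G, Y = Y)
    })
  }

  truth <- structure(list(
    causal_snps = lapply(seq_len(config$p), function(t) which(E[, t] != 0)),
    causal_genes = vapply(config$causal_genes, function(cg)
      sprintf("GENE%03d", cg$gene), ""),
    effects = E, h2 = h2, generator_version = "1"), class = "sim_truth")
  list(studies = studies, truth = truth, joint = joint)
}

# Per-SNP simple linear regression of y on each dosage column.
univariate_regression <- function(G, y) {
  n <- length(y)
  xc <- sweep(G, 2, colMeans(G))
  yc <- y - mean(y)
  sxx <- colSums(xc^2)
  sxy <- drop(crossprod(xc, yc))
  syy <- sum(yc^2)
  beta <- sxy / sxx
  rss <- pmax(syy - beta * sxy, 0)
  se <- sqrt(rss / ((n - 2) * sxx))
  tstat <- beta / se
  p <- pmin(pmax(2 * pt(-abs(tstat), n - 2), .Machine$double.xmin), 1)
  list(beta = beta, se = se, p = p)
}

#' Individual-level canonical correlation oracle
#'
#' Textbook CCA on standardized individual-level data, computed through
#' `stats::cancor` — a code path independent of the summary-statistic
#' engine — with the same Bartlett chi-square significance convention.
#'
#' @param genotypes n x g dosage matrix for the tested SNP set.
#' @param traits n x p phenotype matrix.
#' @return A `cca_result` with `unit_type = "oracle"`.
#' @export
oracle_cca <- function(genotypes, traits) {
  G <- as.matrix(genotypes); Y <- as.matrix(traits)
  if (nrow(G) != nrow(Y)) stopf("oracle_cca: row counts disagree")
  if (any(apply(G, 2, sd) == 0) || any(apply(Y, 2, sd) == 0))
    stopf("oracle_cca: constant column")
  g <- ncol(G); p <- ncol(Y); n <- nrow(G)
  if (qr(G)$rank < g) stopf("oracle_cca: rank-deficient genotype block")
  cc <- cancor(scale(G), scale(Y))
  rs <- pmin(pmax(cc$cor, 0), 1 - 1e-8)
  lambda <- prod(1 - rs^2)
  statistic <- -(n - 1 - (g + p + 1) / 2) * log(lambda)
  df <- g * p
  structure(list(unit_id = "oracle", unit_type = "oracle", g = g, p = p,
                 r = rs[1], statistic = statistic, df = df,
                 pvalue = max(pchisq(statistic, df, lower.tail = FALSE),
                              .Machine$double.xmin),
                 n_eff = n, shrink_iterations = 0L),
            class = "cca_result")
}

#' Write a reference panel as an uncompressed VCF
#'
#' Minimal VCFv4.2 with GT-only genotypes (`0/0`, `0/1`, `1/1` from the
#' dosages); REF is the panel's other allele and ALT its effect allele,
#' so a round-trip through [load_reference()] reproduces the dosage
#' matrix.
#'
#' @param panel a `reference_panel`.
#' @param path output `.vcf` path.
#' @return Invisibly, `path`.
#' @export
write_reference_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "reference_panel"))
  n <- panel$individuals
  samples <- sprintf("S%04d", seq_len(n))
  gt_codes <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(ncol(panel$G)), function(j) {
    paste(c(panel$snps$chrom[j], panel$snps$pos[j], panel$snps$id[j],
            panel$snps$a2[j], panel$snps$a1[j], ".", "PASS", ".", "GT",
            gt_codes[panel$G[, j] + 1]), collapse = "\t")
  }, "")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t"),
               body), path)
  invisible(path)
}

#' Write gene regions in the whitespace-delimited glist dialect
#'
#' @param genes data.frame with `chrom, start, end, name`, or a list of
#'   `gene_region` objects.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gene_list <- function(genes, path) {
  if (!is.data.frame(genes)) {
    genes <- data.table::rbindlist(lapply(genes, function(g)
      data.table::data.table(chrom = g$chrom, start = g$start,
                             end = g$end, name = g$name)))
  }
  writeLines(sprintf("%s %d %d %s", genes$chrom, genes$start,
                     genes$end, genes$name), path)
  invisible(path)
}

#' Gene regions of a simulation config
#'
#' @param config a `sim_config`.
#' @return data.table `chrom, start, end, name` for the simulated genes.
#' @export
sim_gene_regions <- function(config) {
  build_population(config)$genes
}

#' Write simulation ground truth as JSON
#'
#' @param truth a `sim_truth` from [simulate_gwas()].
#' @param path output `.json` path.
#' @return Invisibly, `path`.
#' @export
write_sim_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  write_json_sidecar(list(causal_snps = truth$causal_snps,
                          causal_genes = as.list(truth$causal_genes),
                          h2 = truth$h2,
                          effects_nonzero = which(truth$effects != 0),
                          generator_version = truth$generator_version), path)
  invisible(path)
}
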