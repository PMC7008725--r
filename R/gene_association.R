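#' Per-disease gene-based association test
#'
#' @description
#' Refinement of multivariate gene hits requires knowing, disease by
#' disease, whether a gene's SNPs are jointly associated with that one
#' trait. The test statistic is the sum of squared per-SNP z-scores
#' (`z = beta/se`) over the gene's members; its null distribution under
#' LD is that of `sum(w_i^2)` with `w ~ MVN(0, Sigma_XX)`, equivalently
#' a weighted sum of independent chi-square(1) variables weighted by the
#' eigenvalues of the LD matrix. The p-value is Monte-Carlo:
#' `(# null >= T + 1) / (n_sims + 1)`, floored at `1/(n_sims + 1)`.
#' Simulation is staged adaptively (1e3 up to `n_sims` draws), stopping
#' early once the p estimate's relative standard error drops below 10%.
#'
#' @name gene_association
NULL

#' Monte-Carlo gene-based test for one gene and one disease
#'
#' @param z numeric vector of member-SNP z-scores (`beta/se`).
#' @param sigma_xx member LD (correlation) matrix; repaired by
#'   off-diagonal damping if not PSD (logged via warning).
#' @param n_sims maximum null draws (default 1e6, giving the 1e-6
#'   p-value floor).
#' @param seed optional integer seed; the caller's RNG state is
#'   preserved.
#' @param adaptive stage the simulation and stop early when the
#'   relative standard error of the p estimate is below 10%
#'   (default TRUE).
#' @return A `gene_test_result`: `g`, `statistic`, `n_sims` (draws
#'   actually used), `pvalue`.
#' @export
gene_test <- function(z, sigma_xx, n_sims = 1e6, seed = NULL, adaptive = TRUE) {
  g <- length(z)
  sigma_xx <- as.matrix(sigma_xx)
  if (!g || nrow(sigma_xx) != g || ncol(sigma_xx) != g)
    stopf("gene_test: z (length %d) and sigma_xx (%dx%d) disagree",
          g, nrow(sigma_xx), ncol(sigma_xx))
  if (!is_count(n_sims)) stopf("gene_test: n_sims must be a positive integer")
  lam <- eigen(sigma_xx, symmetric = TRUE, only.values = TRUE)$values
  if (min(lam) < -1e-8) {
    warnf("gene_test: LD matrix not PSD (min eig %.3g); repaired by off-diagonal damping",
          min(lam))
    b <- shrink_to_psd(assemble_full_cov(sigma_xx,
                                         matrix(0, g, 1), matrix(1),
                                         unit_id = "ld_repair"))
    lam <- eigen(b$sigma_xx, symmetric = TRUE, only.values = TRUE)$values
  }
  lam <- pmax(lam, 0)
  statistic <- sum(z^2)

  with_seed(seed, {
    total <- 0; hits <- 0
    stage_targets <- unique(pmin(10^(3:15), n_sims))
    stage_targets <- stage_targets[stage_targets <= n_sims]
    if (!length(stage_targets) || max(stage_targets) < n_sims)
      stage_targets <- c(stage_targets, n_sims)
    chunk_max <- max(1e4, floor(2e6 / g))
    for (target in stage_targets) {
      while (total < target) {
        m <- min(chunk_max, target - total)
        Z2 <- matrix(rnorm(g * m)^2, nrow = g)
        null_stats <- if (g == 1L) lam * Z2[1, ] else colSums(lam * Z2)
        hits <- hits + sum(null_stats >= statistic)
        total <- total + m
      }
      phat <- (hits + 1) / (total + 1)
      rel_se <- sqrt(phat * (1 - phat) / total) / phat
      if (adaptive && rel_se < 0.1) break
    }
    structure(list(gene = NA_character_, disease = NA_character_,
                   g = g, statistic = statistic,
                   n_sims = as.integer(total),
                   pvalue = (hits + 1) / (total + 1)),
              class = "gene_test_result")
  })
}

#' @export
print.gene_test_result <- function(x, ...) {
  cat(sprintf("<gene_test_result> %s/%s: g=%d, T=%.2f, p=%.3g (%d draws)\n",
              x$gene, x$disease, x$g, x$statistic, x$pvalue, x$n_sims))
  invisible(x)
}

#' Gene-based test over every (gene, disease) pair
#'
#' z-scores are taken as `beta/se` from the harmonized panel; each
#' gene's LD matrix comes from the reference panel. Results are
#' deterministic under a fixed seed.
#'
#' @param panel a `beta_panel` whose SNP ids match the reference panel.
#' @param reference a `reference_panel`.
#' @param genes list of `gene_region` objects (member indices into the
#'   reference panel).
#' @param kept optional pruned SNP indices; gene members are restricted
#'   to them (default: all panel SNPs).
#' @param n_sims maximum null draws per cell (default 1e6).
#' @param seed integer seed for the whole scan (default 1).
#' @param adaptive early-stop staging, see [gene_test()].
#' @return data.table with columns `gene, disease, g, statistic,
#'   n_sims, pvalue`; attribute `"skipped"` lists genes with no usable
#'   member SNPs.
#' @export
gene_test_scan <- function(panel, reference, genes, kept = NULL,
                           n_sims = 1e6, seed = 1, adaptive = TRUE) {
  stopifnot(inherits(panel, "beta_panel"), inherits(reference, "reference_panel"))
  kept <- kept %||% seq_len(ncol(reference$G))
  Z <- panel$B / panel$SE
  rows <- list(); skipped <- character(0)
  with_seed(seed, {
    for (gr in genes) {
      members <- intersect(gr$member_snps, kept)
      prows <- match(reference$snps$id[members], panel$snps$id)
      ok <- !is.na(prows)
      members <- members[ok]; prows <- prows[ok]
      if (!length(members)) { skipped <- c(skipped, gr$name); next }
      sxx <- estimate_sigma_xx(reference, members)
      for (d in seq_along(panel$diseases)) {
        res <- gene_test(Z[prows, d], sxx, n_sims = n_sims, seed = NULL,
                         adaptive = adaptive)
        rows[[length(rows) + 1L]] <- data.table::data.table(
          gene = gr$name, disease = panel$diseases[d], g = res$g,
          statistic = res$statistic, n_sims = res$n_sims, pvalue = res$pvalue)
      }
    }
  })
  out <- data.table::rbindlist(rows)
  structure(out[], skipped = skipped, seed = seed)
}
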