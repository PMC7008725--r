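#' Summary-statistic canonical correlation engine
#'
#' @description
#' The engine turns per-disease univariate GWAS outputs into multivariate
#' genotype-phenotype association tests without individual-level data.
#' Regression coefficients are standardized to the correlation scale,
#' `beta_std = beta / (se * sqrt(n))`, so that for standardized genotype
#' and phenotype they approximate the sample genotype-phenotype
#' correlation. A full covariance matrix
#'
#' \deqn{\Sigma = \begin{pmatrix} \Sigma_{XX} & \Sigma_{XY} \\
#'       \Sigma_{XY}^T & \Sigma_{YY} \end{pmatrix}}
#'
#' is assembled from the reference-panel LD block (`Sigma_XX`), the
#' standardized betas (`Sigma_XY`), and the phenotype correlation
#' estimated as Pearson correlation between the per-trait beta vectors
#' across all harmonized SNPs (`Sigma_YY`). Non-PSD matrices are shrunk
#' by iteratively damping the off-diagonal entries, then canonical
#' correlations and a Bartlett chi-square p-value are computed.
#'
#' @name metacca_core
NULL

#' Standardize regression coefficients to the correlation scale
#'
#' Each entry becomes `beta / (se * sqrt(n))` with the study's sample
#' size `n` — the per-study z-score divided by `sqrt(n)`. On this scale
#' the coefficients are comparable across studies of different size and
#' approximate genotype-phenotype correlations for standardized data.
#'
#' @param panel a `beta_panel`.
#' @return A `std_beta_panel` with `snps`, `diseases`, matrix `Bstd` and `N`.
#' @export
standardize_beta <- function(panel) {
  stopifnot(inherits(panel, "beta_panel"))
  bad <- which(!is.finite(panel$SE) | panel$SE <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stopf("standardize_beta: non-positive se at (%s)",
          paste(sprintf("%s/%s", panel$snps$id[bad[, 1]],
                        panel$diseases[bad[, 2]]), collapse = ", "))
  if (any(!is.finite(panel$N) | panel$N <= 0))
    stopf("standardize_beta: non-positive sample size for %s",
          paste(panel$diseases[panel$N <= 0], collapse = ", "))
  Bstd <- sweep(panel$B / panel$SE, 2, sqrt(panel$N), "/")
  if (any(!is.finite(Bstd)))
    stopf("standardize_beta: non-finite standardized coefficients")
  over <- abs(Bstd) > 1 + 1e-9
  if (any(over)) {
    w <- which(over, arr.ind = TRUE)
    stopf("standardize_beta: |standardized beta| > 1 at (%s); inputs are not on a correlation scale",
          paste(sprintf("%s/%s", panel$snps$id[w[, 1]],
                        panel$diseases[w[, 2]]), collapse = ", "))
  }
  structure(list(snps = panel$snps, diseases = panel$diseases,
                 Bstd = Bstd, N = panel$N),
            class = "std_beta_panel")
}

#' Phenotype-phenotype correlation from standardized betas
#'
#' Entry (a, b) is the Pearson correlation of the standardized beta
#' vectors of traits a and b across SNP rows. Designed to be computed on
#' ALL harmonized SNPs (before pruning): accuracy grows with the number
#' of SNP rows, and the same matrix is reused for every tested unit.
#'
#' @param std a `std_beta_panel` with at least 3 SNP rows.
#' @return p x p symmetric correlation matrix with unit diagonal.
#' @export
estimate_sigma_yy <- function(std) {
  stopifnot(inherits(std, "std_beta_panel"))
  if (nrow(std$Bstd) < 3L)
    stopf("estimate_sigma_yy: need at least 3 SNP rows, got %d", nrow(std$Bstd))
  sds <- apply(std$Bstd, 2, sd)
  if (any(sds == 0))
    stopf("estimate_sigma_yy: degenerate study with constant betas: %s",
          paste(std$diseases[sds == 0], collapse = ", "))
  as_correlation(cor(std$Bstd))
}

#' Genotype-genotype correlation (LD block) from the reference panel
#'
#' @param panel a `reference_panel`.
#' @param members SNP column indices of the tested unit.
#' @return g x g sample Pearson correlation matrix of the dosage columns.
#' @export
estimate_sigma_xx <- function(panel, members) {
  stopifnot(inherits(panel, "reference_panel"))
  if (!length(members) || any(members < 1 | members > ncol(panel$G)))
    stopf("estimate_sigma_xx: invalid member indices")
  as_correlation(cor(panel$G[, members, drop = FALSE]))
}

#' Assemble the full block covariance matrix for one tested unit
#'
#' Builds `[[Sigma_XX, Sigma_XY], [Sigma_XY', Sigma_YY]]` and records
#' its PSD status and minimum eigenvalue.
#'
#' @param sigma_xx g x g genotype correlation.
#' @param sigma_xy g x p standardized betas for the unit.
#' @param sigma_yy p x p phenotype correlation.
#' @param unit_id label for error messages and outputs.
#' @param psd_tol eigenvalue tolerance for the PSD flag (default 1e-8).
#' @return A `cov_bundle`: blocks, `full`, `g`, `p`, `psd`,
#'   `min_eigenvalue`, `shrink_iterations` (0).
#' @export
assemble_full_cov <- function(sigma_xx, sigma_xy, sigma_yy, unit_id = "unit",
                              psd_tol = 1e-8) {
  sigma_xx <- as.matrix(sigma_xx); sigma_yy <- as.matrix(sigma_yy)
  if (!is.matrix(sigma_xy)) sigma_xy <- matrix(sigma_xy, nrow = nrow(sigma_xx))
  g <- nrow(sigma_xx); p <- nrow(sigma_yy)
  if (ncol(sigma_xx) != g || ncol(sigma_yy) != p ||
      nrow(sigma_xy) != g || ncol(sigma_xy) != p)
    stopf("assemble_full_cov(%s): non-conformable blocks (g=%d, p=%d, xy=%dx%d)",
          unit_id, g, p, nrow(sigma_xy), ncol(sigma_xy))
  for (nm in c("sigma_xx", "sigma_yy")) {
    m <- get(nm)
    if (max(abs(m - t(m))) > 1e-10 || max(abs(diag(m) - 1)) > 1e-10)
      stopf("assemble_full_cov(%s): %s must be symmetric with unit diagonal",
            unit_id, nm)
  }
  full <- rbind(cbind(sigma_xx, sigma_xy),
                cbind(t(sigma_xy), sigma_yy))
  min_eig <- min(eigen(full, symmetric = TRUE, only.values = TRUE)$values)
  structure(list(unit_id = unit_id, g = g, p = p,
                 sigma_xx = sigma_xx, sigma_xy = sigma_xy, sigma_yy = sigma_yy,
                 full = full, psd = min_eig >= -psd_tol,
                 shrink_iterations = 0L, min_eigenvalue = min_eig),
            class = "cov_bundle")
}

#' @export
print.cov_bundle <- function(x, ...) {
  cat(sprintf("<cov_bundle> %s: g=%d, p=%d, psd=%s, min eig=%.3g, shrink iters=%d\n",
              x$unit_id, x$g, x$p, x$psd, x$min_eigenvalue, x$shrink_iterations))
  invisible(x)
}

#' Shrink a covariance bundle to positive semidefiniteness
#'
#' While the minimum eigenvalue of the full matrix is below `tol`, all
#' off-diagonal entries (across every block, including `Sigma_XY`) are
#' multiplied by `factor`; the diagonal is untouched and the blocks are
#' rebuilt consistently. Because the diagonal is all ones, k damping
#' steps move the minimum eigenvalue to `factor^k * lambda_min +
#' (1 - factor^k)` exactly, which the implementation exploits to take
#' the k steps in one multiplication; the iteration count equals the
#' number of single damping steps the literal loop would perform.
#'
#' @param bundle a `cov_bundle`.
#' @param factor off-diagonal damping per iteration, in (0,1); default 0.999.
#' @param tol minimum-eigenvalue target (default 1e-8).
#' @param max_iter safety cap (default 1e5).
#' @return The PSD `cov_bundle` with `shrink_iterations` and
#'   `min_eigenvalue` updated.
#' @export
shrink_to_psd <- function(bundle, factor = 0.999, tol = 1e-8, max_iter = 1e5) {
  stopifnot(inherits(bundle, "cov_bundle"))
  if (!(factor > 0 && factor < 1)) stopf("shrink_to_psd: factor must be in (0,1)")
  min_eig <- min(eigen(bundle$full, symmetric = TRUE, only.values = TRUE)$values)
  if (min_eig >= tol) {
    bundle$min_eigenvalue <- min_eig
    bundle$psd <- TRUE
    return(bundle)
  }
  unit_diag <- max(abs(diag(bundle$full) - 1)) < 1e-12
  iters <- 0L
  full <- bundle$full
  if (unit_diag) {
    # f^k * lambda_min + (1 - f^k) >= tol  <=>  f^k <= (1 - tol)/(1 - lambda_min)
    k <- ceiling(log((1 - tol) / (1 - min_eig)) / log(factor))
    k <- max(1L, as.integer(k))
    if (k > max_iter) stopf("shrink_to_psd(%s): max_iter exceeded", bundle$unit_id)
    damp <- factor^k
    full <- damp * full + (1 - damp) * diag(nrow(full))
    iters <- k
    min_eig <- min(eigen(full, symmetric = TRUE, only.values = TRUE)$values)
  }
  while (min_eig < tol) {   # non-unit diagonals, or residual numerical slack
    if (iters >= max_iter) stopf("shrink_to_psd(%s): max_iter exceeded", bundle$unit_id)
    d <- diag(full)
    full <- factor * full
    diag(full) <- d
    iters <- iters + 1L
    min_eig <- min(eigen(full, symmetric = TRUE, only.values = TRUE)$values)
  }
  g <- bundle$g; p <- bundle$p
  bundle$full <- full
  bundle$sigma_xx <- full[seq_len(g), seq_len(g), drop = FALSE]
  bundle$sigma_xy <- full[seq_len(g), g + seq_len(p), drop = FALSE]
  bundle$sigma_yy <- full[g + seq_len(p), g + seq_len(p), drop = FALSE]
  bundle$psd <- TRUE
  bundle$min_eigenvalue <- min_eig
  bundle$shrink_iterations <- bundle$shrink_iterations + iters
  bundle
}

# Symmetric inverse square root with a ridge when the smallest eigenvalue
# falls below `ridge_tol` (near-singular LD blocks of large genes).
sym_inv_sqrt <- function(m, ridge_tol = 1e-6, unit_id = "unit") {
  e <- eigen(m, symmetric = TRUE)
  eps <- max(0, ridge_tol - min(e$values))
  vals <- e$values + eps
  if (any(vals <= 0))
    stopf("singular covariance block beyond ridge repair in unit %s", unit_id)
  e$vectors %*% (t(e$vectors) / sqrt(vals))
}

#' Canonical correlation test from a covariance bundle
#'
#' Canonical correlations are the singular values of
#' `Sigma_XX^{-1/2} Sigma_XY Sigma_YY^{-1/2}` (symmetric inverse square
#' roots, ridge-stabilized for near-singular LD blocks), clipped to
#' `[0, 1 - 1e-8]`. Significance uses Bartlett's chi-square
#' approximation on Wilks' lambda over all canonical correlations:
#' `statistic = -(n_eff - 1 - (g + p + 1)/2) * log(prod(1 - r_i^2))`
#' with `df = g * p`.
#'
#' @param bundle a PSD `cov_bundle` (shrink first if needed).
#' @param n_eff effective sample size; must exceed `g + p + 1`.
#' @param ridge_tol smallest eigenvalue tolerated in `Sigma_XX` /
#'   `Sigma_YY` before a ridge is added (default 1e-6).
#' @return A `cca_result`: `unit_id, unit_type, g, p, r, statistic, df,
#'   pvalue, n_eff, shrink_iterations`.
#' @export
cca_from_cov <- function(bundle, n_eff, ridge_tol = 1e-6) {
  stopifnot(inherits(bundle, "cov_bundle"))
  if (!bundle$psd)
    stopf("cca_from_cov(%s): bundle is not PSD; apply shrink_to_psd first",
          bundle$unit_id)
  g <- bundle$g; p <- bundle$p
  if (!is_count(n_eff) || n_eff <= g + p + 1)
    stopf("cca_from_cov(%s): n_eff must exceed g + p + 1 = %d",
          bundle$unit_id, g + p + 1)
  if (g >= 0.9 * n_eff)
    warnf("cca_from_cov(%s): g = %d approaches n_eff = %d; results unstable",
          bundle$unit_id, g, n_eff)
  K <- sym_inv_sqrt(bundle$sigma_xx, ridge_tol, bundle$unit_id) %*%
       bundle$sigma_xy %*%
       sym_inv_sqrt(bundle$sigma_yy, ridge_tol, bundle$unit_id)
  rs <- svd(K, nu = 0, nv = 0)$d[seq_len(min(g, p))]
  rs <- pmin(pmax(rs, 0), 1 - 1e-8)
  lambda <- prod(1 - rs^2)
  statistic <- -(n_eff - 1 - (g + p + 1) / 2) * log(lambda)
  df <- g * p
  pvalue <- max(pchisq(statistic, df, lower.tail = FALSE), .Machine$double.xmin)
  structure(list(unit_id = bundle$unit_id, unit_type = "snp",
                 g = g, p = p, r = rs[1], statistic = statistic, df = df,
                 pvalue = pvalue, n_eff = as.integer(n_eff),
                 shrink_iterations = bundle$shrink_iterations),
            class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf("<cca_result> %s (%s): g=%d, p=%d, r=%.4f, chi2=%.2f, df=%d, p=%.3g\n",
              x$unit_id, x$unit_type, x$g, x$p, x$r, x$statistic, x$df, x$pvalue))
  invisible(x)
}

cca_result_row <- function(res) {
  data.table::data.table(unit_id = res$unit_id, unit_type = res$unit_type,
                         g = res$g, p = res$p, r = res$r,
                         statistic = res$statistic, df = res$df,
                         pvalue = res$pvalue, n_eff = res$n_eff,
                         shrink_iterations = res$shrink_iterations)
}

#' Effective sample size across studies
#'
#' The conservative default takes the minimum per-study n; harmonic and
#' arithmetic means are available.
#'
#' @param N vector of per-study sample sizes.
#' @param rule one of `"min"` (default), `"harmonic"`, `"mean"`.
#' @return integer effective n.
#' @export
effective_n <- function(N, rule = c("min", "harmonic", "mean")) {
  rule <- match.arg(rule)
  as.integer(round(switch(rule,
    min = min(N),
    harmonic = length(N) / sum(1 / N),
    mean = mean(N))))
}

#' Univariate-SNP, multivariate-phenotype scan
#'
#' One canonical correlation test per kept SNP with `g = 1`
#' (`Sigma_XX = [1]`), all traits jointly as the phenotype side.
#'
#' @param std a `std_beta_panel`.
#' @param sigma_yy phenotype correlation matrix (global, from
#'   [estimate_sigma_yy()] on all harmonized SNPs).
#' @param kept SNP row indices to test (default all).
#' @param n_eff effective sample size (default `min` over studies).
#' @param shrink_factor,shrink_tol PSD shrinkage parameters applied when
#'   an assembled unit is not PSD.
#' @return data.table with one row per SNP, columns `unit_id, unit_type,
#'   g, p, r, statistic, df, pvalue, n_eff, shrink_iterations`.
#' @export
snp_scan <- function(std, sigma_yy, kept = NULL, n_eff = NULL,
                     shrink_factor = 0.999, shrink_tol = 1e-8) {
  stopifnot(inherits(std, "std_beta_panel"))
  kept <- kept %||% seq_len(nrow(std$Bstd))
  n_eff <- n_eff %||% effective_n(std$N)
  rows <- vector("list", length(kept))
  for (k in seq_along(kept)) {
    s <- kept[k]
    b <- assemble_full_cov(matrix(1), std$Bstd[s, , drop = FALSE], sigma_yy,
                           unit_id = std$snps$id[s])
    if (!b$psd) b <- shrink_to_psd(b, factor = shrink_factor, tol = shrink_tol)
    rows[[k]] <- cca_result_row(cca_from_cov(b, n_eff))
  }
  out <- data.table::rbindlist(rows)
  out[, unit_type := "snp"]
  out[]
}

#' Multivariate-SNP, multivariate-phenotype scan at the gene level
#'
#' One canonical correlation test per gene; `g` is the count of the
#' gene's member SNPs that survived pruning, and `Sigma_XX` is their
#' reference-panel correlation. Genes left with zero pruned members are
#' skipped (attribute `"skipped"`).
#'
#' @param std a `std_beta_panel` whose SNP ids match the reference panel.
#' @param panel the `reference_panel`.
#' @param genes list of `gene_region` objects (member indices into the
#'   reference panel).
#' @param sigma_yy global phenotype correlation matrix.
#' @param kept pruned SNP indices into the reference panel (default all).
#' @param n_eff effective sample size (default `min` over studies).
#' @param shrink_factor,shrink_tol PSD shrinkage parameters.
#' @return data.table as in [snp_scan()] with `unit_type = "gene"`.
#' @export
gene_scan <- function(std, panel, genes, sigma_yy, kept = NULL, n_eff = NULL,
                      shrink_factor = 0.999, shrink_tol = 1e-8) {
  stopifnot(inherits(std, "std_beta_panel"), inherits(panel, "reference_panel"))
  kept <- kept %||% seq_len(ncol(panel$G))
  n_eff <- n_eff %||% effective_n(std$N)
  rows <- list(); skipped <- character(0)
  for (gr in genes) {
    members <- intersect(gr$member_snps, kept)
    if (!length(members)) { skipped <- c(skipped, gr$name); next }
    srows <- match(panel$snps$id[members], std$snps$id)
    if (anyNA(srows))
      stopf("gene_scan(%s): member SNPs missing from the beta panel", gr$name)
    if (length(members) >= panel$individuals)
      warnf("gene_scan(%s): g = %d >= reference individuals %d; LD estimate rank-deficient",
            gr$name, length(members), panel$individuals)
    b <- assemble_full_cov(estimate_sigma_xx(panel, members),
                           std$Bstd[srows, , drop = FALSE],
                           sigma_yy, unit_id = gr$name)
    if (!b$psd) b <- shrink_to_psd(b, factor = shrink_factor, tol = shrink_tol)
    res <- cca_from_cov(b, n_eff)
    res$unit_type <- "gene"
    rows[[length(rows) + 1L]] <- cca_result_row(res)
  }
  out <- data.table::rbindlist(rows)
  structure(out[], skipped = skipped)
}

#' Write a scan result table
#'
#' Tab-delimited, full-precision scientific notation, plus a JSON
#' sidecar of run metadata.
#'
#' @param scan data.table from [snp_scan()] or [gene_scan()].
#' @param path output file; sidecar gets `.json` appended.
#' @param meta named list of run metadata (thresholds, seeds, rules).
#' @return Invisibly, the two paths.
#' @export
write_scan <- function(scan, path, meta = list()) {
  data.table::fwrite(scan, path, sep = "\t", scipen = 0)
  sidecar <- paste0(path, ".json")
  write_json_sidecar(meta, sidecar)
  invisible(c(path, sidecar))
}
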