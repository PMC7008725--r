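#' @importFrom data.table fread fwrite data.table as.data.table setorder :=
#' @importFrom stats cor pchisq pnorm pt qnorm rnorm sd var cancor setNames
#' @importFrom utils head
NULL

# Deterministic chromosome ordering: numeric chromosomes first in numeric
# order, then the rest lexicographically (X, Y, MT, ...).
chrom_rank <- function(chrom) {
  ch <- sub("^chr", "", as.character(chrom))
  num <- suppressWarnings(as.numeric(ch))
  rank <- ifelse(is.na(num), 1e6 + as.numeric(factor(ch, levels = sort(unique(ch[is.na(num)])))), num)
  rank
}

# Order of SNP rows: (chrom, pos), ties by id for full determinism.
snp_order <- function(chrom, pos, id) {
  order(chrom_rank(chrom), pos, id)
}

# Run `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is untouched. seed = NULL means: use (and advance) the
# global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)

# Symmetrize and force a unit diagonal (numerical hygiene for correlation
# matrices assembled from sample moments).
as_correlation <- function(m) {
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

write_json_sidecar <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
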