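---
title: "Detecting cross-trait pleiotropy from GWAS summary statistics by canonical correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cross-trait pleiotropy from GWAS summary statistics by canonical correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleiocca)
```

## The problem

Univariate GWAS tests one SNP against one trait. When several related
diseases — say, a set of autoimmune/autoinflammatory conditions studied
by different consortia — share genetic risk factors, the univariate view
is both underpowered and blind to the sharing itself. `pleiocca`
implements a meta-analytic canonical correlation analysis that takes
only per-disease summary statistics (beta, SE, p, n per SNP), plus a
reference genotype panel of matched ancestry, and tests multivariate
genotype-phenotype association at the SNP and gene level. Gene hits are
then refined by per-disease gene-based tests into a final set of
pleiotropic gene calls.

## Model

For study $t$ with sample size $n_t$, the per-SNP coefficient is
standardized to the correlation scale:

$$\beta^{std}_{gt} = \frac{\beta_{gt}}{SE_{gt}\,\sqrt{n_t}},$$

i.e. the z-score divided by $\sqrt{n_t}$. When genotype and phenotype
are standardized, $\hat\beta/SE \approx \sqrt{n}\,\hat{r}$, so
$\beta^{std}$ approximates the sample genotype-phenotype correlation —
which is what makes coefficients from cohorts of very different sizes
commensurable. The printed form of this equation in the summary-statistic
CCA literature is occasionally garbled by typesetting; the
reading implemented here is the one under which the standardized
coefficients are correlations, which the whole construction requires.

For a tested unit of $g$ SNPs and $p$ traits the full covariance matrix
is assembled blockwise:

$$\Sigma = \begin{pmatrix} \hat\Sigma_{XX} & \Sigma_{XY} \\
\Sigma_{XY}^{\mathsf T} & \hat\Sigma_{YY} \end{pmatrix}$$

* $\hat\Sigma_{XX}$ ($g \times g$): sample correlation of the unit's
  dosage columns in the reference panel. LD is never estimated from the
  summary statistics.
* $\Sigma_{XY}$ ($g \times p$): the standardized betas.
* $\hat\Sigma_{YY}$ ($p \times p$): Pearson correlation between the
  per-trait standardized beta vectors, computed once across **all**
  harmonized SNPs (not just the pruned ones — accuracy grows with the
  number of SNP rows) and reused for every unit. No correction for
  shared controls between cohorts is applied; overlapping samples would
  inflate $\hat\Sigma_{YY}$ off-diagonals and make the test
  conservative rather than anticonservative.

Because the three blocks are estimated from different data, $\Sigma$
need not be positive semidefinite. When it is not, every off-diagonal
entry of the full matrix (including $\Sigma_{XY}$) is multiplied by a
factor of 0.999 repeatedly until the smallest eigenvalue reaches
$10^{-8}$; the diagonal is untouched and the blocks are rebuilt from the
damped matrix. Shrinking the full matrix rather than individual blocks
keeps the three estimates mutually consistent. Since the diagonal is
all ones, $k$ damping steps move the minimum eigenvalue to
$f^k\lambda_{\min} + (1-f^k)$ exactly, so the implementation computes
the required $k$ in closed form and applies it in one multiplication —
the reported iteration count is identical to the literal loop's.

Canonical correlations are the singular values of
$\hat\Sigma_{XX}^{-1/2}\,\Sigma_{XY}\,\hat\Sigma_{YY}^{-1/2}$, clipped
to $[0, 1-10^{-8}]$ so the log below stays finite. Significance uses
Bartlett's chi-square approximation on Wilks' lambda over all
correlations:

$$\chi^2 = -\Big(n_{\mathrm{eff}} - 1 - \tfrac{g+p+1}{2}\Big)
\log \prod_i (1 - r_i^2), \qquad df = g\,p.$$

The p-value construction is validated by null simulation (uniform
p-values, calibrated type-I error) rather than by citation; testing only
the leading correlation is a possible variant but is not the default.
With studies of unequal size, $n_{\mathrm{eff}}$ defaults to the
minimum per-study $n$ (conservative); harmonic and arithmetic means are
available via `effective_n()`.

## Pipeline stages and their parameters

**Harmonization** (`harmonize`). SNPs present in every study are kept;
alleles are matched as unordered pairs against the first study's
convention, with beta signs flipped for swapped orientation.
Strand-ambiguous A/T and C/G SNPs are dropped by default
(`ambiguous_policy = "keep"` retains them), and irreconcilable pairs
are dropped and logged. Frequency-based strand resolution is
deliberately out of scope: the intended inputs are single-ancestry
studies where the ambiguous fraction is small and frequency matching is
error-prone. A per-SNP `N` column is collapsed to the study median with
a warning, since standardization treats $n$ as a per-study scalar.

**LD pruning** (`prune`). PLINK-style `indep-pairwise` semantics:
windows of 50 SNPs advanced by 5, within-window pairs with $r^2 > 0.2$
resolved by removing the smaller-MAF SNP (equal MAFs: the
later-positioned one, for determinism), repeated to a fixed point.
Windows are SNP-count based and per chromosome. The tie-break and the
fixed-point repetition make the survivor set reproducible regardless of
individual ordering in the panel.

**Gene assignment** (`assign_snps_to_genes`). Gene intervals are
1-based and inclusive on both ends (the glist convention), with no
flanking window. A SNP in $k$ overlapping genes belongs to all $k$.
Interval overlap is delegated to `IRanges::findOverlaps`.

**Gene-based per-disease test** (`gene_test`). The statistic is
$T = \sum_j z_j^2$ over the gene's member SNPs with $z = \beta/SE$
(z-scores are taken from beta and SE, not back-computed from p-values,
preserving sign and avoiding underflow at p-value floors). Under the
null, $T \sim \sum_j \lambda_j \chi^2_1$ with $\lambda_j$ the
eigenvalues of the member LD matrix; the p-value is Monte-Carlo,
$(\#\{T_{null} \ge T\} + 1)/(n_{sims}+1)$, floored at
$1/(n_{sims}+1)$. The default $n_{sims} = 10^6$ gives a floor of
$10^{-6}$, the same floor the selection gate below treats as an
association. Simulation is staged ($10^3 \to 10^6$) and stops early
once the relative standard error of the estimate is below 10%, so
unremarkable genes cost thousands of draws, not millions. Exact
analytic tail methods for chi-square mixtures (Davies/Imhof) are a
non-goal; the Monte-Carlo floor is part of the method's observable
behaviour.

**Refinement** (`refine_pleiotropic`). Two gates define a pleiotropic
call: the multivariate gene p-value below the Bonferroni threshold
$\alpha/m_{genes}$ (strict `<`, matching the usual "smaller than"
convention), and a per-disease gene-based p-value at or below the
association cutoff (default $10^{-6}$; `<=` rather than `<` because
floored Monte-Carlo p-values of exactly $10^{-6}$ count as
associations). Genes reaching the cutoff for two or more diseases are
flagged multi-disease. The confirmed/novel annotation is always an
input (curated externally); the package never infers novelty.
Thresholds default to $\alpha/m$ computed from the run's own SNP and
gene counts.

## What the synthetic generator emulates — and what it does not

`simulate_reference`/`simulate_gwas` produce: blockwise-LD genotypes
(two haplotypes per individual, each a latent block-AR(1) Gaussian
thresholded at the SNP's MAF quantile, summed to a dosage), disjoint
per-trait cohorts of configurable size drawn from the same population
model, phenotypes built from standardized-genotype effects plus
Gaussian noise with total variance about 1, and per-SNP univariate
regression outputs. Effects are specified on the standardized scale so
the truth is directly comparable to standardized betas. Defaults were
chosen once as the study conditions for validation: MAF uniform on
[0.05, 0.5], within-block latent correlation 0.7 (adjacent-dosage
$r^2$ well above the 0.2 pruning threshold), reference panel of 500
individuals, five cohorts of 5,000, and per-SNP causal effects of 0.05
— a modest effect detectable but not trivial at that sample size.
Allele pairs are drawn from the non-complementary combinations,
mirroring post-QC GWAS inputs in which strand-ambiguous SNPs have
already been excluded (harmonization's ambiguous-drop path is exercised
by dedicated tests instead).

The generator does **not** emulate: realistic human demography or
coalescent LD (the AR(1) blocks have no long-range structure),
imputation error, case-control ascertainment, sample overlap between
cohorts (a knob exists for residual trait correlation in the joint
cohort only), or genomic control. Passing the recovery study therefore
shows the statistical machinery is correct under its assumptions, not
that real-data applications are free of those complications.

## Numerical choices

* Near-singular LD blocks (large genes, $g$ approaching the reference
  panel size) get a ridge: $\hat\Sigma_{XX} + \varepsilon I$ with
  $\varepsilon = \max(0, 10^{-6} - \lambda_{\min})$; a warning fires
  when $g \ge n_{reference}$.
* Canonical correlations clipped below 1 by $10^{-8}$; p-values floored
  at the smallest positive double.
* The PSD flag tolerates eigenvalues down to $-10^{-8}$; shrinkage
  targets $+10^{-8}$.
* MAF ties in pruning remove the later-positioned SNP; duplicate SNP
  ids keep the first occurrence; both choices exist purely for
  determinism and auditability.
* Degenerate inputs fail loudly: empty SNP intersections, constant
  dosage columns, non-positive SEs, heritability above 1 in the
  generator, zero-member genes (skipped and logged).

## Validation experiments

Two built-in experiments double as the package's empirical validation
(sizes chosen to characterize the method well at desk scale):

* `null_calibration()` — 2,000 null SNPs, 3 traits, cohorts of 2,000:
  SNP-scan p-values are checked for uniformity (Kolmogorov-Smirnov) and
  5%-level type-I error.
* `recovery_study()` — 60 genes of 5 SNPs, three of them carrying a
  0.05 standardized effect on three of five traits, cohorts of 5,000,
  20 replicates: sensitivity and false-discovery proportion of the
  final selected gene set at the run's own Bonferroni threshold.

The central correctness oracle is exact equivalence: when the three
covariance blocks are the sample moments of one individual-level
dataset, `cca_from_cov` must reproduce textbook individual-level CCA
(`oracle_cca`, an independent code path through `stats::cancor`) to
numerical precision. The test suite checks this across random
dimensions, along with scale invariance, monotonicity of $r$ in
$\Sigma_{XY}$, shrinkage's closed-form iteration count, and brute-force
verification of the pruning contract.

## A worked refinement replay

The package bundles the result tables of a published seven-disease
autoimmune pleiotropy screen (67 genes, multivariate p-values, seven
per-disease gene-based p-values floored at $10^{-6}$, and a curated
confirmed/novel annotation). Replaying the intersection filter on those
printed values reproduces that screen's headline counts:

```{r replay}
scr <- published_screen()
cfg <- refine_config(alpha = 0.05, m_snps = scr$m_snps, m_genes = scr$m_genes,
                     gene_p_threshold = 1e-6)
calls <- refine_pleiotropic(scr$pvalues[, c("gene", "metacca_p")],
                            scr$pvalues[, !"metacca_p"], cfg,
                            novelty_map = scr$novelty_map)
attr(calls, "counts")
calls[calls$multi_disease & calls$novelty == "confirmed", "gene"]
```

67 selected genes, 17 of them associated with more than one disease,
27 confirmed / 40 novel, and 6 genes both confirmed and multi-disease.

## Limitations

* Single-ancestry design: one reference panel, no multi-ancestry LD
  mixing, no frequency-based strand resolution.
* $\hat\Sigma_{YY}$ from betas assumes the null dominates genome-wide;
  strongly polygenic trait sets with massive shared signal would bias
  it.
* No correction for overlapping controls between cohorts.
* Canonical weights/loadings are not exposed for interpretation — the
  package tests association, it does not decompose it.
* Gene-based tests use a 0 kb window around gene bounds; regulatory
  variants outside the gene body are invisible to the gene-level
  scans.
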