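---
title: "Models and methods: robust polygenic scores from summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: robust polygenic scores from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

GWAS summary statistics — a per-allele marginal effect $\hat\gamma_j$, its
standard error, a sample size, and sometimes an allele frequency and an
imputation INFO score, for each of hundreds of thousands of variants — are
the raw material of polygenic scores (PGS).  They are also uneven: the
per-variant sample size $n_j$ can be far below the advertised total after
meta-analysis, effect sizes computed on imputed dosages are distorted
relative to true genotypes, alleles can be inverted, and the linkage
disequilibrium (LD) reference panel used downstream rarely comes from the
GWAS sample itself.  Bayesian and iterative PGS methods, which pass
residuals through the LD matrix thousands of times, can amplify such
inconsistencies into outright divergence.

`robpgs` provides (i) tools to *detect* these misspecifications from the
summary statistics themselves, (ii) *corrections* for them, and (iii) PGS
solvers with explicit robustness controls.  Everything is testable offline
because the package ships a generator for complete synthetic studies.

# The standard-deviation identity

Almost everything rests on one identity relating a variant's genotype
standard deviation to its summary statistics.  For a quantitative trait
analysed by linear regression,

$$\operatorname{sd}(G_j) \;\approx\; \frac{\operatorname{sd}(y)}
  {\sqrt{n_j\,\operatorname{se}(\hat\gamma_j)^2 + \hat\gamma_j^2}},$$

and for a binary trait analysed by logistic regression the same expression
holds with $\operatorname{sd}(y)$ replaced by 2 and $n_j$ by the effective
sample size $n^{\mathrm{eff}}_j = 4/(1/n_{\mathrm{cases}} +
1/n_{\mathrm{controls}})$ (`sd_from_sumstats()`).  Three consequences:

* **Scaled effects.**  $\hat\beta_j = \hat\gamma_j / \sqrt{n_j
  \operatorname{se}_j^2 + \hat\gamma_j^2}$ is the marginal correlation
  ($Z/\sqrt{n+Z^2}$); all solvers work on this scale
  (`scaled_effects()`, inverse `per_allele_effects()`).
* **Sample-size imputation.**  Solving for $n_j$, with
  $\operatorname{var}(G_j) = 2 f_j (1-f_j)\,\mathrm{INFO}_j$ from the
  reported frequencies, recovers missing per-variant sample sizes
  (`impute_n()`); estimates are clamped to $[0.5N, 1.1N]$ by default with a
  flag so QC may remove rather than clamp.  $\operatorname{var}(y)$ is
  estimated as the first percentile of $0.5(N\operatorname{se}_j^2 +
  \hat\gamma_j^2)$ — an upper envelope whose lower tail approximates the
  minimum while staying robust to outliers (`estimate_var_y()`; percentiles
  use linear interpolation between order statistics throughout).
* **QC.**  Comparing the identity-based sd (`sd_ss`) with the
  frequency-based sd (`sd_af`), after dividing `sd_ss` by
  $\sqrt{\mathrm{INFO}}$ when INFO is available, exposes overestimated
  sample sizes, uncorrected dosage effects, and frequency errors
  (`qc_sd_filter()`, `qc_plot_data()`).  The outlier rule constants
  (ratio 0.5, difference 0.1, floors 0.1 and 0.05) are inherited
  configuration, not model.

INFO-based corrections are exponent triples applied as $\hat\gamma \cdot
\mathrm{INFO}^{a_\gamma}$, $\operatorname{se}\cdot\mathrm{INFO}^{a_{se}}$,
$n\cdot\mathrm{INFO}^{a_n}$: `sqrt_info` $=(\tfrac12,\tfrac12,0)$ (preserves
$Z$ and hence the fit; equivalent to post-processing the PGS weights),
`info` $=(1,0,1)$ (the multiple-imputation relation), and `in_between`
$=(1,\tfrac12,1)$.  The triples are configuration entries
(`info_correction()`) so they can be revised without code changes.

# The LD reference

`build_ld()` computes a windowed sparse correlation matrix: variants
further apart than 3 cM (default) are assumed uncorrelated and their
entries are exact zeros.  Genetic distance defines the window; when no map
exists, 1 cM = 1 Mbp.  Operations on the reference:

* `split_blocks()` — an exact dynamic program over contiguous split points
  minimizing $w\,C_2 + C_1$, where $C_1$ is the sum of squared
  correlations outside blocks and $C_2$ the sum of squared block sizes
  ($w = 5$ by default, configurable; both components are always reported
  because their scales differ by orders of magnitude and users may want to
  re-weight — with smooth LD, $w=5$ equalizes sizes rather than cutting at
  recombination breaks, so the benchmark uses $w = 0.002$ with a block
  count range).  `max_r2` bounds the largest squared correlation allowed
  outside blocks; boundaries crossed by a stronger pair are forbidden,
  which also prunes the search.  Infeasible settings return a flagged
  result with the binding pair.
* `apply_blocks()` — zeroes cross-block entries, preventing small solver
  errors from propagating genome-wide.
* `shrink_offdiag()` — replaces $R$ by $cR + (1-c)I$, raising the minimum
  eigenvalue by $(1-c)(1-\lambda_{\min})$.
* On disk, the matrix uses a compact run-length column format (`.sfbm`):
  per column only the first stored row index and the contiguous values up
  to the last non-zero, plus a trailing offset table for random access;
  about twice as compact as index–value pairs on run-dominated columns.
  Interior zeros are stored explicitly, keeping the format simple.

# The solvers

**lassosum2** (`fit_lassosum2()`) solves the summary-statistics elastic
net by cyclic coordinate descent with soft-thresholding,

$$\beta_j \leftarrow \frac{\operatorname{soft}\!\big(\hat\beta_j -
  (R\beta)_j + \beta_j,\; \lambda q_j\big)}{1 + \delta q_j},$$

with per-variant penalty factors $q_j = \max_k(n_k)/n_j$ so variants with
smaller GWAS samples are penalized more.  The rotated residual $R\beta$ is
cached and updated incrementally, touching only stored LD neighbors of a
changed coordinate, with an active-set cycle (full passes certify
convergence).  The grid is 30 $\lambda$ values log-spaced in
$[\lambda_0/100, \lambda_0]$, $\lambda_0 = \max_j|\hat\beta_j|$ (at which
the solution is exactly zero), crossed with $\delta \in \{0.001, 0.01,
0.1, 1\}$; warm starts run along decreasing $\lambda$.  Convergence: the
maximum absolute coefficient change below $10^{-5}\lambda_0$, at most 500
sweeps (both configurable); fixed ascending sweep order; a divergence
guard flags fits whose coefficients pass 5 (scaled effects are
correlations, so this is far outside the valid region) instead of
raising.

**LDpred2-style spike-and-slab** (`gibbs_fit()`).  The model:
$\hat\beta \mid \beta \sim N(R\beta, R/n)$ with
$\beta_j \sim p\,N(0, h^2/(Mp)) + (1-p)\,\delta_0$.  Grid mode fixes
$(p, h^2)$; `grid_search()` tunes them on validation data with ties broken
toward more regularization.  The heritability grid is anchored on the LD
score regression estimate (`ldsc_h2()`, two-step weighted least squares of
$\chi^2$ on $\ell_j n_j / M$ with a block jackknife):
$\{0.3,0.7,1,1.4\}\cdot\hat h^2_{\mathrm{LDSC}}$ normally, and the larger
$\{0.01,0.1,0.3,0.7,1,1.4\}$ set ("low-h2") under strong
misspecification, where extra shrinkage is exactly what rescues the
sampler.  Auto mode estimates $p \sim \mathrm{Beta}(1+M_c, 1+M-M_c)$ and
$h^2 \leftarrow \beta^\top R\beta$ each sweep, with 10 chains whose
initial $p$ are log-spaced in $[10^{-4}, 0.2]$.  Two robustness
parameters: `shrink_corr` multiplies off-diagonal LD inside the sampler
only (0.9 for simulated data, 0.95 for real data in the `rob` presets; the
$h^2$ update keeps the unshrunk $R$, since the shrink is a sampler
regularization, not a model change), and `allow_jump_sign = FALSE` zeroes
a draw whose sign conflicts with the current non-zero effect, forcing
effects through zero before changing sign.  Divergence heuristics (pinned
here; the original implementation does not document its own): flag when
the $h^2$ trace exceeds 1.5 or the causal fraction stays above 0.95 for
more than 50 consecutive sweeps; abort only on numerical overflow.
Burn-in 100 / 400 kept sweeps by default.  On exactly null input the
$h^2 \leftarrow \beta^\top R\beta$ update is allowed to reach 0, making
the all-zero state absorbing — without this, the $p$ update's Beta prior
drifts the chain toward $p = 1/2$ on data containing no signal.
`fit_inf()` is the $p=1$ closed form $(R + \tfrac{M}{nh^2}I)^{-1}\hat\beta$,
solved per LD block.

# The synthetic-data generator

`simulate_genotypes()` builds a mosaic-of-founder-haplotypes panel: each
haplotype copies founder segments with recombination breakpoints at rate
`ld_decay` per cM, so LD decays as $e^{-\lambda d}$ times the founder-pool
allele correlation (pairwise $r^2$ of order $1/K$ for $K$ founders).  The
genetic map includes recombination hotspots (a ~1 cM jump every ~2 cM by
default), giving the blocky LD of real genomes and making independent-block
splitting meaningful.  Founder alleles are drawn with rejection so
empirical MAFs stay in range and no column is monomorphic.  Genotypes are
exact 0/1/2 values in Hardy–Weinberg proportions.

`simulate_dosages()` uses the linear conditional-expectation construction
$D_j = 2f_j + \mathrm{INFO}_j (G_j - 2f_j + \varepsilon_j)$, which makes
$\operatorname{var}(D) = \mathrm{INFO}\cdot\operatorname{var}(G)$ and
$\operatorname{cov}(D, G) = \operatorname{var}(D)$ exactly.  Clipping to
$[0,2]$ (the default) erodes several percent of the variance because the
Gaussian noise places mass outside the box at boundary genotypes; the
stored INFO is therefore always *recomputed post-clipping* (MACH form,
$\operatorname{var}(D)/(2\hat f(1-\hat f))$) and is the value the pipeline
uses; `clip = FALSE` preserves the exact identities for verification.
`hard_call_dosages()` resolves each dosage to an adjacent integer with the
correct expectation — the synthetic counterpart of reading imputed data as
sampled hard calls; integer dosages round-trip exactly.

`simulate_phenotype()` draws causal effects $N(0, h^2/n_{\mathrm{causal}})$
on the scaled-genotype scale and rescales (and orthogonalizes) the noise so
the in-sample heritability is exact; a flag disables rescaling.
`run_gwas_linear()` regresses the phenotype on each variant over an
independent seeded subsample of the stated fraction, emulating
meta-analyses where cohorts cover different variants.
`run_gwas_multiple_imputation()` pools hard-call GWAS runs by Rubin's
rules.

`build_scenario()` assembles the three study designs: per-variant sample
sizes at fractions (1.0, 0.8, 0.6) in proportions (1/2, 1/4, 1/4);
dosage-based GWAS with heterogeneous INFO (uniform 0.3–1), the phenotype
defined on hard calls and the LD reference on true genotypes; and a
drifted-founder LD panel (allele flip probability 0.01, calibrated so
cross-panel allele-frequency correlation is about 0.99).

## Desk scale, and what it does and does not show

The default conditions are 2,500 variants, a 10,000 / 2,000 / 3,000
train/validation/test split, $h^2 = 0.2$ with 125 causal variants (5%
polygenicity), founder pool 8, 0.03 cM mean spacing — sizes chosen so a
ten-seed benchmark of every method completes in minutes on one core.
Parameter-recovery checks use larger single runs (4,000 variants with
$n = 20{,}000$ for the auto sampler; the LD score regression slope, whose
per-simulation spread at this scale is dominated by where the random
causal set happens to fall relative to the LD clusters, is assessed on
its mean over twelve 8,000-variant simulations).  The
generator reproduces the qualitative regime of biobank-scale analyses:
blocky LD vanishing beyond the 3 cM window, the auto sampler's causal
fraction drifting to 1 under sample-size misspecification (making it
behave as an infinitesimal model) and its rescue by the robust preset, the
low-h2 grid recovering what the plain grid loses, and lassosum2's relative
insensitivity to per-variant sample sizes.

Two features of real data are *not* reproduced at this scale.  First, real
chromosome-wide panels have LD scores of order 100, so marginal effects
are dominated by LD cross-terms; at desk scale (mean LD score ~5) the
direct causal term dominates instead.  INFO corrections, whose benefit
lives in the cross-term regime, therefore show only marginal effects here
— in particular the `sqrt_info` correction, which provably leaves the
model fit unchanged (it preserves $Z$ and $n$) and acts only through the
final weight conversion, moves test $r^2$ by amounts comparable to Monte
Carlo noise.  Second, absolute $r^2$ values depend on the real genotype
panel and are not comparable to published figures; only directions and
orderings are.  Passing benchmark tests therefore demonstrate the
machinery and the direction of each effect, not effect sizes on real
data.

# Numerical choices and degenerate inputs

Monomorphic variants keep only their diagonal LD entry and are flagged;
zero-variance variants in a GWAS subsample yield missing statistics rather
than dropping rows; operations generally emit aligned vectors with flags
and never silently remove variants.  The percentile convention (linear
interpolation), the 1-based inclusive coordinate convention, the
(chr, pos) join key with allele reconciliation (rsIDs drift across
builds), strand-ambiguous palindromic variants removed by default, and the
`.sfbm` empty-column record $(i_0 = 0, L = 0)$ are all pinned and tested.
Fixed seeds give byte-identical scenarios and sampler traces (all
randomness flows through R's RNG, single-threaded).

# Known limitations

The generator produces quantitative traits only; binary-trait formulas are
implemented and tested analytically on the effective-sample-size scale.
There is no BGEN/VCF ingestion — panels come from the simulator or the
simple binary container.  LDSC standard errors use a plain block
jackknife; the intercept is well calibrated only in simulations.  The
lassosum2 path does not implement the original `s`-parameterization or
pseudo-validation, which the reimplementation deliberately drops.
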