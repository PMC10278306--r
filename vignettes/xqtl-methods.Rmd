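---
title: "Methods: X-chromosome heritability partitioning and QTL mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: X-chromosome heritability partitioning and QTL mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

The X chromosome is routinely dropped from genetic analyses of complex
traits because of male hemizygosity and dosage compensation. In all-female
cohorts — such as the dairy-cattle populations this package is modeled on —
neither complication applies: every animal carries two active-by-assumption
X copies and X-linked variants can be analyzed with the same machinery as
autosomal ones. `xqtl` implements that analysis end to end:

1. partition phenotypic variance into autosomal, X-linked, and residual
   components by two-variance-component REML on genomic relationship
   matrices (GRMs);
2. scan imputed X-chromosome allele dosages for trait associations with a
   mixed linear model controlling for autosomal relatedness;
3. combine per-population scans by fixed-effects inverse-variance
   meta-analysis;
4. delineate QTL regions with an iterative LD-peeling procedure built on a
   conditional Wald statistic.

Because breeding-company genotypes and phenotypes are proprietary, the
package ships a founder-mosaic population simulator that reproduces the
features the methods depend on — within-population LD, elevated X-linked
LD, a controllable autosomal/X variance split, planted major QTL — so every
stage is testable without any external data.

## Data model

Genotypes are ALT-allele dosages in [0, 2] (the expected ALT count from
imputation), held in a `dosage_matrix` with per-variant metadata
(chromosome, 1-based bp position, alleles, MAF, imputation R²) and
per-sample metadata (population, sex, optionally sire). MAF is always the
folded ALT frequency `min(p, 1-p)` with `p = mean(dosage)/2`, recomputed
from the analyzed cohort. Missing dosages are rejected at read time rather
than imputed: the intended inputs are fully imputed files, and silent
imputation inside an analysis package hides data problems.

Phenotypes are *yield deviations*: performances already adjusted for
environmental effects by a national evaluation system and averaged per cow.
They are modeled with an intercept as the only fixed effect.

Two QC stages mirror the chip-plus-imputation workflow. The chip stage
keeps variants with folded MAF strictly above 1% and Hardy-Weinberg
chi-square P above 1e-4; genotypes are hard-called (rounded) only here,
because the test concerns array calls. The sequence stage keeps variants
with MAF at least 0.005 and imputation R² at least 0.20; dosages are never
rounded.

## Genomic relationship matrices

The GRM over a SNP subset is the VanRaden estimator

$$G_{jk} = \frac{1}{m}\sum_i \frac{(x_{ij}-2p_i)(x_{ik}-2p_i)}{2p_i(1-p_i)},$$

with allele frequencies taken from the analyzed cohort. The same estimator
is used on the diagonal, so `G = ZZ'/m` for standardized `Z` and the matrix
is positive semi-definite by construction; the difference from the
alternative diagonal estimator used by some software is O(1/m) and
irrelevant at the SNP counts involved. Monomorphic SNPs are a hard error
(the scaling divides by `p(1-p)`); filtering is the QC stage's job, and
silently dropping SNPs inside the GRM would desynchronize `n_snps`
bookkeeping. Because all analyzed animals are female, X-linked SNPs enter
exactly like autosomal ones — no dosage-compensation coding.

## Two-component REML

The partition model is

$$y = 1\mu + g_A + g_X + e,\qquad
g_A \sim N(0, G_A\sigma^2_A),\quad
g_X \sim N(0, G_X\sigma^2_X),\quad
e \sim N(0, I\sigma^2_e),$$

fitted by average-information (AI) REML. Derived quantities are
$h^2 = (\sigma^2_A+\sigma^2_X)/(\sigma^2_A+\sigma^2_X+\sigma^2_e)$ and its
components $h^2_{AUT}$ and $h^2_X$; $h^2 = h^2_{AUT} + h^2_X$ holds exactly
by construction. Standard errors of the ratios come from the delta method
on the inverse AI matrix.

Numerical choices, all of which matter in practice:

* **Starting values.** Default is a Haseman–Elston regression of centered
  phenotype cross-products on the corresponding GRM entries — a cheap
  method-of-moments estimate that lands near the optimum and roughly halves
  the iteration count at n = 2000. A neutral equal-thirds start is
  available (`init = "equal"`); both reach the same optimum, and the choice
  affects runtime only.
* **Updates.** One Cholesky of the dense n x n covariance per iteration;
  AI steps with per-component clamping of negative proposals to
  `1e-8 * var(y)`; EM fallback when the AI system is singular or an AI step
  decreases the restricted likelihood (the EM update never does). A
  component clamped on three consecutive iterations *with an outward
  gradient* is fixed at the zero boundary; the gradient condition matters
  because early AI overshoots would otherwise pin genuinely positive
  components at zero.
* **Convergence.** `|change in logL| < 1e-6` and maximum parameter change
  below `1e-8` of the phenotypic variance, within 200 iterations.
* **Identifiability.** With proportional GRMs (e.g. both identity) the
  autosomal/X split is not identifiable; the AI matrix is then numerically
  singular and the fit is flagged non-converged instead of returning an
  arbitrary split.

Dense algebra restricts the fitter to desk-scale cohorts (a few thousand
samples), which matches the simulation study sizes below.

## Mixed-model association scan

Each X-linked variant is tested under $y = 1\mu + xb + g_A + e$ with
$g_A \sim N(0, G_A\sigma^2_A)$ estimated from **autosomal** SNPs only —
leave-one-chromosome-out by construction, which `run_scan` enforces by
refusing GRMs whose SNP set intersects the scanned variants. The variance
components are fitted once under the no-marker null (single-GRM REML via
one eigendecomposition and a 1-D profile-likelihood search), then each
variant's `b` and `se` come from generalized least squares in the rotated
space with the covariance fixed at the null estimates — the EMMAX-style
approximation, the same class of approximation used by the standard
MLM-association tools. P-values are two-sided normal on `b/se`; cohorts
here number in the hundreds to thousands, where the normal and t references
are indistinguishable at the precision that matters, and the package's own
test oracles use the same convention.

Two behaviors worth knowing: variants with zero dosage variance are skipped
with a warning rather than emitting NaN rows, and samples missing the
phenotype are silently intersected (with a logged count), mirroring
per-trait cohort variation in real data.

Mixed-model scans shrink the signal of variants whose dosage distribution
aligns with the relatedness structure in the GRM. On the simulated X — where
paternal half-sib daughters share an intact X — this shrinkage is visible
(roughly 10–25% of the Wald statistic at the default family structure), and
planted-QTL effect sizes in the package's studies are chosen with it in
mind. Conversely, calibration studies of the null distribution use an
unstructured cohort (many sires, large founder pool, dense map), because a
structured null cohort makes the scan conservative rather than
miscalibrated in an interesting way.

## Meta-analysis

Per-variant effects are combined across populations under the fixed-effects
assumption with inverse-variance weights ($w_i = 1/se_i^2$,
$b = \sum w_i b_i / \sum w_i$, $se = (\sum w_i)^{-1/2}$), the METAL
"STDERR" scheme. The source description of the method mentions both
error-variance and sample-size weighting; the two coincide only under equal
per-study residual variances and allele frequencies, and the error-variance
scheme is the one consistent with "weighting them by the inverse of their
error variance", so it is the default. A sample-size-weighted z-score
scheme is provided behind `scheme = "samplesize"` for comparison; it yields
no pooled effect estimate.

Variants are matched across studies by (chromosome, position, allele pair);
REF/ALT swaps are flipped, irreconcilable allele pairs are dropped with a
warning, and variants absent from some studies are combined over the
studies that carry them, with `?` in the direction string.

## QTL peeling

Scans are turned into QTL regions by iterating six steps on the working set
of a chromosome: (1) the most significant variant at or above the threshold
(default 7.3 = -log10 of 0.05 Bonferroni-corrected for ~1 million tests)
becomes the lead; (2) a 20-Mb window is centered on it; (3) signed Pearson
correlations `r` between the lead's and each window variant's dosages are
computed in the scan cohort; (4) window variants with `|r| >= 0.7` form the
QTL's confidence interval; (5) window variants outside the interval are
tested with the conditional statistic `T_new = (b_i - b_lead * r) / se_i`;
those whose `-log10(p_new)` drops below the threshold *and* whose `T_new`
keeps the sign of the marginal `T_i` are declared explained by the lead;
(6) interval members and explained variants leave the working set, and the
procedure repeats until nothing reaches the threshold.

Decisions taken where the procedure's description is ambiguous:

* The step-5 condition is read as `-log10(p_new) < 7.3` — a significance
  statement; a literal `log10(p_new) < 7.3` is vacuously true for any
  p-value.
* `p_new` uses the standard normal, consistent with the scan's Wald test.
* `r` keeps its sign (the conditional statistic needs it) and is computed
  from unstandardized dosages of the scan cohort itself.
* Ties on the lead's significance break by smallest position, then
  lexicographic id, making the procedure deterministic.
* Interval bounds are the min/max positions of member variants, so interval
  length reflects actual LD extent rather than a fixed width.
* Windows are clipped at the data extent; removals outside the window never
  happen, even though long-range LD can in principle extend past 10 Mb
  (a known caveat of the window size on the X).

Termination is guaranteed because each iteration removes at least the lead
(its self-correlation is 1). An optional trace file logs every removal with
its `r`, `T_new` and `p_new` for audit.

## LD decay

`pairwise_r2` computes squared dosage correlations for all intra-chromosome
pairs up to a maximum distance (default 10 Mb) after excluding variants
with MAF < 0.01; `bin_decay` averages them in half-open distance bins. The
default bins are 0–10 kb followed by log-spaced edges, a conventional
layout when the original binning is unspecified; they are fully
configurable. An optional one-daughter-per-sire subsampling (used to avoid
stacking identical paternal X haplotypes) activates when sire metadata is
present and says so when it is not.

## The simulator

LD is produced by **founder-mosaic copying**: each population has a pool of
`n_founder_haplotypes` founder haplotypes (drawn around ancestral allele
frequencies shared across populations, so variants segregate everywhere at
different frequencies), and every transmitted haplotype is a mosaic of pool
members with a per-bp donor-switch probability (`recomb_rate_female`,
default 2e-7, giving LD decay over a few Mb as in within-breed cattle
data). This is deliberately not a coalescent: it is fast, exactly seedable,
and gives tunable LD, which is what the downstream methods need; it does
not model demography, mutation, or selection.

The X chromosome differs from the autosome in two a-priori ways:

* each daughter's **paternal X is her sire's single X copied intact** (no
  recombination in males), and a small sire pool (default 25 per
  population) makes paternal half-sib groups share whole X haplotypes;
* the **X founder pool is 3/4 of the autosomal pool**, reflecting the X's
  reduced effective population size (three X copies per four autosomal
  copies).

Together these elevate X-linked LD above autosomal LD at matched distances,
the qualitative property the LD module is tested against. Founder pools are
conditioned on segregation per variant (variants are ascertained as
polymorphic, as on a genotyping chip).

Phenotypes are built on per-population standardized dosages: every variant
receives an independent Gaussian effect scaled so the expected variance
fractions equal `target_h2_aut` and `target_h2_x`; planted major QTL are
specified in phenotype standard deviations per standard deviation of dosage
(so the expected marginal association z-statistic is about
`effect * sqrt(n)` before mixed-model shrinkage) and are counted inside the
corresponding genetic component of the recorded truth. Residuals top the
variance up to 1. The Gaussian effect-size choice is a modeling
convenience — real trait architectures are unknown — and only the variance
scaling, not the effect-size shape, is relied on by the tests.

All randomness flows from one integer seed through R's default generator;
identical seeds give byte-identical cohorts.

## Study sizes and what the tests show

The packaged simulation studies use sizes chosen to make Monte-Carlo error
small relative to what they assert on a single CPU:

* REML recovery: 100 replicates at n = 2000 (600 autosomal + 300 X SNPs),
  true split 0.30/0.02; the replicate means must sit within two Monte-Carlo
  standard errors of the realized truth.
* Scan calibration: four independent unstructured null cohorts of n = 800
  with 20,000 tested X variants each; per-cohort p < 0.05 fractions and the
  replicate-averaged inflation factor are checked, because a single
  median-based lambda over 20,000 tests has Monte-Carlo sd ~0.017 — wider
  than the ±0.03 band being verified.
* QTL peeling: three planted X QTL 40 Mb apart at n = 2000, sized for
  realized -log10(P) near 15; the caller must return exactly three regions,
  each containing its causal variant, and match an independently written
  naive implementation of the six steps.
* Meta-analysis gain: a shared X QTL sized for per-population
  -log10(P) ≈ 5 across three cohorts of n = 1200 — individually
  sub-threshold most of the time, decisively significant when combined.
* LD contrast: 20 seeds at n = 250; the X must beat the autosome in at
  least 80% of matched distance bins.

Passing these shows the estimators are unbiased, calibrated, and internally
consistent *under the simulator's assumptions*: fully imputed dosages, a
polygenic Gaussian architecture matching the GRM model, and LD generated by
founder mosaics. It does not certify behavior under model misspecification
that real data bring — non-Gaussian effect distributions, imputation error
correlated with MAF, cryptic relatedness beyond the simulated families, or
selection-induced LD — and the published analyses' own cohort sizes (up to
~80,000 cows) are far beyond the dense-REML scale used here.

## Known limitations

* The REML fitter is dense-matrix only; tens of thousands of samples need
  factored or randomized algorithms that are out of scope.
* The scan's normal reference is inappropriate below roughly n = 100.
* The meta-analysis implements no heterogeneity statistics or
  random-effects model; the fixed-effects assumption is taken as given.
* The QTL caller conditions on one lead at a time (no joint multi-SNP
  refitting), and windows are hard-limited to 20 Mb.
* One printed reference row set (the Holstein column of the breed x trait
  heritability table) is internally inconsistent by up to 0.004 between
  `h2` and `h2_aut + h2_x`; the fixture reproduces the table as printed and
  the consistency test documents the discrepancy rather than hiding it.
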