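---
title: "Mapping direct and social genetic effects: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping direct and social genetic effects: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sgegwas)
```

# The problem

In group-housed livestock, an animal's phenotype depends not only on its
own genotype but on the genotypes of its pen mates: a pig that crowds the
feeder changes the feed intake and growth of every other pig in the pen.
The heritable component of that influence is the *social* (indirect)
genetic effect, SGE, as opposed to the *direct* genetic effect, DGE, of
an animal's own genotype. `sgegwas` implements a two-layer analysis for
traits of this kind — feed intake, growth, feeding behaviour — in cohorts
housed in pens:

1. **Quantitative-genetic layer.** A social genetic effects mixed model
   partitions phenotypic variance into direct genetic, social genetic,
   litter, pen and residual components, and yields per-animal EBVs for
   both genetic effects, which are deregressed into pseudo-phenotypes.
2. **Association layer.** Each deregressed response is scanned with a
   unified mixed linear model against single SNPs and against
   multi-allelic haplotype loci built from Gabriel-style LD blocks, with
   Bonferroni thresholds, genomic-control diagnostics and 1-Mb
   QTL-region reporting.

# The social genetic effects model

Layer one fits, by restricted maximum likelihood,

$$y = Xb + Z_D a_D + Z_S a_S + Wl + Vg + e$$

where `y` holds one record per animal; `b` the fixed effects (sex, test
year-month, birth year-month); `a_D` and `a_S` the direct and social
breeding values with
$\mathrm{Var}([a_D; a_S]) = C \otimes K$, `C` the 2x2 genetic
(co)variance matrix and `K` a relationship matrix; `l` and `g` litter
and pen effects; `e` the residual. `Z_S` carries a 1 in the column of
every pen mate of a record's animal and 0 on the diagonal, so each row
sums to pen size minus one. Pen-mate social contributions are unweighted
(no dilution by pen size), following the classical formulation for
fixed-size pens.

Estimation uses average-information (AI) REML with standard safeguards:
step-halving when an AI step leaves the parameter space or would lower
the restricted likelihood, an EM-REML fallback step (guaranteed uphill
for variances), a variance floor of `1e-10 * var(y)`, projection of `C`
back onto the PSD cone, and an active-set rule that freezes variances
stuck at the floor with downhill gradients. Accepted iterations never
decrease the restricted likelihood. Convergence is declared when the
largest relative parameter change drops below `1e-8` (near-zero
parameters measured against `0.001 * var(y)`) or the likelihood stops
moving; the cap is 200 iterations, and a fit that hits the cap is
returned with `converged = FALSE` rather than an error.

Open design points and the choices made:

* **Genetic covariance.** The printed model form does not state whether
  the direct-social covariance is estimated. The classical social model
  includes it, so it is estimated by default; `fix_cov_zero = TRUE`
  constrains it to zero.
* **Relationship matrix.** `K` is an argument: the pipeline passes a
  genomic matrix from the analysis markers, but a pedigree numerator
  matrix is equally valid. Non-PSD inputs are bent by eigenvalue
  clipping, with a message.
* **PEV and accuracy.** Prediction-error variances come from
  `diag(G_a - G_a Z' P Z G_a)`, algebraically the diagonal of the
  inverse MME coefficient matrix. Accuracy is
  $r = \sqrt{1 - \mathrm{PEV}/\sigma^2}$ with the *effect-specific*
  genetic variance in the denominator, clamped to 0 (and flagged) when
  PEV exceeds the variance.
* **Deregression.** $dEBV = g/r^2$; records with $r^2 < 0.01$ are marked
  unusable instead of producing exploding pseudo-phenotypes.

# Genomic relationship matrices

`grm_centered()` implements the centered cross-product GRM verbatim:
columns are mean-centered and the cross-product is divided by the marker
count `p`, with no per-marker variance scaling. This matches the printed
formula used by the association layer. A trace-normalised variant
(`method = "scaled"`, division by `sum(2pq)`) is available and is what
the simulator uses as generative covariance, because its mean diagonal
near 1 puts variance components on the familiar scale. Missing dosages
are mean-imputed per marker, the standard MLM-GWAS practice.

# The association scan

`fit_mlm_null()` profiles the model $y = Xm + Wa + e$,
$a \sim N(0, G\sigma_a^2)$, $e \sim N(0, I\sigma_e^2)$ on the ratio
$\delta = \sigma_e^2/\sigma_a^2$ in the eigenbasis of `G` (the spectral
trick that makes each of the thousands of per-marker fits a weighted
regression). $\delta$ is found by bounded 1-D search of the restricted
likelihood over $\log\delta \in [-10, 10]$. Negative GRM eigenvalues
(the centered GRM is rank-deficient by construction) are clipped at zero
and counted.

`wald_scan()` tests each marker by its Wald statistic
$\hat m^2/\mathrm{SE}^2$ referred to $F(1, n-k-1)$, with the residual
variance re-estimated per marker. The F reference (rather than the
asymptotic 1-df chi-square) is deliberate: it is what the widely used
mixed-model association software computes, and it makes the scan reduce
*exactly* to the ordinary regression t-test when the polygenic variance
vanishes — a property the test suite checks to 1e-10. Two modes are
offered: `p3d` (default) reuses the null $\delta$ for every marker;
`per-marker-reml` re-optimizes it with the marker in the model. On null
simulations their p-values rank-correlate above 0.99; `p3d` is hundreds
of times faster.

Thresholds are plain Bonferroni: genome-wide `0.05/N`, suggestive `1/N`,
with `N` the number of tests (markers, or retained haplotype alleles for
the haplotype scan); values are kept at full precision and displayed at
3 significant digits. The genomic inflation factor is the median of the
implied 1-df chi-square statistics over 0.4549364; the phrase "observed
over expected P values" is ambiguous between the median and regression
estimators, so the median is the default and the regression estimator
sits behind a flag.

# Haplotype blocks and the haplotype scan

Blocks follow the Gabriel confidence-interval recipe. For each marker
pair, D' is estimated (directly from phase, or by two-locus EM for
unphased input) and a 90% central confidence interval is read off the
normalized likelihood profile of D' on a 201-point grid — the approach
of the common Haploview/PLINK implementation. A pair is *strong LD* when
its CI lower bound reaches 0.8 (the printed strong-LD parameter) and its
upper bound 0.98; *strong recombination* when the upper bound falls
below 0.90. A span of two or more markers becomes a block when at least
95% of its informative pairs are strong, capped at 1000 kb; overlaps are
resolved longest-first with a leftmost tie-break so output is
deterministic. One source sentence mentions a confidence interval "of
r-squared"; Gabriel's method is defined on D' intervals and the printed
parameter is the strong-LD lower CI bound, so the D' formulation with
that bound is implemented, and this interpretation is recorded here.

Each block's distinct haplotype strings over its member SNPs become the
alleles of a multi-allelic pseudo-marker; an individual's allele dosage
is its count of matching phased haplotypes, so dosages sum to 2 per
individual per block. Alleles at frequency 0.01 or below are dropped
from testing (still counted in the frequency table), and each retained
allele is tested exactly like a biallelic marker. Phase must come from
the input (imputation output is phased); no phasing algorithm is
implemented.

# The synthetic cohort

The generator (`sim_config()`, `sim_genotypes()`,
`sim_effects_and_phenotypes()`, `sim_feeder_records()`) defines the desk
study conditions: 600 animals in pens of 10, 3,000 SNPs in 300 LD
blocks, and variance components (0.30, 0.03, 0, 0.05, 0.05, 0.57) for
direct, social, direct-social covariance, litter, pen and residual on a
unit-phenotypic-variance scale. The direct and social values are
plausible choices for feed-intake-type traits in pigs (direct
heritability near 0.3, social variance an order of magnitude smaller),
fixed once here. The
full-scale layout (1,204 animals, pens of 20, 36,969 chip markers) is
reachable by configuration; the desk defaults keep every stage runnable
in seconds to minutes.

Genotypes are LD-blocked: each block has a small founder haplotype pool
and every individual carries two whole-block founder copies, which
induces strong within-block and near-zero between-block LD. Individuals
are grouped into full-sib litters (two sire and two dam haplotypes per
litter and block, Mendelian sampling), so the genomic relationship
matrix has real between-family contrast — without it, GRM-based REML at
desk scale is barely identified. Pens are filled in random order so
litters spread across pens; the last incomplete pen is kept with its
size recorded, deliberately exercising unbalanced-group code.

True breeding values are the sum of a polygenic draw
$K^{1/2}z$ against the trace-normalised GRM and a sparse QTL layer,
rescaled so the realized sample variance hits the configured component
exactly — this keeps recovery tests tight at modest replicate counts.
Phenotypes then follow the generative social model exactly (each
animal's own direct effect plus the sum of its pen mates' social
effects), and the ground truth of every component is returned for
parameter-recovery testing.

What the generator does *not* emulate: genotyping error, imputation
uncertainty (a per-marker quality score can be attached but is not
generated), selection, multi-generation pedigrees, non-additive genetic
effects, and time trends in the feeder records. Passing tests therefore
demonstrate correctness of the estimators under the stated generative
model, not robustness to those real-data features.

Feeder records emulate electronic feeding stations: per-visit body
weights follow a linear gain trajectory plus noise and per-visit feed
and occupation times are drawn to reproduce each animal's totals
exactly, so the derived average daily feed intake and feeder time agree
with the generator's targets to numerical precision.

# Trait derivations

The eight socially affected traits are derived as in performance-test
practice: ADG is the OLS slope of visit body weight on day (all visits,
not endpoints); ADFI and TPD divide total feed intake and feeder time by
feed days; FS converts ADFI to g/min. FCR, D100, B100 and RFI use the
standardisation formulas with sex constants A = 50.775/46.415 and
B = -7.277/-9.440 (male/female). Two numerical choices: the average
metabolic weight returns its analytic limit $W_1^{0.6}$ at the boundary
$W_2 = W_1$ (continuity rather than NaN), and the RFI formula is
evaluated literally with a unit-convention switch (`rfi_units`), because
the regression coefficients in common use do not come with a stated
unit system — neither convention is asserted as canonical.

# Problem sizes and numerical tolerances

The shipped tests and the acceptance script use the desk-scale
conditions: REML parameter recovery on 20 replicates of the default
cohort (n = 600, pens of 10) plus 20 null-social replicates at n = 400;
scan calibration on 2,000 unlinked markers at n = 400; power floors on
20 replicates at n = 600; block-detection oracle checks on 6-SNP
panels; and end-to-end determinism on the default configuration run
twice. Key tolerances: GRM against the brute-force loop at 1e-12, the
OLS-limit identity at 1e-10, spectral-vs-dense likelihood at 1e-8, and
the single-random-effect REML optimum against a derivative-free oracle
at 1e-6.

# Known limitations

* Social and pen variance are weakly separable when pen sizes are
  constant — identification of the social variance rests on genomic
  covariance among pen mates, so estimates of `sigma2_S` at desk scale
  are noisy (the standing recovery study is correspondingly a
  median-level check). Estimating the direct-social covariance can sit on a
  likelihood ridge; `fix_cov_zero = TRUE` is the stable choice when the
  covariance is not of interest.
* Per-marker REML mode re-optimizes one ratio per marker and is
  intended for verification, not full scans.
* The haplotype layer requires phased input; unphased data can be
  block-detected (EM path) but not allele-coded.
* Sample-level QC (relatedness pruning, heterozygosity outliers) is out
  of scope; marker QC covers position/sex-chromosome, quality score,
  call rate, MAF and exact HWE filters only.
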