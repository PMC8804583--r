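---
title: "Pooled-DNA GWAS: models, quality control and replication statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled-DNA GWAS: models, quality control and replication statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolgwas)
```

## The design this package models

DNA pooling trades individual genotypes for throughput: equimolar DNA from
hundreds of subjects is hybridised to a single two-channel genotyping array,
and the relative fluorescence of the two allele-specific dyes (Cy3/Cy5)
estimates the pool's allele frequency at every SNP. A case-control scan then
contrasts case-pool and control-pool frequencies. `poolgwas` implements the
complete workflow of a two-batch high-myopia pooling study — case pools of
331 and 176 subjects against control pools of 145 and 149, three replicate
arrays per pool — from raw channel intensities through quality control,
a combined association statistic with empirical-null calibration and genomic
control, and the individual-genotyping statistics used in verification,
validation and replication stages.

## The measurement model

For a replicate array, the frequency of the Cy3-labelled allele is estimated
as the intensity fraction

$$\hat f = \frac{X_{raw}}{X_{raw} + Y_{raw}}.$$

Raw intensities are modelled as $x = I\,g\,f$ and $y = I\,(1-f)$ with $I$ a
per-probe intensity scale and $g$ the multiplicative Cy3/Cy5 gain imbalance.
The intensity fraction then has expectation

$$E[\hat f] = \frac{f\,g}{f\,g + 1 - f},$$

which exceeds $f$ whenever $g > 1$ — the systematic overestimation that
pooling studies observe when estimated frequencies are compared against
database frequencies. Channel normalisation
(`normalize_channels()`) removes the array-wide component of $g$ by
rescaling the x channel so the two channel medians match. This is only
well-posed because dye assignment is arbitrary per SNP: across a large
panel, the counted-allele frequency is symmetric around 0.5, so equal
channel medians is the correct null. The synthetic generator therefore
randomises the counted allele per SNP; a generator that made every counted
allele the minor one would make median matching itself inject a large
artificial gain.

## The synthetic world

`simulate_truth()`, `simulate_pool_intensities()` and
`simulate_genotypes()` generate data with exactly the structure the
analysis assumes:

* **Pool composition.** A pool of $N$ subjects realises its frequency as a
  $\mathrm{Binomial}(2N, f)/2N$ draw — no pipetting or unequal-contribution
  error, which the modelled study does not describe.
* **Replicate noise.** Each replicate array observes the pool frequency
  plus Gaussian noise with `sd_array` (default 0.015 on the frequency
  scale, clipped to $[0,1]$). The study does not report its replicate
  noise magnitude, so this default is a configuration value, not a claim:
  0.015 is in the range routinely reported for pooled two-channel arrays
  and small enough that binomial pool-composition variance dominates for
  pools of a few hundred subjects.
* **Channel gain.** Default `gain_ratio` 1.05, a modest imbalance that
  reproduces the documented overestimation before normalisation.
* **Bad arrays.** With probability `bad_array_rate` a replicate's
  frequencies are resampled and shuffled across SNPs, destroying the
  inter-replicate correlation the QC filter tests. The modelled study lost
  one chip in twelve arrays, hence `1/12` in end-to-end runs. Two
  independent binomial draws at the same frequencies would still correlate
  at $R > 0.97$ across SNPs (the correlation is carried by the spread of
  true frequencies), so decorrelation requires the shuffle.
* **Stratification.** `stratification_delta` shifts a fraction of SNPs in
  the case pools, inflating the genomic-control $\lambda$ without creating
  reproducible single-SNP signals.

What the generator does **not** emulate: probe cross-hybridisation, batch
chemistry differences, spatial artefacts, IDAT-level preprocessing, and
linkage disequilibrium between panel SNPs (each SNP is drawn
independently; LD enters only through the dedicated two-locus simulator).
A green pipeline test therefore establishes statistical correctness of the
estimators under the stated error model, not robustness to every array
pathology.

## The QC cascade

`pool_frequencies()` applies four filters in a fixed order, then averages
surviving replicate frequencies per pool:

1. **Replicate correlation** (`r_min = 0.99`). Pearson correlation of
   per-SNP frequency estimates between replicate arrays of the same pool.
   The rule as usually stated — drop arrays with mean pairwise $R$ below
   the cutoff — destroys whole pools when applied literally: with three
   replicates and one bad array, each good array's mean pairwise $R$ is
   dragged to roughly $(1 + 0)/2$. We therefore remove greedily: while any
   replicate falls below the cutoff, discard the worst one and recompute.
   One bad array in three then costs exactly one array.
2. **Low intensity** (lowest 5%). SNPs are ranked by total
   $X_{raw}+Y_{raw}$ over retained replicates; the bottom
   $\lfloor 0.05\,n\rfloor$ are removed, ties broken lexicographically by
   SNP id for reproducibility. The cut is applied after bad-array removal
   (the study does not state the order), so a discarded array cannot drag
   down a SNP's total.
3. **Replicate divergence** (span > 5%, strict). A SNP is removed when in
   any single pool its replicate estimates span more than the cutoff;
   per-pool evaluation is chosen because divergence is an array-quality
   symptom, and pooling replicates across pools would conflate it with
   real case-control differences.
4. **Control MAF** (< 1%, strict). The control-pool frequency is averaged
   across control pools, folded to $\min(\bar f, 1-\bar f)$.

Filters only ever remove; surviving values are never modified. The
correlation, divergence and MAF filters are idempotent; the percentile
filter is by construction not (it removes the bottom 5% of whatever it
receives), so "run the cascade once per panel" is part of the contract.

## The pooled association statistic

Per batch, each SNP's case/control frequency contrast is

$$z = \frac{\hat f_c - \hat f_k}
{\sqrt{\bar f(1-\bar f)\left(\frac{1}{2n_c} + \frac{1}{2n_k}\right)
 + V_c + V_k}},$$

binomial sampling variance at the pooled mean frequency plus each pool's
array-measurement variance $V$, taken as the squared standard error of the
replicate mean (replicate variance / replicate count). This follows the
pooled-GWAS literature's combined statistic; the exact published formula is
cited rather than printed in the study this package models, so the variance
model lives in one pluggable function (`pooled_z()`).

Because $V$ is estimated from as few as three replicates, the statistic's
finite-sample null scale is not exactly 1. The scale is estimated from the
data as the slope of the QQ line through the first and third quartiles,
$\hat\sigma = \mathrm{IQR}(z) / (2\,\Phi^{-1}(0.75))$ — robust to true
signals in the tails. Each batch is standardised by its own $\hat\sigma$
**before** combination (the alternative, estimating one scale after
combination, is recorded as an open design point; per-batch scaling is the
choice here because the two batches have different pool sizes and hence
different finite-sample behaviour). Batches are combined by a weighted
Stouffer sum with $w_i = \sqrt{n_{\mathrm{eff},i}}$, where
$n_{\mathrm{eff}} = 4/(1/n_c + 1/n_k)$ is the equal-group size with the
same two-proportion variance; for equal batches this reduces to the
unweighted sum.

Genomic control uses the median of $\chi^2$ statistics over a seeded
random subset (default 20,000 SNPs) divided by 0.4549, floored at 1.0
(standard practice; deflating below the theoretical null is never
helpful). On a 20,000-SNP null simulation at the modelled design, the
pipeline's type-I error at $\alpha = 0.05$ sits inside the 99% binomial
band — the acceptance suite recomputes this on every run.

## Replication statistics

The candidate-SNP stage mirrors standard case-control practice:

* call-rate filter (> 0.8, strict), allelic 1-df Pearson $\chi^2$ without
  continuity correction, and the Cochran–Armitage trend test with scores
  (0, 1, 2). The trend statistic is reported signed; its exact
  (permutation) p-value sits slightly above the asymptotic one on small
  panels because the statistic lives on an integer lattice — the test
  suite quantifies this against a permutation oracle.
* odds ratios with Woolf confidence intervals,
  $\exp(\ln \mathrm{OR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$, with the
  Haldane–Anscombe 0.5 correction when a cell is empty. Orientation is
  explicit: `orient = "case_enriched"` reports the $\geq 1$ OR of the
  allele over-represented in cases, the convention some published tables
  use; the default reports the tabulated risk allele. The shipped summary
  table (`hm_validation_summary()`) records per row which orientation
  reproduces the published value. One published row (rs600242) prints a
  frequency pair that is internally inconsistent with its printed OR and
  is excluded from the reproduction set; the acceptance test documents
  this.
* covariate-adjusted association by logistic regression
  (`status ~ genotype + sex + age`), fitted by IRLS with tolerance
  $10^{-8}$ and at most 50 iterations; separation or degeneracy is
  flagged, not raised.
* fixed-effect inverse-variance meta-analysis on the log-OR scale, with
  standard errors recovered from 95% CIs as
  $(\ln CI_{high} - \ln CI_{low})/(2 \times 1.96)$.
* analytic power of the allelic test from the noncentral $\chi^2_1$
  distribution at the case frequency implied by the odds model
  $f_{case} = OR\,f/(1-f+OR\,f)$. No default parameter set claims to
  reproduce any published power figure; all inputs are explicit.

## Two-locus LD and the haplotype EM

`em_haplotypes()` estimates the four haplotype frequencies from unphased
genotype counts: only double heterozygotes are phase-ambiguous, and the E
step splits them between cis (AB/ab) and trans (Ab/aB) in proportion to
the current frequency products. Initialisation is at linkage equilibrium,
tolerance $10^{-8}$ on frequencies, at most 1000 iterations;
the log-likelihood is nondecreasing and the test suite checks the optimum
against a brute-force simplex grid search. From the converged frequencies,
$D = f_{AB} - f_A f_B$, $r^2 = D^2/(f_A f_a f_B f_b)$, and
$D' = D/D_{max}$ with the sign-dependent $D_{max}$. Monomorphic loci are
flagged rather than producing division by zero. The two-locus simulator
inverts these formulas ($D = \sqrt{r^2 f_1(1-f_1)f_2(1-f_2)}$, positive
coupling) and refuses infeasible targets, reporting the feasible maximum
$r^2$ given the allele frequencies.

## ESE motif scanning

`scan_pwm()` scores every window of the forward strand as the sum of
position weights and reports windows at or above the threshold (2.383 by
convention for SC35-style server output); windows containing N are
skipped. `allele_contrast()` rescans the window span overlapping a
variant for both alleles and reports gained and lost sites — the analysis
that flags a risk allele creating an extra splicing-factor binding site.
The original server's SC35 matrix is not redistributable, so the package
ships a clearly labelled synthetic matrix for testing; published site
scores are not reproducible without the original matrix and genome
sequence, and the package does not pretend otherwise.

## qPCR

`relative_quantity()` implements the comparative-Ct method:
$\Delta Ct = Ct_{target} - Ct_{reference}$ per sample,
$RQ = 2^{-\Delta\Delta Ct}$ against a calibrator, with replicate wells
averaged on the Ct scale before differencing (amplification-efficiency
correction is out of scope).

## Numerical and scale choices

* All stochastic operations take explicit integer seeds; identical seeds
  give byte-identical outputs, and reports are rendered at fixed precision
  (frequencies 4 dp, ORs 2 dp, p-values 3 s.f. scientific) so runs are
  diffable.
* Thresholds (0.99, 5%, 5%, 1%, call rate 0.8, 20,000 genomic-control
  SNPs, $\alpha = 0.05$) are configuration, not constants, with the
  modelled study's values as defaults (`default_config()`, YAML or JSON).
* Genome-scale panels (~10^6 SNPs) are supported by the same code paths
  but the shipped tests and the acceptance script run at 20,000 SNPs to
  keep a single-CPU run under a minute; nothing in the statistics depends
  on panel size beyond Monte-Carlo resolution.

## Known limitations

Pools only — no individual-array genotype calling; no imputation or
mixed-model association; pairwise LD only (no block partitioning or
multi-locus phasing); no modelling of probe chemistry. The replication
module targets candidate panels (up to ~10^3 SNPs), not genome-wide
individual-level data.
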