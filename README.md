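# poolgwas

Statistical workflow for **pooled-DNA genome-wide association studies** of
case-control designs, modelled on a two-batch high-myopia study (case pools
of 331 and 176 subjects vs control pools of 145 and 149, three replicate
two-channel arrays per pool), plus the individual-genotyping statistics of
its verification, validation and replication stages.

In a pooling scan, equimolar DNA from many subjects is hybridised to one
array and a SNP's pooled allele frequency is estimated from the two
allele-specific dye channels as

    f̂ = X_raw / (X_raw + Y_raw)

Case and control pools are then contrasted per SNP with a combined
z statistic whose variance sums binomial pool-composition sampling and
array-measurement error,

    z = (f̂_case − f̂_control) /
        sqrt( f̄(1−f̄)(1/(2n_case) + 1/(2n_control)) + V_case + V_control )

standardised by the empirical null SD (the slope of the QQ line through the
first and third quartiles), combined across batches by a weighted Stouffer
sum, and corrected by genomic control (λ = median χ²/0.4549, floored at 1).

The package covers:

* **Synthetic data** — pooled intensities and individual genotypes with the
  statistical structure the analysis assumes: replicate noise, Cy3/Cy5 gain
  imbalance (and the overestimation bias f·g/(f·g+1−f) it causes), bad
  arrays, population stratification, configurable risk loci.
* **Pool QC** — channel-median normalisation and the four-stage cascade:
  replicate correlation (R ≥ 0.99), lowest-5% total intensity, >5%
  replicate divergence, control MAF < 1%.
* **Pooled association** — `run_discovery()`: per-batch z, empirical-null
  scaling, batch combination, genomic control, sorted p-values.
* **Replication statistics** — allelic χ², odds ratios with Woolf CIs
  (Haldane–Anscombe corrected, with explicit allele orientation),
  Cochran–Armitage trend test, covariate-adjusted logistic association,
  Bonferroni thresholds, fixed-effect inverse-variance meta-analysis,
  analytic power of the allelic test.
* **LD** — two-locus haplotype EM and D/D′/r² summaries.
* **ESE scanning** — position-weight-matrix motif scan and per-allele
  gain/loss contrast. **qPCR** — comparative-Ct (2^−ΔΔCt) quantification.

## Worked example

A 20,000-SNP pooled scan at the modelled design, with one risk locus
(OR 2.5 at control MAF 0.10) and one bad chip in twelve arrays:

```r
library(poolgwas)

truth  <- simulate_truth(20000, causal = data.frame(index = 1, or = 2.5), seed = 42)
truth$f_control[1] <- 0.10
truth$f_case[1]    <- case_frequency(0.10, 2.5)

design <- pool_design(bad_array_rate = 1/12)
panel  <- simulate_pool_intensities(truth, design, seed = 43)
freqs  <- pool_frequencies(panel)        # QC cascade + per-pool averaging
assoc  <- run_discovery(freqs, design, n_random = 20000, seed = 44)

attr(assoc, "lambda")
#> [1] 1.003527
attr(assoc, "null_sd")
#>   batch1   batch2
#> 1.020773 1.022599
head(assoc, 3)
#>      snp_id      z_b1      z_b2    z_comb        p_raw  chi2_gc         p_gc
#> 1 snp000001  5.319129  4.181911  6.752552 1.452672e-11 45.43669 1.576535e-11
#> 2 snp014062  4.477184  1.266539  4.181295 2.898531e-05 17.42178 2.993761e-05
#> 3 snp013194 -3.468690 -2.209262 -4.058198 4.945292e-05 16.41108 5.098631e-05
```

QC removed 3,478 units (bad replicate arrays and filtered SNPs; 16,524
SNPs survive), the genomic inflation factor is ~1.00 on this
stratification-free panel, the per-batch empirical null SDs are ~1.02, and
the planted risk locus tops the ranking at p ≈ 1.6 × 10⁻¹¹ while the best
null SNP sits five orders of magnitude behind.

Replication-style statistics from published summary frequencies (6.92%
cases vs 5.46% controls, 1,091 cases vs 52,708 database controls):

```r
tab <- allele_table_from_freq(0.0692, 1091, 0.0546, 52708)
allelic_or(tab)[c("or", "ci_low", "ci_high")]
#> $or:      1.287279      # prints as 1.29 (1.09, 1.52)
#> $ci_low:  1.088808
#> $ci_high: 1.521927
allelic_chi2(tab)
#> $chi2: 8.782981   $p: 0.00304054

ivw_meta(hm_replication_rs10889602()[, c("or", "ci_low", "ci_high")])[c("or", "p")]
#> $or: 1.2897630    # fixed-effect meta of the two replication stages
#> $p:  0.0007700893
```

## Acceptance script

`scripts/acceptance.R` re-runs the whole workflow from scratch against the
installed package — simulating the two-batch pooled design, running the QC
cascade and discovery scan, genotyping-stage replication of the top SNPs,
re-analysis of the shipped published-summary table (validation ORs,
meta-analysis, power), LD estimation and the motif scan — and writes its
JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Progress and headline numbers are logged to stderr; all randomness derives
from `--seed`.
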