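#' Risk-allele case frequency implied by an odds ratio
#'
#' Given the risk-allele frequency \eqn{f} in controls and an allelic odds
#' ratio OR, the case frequency under the standard allelic odds model is
#' \deqn{f_{case} = \frac{OR \cdot f}{1 - f + OR \cdot f}.}
#'
#' @param f_control control allele frequency in \[0, 1\].
#' @param or allelic odds ratio (> 0); 1 gives \code{f_case == f_control}.
#' @return Case allele frequency, same length as the inputs.
#' @examples
#' case_frequency(0.0546, 1.28)   # ~0.0688
#' @export
case_frequency <- function(f_control, or) {
  stopifnot(all(f_control >= 0 & f_control <= 1), all(or > 0))
  (or * f_control) / (1 - f_control + or * f_control)
}

#' Simulate a panel of SNPs with known truth
#'
#' Draws control-population allele frequencies for \code{n_snps} biallelic
#' SNPs and assigns odds ratios to a chosen set of causal loci; all other
#' SNPs are null (OR = 1). Case frequencies follow the allelic odds model
#' (see [case_frequency()]).
#'
#' @param n_snps number of SNPs (>= 1).
#' @param maf_sampler function of one argument \code{n} returning \code{n}
#'   control minor allele frequencies; default uniform on \[0.05, 0.5\], the
#'   common-variant range an array targets. The counted (Cy3-labelled)
#'   allele of each SNP is oriented at random, so \code{f_control} is the
#'   sampled MAF or its complement with equal probability — on a real array
#'   the dye assignment is arbitrary per SNP, which is what makes the
#'   per-array channel medians comparable.
#' @param causal data frame with columns \code{index} (SNP position in
#'   1..n_snps) and \code{or} (odds ratio > 0), or \code{NULL} for an all-null
#'   panel.
#' @param seed integer seed; output is deterministic given the seed.
#' @return A \code{truth_panel} data frame with columns \code{snp_id},
#'   \code{chrom}, \code{pos}, \code{allele_a}, \code{allele_b},
#'   \code{f_control}, \code{or_risk}, \code{f_case}.
#' @export
simulate_truth <- function(n_snps,
                           maf_sampler = function(n) runif(n, 0.05, 0.5),
                           causal = NULL,
                           seed = 1L) {
  stopifnot(n_snps >= 1)
  set.seed(seed)
  f <- maf_sampler(n_snps)
  stopifnot(all(f >= 0 & f <= 1))
  flip <- runif(n_snps) < 0.5
  f <- ifelse(flip, 1 - f, f)
  or <- rep(1, n_snps)
  if (!is.null(causal) && nrow(causal) > 0) {
    bad <- causal$index[causal$index < 1 | causal$index > n_snps]
    if (length(bad) > 0) {
      stop("causal index out of range: ", paste(bad, collapse = ", "))
    }
    stopifnot(all(causal$or > 0))
    or[causal$index] <- causal$or
  }
  bases <- c("A", "C", "G", "T")
  a <- sample(bases, n_snps, replace = TRUE)
  b <- vapply(a, function(x) sample(setdiff(bases, x), 1L), character(1))
  out <- data.frame(
    snp_id = sprintf("snp%06d", seq_len(n_snps)),
    chrom = sample(1:22, n_snps, replace = TRUE),
    pos = sample.int(2.4e8, n_snps, replace = TRUE),
    allele_a = a,
    allele_b = unname(b),
    f_control = f,
    or_risk = or,
    f_case = case_frequency(f, or),
    stringsAsFactors = FALSE
  )
  class(out) <- c("truth_panel", "data.frame")
  out
}

#' Pooled-study design and array error model
#'
#' Describes the pools and the measurement model of a two-channel pooling
#' experiment. The default mirrors the two-batch high-myopia design: case
#' pools of 331 and 176 subjects paired with control pools of 145 and 149
#' subjects, three replicate arrays per pool.
#'
#' The error model has four parts, applied in [simulate_pool_intensities()]:
#' \describe{
#'   \item{\code{sd_array}}{per-replicate measurement SD on the frequency
#'     scale (Gaussian, clipped to \[0, 1\]).}
#'   \item{\code{gain_ratio}}{multiplicative Cy3/Cy5 channel imbalance
#'     \eqn{g}; raw intensities are \eqn{x = I g f}, \eqn{y = I (1-f)}, so
#'     the naive estimate \eqn{x/(x+y)} has expectation
#'     \eqn{f g / (f g + 1 - f)} — an overestimate for \eqn{g > 1}.}
#'   \item{\code{bad_array_rate}}{probability that a replicate array is
#'     "bad": its frequencies are independently resampled, destroying the
#'     inter-replicate correlation that the QC correlation filter tests.}
#'   \item{\code{stratification_delta}}{frequency shift added to a random
#'     fraction \code{strat_fraction} of SNPs in the case pools, emulating
#'     population stratification.}
#' }
#'
#' @param n_cases,n_controls per-batch pool sizes (subjects).
#' @param replicates replicate arrays per pool (>= 1).
#' @param sd_array per-replicate frequency-scale SD (default 0.015).
#' @param gain_ratio Cy3/Cy5 gain imbalance (default 1.05).
#' @param intensity_meanlog,intensity_sdlog log-normal parameters of the
#'   per-probe total intensity scale.
#' @param bad_array_rate probability a replicate is bad (default 0).
#' @param stratification_delta case-group frequency shift (default 0).
#' @param strat_fraction fraction of SNPs affected by stratification.
#' @return A \code{pool_design} object (list) with a \code{pools} data frame
#'   (pool_id, group, batch, n_subjects) and the error-model parameters.
#' @export
pool_design <- function(n_cases = c(331L, 176L),
                        n_controls = c(145L, 149L),
                        replicates = 3L,
                        sd_array = 0.015,
                        gain_ratio = 1.05,
                        intensity_meanlog = log(2000),
                        intensity_sdlog = 0.4,
                        bad_array_rate = 0,
                        stratification_delta = 0,
                        strat_fraction = 0.1) {
  stopifnot(
    length(n_cases) == length(n_controls),
    all(n_cases > 0), all(n_controls > 0),
    replicates >= 1, sd_array >= 0, gain_ratio >= 0,
    bad_array_rate >= 0, bad_array_rate <= 1,
    strat_fraction >= 0, strat_fraction <= 1
  )
  n_batch <- length(n_cases)
  pools <- data.frame(
    pool_id = c(sprintf("case_b%d", seq_len(n_batch)),
                sprintf("control_b%d", seq_len(n_batch))),
    group = rep(c("case", "control"), each = n_batch),
    batch = rep(seq_len(n_batch), 2L),
    n_subjects = c(as.integer(n_cases), as.integer(n_controls)),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      pools = pools,
      replicates = as.integer(replicates),
      sd_array = sd_array,
      gain_ratio = gain_ratio,
      intensity_meanlog = intensity_meanlog,
      intensity_sdlog = intensity_sdlog,
      bad_array_rate = bad_array_rate,
      stratification_delta = stratification_delta,
      strat_fraction = strat_fraction
    ),
    class = "pool_design"
  )
}

#' Simulate raw two-channel pool intensities
#'
#' For each pool the realised pool allele frequency is a binomial draw of
#' \eqn{2N} alleles at the group frequency (cases use \code{f_case}, controls
#' \code{f_control}). Each replicate array observes the pool frequency plus
#' Gaussian measurement noise (clipped to \[0, 1\]) and reports raw channel
#' intensities \eqn{x = I g f_{rep}}, \eqn{y = I (1 - f_{rep})} with a
#' log-normal intensity scale \eqn{I} (a per-SNP scale shared across
#' replicates times a per-array draw) and channel gain \eqn{g}. With
#' probability \code{bad_array_rate} a replicate array is bad: its
#' frequencies are resampled independently of the pool, so it decorrelates
#' from its siblings.
#'
#' @param truth a \code{truth_panel} from [simulate_truth()].
#' @param design a \code{pool_design}.
#' @param seed integer seed.
#' @return An \code{intensity_panel} data frame with columns \code{snp_id},
#'   \code{chrom}, \code{pos}, \code{pool_id}, \code{group}, \code{batch},
#'   \code{replicate}, \code{x_raw}, \code{y_raw}. The realised per-pool
#'   frequencies are attached as attribute \code{"pool_truth"} (SNP x pool
#'   matrix) for bias diagnostics.
#' @export
simulate_pool_intensities <- function(truth, design, seed = 1L) {
  stopifnot(inherits(design, "pool_design"), nrow(truth) > 0)
  set.seed(seed)
  n_snps <- nrow(truth)
  pools <- design$pools
  n_pools <- nrow(pools)

  strat <- rep(0, n_snps)
  if (design$stratification_delta != 0 && design$strat_fraction > 0) {
    idx <- sample.int(n_snps, size = round(design$strat_fraction * n_snps))
    strat[idx] <- design$stratification_delta
  }

  # per-SNP intensity scale shared across arrays (probe efficiency)
  snp_scale <- rlnorm(n_snps, 0, 0.5)

  pool_truth <- matrix(NA_real_, n_snps, n_pools,
                       dimnames = list(truth$snp_id, pools$pool_id))
  recs <- vector("list", n_pools * design$replicates)
  k <- 0L
  for (p in seq_len(n_pools)) {
    f_grp <- if (pools$group[p] == "case") {
      pmin(pmax(truth$f_case + strat, 0), 1)
    } else {
      truth$f_control
    }
    n2 <- 2L * pools$n_subjects[p]
    f_pool <- rbinom(n_snps, n2, f_grp) / n2
    pool_truth[, p] <- f_pool
    for (r in seq_len(design$replicates)) {
      f_rep <- pmin(pmax(f_pool + rnorm(n_snps, 0, design$sd_array), 0), 1)
      if (runif(1) < design$bad_array_rate) {
        # bad chip: frequencies unrelated to the pool
        f_bad <- rbinom(n_snps, n2, f_grp) / n2
        f_rep <- pmin(pmax(sample(f_bad) + rnorm(n_snps, 0, design$sd_array), 0), 1)
      }
      intensity <- snp_scale *
        rlnorm(n_snps, design$intensity_meanlog, design$intensity_sdlog)
      k <- k + 1L
      recs[[k]] <- data.frame(
        snp_id = truth$snp_id,
        chrom = truth$chrom,
        pos = truth$pos,
        pool_id = pools$pool_id[p],
        group = pools$group[p],
        batch = pools$batch[p],
        replicate = r,
        x_raw = intensity * design$gain_ratio * f_rep,
        y_raw = intensity * (1 - f_rep),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  attr(out, "pool_truth") <- pool_truth
  class(out) <- c("intensity_panel", "data.frame")
  out
}

#' Simulate individual genotypes under Hardy-Weinberg equilibrium
#'
#' Case genotypes are drawn at the SNP's case frequency, control genotypes at
#' the control frequency, each as the sum of two Bernoulli alleles (HWE).
#' Sex and age covariates are generated independently of genotype and
#' phenotype.
#'
#' @param truth a \code{truth_panel}.
#' @param n_case,n_control sample sizes (>= 1).
#' @param missing_rate per-entry missingness probability.
#' @param seed integer seed.
#' @return A \code{genotype_matrix} data frame: columns \code{sample_id},
#'   \code{status} (1 = case, 0 = control), \code{sex} (1/2), \code{age},
#'   then one 0/1/2 column per SNP (NA = missing). A PLINK-style map
#'   (\code{chrom}, \code{snp_id}, \code{cm}, \code{pos}) is attached as
#'   attribute \code{"map"}.
#' @export
simulate_genotypes <- function(truth, n_case, n_control,
                               missing_rate = 0, seed = 1L) {
  stopifnot(n_case >= 1, n_control >= 1,
            missing_rate >= 0, missing_rate <= 1)
  set.seed(seed)
  n <- n_case + n_control
  status <- rep(c(1L, 0L), c(n_case, n_control))
  geno <- matrix(NA_integer_, n, nrow(truth),
                 dimnames = list(NULL, truth$snp_id))
  for (j in seq_len(nrow(truth))) {
    f <- ifelse(status == 1L, truth$f_case[j], truth$f_control[j])
    geno[, j] <- rbinom(n, 2L, f)
  }
  if (missing_rate > 0) {
    geno[matrix(runif(length(geno)) < missing_rate, nrow(geno))] <- NA_integer_
  }
  out <- data.frame(
    sample_id = sprintf("s%05d", seq_len(n)),
    status = status,
    sex = sample(1:2, n, replace = TRUE),
    age = as.integer(round(runif(n, 18, 60))),
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(geno))
  attr(out, "map") <- data.frame(
    chrom = truth$chrom, snp_id = truth$snp_id, cm = 0L, pos = truth$pos,
    stringsAsFactors = FALSE
  )
  class(out) <- c("genotype_matrix", "data.frame")
  out
}

#' Maximum achievable r-squared for two loci
#'
#' For allele frequencies \code{f1}, \code{f2} the disequilibrium coefficient
#' D is bounded by the haplotype-frequency constraints; taking D > 0 the
#' bound is \code{min(f1 (1 - f2), (1 - f1) f2)}, which caps the achievable
#' \eqn{r^2 = D^2 / (f1 (1-f1) f2 (1-f2))}.
#'
#' @param f1,f2 allele frequencies in (0, 1).
#' @return The maximum achievable \eqn{r^2} (with positive D).
#' @export
max_r2 <- function(f1, f2) {
  d_max <- pmin(f1 * (1 - f2), (1 - f1) * f2)
  d_max^2 / (f1 * (1 - f1) * f2 * (1 - f2))
}

#' Simulate unphased genotypes at two loci in linkage disequilibrium
#'
#' Haplotypes AB, Ab, aB, ab are drawn from the four-haplotype distribution
#' with \eqn{D = \sqrt{r^2_{target} f_1 (1-f_1) f_2 (1-f_2)}} (positive
#' association between the A and B alleles); each individual's genotype at a
#' locus is the sum of two independent haplotypes.
#'
#' @param f1,f2 allele frequencies of the counted alleles (A, B) in (0, 1).
#' @param r2_target desired \eqn{r^2} in \[0, 1\]; must not exceed
#'   [max_r2()] for the given frequencies.
#' @param n number of individuals.
#' @param seed integer seed.
#' @return A \code{genotype_matrix} data frame with two SNP columns
#'   \code{locus1}, \code{locus2}; the haplotype frequencies used are
#'   attached as attribute \code{"haplotype_freqs"}.
#' @export
simulate_two_locus <- function(f1, f2, r2_target, n, seed = 1L) {
  stopifnot(f1 > 0, f1 < 1, f2 > 0, f2 < 1,
            r2_target >= 0, r2_target <= 1, n >= 1)
  r2_max <- max_r2(f1, f2)
  if (r2_target > r2_max + 1e-12) {
    stop(sprintf(
      "r2_target %.4f unachievable for f1=%.3f, f2=%.3f; feasible maximum is %.4f",
      r2_target, f1, f2, r2_max
    ))
  }
  d <- sqrt(r2_target * f1 * (1 - f1) * f2 * (1 - f2))
  h <- c(AB = f1 * f2 + d, Ab = f1 * (1 - f2) - d,
         aB = (1 - f1) * f2 - d, ab = (1 - f1) * (1 - f2) + d)
  h <- pmax(h, 0)
  h <- h / sum(h)
  set.seed(seed)
  hap1 <- sample.int(4L, n, replace = TRUE, prob = h)
  hap2 <- sample.int(4L, n, replace = TRUE, prob = h)
  carries_a <- c(1L, 1L, 0L, 0L)  # haplotypes carrying allele A
  carries_b <- c(1L, 0L, 1L, 0L)  # haplotypes carrying allele B
  out <- data.frame(
    sample_id = sprintf("s%05d", seq_len(n)),
    status = NA_integer_,
    sex = NA_integer_,
    age = NA_real_,
    locus1 = carries_a[hap1] + carries_a[hap2],
    locus2 = carries_b[hap1] + carries_b[hap2],
    stringsAsFactors = FALSE
  )
  attr(out, "haplotype_freqs") <- h
  class(out) <- c("genotype_matrix", "data.frame")
  out
}
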