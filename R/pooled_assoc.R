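#' Pooled case-control allele-frequency z statistic
#'
#' The combined pooled statistic contrasts the estimated case and control
#' pool frequencies against a variance that sums the binomial sampling
#' variance of the pooled subjects and the array-measurement variance of
#' each pool's replicate mean:
#' \deqn{z = \frac{\hat f_c - \hat f_k}{\sqrt{\bar f (1 - \bar f)
#'   \left(\frac{1}{2 n_c} + \frac{1}{2 n_k}\right) + V_c + V_k}}}
#' where \eqn{\bar f} is the average of the two pool frequencies and
#' \eqn{V_c, V_k} are the squared standard errors of the replicate means
#' (replicate variance divided by replicate count). With \eqn{V = 0} this is
#' the textbook two-proportion z test on allele counts.
#'
#' @param f_case,f_control estimated pool frequencies in (0, 1), vectorised.
#' @param n_case,n_control pooled subject counts (alleles are 2n).
#' @param var_e_case,var_e_control squared standard errors of the replicate
#'   means (default 0).
#' @return z scores (positive when cases have the higher frequency).
#' @export
pooled_z <- function(f_case, f_control, n_case, n_control,
                     var_e_case = 0, var_e_control = 0) {
  stopifnot(all(n_case > 0), all(n_control > 0),
            all(var_e_case >= 0), all(var_e_control >= 0))
  fbar <- (f_case + f_control) / 2
  v <- fbar * (1 - fbar) * (1 / (2 * n_case) + 1 / (2 * n_control)) +
    var_e_case + var_e_control
  if (any(v <= 0)) stop("zero variance in pooled z denominator")
  (f_case - f_control) / sqrt(v)
}

#' Empirical null standard deviation from the quantile-quantile slope
#'
#' Estimates the scale of a z-statistic collection as the slope of the line
#' through the first and third quartiles of its QQ plot against the standard
#' normal: \eqn{\hat\sigma = IQR(z) / (2 \Phi^{-1}(0.75))} with
#' \eqn{\Phi^{-1}(0.75) \approx 0.6745}. Quartile-based, so a small fraction
#' of true signals in the tails does not perturb the estimate.
#'
#' @param z numeric vector of statistics (>= 100 finite values).
#' @return The estimated null SD.
#' @export
estimate_null_sd <- function(z) {
  z <- z[is.finite(z)]
  if (length(z) < 100) stop("need at least 100 finite values")
  iqr <- diff(quantile(z, c(0.25, 0.75), names = FALSE, type = 7))
  if (iqr <= 0) stop("degenerate z collection: zero interquartile range")
  iqr / (2 * qnorm(0.75))
}

#' Combine per-batch z statistics (weighted Stouffer method)
#'
#' Combines standardized z scores from independent batches as
#' \eqn{z = \sum_i w_i z_i / \sqrt{\sum_i w_i^2}} with weights
#' \eqn{w_i = \sqrt{n_i}} where \eqn{n_i} is the batch's effective sample
#' size. If the second batch is absent (\code{NA}), the first is returned
#' unchanged.
#'
#' @param z1,z2 z scores (vectorised); \code{z2} may contain \code{NA}.
#' @param n1,n2 effective sample sizes (> 0); for a case-control batch use
#'   \code{4 / (1/n_case + 1/n_control)}.
#' @return Combined z scores.
#' @export
combine_batches <- function(z1, n1, z2 = NA, n2 = NA) {
  if (any(!is.na(n1) & n1 <= 0) || any(!is.na(n2) & n2 <= 0)) {
    stop("effective sample sizes must be positive")
  }
  k <- max(length(z1), length(z2))
  z1 <- rep_len(z1, k); z2 <- rep_len(z2, k)
  w1 <- rep_len(sqrt(n1), k); w2 <- rep_len(sqrt(n2), k)
  miss <- is.na(z2)
  out <- (w1 * z1 + ifelse(miss, 0, w2 * z2)) /
    sqrt(w1^2 + ifelse(miss, 0, w2^2))
  out[miss] <- z1[miss]
  out
}

#' Effective sample size of a case-control comparison
#'
#' @param n_case,n_control group sizes.
#' @return \code{4 / (1/n_case + 1/n_control)}, the equal-group sample size
#'   with the same two-proportion variance.
#' @export
effective_n <- function(n_case, n_control) {
  4 / (1 / n_case + 1 / n_control)
}

#' Genomic-control correction of chi-square statistics
#'
#' The inflation factor \eqn{\lambda} is the median of the association
#' chi-square statistics over a random SNP subset divided by the null median
#' of \eqn{\chi^2_1} (0.4549), floored at 1. All statistics are deflated by
#' \eqn{\lambda} and p-values recomputed from the upper \eqn{\chi^2_1} tail.
#'
#' @param chi2 nonnegative chi-square statistics (1 df).
#' @param n_random number of SNPs sampled (without replacement) for the
#'   median; default 20000, capped at the panel size.
#' @param seed integer seed for the random subset.
#' @return A list with \code{lambda}, \code{chi2_adj} and \code{p_adj}.
#' @export
genomic_control <- function(chi2, n_random = 20000L, seed = 1L) {
  stopifnot(all(chi2 >= 0), n_random >= 1)
  set.seed(seed)
  n_random <- min(n_random, length(chi2))
  sub <- chi2[sample.int(length(chi2), n_random)]
  if (length(sub) == 0) stop("empty chi-square subset")
  lambda <- max(1, median(sub) / qchisq(0.5, df = 1))
  chi2_adj <- chi2 / lambda
  list(lambda = lambda, chi2_adj = chi2_adj,
       p_adj = pchisq(chi2_adj, df = 1, lower.tail = FALSE))
}

#' Pooled discovery-stage association scan
#'
#' Runs the full pooled association pipeline on QC-passed pool frequency
#' tables: a per-batch pooled z statistic ([pooled_z()]) contrasting the
#' batch's case and control pools, standardisation of each batch by its
#' empirical null SD ([estimate_null_sd()]), Stouffer combination across
#' batches ([combine_batches()]) weighted by effective sample size,
#' conversion to a 1-df chi-square, genomic-control correction
#' ([genomic_control()]) and two-sided p-values.
#'
#' @param freq_table a \code{pool_freq_table} from [pool_frequencies()]
#'   covering the case and control pools of one or more batches.
#' @param design the \code{pool_design} (supplies per-batch pool sizes).
#' @param n_random SNPs used for the genomic-control median (default 20000).
#' @param seed seed for the genomic-control subset.
#' @return An \code{assoc_result} data frame sorted by \code{p_gc} with
#'   columns \code{snp_id}, \code{z_b1}, \code{z_b2} (NA for single-batch
#'   designs), \code{z_comb}, \code{p_raw}, \code{chi2_gc}, \code{p_gc};
#'   attributes \code{null_sd} (per batch), \code{lambda}.
#' @export
run_discovery <- function(freq_table, design, n_random = 20000L, seed = 1L) {
  pools <- design$pools
  batches <- sort(unique(pools$batch))
  snps <- sort(unique(freq_table$snp_id))
  zmat <- matrix(NA_real_, length(snps), length(batches),
                 dimnames = list(snps, paste0("z_b", batches)))
  n_eff <- numeric(length(batches))
  null_sd <- numeric(length(batches))

  for (b in seq_along(batches)) {
    bp <- pools[pools$batch == batches[b], ]
    n_case <- sum(bp$n_subjects[bp$group == "case"])
    n_control <- sum(bp$n_subjects[bp$group == "control"])
    n_eff[b] <- effective_n(n_case, n_control)

    bt <- freq_table[freq_table$batch == batches[b], ]
    cs <- bt[bt$group == "case", ]
    ct <- bt[bt$group == "control", ]
    common <- intersect(cs$snp_id, ct$snp_id)
    ic <- match(common, cs$snp_id)
    ik <- match(common, ct$snp_id)
    z <- pooled_z(cs$f_hat[ic], ct$f_hat[ik], n_case, n_control,
                  cs$se2[ic], ct$se2[ik])
    null_sd[b] <- estimate_null_sd(z)
    zmat[match(common, snps), b] <- z / null_sd[b]
  }

  z_comb <- if (length(batches) >= 2) {
    combine_batches(zmat[, 1], n_eff[1], zmat[, 2], n_eff[2])
  } else {
    zmat[, 1]
  }
  keep <- is.finite(z_comb)
  z_comb <- z_comb[keep]
  snps <- snps[keep]
  zmat <- zmat[keep, , drop = FALSE]

  chi2 <- z_comb^2
  gc <- genomic_control(chi2, n_random = n_random, seed = seed)
  out <- data.frame(
    snp_id = snps,
    z_b1 = zmat[, 1],
    z_b2 = if (ncol(zmat) >= 2) zmat[, 2] else NA_real_,
    z_comb = z_comb,
    p_raw = pchisq(chi2, 1, lower.tail = FALSE),
    chi2_gc = gc$chi2_adj,
    p_gc = gc$p_adj,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p_gc, out$snp_id), ]
  rownames(out) <- NULL
  attr(out, "null_sd") <- setNames(null_sd, paste0("batch", batches))
  attr(out, "lambda") <- gc$lambda
  class(out) <- c("assoc_result", "data.frame")
  out
}
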