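#' Cross-tabulate two loci of unphased genotypes
#'
#' @param g1,g2 genotype vectors coded 0/1/2 (NA dropped pairwise).
#' @return A 3x3 matrix of counts, rows = genotype at locus 1, columns =
#'   genotype at locus 2 (codes 0, 1, 2).
#' @export
two_locus_counts <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  stopifnot(all(g1 %in% 0:2), all(g2 %in% 0:2))
  tab <- matrix(0, 3, 3, dimnames = list(0:2, 0:2))
  for (i in 0:2) for (j in 0:2) tab[i + 1, j + 1] <- sum(g1 == i & g2 == j)
  tab
}

# log-likelihood of a 3x3 genotype count table given haplotype frequencies
# h = (AB, Ab, aB, ab); rows of the table are coded by copies of allele A,
# columns by copies of allele B. Genotype class probabilities are sums over
# the (unordered) haplotype pairs consistent with the class; the double
# heterozygote mixes cis (AB/ab) and trans (Ab/aB) phase.
.hap_loglik <- function(h, counts) {
  p <- .genotype_probs(h)
  ll <- sum(counts[p > 0] * log(p[p > 0]))
  if (any(counts[p == 0] > 0)) ll <- -Inf
  ll
}

.genotype_probs <- function(h) {
  hAB <- h[1]; hAb <- h[2]; haB <- h[3]; hab <- h[4]
  m <- matrix(0, 3, 3)
  m[3, 3] <- hAB^2                    # AA BB
  m[3, 2] <- 2 * hAB * hAb            # AA Bb
  m[3, 1] <- hAb^2                    # AA bb
  m[2, 3] <- 2 * hAB * haB            # Aa BB
  m[2, 2] <- 2 * hAB * hab + 2 * hAb * haB  # Aa Bb (cis + trans)
  m[2, 1] <- 2 * hAb * hab            # Aa bb
  m[1, 3] <- haB^2                    # aa BB
  m[1, 2] <- 2 * haB * hab            # aa Bb
  m[1, 1] <- hab^2                    # aa bb
  m                                   # rows/cols = 0,1,2 copies of A / B
}

#' Two-locus haplotype frequencies by EM
#'
#' Maximum-likelihood estimation of the four haplotype frequencies (AB, Ab,
#' aB, ab) from unphased two-locus genotype counts. Phase is ambiguous only
#' for double heterozygotes; the EM step splits them between the cis (AB/ab)
#' and trans (Ab/aB) configurations in proportion to the current haplotype
#' frequencies. Initialised at linkage equilibrium; iterated to a tolerance
#' of 1e-8 on the frequencies, at most 1000 iterations. The log-likelihood
#' is nondecreasing across iterations.
#'
#' @param counts a 3x3 genotype count matrix from [two_locus_counts()], or a
#'   pair of genotype vectors via \code{em_haplotypes(g1, g2)}.
#' @param g2 optional second genotype vector when \code{counts} is a vector.
#' @param tol convergence tolerance (default 1e-8).
#' @param max_iter iteration cap (default 1000).
#' @param trace record the log-likelihood at every iteration (returned as
#'   \code{loglik_trace}).
#' @return A \code{haplotype_freqs} list: \code{freqs} (named AB, Ab, aB,
#'   ab, summing to 1), \code{loglik}, \code{iterations}, \code{converged}.
#' @export
em_haplotypes <- function(counts, g2 = NULL, tol = 1e-8, max_iter = 1000L,
                          trace = FALSE) {
  if (!is.null(g2)) counts <- two_locus_counts(counts, g2)
  stopifnot(is.matrix(counts), all(dim(counts) == c(3, 3)),
            all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("empty genotype table")
  # allele counts: row index i (1..3) = i-1 copies of A
  nA <- sum((0:2) * rowSums(counts))
  nB <- sum((0:2) * colSums(counts))
  pA <- nA / (2 * n)
  pB <- nB / (2 * n)
  h <- c(AB = pA * pB, Ab = pA * (1 - pB), aB = (1 - pA) * pB,
         ab = (1 - pA) * (1 - pB))
  h <- pmax(h, 1e-12)
  h <- h / sum(h)
  n_dh <- counts[2, 2]  # double heterozygotes
  converged <- FALSE
  it <- 0L
  ll_trace <- if (trace) .hap_loglik(h, counts)
  for (it in seq_len(max_iter)) {
    # E step: expected cis fraction of double heterozygotes
    cis <- unname(h["AB"] * h["ab"])
    trans <- unname(h["Ab"] * h["aB"])
    pc <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    # M step: haplotype counts from phase-known genotypes + expected phases
    cAB <- 2 * counts[3, 3] + counts[3, 2] + counts[2, 3] + n_dh * pc
    cAb <- 2 * counts[3, 1] + counts[3, 2] + counts[2, 1] + n_dh * (1 - pc)
    caB <- 2 * counts[1, 3] + counts[2, 3] + counts[1, 2] + n_dh * (1 - pc)
    cab <- 2 * counts[1, 1] + counts[1, 2] + counts[2, 1] + n_dh * pc
    h_new <- c(AB = unname(cAB), Ab = unname(cAb), aB = unname(caB),
               ab = unname(cab)) / (2 * n)
    if (trace) ll_trace <- c(ll_trace, .hap_loglik(h_new, counts))
    if (max(abs(h_new - h)) < tol) {
      h <- h_new
      converged <- TRUE
      break
    }
    h <- h_new
  }
  out <- structure(
    list(freqs = h, loglik = .hap_loglik(h, counts), iterations = it,
         converged = converged),
    class = "haplotype_freqs"
  )
  if (trace) out$loglik_trace <- ll_trace
  out
}

#' Linkage-disequilibrium summaries from haplotype frequencies
#'
#' Computes \eqn{D = f_{AB} - f_A f_B}, the squared correlation
#' \eqn{r^2 = D^2 / (f_A f_a f_B f_b)}, and the normalised
#' \eqn{D' = D / D_{max}} where \eqn{D_{max} = \min(f_A f_b, f_a f_B)} for
#' \eqn{D > 0} and \eqn{\min(f_A f_B, f_a f_b)} for \eqn{D < 0}.
#'
#' @param h a \code{haplotype_freqs} object or a length-4 frequency vector
#'   (AB, Ab, aB, ab).
#' @return A list with \code{D}, \code{Dprime}, \code{r2}, \code{p_A},
#'   \code{p_B}; all \code{NA} (with \code{monomorphic = TRUE}) when either
#'   locus is monomorphic.
#' @export
ld_stats <- function(h) {
  if (inherits(h, "haplotype_freqs")) h <- h$freqs
  stopifnot(length(h) == 4, all(h >= -1e-12), abs(sum(h) - 1) < 1e-6)
  pA <- h[1] + h[2]
  pB <- h[1] + h[3]
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) {
    return(list(D = NA_real_, Dprime = NA_real_, r2 = NA_real_,
                p_A = unname(pA), p_B = unname(pB), monomorphic = TRUE))
  }
  d <- h[1] - pA * pB
  r2 <- d^2 / (pA * (1 - pA) * pB * (1 - pB))
  d_max <- if (d >= 0) {
    min(pA * (1 - pB), (1 - pA) * pB)
  } else {
    min(pA * pB, (1 - pA) * (1 - pB))
  }
  dprime <- if (d_max > 0) d / d_max else 0
  list(D = unname(d), Dprime = unname(dprime), r2 = unname(r2),
       p_A = unname(pA), p_B = unname(pB), monomorphic = FALSE)
}

#' Pairwise LD of a focal SNP against its neighbours
#'
#' Runs the haplotype EM for the focal SNP against every other SNP in the
#' genotype matrix (optionally within a window around the focal position,
#' when a map is attached) and reports D, D' and r-squared.
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param focal focal SNP column name.
#' @param window half-width in bp (requires a map attribute); NULL = all SNPs.
#' @return Data frame (snp_a, snp_b, D, Dprime, r2, n_used).
#' @export
ld_scan <- function(genotypes, focal, window = NULL) {
  snps <- .snp_cols(genotypes)
  if (!focal %in% snps) stop("unknown focal snp: ", focal)
  others <- setdiff(snps, focal)
  map <- attr(genotypes, "map")
  if (!is.null(window) && !is.null(map)) {
    pos <- setNames(map$pos, map$snp_id)
    others <- others[abs(pos[others] - pos[focal]) <= window]
  }
  rows <- lapply(others, function(s) {
    g1 <- genotypes[[focal]]
    g2 <- genotypes[[s]]
    n_used <- sum(!is.na(g1) & !is.na(g2))
    ld <- ld_stats(em_haplotypes(g1, g2))
    data.frame(snp_a = focal, snp_b = s, D = ld$D, Dprime = ld$Dprime,
               r2 = ld$r2, n_used = n_used, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
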