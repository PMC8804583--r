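.snp_cols <- function(genotypes) {
  setdiff(names(genotypes), c("sample_id", "status", "sex", "age"))
}

#' Filter SNPs by genotyping call rate
#'
#' Keeps SNPs whose call rate (fraction of non-missing genotypes) is
#' strictly greater than \code{min_rate}; a SNP at exactly the cutoff is
#' removed.
#'
#' @param genotypes a \code{genotype_matrix} data frame (0/1/2 coding,
#'   \code{NA} = missing).
#' @param min_rate call-rate cutoff (default 0.8).
#' @return The filtered matrix with attributes \code{"removed_snps"} and
#'   \code{"call_rates"} (named vector over all input SNPs).
#' @export
call_rate_filter <- function(genotypes, min_rate = 0.8) {
  snps <- .snp_cols(genotypes)
  cr <- vapply(snps, function(s) mean(!is.na(genotypes[[s]])), numeric(1))
  removed <- snps[cr <= min_rate]
  out <- genotypes[, !(names(genotypes) %in% removed), drop = FALSE]
  attr(out, "map") <- attr(genotypes, "map")
  attr(out, "removed_snps") <- removed
  attr(out, "call_rates") <- cr
  class(out) <- class(genotypes)
  out
}

#' 2x2 allele-count table for a SNP
#'
#' Tallies risk- and other-allele counts in cases and controls. Genotype
#' codes are taken as the number of copies of the coded allele; with
#' \code{risk_allele = "other"} the orientation is flipped (counts become
#' \code{2 - g}). Individuals with a missing genotype are excluded.
#'
#' @param genotypes a \code{genotype_matrix} with a \code{status} column
#'   (1 = case, 0 = control).
#' @param snp_id SNP column name.
#' @param risk_allele \code{"coded"} (default) or \code{"other"}.
#' @return An \code{allele_table_2x2} list with fields \code{a} (case risk
#'   alleles), \code{b} (case other), \code{c} (control risk), \code{d}
#'   (control other).
#' @export
allele_table <- function(genotypes, snp_id, risk_allele = c("coded", "other")) {
  risk_allele <- match.arg(risk_allele)
  if (!snp_id %in% names(genotypes)) stop("unknown snp: ", snp_id)
  g <- genotypes[[snp_id]]
  ok <- !is.na(g)
  g <- g[ok]
  if (risk_allele == "other") g <- 2L - g
  case <- genotypes$status[ok] == 1L
  structure(
    list(a = sum(g[case]), b = sum(2L - g[case]),
         c = sum(g[!case]), d = sum(2L - g[!case])),
    class = "allele_table_2x2"
  )
}

#' 2x2 allele-count table from summary frequencies
#'
#' Reconstructs allele counts from reported minor/risk allele frequencies and
#' sample sizes, as done when testing candidate SNPs against database control
#' frequencies. Counts are left unrounded.
#'
#' @param f_case,f_control risk-allele frequencies.
#' @param n_case,n_control numbers of genotyped individuals (2n alleles).
#' @return An \code{allele_table_2x2}.
#' @export
allele_table_from_freq <- function(f_case, n_case, f_control, n_control) {
  stopifnot(f_case >= 0, f_case <= 1, f_control >= 0, f_control <= 1,
            n_case > 0, n_control > 0)
  structure(
    list(a = 2 * n_case * f_case, b = 2 * n_case * (1 - f_case),
         c = 2 * n_control * f_control, d = 2 * n_control * (1 - f_control)),
    class = "allele_table_2x2"
  )
}

#' Allelic odds ratio with Woolf 95\% confidence interval
#'
#' \eqn{OR = (a/b) / (c/d)} with the Woolf interval
#' \eqn{\exp(\ln OR \pm 1.96 \sqrt{1/a + 1/b + 1/c + 1/d})}. If any cell is
#' zero, 0.5 is added to every cell (Haldane-Anscombe correction). With
#' \code{orient = "case_enriched"} the table is flipped when needed so the
#' reported OR is >= 1 (the odds ratio of the allele over-represented in
#' cases), as association tables are often printed.
#'
#' @param table an \code{allele_table_2x2}.
#' @param orient \code{"risk"} (as tabulated, default) or
#'   \code{"case_enriched"}.
#' @param conf_level confidence level (default 0.95).
#' @return A list with \code{or}, \code{ci_low}, \code{ci_high}, \code{se}
#'   (SE of log OR) and \code{flipped} (logical).
#' @export
allelic_or <- function(table, orient = c("risk", "case_enriched"),
                       conf_level = 0.95) {
  orient <- match.arg(orient)
  x <- c(table$a, table$b, table$c, table$d)
  if (sum(x[1:2]) == 0 || sum(x[3:4]) == 0) {
    stop("empty case or control margin")
  }
  if (any(x == 0)) x <- x + 0.5
  flipped <- FALSE
  if (orient == "case_enriched" && (x[1] / x[2]) / (x[3] / x[4]) < 1) {
    x <- x[c(2, 1, 4, 3)]
    flipped <- TRUE
  }
  log_or <- log(x[1]) - log(x[2]) - log(x[3]) + log(x[4])
  se <- sqrt(sum(1 / x))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  list(or = exp(log_or),
       ci_low = exp(log_or - zq * se),
       ci_high = exp(log_or + zq * se),
       se = se,
       flipped = flipped)
}

#' 1-df allelic chi-square test
#'
#' Pearson chi-square of the 2x2 allele-count table, without continuity
#' correction; the two-sided p-value comes from the upper \eqn{\chi^2_1}
#' tail.
#'
#' @param table an \code{allele_table_2x2}.
#' @return A list with \code{chi2} and \code{p}.
#' @export
allelic_chi2 <- function(table) {
  a <- as.numeric(table$a); b <- as.numeric(table$b)
  c <- as.numeric(table$c); d <- as.numeric(table$d)
  n <- a + b + c + d
  if (n <= 0) stop("empty table")
  if ((a + c) == 0 || (b + d) == 0 || (a + b) == 0 || (c + d) == 0) {
    stop("zero margin in allele table")
  }
  chi2 <- n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Cochran-Armitage trend test
#'
#' Tests for a linear trend in case proportion across the three genotype
#' classes with scores (0, 1, 2) — the 1-df additive-dose test. The signed z
#' is positive when the case proportion rises with the genotype score.
#'
#' @param counts a 2x3 matrix of genotype counts, rows = (case, control),
#'   columns = genotype codes 0, 1, 2.
#' @return A list with \code{z}, \code{chi2} and the two-sided \code{p}.
#' @export
trend_test <- function(counts) {
  stopifnot(is.matrix(counts), nrow(counts) == 2, ncol(counts) == 3,
            all(counts >= 0))
  s <- c(0, 1, 2)
  n_j <- colSums(counts)
  n <- sum(counts)
  r <- sum(counts[1, ])
  if (n == 0 || r == 0 || r == n) stop("degenerate table: no cases or no controls")
  u <- sum(s * counts[1, ]) - r * sum(s * n_j) / n
  v <- r * (n - r) / n^3 * (n * sum(s^2 * n_j) - sum(s * n_j)^2)
  if (v <= 0) stop("degenerate table: no genotype variation")
  z <- u / sqrt(v)
  list(z = z, chi2 = z^2, p = pchisq(z^2, df = 1, lower.tail = FALSE))
}

#' Genotype-count table for a SNP
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param snp_id SNP column name.
#' @return 2x3 matrix of counts (rows case/control, columns genotypes 0/1/2)
#'   suitable for [trend_test()].
#' @export
genotype_counts <- function(genotypes, snp_id) {
  if (!snp_id %in% names(genotypes)) stop("unknown snp: ", snp_id)
  g <- genotypes[[snp_id]]
  ok <- !is.na(g)
  tab <- matrix(0, 2, 3, dimnames = list(c("case", "control"), 0:2))
  for (k in 0:2) {
    tab[1, k + 1] <- sum(g[ok] == k & genotypes$status[ok] == 1L)
    tab[2, k + 1] <- sum(g[ok] == k & genotypes$status[ok] == 0L)
  }
  tab
}

#' Covariate-adjusted association by logistic regression
#'
#' Fits \code{status ~ genotype + covariates} by iteratively reweighted
#' least squares (convergence tolerance 1e-8, at most 50 iterations) and
#' reports the Wald p-value of the additive genotype term. Non-convergence
#' or a degenerate genotype column is flagged, not raised.
#'
#' @param genotypes a \code{genotype_matrix} with \code{status} and covariate
#'   columns.
#' @param snp_id SNP column name.
#' @param covariates covariate column names (default sex and age).
#' @return A list with \code{beta}, \code{se}, \code{p_adjusted} and
#'   \code{converged}; \code{p_adjusted} is \code{NA} when flagged.
#' @export
adjusted_association <- function(genotypes, snp_id,
                                 covariates = c("sex", "age")) {
  if (!snp_id %in% names(genotypes)) stop("unknown snp: ", snp_id)
  dat <- genotypes[, c("status", snp_id, covariates)]
  names(dat)[2] <- "g"
  dat <- dat[complete.cases(dat), ]
  if (length(unique(dat$g)) < 2) {
    return(list(beta = NA_real_, se = NA_real_, p_adjusted = NA_real_,
                converged = FALSE))
  }
  fit <- suppressWarnings(glm(
    status ~ .,
    family = binomial(),
    data = dat,
    control = glm.control(epsilon = 1e-8, maxit = 50)
  ))
  cf <- summary(fit)$coefficients
  if (!fit$converged || !("g" %in% rownames(cf)) ||
      abs(cf["g", "Estimate"]) > 15) {
    return(list(beta = NA_real_, se = NA_real_, p_adjusted = NA_real_,
                converged = FALSE))
  }
  list(beta = cf["g", "Estimate"], se = cf["g", "Std. Error"],
       p_adjusted = cf["g", "Pr(>|z|)"], converged = TRUE)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error level.
#' @param m number of tests (>= 1).
#' @return A list with the exact \code{threshold} (alpha / m) and
#'   \code{threshold_2sf}, the same value rounded to two significant figures
#'   as it would be quoted in a report.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  t <- alpha / m
  list(threshold = t, threshold_2sf = signif(t, 2))
}

#' Fixed-effect inverse-variance-weighted meta-analysis of odds ratios
#'
#' Per-study log odds ratios are pooled with weights \eqn{w_i = 1/SE_i^2};
#' standard errors are recovered from 95\% confidence intervals as
#' \eqn{(\ln CI_{high} - \ln CI_{low}) / (2 \times 1.96)} when not given
#' directly. The pooled estimate is
#' \eqn{\hat\beta = \sum w_i \beta_i / \sum w_i} with
#' \eqn{SE = 1/\sqrt{\sum w_i}}, reported as an OR with 95\% CI and a
#' two-sided normal p-value. A single study is returned unchanged.
#'
#' @param studies data frame with either columns \code{or}, \code{ci_low},
#'   \code{ci_high} (95\% CI) or columns \code{beta}, \code{se}.
#' @return A list with \code{or}, \code{ci_low}, \code{ci_high}, \code{z},
#'   \code{p}, \code{se} and the per-study weights.
#' @export
ivw_meta <- function(studies) {
  if (all(c("beta", "se") %in% names(studies))) {
    beta <- studies$beta
    se <- studies$se
  } else {
    stopifnot(all(c("or", "ci_low", "ci_high") %in% names(studies)))
    stopifnot(all(studies$ci_low < studies$or),
              all(studies$or < studies$ci_high))
    beta <- log(studies$or)
    se <- (log(studies$ci_high) - log(studies$ci_low)) / (2 * qnorm(0.975))
  }
  if (any(se <= 0)) stop("nonpositive standard error")
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- 1 / sqrt(sum(w))
  z <- b / s
  zq <- qnorm(0.975)
  list(or = exp(b), ci_low = exp(b - zq * s), ci_high = exp(b + zq * s),
       z = z, p = 2 * pnorm(-abs(z)), se = s, weights = w)
}

#' Analytic power of the 1-df allelic association test
#'
#' Computes the noncentrality parameter of the allelic chi-square at the
#' case frequency implied by the odds ratio,
#' \deqn{ncp = \frac{(f_{case} - f_{control})^2}{\bar p (1 - \bar p)
#'   \left(\frac{1}{2 n_{case}} + \frac{1}{2 n_{control}}\right)}}
#' with \eqn{\bar p} the allele-count-weighted mean frequency, and returns
#' the power of the level-\code{alpha} test from the noncentral
#' \eqn{\chi^2_1} distribution. At OR = 1 the power equals \code{alpha}.
#'
#' @param n_case,n_control genotyped sample sizes.
#' @param maf_control control risk-allele frequency.
#' @param or_value allelic odds ratio.
#' @param alpha significance level (default 0.05).
#' @return Power in \[alpha, 1\].
#' @export
allelic_power <- function(n_case, n_control, maf_control, or_value,
                          alpha = 0.05) {
  stopifnot(n_case > 0, n_control > 0,
            maf_control > 0, maf_control < 1, or_value > 0,
            alpha > 0, alpha < 1)
  f1 <- case_frequency(maf_control, or_value)
  f0 <- maf_control
  pbar <- (n_case * f1 + n_control * f0) / (n_case + n_control)
  v <- pbar * (1 - pbar) * (1 / (2 * n_case) + 1 / (2 * n_control))
  ncp <- (f1 - f0)^2 / v
  crit <- qchisq(1 - alpha, df = 1)
  pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
}

#' Candidate-SNP association summary from individual genotypes
#'
#' Convenience wrapper producing, per SNP surviving the call-rate filter:
#' case/control allele frequencies, allelic chi-square p, trend-test p,
#' covariate-adjusted p, and the allelic OR with 95\% CI.
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param covariates covariate columns for the adjusted model (NULL to skip).
#' @param min_call_rate call-rate cutoff (default 0.8).
#' @param orient OR orientation passed to [allelic_or()].
#' @return A \code{stage_result} data frame, one row per SNP.
#' @export
replication_summary <- function(genotypes, covariates = c("sex", "age"),
                                min_call_rate = 0.8,
                                orient = c("risk", "case_enriched")) {
  orient <- match.arg(orient)
  genotypes <- call_rate_filter(genotypes, min_call_rate)
  snps <- .snp_cols(genotypes)
  rows <- lapply(snps, function(s) {
    tab <- allele_table(genotypes, s)
    or <- allelic_or(tab, orient = orient)
    chi <- allelic_chi2(tab)
    tr <- trend_test(genotype_counts(genotypes, s))
    padj <- if (is.null(covariates)) {
      NA_real_
    } else {
      adjusted_association(genotypes, s, covariates)$p_adjusted
    }
    data.frame(
      snp_id = s,
      maf_case = tab$a / (tab$a + tab$b),
      maf_control = tab$c / (tab$c + tab$d),
      p_allelic = chi$p,
      p_trend = tr$p,
      p_adjusted = padj,
      or_value = or$or,
      ci_low = or$ci_low,
      ci_high = or$ci_high,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("stage_result", "data.frame")
  out
}
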