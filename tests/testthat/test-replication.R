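test_that("call-rate filter keeps SNPs strictly above the cutoff", {
  geno <- cbind(
    full = c(0, 1, 2, 1, 0, 2, 1, 0, 1, 2),           # call rate 1.0
    at_cut = c(0, 1, 2, 1, 0, 2, 1, 0, NA, NA),       # exactly 0.8
    below = c(0, 1, 2, NA, NA, NA, NA, NA, NA, NA),   # 0.3
    above = c(0, 1, 2, 1, 0, 2, 1, 0, 1, NA)          # 0.9
  )
  g <- make_genotypes(geno, status = rep(c(1L, 0L), 5))
  out <- call_rate_filter(g, 0.8)
  expect_setequal(attr(out, "removed_snps"), c("at_cut", "below"))
  expect_true(all(c("full", "above") %in% names(out)))
  # brute-force call rates agree
  expect_equal(unname(attr(out, "call_rates")),
               c(1, 0.8, 0.3, 0.9))
  # no missing data: everything retained
  g0 <- make_genotypes(geno[, "full", drop = FALSE], rep(c(1L, 0L), 5))
  expect_length(attr(call_rate_filter(g0, 0.8), "removed_snps"), 0)
})

test_that("allele tables tally risk alleles with missing individuals dropped", {
  g <- make_genotypes(cbind(rs1 = c(2L, 1L, 0L, 1L, NA)),
                      status = c(1L, 1L, 0L, 0L, 1L))
  tab <- allele_table(g, "rs1")
  expect_equal(tab[c("a", "b", "c", "d")],
               list(a = 3, b = 1, c = 1, d = 3))
  # flipped orientation swaps the roles
  tab2 <- allele_table(g, "rs1", risk_allele = "other")
  expect_equal(tab2[c("a", "b", "c", "d")],
               list(a = 1, b = 3, c = 3, d = 1))
  # all homozygous other: zero risk alleles in cases
  g0 <- make_genotypes(cbind(rs1 = rep(0L, 4)), status = c(1L, 1L, 0L, 0L))
  expect_equal(allele_table(g0, "rs1")$a, 0)
  expect_error(allele_table(g, "rs9"), "unknown snp")

  # larger fixture: brute-force tally
  tr <- simulate_truth(3, seed = 61)
  gg <- simulate_genotypes(tr, 500, 500, missing_rate = 0.05, seed = 62)
  tt <- allele_table(gg, "snp000002")
  v <- gg$snp000002
  expect_equal(tt$a, sum(v[gg$status == 1], na.rm = TRUE))
  expect_equal(tt$d, sum(2 - v[gg$status == 0], na.rm = TRUE))
})

test_that("allelic OR and Woolf CI reproduce published validation values", {
  # frequencies 16.0% cases vs 13.2% controls, 1,091 cases vs 52,708 controls
  tab <- allele_table_from_freq(0.160, 1091, 0.132, 52708)
  or <- allelic_or(tab)
  expect_equal(round(or$or, 2), 1.25)
  # Woolf interval against the closed form, written out by hand
  se <- sqrt(1 / tab$a + 1 / tab$b + 1 / tab$c + 1 / tab$d)
  expect_equal(or$ci_low, exp(log(or$or) - qnorm(0.975) * se))
  expect_equal(or$ci_high, exp(log(or$or) + qnorm(0.975) * se))
  expect_equal(round(or$ci_low, 2), 1.12)
  # equal odds: OR = 1
  t1 <- allele_table_from_freq(0.2, 100, 0.2, 100)
  expect_equal(allelic_or(t1)$or, 1)
  # swapping alleles inverts OR and the CI
  t2 <- list(a = 30, b = 70, c = 20, d = 80)
  sw <- list(a = 70, b = 30, c = 80, d = 20)
  o2 <- allelic_or(t2); osw <- allelic_or(sw)
  expect_equal(osw$or, 1 / o2$or)
  expect_equal(osw$ci_low, 1 / o2$ci_high)
  expect_equal(osw$ci_high, 1 / o2$ci_low)
  # Haldane-Anscombe correction with an empty cell
  t0 <- list(a = 0, b = 50, c = 5, d = 45)
  expect_equal(allelic_or(t0)$or, (0.5 / 50.5) / (5.5 / 45.5))
  expect_error(allelic_or(list(a = 0, b = 0, c = 5, d = 45)), "margin")
  # case-enriched orientation always reports OR >= 1
  t3 <- list(a = 10, b = 90, c = 20, d = 80)
  oc <- allelic_or(t3, orient = "case_enriched")
  expect_gte(oc$or, 1)
  expect_true(oc$flipped)
  expect_equal(oc$or, 1 / allelic_or(t3)$or)
})

test_that("allelic chi-square equals the expected-counts oracle", {
  t0 <- allele_table_from_freq(0.25, 200, 0.25, 300)
  expect_equal(allelic_chi2(t0)$chi2, 0)
  expect_equal(allelic_chi2(t0)$p, 1)
  tab <- list(a = 20, b = 80, c = 10, d = 90)
  got <- allelic_chi2(tab)
  expect_equal(got$chi2, oracle_chi2_2x2(20, 80, 10, 90))
  expect_equal(got$chi2,
               unname(chisq.test(matrix(c(20, 80, 10, 90), 2, byrow = TRUE),
                                 correct = FALSE)$statistic))
  # doubling every cell doubles the statistic
  tab2 <- list(a = 40, b = 160, c = 20, d = 180)
  expect_equal(allelic_chi2(tab2)$chi2, 2 * got$chi2)
  expect_error(allelic_chi2(list(a = 0, b = 0, c = 0, d = 0)), "empty")
})

test_that("trend test matches reference and permutation oracles", {
  # identical genotype distributions: no trend
  flat <- matrix(c(30, 20, 10, 30, 20, 10), 2, byrow = TRUE)
  expect_equal(trend_test(flat)$z, 0)
  expect_equal(trend_test(flat)$p, 1)

  # agreement with the base-R Cochran-Armitage implementation
  cnt <- matrix(c(25, 40, 15, 45, 35, 8), 2, byrow = TRUE)
  got <- trend_test(cnt)
  ref <- stats::prop.trend.test(cnt[1, ], colSums(cnt), score = 0:2)
  expect_equal(got$chi2, unname(ref$statistic))
  expect_equal(got$p, ref$p.value)

  # permutation oracle; the asymptotic p sits slightly below the exact one
  # because the trend statistic lives on a lattice (no continuity correction)
  case <- c(160, 210, 130)
  ctrl <- c(180, 205, 115)
  genotype <- rep(0:2, times = case + ctrl)
  status <- unlist(mapply(function(a, b) c(rep(1L, a), rep(0L, b)),
                          case, ctrl))
  cnt2 <- matrix(c(case, ctrl), 2, byrow = TRUE)
  p_perm <- oracle_trend_permutation_p(genotype, status,
                                       n_perm = 2e4, seed = 9)
  expect_lt(abs(trend_test(cnt2)$p - p_perm), 0.02)

  # under HWE the trend and allelic chi-squares agree asymptotically
  tr <- simulate_truth(1, maf_sampler = function(n) rep(0.3, n),
                       causal = data.frame(index = 1, or = 1.4), seed = 71)
  gg <- simulate_genotypes(tr, 20000, 20000, seed = 72)
  chi_t <- trend_test(genotype_counts(gg, "snp000001"))$chi2
  chi_a <- allelic_chi2(allele_table(gg, "snp000001"))$chi2
  expect_equal(chi_t / chi_a, 1, tolerance = 0.02)
  expect_error(trend_test(matrix(c(5, 3, 1, 0, 0, 0), 2, byrow = TRUE)),
               "degenerate")
})

test_that("covariate-adjusted logistic association approximates the trend test", {
  tr <- simulate_truth(1, maf_sampler = function(n) rep(0.3, n),
                       causal = data.frame(index = 1, or = 1.3), seed = 81)
  gg <- simulate_genotypes(tr, 5000, 5000, seed = 82)
  adj <- adjusted_association(gg, "snp000001")
  tr_p <- trend_test(genotype_counts(gg, "snp000001"))$p
  expect_true(adj$converged)
  # with covariates independent of genotype and outcome the two p-values
  # estimate the same test
  expect_equal(log10(adj$p_adjusted), log10(tr_p), tolerance = 0.05)
  # degenerate genotype column is flagged, not an error
  g_const <- make_genotypes(cbind(rs1 = rep(1L, 40)),
                            status = rep(c(1L, 0L), 20))
  expect_false(adjusted_association(g_const, "rs1")$converged)
})

test_that("adjusted p-values are uniform under the null", {
  set.seed(91)
  pvals <- replicate(150, {
    g <- make_genotypes(cbind(rs1 = rbinom(120, 2, 0.3)),
                        status = rep(c(1L, 0L), 60),
                        sex = sample(1:2, 120, TRUE),
                        age = runif(120, 20, 60))
    adjusted_association(g, "rs1")$p_adjusted
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("Bonferroni threshold matches the 9-SNP correction", {
  got <- bonferroni_threshold(0.05, 9)
  expect_equal(got$threshold, 0.05 / 9)
  expect_equal(got$threshold_2sf, 0.0056)
  expect_equal(bonferroni_threshold(0.05, 1)$threshold, 0.05)
  expect_equal(bonferroni_threshold(0.01, 10)$threshold, 0.001)
})

test_that("inverse-variance meta-analysis pools log odds ratios", {
  # identical studies: same OR, SE shrunk by sqrt(2)
  s2 <- data.frame(or = c(1.5, 1.5), ci_low = c(1.2, 1.2),
                   ci_high = c(1.875, 1.875))
  m2 <- ivw_meta(s2)
  se1 <- (log(1.875) - log(1.2)) / (2 * qnorm(0.975))
  expect_equal(m2$or, 1.5)
  expect_equal(m2$se, se1 / sqrt(2))
  # single study: unchanged
  m1 <- ivw_meta(data.frame(or = 1.5, ci_low = 1.2, ci_high = 1.875))
  expect_equal(m1$or, 1.5)
  expect_equal(m1$ci_low, 1.2, tolerance = 1e-10)
  expect_equal(m1$ci_high, 1.875, tolerance = 1e-10)
  # beta/se input is equivalent to the CI input
  mb <- ivw_meta(data.frame(beta = log(c(1.5, 1.5)), se = c(se1, se1)))
  expect_equal(mb$or, m2$or)
  # the pooled OR lies between the component ORs
  mm <- ivw_meta(data.frame(or = c(1.28, 1.32), ci_low = c(1.08, 0.98),
                            ci_high = c(1.52, 1.78)))
  expect_gt(mm$or, 1.28)
  expect_lt(mm$or, 1.32)
  expect_error(ivw_meta(data.frame(beta = 0.1, se = 0)), "nonpositive")
})

test_that("analytic power behaves at its limits", {
  expect_equal(allelic_power(500, 500, 0.2, 1, alpha = 0.05), 0.05)
  expect_gt(allelic_power(1e6, 1e6, 0.2, 1.2), 0.999)
  # monotone in OR and in n
  expect_gt(allelic_power(500, 500, 0.2, 1.8),
            allelic_power(500, 500, 0.2, 1.3))
  expect_gt(allelic_power(2000, 2000, 0.2, 1.3),
            allelic_power(500, 500, 0.2, 1.3))
})

test_that("replication summary mirrors its component statistics", {
  tr <- simulate_truth(4, causal = data.frame(index = 2, or = 1.6), seed = 95)
  gg <- simulate_genotypes(tr, 800, 800, missing_rate = 0.02, seed = 96)
  res <- replication_summary(gg)
  expect_equal(res$snp_id, sprintf("snp%06d", 1:4))
  i <- 2
  tab <- allele_table(gg, "snp000002")
  expect_equal(res$maf_case[i], tab$a / (tab$a + tab$b))
  expect_equal(res$p_allelic[i], allelic_chi2(tab)$p)
  expect_equal(res$or_value[i], allelic_or(tab)$or)
  expect_true(all(res$ci_low <= res$or_value & res$or_value <= res$ci_high))
})
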