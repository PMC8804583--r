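test_that("frequency estimation is the intensity fraction", {
  expect_equal(estimate_frequency(120, 40), 0.75)
  expect_equal(estimate_frequency(0, 50), 0)
  expect_equal(estimate_frequency(100, 100), 0.5)
  expect_equal(estimate_frequency(c(1, 3), c(3, 1)), c(0.25, 0.75))
  expect_error(estimate_frequency(0, 0), "undefined frequency")
})

test_that("channel normalisation equalises per-array medians", {
  set.seed(1)
  fm <- matrix(runif(60, 0.1, 0.9), 20,
               dimnames = list(sprintf("s%02d", 1:20), NULL))
  pan <- make_panel(list(case_a = fm))
  # x == y everywhere: identity
  pan_eq <- pan
  pan_eq$x_raw <- pan_eq$y_raw
  expect_equal(normalize_channels(pan_eq), pan_eq)
  # x doubled: rescale factor exactly 0.5
  pan2 <- pan
  pan2$x_raw <- 2 * pan2$y_raw
  norm2 <- normalize_channels(pan2)
  expect_equal(norm2$x_raw, pan2$y_raw)
  # mixed panel: per-array medians match afterwards
  norm <- normalize_channels(pan)
  for (r in unique(norm$replicate)) {
    i <- norm$replicate == r
    expect_equal(median(norm$x_raw[i]), median(norm$y_raw[i]))
  }
  # an all-zero channel is an error naming the array
  pan0 <- pan
  pan0$x_raw[pan0$replicate == 2] <- 0
  expect_error(normalize_channels(pan0), "case_a/2")
})

test_that("replicate correlation filter drops decorrelated arrays only", {
  set.seed(42)
  n <- 300
  base <- runif(n, 0.1, 0.9)
  ids <- sprintf("s%03d", 1:n)
  good <- sapply(1:3, function(r) pmin(pmax(base + rnorm(n, 0, 0.005), 0), 1))
  rownames(good) <- ids
  pan <- make_panel(list(case_a = good))
  kept <- replicate_correlation_filter(pan, 0.99)
  expect_equal(nrow(attr(kept, "dropped_replicates")), 0)
  expect_equal(nrow(kept), nrow(pan))

  # shuffle replicate 2: its pairwise R with siblings collapses
  bad <- good
  bad[, 2] <- sample(bad[, 2])
  expect_lt(cor(bad[, 1], bad[, 2]), 0.2)  # brute-force check of the fixture
  pan_bad <- make_panel(list(case_a = bad))
  kept_bad <- replicate_correlation_filter(pan_bad, 0.99)
  expect_equal(attr(kept_bad, "dropped_replicates")$replicate, 2)
  expect_setequal(unique(kept_bad$replicate), c(1, 3))

  # two identical replicates: R = 1, nothing dropped
  two <- cbind(base, base)
  rownames(two) <- ids
  pan_two <- make_panel(list(case_a = two))
  expect_equal(nrow(attr(replicate_correlation_filter(pan_two, 0.99),
                         "dropped_replicates")), 0)
})

test_that("low-intensity filter removes the bottom fraction with tie rule", {
  ids <- sprintf("s%03d", 1:100)
  fm <- matrix(0.5, 100, 2, dimnames = list(ids, NULL))
  pan <- make_panel(list(case_a = fm))
  # distinct totals: removed set equals the brute-force bottom-k
  set.seed(3)
  scale <- runif(100, 0.5, 2)
  pan$x_raw <- pan$x_raw * scale[match(pan$snp_id, ids)]
  pan$y_raw <- pan$y_raw * scale[match(pan$snp_id, ids)]
  out <- low_intensity_filter(pan, 0.05)
  expect_length(attr(out, "removed_snps"), 5)
  tot <- tapply(pan$x_raw + pan$y_raw, pan$snp_id, sum)
  expect_setequal(attr(out, "removed_snps"),
                  names(sort(tot))[1:5])
  # all totals equal: lexicographically smallest ids go
  pan_eq <- make_panel(list(case_a = fm))
  out_eq <- low_intensity_filter(pan_eq, 0.05)
  expect_equal(attr(out_eq, "removed_snps"), ids[1:5])
})

test_that("divergence filter uses a strict span cutoff per pool", {
  tab <- data.frame(
    snp_id = c("a", "b", "c"),
    pool_id = "p1", group = "case",
    f_hat = c(0.13, 0.11, 0.125),
    f_span = c(0.07, 0.02, 0.05),
    stringsAsFactors = FALSE
  )
  out <- divergence_filter(tab, 0.05)
  expect_equal(attr(out, "removed_snps"), "a")   # span 0.07 > 0.05
  expect_setequal(out$snp_id, c("b", "c"))       # 0.05 is kept (strict >)
})

test_that("MAF filter folds control frequency and is strict at the cutoff", {
  tab <- data.frame(
    snp_id = rep(c("a", "b", "c", "d"), each = 2),
    pool_id = rep(c("ctrl1", "ctrl2"), 4),
    group = "control",
    f_hat = c(0.005, 0.005,   # MAF 0.005 -> removed
              0.995, 0.995,   # folded MAF 0.005 -> removed
              0.010, 0.010,   # exactly the cutoff -> kept
              0.30, 0.32),
    f_span = 0,
    stringsAsFactors = FALSE
  )
  out <- maf_filter(tab, 0.01)
  expect_setequal(attr(out, "removed_snps"), c("a", "b"))
  expect_setequal(unique(out$snp_id), c("c", "d"))
})

test_that("the QC cascade matches an independent brute-force oracle", {
  # panel with one shuffled replicate, some rare SNPs and uneven intensities
  tr <- simulate_truth(
    400,
    maf_sampler = function(n) c(rep(0.004, 6), runif(n - 6, 0.05, 0.5)),
    seed = 21
  )
  des <- pool_design(sd_array = 0.012, gain_ratio = 1, bad_array_rate = 0)
  pan <- simulate_pool_intensities(tr, des, seed = 22)
  # corrupt one array by hand (shuffle its frequencies)
  set.seed(23)
  i <- which(pan$pool_id == "control_b2" & pan$replicate == 3)
  f <- estimate_frequency(pan$x_raw[i], pan$y_raw[i])
  f_shuf <- sample(f)
  tot <- pan$x_raw[i] + pan$y_raw[i]
  pan$x_raw[i] <- tot * f_shuf
  pan$y_raw[i] <- tot * (1 - f_shuf)

  cfg <- qc_config()
  ft <- pool_frequencies(pan, cfg)
  expect_equal(attr(ft, "dropped_replicates")$pool_id, "control_b2")
  oracle <- oracle_qc_survivors(normalize_channels(pan))
  expect_setequal(unique(ft$snp_id), oracle)
  # rare SNPs were among the removals
  expect_gt(length(attr(ft, "removed_snps")$low_maf), 0)
})

test_that("filters only remove and the downstream stages are idempotent", {
  tr <- simulate_truth(200, seed = 31)
  des <- pool_design(sd_array = 0.01, bad_array_rate = 0)
  pan <- normalize_channels(simulate_pool_intensities(tr, des, seed = 32))
  kept <- replicate_correlation_filter(pan, 0.99)
  # surviving rows are untouched
  expect_true(all(paste(kept$snp_id, kept$pool_id, kept$replicate) %in%
                    paste(pan$snp_id, pan$pool_id, pan$replicate)))
  merged <- merge(kept, pan, by = c("snp_id", "pool_id", "replicate"))
  expect_equal(merged$x_raw.x, merged$x_raw.y)
  # correlation, divergence and MAF filters are idempotent
  kept2 <- replicate_correlation_filter(kept, 0.99)
  expect_equal(nrow(attr(kept2, "dropped_replicates")), 0)
  ft <- pool_frequencies(pan)
  tab <- as.data.frame(ft)
  tab$f_span <- 0
  expect_length(attr(divergence_filter(tab, 0.05), "removed_snps"), 0)
  expect_length(attr(maf_filter(tab, 0.01), "removed_snps"), 0)
})

test_that("bias report recovers the gain-induced overestimation", {
  # single SNP arithmetic
  tab <- data.frame(snp_id = "rs1", pool_id = "p", group = "control",
                    f_hat = 0.07, stringsAsFactors = FALSE)
  truth <- data.frame(snp_id = "rs1", f_control = 0.05, f_case = 0.05,
                      stringsAsFactors = FALSE)
  rep1 <- frequency_bias_report(tab, truth)
  expect_equal(rep1$error, 0.02)
  expect_error(frequency_bias_report(
    data.frame(snp_id = "rsX", pool_id = "p", group = "control",
               f_hat = 0.1), truth), "missing from truth")

  # unbiased when gain = 1 and noise = 0 (raw intensity fractions; channel
  # median-matching itself adds a small panel-size-dependent wobble)
  tr <- simulate_truth(300, seed = 41)
  des <- pool_design(sd_array = 0, gain_ratio = 1, bad_array_rate = 0)
  pan <- simulate_pool_intensities(tr, des, seed = 42)
  f0 <- estimate_frequency(pan$x_raw, pan$y_raw)
  key0 <- paste(pan$snp_id, pan$pool_id)
  tab0 <- data.frame(
    snp_id = tapply(pan$snp_id, key0, `[`, 1),
    pool_id = tapply(pan$pool_id, key0, `[`, 1),
    group = tapply(pan$group, key0, `[`, 1),
    f_hat = as.numeric(tapply(f0, key0, mean)),
    stringsAsFactors = FALSE
  )
  expect_lt(abs(attr(frequency_bias_report(tab0, tr), "mean_bias")), 0.003)

  # raw (un-normalised) estimates at f = 0.5, g = 1.1: bias ~ +0.0238
  tr5 <- simulate_truth(200, maf_sampler = function(n) rep(0.5, n), seed = 43)
  des5 <- pool_design(n_cases = 50000, n_controls = 50000, sd_array = 0,
                      gain_ratio = 1.1, bad_array_rate = 0)
  pan5 <- simulate_pool_intensities(tr5, des5, seed = 44)
  f <- estimate_frequency(pan5$x_raw, pan5$y_raw)
  key <- paste(pan5$snp_id, pan5$pool_id)
  tab5 <- data.frame(
    snp_id = tapply(pan5$snp_id, key, `[`, 1),
    pool_id = tapply(pan5$pool_id, key, `[`, 1),
    group = tapply(pan5$group, key, `[`, 1),
    f_hat = as.numeric(tapply(f, key, mean)),
    stringsAsFactors = FALSE
  )
  bias <- attr(frequency_bias_report(tab5, tr5), "mean_bias")
  expect_equal(bias, 0.55 / 1.05 - 0.5, tolerance = 2e-3)
})
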