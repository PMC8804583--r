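# Independent brute-force oracles. These deliberately re-derive each
# quantity from first principles, without calling the package functions
# they are used to check.

# textbook two-proportion z test on allele counts
oracle_two_prop_z <- function(f1, f0, n1, n0) {
  pbar <- (f1 + f0) / 2
  (f1 - f0) / sqrt(pbar * (1 - pbar) * (1 / (2 * n1) + 1 / (2 * n0)))
}

# Pearson chi-square of a 2x2 table by explicit expected counts
oracle_chi2_2x2 <- function(a, b, c, d) {
  obs <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  n <- sum(obs)
  expd <- outer(rowSums(obs), colSums(obs)) / n
  sum((obs - expd)^2 / expd)
}

# Monte-Carlo permutation p-value for the Cochran-Armitage trend test:
# permute case labels over individuals, recompute the trend statistic
oracle_trend_permutation_p <- function(genotype, status, n_perm, seed) {
  set.seed(seed)
  stat <- function(st) {
    # trend statistic recomputed from scratch per permutation
    n <- length(st)
    r <- sum(st)
    nj <- tabulate(genotype + 1L, nbins = 3L)
    s <- 0:2
    u <- sum(s * tabulate(genotype[st == 1] + 1L, nbins = 3L)) -
      r * sum(s * nj) / n
    v <- r * (n - r) / n^3 * (n * sum(s^2 * nj) - sum(s * nj)^2)
    u^2 / v
  }
  obs <- stat(status)
  perm <- replicate(n_perm, stat(sample(status)))
  mean(perm >= obs - 1e-12)
}

# brute-force re-implementation of the four pool-QC rules, written as the
# rules are stated rather than as the package implements them
oracle_qc_survivors <- function(panel, r_min = 0.99, low_frac = 0.05,
                                max_div = 0.05, maf_min = 0.01) {
  panel$f <- panel$x_raw / (panel$x_raw + panel$y_raw)
  # rule 1: drop arrays decorrelated from pool siblings (greedy worst-first)
  repeat {
    drop_one <- NULL
    for (p in unique(panel$pool_id)) {
      sub <- panel[panel$pool_id == p, ]
      reps <- sort(unique(sub$replicate))
      if (length(reps) < 2) next
      fm <- sapply(reps, function(r) {
        s <- sub[sub$replicate == r, ]
        s$f[order(s$snp_id)]
      })
      mean_r <- sapply(seq_along(reps), function(i) {
        mean(sapply(setdiff(seq_along(reps), i), function(j) {
          cor(fm[, i], fm[, j])
        }))
      })
      if (min(mean_r) < r_min) {
        drop_one <- c(p, reps[which.min(mean_r)])
        break
      }
    }
    if (is.null(drop_one)) break
    panel <- panel[!(panel$pool_id == drop_one[1] &
                       panel$replicate == as.integer(drop_one[2])), ]
  }
  # rule 2: lowest-intensity fraction
  tot <- tapply(panel$x_raw + panel$y_raw, panel$snp_id, sum)
  o <- order(tot, names(tot))  # ties broken lexicographically
  ranked <- names(tot)[o]
  low <- ranked[seq_len(floor(low_frac * length(tot)))]
  panel <- panel[!(panel$snp_id %in% low), ]
  # rule 3: replicate divergence within any pool
  div_bad <- c()
  for (s in unique(panel$snp_id)) {
    for (p in unique(panel$pool_id)) {
      fr <- panel$f[panel$snp_id == s & panel$pool_id == p]
      if (length(fr) >= 1 && diff(range(fr)) > max_div) div_bad <- c(div_bad, s)
    }
  }
  panel <- panel[!(panel$snp_id %in% div_bad), ]
  # rule 4: control MAF
  maf_bad <- c()
  for (s in unique(panel$snp_id)) {
    sub <- panel[panel$snp_id == s & panel$group == "control", ]
    fbar <- mean(tapply(sub$f, sub$pool_id, mean))
    if (min(fbar, 1 - fbar) < maf_min) maf_bad <- c(maf_bad, s)
  }
  panel <- panel[!(panel$snp_id %in% maf_bad), ]
  sort(unique(panel$snp_id))
}

# brute-force maximisation of the two-locus haplotype likelihood over a
# 3-simplex grid: coarse pass at `step_coarse`, then a fine pass at
# `step_fine` in a box around the coarse optimum
oracle_hap_grid <- function(counts, step_coarse = 0.01, step_fine = 1e-3,
                            box = 0.02) {
  loglik <- function(h1, h2, h3) {
    h4 <- 1 - h1 - h2 - h3
    p11 <- h1^2; p12 <- 2 * h1 * h2; p13 <- h2^2
    p21 <- 2 * h1 * h3; p22 <- 2 * h1 * h4 + 2 * h2 * h3; p23 <- 2 * h2 * h4
    p31 <- h3^2; p32 <- 2 * h3 * h4; p33 <- h4^2
    # genotype table rows/cols are copies of A/B: row 3 = 2 copies of A
    p <- cbind(p33, p32, p31, p23, p22, p21, p13, p12, p11)
    cts <- c(counts[1, 1], counts[1, 2], counts[1, 3],
             counts[2, 1], counts[2, 2], counts[2, 3],
             counts[3, 1], counts[3, 2], counts[3, 3])
    lp <- log(pmax(p, 1e-300))
    as.numeric(lp %*% cts)
  }
  search <- function(g1, g2, g3) {
    grid <- expand.grid(h1 = g1, h2 = g2, h3 = g3)
    grid <- grid[grid$h1 + grid$h2 + grid$h3 <= 1 + 1e-12, ]
    ll <- loglik(grid$h1, grid$h2, grid$h3)
    list(h = unlist(grid[which.max(ll), ]), loglik = max(ll))
  }
  g <- seq(0, 1, by = step_coarse)
  coarse <- search(g, g, g)
  fine <- lapply(coarse$h, function(x) {
    seq(max(0, x - box), min(1, x + box), by = step_fine)
  })
  best <- search(fine$h1, fine$h2, fine$h3)
  h <- c(best$h, 1 - sum(best$h))
  names(h) <- c("AB", "Ab", "aB", "ab")
  list(freqs = h, loglik = best$loglik)
}

# small deterministic genotype data frame built by hand
make_genotypes <- function(geno, status, sex = NULL, age = NULL) {
  n <- nrow(geno)
  out <- data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    status = status,
    sex = if (is.null(sex)) rep(1L, n) else sex,
    age = if (is.null(age)) rep(30, n) else age,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(geno))
  class(out) <- c("genotype_matrix", "data.frame")
  out
}

# hand-built intensity panel: freqs matrix is SNP x replicate per pool;
# intensity fixed so estimate_frequency returns the freqs exactly
make_panel <- function(freq_list, groups = NULL, intensity = 1000) {
  # freq_list: named list pool_id -> matrix [snp, replicate]
  rows <- list()
  for (p in names(freq_list)) {
    fm <- freq_list[[p]]
    grp <- if (is.null(groups)) {
      if (grepl("case", p)) "case" else "control"
    } else {
      groups[[p]]
    }
    for (r in seq_len(ncol(fm))) {
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = rownames(fm),
        chrom = 1L,
        pos = seq_len(nrow(fm)),
        pool_id = p,
        group = grp,
        batch = 1L,
        replicate = r,
        x_raw = intensity * fm[, r],
        y_raw = intensity * (1 - fm[, r]),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("intensity_panel", "data.frame")
  out
}
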