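#' Quality-control configuration for pooled arrays
#'
#' Thresholds of the four-stage QC cascade applied to pooled replicate
#' arrays, with the study defaults: replicate arrays must correlate at
#' R >= 0.99 with their siblings; the 5\% of SNPs with the lowest total
#' hybridisation intensity are removed; SNPs whose replicate frequency
#' estimates span more than 5\% are removed; SNPs with control-pool
#' MAF below 1\% are removed.
#'
#' @param r_min replicate Pearson-correlation cutoff (default 0.99).
#' @param low_intensity_fraction fraction of lowest-intensity SNPs removed
#'   (default 0.05).
#' @param max_divergence maximum allowed replicate frequency span
#'   (default 0.05, strict inequality).
#' @param maf_min minimum control-pool MAF (default 0.01, strict inequality).
#' @return A \code{qc_config} list.
#' @export
qc_config <- function(r_min = 0.99, low_intensity_fraction = 0.05,
                      max_divergence = 0.05, maf_min = 0.01) {
  stopifnot(
    r_min > 0, r_min <= 1,
    low_intensity_fraction > 0, low_intensity_fraction <= 1,
    max_divergence > 0, max_divergence <= 1,
    maf_min > 0, maf_min <= 1
  )
  structure(list(r_min = r_min,
                 low_intensity_fraction = low_intensity_fraction,
                 max_divergence = max_divergence,
                 maf_min = maf_min),
            class = "qc_config")
}

#' Allele frequency from raw channel intensities
#'
#' The pooled estimate of the Cy3-labelled allele's frequency is the
#' intensity fraction \eqn{f = x_{raw} / (x_{raw} + y_{raw})}.
#'
#' @param x_raw,y_raw nonnegative channel intensities (vectorised).
#' @return Frequencies in \[0, 1\].
#' @export
estimate_frequency <- function(x_raw, y_raw) {
  stopifnot(all(x_raw >= 0), all(y_raw >= 0))
  tot <- x_raw + y_raw
  if (any(tot <= 0)) {
    stop("undefined frequency: x_raw + y_raw must be > 0")
  }
  x_raw / tot
}

.array_key <- function(panel) paste(panel$pool_id, panel$replicate, sep = "/")

#' Normalise the two channels of each replicate array
#'
#' Rescales the x (Cy3) channel of every replicate array by
#' (median y) / (median x) so that the two channel medians match; the y
#' channel is unchanged and row order is preserved. This removes a global
#' multiplicative gain imbalance between the dyes on each array.
#'
#' @param panel an \code{intensity_panel}.
#' @return The panel with rescaled \code{x_raw}.
#' @export
normalize_channels <- function(panel) {
  stopifnot(nrow(panel) > 0)
  key <- .array_key(panel)
  for (a in unique(key)) {
    i <- key == a
    mx <- median(panel$x_raw[i])
    my <- median(panel$y_raw[i])
    if (mx <= 0 || my <= 0) {
      stop("array ", a, " has an all-zero (or zero-median) channel")
    }
    panel$x_raw[i] <- panel$x_raw[i] * (my / mx)
  }
  panel
}

#' Drop replicate arrays that decorrelate from their siblings
#'
#' Within each pool, Pearson correlations of the per-SNP frequency estimates
#' are computed for every pair of replicate arrays. Replicates are removed
#' greedily: while any replicate's mean pairwise correlation with the others
#' falls below \code{r_min} and more than one replicate remains, the
#' replicate with the lowest mean correlation is discarded and the
#' correlations recomputed. A pool is never reduced below one replicate.
#'
#' @param panel an \code{intensity_panel} (normalised).
#' @param r_min correlation cutoff (default 0.99).
#' @return The filtered panel, with attribute \code{"dropped_replicates"}: a
#'   data frame of (pool_id, replicate, mean_r) for each discarded array.
#' @export
replicate_correlation_filter <- function(panel, r_min = 0.99) {
  f <- estimate_frequency(panel$x_raw, panel$y_raw)
  dropped <- list()
  keep <- rep(TRUE, nrow(panel))
  for (p in unique(panel$pool_id)) {
    in_pool <- panel$pool_id == p
    reps <- sort(unique(panel$replicate[in_pool]))
    if (length(reps) < 2L) next
    # SNP x replicate matrix of frequencies for this pool
    fm <- vapply(reps, function(r) {
      i <- in_pool & panel$replicate == r
      f[i][order(panel$snp_id[i])]
    }, numeric(sum(in_pool & panel$replicate == reps[1])))
    colnames(fm) <- as.character(reps)
    active <- rep(TRUE, length(reps))
    repeat {
      if (sum(active) < 2L) break
      cm <- cor(fm[, active, drop = FALSE])
      mean_r <- (rowSums(cm) - 1) / (sum(active) - 1)
      if (all(mean_r >= r_min)) break
      worst <- which.min(mean_r)
      worst_rep <- reps[active][worst]
      dropped[[length(dropped) + 1L]] <- data.frame(
        pool_id = p, replicate = worst_rep, mean_r = mean_r[worst],
        stringsAsFactors = FALSE
      )
      active[which(active)[worst]] <- FALSE
      keep[in_pool & panel$replicate == worst_rep] <- FALSE
    }
    if (!any(active)) stop("pool ", p, " left with zero replicates")
  }
  out <- panel[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_replicates") <- if (length(dropped)) {
    do.call(rbind, dropped)
  } else {
    data.frame(pool_id = character(), replicate = integer(),
               mean_r = numeric(), stringsAsFactors = FALSE)
  }
  class(out) <- class(panel)
  out
}

#' Remove the lowest-intensity SNPs
#'
#' Ranks SNPs by their total hybridisation signal, the sum of
#' \code{x_raw + y_raw} over all retained replicate arrays, and removes the
#' \code{floor(fraction * n_snps)} lowest-ranked SNPs. Ties are broken by
#' lexicographic \code{snp_id} order (smaller ids removed first) so the
#' result is reproducible.
#'
#' @param panel an \code{intensity_panel}.
#' @param fraction fraction of SNPs to remove (default 0.05).
#' @return The filtered panel with attribute \code{"removed_snps"} (character
#'   vector of removed snp_ids).
#' @export
low_intensity_filter <- function(panel, fraction = 0.05) {
  stopifnot(fraction > 0, fraction < 1)
  tot <- tapply(panel$x_raw + panel$y_raw, panel$snp_id, sum)
  ids <- names(tot)
  o <- order(tot, ids)  # ascending intensity, snp_id breaks ties
  n_remove <- floor(fraction * length(ids))
  removed <- ids[o[seq_len(n_remove)]]
  out <- panel[!(panel$snp_id %in% removed), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed_snps") <- removed
  class(out) <- class(panel)
  out
}

# per-(snp, pool) replicate frequency summaries
.pool_replicate_stats <- function(panel) {
  f <- estimate_frequency(panel$x_raw, panel$y_raw)
  key <- interaction(panel$snp_id, panel$pool_id, drop = TRUE)
  agg <- data.frame(
    snp_id = tapply(panel$snp_id, key, `[`, 1L),
    pool_id = tapply(panel$pool_id, key, `[`, 1L),
    group = tapply(panel$group, key, `[`, 1L),
    batch = tapply(panel$batch, key, `[`, 1L),
    f_hat = as.numeric(tapply(f, key, mean)),
    f_span = as.numeric(tapply(f, key, function(v) max(v) - min(v))),
    f_var = as.numeric(tapply(f, key, function(v) {
      if (length(v) > 1L) var(v) else 0
    })),
    n_reps = as.integer(tapply(f, key, length)),
    total_intensity = as.numeric(tapply(panel$x_raw + panel$y_raw, key, sum)),
    stringsAsFactors = FALSE
  )
  rownames(agg) <- NULL
  agg
}

#' Remove SNPs with divergent replicate frequencies
#'
#' A SNP is removed when, in any single pool, the span of its replicate
#' frequency estimates (max minus min) exceeds \code{max_divergence}; the
#' comparison is strict, so a span of exactly the cutoff is kept.
#'
#' @param freq_table per-(snp, pool) replicate summary as produced internally
#'   by [pool_frequencies()]; must contain \code{snp_id} and \code{f_span}.
#' @param max_divergence span cutoff (default 0.05).
#' @return The filtered table with attribute \code{"removed_snps"}.
#' @export
divergence_filter <- function(freq_table, max_divergence = 0.05) {
  bad <- unique(freq_table$snp_id[freq_table$f_span > max_divergence])
  out <- freq_table[!(freq_table$snp_id %in% bad), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed_snps") <- sort(bad)
  out
}

#' Remove SNPs rare in the control pools
#'
#' Averages the estimated frequency across control pools, folds it to a
#' minor allele frequency \code{MAF = min(f, 1 - f)}, and removes SNPs with
#' MAF strictly below \code{maf_min}.
#'
#' @param freq_table per-(snp, pool) summary with \code{group} labels.
#' @param maf_min MAF cutoff (default 0.01).
#' @return The filtered table with attribute \code{"removed_snps"}.
#' @export
maf_filter <- function(freq_table, maf_min = 0.01) {
  ctrl <- freq_table[freq_table$group == "control", , drop = FALSE]
  if (nrow(ctrl) == 0) stop("no control pools present")
  fbar <- tapply(ctrl$f_hat, ctrl$snp_id, mean)
  maf <- pmin(fbar, 1 - fbar)
  bad <- names(maf)[maf < maf_min]
  out <- freq_table[!(freq_table$snp_id %in% bad), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed_snps") <- sort(bad)
  out
}

#' Run the full QC cascade and estimate per-pool frequencies
#'
#' Applies, in order: the replicate-correlation filter, the low-intensity
#' filter, the replicate-divergence filter and the control-MAF filter, then
#' averages the surviving replicate frequencies within each pool. The
#' returned table also carries the replicate-mean squared standard error
#' (\code{se2 = f_var / n_reps}) needed by the pooled association statistic.
#'
#' @param panel an \code{intensity_panel}; it is channel-normalised first
#'   (idempotent if already normalised).
#' @param config a [qc_config()].
#' @return A \code{pool_freq_table} data frame with columns \code{snp_id},
#'   \code{pool_id}, \code{group}, \code{batch}, \code{f_hat}, \code{se2},
#'   \code{n_reps}, \code{total_intensity}, and a \code{qc_log} attribute
#'   recording every removal (stage, unit, reason) plus
#'   \code{dropped_replicates} and \code{removed_snps} attributes.
#' @export
pool_frequencies <- function(panel, config = qc_config()) {
  panel <- normalize_channels(panel)
  panel <- replicate_correlation_filter(panel, config$r_min)
  dropped_reps <- attr(panel, "dropped_replicates")
  panel <- low_intensity_filter(panel, config$low_intensity_fraction)
  rm_low <- attr(panel, "removed_snps")

  tab <- .pool_replicate_stats(panel)
  tab <- divergence_filter(tab, config$max_divergence)
  rm_div <- attr(tab, "removed_snps")
  tab <- maf_filter(tab, config$maf_min)
  rm_maf <- attr(tab, "removed_snps")

  tab$se2 <- tab$f_var / tab$n_reps
  out <- tab[order(tab$snp_id, tab$pool_id),
             c("snp_id", "pool_id", "group", "batch", "f_hat", "se2",
               "n_reps", "total_intensity")]
  rownames(out) <- NULL

  log_df <- rbind(
    if (nrow(dropped_reps)) {
      data.frame(stage = "replicate_correlation",
                 unit = paste0(dropped_reps$pool_id, "/rep",
                               dropped_reps$replicate),
                 reason = sprintf("mean pairwise R %.4f < %.2f",
                                  dropped_reps$mean_r, config$r_min),
                 stringsAsFactors = FALSE)
    },
    if (length(rm_low)) {
      data.frame(stage = "low_intensity", unit = rm_low,
                 reason = sprintf("total intensity in lowest %.0f%%",
                                  100 * config$low_intensity_fraction),
                 stringsAsFactors = FALSE)
    },
    if (length(rm_div)) {
      data.frame(stage = "divergence", unit = rm_div,
                 reason = sprintf("replicate span > %.2f",
                                  config$max_divergence),
                 stringsAsFactors = FALSE)
    },
    if (length(rm_maf)) {
      data.frame(stage = "low_maf", unit = rm_maf,
                 reason = sprintf("control MAF < %.2f", config$maf_min),
                 stringsAsFactors = FALSE)
    }
  )
  attr(out, "qc_log") <- if (is.null(log_df)) {
    data.frame(stage = character(), unit = character(), reason = character(),
               stringsAsFactors = FALSE)
  } else {
    log_df
  }
  attr(out, "dropped_replicates") <- dropped_reps
  attr(out, "removed_snps") <- list(low_intensity = rm_low,
                                    divergence = rm_div, low_maf = rm_maf)
  class(out) <- c("pool_freq_table", "data.frame")
  out
}

#' Compare estimated pool frequencies with the simulated truth
#'
#' Reports the signed estimation error of the case- and control-pool
#' frequency estimates against the generating frequencies, and the mean bias.
#' With a channel gain imbalance \eqn{g} the intensity-fraction estimator has
#' expectation \eqn{f g / (f g + 1 - f)}, so pooled estimates overestimate
#' the Cy3 allele frequency whenever \eqn{g > 1} — unless the channels were
#' normalised first.
#'
#' @param freq_table a \code{pool_freq_table}.
#' @param truth a \code{truth_panel}.
#' @return A data frame (snp_id, pool_id, f_hat, f_true, error) with the
#'   mean bias attached as attribute \code{"mean_bias"}.
#' @export
frequency_bias_report <- function(freq_table, truth) {
  if (!all(freq_table$snp_id %in% truth$snp_id)) {
    stop("snp ids in freq_table missing from truth panel")
  }
  i <- match(freq_table$snp_id, truth$snp_id)
  f_true <- ifelse(freq_table$group == "case",
                   truth$f_case[i], truth$f_control[i])
  out <- data.frame(
    snp_id = freq_table$snp_id,
    pool_id = freq_table$pool_id,
    f_hat = freq_table$f_hat,
    f_true = f_true,
    error = freq_table$f_hat - f_true,
    stringsAsFactors = FALSE
  )
  attr(out, "mean_bias") <- mean(out$error)
  out
}
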