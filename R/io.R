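#' Write / read an intensity panel as TSV
#'
#' Columns: snp_id, chrom, pos, pool_id, group, batch, replicate, x_raw,
#' y_raw.
#'
#' @param panel an \code{intensity_panel}.
#' @param path output path.
#' @export
write_intensity_panel <- function(panel, path) {
  write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_intensity_panel
#' @return \code{read_intensity_panel} returns an \code{intensity_panel}.
#' @export
read_intensity_panel <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp_id", "pool_id", "group", "batch", "replicate",
            "x_raw", "y_raw")
  missing <- setdiff(need, names(out))
  if (length(missing)) {
    stop("intensity table missing columns: ", paste(missing, collapse = ", "))
  }
  class(out) <- c("intensity_panel", "data.frame")
  out
}

#' Write a genotype matrix as TSV with a PLINK-style .map sidecar
#'
#' The TSV has one row per sample (columns sample_id, status, sex, age, then
#' one 0/1/2 column per SNP, missing as NA); the sidecar
#' \code{<path>.map} holds (chrom, snp_id, cm, pos) when a map is attached.
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param path output path.
#' @export
write_genotype_table <- function(genotypes, path) {
  write.table(as.data.frame(genotypes), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  map <- attr(genotypes, "map")
  if (!is.null(map)) {
    write.table(map, paste0(path, ".map"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read and validate a genotype table
#'
#' Validates that every genotype entry is 0, 1, 2 or NA, naming the first
#' offending line otherwise, and records per-SNP call rates. A
#' \code{<path>.map} sidecar is attached as the \code{"map"} attribute when
#' present.
#'
#' @param path TSV path written by [write_genotype_table()].
#' @return A \code{genotype_matrix} with attribute \code{"call_rates"}.
#' @export
read_genotype_table <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "status")
  missing <- setdiff(need, names(out))
  if (length(missing)) {
    stop("genotype table missing columns: ", paste(missing, collapse = ", "))
  }
  snps <- setdiff(names(out), c("sample_id", "status", "sex", "age"))
  for (s in snps) {
    v <- out[[s]]
    bad <- which(!is.na(v) & !(v %in% 0:2))
    if (length(bad)) {
      stop(sprintf("invalid genotype code %s at line %d (snp %s)",
                   v[bad[1]], bad[1] + 1L, s))  # +1 for the header line
    }
    out[[s]] <- as.integer(v)
  }
  map_path <- paste0(path, ".map")
  if (file.exists(map_path)) {
    map <- read.delim(map_path, header = FALSE, stringsAsFactors = FALSE)
    names(map) <- c("chrom", "snp_id", "cm", "pos")
    attr(out, "map") <- map
  }
  attr(out, "call_rates") <-
    vapply(setNames(snps, snps),
           function(s) mean(!is.na(out[[s]])), numeric(1))
  class(out) <- c("genotype_matrix", "data.frame")
  out
}

#' Write a pool frequency table with its QC log
#'
#' @param freq_table a \code{pool_freq_table}.
#' @param path output TSV path; the QC log (one line per removal) is written
#'   alongside as \code{<path>.qclog}.
#' @export
write_pool_frequencies <- function(freq_table, path) {
  write.table(as.data.frame(freq_table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  qc_log <- attr(freq_table, "qc_log")
  if (!is.null(qc_log)) {
    writeLines(sprintf("%s\t%s\t%s", qc_log$stage, qc_log$unit,
                       qc_log$reason),
               paste0(path, ".qclog"))
  }
  invisible(path)
}

#' Render numbers the way association reports print them
#'
#' Frequencies to 4 decimals, odds ratios to 2 decimals, p-values in
#' scientific notation with 3 significant figures — the fixed precisions
#' that make two reports diffable.
#'
#' @param x numeric vector.
#' @return Character vector.
#' @name render
NULL

#' @rdname render
#' @export
render_freq <- function(x) sprintf("%.4f", x)

#' @rdname render
#' @export
render_or <- function(x) sprintf("%.2f", x)

#' @rdname render
#' @export
render_p <- function(x) {
  out <- sprintf("%.2e", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write a stage result as a fixed-precision TSV report
#'
#' Column order is deterministic and floats are rendered with the fixed
#' precisions of [render_freq()], [render_or()] and [render_p()], so reports
#' from the same configuration and seed are byte-identical.
#'
#' @param results a \code{stage_result} (or any data frame with a subset of
#'   its columns).
#' @param path output path.
#' @export
write_report <- function(results, path) {
  out <- results
  for (col in intersect(c("maf_case", "maf_control"), names(out))) {
    out[[col]] <- render_freq(out[[col]])
  }
  for (col in intersect(c("or_value", "ci_low", "ci_high"), names(out))) {
    out[[col]] <- render_or(out[[col]])
  }
  for (col in intersect(c("p_allelic", "p_trend", "p_adjusted", "p_raw",
                          "p_gc"), names(out))) {
    out[[col]] <- render_p(out[[col]])
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  write.table(as.data.frame(out), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' All analysis thresholds in one place, with the study defaults: QC cutoffs
#' (R >= 0.99, lowest 5\% intensity, 5\% replicate divergence, 1\% control
#' MAF), genotyping call rate > 0.8, 20,000 SNPs for the genomic-control
#' median, and alpha = 0.05. Every stochastic step takes a seed derived from
#' the single run seed.
#'
#' @param seed run seed.
#' @return A nested list; serialisable to YAML/JSON.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    qc = list(r_min = 0.99, low_intensity_fraction = 0.05,
              max_divergence = 0.05, maf_min = 0.01),
    assoc = list(n_random = 20000L, alpha = 0.05),
    replication = list(min_call_rate = 0.8, alpha = 0.05),
    design = list(n_cases = c(331L, 176L), n_controls = c(145L, 149L),
                  replicates = 3L, sd_array = 0.015, gain_ratio = 1.05,
                  bad_array_rate = 0, stratification_delta = 0)
  )
}

#' Read a run configuration from YAML or JSON
#'
#' Values present in the file override the defaults of [default_config()].
#'
#' @param path file path ending in .yaml/.yml or .json.
#' @return The merged configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("the jsonlite package is required to read JSON configs")
    }
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  base <- default_config(seed = if (!is.null(cfg$seed)) cfg$seed else 1L)
  merge_list <- function(a, b) {
    for (k in names(b)) {
      a[[k]] <- if (is.list(a[[k]]) && is.list(b[[k]])) {
        merge_list(a[[k]], b[[k]])
      } else {
        b[[k]]
      }
    }
    a
  }
  merge_list(base, cfg)
}
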