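#' Position weight matrix for splicing-enhancer motif scanning
#'
#' @param weights numeric matrix with rows A, C, G, T and one column per
#'   motif position.
#' @param name motif name (e.g. \code{"SC35"}).
#' @param threshold minimum reported score; 2.383 is the conventional SC35
#'   cutoff of exonic-splicing-enhancer prediction servers.
#' @return A \code{motif_matrix} object.
#' @export
motif_matrix <- function(weights, name = "motif", threshold = 2.383) {
  weights <- as.matrix(weights)
  stopifnot(nrow(weights) == 4, ncol(weights) >= 1)
  if (is.null(rownames(weights))) {
    rownames(weights) <- c("A", "C", "G", "T")
  }
  stopifnot(setequal(rownames(weights), c("A", "C", "G", "T")))
  weights <- weights[c("A", "C", "G", "T"), , drop = FALSE]
  structure(list(name = name, threshold = threshold, weights = weights,
                 width = ncol(weights)),
            class = "motif_matrix")
}

#' Read a position weight matrix from a TSV file
#'
#' Expected format: an optional comment header
#' \code{#name=<motif> threshold=<t>} followed by four tab-separated rows
#' labelled A, C, G, T, each with L weight columns.
#'
#' @param path file path.
#' @return A \code{motif_matrix}.
#' @export
read_pwm <- function(path) {
  lines <- readLines(path)
  name <- "motif"
  threshold <- 2.383
  hdr <- grep("^#", lines, value = TRUE)
  if (length(hdr) > 0) {
    m <- regmatches(hdr[1], regexec("name=(\\S+)", hdr[1]))[[1]]
    if (length(m) == 2) name <- m[2]
    m <- regmatches(hdr[1], regexec("threshold=([0-9.eE+-]+)", hdr[1]))[[1]]
    if (length(m) == 2) threshold <- as.numeric(m[2])
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bases <- vapply(parts, `[`, character(1), 1L)
  w <- t(vapply(parts, function(p) as.numeric(p[-1]),
                numeric(length(parts[[1]]) - 1L)))
  rownames(w) <- bases
  motif_matrix(w, name = name, threshold = threshold)
}

#' Scan a sequence for motif hits above threshold
#'
#' Scores every length-L window of the forward strand as the sum of the
#' matrix weights of its bases; windows containing \code{N} are skipped.
#' Hits (score >= threshold) are returned sorted by position.
#'
#' @param sequence nucleotide string over A/C/G/T/N (case-insensitive), or a
#'   \code{Biostrings::DNAString}.
#' @param matrix a \code{motif_matrix}.
#' @param threshold override of the matrix threshold.
#' @return Data frame (start, end, window, score), 1-based coordinates; zero
#'   rows when the sequence is shorter than the motif.
#' @export
scan_pwm <- function(sequence, matrix, threshold = matrix$threshold) {
  sequence <- toupper(as.character(sequence))
  stopifnot(grepl("^[ACGTN]*$", sequence))
  L <- matrix$width
  n <- nchar(sequence)
  if (n < L) {
    return(data.frame(start = integer(), end = integer(),
                      window = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  idx <- match(chars, c("A", "C", "G", "T"))  # NA for N
  # per-position weight lookup for each motif column
  starts <- seq_len(n - L + 1L)
  scores <- numeric(length(starts))
  valid <- rep(TRUE, length(starts))
  for (j in seq_len(L)) {
    b <- idx[starts + j - 1L]
    valid <- valid & !is.na(b)
    w <- matrix$weights[cbind(ifelse(is.na(b), 1L, b), j)]
    scores <- scores + ifelse(is.na(b), 0, w)
  }
  hit <- valid & scores >= threshold
  data.frame(
    start = starts[hit],
    end = starts[hit] + L - 1L,
    window = vapply(starts[hit], function(s) {
      substr(sequence, s, s + L - 1L)
    }, character(1)),
    score = scores[hit],
    stringsAsFactors = FALSE
  )
}

#' Motif gain/loss between two alleles of a variant
#'
#' Substitutes the reference and alternate base at a position, scans both
#' allelic sequences over the window of all motif positions overlapping the
#' variant (\code{position - L + 1} to \code{position + L - 1}), and reports
#' hits unique to each allele. A hit present for the alternate allele only is
#' "gained" (e.g. a risk allele creating an extra splicing-factor binding
#' site); one present for the reference only is "lost".
#'
#' @param sequence nucleotide string.
#' @param position 1-based position of the variant.
#' @param ref_base,alt_base single bases; \code{sequence[position]} must
#'   equal \code{ref_base}.
#' @param matrix a \code{motif_matrix}.
#' @param threshold override of the matrix threshold.
#' @return A list with \code{hits_ref}, \code{hits_alt}, \code{gained},
#'   \code{lost} (data frames in the coordinates of the full sequence).
#' @export
allele_contrast <- function(sequence, position, ref_base, alt_base, matrix,
                            threshold = matrix$threshold) {
  sequence <- toupper(as.character(sequence))
  ref_base <- toupper(ref_base)
  alt_base <- toupper(alt_base)
  found <- substr(sequence, position, position)
  if (found != ref_base) {
    stop(sprintf("base at position %d is %s, not the stated reference %s",
                 position, found, ref_base))
  }
  alt_seq <- sequence
  substr(alt_seq, position, position) <- alt_base
  L <- matrix$width
  lo <- max(1L, position - L + 1L)
  hi <- min(nchar(sequence), position + L - 1L)
  scan_window <- function(s) {
    h <- scan_pwm(substr(s, lo, hi), matrix, threshold)
    h$start <- h$start + lo - 1L
    h$end <- h$end + lo - 1L
    h
  }
  hits_ref <- scan_window(sequence)
  hits_alt <- scan_window(alt_seq)
  key <- function(h) paste(h$start, h$window)
  list(
    hits_ref = hits_ref,
    hits_alt = hits_alt,
    gained = hits_alt[!(key(hits_alt) %in% key(hits_ref)), , drop = FALSE],
    lost = hits_ref[!(key(hits_ref) %in% key(hits_alt)), , drop = FALSE]
  )
}
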