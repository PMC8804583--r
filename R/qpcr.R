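#' Relative expression by the comparative-Ct (2^-ddCt) method
#'
#' For each record, \eqn{\Delta Ct = Ct_{target} - Ct_{reference}}
#' (normalisation to a housekeeping gene such as GAPDH); the fold change of
#' the treated sample relative to the calibrator is
#' \deqn{RQ = 2^{-(\Delta Ct_{treated} - \Delta Ct_{calibrator})}.}
#' Replicate wells (\code{ct_target}/\code{ct_reference} vectors) are
#' averaged on the Ct scale before the deltas are taken.
#'
#' @param treated,calibrator lists or one-row data frames with numeric
#'   fields \code{ct_target} and \code{ct_reference} (cycles; vectors allowed
#'   for replicate wells).
#' @return The relative quantity (fold change), a positive scalar.
#' @examples
#' relative_quantity(list(ct_target = 24, ct_reference = 18),
#'                   list(ct_target = 26, ct_reference = 18))  # 4
#' @export
relative_quantity <- function(treated, calibrator) {
  d_treated <- mean(treated$ct_target) - mean(treated$ct_reference)
  d_calib <- mean(calibrator$ct_target) - mean(calibrator$ct_reference)
  stopifnot(is.finite(d_treated), is.finite(d_calib))
  2^(-(d_treated - d_calib))
}

#' Relative quantities for a table of qPCR samples
#'
#' @param records data frame with columns \code{sample_id}, \code{group}
#'   (\code{"treated"} or \code{"calibrator"}), \code{ct_target},
#'   \code{ct_reference}; duplicate rows per sample are replicate wells and
#'   are averaged on the Ct scale.
#' @return Data frame (sample_id, group, delta_ct, rq) where \code{rq} is
#'   relative to the mean \eqn{\Delta Ct} of the calibrator group.
#' @export
relative_quantity_table <- function(records) {
  stopifnot(all(c("sample_id", "group", "ct_target", "ct_reference") %in%
                  names(records)),
            all(records$group %in% c("treated", "calibrator")))
  ct_t <- tapply(records$ct_target, records$sample_id, mean)
  ct_r <- tapply(records$ct_reference, records$sample_id, mean)
  grp <- tapply(records$group, records$sample_id, `[`, 1L)
  d_ct <- ct_t - ct_r
  d_cal <- mean(d_ct[grp == "calibrator"])
  if (!is.finite(d_cal)) stop("no calibrator samples")
  out <- data.frame(
    sample_id = names(d_ct),
    group = as.character(grp),
    delta_ct = as.numeric(d_ct),
    rq = 2^(-(as.numeric(d_ct) - d_cal)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
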