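#' Replication-stage summary statistics of the high-myopia pooling study
#'
#' Printed summary inputs of the study the package models, for re-analysis
#' with [allele_table_from_freq()], [allelic_or()], [allelic_chi2()] and
#' [ivw_meta()].
#'
#' \code{hm_validation_summary()} returns the validation stage: risk-allele
#' frequencies of the candidate SNPs in 1,091 high-myopia cases (combined
#' WMU and SPPH cohorts) against 52,708 population-database controls, with
#' the published odds ratio per SNP (\code{or_published}) and the
#' orientation in which it was reported (\code{"risk"} = as tabulated,
#' \code{"case_enriched"} = flipped to the allele over-represented in
#' cases).
#'
#' \code{hm_replication_rs10889602()} returns the per-stage odds ratios and
#' 95\% confidence intervals of the lead SNP rs10889602 (validation stage
#' and the independent KMUH cohort of 991 cases / 1,025 controls), the
#' inputs of the fixed-effect meta-analysis.
#'
#' @return Data frames; see Details.
#' @name hm_study_summary
NULL

#' @rdname hm_study_summary
#' @export
hm_validation_summary <- function() {
  out <- data.frame(
    snp_id = c("rs11580093", "rs10889602", "rs7762018", "rs600242",
               "rs4149152", "rs2193015", "rs9676191"),
    gene = c("PODN", "PDE4B", "PHF10", "ME3", "SLCO1B3", "NEDD1", "DCC"),
    risk_allele = c("C", "G", "A", "G", "G", "C", "C"),
    maf_case = c(0.0339, 0.0692, 0.322, 0.184, 0.0875, 0.404, 0.160),
    maf_control = c(0.0321, 0.0546, 0.299, 0.176, 0.0814, 0.432, 0.132),
    n_case = 1091L,
    n_control = 52708L,
    or_published = c(1.06, 1.28, 1.11, 1.04, 1.08, 1.12, 1.25),
    orientation = c("risk", "risk", "risk", "risk", "risk",
                    "case_enriched", "risk"),
    stringsAsFactors = FALSE
  )
  out
}

#' @rdname hm_study_summary
#' @export
hm_replication_rs10889602 <- function() {
  data.frame(
    stage = c("validation", "KMUH"),
    n_case = c(1091L, 991L),
    n_control = c(52708L, 1025L),
    maf_case = c(0.0692, 0.0400),
    maf_control = c(0.0546, 0.0524),
    or = c(1.28, 1.32),
    ci_low = c(1.08, 0.98),
    ci_high = c(1.52, 1.78),
    stringsAsFactors = FALSE
  )
}
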