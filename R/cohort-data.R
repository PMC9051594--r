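# Bundled example test-retest cohort: per-patient whole-body molecular tumor
# volume from two scans, each read independently by two readers, plus serum
# PSA and Gleason score. 18 patients, two of them with no detectable disease
# on any read. Used as a realistic worked example and as a regression
# fixture for the repeatability statistics.

#' Example per-patient test-retest cohort
#'
#' Loads the bundled 18-patient cohort of whole-body MTV_total values (mL),
#' one column per reader and scan, together with serum PSA (ng/mL) and
#' Gleason score. Two patients have zero measured tumor volume on all four
#' reads; they are the both-zero pairs that the wCV zero policy handles.
#'
#' @return Data frame with columns `patient_id`, `psa_ng_ml`, `gleason`,
#'   `r1_scan1`, `r2_scan1`, `r1_scan2`, `r2_scan2`.
#' @export
testretest_cohort <- function() {
  path <- system.file("extdata", "mtv_testretest_cohort.csv",
                      package = "psmarepeat", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Paired samples from the example cohort
#'
#' Builds the [paired_samples()] table for MTV_total under the standard
#' designs: each reader against themselves across scans (`"R1"`, `"R2"`),
#' the two-reader average per scan (`"mean"`), or the reader-swap designs
#' (`"R1,R2"`: scan 1 read by reader 1 vs scan 2 read by reader 2;
#' `"R2,R1"`: the converse).
#'
#' @param cohort A [testretest_cohort()] data frame (loaded if missing).
#' @param design One of `"R1"`, `"R2"`, `"mean"`, `"R1,R2"`, `"R2,R1"`.
#' @return A [paired_samples()] data frame.
#' @export
cohort_pairs <- function(cohort = testretest_cohort(),
                         design = c("R1", "R2", "mean", "R1,R2", "R2,R1")) {
  design <- match.arg(design)
  ab <- switch(design,
    "R1"    = list(cohort$r1_scan1, cohort$r1_scan2),
    "R2"    = list(cohort$r2_scan1, cohort$r2_scan2),
    "mean"  = list((cohort$r1_scan1 + cohort$r2_scan1) / 2,
                   (cohort$r1_scan2 + cohort$r2_scan2) / 2),
    "R1,R2" = list(cohort$r1_scan1, cohort$r2_scan2),
    "R2,R1" = list(cohort$r2_scan1, cohort$r1_scan2))
  paired_samples(cohort$patient_id, ab[[1]], ab[[2]],
                 metric_name = "mtv_total", reader_tag = design)
}
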