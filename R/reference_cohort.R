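#' Reported per-patient metrics of the original clinical study cohort
#'
#' The published per-patient values of the 18-patient SEEG resection
#' cohort on which the virtual-resection method was developed, shipped
#' as plain-text tables:
#'
#' * `"resection_szfree"` — the nine seizure-free patients: virtual and
#'   actual resection radii, SOZ/RonS/FR resection ratios, the three
#'   FRnet factors, and the virtual/actual overlap fractions
#'   (`percent_r`, `novel_r`).
#' * `"resection_nonszfree"` — the nine non-seizure-free patients
#'   (same columns, plus whether the virtual resection reached a
#'   seizure-free label; virtual radii are missing for the four whose
#'   simulation never did).
#' * `"overlap_szfree"`, `"overlap_nonszfree"` — contact-level
#'   contingency metrics (sensitivity through F1) comparing virtual and
#'   actual resections, for the patients whose virtual resection was
#'   labelled seizure-free.
#'
#' These reported values serve as desk-scale reference inputs: the
#' summary statistics the study quotes (signed-rank p-value on the
#' radius pairs, column means) are recomputed from them by the test
#' suite and the acceptance script.
#'
#' @param table one of `"resection_szfree"`, `"resection_nonszfree"`,
#'   `"overlap_szfree"`, `"overlap_nonszfree"`.
#' @return data frame.
#' @export
reference_cohort <- function(table = c("resection_szfree", "resection_nonszfree",
                                       "overlap_szfree", "overlap_nonszfree")) {
  table <- match.arg(table)
  fname <- switch(table,
                  resection_szfree = "resection_cohort_szfree.tsv",
                  resection_nonszfree = "resection_cohort_nonszfree.tsv",
                  overlap_szfree = "overlap_szfree.tsv",
                  overlap_nonszfree = "overlap_nonszfree.tsv")
  path <- system.file("extdata", fname, package = "frnetsim", mustWork = TRUE)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(patient_id = "character"))
}
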