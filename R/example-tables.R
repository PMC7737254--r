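# Published per-size audit summaries of two hierarchies, usable as worked
# examples and as inputs to the threshold scan and Fisher analysis.

#' Example audit summary: SNOMED CT Specimen hierarchy
#'
#' The per-partial-area-size audit summary of the blinded 100-concept study
#' of the SNOMED CT Specimen hierarchy (January 2018 international release;
#' 1696 concepts, 530 partial-areas in 23 areas; sample drawn from the 1463
#' non-overlapping concepts with 50 small- and 50 large-stratum concepts,
#' allocated over small sizes proportionally to their populations). Columns
#' `n_partial_areas` and `n_concepts` describe the complete hierarchy
#' (concept counts exclude overlapping concepts); `n_sampled`/`n_erroneous`
#' are the audit outcomes. 14 of the 100 reviewed concepts had modeling
#' issues.
#'
#' @return A `size_error_table` with the extra population columns.
#' @examples
#' select_threshold(example_specimen_audit())$selected  # 9
#' @export
example_specimen_audit <- function() {
  t <- .df(
    size_label = c(as.character(1:10), "> 10", "Total"),
    size = c(1:10, NA, NA),
    n_partial_areas = c(345, 72, 25, 12, 11, 10, 7, 4, 6, 2, 36, 530),
    n_concepts = c(345, 120, 61, 40, 39, 51, 36, 28, 52, 10, 681, 1463),
    n_sampled = c(22, 8, 4, 3, 2, 3, 2, 2, 3, 1, 50, 100),
    n_erroneous = c(3, 1, 2, 1, 1, 0, 1, 0, 2, 0, 3, 14))
  as_size_error_table(t)
}

#' Example audit summary: NCIt Gene hierarchy
#'
#' The per-partial-area-size audit summary of the blinded 100-concept study
#' of the NCI Thesaurus Gene hierarchy (March 2018 release; 10,117 concepts,
#' 5594 partial-areas in 143 areas; sample drawn from the 10,005
#' non-overlapping concepts with fixed per-size quotas — 10 concepts from
#' size 1, 5 from each larger small size — plus 50 large-stratum concepts).
#' There are no partial-areas of size 9, so that row is absent. 62 of the
#' 100 reviewed concepts had modeling issues.
#'
#' @return A `size_error_table` with the extra population columns.
#' @examples
#' select_threshold(example_gene_audit())$selected  # 2
#' @export
example_gene_audit <- function() {
  t <- .df(
    size_label = c(as.character(c(1:8, 10)), "> 10", "Total"),
    size = c(1:8, 10, NA, NA),
    n_partial_areas = c(5450, 90, 4, 5, 2, 1, 2, 2, 1, 37, 5594),
    n_concepts = c(5450, 180, 12, 20, 10, 6, 14, 16, 9, 4288, 10005),
    n_sampled = c(10, 5, 5, 5, 5, 5, 5, 5, 5, 50, 100),
    n_erroneous = c(9, 4, 1, 3, 3, 3, 2, 1, 3, 33, 62))
  as_size_error_table(t)
}
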