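#' Published reference cohort counts (worked-example fixture)
#'
#' Summary counts from a large published multisite ED cohort (149,449 adult
#' encounters with urinalysis and urine culture): culture-positive and
#' strict-UTI case counts, the physician proxy's confusion cells against
#' the strict definition, the explicit-diagnosis share and the reported
#' cross-group CV point estimates. These are aggregate counts only and are
#' used to exercise the package's metric operations on known arithmetic —
#' e.g. prevalences, over-/underdiagnosis rates and CV intervals recomputed
#' from first principles.
#'
#' @return named list of counts and CV points.
#' @export
reference_cohort_counts <- function() {
  path <- system.file("extdata", "reference_cohort_counts.json",
                      package = "utiaudit")
  jsonlite::read_json(path, simplifyVector = TRUE)
}
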