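#' Load outcome-labeling code lists
#'
#' Loads the organism, diagnosis and antibiotic code lists that drive the
#' three outcome labels: pathogenic organisms (for culture positivity),
#' explicit UTI diagnosis codes, UTI-relevant antibiotics, nonspecific
#' UTI-attributable diagnoses and alternative infectious diagnoses (for the
#' physician-diagnosis proxy). The packaged defaults are documented
#' stand-ins for site-specific lists and can be overridden with a JSON file
#' of the same shape.
#'
#' Validated invariants: every list non-empty; explicit UTI diagnoses and
#' alternative infectious diagnoses are disjoint.
#'
#' @param path optional path to an override JSON file.
#' @return object of class `code_lists`: named list of normalized character
#'   vectors.
#' @export
load_code_lists <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "code_lists.json", package = "utiaudit")
  }
  if (!file.exists(path)) stop("load_code_lists: file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  fields <- c("pathogenic_organisms", "uti_explicit_dx",
              "uti_relevant_antibiotics", "nonspecific_uti_attributable_dx",
              "alternative_infectious_dx")
  lists <- lapply(fields, function(f) {
    v <- raw[[f]]
    if (is.null(v) || length(v) == 0L) {
      stop_field("load_code_lists", f, "must be a non-empty list")
    }
    normalize_label(v)
  })
  names(lists) <- fields
  if (length(intersect(lists$uti_explicit_dx,
                       lists$alternative_infectious_dx))) {
    stop("load_code_lists: uti_explicit_dx and alternative_infectious_dx overlap")
  }
  lists$display_organisms <- as.character(raw$pathogenic_organisms)
  structure(lists, class = "code_lists", version = raw$version %||% "unversioned")
}

the_default_code_lists <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_code_lists()
    cache
  }
})

#' Call urine-culture positivity
#'
#' A culture is positive when it grew at least 10,000 colony-forming units
#' per milliliter (CFU/mL) of a pathogenic organism. Non-pathogenic growth
#' (e.g. skin or vaginal flora) and sub-threshold growth are negative, as is
#' an absent organism.
#'
#' @param organism character vector of organism labels; `NA`, `""` or
#'   `"none"` means no growth.
#' @param cfu_per_ml non-negative numeric vector of CFU/mL.
#' @param code_lists code lists from [load_code_lists()].
#' @param threshold_cfu positivity cutoff in CFU/mL (default 10,000).
#' @return logical vector.
#' @export
call_culture_positive <- function(organism, cfu_per_ml,
                                  code_lists = the_default_code_lists(),
                                  threshold_cfu = 10000) {
  if (any(cfu_per_ml < 0, na.rm = TRUE)) {
    stop("call_culture_positive: cfu_per_ml must be non-negative")
  }
  org <- normalize_label(organism)
  absent <- is.na(org) | org %in% c("", "none")
  pathogenic <- !absent & org %in% code_lists$pathogenic_organisms
  pathogenic & !is.na(cfu_per_ml) & cfu_per_ml >= threshold_cfu
}

#' Label an encounter as UTI under the strict or liberal definition
#'
#' Strict: positive urine culture AND at least one UTI sign or symptom
#' (distinguishing true UTI from asymptomatic bacteriuria, which typically
#' is not treated). Liberal: positive urine culture alone.
#'
#' @param culture_positive logical vector.
#' @param any_symptom logical vector: any UTI sign or symptom present.
#' @param definition `"strict"` or `"liberal"`.
#' @return logical vector.
#' @export
label_uti <- function(culture_positive, any_symptom,
                      definition = c("strict", "liberal")) {
  definition <- match.arg(definition)
  if (definition == "strict") culture_positive & any_symptom
  else culture_positive
}

#' Infer physician UTI diagnosis from coded actions (composite proxy)
#'
#' Rule-based proxy for a physician's UTI diagnosis, needed because
#' diagnoses are not always explicitly coded. An encounter counts as
#' physician-diagnosed if either:
#' \enumerate{
#'   \item \strong{explicit}: any visit diagnosis is an explicit UTI code
#'     (cystitis, pyelonephritis, unspecified UTI or a synonym); or
#'   \item \strong{inferred}: a UTI-relevant antibiotic was prescribed AND a
#'     nonspecific UTI-attributable diagnosis was coded AND no alternative
#'     infectious diagnosis that would explain the antibiotic was coded.
#' }
#' Adding an alternative infectious diagnosis can therefore only revoke an
#' inferred diagnosis, never create one.
#'
#' @param explicit_dx character vector of `";"`-joined visit diagnoses (or a
#'   list of character vectors).
#' @param antibiotic_rx prescriptions, same encoding.
#' @param other_dx other visit diagnoses, same encoding.
#' @param code_lists code lists from [load_code_lists()].
#' @return data.frame with logical `physician_diagnosed` and factor
#'   `proxy_branch` in `{explicit, inferred, none}`.
#' @export
infer_physician_diagnosis <- function(explicit_dx, antibiotic_rx, other_dx,
                                      code_lists = the_default_code_lists()) {
  ex <- split_codes(explicit_dx)
  rx <- split_codes(antibiotic_rx)
  ot <- split_codes(other_dx)
  n <- max(length(ex), length(rx), length(ot))
  has <- function(codes, set) {
    vapply(codes, function(el) any(el %in% set), logical(1))
  }
  explicit <- has(ex, code_lists$uti_explicit_dx)
  inferred <- !explicit &
    has(rx, code_lists$uti_relevant_antibiotics) &
    has(ot, code_lists$nonspecific_uti_attributable_dx) &
    !has(ot, code_lists$alternative_infectious_dx)
  branch <- rep("none", n)
  branch[inferred] <- "inferred"
  branch[explicit] <- "explicit"
  data.frame(
    physician_diagnosed = explicit | inferred,
    proxy_branch = factor(branch, levels = c("explicit", "inferred", "none"))
  )
}

#' Append outcome labels to an encounter table
#'
#' Adds `culture_positive`, `any_symptom`, `strict_uti`, `liberal_uti`,
#' `physician_diagnosed` and `proxy_branch` columns. By construction
#' `strict_uti` implies `liberal_uti` and `liberal_uti == culture_positive`.
#'
#' @param encounters encounter data.frame (see [generate_cohort()] for the
#'   column dictionary).
#' @param code_lists code lists from [load_code_lists()].
#' @return the input data.frame with six label columns appended.
#' @export
label_cohort <- function(encounters, code_lists = the_default_code_lists()) {
  need <- c("culture_organism", "culture_cfu_per_ml", "sym_likely_uti_symptom",
            "sym_exam_finding", "sym_systemic", "explicit_dx",
            "antibiotic_rx", "other_dx")
  miss <- setdiff(need, names(encounters))
  if (length(miss)) {
    stop("label_cohort: missing column(s): ", paste(miss, collapse = ", "))
  }
  encounters$culture_positive <- call_culture_positive(
    encounters$culture_organism, encounters$culture_cfu_per_ml, code_lists)
  encounters$any_symptom <- encounters$sym_likely_uti_symptom |
    encounters$sym_exam_finding | encounters$sym_systemic
  encounters$strict_uti <- label_uti(encounters$culture_positive,
                                     encounters$any_symptom, "strict")
  encounters$liberal_uti <- label_uti(encounters$culture_positive,
                                      encounters$any_symptom, "liberal")
  proxy <- infer_physician_diagnosis(encounters$explicit_dx,
                                     encounters$antibiotic_rx,
                                     encounters$other_dx, code_lists)
  encounters$physician_diagnosed <- proxy$physician_diagnosed
  encounters$proxy_branch <- proxy$proxy_branch
  encounters
}
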