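`%||%` <- function(x, y) if (is.null(x)) y else x

#' Normalize a code or raw-result label for lookup
#'
#' Case-folds, trims leading/trailing whitespace and collapses internal runs
#' of whitespace to a single space. Matching throughout the package is exact
#' on normalized labels; there is no fuzzy matching.
#'
#' @param x character vector.
#' @return normalized character vector (NA preserved).
#' @keywords internal
normalize_label <- function(x) {
  out <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", out)
}

# Deterministic per-stage seed derivation from one master seed. Offsets are
# fixed per logical stream so that perturbing one stream's draws leaves the
# others unchanged. Result kept inside 32-bit integer range.
derive_seed <- function(seed, stream) {
  offsets <- c(
    demographics = 101L, biology = 211L, urinalysis = 307L,
    symptoms = 401L, physician = 503L, split = 601L,
    tuning = 701L, crossfit = 809L, evaluation = 907L
  )
  if (!stream %in% names(offsets)) {
    stop("derive_seed: unknown stream '", stream, "'")
  }
  as.integer((as.numeric(seed) * 2654435.0 + offsets[[stream]]) %% 2147483647)
}

# Split a ";"-joined code string into a normalized character vector.
split_codes <- function(x) {
  if (is.list(x)) {
    return(lapply(x, function(el) normalize_label(el[nzchar(el)])))
  }
  lapply(strsplit(ifelse(is.na(x), "", as.character(x)), ";", fixed = TRUE),
         function(el) normalize_label(trimws(el[nzchar(trimws(el))])))
}

join_codes <- function(x) {
  vapply(x, function(el) paste(el, collapse = ";"), character(1))
}

stop_field <- function(where, field, msg) {
  stop(sprintf("%s: `%s` %s", where, field, msg), call. = FALSE)
}

check_probability <- function(value, field, where) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < 0 || value > 1) {
    stop_field(where, field, "must be a single probability in [0, 1]")
  }
  invisible(value)
}

check_count <- function(value, field, where, min = 1L) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < min || value != round(value)) {
    stop_field(where, field, sprintf("must be a single integer >= %d", min))
  }
  invisible(as.integer(value))
}
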