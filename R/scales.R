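#' Urinalysis component names used throughout the package
#'
#' The nine urinalysis components used as model predictors: the six dipstick
#' chemistries (blood, glucose, ketones, leukocyte esterase, nitrites,
#' protein) and the three microscopy counts (bacteria, epithelial cells,
#' white blood cells).
#'
#' @return character vector of component names (snake_case).
#' @export
ua_components <- function() {
  c("blood", "glucose", "ketones", "leukocyte_esterase", "nitrites",
    "protein", "bacteria", "epithelial_cells", "white_blood_cells")
}

#' Reporting dialects recognized by the harmonizer
#'
#' Sites report urinalysis components on qualitative (worded),
#' semiquantitative (plus-grade) or quantitative (numeric with units)
#' scales; each encounter records which dialect its site uses.
#'
#' @return character vector of dialect names.
#' @export
ua_dialects <- function() {
  c("qualitative", "semiquantitative", "quantitative")
}

#' Load urinalysis harmonization scale maps
#'
#' Reads the per-component unified ordinal scale and its per-dialect
#' raw-string -> level maps. The default table shipped with the package uses
#' four levels for dipstick chemistries (negative, trace/1+, moderate/2+,
#' large/>=3+), four binned levels for microscopy counts (none, 0-10/hpf,
#' 11-50/hpf, >50/hpf) and a binary scale for nitrites. The table is a
#' documented stand-in for site-specific reconciliation tables and can be
#' overridden with a JSON file of the same shape.
#'
#' Validated invariants: level indices are consecutive integers starting at
#' 0; every dialect map is total on its declared vocabulary and surjective
#' onto the level set.
#'
#' @param path optional path to an override JSON file; `NULL` loads the
#'   packaged default.
#' @return an object of class `ua_scales`: a named list with one entry per
#'   component, each holding `levels` (ordered labels) and `dialects`
#'   (named integer vectors mapping normalized raw strings to levels).
#' @export
load_scales <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ua_scales.json", package = "utiaudit")
  }
  if (!file.exists(path)) stop("load_scales: file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  comps <- raw$components
  scales <- lapply(comps, function(cmp) {
    n_levels <- length(cmp$levels)
    dialects <- lapply(cmp$dialects, function(map) {
      v <- vapply(map, function(x) as.integer(x), integer(1))
      names(v) <- normalize_label(names(map))
      v
    })
    list(kind = cmp$kind, levels = unlist(cmp$levels), dialects = dialects,
         n_levels = n_levels)
  })
  names(scales) <- names(comps)
  for (cn in names(scales)) {
    sc <- scales[[cn]]
    for (dn in names(sc$dialects)) {
      lv <- sc$dialects[[dn]]
      if (!setequal(unique(lv), seq_len(sc$n_levels) - 1L)) {
        stop(sprintf(
          "load_scales: dialect map %s/%s is not surjective onto levels 0..%d",
          cn, dn, sc$n_levels - 1L))
      }
    }
  }
  structure(scales, class = "ua_scales", version = raw$version %||% "unversioned")
}

the_default_scales <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_scales()
    cache
  }
})

#' Harmonize one urinalysis component value onto its unified ordinal scale
#'
#' Maps a raw reported string (in a registered dialect) to the component's
#' unified ordinal level. Lookup is case- and whitespace-insensitive on the
#' normalized string. Missing input passes through as missing; a non-missing
#' string that is not in the dialect's vocabulary is an error, never
#' silently coerced to missing (only true missingness may pass — downstream
#' modelling takes missing values natively, without imputation). A numeric
#' input already on the ordinal scale is returned unchanged (idempotence),
#' provided it is in range.
#'
#' @param raw character (or already-ordinal numeric) vector of raw results;
#'   `NA` allowed.
#' @param component one of [ua_components()].
#' @param dialect one of [ua_dialects()].
#' @param scales scale maps from [load_scales()].
#' @return integer vector of ordinal levels, `NA` where input was missing.
#' @export
harmonize_component <- function(raw, component, dialect,
                                scales = the_default_scales()) {
  if (!component %in% names(scales)) {
    stop("harmonize_component: unknown component '", component, "'")
  }
  sc <- scales[[component]]
  if (!dialect %in% names(sc$dialects)) {
    stop("harmonize_component: unknown dialect '", dialect,
         "' for component '", component, "'")
  }
  if (is.numeric(raw)) {
    bad <- !is.na(raw) & (raw != round(raw) | raw < 0 | raw > sc$n_levels - 1L)
    if (any(bad)) {
      stop(sprintf(
        "harmonize_component: ordinal value out of range for %s: %s",
        component, paste(unique(raw[bad]), collapse = ", ")))
    }
    return(as.integer(raw))
  }
  map <- sc$dialects[[dialect]]
  key <- normalize_label(raw)
  out <- unname(map[key])
  bad <- is.na(out) & !is.na(key)
  if (any(bad)) {
    stop(sprintf(
      "harmonize_component: unmappable value for component '%s', dialect '%s': %s",
      component, dialect,
      paste(sprintf("'%s'", unique(raw[bad])), collapse = ", ")))
  }
  as.integer(out)
}

#' Render an ordinal urinalysis level as a raw string in a dialect
#'
#' Inverse of [harmonize_component()]: emits the canonical raw string (the
#' first vocabulary entry declared for that level in the dialect map), so
#' that `harmonize_component(render_raw_urinalysis(x, component, dialect))`
#' is the identity on levels for every component and dialect.
#'
#' @param level integer vector of ordinal levels in the component's range.
#' @param component one of [ua_components()].
#' @param dialect one of [ua_dialects()].
#' @param scales scale maps from [load_scales()].
#' @return character vector of raw strings; `NA` level renders as `NA`.
#' @export
render_raw_urinalysis <- function(level, component, dialect,
                                  scales = the_default_scales()) {
  if (!component %in% names(scales)) {
    stop("render_raw_urinalysis: unknown component '", component, "'")
  }
  sc <- scales[[component]]
  if (!dialect %in% names(sc$dialects)) {
    stop("render_raw_urinalysis: unknown dialect '", dialect, "'")
  }
  map <- sc$dialects[[dialect]]
  # canonical string per level: first declared vocabulary entry
  canon <- names(map)[match(seq_len(sc$n_levels) - 1L, unname(map))]
  bad <- !is.na(level) & (level < 0 | level > sc$n_levels - 1L |
                            level != round(level))
  if (any(bad)) {
    stop(sprintf(
      "render_raw_urinalysis: level out of range for %s: %s",
      component, paste(unique(level[bad]), collapse = ", ")))
  }
  out <- canon[as.integer(level) + 1L]
  out[is.na(level)] <- NA_character_
  out
}

#' Harmonize the urinalysis panel of a whole encounter table
#'
#' For each of the nine components, maps the raw per-encounter string (in
#' the row's recorded dialect, column `dialect`) to the unified ordinal
#' level, appending one integer column per component named after the
#' component itself. Raw columns are expected as `ua_<component>`. Row count
#' and order are preserved; per-component harmonized value counts are
#' reported via `message()`.
#'
#' @param encounters data.frame with `ua_*` raw columns and a `dialect`
#'   column.
#' @param scales scale maps from [load_scales()].
#' @param quiet suppress the per-component count log.
#' @return the input data.frame with nine ordinal component columns added.
#' @export
harmonize_table <- function(encounters, scales = the_default_scales(),
                            quiet = FALSE) {
  comps <- ua_components()
  if (nrow(encounters) == 0L) {
    for (cn in comps) encounters[[cn]] <- integer(0)
    return(encounters)
  }
  if (!"dialect" %in% names(encounters)) {
    stop("harmonize_table: `dialect` column is required")
  }
  unknown <- setdiff(unique(encounters$dialect), ua_dialects())
  if (length(unknown)) {
    stop("harmonize_table: unknown dialect(s): ", paste(unknown, collapse = ", "))
  }
  for (cn in comps) {
    raw_col <- paste0("ua_", cn)
    if (!raw_col %in% names(encounters)) {
      stop("harmonize_table: missing raw column `", raw_col, "`")
    }
    out <- rep(NA_integer_, nrow(encounters))
    for (dn in unique(encounters$dialect)) {
      idx <- which(encounters$dialect == dn)
      out[idx] <- tryCatch(
        harmonize_component(encounters[[raw_col]][idx], cn, dn, scales),
        error = function(e) {
          stop(sprintf("harmonize_table: rows %s: %s",
                       paste(head(idx, 5L), collapse = ","),
                       conditionMessage(e)), call. = FALSE)
        })
    }
    encounters[[cn]] <- out
    if (!quiet) {
      tab <- table(factor(out, levels = 0:(scales[[cn]]$n_levels - 1L)),
                   useNA = "ifany")
      message(sprintf("harmonize_table: %s counts [%s]", cn,
                      paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                            collapse = " ")))
    }
  }
  encounters
}
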