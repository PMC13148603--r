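#' Default demographic mix for the synthetic ED cohort
#'
#' Joint distribution over (age bin, sex, race, ethnicity) cells built from
#' realistic ED marginals — age skewed young-adult with a long older tail,
#' ~71% female (urine testing is far more common in women), seven race and
#' three ethnicity categories with race conditioned on ethnicity — so that
#' intersection sizes are realistically unequal: at full study scale about
#' nineteen cells clear a 2000-encounter size threshold while the remaining
#' cells stay small.
#'
#' @return data.frame with columns `age_bin`, `sex`, `race`, `ethnicity`,
#'   `weight` (weights sum to 1).
#' @export
default_demographic_mix <- function() {
  age <- c("18-44" = 0.463, "45-64" = 0.257, "65-84" = 0.197, "85+" = 0.083)
  sex <- c(female = 0.712, male = 0.288)
  eth <- c(hispanic = 0.256, non_hispanic = 0.739, unknown = 0.005)
  race_by_eth <- list(
    hispanic = c(white = 0.300, black = 0.060, other = 0.620, asian = 0.005,
                 american_indian_alaska_native = 0.005,
                 native_hawaiian_pacific_islander = 0.002, unknown = 0.008),
    non_hispanic = c(white = 0.650, black = 0.277, other = 0.030,
                     asian = 0.019, american_indian_alaska_native = 0.003,
                     native_hawaiian_pacific_islander = 0.003,
                     unknown = 0.018),
    unknown = c(white = 0.400, black = 0.150, other = 0.200, asian = 0.020,
                american_indian_alaska_native = 0.010,
                native_hawaiian_pacific_islander = 0.010, unknown = 0.210)
  )
  rows <- list()
  for (a in names(age)) for (s in names(sex)) for (e in names(eth)) {
    rb <- race_by_eth[[e]]
    for (r in names(rb)) {
      rows[[length(rows) + 1L]] <- data.frame(
        age_bin = a, sex = s, race = r, ethnicity = e,
        weight = age[[a]] * sex[[s]] * eth[[e]] * rb[[r]])
    }
  }
  mix <- do.call(rbind, rows)
  mix$weight <- mix$weight / sum(mix$weight)
  mix
}

#' Default per-component urinalysis signal strengths
#'
#' Monotone link strength between the latent infection intensity and each
#' component's ordinal level, on the scale of a standardized latent factor
#' loading. Microbiologically proximal components (bacteria, nitrites,
#' leukocyte esterase, white blood cells) carry most of the signal;
#' epithelial cells (a contamination marker) load negatively; glucose and
#' ketones are near-noise. Magnitudes chosen once so that the default
#' cohort supports a culture-positivity classifier in the low-0.9 AUROC
#' range.
#'
#' @return named numeric vector over [ua_components()].
#' @export
default_urinalysis_signal <- function() {
  c(blood = 0.40, glucose = 0.05, ketones = 0.08, leukocyte_esterase = 0.95,
    nitrites = 0.85, protein = 0.30, bacteria = 1.10,
    epithelial_cells = -0.25, white_blood_cells = 1.00)
}

#' Default physician-behavior table
#'
#' Per-group (sensitivity, false-positive rate) of the simulated physician
#' acting on the latent strict-UTI state. Rows may fix any subset of the
#' four demographic axes (NA = wildcard); the most specific matching row
#' wins, the all-wildcard row is the fallback. The default single row uses
#' the overall operating point reported for ED physicians in a large
#' multisite cohort: sensitivity 0.634 (false-negative rate 36.6%) and
#' false-positive rate 0.091.
#'
#' @return data.frame with columns `age_bin`, `sex`, `race`, `ethnicity`
#'   (NA = any), `sensitivity`, `fpr`.
#' @export
default_physician_behavior <- function() {
  data.frame(age_bin = NA_character_, sex = NA_character_,
             race = NA_character_, ethnicity = NA_character_,
             sensitivity = 0.634, fpr = 0.091)
}

#' Configuration for the synthetic ED encounter cohort
#'
#' Bundles and validates every generative choice behind the synthetic
#' cohort: size, culture-positivity prevalence, symptom rates conditional
#' on culture status, demographic mix, number of sites, physician behavior,
#' per-component urinalysis signal, reporting-dialect mix, missingness and
#' the master seed. The same config and seed always reproduce the identical
#' table.
#'
#' Defaults mirror a large multisite ED cohort: 15.1% culture positivity,
#' 89.2% of culture-positives and 86.3% of culture-negatives with at least
#' one UTI sign or symptom, physician sensitivity 63.4% / false-positive
#' rate 9.1% against the strict UTI state, and 92% of physician diagnoses
#' carried by an explicit code.
#'
#' @param n_encounters number of ED encounters.
#' @param n_patients number of distinct patients (<= n_encounters).
#' @param culture_positive_prevalence P(positive urine culture).
#' @param symptom_rate_given_positive P(any UTI sign/symptom | positive).
#' @param symptom_rate_given_negative P(any UTI sign/symptom | negative).
#' @param demographic_mix data.frame of (age_bin, sex, race, ethnicity,
#'   weight) cells; weights are normalized to sum to 1.
#' @param n_sites number of clinical sites.
#' @param physician_behavior data.frame per [default_physician_behavior()].
#' @param urinalysis_signal named vector per [default_urinalysis_signal()].
#' @param dialect_mix named proportions over [ua_dialects()]; each site is
#'   assigned one dialect drawn from this mix.
#' @param missing_rate per-component independent missingness probability.
#' @param explicit_dx_share fraction of physician diagnoses emitted as an
#'   explicit UTI code (the rest go through the antibiotic + nonspecific
#'   diagnosis route).
#' @param seed master integer seed; per-stream seeds (demographics, biology,
#'   urinalysis, symptoms, physician) are derived from it so perturbing one
#'   stream leaves the others unchanged.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_encounters = 20000L,
                          n_patients = max(1L, round(0.8 * n_encounters)),
                          culture_positive_prevalence = 0.151,
                          symptom_rate_given_positive = 0.892,
                          symptom_rate_given_negative = 0.863,
                          demographic_mix = default_demographic_mix(),
                          n_sites = 9L,
                          physician_behavior = default_physician_behavior(),
                          urinalysis_signal = default_urinalysis_signal(),
                          dialect_mix = c(qualitative = 0.4,
                                          semiquantitative = 0.4,
                                          quantitative = 0.2),
                          missing_rate = 0.02,
                          explicit_dx_share = 0.92,
                          seed = 1L) {
  where <- "cohort_config"
  n_encounters <- check_count(n_encounters, "n_encounters", where)
  n_patients <- check_count(n_patients, "n_patients", where)
  if (n_patients > n_encounters) {
    stop_field(where, "n_patients", "must not exceed n_encounters")
  }
  check_probability(culture_positive_prevalence,
                    "culture_positive_prevalence", where)
  check_probability(symptom_rate_given_positive,
                    "symptom_rate_given_positive", where)
  check_probability(symptom_rate_given_negative,
                    "symptom_rate_given_negative", where)
  check_probability(missing_rate, "missing_rate", where)
  check_probability(explicit_dx_share, "explicit_dx_share", where)
  n_sites <- check_count(n_sites, "n_sites", where)
  if (!is.data.frame(demographic_mix) ||
      !all(c("age_bin", "sex", "race", "ethnicity", "weight") %in%
           names(demographic_mix)) ||
      any(demographic_mix$weight < 0) || sum(demographic_mix$weight) <= 0) {
    stop_field(where, "demographic_mix",
               "must be a data.frame of cells with non-negative weights")
  }
  demographic_mix$weight <- demographic_mix$weight / sum(demographic_mix$weight)
  if (!is.data.frame(physician_behavior) ||
      !all(c("sensitivity", "fpr") %in% names(physician_behavior)) ||
      nrow(physician_behavior) == 0L) {
    stop_field(where, "physician_behavior",
               "must be a data.frame with sensitivity and fpr columns")
  }
  for (col in c("sensitivity", "fpr")) {
    if (any(is.na(physician_behavior[[col]])) ||
        any(physician_behavior[[col]] < 0 | physician_behavior[[col]] > 1)) {
      stop_field(where, paste0("physician_behavior$", col),
                 "must be probabilities in [0, 1]")
    }
  }
  if (!all(ua_components() %in% names(urinalysis_signal))) {
    stop_field(where, "urinalysis_signal",
               "must name every urinalysis component")
  }
  if (is.null(names(dialect_mix)) ||
      !all(names(dialect_mix) %in% ua_dialects()) || any(dialect_mix < 0) ||
      sum(dialect_mix) <= 0) {
    stop_field(where, "dialect_mix",
               "must be non-negative proportions named by dialect")
  }
  dialect_mix <- dialect_mix / sum(dialect_mix)
  seed <- check_count(seed, "seed", where, min = 0L)
  structure(list(
    n_encounters = n_encounters, n_patients = n_patients,
    culture_positive_prevalence = culture_positive_prevalence,
    symptom_rate_given_positive = symptom_rate_given_positive,
    symptom_rate_given_negative = symptom_rate_given_negative,
    demographic_mix = demographic_mix, n_sites = n_sites,
    physician_behavior = physician_behavior,
    urinalysis_signal = urinalysis_signal, dialect_mix = dialect_mix,
    missing_rate = missing_rate, explicit_dx_share = explicit_dx_share,
    seed = seed
  ), class = "cohort_config")
}

# Match each encounter to the most specific physician-behavior row.
# Specificity = number of non-NA axes matched; the all-NA row is the
# fallback. Ties go to the earliest row.
match_behavior <- function(encounters, behavior) {
  axes <- c("age_bin", "sex", "race", "ethnicity")
  for (ax in axes) if (!ax %in% names(behavior)) behavior[[ax]] <- NA_character_
  n <- nrow(encounters)
  row_idx <- rep(NA_integer_, n)
  specificity <- rep(-1L, n)
  for (b in seq_len(nrow(behavior))) {
    ok <- rep(TRUE, n)
    spec <- 0L
    for (ax in axes) {
      val <- behavior[[ax]][b]
      if (!is.na(val)) {
        ok <- ok & encounters[[ax]] == val
        spec <- spec + 1L
      }
    }
    take <- ok & spec > specificity
    row_idx[take] <- b
    specificity[take] <- spec
  }
  if (anyNA(row_idx)) {
    stop("generate_cohort: physician_behavior has no matching row for some ",
         "encounters; include an all-wildcard fallback row")
  }
  row_idx
}

# Latent infection-intensity model: the biological state behind both the
# culture result and the urinalysis panel. Location/scale chosen once to
# give a realistic overlap between infected and uninfected urine.
intensity_params <- list(mu_pos = 1.5, sd_pos = 0.8, mu_neg = -0.85, sd_neg = 0.9)

# Per-kind ordinal cutpoints on the noisy component score
# x = signal * intensity + N(0,1). Nitrite's single high cutpoint makes it
# specific but insensitive, the classic dipstick behavior.
component_cuts <- function(kind) {
  switch(kind,
         dipstick = c(0.9, 1.7, 2.5),
         microscopy = c(0.7, 1.5, 2.4),
         binary = 2.0,
         stop("unknown component kind: ", kind))
}

#' Generate a synthetic ED encounter cohort with known ground truth
#'
#' Simulates one row per ED encounter. Patients carry fixed demographics
#' and may own several encounters. Per encounter: a latent culture state is
#' drawn at the configured prevalence; a latent infection intensity drives
#' all nine urinalysis components through monotone thresholds with
#' per-component noise; the culture record (organism + CFU/mL) encodes the
#' latent state exactly (negatives are no growth, non-pathogenic growth, or
#' sub-threshold pathogen growth); symptom flags are drawn at the configured
#' conditional rates; and a simulated physician acts on the latent strict
#' UTI state with group-specific sensitivity and false-positive rate,
#' emitting either an explicit UTI code or an antibiotic plus nonspecific
#' diagnosis (never an alternative infectious diagnosis on that route).
#' Raw urinalysis strings are rendered in the site's reporting dialect and
#' components are independently missing at the configured rate.
#'
#' Latent ground-truth columns (`latent_*`) exist only in synthetic data;
#' every downstream stage is audited against them in the package tests.
#'
#' @param config a [cohort_config()].
#' @param scales scale maps from [load_scales()] used to render raw strings.
#' @param code_lists code lists from [load_code_lists()] used to draw
#'   organisms, antibiotics and diagnosis codes.
#' @return data.frame of encounters; see the package README for the column
#'   dictionary.
#' @export
generate_cohort <- function(config, scales = the_default_scales(),
                            code_lists = the_default_code_lists()) {
  if (!inherits(config, "cohort_config")) {
    stop("generate_cohort: config must be built with cohort_config()")
  }
  n <- config$n_encounters
  np <- config$n_patients

  ## demographics stream: patients, encounter->patient map, sites, dialects
  set.seed(derive_seed(config$seed, "demographics"))
  mix <- config$demographic_mix
  cell <- sample.int(nrow(mix), np, replace = TRUE, prob = mix$weight)
  age_lo <- c("18-44" = 18, "45-64" = 45, "65-84" = 65, "85+" = 85)
  age_hi <- c("18-44" = 44, "45-64" = 64, "65-84" = 84, "85+" = 99)
  p_age_bin <- as.character(mix$age_bin[cell])
  patient <- data.frame(
    patient_id = sprintf("P%06d", seq_len(np)),
    age_bin = p_age_bin,
    age_years = floor(runif(np, age_lo[p_age_bin], age_hi[p_age_bin] + 1)),
    sex = as.character(mix$sex[cell]),
    race = as.character(mix$race[cell]),
    ethnicity = as.character(mix$ethnicity[cell])
  )
  enc_patient <- c(seq_len(np),
                   if (n > np) sample.int(np, n - np, replace = TRUE))
  enc_patient <- sample(enc_patient, n)
  site_dialect <- sample(names(config$dialect_mix), config$n_sites,
                         replace = TRUE, prob = config$dialect_mix)
  site_id <- sample.int(config$n_sites, n, replace = TRUE)
  enc <- patient[enc_patient, , drop = FALSE]
  rownames(enc) <- NULL
  enc <- cbind(data.frame(encounter_id = sprintf("E%07d", seq_len(n))), enc)
  enc$site_id <- sprintf("S%02d", site_id)
  enc$dialect <- site_dialect[site_id]

  ## biology stream: latent culture state, organism, CFU, infection intensity
  set.seed(derive_seed(config$seed, "biology"))
  latent_pos <- runif(n) < config$culture_positive_prevalence
  organism <- rep("none", n)
  cfu <- numeric(n)
  pathogens <- code_lists$display_organisms
  n_pos <- sum(latent_pos)
  organism[latent_pos] <- sample(pathogens, n_pos, replace = TRUE,
                                 prob = c(0.55, rep(0.45 / (length(pathogens) - 1),
                                                    length(pathogens) - 1)))
  cfu[latent_pos] <- sample(c(10000L, 25000L, 50000L, 100000L), n_pos,
                            replace = TRUE, prob = c(0.2, 0.2, 0.25, 0.35))
  neg_idx <- which(!latent_pos)
  neg_kind <- sample(c("none", "contaminant", "subthreshold"),
                     length(neg_idx), replace = TRUE,
                     prob = c(0.70, 0.20, 0.10))
  contam <- c("Lactobacillus species", "Corynebacterium species",
              "mixed flora", "Candida albicans")
  is_ct <- neg_kind == "contaminant"
  organism[neg_idx[is_ct]] <- sample(contam, sum(is_ct), replace = TRUE)
  cfu[neg_idx[is_ct]] <- sample(c(1000L, 5000L, 20000L, 50000L),
                                sum(is_ct), replace = TRUE)
  is_st <- neg_kind == "subthreshold"
  organism[neg_idx[is_st]] <- sample(pathogens, sum(is_st), replace = TRUE)
  cfu[neg_idx[is_st]] <- sample(c(1000L, 2000L, 5000L, 9000L),
                                sum(is_st), replace = TRUE)
  ip <- intensity_params
  intensity <- ifelse(latent_pos,
                      rnorm(n, ip$mu_pos, ip$sd_pos),
                      rnorm(n, ip$mu_neg, ip$sd_neg))
  enc$culture_organism <- organism
  enc$culture_cfu_per_ml <- cfu

  ## urinalysis stream: ordinal levels via monotone thresholds, missingness,
  ## raw-string rendering in the site dialect
  set.seed(derive_seed(config$seed, "urinalysis"))
  for (cn in ua_components()) {
    s <- config$urinalysis_signal[[cn]]
    x <- s * intensity + rnorm(n)
    cuts <- component_cuts(scales[[cn]]$kind)
    lvl <- findInterval(x, cuts)
    lvl[runif(n) < config$missing_rate] <- NA_integer_
    enc[[paste0("ua_", cn)]] <- NA_character_
    for (dn in unique(enc$dialect)) {
      idx <- which(enc$dialect == dn)
      enc[[paste0("ua_", cn)]][idx] <-
        render_raw_urinalysis(lvl[idx], cn, dn, scales)
    }
  }

  ## symptoms stream: "any sign/symptom" at the configured conditional rate,
  ## then flag composition given any
  set.seed(derive_seed(config$seed, "symptoms"))
  p_any <- ifelse(latent_pos, config$symptom_rate_given_positive,
                  config$symptom_rate_given_negative)
  any_sym <- runif(n) < p_any
  f_likely <- any_sym & (runif(n) < 0.85)
  f_exam <- any_sym & (runif(n) < 0.20)
  f_systemic <- any_sym & (runif(n) < 0.45)
  none_drawn <- any_sym & !(f_likely | f_exam | f_systemic)
  f_likely[none_drawn] <- TRUE
  enc$sym_likely_uti_symptom <- f_likely
  enc$sym_exam_finding <- f_exam
  enc$sym_systemic <- f_systemic
  latent_strict <- latent_pos & any_sym

  ## physician stream: decide on the latent strict state with group-specific
  ## sensitivity/FPR, then emit coded actions that the proxy rule decodes
  set.seed(derive_seed(config$seed, "physician"))
  beh_row <- match_behavior(enc, config$physician_behavior)
  sens <- config$physician_behavior$sensitivity[beh_row]
  fpr <- config$physician_behavior$fpr[beh_row]
  p_dx <- ifelse(latent_strict, sens, fpr)
  intent <- runif(n) < p_dx
  explicit_pick <- c("urinary tract infection", "acute cystitis",
                     "acute pyelonephritis")
  nonspecific <- c("dysuria", "urinary frequency", "hematuria", "flank pain",
                   "altered mental status", "fever unspecified")
  alternatives <- c("pneumonia", "cellulitis", "pharyngitis",
                    "intra-abdominal infection", "sinusitis")
  uti_abx <- c("nitrofurantoin", "trimethoprim-sulfamethoxazole",
               "cephalexin", "ciprofloxacin", "ceftriaxone")
  explicit_dx <- rep("", n)
  antibiotic_rx <- rep("", n)
  other_dx <- rep("", n)
  via_explicit <- intent & (runif(n) < config$explicit_dx_share)
  via_inferred <- intent & !via_explicit
  explicit_dx[via_explicit] <- sample(explicit_pick, sum(via_explicit),
                                      replace = TRUE)
  # explicit-coded encounters usually also get an antibiotic
  got_abx <- via_explicit & (runif(n) < 0.9)
  antibiotic_rx[got_abx] <- sample(uti_abx, sum(got_abx), replace = TRUE)
  antibiotic_rx[via_inferred] <- sample(uti_abx, sum(via_inferred),
                                        replace = TRUE)
  other_dx[via_inferred] <- sample(nonspecific, sum(via_inferred),
                                   replace = TRUE)
  # non-diagnosed encounters: mostly no UTI-suggestive actions; some get an
  # antibiotic explained by an alternative diagnosis (the blocked proxy
  # route) or a nonspecific diagnosis without an antibiotic
  no_dx <- which(!intent)
  kind <- sample(c("nothing", "alt_abx", "nonspecific_only"),
                 length(no_dx), replace = TRUE, prob = c(0.70, 0.15, 0.15))
  alt_i <- no_dx[kind == "alt_abx"]
  antibiotic_rx[alt_i] <- sample(uti_abx, length(alt_i), replace = TRUE)
  other_dx[alt_i] <- paste(
    sample(nonspecific, length(alt_i), replace = TRUE),
    sample(alternatives, length(alt_i), replace = TRUE), sep = ";")
  ns_i <- no_dx[kind == "nonspecific_only"]
  other_dx[ns_i] <- sample(nonspecific, length(ns_i), replace = TRUE)
  enc$explicit_dx <- explicit_dx
  enc$antibiotic_rx <- antibiotic_rx
  enc$other_dx <- other_dx

  ## latent ground truth (synthetic only)
  enc$latent_culture_positive <- latent_pos
  enc$latent_strict_uti <- latent_strict
  enc$latent_physician_intent <- intent
  attr(enc, "cohort_seed") <- config$seed
  enc
}

#' Write / read an encounter table as CSV
#'
#' Plain-CSV round trip for pipeline artifacts; list-like code columns are
#' stored `";"`-joined, logicals as TRUE/FALSE.
#'
#' @param encounters encounter data.frame.
#' @param path file path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns the data.frame.
#' @export
write_cohort_csv <- function(encounters, path) {
  write.csv(encounters, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = character(0))
  # empty string means missing for raw urinalysis; logical columns restored
  for (cn in grep("^ua_", names(df), value = TRUE)) {
    df[[cn]][df[[cn]] == ""] <- NA_character_
  }
  for (cn in grep("^(sym_|latent_)|^(culture_positive|any_symptom|strict_uti|liberal_uti|physician_diagnosed)$",
                  names(df), value = TRUE)) {
    df[[cn]] <- as.logical(df[[cn]])
  }
  for (cn in intersect(ua_components(), names(df))) {
    df[[cn]] <- suppressWarnings(as.integer(df[[cn]]))
  }
  df
}
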