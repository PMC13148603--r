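#' Configuration for the intersectional equity audit
#'
#' Defines the audit's group construction and threshold machinery: the four
#' age bins (18-44, 45-64, 65-84, >=85 years) crossed with sex, race and
#' ethnicity; the minimum group size for inclusion in per-group analyses;
#' the integer-percent candidate threshold grid; an externally reported
#' fixed clinician treatment threshold of 42.3% (applied exactly, not
#' rounded); the normal quantile for 95% CIs; and the number of
#' predicted-probability deciles.
#'
#' @param age_breaks lower bounds of the age bins plus `Inf`.
#' @param min_group_size smallest encounter count for a group to enter the
#'   per-group audit (default 2000). Excluded groups still contribute to
#'   overall metrics.
#' @param candidate_thresholds integer percents scanned for threshold
#'   selection (default 1:99).
#' @param fixed_clinician_threshold externally reported treatment threshold
#'   as a probability (default 0.423).
#' @param z_quantile normal quantile for CV confidence intervals (default
#'   1.96).
#' @param decile_count number of equal-count probability bins (default 10).
#' @return object of class `audit_config`.
#' @export
audit_config <- function(age_breaks = c(18, 45, 65, 85, Inf),
                         min_group_size = 2000L,
                         candidate_thresholds = 1:99,
                         fixed_clinician_threshold = 0.423,
                         z_quantile = 1.96,
                         decile_count = 10L) {
  where <- "audit_config"
  if (!is.numeric(age_breaks) || length(age_breaks) < 2L ||
      is.unsorted(age_breaks, strictly = TRUE)) {
    stop_field(where, "age_breaks", "must be strictly increasing")
  }
  min_group_size <- check_count(min_group_size, "min_group_size", where)
  if (!all(candidate_thresholds == round(candidate_thresholds)) ||
      any(candidate_thresholds < 1) || any(candidate_thresholds > 99)) {
    stop_field(where, "candidate_thresholds",
               "must be integer percents in 1..99")
  }
  check_probability(fixed_clinician_threshold, "fixed_clinician_threshold",
                    where)
  decile_count <- check_count(decile_count, "decile_count", where, min = 2L)
  structure(list(age_breaks = age_breaks, min_group_size = min_group_size,
                 candidate_thresholds = as.integer(candidate_thresholds),
                 fixed_clinician_threshold = fixed_clinician_threshold,
                 z_quantile = z_quantile, decile_count = decile_count),
            class = "audit_config")
}

age_bin_labels <- function(breaks) {
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1] - 1
  ifelse(is.infinite(breaks[-1]), paste0(lo, "+"), paste0(lo, "-", hi))
}

#' Build intersectional demographic groups
#'
#' Crosses the four demographic axes (age bin, sex, race, ethnicity) over
#' the cohort. Every encounter belongs to exactly one cell; unknown or
#' declined race/ethnicity form ordinary categories. Cells with fewer than
#' `min_group_size` encounters are flagged out of the per-group audit (but
#' still count in overall metrics). Groups are sorted by size descending.
#'
#' @param encounters data.frame with `age_bin` (or `age_years`), `sex`,
#'   `race`, `ethnicity`.
#' @param config an [audit_config()].
#' @return list of class `intersectional_groups`: `groups` (data.frame with
#'   `group`, axis columns, `n`, `audited`) and `assignment` (per-row group
#'   key, character).
#' @export
build_intersectional_groups <- function(encounters, config = audit_config()) {
  if (nrow(encounters) == 0L) {
    return(structure(list(
      groups = data.frame(group = character(0), age_bin = character(0),
                          sex = character(0), race = character(0),
                          ethnicity = character(0), n = integer(0),
                          audited = logical(0)),
      assignment = character(0)), class = "intersectional_groups"))
  }
  if (!"age_bin" %in% names(encounters)) {
    if (!"age_years" %in% names(encounters)) {
      stop("build_intersectional_groups: need `age_bin` or `age_years`")
    }
    labels <- age_bin_labels(config$age_breaks)
    encounters$age_bin <- labels[findInterval(encounters$age_years,
                                              config$age_breaks)]
  }
  for (ax in c("age_bin", "sex", "race", "ethnicity")) {
    if (!ax %in% names(encounters)) {
      stop("build_intersectional_groups: missing axis column `", ax, "`")
    }
  }
  key <- paste(encounters$age_bin, encounters$sex, encounters$race,
               encounters$ethnicity, sep = "|")
  tab <- as.data.frame(table(key), stringsAsFactors = FALSE)
  names(tab) <- c("group", "n")
  parts <- do.call(rbind, strsplit(tab$group, "|", fixed = TRUE))
  groups <- data.frame(group = tab$group, age_bin = parts[, 1],
                       sex = parts[, 2], race = parts[, 3],
                       ethnicity = parts[, 4], n = as.integer(tab$n))
  groups$audited <- groups$n >= config$min_group_size
  groups <- groups[order(-groups$n, groups$group), ]
  rownames(groups) <- NULL
  structure(list(groups = groups, assignment = key),
            class = "intersectional_groups")
}

#' Diagnostic odds ratio with continuity correction
#'
#' DOR = (TP/FN) / (FP/TN): the odds of a positive call among true cases
#' over the odds among non-cases. When any cell is zero, 0.5 is added to
#' all four cells (Haldane-Anscombe correction) and the correction is
#' flagged.
#'
#' @param TP,FP,FN,TN confusion-cell counts (vectorized).
#' @return data.frame with `dor` and logical `corrected`.
#' @export
diagnostic_odds_ratio <- function(TP, FP, FN, TN) {
  cells <- cbind(TP, FP, FN, TN)
  if (any(cells < 0)) stop("diagnostic_odds_ratio: counts must be >= 0")
  if (any(rowSums(cells) == 0)) {
    stop("diagnostic_odds_ratio: all-zero confusion table")
  }
  corrected <- rowSums(cells == 0) > 0
  adj <- ifelse(corrected, 0.5, 0)
  dor <- ((TP + adj) / (FN + adj)) / ((FP + adj) / (TN + adj))
  data.frame(dor = dor, corrected = corrected)
}

confusion_cells <- function(pred, truth) {
  c(TP = sum(pred & truth), FP = sum(pred & !truth),
    FN = sum(!pred & truth), TN = sum(!pred & !truth))
}

metrics_from_cells <- function(cells) {
  n <- sum(cells)
  dor <- diagnostic_odds_ratio(cells["TP"], cells["FP"], cells["FN"],
                               cells["TN"])
  data.frame(
    n = n, TP = cells[["TP"]], FP = cells[["FP"]], FN = cells[["FN"]],
    TN = cells[["TN"]],
    overdiagnosis = if (cells[["FP"]] + cells[["TN"]] > 0)
      cells[["FP"]] / (cells[["FP"]] + cells[["TN"]]) else NA_real_,
    underdiagnosis = if (cells[["TP"]] + cells[["FN"]] > 0)
      cells[["FN"]] / (cells[["TP"]] + cells[["FN"]]) else NA_real_,
    accuracy = (cells[["TP"]] + cells[["TN"]]) / n,
    dor = dor$dor, dor_corrected = dor$corrected
  )
}

#' Confusion metrics at a decision threshold, per group and overall
#'
#' Classifies `probability >= threshold` as positive (already-binary
#' decisions are used as-is and the threshold is ignored) and tabulates,
#' overall and within each audited intersectional group: the four confusion
#' cells, overdiagnosis rate FP/(FP+TN), underdiagnosis rate FN/(TP+FN),
#' accuracy and DOR. The overall row sums cells over all encounters,
#' including those in sub-threshold groups. A group with no true positives
#' has undefined underdiagnosis, reported as `NA`.
#'
#' @param scores numeric probabilities, or logical decisions.
#' @param truth logical outcome labels (strict or liberal UTI).
#' @param threshold decision threshold as a probability; ignored for
#'   logical `scores`.
#' @param groups [build_intersectional_groups()] result, or NULL for
#'   overall only.
#' @return data.frame of metrics; first row `overall`, then one row per
#'   audited group (size descending).
#' @export
confusion_at_threshold <- function(scores, truth, threshold = 0.5,
                                   groups = NULL) {
  truth <- as.logical(truth)
  pred <- if (is.logical(scores)) scores else scores >= threshold
  rows <- cbind(data.frame(group = "overall"),
                metrics_from_cells(confusion_cells(pred, truth)))
  if (!is.null(groups)) {
    audited <- groups$groups$group[groups$groups$audited]
    for (g in audited) {
      idx <- groups$assignment == g
      rows <- rbind(rows, cbind(data.frame(group = g),
                                metrics_from_cells(
                                  confusion_cells(pred[idx], truth[idx]))))
    }
  }
  rownames(rows) <- NULL
  rows
}

#' Policy-constrained decision threshold
#'
#' Scans the candidate thresholds downward from the top and returns the
#' highest integer percent at which the model's underdiagnosis
#' (false-negative) rate is strictly below the physician's in every audited
#' intersectional group — the operating point at which no audited group
#' would see an increase in missed diagnoses if the model replaced the
#' physician's judgment. By monotonicity (lowering the threshold never
#' increases the false-negative rate) the first satisfying threshold found
#' on the way down is the highest.
#'
#' @param probs model probabilities.
#' @param truth logical outcome labels.
#' @param physician_decisions logical physician-diagnosis vector.
#' @param groups [build_intersectional_groups()] result with >= 1 audited
#'   group.
#' @param config an [audit_config()].
#' @param symptom_gate optional logical vector AND-ed into the model's
#'   decision (the binary sign/symptom rule of the strict definition);
#'   default all TRUE.
#' @return integer percent, with attribute `scan` (data.frame of the full
#'   downward scan: threshold, number of violating groups, feasible flag).
#' @export
select_policy_constrained_threshold <- function(probs, truth,
                                                physician_decisions, groups,
                                                config = audit_config(),
                                                symptom_gate = NULL) {
  truth <- as.logical(truth)
  if (is.null(symptom_gate)) symptom_gate <- rep(TRUE, length(probs))
  audited <- groups$groups$group[groups$groups$audited]
  if (length(audited) == 0L) {
    stop("select_policy_constrained_threshold: no audited groups")
  }
  idx_of <- lapply(audited, function(g) which(groups$assignment == g))
  names(idx_of) <- audited
  phys_fnr <- vapply(audited, function(g) {
    i <- idx_of[[g]]
    pos <- truth[i]
    if (!any(pos)) return(NA_real_)
    mean(!physician_decisions[i][pos])
  }, numeric(1))
  usable <- !is.na(phys_fnr)
  if (!any(usable)) {
    stop("select_policy_constrained_threshold: physician underdiagnosis ",
         "undefined in every audited group")
  }
  cands <- sort(config$candidate_thresholds, decreasing = TRUE)
  scan <- data.frame(threshold = cands, n_violating = NA_integer_,
                     feasible = NA)
  chosen <- NA_integer_
  for (r in seq_along(cands)) {
    t <- cands[r]
    viol <- 0L
    for (g in audited[usable]) {
      i <- idx_of[[g]]
      pos <- truth[i]
      model_fnr <- mean(!((probs[i] >= t / 100) & symptom_gate[i])[pos])
      if (!(model_fnr < phys_fnr[[g]])) viol <- viol + 1L
    }
    scan$n_violating[r] <- viol
    scan$feasible[r] <- viol == 0L
    if (viol == 0L && is.na(chosen)) {
      chosen <- t
      break
    }
  }
  scan <- scan[!is.na(scan$feasible), , drop = FALSE]
  if (is.na(chosen)) {
    bad <- audited[usable][vapply(audited[usable], function(g) {
      i <- idx_of[[g]]
      pos <- truth[i]
      t1 <- min(config$candidate_thresholds)
      model_fnr <- mean(!((probs[i] >= t1 / 100) & symptom_gate[i])[pos])
      !(model_fnr < phys_fnr[[g]])
    }, logical(1))]
    stop("select_policy_constrained_threshold: infeasible -- model ",
         "underdiagnosis is not below the physician's at the lowest ",
         "threshold for group(s): ", paste(bad, collapse = "; "))
  }
  structure(chosen, scan = scan)
}

#' Youden-optimal decision threshold
#'
#' Argmax over the candidate integer-percent thresholds of Youden's
#' J = TPR - FPR. Ties are broken toward the lowest threshold (favoring
#' sensitivity); whether a tie occurred is recorded on the result.
#'
#' @param probs model probabilities.
#' @param truth logical outcomes with both classes present.
#' @param candidate_thresholds integer percents (default 1:99).
#' @return integer percent with attributes `J` (attained maximum) and
#'   `tie_broken` (logical).
#' @export
youden_optimal_threshold <- function(probs, truth,
                                     candidate_thresholds = 1:99) {
  truth <- as.logical(truth)
  if (!any(truth) || all(truth)) {
    stop("youden_optimal_threshold: both classes must be present")
  }
  cands <- sort(as.integer(candidate_thresholds))
  j <- vapply(cands, function(t) {
    pred <- probs >= t / 100
    mean(pred[truth]) - mean(pred[!truth])
  }, numeric(1))
  best <- max(j)
  hits <- which(j >= best - 1e-12)
  structure(cands[hits[1]], J = best, tie_broken = length(hits) > 1L)
}

#' Coefficient of variation across groups
#'
#' CV = sample SD (n-1 denominator) divided by the mean: the package's
#' cross-group equity-variance measure for accuracy and DOR.
#'
#' @param values numeric metric values, one per group (>= 2, positive mean).
#' @return list with `cv` and `n`.
#' @export
coefficient_of_variation <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) {
    stop("coefficient_of_variation: need at least 2 values")
  }
  m <- mean(values)
  if (m <= 0) stop("coefficient_of_variation: mean must be positive")
  list(cv = sd(values) / m, n = length(values))
}

#' Normal-approximation confidence interval for a coefficient of variation
#'
#' Half-width `z * sqrt(1 / (2 * (n_groups - 1)))` around the point CV,
#' with the lower bound floored at 0. The formula used is recorded on the
#' result so reports are explicit about the approximation.
#'
#' @param cv point CV estimate.
#' @param n_groups number of groups the CV was computed over (>= 2).
#' @param z_quantile normal quantile (default 1.96 for 95%).
#' @return numeric `c(ci_low, ci_high)` with attribute `formula`.
#' @export
cv_confidence_interval <- function(cv, n_groups, z_quantile = 1.96) {
  if (n_groups < 2L) stop("cv_confidence_interval: n_groups must be >= 2")
  half <- z_quantile * sqrt(1 / (2 * (n_groups - 1)))
  structure(c(ci_low = max(0, cv - half), ci_high = cv + half),
            formula = "normal approximation, half-width z*sqrt(1/(2*(n-1)))")
}

cv_estimate <- function(values, metric, z_quantile = 1.96) {
  est <- coefficient_of_variation(values)
  ci <- cv_confidence_interval(est$cv, est$n, z_quantile)
  data.frame(metric = metric, cv = est$cv, n_groups = est$n,
             ci_low = ci[["ci_low"]], ci_high = ci[["ci_high"]],
             ci_formula = attr(ci, "formula"))
}

#' Physician diagnosis rate by decile of model-predicted probability
#'
#' Ranks encounters into equal-count bins of model-predicted culture
#' positivity and reports, per decile, the encounter count, the physician
#' diagnosis rate and the observed culture-positivity rate — an indirect
#' read on the probability threshold physicians implicitly operate at.
#'
#' @param probs model probabilities in [0, 1].
#' @param physician_decisions logical physician-diagnosis vector.
#' @param culture_truth logical observed culture positivity.
#' @param n_deciles number of bins (default 10).
#' @return data.frame with `decile`, `n`, `mean_prob`,
#'   `physician_dx_rate`, `culture_positive_rate`.
#' @export
decile_diagnosis_table <- function(probs, physician_decisions, culture_truth,
                                   n_deciles = 10L) {
  n <- length(probs)
  if (n < n_deciles) {
    stop("decile_diagnosis_table: need at least ", n_deciles, " encounters")
  }
  if (any(probs < 0 | probs > 1, na.rm = TRUE)) {
    stop("decile_diagnosis_table: probs must be in [0, 1]")
  }
  dec <- ceiling(n_deciles * rank(probs, ties.method = "first") / n)
  agg <- function(v) tapply(v, dec, mean)
  data.frame(decile = sort(unique(dec)),
             n = as.integer(table(dec)),
             mean_prob = as.numeric(agg(probs)),
             physician_dx_rate = as.numeric(agg(as.numeric(physician_decisions))),
             culture_positive_rate = as.numeric(agg(as.numeric(culture_truth))))
}

#' Run the full intersectional equity audit
#'
#' Assembles the complete model-versus-physician comparison on a labeled
#' cohort with model probabilities: intersectional groups; the
#' policy-constrained threshold (chosen on the strict definition, the
#' primary analysis), the Youden-optimal threshold (on culture positivity,
#' the model's target) and the fixed externally reported clinician
#' threshold; per-group and overall confusion metrics for each of
#' {model at policy threshold, model at fixed threshold, model at Youden
#' threshold, physician proxy} under each requested UTI definition; the
#' cross-group coefficient of variation (with normal-approximation CIs)
#' for accuracy and DOR; and the decile table of physician diagnosis rates.
#'
#' Under the strict definition the model's decision is
#' `probability >= threshold AND any sign/symptom` (the binary symptom
#' rule); under the liberal definition it is the probability threshold
#' alone. Physician metrics always use the same truth labels as model
#' metrics, never each other.
#'
#' @param labeled labeled, harmonized cohort (see [label_cohort()]).
#' @param probs cohort-wide model probabilities (see
#'   [cross_fit_probabilities()]).
#' @param config an [audit_config()].
#' @param definitions subset of `c("strict", "liberal")`.
#' @return object of class `equity_report`.
#' @export
run_full_audit <- function(labeled, probs, config = audit_config(),
                           definitions = c("strict", "liberal")) {
  definitions <- match.arg(definitions, several.ok = TRUE)
  if (length(probs) != nrow(labeled)) {
    stop("run_full_audit: probs length must match the cohort")
  }
  groups <- build_intersectional_groups(labeled, config)
  phys <- as.logical(labeled$physician_diagnosed)
  gate <- as.logical(labeled$any_symptom)
  strict_truth <- as.logical(labeled$strict_uti)
  policy <- select_policy_constrained_threshold(
    probs, strict_truth, phys, groups, config, symptom_gate = gate)
  youden <- youden_optimal_threshold(probs,
                                     as.logical(labeled$culture_positive),
                                     config$candidate_thresholds)
  thresholds <- list(
    policy = as.integer(policy) / 100,
    fixed = config$fixed_clinician_threshold,
    youden = as.integer(youden) / 100
  )
  sources <- c("model_policy", "model_fixed", "model_youden", "physician")
  by_definition <- lapply(definitions, function(def) {
    truth <- as.logical(labeled[[paste0(def, "_uti")]])
    use_gate <- if (def == "strict") gate else rep(TRUE, length(probs))
    decisions <- list(
      model_policy = (probs >= thresholds$policy) & use_gate,
      model_fixed = (probs >= thresholds$fixed) & use_gate,
      model_youden = (probs >= thresholds$youden) & use_gate,
      physician = phys
    )
    per_source <- lapply(sources, function(src) {
      m <- confusion_at_threshold(decisions[[src]], truth, groups = groups)
      grp <- m[m$group != "overall", , drop = FALSE]
      cv <- rbind(cv_estimate(grp$accuracy, "accuracy", config$z_quantile),
                  cv_estimate(grp$dor, "dor", config$z_quantile))
      list(metrics = m, cv = cv)
    })
    names(per_source) <- sources
    per_source
  })
  names(by_definition) <- definitions
  structure(list(
    config = config, groups = groups$groups,
    n_encounters = nrow(labeled),
    thresholds = c(thresholds, list(
      policy_scan = attr(policy, "scan"),
      youden_J = attr(youden, "J"),
      youden_tie_broken = attr(youden, "tie_broken"),
      youden_tie_break = "lowest threshold (favors sensitivity)")),
    results = by_definition,
    deciles = decile_diagnosis_table(probs, phys,
                                     as.logical(labeled$culture_positive),
                                     config$decile_count),
    metadata = list(
      cv_ci_formula = "normal approximation, half-width z*sqrt(1/(2*(n-1)))",
      decision_rule = "probability >= threshold (strict adds the binary sign/symptom gate)")
  ), class = "equity_report")
}

#' @export
print.equity_report <- function(x, ...) {
  cat("Intersectional diagnostic-equity report\n")
  cat(sprintf("  %d encounters; %d groups, %d audited (>= %d encounters)\n",
              x$n_encounters, nrow(x$groups), sum(x$groups$audited),
              x$config$min_group_size))
  cat(sprintf("  thresholds: policy %d%%, fixed %.1f%%, Youden %d%%\n",
              round(100 * x$thresholds$policy),
              100 * x$thresholds$fixed, round(100 * x$thresholds$youden)))
  for (def in names(x$results)) {
    cat(sprintf("  [%s definition]\n", def))
    for (src in names(x$results[[def]])) {
      ov <- x$results[[def]][[src]]$metrics[1, ]
      cv <- x$results[[def]][[src]]$cv
      cat(sprintf(
        "    %-13s overdx %5.1f%%  underdx %5.1f%%  acc %.3f  DOR %6.1f  CV(acc) %.3f  CV(DOR) %.3f\n",
        src, 100 * ov$overdiagnosis, 100 * ov$underdiagnosis, ov$accuracy,
        ov$dor, cv$cv[cv$metric == "accuracy"], cv$cv[cv$metric == "dor"]))
    }
  }
  invisible(x)
}

#' @export
summary.equity_report <- function(object, ...) {
  print(object)
  cat("\nAudited groups (size descending):\n")
  print(head(object$groups[object$groups$audited, ], 25), row.names = FALSE)
  invisible(object)
}

#' Write an equity report to disk
#'
#' Emits `report.json` (machine-readable, full content minus the scan),
#' `per_group.csv` (per-definition, per-source group metrics),
#' `threshold_scan.csv` and `deciles.csv`.
#'
#' @param report an [run_full_audit()] result.
#' @param dir output directory (created if absent).
#' @return invisible character vector of file paths.
#' @export
write_equity_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  per_group <- do.call(rbind, lapply(names(report$results), function(def) {
    do.call(rbind, lapply(names(report$results[[def]]), function(src) {
      cbind(data.frame(definition = def, source = src),
            report$results[[def]][[src]]$metrics)
    }))
  }))
  cv_table <- do.call(rbind, lapply(names(report$results), function(def) {
    do.call(rbind, lapply(names(report$results[[def]]), function(src) {
      cbind(data.frame(definition = def, source = src),
            report$results[[def]][[src]]$cv)
    }))
  }))
  json <- list(
    n_encounters = report$n_encounters,
    min_group_size = report$config$min_group_size,
    n_groups = nrow(report$groups),
    n_audited_groups = sum(report$groups$audited),
    thresholds = list(policy = report$thresholds$policy,
                      fixed = report$thresholds$fixed,
                      youden = report$thresholds$youden,
                      youden_J = report$thresholds$youden_J),
    overall = lapply(report$results, function(defres) {
      lapply(defres, function(srcres) {
        ov <- srcres$metrics[1, ]
        list(TP = ov$TP, FP = ov$FP, FN = ov$FN, TN = ov$TN,
             overdiagnosis = ov$overdiagnosis,
             underdiagnosis = ov$underdiagnosis,
             accuracy = ov$accuracy, dor = ov$dor)
      })
    }),
    cv = lapply(report$results, function(defres) {
      lapply(defres, function(srcres) {
        stats::setNames(lapply(seq_len(nrow(srcres$cv)), function(i) {
          list(cv = srcres$cv$cv[i], ci_low = srcres$cv$ci_low[i],
               ci_high = srcres$cv$ci_high[i])
        }), srcres$cv$metric)
      })
    }),
    deciles = report$deciles,
    metadata = report$metadata
  )
  paths <- c(
    report = file.path(dir, "report.json"),
    per_group = file.path(dir, "per_group.csv"),
    scan = file.path(dir, "threshold_scan.csv"),
    deciles = file.path(dir, "deciles.csv")
  )
  jsonlite::write_json(json, paths["report"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  write.csv(per_group, paths["per_group"], row.names = FALSE)
  write.csv(report$thresholds$policy_scan, paths["scan"], row.names = FALSE)
  write.csv(report$deciles, paths["deciles"], row.names = FALSE)
  invisible(paths)
}
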