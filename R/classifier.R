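#' Default hyperparameter search space for the gradient-boosted classifier
#'
#' Standard XGBoost ranges: tree depth 2-10, learning rate 0.01-0.3 sampled
#' on the log scale, 100-1000 trees, row/column subsampling 0.5-1, L1/L2
#' regularization 0-5.
#'
#' @return named list of `c(lower, upper)` ranges; integer ranges for
#'   `max_depth` and `nrounds`, log-scale sampling for `eta`.
#' @export
default_search_space <- function() {
  list(max_depth = c(2L, 10L), eta = c(0.01, 0.3), nrounds = c(100L, 1000L),
       subsample = c(0.5, 1), colsample_bytree = c(0.5, 1),
       alpha = c(0, 5), lambda = c(0, 5))
}

#' Training protocol for the culture-positivity classifier
#'
#' Bundles the training contract: an 80/20 patient-level train/test split,
#' 5-fold cross-validation during tuning, AUROC as the tuning objective,
#' a trial budget for seeded random search over the hyperparameter space,
#' and class weighting by the negative:positive ratio.
#'
#' @param test_fraction held-out test fraction in (0, 1); default 0.20.
#' @param n_folds cross-validation folds (>= 2); default 5.
#' @param tuning_budget number of random-search trials; default 50. A
#'   budget of 0 fits documented default hyperparameters and flags it.
#' @param search_space ranges per [default_search_space()].
#' @param seed integer seed governing the split, fold assignment, trial
#'   sampling and the booster's own RNG.
#' @return object of class `training_protocol`.
#' @export
training_protocol <- function(test_fraction = 0.2, n_folds = 5L,
                              tuning_budget = 50L,
                              search_space = default_search_space(),
                              seed = 1L) {
  where <- "training_protocol"
  if (!is.numeric(test_fraction) || length(test_fraction) != 1L ||
      test_fraction <= 0 || test_fraction >= 1) {
    stop_field(where, "test_fraction", "must be in (0, 1)")
  }
  n_folds <- check_count(n_folds, "n_folds", where, min = 2L)
  tuning_budget <- check_count(tuning_budget, "tuning_budget", where, min = 0L)
  need <- names(default_search_space())
  if (!all(need %in% names(search_space))) {
    stop_field(where, "search_space",
               paste("must define ranges for:", paste(need, collapse = ", ")))
  }
  seed <- check_count(seed, "seed", where, min = 0L)
  structure(list(test_fraction = test_fraction, n_folds = n_folds,
                 objective_metric = "auroc", tuning_budget = tuning_budget,
                 search_space = search_space, seed = seed),
            class = "training_protocol")
}

#' Patient-level stratified train/test split
#'
#' Splits encounters into train and test partitions by patient, so no
#' patient contributes encounters to both sides (no leakage), stratifying
#' patients by whether any of their encounters is outcome-positive so that
#' outcome prevalence is comparable across partitions.
#'
#' @param data labeled encounter data.frame with `patient_id`.
#' @param protocol a [training_protocol()].
#' @param outcome name of the logical outcome column (default
#'   `"culture_positive"`).
#' @return list with `train` and `test` data.frames; their union is the
#'   input.
#' @export
split_patient_stratified <- function(data, protocol,
                                     outcome = "culture_positive") {
  if (!"patient_id" %in% names(data)) {
    stop("split_patient_stratified: `patient_id` column is required")
  }
  if (!outcome %in% names(data)) {
    stop("split_patient_stratified: outcome column `", outcome, "` not found")
  }
  y <- as.logical(data[[outcome]])
  pat_pos <- tapply(y, data$patient_id, any)
  n_by_class <- table(pat_pos)
  if (length(n_by_class) < 2L || any(n_by_class < 10L)) {
    stop("split_patient_stratified: need at least 10 patients per ",
         "patient-level outcome class")
  }
  set.seed(derive_seed(protocol$seed, "split"))
  test_patients <- unlist(lapply(split(names(pat_pos), pat_pos), function(p) {
    sample(p, round(length(p) * protocol$test_fraction))
  }), use.names = FALSE)
  in_test <- data$patient_id %in% test_patients
  list(train = data[!in_test, , drop = FALSE],
       test = data[in_test, , drop = FALSE])
}

#' Per-observation class weights from the class ratio
#'
#' Positive observations receive weight `n_negative / n_positive`, negative
#' observations weight 1, balancing the total weight on each class.
#'
#' @param labels logical (or 0/1) outcome vector with both classes present.
#' @return numeric weight per observation.
#' @export
compute_class_weights <- function(labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("compute_class_weights: both classes must be present")
  }
  ifelse(labels, n_neg / n_pos, 1)
}

# Model feature matrix: the nine ordinal urinalysis components as integers
# (missing stays missing -- xgboost routes NA natively, no imputation) plus
# the clinical site one-hot encoded. Demographics never enter: asserted.
build_feature_matrix <- function(data, site_levels = NULL) {
  comps <- ua_components()
  miss <- setdiff(c(comps, "site_id"), names(data))
  if (length(miss)) {
    stop("build_feature_matrix: missing feature column(s): ",
         paste(miss, collapse = ", "), " (run harmonize_table first?)")
  }
  if (is.null(site_levels)) site_levels <- sort(unique(data$site_id))
  site <- factor(data$site_id, levels = site_levels)
  site_oh <- matrix(0, nrow(data), length(site_levels),
                    dimnames = list(NULL, paste0("site_", site_levels)))
  site_oh[cbind(seq_len(nrow(data)), as.integer(site))] <- 1
  x <- cbind(as.matrix(data[, comps, drop = FALSE]) * 1.0, site_oh)
  forbidden <- c("age_years", "age_bin", "sex", "race", "ethnicity",
                 "patient_id")
  if (any(forbidden %in% colnames(x))) {
    stop("build_feature_matrix: demographic feature leaked into the model matrix")
  }
  attr(x, "site_levels") <- site_levels
  x
}

# Trials are drawn one at a time from the seeded stream, so the first k
# trials are identical for every budget >= k (monotone-budget property).
sample_trials <- function(space, budget, seed) {
  set.seed(derive_seed(seed, "tuning"))
  draw <- function(rng, int = FALSE, log = FALSE) {
    u <- runif(1)
    v <- if (log) exp(log(rng[1]) + u * (log(rng[2]) - log(rng[1])))
    else rng[1] + u * (rng[2] - rng[1])
    if (int) as.integer(round(v)) else v
  }
  do.call(rbind, lapply(seq_len(budget), function(i) {
    data.frame(
      trial = i,
      max_depth = draw(space$max_depth, int = TRUE),
      eta = draw(space$eta, log = TRUE),
      nrounds = draw(space$nrounds, int = TRUE),
      subsample = draw(space$subsample),
      colsample_bytree = draw(space$colsample_bytree),
      alpha = draw(space$alpha),
      lambda = draw(space$lambda)
    )
  }))
}

fit_booster <- function(x, y, weights, params, nrounds, seed) {
  dtrain <- xgboost::xgb.DMatrix(x, label = as.numeric(y), weight = weights)
  xgboost::xgb.train(
    params = c(params, list(objective = "binary:logistic", nthread = 1L,
                            seed = seed, verbosity = 0L)),
    data = dtrain, nrounds = nrounds, verbose = 0)
}

# Patient-grouped, patient-label-stratified fold assignment (per encounter).
assign_folds <- function(patient_id, y, n_folds, seed) {
  set.seed(seed)
  pat_pos <- tapply(as.logical(y), patient_id, any)
  fold_of_patient <- unlist(unname(lapply(split(names(pat_pos), pat_pos),
                                          function(p) {
    setNames(sample(rep_len(seq_len(n_folds), length(p))), p)
  })))
  unname(fold_of_patient[as.character(patient_id)])
}

#' Tune and fit the gradient-boosted culture-positivity classifier
#'
#' Seeded random search over the protocol's hyperparameter space: each
#' trial is scored by mean patient-grouped k-fold cross-validated AUROC on
#' the training set (class weights recomputed within each fold's training
#' part), the best trial is refit on the full training set, and every trial
#' is recorded. Trials are drawn up-front from the seeded stream, so a
#' larger budget evaluates a superset of a smaller budget's trials and the
#' attained objective is monotone in the budget. A budget of 0 skips the
#' search and fits documented defaults (depth 6, eta 0.1, 300 trees), with
#' `default_hyperparameters = TRUE` flagged on the result.
#'
#' @param train training data.frame (harmonized + labeled).
#' @param protocol a [training_protocol()].
#' @param outcome logical outcome column name (default `"culture_positive"`).
#' @return object of class `uti_model`: the fitted booster plus the tuned
#'   hyperparameters, the trial log, fold scores, feature names and site
#'   levels.
#' @export
tune_and_fit <- function(train, protocol, outcome = "culture_positive") {
  y <- as.logical(train[[outcome]])
  x <- build_feature_matrix(train)
  folds <- assign_folds(train$patient_id, y, protocol$n_folds,
                        derive_seed(protocol$seed, "split"))
  default_used <- protocol$tuning_budget == 0L
  if (default_used) {
    message("tune_and_fit: tuning budget 0 -- fitting default hyperparameters")
    trials <- data.frame(trial = 1L, max_depth = 6L, eta = 0.1,
                         nrounds = 300L, subsample = 1, colsample_bytree = 1,
                         alpha = 0, lambda = 1)
  } else {
    trials <- sample_trials(protocol$search_space, protocol$tuning_budget,
                            protocol$seed)
  }
  cv_auc <- function(tr) {
    params <- list(max_depth = tr$max_depth, eta = tr$eta,
                   subsample = tr$subsample,
                   colsample_bytree = tr$colsample_bytree,
                   alpha = tr$alpha, lambda = tr$lambda)
    scores <- vapply(seq_len(protocol$n_folds), function(k) {
      tr_i <- folds != k
      w <- compute_class_weights(y[tr_i])
      fit <- fit_booster(x[tr_i, , drop = FALSE], y[tr_i], w, params,
                         tr$nrounds, protocol$seed)
      auroc(predict(fit, xgboost::xgb.DMatrix(x[!tr_i, , drop = FALSE])),
            y[!tr_i])
    }, numeric(1))
    mean(scores)
  }
  trials$mean_cv_auroc <- vapply(seq_len(nrow(trials)),
                                 function(i) cv_auc(trials[i, ]), numeric(1))
  best <- trials[which.max(trials$mean_cv_auroc), ]
  params <- list(max_depth = best$max_depth, eta = best$eta,
                 subsample = best$subsample,
                 colsample_bytree = best$colsample_bytree,
                 alpha = best$alpha, lambda = best$lambda)
  booster <- fit_booster(x, y, compute_class_weights(y), params,
                         best$nrounds, protocol$seed)
  structure(list(
    booster = booster, params = params, nrounds = best$nrounds,
    best_cv_auroc = best$mean_cv_auroc, trials = trials,
    feature_names = colnames(x), site_levels = attr(x, "site_levels"),
    outcome = outcome, protocol = protocol,
    default_hyperparameters = default_used,
    n_train = nrow(train), prevalence_train = mean(y)
  ), class = "uti_model")
}

#' Predict culture-positivity probabilities
#'
#' @param object a fitted [tune_and_fit()] model.
#' @param newdata harmonized encounter data.frame.
#' @param ... unused.
#' @return numeric probabilities in [0, 1].
#' @export
predict.uti_model <- function(object, newdata, ...) {
  x <- build_feature_matrix(newdata, site_levels = object$site_levels)
  predict(object$booster, xgboost::xgb.DMatrix(x))
}

#' @export
print.uti_model <- function(x, ...) {
  cat("Gradient-boosted urine-culture positivity classifier\n")
  cat(sprintf("  trained on %d encounters (prevalence %.3f)\n",
              x$n_train, x$prevalence_train))
  cat(sprintf("  features: %d urinalysis components + %d site indicators\n",
              length(ua_components()), length(x$site_levels)))
  cat(sprintf("  tuning: %d trial(s), best mean %d-fold CV AUROC %.4f%s\n",
              nrow(x$trials), x$protocol$n_folds, x$best_cv_auroc,
              if (x$default_hyperparameters) " (default hyperparameters)" else ""))
  cat(sprintf("  chosen: depth %d, eta %.3f, %d trees, subsample %.2f\n",
              x$params$max_depth, x$params$eta, x$nrounds, x$params$subsample))
  invisible(x)
}

#' @export
summary.uti_model <- function(object, ...) {
  print(object)
  cat("\nTrial log (top 5 by CV AUROC):\n")
  tl <- object$trials[order(-object$trials$mean_cv_auroc), ]
  print(head(tl, 5), row.names = FALSE, digits = 4)
  invisible(object$trials)
}

#' Cohort-wide cross-fitted probabilities
#'
#' With the tuned configuration fixed, refits the model on k-1 folds and
#' scores the held-out fold, for each fold in a patient-grouped partition of
#' the full cohort, so every encounter is scored by a model that never saw
#' it (or its patient). This is the probability vector the equity audit
#' consumes.
#'
#' @param data full labeled cohort.
#' @param model fitted [tune_and_fit()] model supplying hyperparameters.
#' @param outcome logical outcome column (default the model's).
#' @return numeric probability per row of `data`.
#' @export
cross_fit_probabilities <- function(data, model, outcome = model$outcome) {
  y <- as.logical(data[[outcome]])
  x <- build_feature_matrix(data, site_levels =
                              sort(unique(c(model$site_levels, data$site_id))))
  n_folds <- model$protocol$n_folds
  folds <- assign_folds(data$patient_id, y, n_folds,
                        derive_seed(model$protocol$seed, "crossfit"))
  probs <- rep(NA_real_, nrow(data))
  for (k in seq_len(n_folds)) {
    tr_i <- folds != k
    w <- compute_class_weights(y[tr_i])
    fit <- fit_booster(x[tr_i, , drop = FALSE], y[tr_i], w, model$params,
                       model$nrounds, model$protocol$seed)
    probs[!tr_i] <- predict(fit, xgboost::xgb.DMatrix(x[!tr_i, , drop = FALSE]))
  }
  probs
}

#' Evaluate classifier probabilities
#'
#' Overall AUROC and PR-AUC, a 10-bin equal-width calibration curve, and
#' (optionally) per-intersectional-group AUROC with bootstrap CIs. A group
#' observing a single outcome class gets `NA` AUROC, reported, not dropped.
#'
#' @param probs predicted probabilities.
#' @param truth logical outcomes.
#' @param group optional group membership vector for per-group AUROC.
#' @param bins calibration bins (default 10).
#' @param n_boot bootstrap replicates for group CIs (default 200).
#' @param seed bootstrap seed.
#' @return list of class `model_metrics`: `auroc`, `pr_auc`, `calibration`,
#'   `group_auroc` (NULL when no groups given), `n`, `prevalence`.
#' @export
evaluate_model <- function(probs, truth, group = NULL, bins = 10L,
                           n_boot = 200L, seed = 1L) {
  truth <- as.logical(truth)
  out <- list(
    auroc = auroc(probs, truth),
    pr_auc = pr_auc(probs, truth),
    calibration = calibration_curve(probs, truth, bins),
    group_auroc = if (!is.null(group)) {
      group_auroc(probs, truth, group, n_boot = n_boot,
                  seed = derive_seed(seed, "evaluation"))
    },
    n = length(truth), prevalence = mean(truth)
  )
  structure(out, class = "model_metrics")
}

#' @export
print.model_metrics <- function(x, ...) {
  cat(sprintf("n = %d encounters, prevalence %.3f\n", x$n, x$prevalence))
  cat(sprintf("AUROC  %.4f\nPR-AUC %.4f\n", x$auroc, x$pr_auc))
  if (!is.null(x$group_auroc)) {
    cat(sprintf("per-group AUROC over %d groups (range %.3f-%.3f)\n",
                nrow(x$group_auroc), min(x$group_auroc$auroc, na.rm = TRUE),
                max(x$group_auroc$auroc, na.rm = TRUE)))
  }
  invisible(x)
}

#' Additive per-feature attribution for a fitted model
#'
#' Tree-path additive contributions (SHAP values) from the booster itself:
#' per row, per-feature contributions plus the base value reconstruct the
#' model's margin (log-odds) output exactly, which is verified and reported.
#' Site indicator columns are aggregated into a single `site` feature.
#' The summary ranks features by mean absolute contribution with the mean
#' signed contribution among rows where the feature is elevated as the
#' direction.
#'
#' @param model fitted [tune_and_fit()] model.
#' @param data harmonized encounter data.frame to explain.
#' @return list of class `feature_attribution`: `contributions` (row x
#'   feature matrix incl. `site` and `BIAS`), `summary` (ranked data.frame),
#'   `additivity_max_error`.
#' @export
feature_attribution <- function(model, data) {
  x <- build_feature_matrix(data, site_levels = model$site_levels)
  dm <- xgboost::xgb.DMatrix(x)
  contrib <- predict(model$booster, dm, predcontrib = TRUE)
  margin <- predict(model$booster, dm, outputmargin = TRUE)
  add_err <- max(abs(rowSums(contrib) - margin))
  bias_col <- intersect(c("BIAS", "(Intercept)"), colnames(contrib))[1]
  site_cols <- grep("^site_", colnames(contrib))
  comp_cols <- setdiff(colnames(contrib),
                       c(colnames(contrib)[site_cols], bias_col))
  out <- cbind(contrib[, comp_cols, drop = FALSE],
               site = rowSums(contrib[, site_cols, drop = FALSE]),
               BIAS = contrib[, bias_col])
  feats <- setdiff(colnames(out), "BIAS")
  mean_abs <- colMeans(abs(out[, feats, drop = FALSE]))
  direction <- vapply(feats, function(f) {
    if (f == "site") return(NA_real_)
    v <- x[, f]
    hi <- !is.na(v) & v > 0
    if (!any(hi)) return(NA_real_)
    mean(out[hi, f])
  }, numeric(1))
  summ <- data.frame(feature = feats, mean_abs_contribution = mean_abs,
                     mean_contribution_when_elevated = direction,
                     row.names = NULL)
  summ <- summ[order(-summ$mean_abs_contribution), ]
  summ$rank <- seq_len(nrow(summ))
  structure(list(contributions = out, summary = summ,
                 additivity_max_error = add_err),
            class = "feature_attribution")
}

#' @export
print.feature_attribution <- function(x, ...) {
  cat(sprintf("Additive feature attribution (additivity max error %.2e)\n",
              x$additivity_max_error))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
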