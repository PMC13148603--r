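test_that("patient-stratified split never leaks a patient and balances prevalence", {
  lab <- shared_labeled_cohort()
  prot <- training_protocol(seed = 3, tuning_budget = 1)
  sp <- split_patient_stratified(lab, prot)
  expect_identical(nrow(sp$train) + nrow(sp$test), nrow(lab))
  expect_length(intersect(sp$train$patient_id, sp$test$patient_id), 0)
  expect_lt(abs(mean(sp$train$culture_positive) -
                  mean(sp$test$culture_positive)), 0.02)
  # same seed, same split
  sp2 <- split_patient_stratified(lab, prot)
  expect_identical(sp$test$encounter_id, sp2$test$encounter_id)
  # all encounters of one patient land on one side
  multi <- names(which(table(lab$patient_id) >= 3))[1]
  sides <- c(multi %in% sp$train$patient_id, multi %in% sp$test$patient_id)
  expect_identical(sum(sides), 1L)
})

test_that("split refuses cohorts with under 10 patients per class", {
  lab <- head(shared_labeled_cohort(), 40)
  expect_error(split_patient_stratified(lab, training_protocol()),
               "at least 10 patients")
})

test_that("class weights follow the negative:positive ratio rule", {
  w <- compute_class_weights(rep(c(TRUE, FALSE), c(25, 100)))
  expect_equal(unique(w[1:25]), 4)
  expect_equal(unique(w[26:125]), 1)
  expect_equal(unique(compute_class_weights(c(TRUE, FALSE))), 1)
  # study-scale marginals: 129,369 negatives to 20,080 positives
  w2 <- compute_class_weights(rep(c(TRUE, FALSE), c(20080, 129369)))
  expect_equal(w2[1], 129369 / 20080)
  expect_equal(round(w2[1], 2), 6.44)
  expect_error(compute_class_weights(rep(TRUE, 5)), "both classes")
})

test_that("demographics never enter the model matrix; feature set is fixed", {
  lab <- shared_labeled_cohort()
  x <- utiaudit:::build_feature_matrix(lab)
  expect_setequal(colnames(x),
                  c(ua_components(), paste0("site_", sort(unique(lab$site_id)))))
  expect_false(any(c("age_years", "sex", "race", "ethnicity") %in% colnames(x)))
  # missing component values stay missing in the matrix (no imputation)
  expect_identical(sum(is.na(x[, "blood"])), sum(is.na(lab$blood)))
})

test_that("tuning objective is monotone in budget and deterministic in seed", {
  lab <- head(shared_labeled_cohort(), 2500)
  p1 <- training_protocol(tuning_budget = 1, seed = 17,
                          search_space = small_search(c(30L, 60L)))
  p4 <- training_protocol(tuning_budget = 4, seed = 17,
                          search_space = small_search(c(30L, 60L)))
  m1 <- tune_and_fit(lab, p1)
  m4 <- tune_and_fit(lab, p4)
  # trials are drawn from one seeded stream: budget-4 extends budget-1
  expect_equal(m1$trials$eta[1], m4$trials$eta[1])
  expect_gte(m4$best_cv_auroc, m1$best_cv_auroc)
  # every trial is recorded with its score
  expect_identical(nrow(m4$trials), 4L)
  expect_false(anyNA(m4$trials$mean_cv_auroc))
  # identical seed reproduces the tuned configuration and predictions
  m1b <- tune_and_fit(lab, p1)
  expect_identical(m1$params, m1b$params)
  expect_identical(predict(m1, lab), predict(m1b, lab))
})

test_that("budget zero fits flagged default hyperparameters", {
  lab <- head(shared_labeled_cohort(), 1500)
  prot <- training_protocol(tuning_budget = 0, seed = 1)
  expect_message(m <- tune_and_fit(lab, prot), "default hyperparameters")
  expect_true(m$default_hyperparameters)
  expect_true(all(predict(m, lab) >= 0 & predict(m, lab) <= 1))
})

test_that("strong urinalysis signal trains well above 0.9; null signal near 0.5", {
  prot <- training_protocol(tuning_budget = 2, seed = 29,
                            search_space = small_search(c(60L, 120L)))
  strong <- cohort_config(n_encounters = 6000, seed = 29)
  lab_s <- label_cohort(harmonize_table(generate_cohort(strong), quiet = TRUE))
  sp <- split_patient_stratified(lab_s, prot)
  m_s <- tune_and_fit(sp$train, prot)
  expect_gt(m_s$best_cv_auroc, 0.9)
  expect_gt(auroc(predict(m_s, sp$test), sp$test$culture_positive), 0.9)

  null_sig <- setNames(rep(0, length(ua_components())), ua_components())
  null <- cohort_config(n_encounters = 6000, urinalysis_signal = null_sig,
                        seed = 31)
  lab_n <- label_cohort(harmonize_table(generate_cohort(null), quiet = TRUE))
  sp_n <- split_patient_stratified(lab_n, prot)
  m_n <- tune_and_fit(sp_n$train, prot)
  # mean out-of-fold AUROC under the null signal: indistinguishable from chance
  expect_gte(m_n$best_cv_auroc, 0.45)
  expect_lte(m_n$best_cv_auroc, 0.55)
})

test_that("attribution is additive and tracks the generating signal", {
  lab <- shared_labeled_cohort()
  prot <- training_protocol(tuning_budget = 1, seed = 7,
                            search_space = small_search(c(40L, 80L)))
  m <- tune_and_fit(head(lab, 4000), prot)
  fa <- feature_attribution(m, head(lab, 1000))
  expect_lt(fa$additivity_max_error, 1e-4)
  # contributions + bias reconstruct each row's log-odds output
  margins <- qlogis(predict(m, head(lab, 1000)))
  expect_equal(unname(rowSums(fa$contributions)), margins, tolerance = 1e-5)
  # bacteria carries the strongest generating signal by default
  expect_lte(fa$summary$rank[fa$summary$feature == "bacteria"], 2)
})

test_that("a nitrite-dominant generator puts nitrite in the top two features", {
  sig <- setNames(rep(0.05, length(ua_components())), ua_components())
  sig["nitrites"] <- 1.4
  cfg <- cohort_config(n_encounters = 5000, urinalysis_signal = sig, seed = 19)
  lab <- label_cohort(harmonize_table(generate_cohort(cfg), quiet = TRUE))
  prot <- training_protocol(tuning_budget = 1, seed = 19,
                            search_space = small_search(c(40L, 80L)))
  m <- tune_and_fit(lab, prot)
  fa <- feature_attribution(m, lab)
  expect_lte(fa$summary$rank[fa$summary$feature == "nitrites"], 2)
})

test_that("cross-fitted probabilities score every encounter out of fold", {
  lab <- head(shared_labeled_cohort(), 3000)
  prot <- training_protocol(tuning_budget = 1, seed = 5,
                            search_space = small_search(c(30L, 60L)))
  m <- tune_and_fit(lab, prot)
  p <- cross_fit_probabilities(lab, m)
  expect_length(p, nrow(lab))
  expect_false(anyNA(p))
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(auroc(p, lab$culture_positive), 0.85)
})
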