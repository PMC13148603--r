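test_that("cohort_config validates fields and names the offender", {
  expect_error(cohort_config(n_encounters = -5), "n_encounters")
  expect_error(cohort_config(culture_positive_prevalence = 1.2),
               "culture_positive_prevalence")
  expect_error(cohort_config(n_encounters = 100, n_patients = 200),
               "n_patients")
  expect_error(cohort_config(dialect_mix = c(foo = 1)), "dialect_mix")
  expect_error(
    cohort_config(physician_behavior = data.frame(sensitivity = 2, fpr = 0)),
    "sensitivity")
  # weights normalize to 1
  cfg <- cohort_config(n_encounters = 10)
  expect_equal(sum(cfg$demographic_mix$weight), 1)
})

test_that("same config and seed give identical tables", {
  cfg <- cohort_config(n_encounters = 600, seed = 7)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg2 <- cohort_config(n_encounters = 600, seed = 8)
  expect_false(identical(generate_cohort(cfg), generate_cohort(cfg2)))
})

test_that("structural record invariants hold", {
  co <- shared_labeled_cohort()
  # each encounter maps to one patient; patients can repeat
  expect_identical(anyDuplicated(co$encounter_id), 0L)
  expect_true(any(duplicated(co$patient_id)))
  # a patient's demographics are constant across encounters
  for (col in c("age_bin", "sex", "race", "ethnicity")) {
    expect_true(all(tapply(co[[col]], co$patient_id,
                           function(v) length(unique(v))) == 1L))
  }
  # cfu == 0 iff no organism grew
  expect_identical(co$culture_cfu_per_ml == 0, co$culture_organism == "none")
  expect_true(all(co$age_years >= 18))
  expect_true(all(co$latent_strict_uti <= co$latent_culture_positive))
})

test_that("empirical culture positivity sits in the 3-SE binomial band", {
  cfg <- cohort_config(n_encounters = 20000, culture_positive_prevalence = 0.151,
                       seed = 13)
  co <- generate_cohort(cfg)
  prev <- mean(co$latent_culture_positive)
  se <- sqrt(0.151 * 0.849 / 20000)
  expect_gte(prev, 0.151 - 3 * se)
  expect_lte(prev, 0.151 + 3 * se)
  # and the labeling module recovers the latent state exactly
  lab <- label_cohort(harmonize_table(co, quiet = TRUE))
  expect_identical(lab$culture_positive, co$latent_culture_positive)
})

test_that("symptom rates condition on culture status as configured", {
  co <- shared_labeled_cohort()
  any_sym <- co$sym_likely_uti_symptom | co$sym_exam_finding | co$sym_systemic
  p_pos <- mean(any_sym[co$latent_culture_positive])
  p_neg <- mean(any_sym[!co$latent_culture_positive])
  se_pos <- sqrt(0.892 * 0.108 / sum(co$latent_culture_positive))
  se_neg <- sqrt(0.863 * 0.137 / sum(!co$latent_culture_positive))
  expect_lt(abs(p_pos - 0.892), 3 * se_pos)
  expect_lt(abs(p_neg - 0.863), 3 * se_neg)
})

test_that("injected group-specific physician error rates are recovered by audit", {
  beh <- rbind(
    data.frame(age_bin = NA, sex = "female", race = NA, ethnicity = NA,
               sensitivity = 0.634, fpr = 0.091),
    data.frame(age_bin = NA, sex = "male", race = NA, ethnicity = NA,
               sensitivity = 0.80, fpr = 0.05),
    data.frame(age_bin = NA, sex = NA, race = NA, ethnicity = NA,
               sensitivity = 0.70, fpr = 0.10))
  cfg <- cohort_config(n_encounters = 12000, physician_behavior = beh,
                       seed = 21)
  lab <- label_cohort(harmonize_table(generate_cohort(cfg), quiet = TRUE))
  for (sx in c("female", "male")) {
    i <- lab$sex == sx & lab$strict_uti
    fnr_hat <- mean(!lab$physician_diagnosed[i])
    fnr_true <- 1 - beh$sensitivity[which(beh$sex == sx)]
    se <- sqrt(fnr_true * (1 - fnr_true) / sum(i))
    expect_lt(abs(fnr_hat - fnr_true), 3 * se, label = sx)
    j <- lab$sex == sx & !lab$strict_uti
    fpr_hat <- mean(lab$physician_diagnosed[j])
    fpr_true <- beh$fpr[which(beh$sex == sx)]
    se_fpr <- sqrt(fpr_true * (1 - fpr_true) / sum(j))
    expect_lt(abs(fpr_hat - fpr_true), 3 * se_fpr, label = sx)
  }
})

test_that("explicit versus inferred proxy branches follow the configured split", {
  co <- shared_labeled_cohort()
  dx <- co[co$physician_diagnosed, ]
  share <- mean(dx$proxy_branch == "explicit")
  se <- sqrt(0.92 * 0.08 / nrow(dx))
  expect_lt(abs(share - 0.92), 3 * se)
  expect_true(all(co$proxy_branch[!co$physician_diagnosed] == "none"))
})

test_that("cohort CSV round-trips through write/read", {
  co <- head(shared_labeled_cohort(), 200)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  back <- read_cohort_csv(path)
  expect_identical(nrow(back), 200L)
  expect_identical(back$culture_positive, co$culture_positive)
  expect_identical(back$blood, co$blood)
  expect_identical(is.na(back$ua_blood), is.na(co$ua_blood))
})
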