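test_that("intersectional groups cross the four axes and apply the size floor", {
  df <- data.frame(
    age_bin = rep(c("18-44", "45-64"), c(2500, 1999)),
    sex = "female", race = "white", ethnicity = "non_hispanic")
  g <- build_intersectional_groups(df, audit_config(min_group_size = 2000))
  expect_identical(nrow(g$groups), 2L)
  expect_identical(g$groups$group[g$groups$audited],
                   "18-44|female|white|non_hispanic")
  # deterministic size-descending order
  expect_identical(g$groups$n, c(2500L, 1999L))
  empty <- build_intersectional_groups(df[0, , drop = FALSE], audit_config())
  expect_identical(nrow(empty$groups), 0L)
  # age binned from years when needed
  df2 <- data.frame(age_years = c(18, 44, 45, 85), sex = "f", race = "w",
                    ethnicity = "n")
  g2 <- build_intersectional_groups(df2, audit_config(min_group_size = 1))
  expect_setequal(g2$groups$age_bin, c("18-44", "45-64", "85+"))
})

test_that("a generator mix with 19 large cells yields exactly 19 audit groups", {
  cfg <- cohort_config(n_encounters = 20000, demographic_mix = mix_19_cells(),
                       seed = 77)
  co <- generate_cohort(cfg)
  g <- build_intersectional_groups(co, audit_config(min_group_size = 500))
  expect_identical(sum(g$groups$audited), 19L)
})

test_that("confusion metrics reproduce the published physician operating point", {
  counts <- reference_cohort_counts()
  truth <- rep(c(TRUE, FALSE), c(counts$n_strict_uti, counts$n_no_uti))
  decisions <- rep(c(TRUE, FALSE, TRUE, FALSE),
                   c(counts$physician_true_positive,
                     counts$physician_false_negative,
                     counts$physician_false_positive,
                     counts$n_no_uti - counts$physician_false_positive))
  m <- confusion_at_threshold(decisions, truth)
  expect_identical(m$TP, counts$physician_true_positive)
  expect_equal(round(100 * m$overdiagnosis, 1), 9.1)
  expect_equal(round(100 * m$underdiagnosis, 1), 36.6)
  expect_equal(m$overdiagnosis + (m$TN / (m$FP + m$TN)), 1)
  # all-correct predictions
  perfect <- confusion_at_threshold(truth, truth)
  expect_equal(perfect$overdiagnosis, 0)
  expect_equal(perfect$underdiagnosis, 0)
  expect_equal(perfect$accuracy, 1)
})

test_that("diagnostic odds ratio matches direct arithmetic incl. correction", {
  expect_equal(diagnostic_odds_ratio(9, 1, 1, 9)$dor, 81)
  expect_equal(diagnostic_odds_ratio(5, 5, 5, 5)$dor, 1)
  z <- diagnostic_odds_ratio(5, 2, 0, 3)
  expect_equal(z$dor, (5.5 / 0.5) / (2.5 / 3.5))
  expect_equal(round(z$dor, 1), 15.4)
  expect_true(z$corrected)
  expect_false(diagnostic_odds_ratio(9, 1, 1, 9)$corrected)
  expect_error(diagnostic_odds_ratio(0, 0, 0, 0), "all-zero")
  # random tables agree with the oracle
  set.seed(8)
  for (i in 1:20) {
    cells <- rpois(4, 5)
    if (sum(cells) == 0) next
    expect_equal(diagnostic_odds_ratio(cells[1], cells[2], cells[3],
                                       cells[4])$dor,
                 oracle_dor(cells[1], cells[2], cells[3], cells[4]))
  }
})

test_that("policy-constrained threshold matches exhaustive enumeration", {
  # two-group toy with separated scores: feasible up to 80
  group <- rep(c("a", "b"), each = 40)
  truth <- rep(c(TRUE, FALSE), 40)
  probs <- ifelse(truth, 0.8, 0.2)
  phys <- truth
  phys[which(truth & group == "a")[1:8]] <- FALSE   # FNR 0.4
  phys[which(truth & group == "b")[1:6]] <- FALSE   # FNR 0.3
  gl <- list(groups = data.frame(group = c("a", "b"), n = c(40L, 40L),
                                 audited = TRUE),
             assignment = group)
  class(gl) <- "intersectional_groups"
  t_pkg <- select_policy_constrained_threshold(probs, truth, phys, gl,
                                               audit_config(min_group_size = 1))
  expect_identical(as.integer(t_pkg), 80L)
  expect_identical(oracle_policy(probs, truth, phys, group), 80L)
  # vacuous constraint at the top of the scan: physician misses everything
  # and the model still detects a positive at the 99% threshold
  probs_hi <- ifelse(truth, 0.995, 0.2)
  t_top <- select_policy_constrained_threshold(probs_hi, truth,
                                               rep(FALSE, 80), gl,
                                               audit_config(min_group_size = 1))
  expect_identical(as.integer(t_top), 99L)
  # infeasible: physician is perfect -> explicit error naming groups
  expect_error(
    select_policy_constrained_threshold(probs, truth, truth, gl,
                                        audit_config(min_group_size = 1)),
    "infeasible")
  # random instances agree with enumeration
  set.seed(14)
  for (i in 1:10) {
    n <- 300
    grp <- sample(c("a", "b", "c"), n, replace = TRUE)
    tr <- runif(n) < 0.3
    pr <- pmin(pmax(ifelse(tr, rnorm(n, 0.6, 0.25), rnorm(n, 0.3, 0.25)),
                    0), 1)
    ph <- ifelse(tr, runif(n) < 0.6, runif(n) < 0.1)
    gl2 <- build_intersectional_groups(
      data.frame(age_bin = grp, sex = "f", race = "w", ethnicity = "n"),
      audit_config(min_group_size = 1))
    want <- oracle_policy(pr, tr, ph, grp)
    if (is.na(want)) {
      expect_error(select_policy_constrained_threshold(
        pr, tr, ph, gl2, audit_config(min_group_size = 1)), "infeasible")
    } else {
      got <- select_policy_constrained_threshold(
        pr, tr, ph, gl2, audit_config(min_group_size = 1))
      expect_identical(as.integer(got), as.integer(want))
    }
  }
})

test_that("Youden threshold maximizes TPR - FPR with low tie-break", {
  truth <- rep(c(TRUE, FALSE), each = 20)
  probs <- ifelse(truth, 0.8, 0.2)
  t <- youden_optimal_threshold(probs, truth)
  expect_identical(as.integer(t), 21L)
  expect_equal(attr(t, "J"), 1)
  expect_true(attr(t, "tie_broken"))
  expect_identical(oracle_youden(probs, truth), 21L)
  # single candidate returns itself
  expect_identical(as.integer(youden_optimal_threshold(probs, truth, 37L)),
                   37L)
  # label-independent scores give J near 0
  set.seed(9)
  s <- runif(5000); y <- rbinom(5000, 1, 0.5)
  expect_lt(attr(youden_optimal_threshold(s, y), "J"), 0.06)
  # random instances agree with enumeration
  for (i in 1:10) {
    s <- round(runif(200), 2)
    y <- rbinom(200, 1, 0.4)
    expect_identical(as.integer(youden_optimal_threshold(s, y)),
                     as.integer(oracle_youden(s, y)))
  }
})

test_that("coefficient of variation and its CI follow the stated formulas", {
  expect_equal(coefficient_of_variation(c(1, 1, 1))$cv, 0)
  expect_equal(coefficient_of_variation(c(2, 4, 6))$cv, 0.5)
  expect_equal(coefficient_of_variation(c(10, 20))$cv, sqrt(50) / 15)
  expect_equal(round(coefficient_of_variation(c(10, 20))$cv, 3), 0.471)
  expect_error(coefficient_of_variation(c(-3, 1)), "mean must be positive")
  expect_error(coefficient_of_variation(5), "at least 2")
  ci <- cv_confidence_interval(0.48, 19)
  expect_equal(unname(ci), c(0.48 - 1.96 / 6, 0.48 + 1.96 / 6),
               ignore_attr = TRUE)
  expect_equal(round(unname(ci), 2), c(0.15, 0.81), ignore_attr = TRUE)
  ci2 <- cv_confidence_interval(0.039, 19)
  expect_equal(unname(ci2[1]), 0, ignore_attr = TRUE)   # floored at zero
  expect_match(attr(ci2, "formula"), "normal approximation")
  # width shrinks to zero as groups grow
  wide <- cv_confidence_interval(0.5, 10)
  narrow <- cv_confidence_interval(0.5, 10000)
  expect_lt(narrow[[2]] - narrow[[1]], wide[[2]] - wide[[1]])
  expect_equal(unname(narrow), c(0.5, 0.5), tolerance = 0.03,
               ignore_attr = TRUE)
})

test_that("decile table exposes thresholding and calibration behavior", {
  set.seed(12)
  p <- runif(5000)
  # physician thresholding at the median: step function across deciles
  phys <- p >= stats::median(p)
  truth <- runif(5000) < p
  tab <- decile_diagnosis_table(p, phys, truth)
  expect_identical(nrow(tab), 10L)
  expect_identical(sum(tab$n), 5000L)
  expect_equal(tab$physician_dx_rate[1:5], rep(0, 5), tolerance = 1e-12)
  expect_equal(tab$physician_dx_rate[6:10], rep(1, 5), tolerance = 1e-12)
  # calibrated truth rises monotonically across deciles
  expect_true(all(diff(tab$culture_positive_rate) > 0))
  # label-independent physician decisions are flat across deciles
  flat <- decile_diagnosis_table(p, runif(5000) < 0.3, truth)
  expect_lt(max(flat$physician_dx_rate) - min(flat$physician_dx_rate), 0.08)
  expect_error(decile_diagnosis_table(runif(5), rep(TRUE, 5), rep(TRUE, 5)),
               "at least 10")
})

test_that("threshold monotonicity: lowering never increases underdiagnosis", {
  set.seed(23)
  truth <- runif(2000) < 0.2
  probs <- pmin(pmax(ifelse(truth, rnorm(2000, 0.6, 0.2),
                            rnorm(2000, 0.3, 0.2)), 0), 1)
  under <- over <- numeric(99)
  for (t in 1:99) {
    m <- confusion_at_threshold(probs, truth, t / 100)
    under[t] <- m$underdiagnosis
    over[t] <- m$overdiagnosis
  }
  expect_true(all(diff(under) >= 0))  # rising threshold -> more misses
  expect_true(all(diff(over) <= 0))   # rising threshold -> fewer false alarms
})

test_that("per-group confusion cells conserve counts and reconcile rates", {
  lab <- shared_labeled_cohort()
  acfg <- audit_config(min_group_size = 150)
  g <- build_intersectional_groups(lab, acfg)
  set.seed(3)
  probs <- pmin(pmax(ifelse(lab$strict_uti, rnorm(nrow(lab), 0.6, 0.2),
                            rnorm(nrow(lab), 0.25, 0.2)), 0), 1)
  m <- confusion_at_threshold(probs, lab$strict_uti, 0.45, g)
  overall <- m[m$group == "overall", ]
  expect_identical(overall$TP + overall$FP + overall$FN + overall$TN,
                   nrow(lab))
  per_group <- m[m$group != "overall", ]
  for (i in seq_len(nrow(per_group))) {
    r <- per_group[i, ]
    expect_identical(r$TP + r$FP + r$FN + r$TN, r$n)
    expect_equal(r$accuracy, (r$TP + r$TN) / r$n)
    if (!r$dor_corrected) {
      expect_equal(r$dor, (r$TP / r$FN) / (r$FP / r$TN))
    }
    expect_equal(r$underdiagnosis + (r$TP / (r$TP + r$FN)), 1)
  }
})

test_that("identical decisions give identical metrics; a model no better than
          the physician makes the policy constraint infeasible", {
  lab <- shared_labeled_cohort()
  g <- build_intersectional_groups(lab, audit_config(min_group_size = 150))
  phys <- lab$physician_diagnosed
  m_model <- confusion_at_threshold(as.numeric(phys), lab$strict_uti, 0.5, g)
  m_phys <- confusion_at_threshold(phys, lab$strict_uti, groups = g)
  expect_equal(m_model, m_phys)
  grp <- m_model[m_model$group != "overall", ]
  expect_equal(utiaudit:::cv_estimate(grp$accuracy, "accuracy"),
               utiaudit:::cv_estimate(m_phys[m_phys$group != "overall",
                                             "accuracy"], "accuracy"))
  # a "model" that exactly replicates the physician can never be strictly
  # better in every group: the policy scan must report infeasibility
  expect_error(
    run_full_audit(lab, as.numeric(phys), audit_config(min_group_size = 150)),
    "infeasible")
})

test_that("full audit report covers sources, definitions, CVs and deciles", {
  lab <- shared_labeled_cohort()
  set.seed(44)
  # a well-separated simulated scorer strictly dominating the physician
  probs <- pmin(pmax(ifelse(lab$culture_positive, rnorm(nrow(lab), 0.8, 0.12),
                            rnorm(nrow(lab), 0.15, 0.12)), 0), 1)
  rep_full <- run_full_audit(lab, probs, audit_config(min_group_size = 150))
  expect_s3_class(rep_full, "equity_report")
  expect_setequal(names(rep_full$results), c("strict", "liberal"))
  for (def in names(rep_full$results)) {
    expect_setequal(names(rep_full$results[[def]]),
                    c("model_policy", "model_fixed", "model_youden",
                      "physician"))
    cv <- rep_full$results[[def]]$physician$cv
    expect_setequal(cv$metric, c("accuracy", "dor"))
    expect_true(all(cv$ci_low <= cv$cv & cv$cv <= cv$ci_high))
    expect_true(all(cv$ci_low >= 0))
  }
  # model dominates the simulated physician in every audited group (strict)
  strict <- rep_full$results$strict
  mp <- strict$model_policy$metrics
  ph <- strict$physician$metrics
  audited <- mp$group != "overall"
  expect_true(all(mp$underdiagnosis[audited] < ph$underdiagnosis[audited]))
  expect_identical(nrow(rep_full$deciles), 10L)
  # report writer emits the full artifact set
  dir <- withr::local_tempdir()
  paths <- write_equity_report(rep_full, dir)
  expect_true(all(file.exists(paths)))
  parsed <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(parsed$n_encounters, nrow(lab))
})
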