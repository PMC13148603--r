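# Shared fixtures built in code. The mid-size labeled cohort is built once
# per test run and reused across files.

small_search <- function(nr = c(40L, 100L)) {
  utils::modifyList(default_search_space(), list(nrounds = nr))
}

# 19 large demographic cells + 6 small ones: at n = 20000 the large cells
# (weights .040/.045) sit far above a 500-encounter floor and the small
# ones (.013) far below it.
mix_19_cells <- function() {
  ages <- c("18-44", "45-64", "65-84", "85+")
  big <- expand.grid(age_bin = ages, sex = c("female", "male"),
                     race = c("white", "black", "other"),
                     ethnicity = "non_hispanic",
                     stringsAsFactors = FALSE)[1:19, ]
  big$weight <- c(rep(0.045, 10), rep(0.040, 9))
  small <- data.frame(age_bin = ages[c(1, 2, 3, 4, 1, 2)],
                      sex = c("female", "male", "female", "male", "female",
                              "male"),
                      race = "asian",
                      ethnicity = c(rep("hispanic", 3), rep("unknown", 3)),
                      weight = rep(0.013, 6))
  rbind(big, small)
}

shared_env <- new.env()

shared_labeled_cohort <- function() {
  if (is.null(shared_env$labeled)) {
    co <- generate_cohort(cohort_config(n_encounters = 8000, seed = 42))
    shared_env$labeled <- label_cohort(harmonize_table(co, quiet = TRUE))
  }
  shared_env$labeled
}
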