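test_that("identical recipe and seed reproduce the cohort byte for byte", {
  spec <- example_model_specs()$logistic
  rec <- cohort_recipe(spec, n = 300, seed = 77,
                       missing_rates = c(grade = 0.1))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(generate_cohort(rec), d1)
  write_cohort(generate_cohort(rec), d2)
  for (f in c("cohort.csv", "mapping.json", "truth.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = f)
  # and the generator does not disturb the caller's RNG stream
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generate_cohort(rec))
  expect_identical(runif(1), before)
})

test_that("MCAR masking hits its target rate", {
  spec <- example_model_specs()$logistic
  rec <- cohort_recipe(spec, n = 10000, seed = 5,
                       missing_rates = c(hilum = 0.24))
  sim <- generate_cohort(rec)
  expect_lt(abs(sim$truth$masked$hilum - 2400),
            3 * sqrt(10000 * 0.24 * 0.76))
  expect_equal(sum(is.na(sim$data$hilum)), sim$truth$masked$hilum)
})

test_that("realized prevalence matches the analytic expectation", {
  spec <- example_model_specs()$logistic
  for (cfg in list(c(0, 1), c(0.5, 0.7))) {
    rec <- cohort_recipe(spec, n = 100000, seed = 8,
                         a_true = cfg[1], b_true = cfg[2])
    sim <- generate_cohort(rec)
    # Monte-Carlo integration of E[plogis(a + b * logit p)] over the
    # covariate recipe, on an independent draw
    rec2 <- cohort_recipe(spec, n = 200000, seed = 1009)
    dat2 <- generate_cohort(rec2)$data
    p_model <- predict_logistic(spec, dat2)
    expected <- mean(plogis(cfg[1] + cfg[2] * qlogis(p_model)))
    expect_lt(abs(sim$truth$prevalence - expected), 0.01)
  }
})

test_that("an uninformative model yields coin-flip discrimination", {
  spec <- example_model_specs()$logistic
  rec <- cohort_recipe(spec, n = 50000, seed = 14, b_true = 0,
                       a_true = qlogis(0.25))
  sim <- generate_cohort(rec)
  # all outcome probabilities collapse to sigmoid(a_true)
  expect_lt(abs(sim$truth$prevalence - 0.25), 0.01)
  p <- predict_logistic(spec, sim$data)
  expect_lt(abs(roc_and_auc(risk_predictions(p, sim$data$y))$auc - 0.5),
            0.02)
})

test_that("the survival variant drops pre-horizon censored records with a count", {
  spec <- example_model_specs()$cox
  rec <- cohort_recipe(spec, n = 5000, seed = 9, horizon = 5,
                       outcome = list(type = "survival", lambda0 = 0.012,
                                      censor_window = 30))
  sim <- generate_cohort(rec)
  expect_gt(sim$truth$n_censored_dropped, 0)
  expect_equal(sim$truth$n + sim$truth$n_censored_dropped,
               sim$truth$n_requested)
  expect_equal(nrow(sim$data), sim$truth$n)
  expect_true(all(sim$data$y %in% 0:1))
})

test_that("invalid recipes are rejected", {
  spec <- example_model_specs()$logistic
  expect_error(cohort_recipe(spec, n = 0), class = "pv_recipe_error")
  expect_error(cohort_recipe(spec, n = 10,
                             missing_rates = c(hilum = 1.0)),
               class = "pv_recipe_error")
  expect_error(cohort_recipe(spec, n = 10,
                             missing_rates = c(nonexistent = 0.1)),
               class = "pv_recipe_error")
  expect_error(cohort_recipe(spec, n = 10,
                             covariate_recipes = list(
                               grade = list(type = "categorical",
                                            levels = c("I", "II", "III"),
                                            probs = c(0.5, 0.4, 0.4)))),
               class = "pv_recipe_error")
  expect_error(cohort_recipe(spec, n = 10,
                             outcome = list(type = "survival")),
               class = "pv_recipe_error")
})

test_that("example specs cover all four families with the expected shapes", {
  specs <- example_model_specs()
  expect_setequal(names(specs),
                  c("logistic", "conditional_logistic", "cox", "lookup"))
  for (fam in names(specs)) {
    expect_identical(specs[[fam]]$family, fam)
    # every example spec survives a serialization round trip
    path <- withr::local_tempfile(fileext = ".json")
    write_model_spec(specs[[fam]], path)
    expect_equal(load_model_spec(path), specs[[fam]])
  }
  # conditional model covers five follow-up years
  expect_length(specs$conditional_logistic$periods, 5L)
  # cox model tabulates 5- and 10-year baseline survival
  expect_equal(specs$cox$baseline_survival$time, c(5, 10))
  expect_equal(specs$cox$horizons, c(5, 10))
})

test_that("generated cohorts span low, medium and high prevalence", {
  specs <- example_model_specs()
  prev <- vapply(c("conditional_logistic", "cox", "logistic"),
                 function(fam) {
                   rec <- cohort_recipe(specs[[fam]], n = 20000,
                                        seed = 42)
                   generate_cohort(rec)$truth$prevalence
                 }, numeric(1))
  expect_lt(prev[["conditional_logistic"]], 0.05)   # rare recurrence
  expect_true(prev[["cox"]] > 0.05 && prev[["cox"]] < 0.2)
  expect_true(prev[["logistic"]] > 0.18 && prev[["logistic"]] < 0.32)
})
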