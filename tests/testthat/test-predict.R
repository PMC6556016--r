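test_that("linear predictor: reference levels, centering, unknown weights", {
  spec <- tiny_logistic_spec(intercept = -2)
  # all covariates at reference / centered values -> LP = intercept
  expect_equal(linear_predictor(spec, list(x = 50, g = "A")), -2)
  # continuous: beta * (x - center)
  spec0 <- tiny_logistic_spec(intercept = 0)
  expect_equal(linear_predictor(spec0, list(x = 55, g = "A")), 1.0)
  # unknown categorical -> weighted average of level coefficients
  # (0.5 * 0 + 0.5 * 1)
  expect_equal(linear_predictor(spec0, list(x = 50, g = NA)), 0.5)
  # unknown continuous -> development mean (52), beta 0.2, center 50
  expect_equal(linear_predictor(spec0, list(x = NA, g = "A")), 0.4)
})

test_that("linear predictor error contracts", {
  spec <- model_spec(
    "m", "logistic",
    list(covariate_def("g", "categorical", levels = c("A", "B"),
                       reference_level = "A"),
         covariate_def("x", "continuous")),
    intercept = 0, coefficients = list(g = c(B = 1), x = 0.1))
  # unknown without unknown_weights / dev mean
  expect_error(linear_predictor(spec, list(g = NA, x = 1)),
               class = "pv_unknown_error")
  expect_error(linear_predictor(spec, list(g = "A", x = NA)),
               class = "pv_unknown_error")
  # unseen level label
  expect_error(linear_predictor(spec, list(g = "Z", x = 1)),
               class = "pv_mapping_error")
  # missing covariate column
  expect_error(linear_predictor(spec, list(g = "A")),
               class = "pv_mapping_error")
})

test_that("LP is additive and the unknown contribution is bracketed", {
  spec <- example_model_specs()$logistic
  set.seed(11)
  base <- list(node_diameter = 12, cortical_thickness = 3.4,
               hilum = "present", grade = "II", tumor_size = 25,
               er_status = "positive")
  lp0 <- linear_predictor(spec, base)
  # changing one covariate changes LP by exactly that covariate's delta
  mod <- base
  mod$grade <- "III"
  delta <- spec$coefficients$grade[["III"]] - spec$coefficients$grade[["II"]]
  expect_equal(linear_predictor(spec, mod) - lp0, delta)

  # unknown contribution lies between the min and max level coefficient
  for (nm in c("hilum", "grade", "er_status")) {
    cd <- spec$covariates[[nm]]
    betas <- c(0, spec$coefficients[[nm]])  # reference contributes 0
    unk <- base
    unk[[nm]] <- NA
    known <- base
    known[[nm]] <- cd$reference_level
    contrib <- linear_predictor(spec, unk) - linear_predictor(spec, known)
    expect_gte(contrib, min(betas) - 1e-12)
    expect_lte(contrib, max(betas) + 1e-12)
  }
})

test_that("logistic predictions follow the sigmoid exactly", {
  spec <- tiny_logistic_spec(intercept = 0)
  expect_equal(predict_logistic(spec, list(x = 50, g = "A")), 0.5)
  expect_equal(predict_logistic(spec, list(x = 50 + log(3) / 0.2, g = "A")),
               0.75)
  # random records vs independent hand computation
  set.seed(7)
  spec2 <- example_model_specs()$logistic
  dat <- generate_cohort(cohort_recipe(spec2, n = 50, seed = 7))$data
  p <- predict_logistic(spec2, dat)
  expect_true(all(p > 0 & p < 1))
  expect_equal(p, oracle_risks(spec2, dat, horizon = NULL),
               tolerance = 1e-12)
})

test_that("cox risk matches the closed form and is monotone", {
  spec <- tiny_cox_spec(s0 = c(0.9, 0.8))
  # LP = 0 -> 1 - S0
  expect_equal(predict_cox(spec, list(x = 0, g = "A"), horizon = 5), 0.1)
  # LP = ln 2 -> 1 - 0.9^2
  x_ln2 <- log(2) / 0.1
  expect_equal(predict_cox(spec, list(x = x_ln2, g = "A"), horizon = 5),
               1 - 0.81, tolerance = 1e-12)
  # risk increases with horizon for any fixed LP, and strictly with LP
  for (xv in c(-3, 0, 4)) {
    r5 <- predict_cox(spec, list(x = xv, g = "A"), horizon = 5)
    r10 <- predict_cox(spec, list(x = xv, g = "A"), horizon = 10)
    expect_gte(r10, r5)
  }
  risks <- predict_cox(spec, data.frame(x = c(0, 1, 2), g = "A"),
                       horizon = 5)
  expect_true(all(diff(risks) > 0))
  # exact horizon lookup only
  expect_error(predict_cox(spec, list(x = 0, g = "A"), horizon = 7),
               class = "pv_horizon_error")
})

test_that("conditional cumulative risk is one minus the survival product", {
  # r = (0.1, 0.1) through year 2 -> 1 - 0.81
  spec <- tiny_conditional_spec(intercepts = qlogis(c(0.1, 0.1)))
  expect_equal(as.numeric(predict_conditional(spec, list(x = 0), 2)),
               1 - 0.81, tolerance = 1e-12)
  # K = 1 degenerates to a plain logistic model on period 1
  spec1 <- tiny_conditional_spec(intercepts = -1.3)
  eq <- model_spec("eq", "logistic", horizons = 1,
                   covariates = list(covariate_def("x", "continuous")),
                   intercept = -1.3, coefficients = list(x = 0.3))
  dat <- data.frame(x = c(-2, 0, 1.5))
  expect_equal(as.numeric(predict_conditional(spec1, dat, 1)),
               predict_logistic(eq, dat), tolerance = 1e-12)
  # cumulative risk is non-decreasing in through_year and matches a
  # brute-force product
  spec5 <- example_model_specs()$conditional_logistic
  dat5 <- generate_cohort(cohort_recipe(spec5, n = 30, seed = 3))$data
  prev <- 0
  for (k in 1:5) {
    cum <- as.numeric(predict_conditional(spec5, dat5, k))
    expect_true(all(cum >= prev - 1e-15))
    expect_equal(cum, oracle_risks(spec5, dat5, k), tolerance = 1e-12)
    prev <- cum
  }
  expect_error(predict_conditional(spec5, dat5, 6),
               class = "pv_horizon_error")
  # annual risks are exposed alongside the cumulative risk
  r <- attr(predict_conditional(spec5, dat5, 3), "annual_risks")
  expect_equal(dim(r), c(30L, 5L))
})

test_that("lookup models discretize half-open and match exactly", {
  spec <- tiny_lookup_spec()
  expect_equal(predict_lookup(spec, list(age = 30, g = "A"), 5), 0.1)
  expect_equal(predict_lookup(spec, list(age = 30, g = "B"), 5), 0.2)
  # half-open convention: 49 -> young, 50 -> old
  expect_equal(predict_lookup(spec, list(age = 49, g = "A"), 5), 0.1)
  expect_equal(predict_lookup(spec, list(age = 50, g = "A"), 5), 0.3)
  # absent profile and unsupported horizon are errors, never fallbacks
  spec2 <- tiny_lookup_spec()
  spec2$lookup_table <- spec2$lookup_table[-1, ]
  expect_error(predict_lookup(spec2, list(age = 30, g = "A"), 5),
               class = "pv_profile_error")
  expect_error(predict_lookup(spec, list(age = 30, g = "A"), 10),
               class = "pv_horizon_error")
  # out-of-support continuous value
  expect_error(predict_lookup(spec, list(age = 150, g = "A"), 5),
               class = "pv_mapping_error")
})

test_that("all engines return probabilities in [0, 1]", {
  specs <- example_model_specs()
  for (fam in names(specs)) {
    spec <- specs[[fam]]
    rec <- cohort_recipe(spec, n = 200, seed = 5)
    dat <- generate_cohort(rec)$data
    p <- predict_risk(spec, dat, horizon = rec$horizon)
    expect_true(all(p >= 0 & p <= 1), label = fam)
  }
})
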