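make_raw <- function(...) {
  data.frame(..., stringsAsFactors = FALSE, check.names = FALSE)
}

simple_spec <- function() {
  model_spec(
    "m", "logistic",
    list(covariate_def("g", "categorical", levels = c("A", "B"),
                       reference_level = "A",
                       unknown_weights = c(A = 0.5, B = 0.5)),
         covariate_def("x", "continuous")),
    intercept = 0, coefficients = list(g = c(B = 1), x = 0.1))
}

simple_mapping <- function() {
  mapping_config(
    covariates = list(
      g = list(column = "grp", value_map = c(`1` = "A", `2` = "B"),
               missing_codes = "9"),
      x = list(column = "meas", scale = 1, missing_codes = "na")),
    outcome = list(column = "out", event_code = "yes",
                   nonevent_code = "no", missing_codes = character(0)))
}

test_that("cohorts load from CSV with basic hygiene checks", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,x", "2,y", "3,z"), path)
  raw <- load_cohort(path)
  expect_equal(nrow(raw), 3L)
  expect_identical(names(raw), c("a", "b"))

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,a", "1,2"), dup)
  expect_error(load_cohort(dup), class = "pv_io_error")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("", empty)
  expect_error(load_cohort(empty), class = "pv_io_error")

  # shipped synthetic fixture: row count equals the generator's n
  fx <- system.file("extdata", "synthetic_cohort", package = "predvalid")
  raw2 <- load_cohort(file.path(fx, "cohort.csv"))
  truth <- jsonlite::read_json(file.path(fx, "truth.json"))
  expect_equal(nrow(raw2), truth$n)
})

test_that("mapping translates codes and applies the missing-data policy", {
  spec <- simple_spec()
  mapping <- simple_mapping()
  raw <- make_raw(grp = c("1", "2", "9", "1"),
                  meas = c("1.5", "na", "2.0", "3.5"),
                  out = c("yes", "no", "no", "yes"))

  # policy to_unknown: g supports unknown, x does not
  mc <- apply_mapping(raw, mapping, spec, policy = "to_unknown")
  expect_equal(mc$n_input, 4L)
  expect_equal(mc$n_excluded, 1L)         # row 2: x missing, not capable
  expect_true(is.na(mc$data$g[mc$data$.row == 3]))  # g kept as unknown
  expect_equal(mc$data$y, c(1L, 0L, 1L))
  expect_equal(mc$exclusion_log$missing_by_variable[["g"]], 1L)
  expect_equal(mc$exclusion_log$missing_by_variable[["x"]], 1L)

  # policy exclude: both missing rows are dropped
  me <- apply_mapping(raw, mapping, spec, policy = "exclude")
  expect_equal(me$n_excluded, 2L)
  expect_equal(me$data$.row, c(1L, 4L))   # order-preserving

  # cohort without missing values: nothing excluded under either policy
  clean <- make_raw(grp = c("1", "2"), meas = c("1", "2"),
                    out = c("yes", "no"))
  for (pol in c("to_unknown", "exclude"))
    expect_equal(apply_mapping(clean, mapping, spec, pol)$n_excluded, 0L)
})

test_that("records missing a covariate without unknown support are excluded", {
  spec <- simple_spec()
  mapping <- simple_mapping()
  raw <- make_raw(grp = rep("1", 10),
                  meas = c(rep("1.0", 8), "na", "na"),
                  out = rep(c("yes", "no"), 5))
  mc <- apply_mapping(raw, mapping, spec, policy = "to_unknown")
  expect_equal(nrow(mc$data), 8L)
  expect_equal(mc$exclusion_log$missing_by_variable[["x"]], 2L)
  expect_equal(mc$exclusion_log$excluded$reason, c("x", "x"))
})

test_that("unmapped codes and unrecognized outcomes are errors, not missing", {
  spec <- simple_spec()
  mapping <- simple_mapping()
  raw <- make_raw(grp = c("1", "7"), meas = c("1", "2"),
                  out = c("yes", "no"))
  err <- tryCatch(apply_mapping(raw, mapping, spec), error = function(e) e)
  expect_s3_class(err, "pv_mapping_error")
  expect_match(conditionMessage(err), "grp")
  expect_match(conditionMessage(err), "'7'")
  expect_match(conditionMessage(err), "row 2")

  raw2 <- make_raw(grp = c("1", "1"), meas = c("1", "2"),
                   out = c("yes", "maybe"))
  expect_error(apply_mapping(raw2, mapping, spec),
               class = "pv_mapping_error")
  # missing outcome always excludes the record
  raw3 <- make_raw(grp = c("1", "1"), meas = c("1", "2"),
                   out = c("yes", ""))
  expect_equal(apply_mapping(raw3, mapping, spec)$n_excluded, 1L)
})

test_that("record conservation holds across policies and missingness", {
  spec <- example_model_specs()$logistic
  for (seed in 1:3) {
    rec <- cohort_recipe(spec, n = 500, seed = seed,
                         missing_rates = c(hilum = 0.24, grade = 0.1,
                                           node_diameter = 0.05))
    sim <- generate_cohort(rec)
    for (pol in c("to_unknown", "exclude")) {
      mc <- apply_mapping(sim$raw, sim$mapping, spec, policy = pol)
      expect_equal(nrow(mc$data) + mc$n_excluded, mc$n_input)
      expect_equal(mc$n_input, nrow(sim$raw))
      # order preserved over retained rows
      expect_true(!is.unsorted(mc$data$.row, strictly = TRUE))
    }
    # all covariates of this spec are unknown-capable: to_unknown
    # excludes nothing
    expect_equal(
      apply_mapping(sim$raw, sim$mapping, spec, "to_unknown")$n_excluded,
      0L)
  }
})

test_that("MCAR exclusion rate matches the binomial expectation", {
  spec <- example_model_specs()$logistic
  rate <- 0.24
  n <- 10000
  rec <- cohort_recipe(spec, n = n, seed = 99,
                       missing_rates = c(hilum = rate))
  sim <- generate_cohort(rec)
  mc <- apply_mapping(sim$raw, sim$mapping, spec, policy = "exclude")
  expected <- n * rate
  tol <- 3 * sqrt(n * rate * (1 - rate))
  expect_lt(abs(mc$n_excluded - expected), tol)
})

test_that("baseline comparison computes standardized differences", {
  spec <- model_spec(
    "m", "logistic",
    list(covariate_def("x", "continuous",
                       dev_summary = list(mean = 50, sd = 10)),
         covariate_def("g", "categorical", levels = c("A", "B"),
                       reference_level = "A",
                       dev_summary = list(frequencies = c(A = 0.5,
                                                          B = 0.5))),
         covariate_def("z", "continuous")),
    intercept = 0, coefficients = list(x = 0.1, g = c(B = 1), z = 0))

  # continuous mean 55 (sd 10) vs dev 50 (sd 10) -> SMD 0.5, flagged
  dat <- data.frame(.row = 1:200,
                    x = rnorm(200, 0, 1e-9) + 55,
                    g = rep(c("A", "B"), 100),
                    z = 1, y = rep(0:1, 100))
  dat$x <- 55 + (dat$x - mean(dat$x)) * (10 / sd(dat$x))  # mean 55, sd 10
  mc <- structure(list(data = dat, n_input = 200L, n_excluded = 0L,
                       policy = "to_unknown",
                       exclusion_log = list(missing_by_variable = integer(0),
                                            excluded = data.frame())),
                  class = "mapped_cohort")
  cmp <- compare_baseline(spec, mc)
  x_row <- cmp$table[cmp$table$covariate == "x", ]
  expect_equal(x_row$std_diff, 0.5, tolerance = 1e-4)
  expect_true(x_row$flag)
  # identical categorical distribution -> 0, not flagged
  g_row <- cmp$table[cmp$table$covariate == "g", ]
  expect_equal(g_row$std_diff, 0)
  expect_false(g_row$flag)
  # covariate without a development summary is listed as not comparable
  expect_identical(cmp$not_comparable, "z")
  # validation frequencies sum to 1 over non-missing records
  expect_equal(sum(cmp$details$g$val_freq), 1, tolerance = 1e-9)

  # no dev_summary anywhere -> empty comparison with a warning
  spec2 <- simple_spec()
  expect_warning(compare_baseline(spec2, mc2 <- local({
    d <- data.frame(.row = 1:4, g = "A", x = 1, y = c(0, 1, 0, 1))
    structure(list(data = d, n_input = 4L, n_excluded = 0L,
                   policy = "exclude",
                   exclusion_log = list(missing_by_variable = integer(0),
                                        excluded = data.frame())),
              class = "mapped_cohort")
  })), "no covariate")
})
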