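test_that("reference inputs carry the published point estimates", {
  p <- reference_inputs()
  expect_equal(pt_est(p$costs$drug_daily$ctz_taz), 36414)
  expect_equal(pt_est(p$costs$drug_daily$mepm), 2589)
  expect_equal(pt_est(p$costs$drug_daily$amk), 714)
  expect_equal(pt_est(p$utilities$u_icu_vent), -0.39)
  expect_equal(unclass(p$arms$mepm$efficacy$cure_first),
               c(value = 0.571, lower = 0.49, upper = 0.75))
  expect_equal(p$settings$wtp, 5e6)
  expect_equal(pt_est(p$settings$discount_rate_annual), 0.02)
  expect_equal(p$settings$horizon_years, 5)
  expect_equal(pt_est(p$settings$ward_mortality), 0.076)
})

test_that("reference inputs validate with only the documented bound anomalies", {
  p <- reference_inputs()
  expect_warning(validate_parameters(p, warn = TRUE),
                 "outside its printed interval")
  an <- attr(suppressWarnings(validate_parameters(p)), "bound_anomalies")
  expect_setequal(an, c("arms.ctz_taz.efficacy.cure_first",
                        "arms.ctz_taz.efficacy.cure_second"))
})

test_that("validation rejects out-of-domain inputs by field name", {
  p <- reference_inputs()
  bad <- param_set(p, "arms.ctz_taz.efficacy.cure_first", 1.2)
  expect_error(validate_parameters(bad), "cure_first")
  bad <- param_set(p, "costs.drug_daily.mepm", -1)
  expect_error(validate_parameters(bad), "negative")
  bad <- p
  bad$arms$mepm$efficacy$cure_first <- rwb(0.8)
  bad$arms$mepm$efficacy$mort_first <- rwb(0.3)
  expect_error(validate_parameters(bad), "cure \\+ mortality > 1")
  bad <- p
  bad$life_table <- bad$life_table[bad$life_table$age < 68, ]
  expect_error(validate_parameters(bad), "life_table must cover")
})

test_that("configuration round-trips identically through YAML and JSON", {
  p <- reference_inputs()
  for (ext in c("yaml", "json")) {
    f <- file.path(tempdir(), paste0("cfg.", ext))
    save_parameters(p, f)
    p2 <- suppressWarnings(load_parameters(f))
    attributes(p2) <- attributes(p2)[c("names", "class")]
    attributes(p) <- attributes(p)[c("names", "class")]
    expect_equal(p2, p, tolerance = 1e-12, label = ext)
    unlink(f)
  }
})

test_that("unknown configuration keys are rejected by name", {
  f <- tempfile(fileext = ".yaml")
  save_parameters(reference_inputs(), f)
  cfg <- yaml::read_yaml(f)
  cfg$typo_key <- 1
  yaml::write_yaml(cfg, f)
  expect_error(suppressWarnings(load_parameters(f)), "typo_key")
  unlink(f)
})

test_that("partial configurations are completed with built-in defaults", {
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(settings = list(cohort_start_age = 70)), f)
  p <- suppressWarnings(load_parameters(f))
  expect_equal(p$settings$cohort_start_age, 70)
  expect_equal(pt_est(p$costs$drug_daily$ctz_taz), 36414)
  unlink(f)
})

test_that("percent-units configurations are converted to proportions", {
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    units = list(rates = "percent"),
    arms = list(mepm = list(efficacy = list(
      cure_first = list(value = 57.1, lower = 49.0, upper = 75.0))))), f)
  p <- suppressWarnings(load_parameters(f))
  expect_equal(pt_est(p$arms$mepm$efficacy$cure_first), 0.571)
  # non-rate leaves are untouched
  expect_equal(pt_est(p$costs$vent_daily_early), 9500)
  unlink(f)
})

test_that("missing configuration file gives a clear error", {
  expect_error(load_parameters("no/such/file.yaml"), "not found")
})

test_that("parameter paths read and write point estimates without touching bounds", {
  p <- reference_inputs()
  x <- param_get(p, "arms.mepm.efficacy.mort_first")
  expect_s3_class(x, "rwb")
  p2 <- param_set(p, "arms.mepm.efficacy.mort_first", 0.2)
  y <- param_get(p2, "arms.mepm.efficacy.mort_first")
  expect_equal(pt_est(y), 0.2)
  expect_equal(y[["lower"]], x[["lower"]])
  expect_equal(y[["upper"]], x[["upper"]])
  expect_error(param_get(p, "arms.nonexistent.thing"), "unknown parameter")
})
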