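test_that("defaults reproduce the published base case", {
  p <- base_params
  expect_equal(p$tests$fit$sensitivity, 0.730)
  expect_equal(p$tests$fit$specificity, 0.919)
  expect_equal(p$tests$fit$compliance, 0.600)
  expect_equal(p$tests$m3crc$sensitivity, 0.665)
  expect_equal(p$tests$m3crc$specificity, 0.838)
  expect_equal(p$tests$m3crc$compliance, 0.990)
  expect_equal(p$colonoscopy$compliance, 0.989)
  expect_equal(p$colonoscopy$workup_compliance, 1.0)
  expect_equal(p$tests$fit$unit_cost, 19)
  expect_equal(p$tests$m3crc$unit_cost, 64)
  expect_equal(p$colonoscopy$unit_cost, 1259)
  expect_equal(unname(p$stages$distribution),
               c(0.113, 0.254, 0.324, 0.310))
  expect_equal(unname(p$stages$annual_mortality),
               c(0.010, 0.045, 0.087, 0.430))
  expect_equal(unname(stage_care_totals(p))[1:3], c(17071, 19755, 26883))
  # stage IV printed sub-components sum to 45,116 (total printed as 45,115)
  expect_equal(unname(stage_care_totals(p))[4], 45116)
  expect_equal(p$economics$discount_rate, 0.03)
  expect_equal(p$economics$cohort_size, 1e5)
  expect_equal(incidence_at_age(p$incidence, 52), 55.9)
  expect_equal(incidence_at_age(p$incidence, 74), 253.2)
  expect_equal(incidence_at_age(p$incidence, 75), 330.5)
  expect_identical(nrow(validate_parameters(p)), 0L)
})

test_that("single-field overrides change only that field", {
  p <- crc_parameters(overrides = list(economics = list(discount_rate = 0)))
  expect_equal(p$economics$discount_rate, 0)
  p2 <- unclass(p)
  d2 <- unclass(base_params)
  p2$economics$discount_rate <- 0.03
  expect_equal(p2, d2, ignore_attr = TRUE)
  prov <- parameter_provenance(p)
  expect_identical(
    prov$source[prov$parameter == "economics.discount_rate"], "override")
  expect_identical(
    prov$source[prov$parameter == "tests.fit.sensitivity"], "default")
})

test_that("every typed invariant is caught by validation", {
  broken <- list(
    list(tests = list(fit = list(compliance = 1.2))),
    list(tests = list(m3crc = list(unit_cost = -5))),
    list(colonoscopy = list(perforation_mortality = 0.5)), # > perforation rate
    list(colonoscopy = list(bleeding_rate = -0.1)),
    list(strategies = list(fit = list(surveillance_interval = 0))),
    list(strategies = list(m3crc = list(prevention = 1.5))),
    list(stages = list(distribution = c(0.5, 0.5, 0.5, 0.5))),
    list(stages = list(annual_mortality = c(0.01, 0.045, 0.087, 1.43))),
    list(economics = list(cohort_size = 0)),
    list(economics = list(start_age = 80)),
    list(economics = list(discount_rate = -0.03)),
    list(incidence = list(age_from = c(50, 60), age_to = c(54, 75),
                          rate = c(50, 100))), # gap at 55-59
    list(conventions = list(compliance_model = "sometimes")),
    list(conventions = list(cure_horizon_years = 0)))
  for (ov in broken) expect_error(crc_parameters(overrides = ov),
                                  class = "rlang_error")
  # validate_parameters itself is total and names the failing field
  p <- unclass(base_params)
  p$tests$fit$compliance <- 1.2
  v <- validate_parameters(p)
  expect_identical(nrow(v), 1L)
  expect_match(v$field, "tests.fit.compliance", fixed = TRUE)
  p$tests$fit$compliance <- 0.6
  p$stages$annual_mortality <- c(I = 0.01, II = 0.045, III = 0.087, IV = 0.43)
  expect_identical(nrow(validate_parameters(p)), 0L)
})

test_that("configuration round-trips field-for-field", {
  f <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(base_params, f)
  p <- read_parameters(f)
  expect_equal(unclass(p), unclass(base_params), ignore_attr = TRUE)
})

test_that("unknown keys are rejected and percent units are converted", {
  expect_error(crc_parameters(overrides = list(testz = list(a = 1))),
               "unknown key")
  expect_error(crc_parameters(overrides = list(tests = list(fit = list(
    sensittivity = 0.5)))), "unknown key")
  p <- crc_parameters(overrides = list(
    units = "percent",
    tests = list(fit = list(sensitivity = 73.0, compliance = 60.0)),
    economics = list(discount_rate = 3)))
  expect_equal(p$tests$fit$sensitivity, 0.73)
  expect_equal(p$tests$fit$compliance, 0.60)
  expect_equal(p$economics$discount_rate, 0.03)
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("units: percent", "tests:", "  m3crc:",
               "    specificity: 83.8"), f)
  expect_equal(read_parameters(f)$tests$m3crc$specificity, 0.838)
  writeLines("tests: {fit: {nope: 1}}", f)
  expect_error(read_parameters(f), "unknown key")
  writeLines("tests: [not, a, mapping", f)
  expect_error(read_parameters(f), "malformed")
})
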