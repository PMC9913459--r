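test_that("positivity is the sum of true- and false-positive fractions", {
  expect_equal(positivity_rate(0.73, 0.919, 0.002),
               0.73 * 0.002 + 0.081 * 0.998) # 0.082298
  expect_equal(positivity_rate(0.73, 0.919, 0.002), 0.082298)
  expect_equal(positivity_rate(base_params$tests$m3crc, prevalence = 0), 0.162)
  expect_equal(positivity_rate(1, 1, 0), 0)    # perfect test, no disease
  expect_equal(positivity_rate(0.5, 0.5, 1), 0.5)
  expect_error(positivity_rate(0.5, 0.5, 1.2), "\\[0, 1\\]")
  expect_error(positivity_rate(-0.1, 0.5, 0.5), "\\[0, 1\\]")
})

test_that("a screening round reproduces the published complication arithmetic", {
  p <- crc_parameters(overrides = list(colonoscopy = list(compliance = 1)))
  r <- screening_round(100000, "colonoscopy", p)
  expect_equal(r$colonoscopies, 100000)
  expect_equal(r$perforations, 80)          # 0.08% per colonoscopy
  expect_equal(r$perforation_deaths, 2.9)   # 0.0029% per colonoscopy
  expect_equal(r$bleeds, 980)               # 0.98% per colonoscopy
  expect_equal(r$therapeutic + r$diagnostic, r$colonoscopies)
  r0 <- screening_round(0, "fit", base_params)
  expect_true(all(unlist(r0) == 0))
})

test_that("polypectomy splits follow the referral-source rate", {
  r <- screening_round(10000, "fit", base_params)
  expect_equal(r$therapeutic / r$referred, 0.73)
  expect_equal(r$diagnostic / r$referred, 0.27)
  expect_equal(r$complied, 10000 * 0.6)
  expect_equal(r$positive, r$complied *
                 positivity_rate(0.73, 0.919, prevalence = 0.004))
  expect_equal(r$referred, r$positive) # workup compliance 100%
  expect_true(r$complied <= r$offered && r$positive <= r$complied &&
                r$referred <= r$positive)
  rm <- screening_round(10000, "m3crc", base_params)
  expect_equal(rm$therapeutic / rm$referred, 0.839)
  expect_error(screening_round(10, "nope", base_params), "unknown strategy")
})

test_that("complication counts scale linearly with volume", {
  r1 <- screening_round(5000, "m3crc", base_params)
  r2 <- screening_round(10000, "m3crc", base_params)
  for (f in c("bleeds", "perforations", "perforation_deaths",
              "cost_colonoscopy"))
    expect_equal(2 * r1[[f]], r2[[f]])
})

test_that("a useless but specific test incurs kit costs only", {
  p <- crc_parameters(overrides = list(tests = list(fit = list(
    sensitivity = 0, specificity = 1, compliance = 1))))
  r <- screening_round(1000, "fit", p)
  expect_equal(r$referred, 0)
  expect_equal(r$colonoscopies, 0)
  expect_equal(r$cost_test, 1000 * 19)
  expect_equal(r$cost_colonoscopy + r$cost_polypectomy + r$cost_bleeding +
                 r$cost_perforation, 0)
})

test_that("scheduling intervals follow the strategy rules", {
  expect_equal(next_due("negative-test", base_params$strategies$fit), 1)
  expect_equal(next_due("normal-colonoscopy", base_params$strategies$fit), 10)
  expect_equal(next_due("polypectomy", base_params$strategies$fit), 3)
  expect_equal(next_due("polyp-free-surveillance",
                        base_params$strategies$colonoscopy), 10)
  expect_error(next_due("lost-to-follow-up", base_params$strategies$fit),
               "unknown round result")
})
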