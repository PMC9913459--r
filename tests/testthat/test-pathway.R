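test_that("screening scales incidence by prevention times coverage", {
  expect_equal(effective_incidence(200, 0.54, 1), 92)
  expect_equal(effective_incidence(200, 0, 1), 200)
  expect_equal(effective_incidence(200, 0.54, 0), 200)
  expect_equal(effective_incidence(100, base_params$strategies$m3crc, 1),
               100 * (1 - 0.515))
  expect_error(effective_incidence(100, 0.5, 1.5), "covered")
})

test_that("stage assignment follows the published distribution and conserves", {
  st <- base_params$stages
  cases <- assign_stages(1000, st)
  expect_equal(sum(cases), 1000)                # exact conservation
  expect_equal(unname(cases), c(113, 254, 324, 310), tolerance = 2e-3)
  expect_equal(unname(assign_stages(0, st)), rep(0, 4))
  for (n in c(1, 37.5, 1e5))
    expect_equal(sum(assign_stages(n, st)), n)
  expect_error(assign_stages(-1, st), ">= 0")
})

test_that("stage survival applies the published annual mortality", {
  st <- base_params$stages
  up <- stage_survival_update(c(I = 0, II = 0, III = 0, IV = 1000), st)
  expect_equal(unname(up$deaths["IV"]), 430)
  expect_equal(unname(up$survivors["IV"]), 570)
  z <- stage_survival_update(c(I = 0, II = 0, III = 0, IV = 0), st)
  expect_true(all(z$deaths == 0) && all(z$survivors == 0))
  st2 <- st
  st2$annual_mortality[] <- 1
  expect_true(all(stage_survival_update(
    c(I = 5, II = 5, III = 5, IV = 5), st2)$survivors == 0))
})

test_that("care costs charge the stage package at diagnosis, discounted", {
  st <- base_params$stages
  zero <- c(I = 0, II = 0, III = 0, IV = 0)
  cc <- care_cost(c(I = 1, II = 0, III = 0, IV = 0), zero, st, t = 0,
                  discount_rate = 0)
  expect_equal(unname(cc["I"]), 17071)
  cc2 <- care_cost(c(I = 0, II = 1, III = 0, IV = 0), zero, st, t = 1,
                   discount_rate = 0.03)
  expect_equal(unname(cc2["II"]), 19755 / 1.03)
  expect_equal(sum(care_cost(zero, zero, st, 3, 0.03)), 0)
  # prevalent survivors are charged the annual follow-up only
  cc3 <- care_cost(zero, c(I = 10, II = 0, III = 0, IV = 0), st, 0, 0)
  expect_equal(unname(cc3["I"]), 10 * 603)
})

test_that("raising prevention lowers cases, care costs and life-years lost", {
  outs <- lapply(c(0, 0.3, 0.6), function(pr) {
    p <- crcscreen:::set_parameter(base_params, "strategies.m3crc.prevention",
                                   pr)
    accumulate(run_strategy(p, "m3crc"))
  })
  cases <- vapply(outs, function(o) o$total_cases, numeric(1))
  care <- vapply(outs, function(o) o$cost_care_total, numeric(1))
  lyl <- vapply(outs, function(o) o$life_years_lost, numeric(1))
  expect_true(all(diff(cases) < 0))
  expect_true(all(diff(care) < 0))
  expect_true(all(diff(lyl) < 0))
})

test_that("with no stage mortality no cancer life-years are lost", {
  p <- crc_parameters(overrides = list(
    stages = list(annual_mortality = c(0, 0, 0, 0))))
  out <- accumulate(run_strategy(p, "none"))
  expect_equal(out$life_years_lost, 0)
  expect_equal(out$crc_deaths, 0)
  expect_true(out$total_cases > 0)
})
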