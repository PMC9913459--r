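test_that("discount factors follow the closed form", {
  expect_equal(discount_factor(0, 0.07), 1)
  expect_equal(discount_factor(13, 0), 1)
  expect_equal(discount_factor(1, 0.03), 1 / 1.03)
  expect_equal(discount_factor(10, 0.03), 1.03^-10)
  expect_error(discount_factor(-1, 0.03), ">= 0")
  expect_error(discount_factor(1, -0.03), ">= 0")
})

test_that("null world: no incidence, no mortality, no screening, no costs", {
  p <- crc_parameters(
    overrides = list(incidence = list(age_from = 50, age_to = 75, rate = 0)),
    life_table = flat_life_table())
  out <- accumulate(run_strategy(p, "none"))
  expect_equal(out$total_cases, 0)
  expect_equal(out$total_cost, 0)
  expect_equal(out$life_years_lost, 0)
  # cohort intact at the end of follow-up
  tr <- run_strategy(p, "none")
  final <- tr$occupancy[tr$occupancy$cycle == max(tr$occupancy$cycle), ]
  expect_equal(sum(final$persons[!grepl("^dead", final$compartment)]), 1e5)
})

test_that("two-cycle toy cohort matches the hand trace exactly", {
  # 100,000 persons, incidence 1000/100k, no background mortality:
  # cycle 0 incidence 1000; cycle 1 incidence 0.01 * 99,000 = 990
  tr <- run_strategy(toy_params(), "none")
  inc <- tr$events[tr$events$event == "incident_total", ]
  expect_equal(inc$count, c(1000, 990))
  stages <- base_params$stages$distribution / sum(base_params$stages$distribution)
  inc4 <- tr$events[tr$events$event == "incident_IV", ]
  expect_equal(inc4$count, c(1000, 990) * unname(stages["IV"]))
  # care costs: full stage package at diagnosis + follow-up for survivors;
  # stage deaths start the cycle after diagnosis
  cc <- tr$costs[tr$costs$category == "care_IV", ]
  iv0 <- 1000 * unname(stages["IV"])
  expect_equal(cc$cost[1], iv0 * 45116)
  expect_equal(cc$cost[2],
               990 * unname(stages["IV"]) * 45116 + iv0 * (1 - 0.43) * 603)
  crc_d <- tr$events[tr$events$event == "crc_deaths", ]
  expect_equal(crc_d$count[1], 0)
  expect_equal(crc_d$count[2],
               sum(c(1000) * unname(stages) * c(0.01, 0.045, 0.087, 0.43)))
})

test_that("occupancy is conserved at every cycle in every arm", {
  m <- cached_base_model()
  for (s in names(m$traces)) {
    tots <- m$traces[[s]]$occupancy |>
      dplyr::group_by(cycle) |>
      dplyr::summarise(n = sum(persons))
    expect_true(all(abs(tots$n - 1e5) < 1e-6), label = paste("arm", s))
  }
})

test_that("death compartments are monotone non-decreasing", {
  m <- cached_base_model()
  for (s in names(m$traces)) {
    dead <- m$traces[[s]]$occupancy |>
      dplyr::filter(grepl("^dead", compartment)) |>
      dplyr::group_by(cycle) |>
      dplyr::summarise(n = sum(persons))
    expect_true(all(diff(dead$n) >= -1e-9), label = paste("arm", s))
  }
})

test_that("zero discount makes discounted and undiscounted ledgers identical", {
  p <- crc_parameters(overrides = list(economics = list(discount_rate = 0)))
  tr <- run_strategy(p, "m3crc")
  expect_equal(tr$costs$cost_discounted, tr$costs$cost)
  out <- accumulate(tr)
  expect_equal(out$total_cost, out$total_cost_undiscounted)
  expect_equal(out$cases_discounted, out$cases_undiscounted)
  # and with discounting, discounted never exceeds undiscounted
  tr3 <- run_strategy(base_params, "m3crc")
  expect_true(all(tr3$costs$cost_discounted <= tr3$costs$cost + 1e-9))
})

test_that("zero compliance is epidemiologically identical to no screening", {
  p <- crc_parameters(overrides = list(
    tests = list(fit = list(compliance = 0), m3crc = list(compliance = 0)),
    colonoscopy = list(compliance = 0)))
  none <- accumulate(run_strategy(p, "none"))
  for (s in c("fit", "m3crc", "colonoscopy")) {
    out <- accumulate(run_strategy(p, s))
    expect_equal(out$total_cases, none$total_cases, label = s)
    expect_equal(out$life_years_lost, none$life_years_lost, label = s)
    expect_equal(out$crc_deaths, none$crc_deaths, label = s)
    expect_equal(out$total_cost, none$total_cost, label = s)
    expect_equal(out$cost_screening_test + out$cost_colonoscopy, 0, label = s)
  }
})

test_that("life-years lost equal residual life expectancy per death", {
  # toy world where the only deaths are cancer deaths at a known age
  p <- toy_params()
  tr <- run_strategy(p, "none")
  deaths <- tr$events[tr$events$event == "crc_deaths", ]$count
  lyl <- tr$events[tr$events$event == "life_years_lost", ]$count
  lt <- p$life_table
  # deaths occur in cycle 1 (age 51) at mid-cycle, d = 0 in the toy world
  expect_equal(lyl[1], 0)
  expect_equal(lyl[2], deaths[2] * residual_life_years(lt, 51))
  expect_equal(accumulate(tr)$life_years_lost,
               deaths[2] * (100 - 51 + 0.5))
})

test_that("a single event class accounts for every colonoscopy", {
  m <- cached_base_model()
  for (s in c("fit", "m3crc", "colonoscopy")) {
    o <- m$outcomes[m$outcomes$strategy == s, ]
    expect_equal(o$colonoscopies_diagnostic + o$colonoscopies_therapeutic,
                 o$colonoscopies)
    expect_equal(o$polypectomies, o$colonoscopies_therapeutic)
    expect_equal(o$cost_care_I + o$cost_care_II + o$cost_care_III +
                   o$cost_care_IV, o$cost_care_total)
    expect_equal(o$total_cost,
                 o$cost_screening_test + o$cost_colonoscopy +
                   o$cost_polypectomy + o$cost_bleeding + o$cost_perforation +
                   o$cost_care_total)
  }
  expect_error(run_strategy(base_params, "sigmoidoscopy"), "unknown strategy")
})

test_that("identical runs are byte-identical (full determinism)", {
  t1 <- run_strategy(base_params, "fit")
  t2 <- run_strategy(base_params, "fit")
  expect_identical(t1$occupancy, t2$occupancy)
  expect_identical(t1$costs, t2$costs)
})
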