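#' Positivity rate of a stool test
#'
#' The per-round probability of a positive result among tested persons is the
#' sum of the true-positive and false-positive fractions:
#' `sensitivity * prevalence + (1 - specificity) * (1 - prevalence)`.
#' FIT operates against preclinical colorectal cancer; M3CRC against the
#' composite of non-advanced adenoma, advanced adenoma and CRC, so each test
#' is paired with its own target prevalence.
#'
#' @param sensitivity,specificity Test operating characteristics in `[0, 1]`.
#'   `sensitivity` may instead be a test parameter list with `sensitivity` and
#'   `specificity` components (e.g. `crc_parameters()$tests$fit`).
#' @param prevalence Prevalence of the test's target condition in `[0, 1]`.
#' @return Fraction of tested persons with a positive result.
#' @examples
#' positivity_rate(0.73, 0.919, 0.002)
#' positivity_rate(crc_parameters()$tests$m3crc, prevalence = 0)
#' @export
positivity_rate <- function(sensitivity, specificity = NULL, prevalence) {
  if (is.list(sensitivity)) {
    perf <- sensitivity
    sensitivity <- perf$sensitivity
    specificity <- perf$specificity
  }
  vals <- c(sensitivity, specificity, prevalence)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1))
    abort("sensitivity, specificity and prevalence must lie in [0, 1]")
  sensitivity * prevalence + (1 - specificity) * (1 - prevalence)
}

#' Expected outcome of one screening round
#'
#' Propagates an eligible mass of (fractional) persons through one offer of a
#' primary test: compliance, positivity, colonoscopy workup, polypectomy, and
#' procedure complications, with the costs each step incurs. For a primary
#' colonoscopy strategy every complier proceeds directly to colonoscopy. This
#' is the expected-value arithmetic the cohort engine applies each cycle; it is
#' exposed so single rounds can be examined and tested in isolation.
#'
#' @param eligible Persons offered the test this round (>= 0).
#' @param strategy A strategy name (`"fit"`, `"m3crc"`, `"colonoscopy"`) from
#'   `params`, or a strategy spec list.
#' @param params A `crc_parameters` object.
#' @return A one-row tibble: `offered`, `complied`, `positive`,
#'   `referred`, `colonoscopies`, `therapeutic`, `diagnostic`, `polypectomies`,
#'   `bleeds`, `perforations`, `perforation_deaths`, and cost columns
#'   `cost_test`, `cost_colonoscopy`, `cost_polypectomy`, `cost_bleeding`,
#'   `cost_perforation` (undiscounted USD).
#' @examples
#' screening_round(1000, "fit", crc_parameters())
#' @export
screening_round <- function(eligible, strategy, params) {
  if (eligible < 0) abort("eligible must be >= 0")
  spec <- if (is.list(strategy)) strategy else params$strategies[[strategy]]
  if (is.null(spec)) abort(paste0("unknown strategy '", strategy, "'"))
  cl <- params$colonoscopy
  if (identical(spec$primary_test, "colonoscopy")) {
    complied <- eligible * cl$compliance
    positive <- complied
    referred <- complied
    cost_test <- 0
    polyp_rate <- cl$polypectomy_rate$primary
  } else {
    test <- params$tests[[spec$primary_test]]
    if (is.null(test)) abort(paste0("unknown test '", spec$primary_test, "'"))
    complied <- eligible * test$compliance
    positive <- complied *
      positivity_rate(test, prevalence = test$target_prevalence)
    referred <- positive * cl$workup_compliance
    cost_test <- complied * test$unit_cost
    polyp_rate <- cl$polypectomy_rate[[spec$primary_test]]
  }
  colonoscopy_block(referred, polyp_rate, params,
                    offered = eligible, complied = complied,
                    positive = positive, cost_test = cost_test)
}

# complications and costs for a mass of colonoscopies from one referral source
colonoscopy_block <- function(referred, polyp_rate, params, offered = referred,
                              complied = referred, positive = referred,
                              cost_test = 0) {
  cl <- params$colonoscopy
  colonoscopies <- referred
  perforations <- colonoscopies * cl$perforation_rate
  perforation_deaths <- switch(params$conventions$perforation_mortality_basis,
    per_colonoscopy = colonoscopies * cl$perforation_mortality,
    per_perforation = perforations * cl$perforation_mortality)
  therapeutic <- colonoscopies * polyp_rate
  diagnostic <- colonoscopies - therapeutic
  bleeds <- switch(params$conventions$bleeding_scope,
                   all = colonoscopies, therapeutic = therapeutic) *
    cl$bleeding_rate
  tibble(
    offered = offered, complied = complied, positive = positive,
    referred = referred, colonoscopies = colonoscopies,
    therapeutic = therapeutic, diagnostic = diagnostic,
    polypectomies = therapeutic, bleeds = bleeds,
    perforations = perforations, perforation_deaths = perforation_deaths,
    cost_test = cost_test,
    cost_colonoscopy = colonoscopies * (cl$unit_cost + cl$consultation_cost),
    cost_polypectomy = therapeutic * cl$histopathology_cost,
    cost_bleeding = bleeds * cl$bleeding_cost,
    cost_perforation = perforations * cl$perforation_cost)
}

#' Years until the next screening offer
#'
#' Scheduling rules shared by all strategies: a negative stool test is
#' repeated after the routine interval (one year); a normal colonoscopy earns
#' a ten-year holiday before routine screening resumes; a polypectomy triggers
#' surveillance colonoscopy every three years until a polyp-free examination,
#' which earns the ten-year holiday.
#'
#' @param result One of `"negative-test"`, `"normal-colonoscopy"`,
#'   `"polypectomy"`, `"polyp-free-surveillance"`.
#' @param strategy A strategy spec list (defaults to the base-case intervals).
#' @return Integer years until the next offer.
#' @examples
#' next_due("negative-test")
#' next_due("polypectomy")
#' @export
next_due <- function(result, strategy = crc_parameters()$strategies$fit) {
  switch(result,
         "negative-test" = strategy$routine_interval,
         "normal-colonoscopy" = strategy$post_normal_interval,
         "polypectomy" = strategy$surveillance_interval,
         "polyp-free-surveillance" = strategy$post_normal_interval,
         abort(paste0("unknown round result class '", result, "'")))
}
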