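#' Age-specific incidence under screening
#'
#' The strategy's preventive effect scales the background age-specific
#' incidence down by `prevention * covered`, where `covered` is the fraction
#' of the living, undiagnosed cohort actively participating in the screening
#' schedule that cycle (this cycle's compliers plus everyone inside a
#' surveillance or post-colonoscopy interval). Screening prevents cancers by
#' polypectomy of precursor lesions; the model carries that benefit as this
#' single published prevention fraction per strategy rather than an explicit
#' adenoma natural-history submodel.
#'
#' @param base_rate Background annual incidence per 100,000.
#' @param prevention Strategy prevention fraction in `[0, 1]` (21.0% FIT,
#'   51.5% M3CRC, 54.0% colonoscopy in the base case). A strategy spec list is
#'   also accepted.
#' @param covered Fraction of the living cohort actively participating.
#' @return Effective annual incidence per 100,000.
#' @examples
#' effective_incidence(200, 0.54, 1) # 92 per 100,000
#' @export
effective_incidence <- function(base_rate, prevention, covered) {
  if (is.list(prevention)) prevention <- prevention$prevention
  if (covered < 0 || covered > 1) abort("covered must lie in [0, 1]")
  base_rate * (1 - prevention * covered)
}

# annual incidence rate per 100,000 at a given integer age
incidence_at_age <- function(incidence, age) {
  i <- which(incidence$age_from <= age & age <= incidence$age_to)
  if (length(i) != 1)
    abort(paste0("age ", age, " not covered by the incidence schedule"))
  incidence$rate[i]
}

#' Distribute incident cancers over stages at diagnosis
#'
#' Splits incident cases by the stage-at-diagnosis distribution (base case
#' 11.3% / 25.4% / 32.4% / 31.0% for stages I-IV). The published fractions sum
#' to 100.1%; they are renormalised so the components always sum exactly to
#' the input (cohort conservation takes precedence over the printed rounding).
#'
#' @param total_cases Incident cases (expected persons, >= 0).
#' @param stages The `stages` component of a `crc_parameters` object.
#' @return Named numeric vector of per-stage cases summing to `total_cases`.
#' @examples
#' assign_stages(1000, crc_parameters()$stages)
#' @export
assign_stages <- function(total_cases, stages) {
  if (total_cases < 0) abort("total_cases must be >= 0")
  w <- stages$distribution / sum(stages$distribution)
  total_cases * w
}

#' One-year survival update for diagnosed patients
#'
#' Applies the stage-specific annual mortality (1.0% / 4.5% / 8.7% / 43.0% for
#' stages I-IV in the base case) to the prevalent diagnosed pool.
#'
#' @param prevalent Named numeric vector of prevalent patients by stage.
#' @param stages The `stages` component of a `crc_parameters` object.
#' @return A list with per-stage `deaths` and `survivors`.
#' @examples
#' stage_survival_update(c(I = 0, II = 0, III = 0, IV = 1000),
#'                       crc_parameters()$stages)
#' @export
stage_survival_update <- function(prevalent, stages) {
  if (any(prevalent < 0)) abort("prevalent counts must be >= 0")
  deaths <- prevalent * stages$annual_mortality
  list(deaths = deaths, survivors = prevalent - deaths)
}

#' Care costs for incident and prevalent cancer patients
#'
#' Incident cases are charged the full stage care package (diagnosis and
#' pre-operative assessment, stage-specific treatment, and the first year of
#' follow-up) in the diagnosis year; surviving, non-cured patients are charged
#' the annual follow-up cost in each later year. All charges are discounted to
#' the model origin with [discount_factor()].
#'
#' @param incident Named per-stage incident cases this cycle.
#' @param prevalent Named per-stage surviving non-cured patients from earlier
#'   cycles (charged follow-up this cycle).
#' @param stages The `stages` component of a `crc_parameters` object.
#' @param t Years since the model origin at which the charges occur.
#' @param discount_rate Yearly discount rate.
#' @return Named per-stage discounted USD.
#' @examples
#' st <- crc_parameters()$stages
#' care_cost(c(I = 1, II = 0, III = 0, IV = 0), c(I = 0, II = 0, III = 0,
#'   IV = 0), st, t = 0, discount_rate = 0)  # 17,071 at diagnosis
#' @export
care_cost <- function(incident, prevalent, stages, t, discount_rate = 0) {
  if (t < 0) abort("t must be >= 0")
  totals <- stage_care_totals(stages)
  (incident * totals + prevalent * stages$followup_cost) *
    discount_factor(t, discount_rate)
}
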