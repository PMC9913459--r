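#' Discount factor
#'
#' Present-value weight `(1 + d)^-t` for a cost or effect occurring `t` years
#' after the model origin (age 50). The base case discounts yearly at 3%.
#'
#' @param t Years since the model origin (>= 0; may be fractional under the
#'   mid-cycle convention).
#' @param rate Yearly discount rate `d` (>= 0).
#' @return The discount factor.
#' @examples
#' discount_factor(1, 0.03) # 1 / 1.03
#' @export
discount_factor <- function(t, rate) {
  if (any(t < 0)) abort("t must be >= 0")
  if (any(rate < 0)) abort("rate must be >= 0")
  (1 + rate)^-t
}

# compartment labels for one strategy arm
engine_compartments <- function() {
  c(paste0("scr_", 0:10),          # routine screening, years until next offer
    paste0("srv_", 0:3),           # surveillance, years until next colonoscopy
    "never",                       # never-attenders (one-shot compliance model)
    paste0("crc_", rep(c("I", "II", "III"), each = 5), "_", 0:4),
    "crc_IV",                      # stage IV remains at risk until death
    "cured",                       # recurrence-free beyond the cure horizon
    "dead_crc", "dead_other", "dead_proc")
}

#' Run the cohort model for one strategy
#'
#' Advances the closed cohort through annual cycles from the start age to the
#' end age (26 cycles, ages 50-75, in the base case), applying in each cycle:
#' screening offers at cycle start (routine tests, colonoscopy workup of
#' positives, surveillance colonoscopies, complications), then mid-cycle
#' cancer incidence with the strategy's preventive effect, stage-specific
#' cancer mortality, background mortality from the life table, care costs,
#' and scheduling-counter updates. The cohort is an expected-value
#' (fractional-person) model: no sampling, fully deterministic.
#'
#' @param params A `crc_parameters` object.
#' @param strategy Strategy name: one of `names(params$strategies)`
#'   (`"none"`, `"fit"`, `"m3crc"`, `"colonoscopy"` in the base case).
#' @return A `crc_trace`: a list with tibbles `occupancy` (cycle x compartment
#'   persons at cycle end), `events` (per-cycle counts of tests, procedures,
#'   complications, incident cases by stage, deaths, and life-years lost) and
#'   `costs` (per-cycle USD by category, discounted and undiscounted), plus
#'   the strategy name and the parameters used.
#' @examples
#' tr <- run_strategy(crc_parameters(), "none")
#' dplyr::count(tr$occupancy, compartment, wt = persons)
#' @export
run_strategy <- function(params, strategy) {
  spec <- params$strategies[[strategy]]
  if (is.null(spec)) abort(paste0("unknown strategy '", strategy, "'"))
  ec <- params$economics
  cv <- params$conventions
  cl <- params$colonoscopy
  lt <- params$life_table
  d <- ec$discount_rate
  stage_names <- c("I", "II", "III", "IV")
  q_stage <- params$stages$annual_mortality
  care_totals <- stage_care_totals(params$stages)
  horizon <- min(cv$cure_horizon_years, 5)
  screened_arm <- !identical(spec$primary_test, "none")
  colo_arm <- identical(spec$primary_test, "colonoscopy")
  if (screened_arm && !colo_arm) {
    test <- params$tests[[spec$primary_test]]
    pos_rate <- positivity_rate(test, prevalence = test$target_prevalence)
    arm_compliance <- test$compliance
    polyp_rate <- cl$polypectomy_rate[[spec$primary_test]]
  } else if (colo_arm) {
    arm_compliance <- cl$compliance
    polyp_rate <- cl$polypectomy_rate$primary
  }

  comps <- engine_compartments()
  occ <- stats::setNames(numeric(length(comps)), comps)
  occ["scr_0"] <- ec$cohort_size
  n_cycles <- ec$end_age - ec$start_age + 1L
  t_half <- if (cv$half_cycle == "mid") 0.5 else 0

  occupancy <- matrix(0, n_cycles, length(comps),
                      dimnames = list(NULL, comps))
  ev_names <- c("tests", "colonoscopies", "colonoscopies_diagnostic",
                "colonoscopies_therapeutic", "polypectomies", "bleeds",
                "perforations", "perforation_deaths",
                paste0("incident_", stage_names), "incident_total",
                "incident_total_discounted", "crc_deaths",
                "crc_deaths_discounted", "other_deaths",
                "life_years_lost", "life_years_lost_undiscounted")
  events <- matrix(0, n_cycles, length(ev_names),
                   dimnames = list(NULL, ev_names))
  cost_cats <- c("screening_test", "colonoscopy", "polypectomy", "bleeding",
                 "perforation", paste0("care_", stage_names))
  costs <- matrix(0, n_cycles, length(cost_cats),
                  dimnames = list(NULL, cost_cats))
  costs_undisc <- costs

  scr_idx <- paste0("scr_", 0:10)
  srv_idx <- paste0("srv_", 0:3)
  undx_idx <- c(scr_idx, srv_idx, "never")

  for (t in seq_len(n_cycles) - 1L) {
    age <- ec$start_age + t
    q_bg <- lt$qx[match(age, lt$age)]
    df_scr <- discount_factor(t, d)
    t_event <- t + t_half
    df_clin <- discount_factor(t_event, d)
    covered <- 0

    ## -- step A: screening offers at cycle start ---------------------------
    if (screened_arm) {
      undx_alive <- sum(occ[undx_idx])
      # waiters inside a surveillance or post-colonoscopy interval count as
      # actively covered; tallied before this cycle's transitions land
      pre_wait <- sum(occ[c(paste0("scr_", 1:10), paste0("srv_", 1:3))])
      due <- occ[["scr_0"]]
      due_srv <- occ[["srv_0"]]
      occ["scr_0"] <- 0
      occ["srv_0"] <- 0
      if (cv$compliance_model == "never") {
        comply_p <- if (t == 0L) arm_compliance else 1
      } else comply_p <- arm_compliance
      complied <- due * comply_p
      noncomplied <- due - complied
      if (cv$compliance_model == "never") {
        occ["never"] <- occ["never"] + noncomplied
      } else {
        occ["scr_1"] <- occ["scr_1"] + noncomplied
      }
      if (colo_arm) {
        referred <- complied
        negative_back <- 0
        kit_cost <- 0
        n_tests <- 0
      } else {
        positive <- complied * pos_rate
        referred <- positive * cl$workup_compliance
        negative_back <- complied - referred # negatives + workup refusals
        kit_cost <- complied * test$unit_cost
        n_tests <- complied
      }
      occ[paste0("scr_", spec$routine_interval)] <-
        occ[paste0("scr_", spec$routine_interval)] + negative_back
      blk <- colonoscopy_block(referred, polyp_rate, params)
      # surveillance colonoscopies (same compliance knob as routine offers)
      complied_srv <- due_srv * comply_p
      occ["srv_1"] <- occ["srv_1"] + (due_srv - complied_srv)
      blk_s <- colonoscopy_block(complied_srv,
                                 cl$polypectomy_rate$surveillance, params)
      for (b in list(blk, blk_s)) {
        n <- b$colonoscopies
        surv_frac <- if (n > 0) 1 - b$perforation_deaths / n else 1
        occ[paste0("srv_", spec$surveillance_interval)] <-
          occ[paste0("srv_", spec$surveillance_interval)] +
          b$therapeutic * surv_frac
        occ[paste0("scr_", spec$post_normal_interval)] <-
          occ[paste0("scr_", spec$post_normal_interval)] +
          b$diagnostic * surv_frac
        occ["dead_proc"] <- occ["dead_proc"] + b$perforation_deaths
      }
      both <- dplyr::bind_rows(blk, blk_s)
      events[t + 1L, c("tests", "colonoscopies", "colonoscopies_diagnostic",
                       "colonoscopies_therapeutic", "polypectomies", "bleeds",
                       "perforations", "perforation_deaths")] <-
        c(n_tests, sum(both$colonoscopies), sum(both$diagnostic),
          sum(both$therapeutic), sum(both$polypectomies), sum(both$bleeds),
          sum(both$perforations), sum(both$perforation_deaths))
      step_costs <- c(screening_test = kit_cost,
                      colonoscopy = sum(both$cost_colonoscopy),
                      polypectomy = sum(both$cost_polypectomy),
                      bleeding = sum(both$cost_bleeding),
                      perforation = sum(both$cost_perforation))
      costs_undisc[t + 1L, names(step_costs)] <-
        costs_undisc[t + 1L, names(step_costs)] + step_costs
      costs[t + 1L, names(step_costs)] <-
        costs[t + 1L, names(step_costs)] + step_costs * df_scr
      perf_deaths_now <- sum(both$perforation_deaths)
      covered <- if (undx_alive > 0)
        (complied + complied_srv + pre_wait) / undx_alive else 0
      covered <- min(max(covered, 0), 1)
    } else perf_deaths_now <- 0

    ## -- step B: mid-cycle incidence among the undiagnosed -----------------
    base_rate <- incidence_at_age(params$incidence, age)
    rate_eff <- effective_incidence(base_rate, spec$prevention, covered) / 1e5
    u <- occ[undx_idx]
    deaths_other_u <- u * q_bg
    at_risk <- switch(cv$half_cycle,
                      mid = u - deaths_other_u / 2,
                      start = u,
                      end = u - deaths_other_u)
    cases_u <- at_risk * rate_eff
    occ[undx_idx] <- u - deaths_other_u - cases_u
    total_cases <- sum(cases_u)
    incident <- assign_stages(total_cases, params$stages)
    events[t + 1L, paste0("incident_", stage_names)] <- incident
    events[t + 1L, "incident_total"] <- total_cases
    events[t + 1L, "incident_total_discounted"] <- total_cases * df_clin
    occ["dead_other"] <- occ["dead_other"] + sum(deaths_other_u)

    ## -- step C: diagnosed pool -- mortality, cure, follow-up --------------
    prev <- stats::setNames(numeric(4), stage_names)
    for (s in c("I", "II", "III"))
      prev[s] <- sum(occ[paste0("crc_", s, "_", 0:4)])
    prev["IV"] <- occ["crc_IV"]
    q_d <- switch(cv$diagnosed_mortality,
                  replace = pmax(q_stage, q_bg),
                  additive = 1 - (1 - q_stage) * (1 - q_bg))
    deaths_crc_s <- prev * q_stage
    deaths_other_s <- prev * (q_d - q_stage)
    crc_deaths <- sum(deaths_crc_s)
    occ["dead_crc"] <- occ["dead_crc"] + crc_deaths
    occ["dead_other"] <- occ["dead_other"] + sum(deaths_other_s)
    # pre-existing cured face background mortality only (before this cycle's
    # cure exits arrive, whose mortality was applied as diagnosed above)
    cured_deaths <- occ["cured"] * q_bg
    occ["cured"] <- occ["cured"] - cured_deaths
    occ["dead_other"] <- occ["dead_other"] + cured_deaths
    surv_frac_s <- 1 - q_d
    # advance time-since-diagnosis; cure exit for stages I-III
    for (s in c("I", "II", "III")) {
      ids <- paste0("crc_", s, "_", 0:4)
      survived <- occ[ids] * surv_frac_s[s]
      occ[ids] <- 0
      exit_y <- horizon # survivors of year (horizon-1) exit to cured
      for (y in 4:0) {
        if (y + 1L >= exit_y) occ["cured"] <- occ["cured"] + survived[y + 1L]
        else occ[paste0("crc_", s, "_", y + 1L)] <- survived[y + 1L]
      }
    }
    occ["crc_IV"] <- occ["crc_IV"] * surv_frac_s["IV"]
    followup_pool <- prev - deaths_crc_s - deaths_other_s
    cc <- incident * care_totals + followup_pool * params$stages$followup_cost
    costs_undisc[t + 1L, paste0("care_", stage_names)] <-
      costs_undisc[t + 1L, paste0("care_", stage_names)] + cc
    costs[t + 1L, paste0("care_", stage_names)] <-
      costs[t + 1L, paste0("care_", stage_names)] + cc * df_clin
    # new diagnoses enter the diagnosed pool (stage mortality from next cycle)
    for (s in c("I", "II", "III"))
      occ[paste0("crc_", s, "_0")] <- occ[paste0("crc_", s, "_0")] + incident[s]
    occ["crc_IV"] <- occ["crc_IV"] + incident["IV"]

    ## -- life-years lost to cancer and procedure deaths --------------------
    prem_deaths <- crc_deaths + perf_deaths_now
    offset <- if (cv$ly_discount_from == "model_start") t_event else 0
    events[t + 1L, "life_years_lost"] <- prem_deaths *
      residual_life_years(lt, age, d, offset, half_cycle = cv$half_cycle)
    events[t + 1L, "life_years_lost_undiscounted"] <- prem_deaths *
      residual_life_years(lt, age, 0, 0, half_cycle = cv$half_cycle)
    events[t + 1L, "crc_deaths"] <- crc_deaths
    events[t + 1L, "crc_deaths_discounted"] <- crc_deaths * df_clin
    events[t + 1L, "other_deaths"] <- sum(deaths_other_u) +
      sum(deaths_other_s) + cured_deaths

    ## -- step D: advance scheduling counters -------------------------------
    for (j in 0:9) {
      src <- paste0("scr_", j + 1L)
      occ[paste0("scr_", j)] <- occ[paste0("scr_", j)] + occ[src]
      occ[src] <- 0
    }
    for (j in 0:2) {
      src <- paste0("srv_", j + 1L)
      occ[paste0("srv_", j)] <- occ[paste0("srv_", j)] + occ[src]
      occ[src] <- 0
    }

    if (abs(sum(occ) - ec$cohort_size) > 1e-6)
      abort(sprintf(
        "internal consistency error at cycle %d: occupancy %.9f != cohort %.0f",
        t, sum(occ), ec$cohort_size))
    occupancy[t + 1L, ] <- occ
  }

  cycles <- seq_len(n_cycles) - 1L
  ages <- ec$start_age + cycles
  trace <- list(
    strategy = strategy,
    occupancy = tibble(cycle = rep(cycles, each = length(comps)),
                       age = rep(ages, each = length(comps)),
                       compartment = rep(comps, n_cycles),
                       persons = as.vector(t(occupancy))),
    events = tidy_matrix(events, cycles, ages, "event", "count"),
    costs = dplyr::left_join(
      tidy_matrix(costs_undisc, cycles, ages, "category", "cost"),
      tidy_matrix(costs, cycles, ages, "category", "cost_discounted"),
      by = c("cycle", "age", "category")),
    params = params)
  class(trace) <- "crc_trace"
  trace
}

tidy_matrix <- function(m, cycles, ages, key, value) {
  tb <- tibble(cycle = rep(cycles, each = ncol(m)),
               age = rep(ages, each = ncol(m)),
               k = rep(colnames(m), nrow(m)),
               v = as.vector(t(m)))
  names(tb)[3:4] <- c(key, value)
  tb
}

#' @export
print.crc_trace <- function(x, ...) {
  cat(sprintf("<crc_trace> strategy '%s', %d cycles\n", x$strategy,
              dplyr::n_distinct(x$occupancy$cycle)))
  invisible(x)
}

#' Summarise a cohort trace into strategy totals
#'
#' Collapses a per-cycle trace into the per-strategy totals used by the
#' cost-effectiveness comparison: discounted total cost by category, cancer
#' cases (by stage and total, with both counting conventions), premature
#' deaths, discounted life-years lost, and procedure/complication counts.
#' Whether `total_cases` is the raw or the discounted tally follows the
#' `discount_cases` convention in the parameters (raw by default).
#'
#' @param trace A `crc_trace` from [run_strategy()].
#' @return A one-row tibble (`crc_outcome`).
#' @examples
#' accumulate(run_strategy(crc_parameters(), "none"))$total_cases
#' @export
accumulate <- function(trace) {
  if (!inherits(trace, "crc_trace")) abort("trace must be a crc_trace")
  ev <- trace$events |>
    dplyr::group_by(.data$event) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
  evs <- stats::setNames(ev$total, ev$event)
  co <- trace$costs |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(cost = sum(.data$cost),
                     cost_discounted = sum(.data$cost_discounted),
                     .groups = "drop")
  cds <- stats::setNames(co$cost_discounted, co$category)
  flag_disc <- trace$params$conventions$discount_cases
  out <- tibble(
    strategy = trace$strategy,
    total_cost = sum(cds),
    cost_screening_test = cds[["screening_test"]],
    cost_colonoscopy = cds[["colonoscopy"]],
    cost_polypectomy = cds[["polypectomy"]],
    cost_bleeding = cds[["bleeding"]],
    cost_perforation = cds[["perforation"]],
    cost_care_I = cds[["care_I"]], cost_care_II = cds[["care_II"]],
    cost_care_III = cds[["care_III"]], cost_care_IV = cds[["care_IV"]],
    cost_care_total = cds[["care_I"]] + cds[["care_II"]] + cds[["care_III"]] +
      cds[["care_IV"]],
    total_cost_undiscounted = sum(co$cost),
    total_cases = if (flag_disc) evs[["incident_total_discounted"]] else
      evs[["incident_total"]],
    cases_undiscounted = evs[["incident_total"]],
    cases_discounted = evs[["incident_total_discounted"]],
    cases_I = evs[["incident_I"]], cases_II = evs[["incident_II"]],
    cases_III = evs[["incident_III"]], cases_IV = evs[["incident_IV"]],
    crc_deaths = evs[["crc_deaths"]],
    life_years_lost = evs[["life_years_lost"]],
    life_years_lost_undiscounted = evs[["life_years_lost_undiscounted"]],
    tests = evs[["tests"]],
    colonoscopies = evs[["colonoscopies"]],
    colonoscopies_diagnostic = evs[["colonoscopies_diagnostic"]],
    colonoscopies_therapeutic = evs[["colonoscopies_therapeutic"]],
    polypectomies = evs[["polypectomies"]],
    bleeds = evs[["bleeds"]],
    perforations = evs[["perforations"]],
    perforation_deaths = evs[["perforation_deaths"]])
  class(out) <- c("crc_outcome", class(out))
  out
}

#' Run the full strategy comparison
#'
#' Runs the cohort engine for every requested strategy and assembles the
#' comparative cost-effectiveness report against the baseline.
#'
#' @param params A `crc_parameters` object.
#' @param strategies Character vector of strategy names to run; defaults to
#'   all strategies defined in `params`.
#' @param baseline Baseline strategy name for the comparative measures.
#' @param keep_traces Keep the per-cycle traces in the result (default TRUE).
#' @return A `crc_model` object: list with `outcomes` (one row per strategy),
#'   `report` (the [cea_report()] against the baseline), `icers` (the pairwise
#'   ICER matrix from [icer_matrix()]), `traces` and `params`.
#' @examples
#' m <- run_model(crc_parameters(), c("none", "fit"))
#' m$report
#' @export
run_model <- function(params, strategies = names(params$strategies),
                      baseline = "none", keep_traces = TRUE) {
  strategies <- unique(strategies)
  unknown <- setdiff(strategies, names(params$strategies))
  if (length(unknown))
    abort(paste0("unknown strategy name(s): ", paste(unknown, collapse = ", ")))
  traces <- lapply(stats::setNames(strategies, strategies),
                   function(s) run_strategy(params, s))
  outcomes <- dplyr::bind_rows(lapply(traces, accumulate))
  report <- if (baseline %in% strategies)
    cea_report(outcomes, baseline = baseline) else NULL
  out <- list(outcomes = outcomes, report = report,
              icers = icer_matrix(outcomes), params = params,
              baseline = baseline,
              traces = if (keep_traces) traces else NULL)
  class(out) <- "crc_model"
  out
}

#' @export
print.crc_model <- function(x, ...) {
  cat("<crc_model>\n")
  print(as.data.frame(x$outcomes[, c("strategy", "total_cost", "total_cases",
                                     "life_years_lost")]), row.names = FALSE)
  if (!is.null(x$report)) {
    cat(sprintf("\nversus '%s':\n", x$baseline))
    print(as.data.frame(x$report), row.names = FALSE)
  }
  invisible(x)
}

#' Export a cohort trace as a tidy table
#'
#' @param trace A `crc_trace`.
#' @return A long tibble with one row per cycle x series (compartment
#'   occupancy, event count, or cost category).
#' @export
trace_table <- function(trace) {
  dplyr::bind_rows(
    trace$occupancy |>
      mutate(series = "occupancy") |>
      dplyr::rename(name = "compartment", value = "persons"),
    trace$events |>
      mutate(series = "events") |>
      dplyr::rename(name = "event", value = "count"),
    trace$costs |>
      select("cycle", "age", name = "category", value = "cost_discounted") |>
      mutate(series = "costs_discounted"))
}
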