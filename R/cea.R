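#' Cases prevented by a screening strategy
#'
#' @param cases Total cancer cases under the strategy.
#' @param baseline_cases Total cases under the no-screening baseline.
#' @return A one-row tibble with `count` and `proportion` (of baseline cases;
#'   `NA` with a warning flag when the baseline has no cases).
#' @examples
#' cases_prevented(3087, 3233) # 146 cases, 4.5%
#' @export
cases_prevented <- function(cases, baseline_cases) {
  count <- baseline_cases - cases
  tibble(count = count,
         proportion = if (baseline_cases > 0) count / baseline_cases else
           NA_real_)
}

#' Life-years saved versus baseline
#'
#' @param life_years_lost Discounted life-years lost under the strategy.
#' @param baseline_life_years_lost The same under the baseline.
#' @return Life-years saved (baseline losses minus strategy losses).
#' @examples
#' life_years_saved(2783, 5635) # 2852
#' @export
life_years_saved <- function(life_years_lost, baseline_life_years_lost) {
  baseline_life_years_lost - life_years_lost
}

#' Incremental cost-effectiveness ratio with dominance handling
#'
#' `icer()` computes `(cost_s - cost_c) / (effect_s - effect_c)` for a strategy
#' against a comparator, where the effect is life-years saved. Degenerate
#' denominators yield flags, never silent division: `"undefined"` when the
#' effect difference is zero; `"dominated"` when the strategy is costlier and
#' less effective (no ratio is reported); `"dominant"` when it is cheaper and
#' more effective (the negative ratio is reported alongside the flag);
#' `"ok"` otherwise. The sign convention is cost difference over effect
#' difference, both taken strategy-minus-comparator.
#'
#' @param cost,effect Total discounted cost and effect of the strategy.
#' @param cost_comparator,effect_comparator The same for the comparator.
#' @return One-row tibble: `cost_diff`, `effect_diff`, `icer`, `flag`.
#' @examples
#' icer(262159983, 339, 225515010, 0)
#' @export
icer <- function(cost, effect, cost_comparator, effect_comparator) {
  dc <- cost - cost_comparator
  de <- effect - effect_comparator
  if (de == 0) {
    flag <- "undefined"
    val <- NA_real_
  } else if (de < 0 && dc >= 0) {
    flag <- "dominated"
    val <- NA_real_
  } else if (de > 0 && dc < 0) {
    flag <- "dominant"
    val <- dc / de
  } else {
    flag <- "ok"
    val <- dc / de
  }
  tibble(cost_diff = dc, effect_diff = de, icer = val, flag = flag)
}

#' Total cost per life-year saved
#'
#' The strategy's total discounted cost divided by the life-years it saves
#' versus the baseline (the published "total costs per life-years saved" row).
#'
#' @param total_cost Total discounted cost of the strategy.
#' @param lys Life-years saved versus baseline.
#' @return USD per life-year saved, or `NA` when no life-years are saved.
#' @examples
#' cost_per_life_year_saved(606234678, 2852)
#' @export
cost_per_life_year_saved <- function(total_cost, lys) {
  if (is.na(lys) || lys <= 0) return(NA_real_)
  total_cost / lys
}

#' Comparative cost-effectiveness report
#'
#' Derives, for every strategy, the baseline comparison rows of the outcome
#' table: cases prevented (count and proportion of baseline), life-years
#' saved, total cost per life-year saved, and the ICER versus the baseline.
#' The input is any data frame of per-strategy totals -- typically
#' [accumulate()] results, but published totals can be fed directly.
#'
#' @param outcomes Data frame with columns `strategy`, `total_cost`,
#'   `total_cases`, `life_years_lost` (one row per strategy).
#' @param baseline Baseline strategy name present in `outcomes`.
#' @return A tibble with one row per non-baseline strategy: `strategy`,
#'   `cases_prevented`, `proportion_prevented`, `life_years_saved`,
#'   `cost_per_life_year_saved`, `icer_vs_baseline`, `icer_flag`.
#' @examples
#' printed <- tibble::tibble(
#'   strategy = c("none", "fit", "m3crc", "colonoscopy"),
#'   total_cost = c(225515010, 262159983, 606234678, 690947627),
#'   total_cases = c(3233, 3087, 1611, 1575),
#'   life_years_lost = c(5635, 5297, 2783, 2719))
#' cea_report(printed)
#' @export
cea_report <- function(outcomes, baseline = "none") {
  if (!all(c("strategy", "total_cost", "total_cases", "life_years_lost") %in%
           names(outcomes)))
    abort("outcomes must have strategy, total_cost, total_cases, life_years_lost")
  if (!baseline %in% outcomes$strategy)
    abort(paste0("baseline '", baseline, "' not among the outcomes"))
  base <- outcomes[outcomes$strategy == baseline, ]
  others <- outcomes[outcomes$strategy != baseline, ]
  purrr::map_dfr(seq_len(nrow(others)), function(i) {
    s <- others[i, ]
    cp <- cases_prevented(s$total_cases, base$total_cases)
    lys <- life_years_saved(s$life_years_lost, base$life_years_lost)
    ic <- icer(s$total_cost, lys, base$total_cost, 0)
    tibble(strategy = s$strategy,
           cases_prevented = cp$count,
           proportion_prevented = cp$proportion,
           life_years_saved = lys,
           cost_per_life_year_saved =
             cost_per_life_year_saved(s$total_cost, lys),
           icer_vs_baseline = ic$icer,
           icer_flag = ic$flag)
  })
}

#' Pairwise ICER matrix with dominance flags
#'
#' Every ordered strategy pair is compared on discounted cost and life-years
#' saved relative to the chosen baseline. Differences are antisymmetric under
#' argument swap and compose transitively; dominance is flagged per pair, and
#' no efficiency-frontier pruning is applied.
#'
#' @inheritParams cea_report
#' @return A tibble with one row per ordered pair: `strategy`, `comparator`,
#'   `cost_diff`, `effect_diff`, `icer`, `flag`.
#' @export
icer_matrix <- function(outcomes, baseline = "none") {
  if (!baseline %in% outcomes$strategy) baseline <- outcomes$strategy[1]
  base <- outcomes[outcomes$strategy == baseline, ]
  eff <- stats::setNames(base$life_years_lost - outcomes$life_years_lost,
                         outcomes$strategy)
  cost <- stats::setNames(outcomes$total_cost, outcomes$strategy)
  pairs <- expand.grid(strategy = outcomes$strategy,
                       comparator = outcomes$strategy,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$strategy != pairs$comparator, ]
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    s <- pairs$strategy[i]
    c_ <- pairs$comparator[i]
    dplyr::bind_cols(tibble(strategy = s, comparator = c_),
                     icer(cost[[s]], eff[[s]], cost[[c_]], eff[[c_]]))
  })
}
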