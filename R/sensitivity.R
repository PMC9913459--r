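#' One-way deterministic sensitivity sweep
#'
#' Re-runs the strategy comparison across a grid of values for a single
#' parameter, identified by its dotted path in the parameter tree (e.g.
#' `"tests.m3crc.specificity"`, `"colonoscopy.unit_cost"`,
#' `"stages.care_cost.IV"` for a stage's total care cost). Every other
#' parameter is held at its current value; the input parameters are never
#' modified. Compliance is a single knob per arm: it drives initial, repeated
#' and follow-up (surveillance) offers alike.
#'
#' @param params A `crc_parameters` object (unchanged on return).
#' @param param Dotted parameter path.
#' @param values Ordered numeric grid (strictly monotone).
#' @param strategies Strategies to run (plus the baseline).
#' @param baseline Baseline strategy for ICERs.
#' @return A `crc_sweep` tibble: one row per grid value x strategy, with the
#'   [cea_report()] columns plus `param` and `value`.
#' @examples
#' sw <- one_way_sweep(crc_parameters(), "tests.fit.compliance",
#'                     c(0.3, 0.6, 0.9), strategies = "fit")
#' sw$icer_vs_baseline
#' @export
one_way_sweep <- function(params, param, values,
                          strategies = setdiff(names(params$strategies),
                                               "none"),
                          baseline = "none") {
  if (length(values) < 1) abort("values grid is empty")
  if (is.unsorted(values, strictly = TRUE) &&
      is.unsorted(rev(values), strictly = TRUE))
    abort("values grid must be strictly monotone")
  get_parameter(params, sub("^stages\\.care_cost", "stages.treatment_cost",
                            param)) # fail early on unresolvable paths
  out <- purrr::map_dfr(values, function(v) {
    pv <- set_parameter(params, param, v)
    m <- run_model(pv, unique(c(baseline, strategies)), baseline = baseline,
                   keep_traces = FALSE)
    mutate(m$report, param = param, value = v, .before = 1)
  })
  class(out) <- c("crc_sweep", class(out))
  out
}

#' Two-way deterministic sensitivity sweep
#'
#' Full factorial grid over two parameter paths; otherwise as
#' [one_way_sweep()].
#'
#' @inheritParams one_way_sweep
#' @param params_paths Character vector of two dotted parameter paths.
#' @param values1,values2 Ordered numeric grids for the two parameters.
#' @return A `crc_sweep` tibble with columns `param1`, `value1`, `param2`,
#'   `value2` plus the [cea_report()] columns.
#' @export
two_way_sweep <- function(params, params_paths, values1, values2,
                          strategies = setdiff(names(params$strategies),
                                               "none"),
                          baseline = "none") {
  if (length(params_paths) != 2) abort("params_paths must name two parameters")
  if (length(values1) < 1 || length(values2) < 1) abort("empty sweep grid")
  grid <- expand.grid(value1 = values1, value2 = values2)
  out <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    pv <- set_parameter(params, params_paths[1], grid$value1[i])
    pv <- set_parameter(pv, params_paths[2], grid$value2[i])
    m <- run_model(pv, unique(c(baseline, strategies)), baseline = baseline,
                   keep_traces = FALSE)
    mutate(m$report,
           param1 = params_paths[1], value1 = grid$value1[i],
           param2 = params_paths[2], value2 = grid$value2[i], .before = 1)
  })
  class(out) <- c("crc_sweep", class(out))
  out
}

#' Threshold detection by bisection
#'
#' Finds the parameter value at which the ICER ordering between two strategies
#' (both versus the baseline) flips, within a bracketing interval. Returns
#' `NA` with an explanatory flag when the ordering does not change over the
#' bracket.
#'
#' @inheritParams one_way_sweep
#' @param lower,upper Bracket endpoints on the parameter scale.
#' @param strategy,comparator The two strategies whose ICERs are compared.
#' @param tol Bisection tolerance on the parameter scale; defaults to 1e-4,
#'   appropriate for fractional parameters (use ~1 for USD-scale parameters).
#' @return One-row tibble: `param`, `threshold` (NA if none), `flag`
#'   (`"crossing"` or `"no-sign-change"`).
#' @export
threshold_scan <- function(params, param, lower, upper, strategy, comparator,
                           baseline = "none", tol = 1e-4) {
  if (!(lower < upper)) abort("invalid bracket: lower must be < upper")
  gap <- function(v) {
    pv <- set_parameter(params, param, v)
    m <- run_model(pv, c(baseline, strategy, comparator), baseline = baseline,
                   keep_traces = FALSE)
    r <- m$report
    r$icer_vs_baseline[r$strategy == strategy] -
      r$icer_vs_baseline[r$strategy == comparator]
  }
  glo <- gap(lower)
  ghi <- gap(upper)
  if (is.na(glo) || is.na(ghi) || sign(glo) == sign(ghi))
    return(tibble(param = param, threshold = NA_real_,
                  flag = "no-sign-change"))
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    gm <- gap(mid)
    if (sign(gm) == sign(glo)) {
      lower <- mid
      glo <- gm
    } else upper <- mid
  }
  tibble(param = param, threshold = (lower + upper) / 2, flag = "crossing")
}
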