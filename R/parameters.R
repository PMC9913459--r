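#' Model parameters for the screening cost-effectiveness model
#'
#' `crc_parameters()` builds the complete, validated parameter bundle for the
#' Markov cohort model. With no arguments it returns the published base case:
#' FIT sensitivity/specificity 73.0%/91.9% for colorectal cancer, M3CRC
#' 66.5%/83.8% for the composite of non-advanced adenoma, advanced adenoma and
#' CRC, compliance 60% (FIT), 99% (M3CRC) and 98.9% (colonoscopy), the stage
#' distribution and stage-specific annual mortality at diagnosis, unit costs in
#' USD, the Hong Kong age-specific incidence schedule, a 3% yearly discount
#' rate, and a synthetic Gompertz life table calibrated to a residual life
#' expectancy of about 33 years at age 50 (see [hk_life_table()]).
#'
#' All probabilities are stored as fractions in `[0, 1]`. Configuration
#' documents may instead carry percentages by declaring `units: percent`
#' (see [read_parameters()]).
#'
#' @param overrides Named nested list of overrides, using the same structure as
#'   the defaults (see [write_parameters()] for the schema). Unknown keys are
#'   rejected.
#' @param file Optional path to a YAML configuration document; applied before
#'   `overrides`.
#' @param life_table Optional life table created by [make_life_table()] or
#'   [read_life_table()]; defaults to [hk_life_table()].
#' @return An object of class `crc_parameters`: a named list with components
#'   `tests`, `colonoscopy`, `strategies`, `stages`, `incidence`, `economics`,
#'   `conventions` and `life_table`, with an `overrides` attribute recording
#'   provenance.
#' @examples
#' p <- crc_parameters()
#' p$tests$fit$sensitivity
#' p2 <- crc_parameters(overrides = list(economics = list(discount_rate = 0)))
#' @export
crc_parameters <- function(overrides = list(), file = NULL, life_table = NULL) {
  p <- default_parameters()
  applied <- character()
  if (!is.null(file)) {
    doc <- read_config_document(file)
    p <- apply_overrides(p, doc$values, "")
    applied <- c(applied, doc$paths)
  }
  if (length(overrides)) {
    overrides <- convert_units(overrides)
    p <- apply_overrides(p, overrides, "")
    applied <- c(applied, leaf_paths(overrides))
  }
  if (!is.null(life_table)) {
    p$life_table <- life_table
    applied <- c(applied, "life_table")
  } else if (is.null(p$life_table)) {
    p$life_table <- hk_life_table()
  }
  p <- structure(p, class = "crc_parameters", overrides = unique(applied))
  v <- validate_parameters(p)
  if (nrow(v) > 0) {
    abort(c("invalid model parameters",
            stats::setNames(paste0(v$field, " = ", v$value, ": ", v$rule),
                            rep("x", nrow(v)))))
  }
  p
}

# Published base-case values (Tables of test performance, costs, incidence).
default_parameters <- function() {
  stage <- c("I", "II", "III", "IV")
  list(
    tests = list(
      fit = list(sensitivity = 0.730, specificity = 0.919, compliance = 0.600,
                 unit_cost = 19, target_prevalence = 0.004),
      m3crc = list(sensitivity = 0.665, specificity = 0.838, compliance = 0.990,
                   unit_cost = 64, target_prevalence = 0.289)
    ),
    colonoscopy = list(
      unit_cost = 1259, consultation_cost = 96, histopathology_cost = 142,
      polypectomy_rate = list(fit = 0.730, m3crc = 0.839, primary = 0.722,
                              surveillance = 0.722),
      bleeding_rate = 0.0098, perforation_rate = 0.0008,
      perforation_mortality = 0.000029,
      bleeding_cost = 3320, perforation_cost = 10790,
      workup_compliance = 1.0, compliance = 0.989
    ),
    strategies = list(
      none = list(primary_test = "none", routine_interval = 1,
                  post_normal_interval = 10, surveillance_interval = 3,
                  prevention = 0),
      fit = list(primary_test = "fit", routine_interval = 1,
                 post_normal_interval = 10, surveillance_interval = 3,
                 prevention = 0.210),
      m3crc = list(primary_test = "m3crc", routine_interval = 1,
                   post_normal_interval = 10, surveillance_interval = 3,
                   prevention = 0.515),
      colonoscopy = list(primary_test = "colonoscopy", routine_interval = 10,
                         post_normal_interval = 10, surveillance_interval = 3,
                         prevention = 0.540)
    ),
    stages = list(
      distribution = stats::setNames(c(0.113, 0.254, 0.324, 0.310), stage),
      annual_mortality = stats::setNames(c(0.010, 0.045, 0.087, 0.430), stage),
      diagnosis_cost = stats::setNames(rep(6091, 4), stage),
      treatment_cost = stats::setNames(c(10377, 13061, 20189, 38422), stage),
      followup_cost = stats::setNames(rep(603, 4), stage)
    ),
    incidence = data.frame(
      age_from = c(50, 55, 60, 65, 70, 75),
      age_to = c(54, 59, 64, 69, 74, 75),
      rate = c(55.9, 89.8, 137, 200, 253.2, 330.5)
    ),
    economics = list(cohort_size = 1e5, start_age = 50, end_age = 75,
                     discount_rate = 0.03, currency = "USD"),
    conventions = list(
      half_cycle = "mid",              # deaths mid-cycle (weight t + 1/2)
      discount_cases = FALSE,          # case counts reported undiscounted
      ly_discount_from = "model_start",
      compliance_model = "never",      # fixed attender/never-attender split
      bleeding_scope = "all",          # bleeds charged per colonoscopy
      perforation_mortality_basis = "per_colonoscopy",
      diagnosed_mortality = "replace", # stage mortality replaces background
      cure_horizon_years = 5
    ),
    life_table = NULL
  )
}

#' Total care cost per stage (diagnosis + treatment + first-year follow-up)
#'
#' @param p A `crc_parameters` object (or its `stages` component).
#' @return Named numeric vector of per-stage totals in USD.
#' @examples
#' stage_care_totals(crc_parameters())
#' @export
stage_care_totals <- function(p) {
  s <- if (inherits(p, "crc_parameters")) p$stages else p
  s$diagnosis_cost + s$treatment_cost + s$followup_cost
}

#' Validate model parameters
#'
#' A total function: returns a tibble describing every violated invariant
#' (empty when the parameters are valid) rather than raising an error.
#'
#' @param p A `crc_parameters` object or a compatible list.
#' @return A tibble with columns `field`, `value`, `rule`.
#' @examples
#' nrow(validate_parameters(crc_parameters())) == 0
#' @export
validate_parameters <- function(p) {
  out <- list()
  bad <- function(field, value, rule) {
    value <- unlist(value)
    if (is.numeric(value)) value <- signif(value, 8)
    out[[length(out) + 1L]] <<- tibble(
      field = field, value = paste(value, collapse = ", "), rule = rule)
  }
  frac <- function(x, field) {
    if (!all(is.finite(x)) || any(x < 0) || any(x > 1))
      bad(field, x, "must be a fraction in [0, 1]")
  }
  nonneg <- function(x, field) {
    if (!all(is.finite(x)) || any(x < 0)) bad(field, x, "must be >= 0")
  }
  for (tn in names(p$tests)) {
    t <- p$tests[[tn]]
    for (f in c("sensitivity", "specificity", "compliance", "target_prevalence"))
      frac(t[[f]], paste0("tests.", tn, ".", f))
    nonneg(t$unit_cost, paste0("tests.", tn, ".unit_cost"))
  }
  cl <- p$colonoscopy
  for (f in c("bleeding_rate", "perforation_rate", "perforation_mortality",
              "workup_compliance", "compliance"))
    frac(cl[[f]], paste0("colonoscopy.", f))
  for (f in names(cl$polypectomy_rate))
    frac(cl$polypectomy_rate[[f]], paste0("colonoscopy.polypectomy_rate.", f))
  for (f in c("unit_cost", "consultation_cost", "histopathology_cost",
              "bleeding_cost", "perforation_cost"))
    nonneg(cl[[f]], paste0("colonoscopy.", f))
  if (is.finite(cl$perforation_mortality) && is.finite(cl$perforation_rate) &&
      cl$perforation_mortality > cl$perforation_rate)
    bad("colonoscopy.perforation_mortality", cl$perforation_mortality,
        "must not exceed the perforation rate")
  for (sn in names(p$strategies)) {
    s <- p$strategies[[sn]]
    frac(s$prevention, paste0("strategies.", sn, ".prevention"))
    for (f in c("routine_interval", "post_normal_interval",
                "surveillance_interval"))
      if (!is.finite(s[[f]]) || s[[f]] < 1)
        bad(paste0("strategies.", sn, ".", f), s[[f]], "interval must be >= 1")
    if (!s$primary_test %in% c("none", names(p$tests), "colonoscopy"))
      bad(paste0("strategies.", sn, ".primary_test"), s$primary_test,
          "unknown primary test")
  }
  st <- p$stages
  frac(st$distribution, "stages.distribution")
  frac(st$annual_mortality, "stages.annual_mortality")
  # printed stage fractions sum to 100.1%; admit reporting rounding only
  if (abs(sum(st$distribution) - 1) > 0.005)
    bad("stages.distribution", st$distribution, "sums to 1")
  for (f in c("diagnosis_cost", "treatment_cost", "followup_cost"))
    nonneg(st[[f]], paste0("stages.", f))
  ec <- p$economics
  if (!is.finite(ec$cohort_size) || ec$cohort_size <= 0)
    bad("economics.cohort_size", ec$cohort_size, "must be > 0")
  if (ec$start_age >= ec$end_age)
    bad("economics.start_age", c(ec$start_age, ec$end_age),
        "start_age must be < end_age")
  nonneg(ec$discount_rate, "economics.discount_rate")
  inc <- p$incidence
  nonneg(inc$rate, "incidence.rate")
  if (any(inc$age_to < inc$age_from))
    bad("incidence", inc$age_to, "bands must have age_to >= age_from")
  if (nrow(inc) > 1 && any(inc$age_from[-1] != inc$age_to[-nrow(inc)] + 1))
    bad("incidence", inc$age_from, "bands must be contiguous, non-overlapping")
  if (inc$age_from[1] > ec$start_age || inc$age_to[nrow(inc)] < ec$end_age)
    bad("incidence", range(c(inc$age_from, inc$age_to)),
        "bands must cover [start_age, end_age]")
  cv <- p$conventions
  allowed <- list(half_cycle = c("mid", "start", "end"),
                  ly_discount_from = c("model_start", "event"),
                  compliance_model = c("recurrent", "never"),
                  bleeding_scope = c("all", "therapeutic"),
                  perforation_mortality_basis = c("per_colonoscopy",
                                                  "per_perforation"),
                  diagnosed_mortality = c("replace", "additive"))
  for (f in names(allowed))
    if (!cv[[f]] %in% allowed[[f]])
      bad(paste0("conventions.", f), cv[[f]],
          paste("must be one of", paste(allowed[[f]], collapse = ", ")))
  if (!is.finite(cv$cure_horizon_years) || cv$cure_horizon_years < 1)
    bad("conventions.cure_horizon_years", cv$cure_horizon_years, "must be >= 1")
  if (!is.logical(cv$discount_cases))
    bad("conventions.discount_cases", cv$discount_cases, "must be logical")
  if (!is.null(p$life_table)) {
    lv <- validate_life_table(p$life_table)
    if (length(lv)) for (m in lv) bad("life_table", "", m)
    if (!is.null(p$life_table) && inherits(p$life_table, "data.frame") &&
        length(lv) == 0 &&
        (min(p$life_table$age) > ec$start_age ||
         max(p$life_table$age) < ec$end_age))
      bad("life_table", range(p$life_table$age),
          "must cover [start_age, end_age]")
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble(field = character(), value = character(), rule = character())
}

#' Parameter provenance
#'
#' @param p A `crc_parameters` object.
#' @return A tibble of leaf parameter paths with their values and whether each
#'   came from the base-case defaults or from an override.
#' @export
parameter_provenance <- function(p) {
  tb <- tidy(p)
  ov <- attr(p, "overrides") %||% character()
  tb$source <- ifelse(vapply(tb$parameter, function(pp)
    any(startsWith(pp, ov) | startsWith(ov, pp)),
    logical(1), USE.NAMES = FALSE), "override", "default")
  tb
}

#' @export
print.crc_parameters <- function(x, ...) {
  ec <- x$economics
  cat("<crc_parameters>\n")
  cat(sprintf("  cohort: %s persons, ages %d-%d, discount %.1f%%/yr (%s)\n",
              format(ec$cohort_size, big.mark = ","), ec$start_age, ec$end_age,
              100 * ec$discount_rate, ec$currency))
  for (tn in names(x$tests)) {
    t <- x$tests[[tn]]
    cat(sprintf("  %-11s sens %.1f%%, spec %.1f%%, compliance %.1f%%, USD %g\n",
                paste0(tn, ":"), 100 * t$sensitivity, 100 * t$specificity,
                100 * t$compliance, t$unit_cost))
  }
  cat(sprintf("  colonoscopy: USD %g, compliance %.1f%%\n",
              x$colonoscopy$unit_cost, 100 * x$colonoscopy$compliance))
  ov <- attr(x, "overrides")
  if (length(ov)) cat("  overrides:", paste(ov, collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn crc_parameters Flatten the parameter bundle to a two-column
#'   tibble of dotted leaf paths and values (the life table and incidence
#'   schedule are kept as their own structures and omitted here).
#' @param x A `crc_parameters` object.
#' @param ... Unused.
#' @export
tidy.crc_parameters <- function(x, ...) {
  flat <- unlist(x[c("tests", "colonoscopy", "strategies", "stages",
                     "economics", "conventions")])
  tibble(parameter = names(flat), value = as.character(flat))
}

#' Read and write configuration documents
#'
#' Parameters are exchanged as YAML. A document holds any subset of the
#' parameter tree; missing keys are filled from the base-case defaults and
#' unknown keys are rejected. A top-level `units: percent` key declares that
#' fraction-typed fields (sensitivities, specificities, compliance, rates,
#' prevention fractions, stage distribution and mortality, the discount rate)
#' are given as percentages and must be divided by 100. A `life_table` block
#' with `baseline_hazard`, `age_slope`, `anchor_age` and `max_age` regenerates
#' the parametric life table.
#'
#' @param file Path to a YAML document.
#' @return For `read_parameters()`, a validated `crc_parameters` object.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("economics:\n  discount_rate: 0.0", f)
#' read_parameters(f)$economics$discount_rate
#' @export
read_parameters <- function(file) {
  crc_parameters(file = file)
}

#' @rdname read_parameters
#' @param p A `crc_parameters` object.
#' @param path Output path; the default writes to the console, which is how the
#'   command-line `print-defaults` path emits the base case.
#' @return For `write_parameters()`, the path (or the YAML text, invisibly,
#'   when writing to the console).
#' @export
write_parameters <- function(p = crc_parameters(), path = stdout()) {
  doc <- unclass(p)
  doc$life_table <- NULL
  doc$incidence <- as.list(as.data.frame(doc$incidence))
  doc <- c(list(units = "fraction"), doc)
  txt <- yaml::as.yaml(doc, precision = 12)
  if (inherits(path, "connection")) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  writeLines(txt, path)
  invisible(path)
}

# -- internal helpers ---------------------------------------------------------

fraction_leaves <- c(
  "sensitivity", "specificity", "compliance", "target_prevalence",
  "bleeding_rate", "perforation_rate", "perforation_mortality",
  "workup_compliance", "prevention", "distribution", "annual_mortality",
  "discount_rate", "fit", "m3crc", "primary")

convert_units <- function(doc, percent = identical(doc$units, "percent")) {
  force(percent)
  doc$units <- NULL
  if (!percent) return(doc)
  rescale <- function(node, name) {
    if (is.list(node)) {
      for (nm in names(node)) node[[nm]] <- rescale(node[[nm]], nm)
      node
    } else if (is.numeric(node) && name %in% fraction_leaves) {
      node / 100
    } else node
  }
  for (nm in names(doc)) doc[[nm]] <- rescale(doc[[nm]], nm)
  doc
}

read_config_document <- function(file) {
  doc <- tryCatch(yaml::read_yaml(file), error = function(e)
    abort(paste0("malformed configuration document '", file, "': ",
                 conditionMessage(e))))
  if (!is.list(doc)) abort("configuration document must be a key-value mapping")
  doc <- convert_units(doc)
  if (!is.null(doc$life_table)) {
    lt_spec <- doc$life_table
    doc$life_table <- NULL
    if (!is.null(lt_spec$file)) {
      lt <- read_life_table(lt_spec$file)
    } else {
      lt <- make_life_table(
        baseline_hazard = lt_spec$baseline_hazard,
        age_slope = lt_spec$age_slope,
        anchor_age = lt_spec$anchor_age %||% 50,
        max_age = lt_spec$max_age %||% 100)
    }
    paths <- c(leaf_paths(doc), "life_table")
    doc$life_table <- lt
    return(list(values = doc, paths = paths))
  }
  list(values = doc, paths = leaf_paths(doc))
}

leaf_paths <- function(x, prefix = "") {
  if (!is.list(x) || inherits(x, "data.frame") || length(x) == 0)
    return(prefix)
  unlist(lapply(names(x), function(nm)
    leaf_paths(x[[nm]], if (nzchar(prefix)) paste0(prefix, ".", nm) else nm)))
}

apply_overrides <- function(defaults, overrides, where) {
  if (inherits(overrides, "crc_life_table")) return(overrides)
  if (!is.list(overrides)) {
    if (is.list(defaults) && !inherits(defaults, "data.frame"))
      abort(paste0("override at '", where, "' must be a mapping"))
    if (!is.null(names(defaults)) && !is.null(names(overrides)))
      return(stats::setNames(overrides, names(overrides)))
    if (!is.null(names(defaults)) && length(overrides) == length(defaults))
      return(stats::setNames(overrides, names(defaults)))
    return(overrides)
  }
  if (inherits(defaults, "data.frame")) {
    repl <- as.data.frame(overrides)
    unknown <- setdiff(names(repl), names(defaults))
    if (length(unknown))
      abort(paste0("unknown key(s) under '", where, "': ",
                   paste(unknown, collapse = ", ")))
    return(repl)
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    abort(paste0("unknown key(s)",
                 if (nzchar(where)) paste0(" under '", where, "'"), ": ",
                 paste(unknown, collapse = ", ")))
  for (nm in names(overrides)) {
    defaults[[nm]] <- apply_overrides(
      defaults[[nm]], overrides[[nm]],
      if (nzchar(where)) paste0(where, ".", nm) else nm)
  }
  defaults
}

# Resolve/assign a dotted parameter path; used by the sensitivity sweeps.
get_parameter <- function(p, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- p
  for (k in keys) {
    if (is.null(node[[k]])) abort(paste0("cannot resolve parameter '", path, "'"))
    node <- node[[k]]
  }
  node
}

set_parameter <- function(p, path, value) {
  # setting the stage care-cost TOTAL adjusts the treatment component so the
  # diagnosis/follow-up sub-components keep their published values
  if (grepl("^stages\\.care_cost\\.", path)) {
    stage <- sub("^stages\\.care_cost\\.", "", path)
    fixed <- p$stages$diagnosis_cost[[stage]] + p$stages$followup_cost[[stage]]
    return(set_parameter(p, paste0("stages.treatment_cost.", stage),
                         value - fixed))
  }
  get_parameter(p, path) # errors when unresolvable
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  p[[keys]] <- value
  attr(p, "overrides") <- unique(c(attr(p, "overrides"), path))
  v <- validate_parameters(p)
  if (nrow(v) > 0)
    abort(paste0("setting '", path, "' violates: ",
                 paste(v$rule, collapse = "; ")))
  p
}
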