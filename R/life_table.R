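#' Build a parametric all-cause-mortality life table
#'
#' Constructs a period life table from a Gompertz-type hazard,
#' `q(a) = 1 - exp(-lambda * exp(gamma * (a - anchor_age)))`, closed out with
#' probability 1 at `max_age`. The table stands in for a national standard
#' life table, which is not distributed with the model; [hk_life_table()]
#' freezes constants calibrated to a Hong-Kong-like residual life expectancy
#' of roughly 33 years at age 50.
#'
#' @param baseline_hazard Hazard at the anchor age (`lambda`, per year, >= 0).
#' @param age_slope Log-hazard slope per year of age (`gamma`, >= 0).
#' @param anchor_age Age at which the baseline hazard applies.
#' @param max_age Closure age; the final row has mortality probability 1.
#' @return A tibble of class `crc_life_table` with columns `age`, `qx` (annual
#'   death probability), `survival` (probability of reaching each age from the
#'   first row) and `ex` (residual life expectancy, half-cycle corrected).
#' @examples
#' lt <- make_life_table(0.0024, 0.10, 50, 100)
#' lt$ex[lt$age == 50]
#' @export
make_life_table <- function(baseline_hazard, age_slope, anchor_age = 50,
                            max_age = 100) {
  if (!is.finite(baseline_hazard) || baseline_hazard < 0)
    abort("baseline_hazard must be >= 0")
  if (!is.finite(age_slope) || age_slope < 0) abort("age_slope must be >= 0")
  if (max_age <= anchor_age) abort("max_age must exceed anchor_age")
  ages <- anchor_age:max_age
  qx <- 1 - exp(-baseline_hazard * exp(age_slope * (ages - anchor_age)))
  qx[length(qx)] <- 1
  new_life_table(ages, qx)
}

new_life_table <- function(ages, qx) {
  survival <- cumprod(c(1, 1 - qx))[seq_along(ages)]
  deaths <- survival * qx
  n <- length(ages)
  # e(a) = sum over later deaths of (years lived + 1/2), conditional on a
  ex <- rev(cumsum(rev(deaths * (ages - ages[1] + 0.5))))
  ex <- ex / survival - (ages - ages[1])
  ex[survival == 0] <- 0
  structure(
    tibble(age = ages, qx = qx, survival = survival, ex = ex),
    class = c("crc_life_table", class(tibble())))
}

#' @describeIn make_life_table Frozen synthetic standard life table used by the
#'   packaged base case: `lambda = 0.0024`, `gamma = 0.10`, anchored at age 50
#'   and closed at 100, giving `q(50) = 0.0024`, survival to 75 of 0.774 and a
#'   residual life expectancy at 50 of 32.9 years.
#' @export
hk_life_table <- function() {
  make_life_table(baseline_hazard = 0.0024, age_slope = 0.10,
                  anchor_age = 50, max_age = 100)
}

validate_life_table <- function(lt) {
  msgs <- character()
  if (!inherits(lt, "data.frame") ||
      !all(c("age", "qx", "survival") %in% names(lt)))
    return("life table must have columns age, qx, survival")
  if (any(lt$qx < 0 | lt$qx > 1)) msgs <- c(msgs, "qx must lie in [0, 1]")
  if (lt$qx[nrow(lt)] != 1) msgs <- c(msgs, "final age must have qx = 1")
  if (any(diff(lt$survival) > 1e-12))
    msgs <- c(msgs, "survival must be non-increasing")
  if (any(diff(lt$age) != 1)) msgs <- c(msgs, "ages must be consecutive years")
  msgs
}

#' Discounted residual life-years
#'
#' Expected remaining life-years for a person alive at `age`, weighted by the
#' table's conditional survival and discounted to the model's time origin:
#' \deqn{\sum_{t \ge 0} S(age + t \mid age) \, w(t) \, (1+d)^{-(offset + t)}}
#' where `w(t)` applies the half-cycle convention (a death during a cycle
#' contributes half that cycle's year). With `discount_rate = 0` and
#' `time_offset = 0` this equals the life table's residual life expectancy at
#' `age`. Life-years lost to a cancer or complication death are this quantity
#' evaluated at the age of death.
#'
#' @param lt A `crc_life_table`.
#' @param age Integer age within the table.
#' @param discount_rate Yearly discount rate `d` (>= 0).
#' @param time_offset Years between the model's time origin and the death; the
#'   discount applies over `offset + t`.
#' @param half_cycle One of `"mid"` (default: deaths mid-cycle), `"start"`
#'   (a death year contributes nothing) or `"end"` (contributes fully).
#' @return Discounted residual life-years (a non-negative scalar).
#' @examples
#' lt <- hk_life_table()
#' residual_life_years(lt, 60)              # undiscounted: equals ex at 60
#' residual_life_years(lt, 60, 0.03, 10)    # discounted to the model origin
#' @export
residual_life_years <- function(lt, age, discount_rate = 0, time_offset = 0,
                                half_cycle = c("mid", "start", "end")) {
  half_cycle <- match.arg(half_cycle)
  if (discount_rate < 0) abort("discount_rate must be >= 0")
  if (time_offset < 0) abort("time_offset must be >= 0")
  i <- match(age, lt$age)
  if (is.na(i)) abort(paste0("age ", age, " outside the life table range"))
  qx <- lt$qx[i:nrow(lt)]
  s_cond <- cumprod(c(1, 1 - qx))[seq_along(qx)] # alive at start of each year
  w <- switch(half_cycle,
              mid = s_cond * (1 - qx / 2),
              start = s_cond * (1 - qx),
              end = s_cond)
  t <- seq_along(qx) - 1
  sum(w * (1 + discount_rate)^-(time_offset + t))
}

#' Import or export a life table as delimited text
#'
#' The interchange format is two whitespace- or tab-separated columns, age and
#' annual mortality probability, so a real national life table can be dropped
#' in place of the synthetic one.
#'
#' @param file Path to a two-column text file (a header line `age qx` is
#'   accepted and ignored).
#' @return For `read_life_table()`, a `crc_life_table`.
#' @export
read_life_table <- function(file) {
  skip <- if (grepl("[A-Za-z]", readLines(file, n = 1))) 1L else 0L
  tb <- readr::read_table(file, col_names = c("age", "qx"),
                          col_types = "dd", comment = "#", skip = skip)
  if (nrow(tb) < 2 || any(!is.finite(tb$age)) || any(!is.finite(tb$qx)))
    abort(paste0("'", file, "' is not a two-column (age, qx) life table"))
  lt <- new_life_table(as.integer(tb$age), tb$qx)
  msgs <- validate_life_table(lt)
  if (length(msgs)) abort(c("invalid life table", msgs))
  lt
}

#' @rdname read_life_table
#' @param lt A `crc_life_table`.
#' @param path Output path.
#' @export
write_life_table <- function(lt, path) {
  readr::write_delim(lt[, c("age", "qx")], path, delim = "\t")
  invisible(path)
}
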