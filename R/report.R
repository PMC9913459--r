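#' Outcome table in the published row layout
#'
#' Arranges a fitted comparison as the familiar four-column outcome table:
#' one row per measure (cases, life-years, procedures, complications, costs
#' by category, comparative rows), one column per strategy.
#'
#' @param model A `crc_model`.
#' @return A tibble with a `measure` column and one column per strategy.
#' @export
outcome_table <- function(model) {
  oc <- model$outcomes
  rep_ <- model$report
  rows <- c(total_cases = "Total number CRC cases",
            life_years_lost = "Total loss of cancer-related life years",
            tests = "Stool tests",
            colonoscopies = "Colonoscopies",
            colonoscopies_diagnostic = "  diagnostic (without polypectomy)",
            colonoscopies_therapeutic = "  therapeutic (with polypectomy)",
            bleeds = "Bleeding complications",
            perforations = "Perforations",
            cost_screening_test = "Cost: screening tests",
            cost_colonoscopy = "Cost: colonoscopy",
            cost_polypectomy = "Cost: polypectomy",
            cost_bleeding = "Cost: bleeding",
            cost_perforation = "Cost: perforation",
            cost_care_I = "Cost: care of CRC stage I",
            cost_care_II = "Cost: care of CRC stage II",
            cost_care_III = "Cost: care of CRC stage III",
            cost_care_IV = "Cost: care of CRC stage IV",
            total_cost = "Total costs")
  tb <- oc |>
    select("strategy", dplyr::all_of(names(rows))) |>
    tidyr::pivot_longer(-"strategy", names_to = "key") |>
    tidyr::pivot_wider(names_from = "strategy") |>
    mutate(measure = rows[.data$key], .before = 1) |>
    select(-"key")
  if (!is.null(rep_)) {
    extra <- rep_ |>
      select("strategy", `Cases of CRC prevented` = "cases_prevented",
             `Proportion of CRC cases prevented` = "proportion_prevented",
             `Life-years saved` = "life_years_saved",
             `Total costs per life-years saved` = "cost_per_life_year_saved",
             `ICER vs baseline` = "icer_vs_baseline") |>
      tidyr::pivot_longer(-"strategy", names_to = "measure") |>
      tidyr::pivot_wider(names_from = "strategy")
    tb <- dplyr::bind_rows(tb, extra)
  }
  tb
}

#' Run manifest
#'
#' Records the provenance and conventions of a run so that any outcome table
#' can be traced back to the exact configuration that produced it: overridden
#' parameters, the convention flags in force, package version and timestamp.
#'
#' @param params A `crc_parameters` object.
#' @return A list suitable for YAML/JSON serialisation.
#' @export
run_manifest <- function(params) {
  list(
    package = "crcscreen",
    version = as.character(utils::packageVersion("crcscreen")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    conventions = params$conventions,
    economics = params$economics,
    overrides = as.list(attr(params, "overrides") %||% character()))
}

#' Write a full run to disk
#'
#' Writes the outcome table, the comparative report, the pairwise ICER matrix,
#' per-strategy traces and the run manifest into a directory. Tables are
#' deterministic: two runs with the same configuration produce byte-identical
#' files (the timestamp lives only in the manifest).
#'
#' @param model A `crc_model`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(outcome_table(model), file.path(dir, "outcomes.csv"))
  if (!is.null(model$report))
    readr::write_csv(model$report, file.path(dir, "cea_report.csv"))
  readr::write_csv(model$icers, file.path(dir, "icer_matrix.csv"))
  if (!is.null(model$traces))
    for (s in names(model$traces))
      readr::write_csv(trace_table(model$traces[[s]]),
                       file.path(dir, paste0("trace_", s, ".csv")))
  yaml::write_yaml(run_manifest(model$params), file.path(dir, "manifest.yaml"))
  invisible(dir)
}
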