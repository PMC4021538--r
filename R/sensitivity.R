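#' One-way sensitivity sweep specification
#'
#' @param parameter dotted path into a [cohort_scenario] resolving to a
#'   scalar, e.g. `"tests.cea.sensitivity"` or
#'   `"life_expectancies.post_salvage_months"`.
#' @param low,high endpoint values (`low <= high`).
#' @param outcomes outcome fields to track; default salvage proportion and
#'   five-year overall survival.
#' @return a `sweep_spec` list.
#' @export
sweep_spec <- function(parameter, low, high,
                       outcomes = c("salvage_prop", "os5")) {
  stopifnot(low <= high)
  structure(list(parameter = parameter, low = low, high = high,
                 outcomes = outcomes), class = "sweep_spec")
}

extract_outcomes <- function(summary, outcomes) {
  vals <- vapply(outcomes, function(o) {
    if (o == "salvage_prop") summary$salvage_prop
    else if (o == "dfs5") summary$dfs5
    else if (grepl("^os[0-9]+$", o)) summary$os[[o]]
    else stop("unknown outcome: ", o, call. = FALSE)
  }, numeric(1))
  stats::setNames(vals, outcomes)
}

#' One-way deterministic sensitivity sweep
#'
#' Runs the scenario at the baseline parameter value and at the two
#' endpoints, all three runs under the identical seed (common random
#' numbers), so outcome differences reflect the parameter change alone.
#' Relative change is expressed as percent of the baseline outcome.
#'
#' @param spec a [sweep_spec].
#' @param scenario a [cohort_scenario]; the baseline value is the one the
#'   scenario currently carries and must lie within `[low, high]`.
#' @param seed integer seed shared by the three runs.
#' @return a `sweep_result` list: `parameter`, `baseline_value`, `low`,
#'   `high`, `baseline`, `at_low`, `at_high` (outcome vectors),
#'   `relative_change_low`, `relative_change_high` (percent of baseline).
#' @export
one_way_sweep <- function(spec, scenario, seed) {
  stopifnot(inherits(spec, "sweep_spec"),
            inherits(scenario, "cohort_scenario"))
  base_val <- scenario_get(scenario, spec$parameter)
  if (base_val < spec$low || base_val > spec$high)
    stop("baseline value ", base_val, " outside sweep range for ",
         spec$parameter, call. = FALSE)
  runs <- lapply(c(base_val, spec$low, spec$high), function(v)
    run_scenario(scenario_set(scenario, spec$parameter, v), seed))
  vals <- lapply(runs, function(r) extract_outcomes(r$summary, spec$outcomes))
  rel <- function(v) 100 * (v - vals[[1]]) / vals[[1]]
  structure(list(parameter = spec$parameter, baseline_value = base_val,
                 low = spec$low, high = spec$high,
                 baseline = vals[[1]], at_low = vals[[2]],
                 at_high = vals[[3]],
                 relative_change_low = rel(vals[[2]]),
                 relative_change_high = rel(vals[[3]])),
            class = "sweep_result")
}

#' Default sweep table
#'
#' The published one-way sensitivity ranges: every modality's sensitivity and
#' specificity, plus the two post-diagnosis life expectancies. Ranges are
#' centred on the base-case estimates (e.g. CEA sensitivity 0.64, range
#' 0.49-0.79; post-salvage life expectancy 21 months, range 15-27).
#'
#' @return list of [sweep_spec]s.
#' @export
default_sweep_table <- function() {
  rng <- list(
    c("tests.cea.sensitivity", 0.49, 0.79),
    c("tests.cea.specificity", 0.75, 1.00),
    c("tests.chest_xray.sensitivity", 0.61, 0.91),
    c("tests.chest_xray.specificity", 0.80, 1.00),
    c("tests.ct_hepatic.sensitivity", 0.68, 0.98),
    c("tests.ct_hepatic.specificity", 0.78, 1.00),
    c("tests.ct_other_abdominal.sensitivity", 0.31, 0.61),
    c("tests.ct_other_abdominal.specificity", 0.83, 1.00),
    c("tests.hepatic_ultrasound.sensitivity", 0.47, 0.77),
    c("tests.hepatic_ultrasound.specificity", 0.70, 1.00),
    c("tests.colonoscopy.sensitivity", 0.80, 1.00),
    c("tests.colonoscopy.specificity", 0.85, 1.00),
    c("tests.clinical_exam.sensitivity", 0.27, 0.57),
    c("tests.clinical_exam.specificity", 0.70, 1.00),
    c("life_expectancies.post_salvage_months", 15, 27),
    c("life_expectancies.post_unresectable_months", 4, 12))
  lapply(rng, function(r)
    sweep_spec(r[1], as.numeric(r[2]), as.numeric(r[3])))
}

#' Run a table of one-way sweeps
#'
#' Sweeps every listed parameter with the same seed and ranks results by the
#' largest absolute relative change in the primary outcome (the first
#' outcome of each spec; ties keep input order).
#'
#' @param table list of [sweep_spec]s (default [default_sweep_table()]).
#' @param scenario a [cohort_scenario].
#' @param seed integer seed shared by every run.
#' @return a data.frame, one row per parameter, columns `parameter`, `low`,
#'   `high`, `baseline_value`, and per tracked outcome the baseline/endpoint
#'   values and relative changes; ranked by impact.
#' @export
sweep_all <- function(table = default_sweep_table(), scenario, seed) {
  stopifnot(length(table) >= 1)
  rows <- lapply(table, function(sp) {
    res <- one_way_sweep(sp, scenario, seed)
    out <- data.frame(parameter = res$parameter,
                      baseline_value = res$baseline_value,
                      low = res$low, high = res$high,
                      stringsAsFactors = FALSE)
    for (o in names(res$baseline)) {
      out[[paste0(o, "_baseline")]] <- res$baseline[[o]]
      out[[paste0(o, "_at_low")]] <- res$at_low[[o]]
      out[[paste0(o, "_at_high")]] <- res$at_high[[o]]
      out[[paste0(o, "_rel_low")]] <- res$relative_change_low[[o]]
      out[[paste0(o, "_rel_high")]] <- res$relative_change_high[[o]]
    }
    out
  })
  df <- do.call(rbind, rows)
  primary <- table[[1]]$outcomes[1]
  impact <- pmax(abs(df[[paste0(primary, "_rel_low")]]),
                 abs(df[[paste0(primary, "_rel_high")]]))
  df$max_abs_rel_change <- impact
  df[order(-impact), , drop = FALSE]
}
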