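#' Per-cycle background mortality
#'
#' Converts a five-year cumulative probability of death from non-CRC causes
#' into the constant per-cycle transition probability p satisfying
#' `(1 - p)^20 = 1 - cum_5yr` (20 three-month cycles in five years).
#'
#' @param cum_5yr cumulative five-year probability, in `[0, 1)`.
#' @return per-cycle probability.
#' @examples
#' per_cycle_mortality(0.016)  # ~8.06e-4
#' @export
per_cycle_mortality <- function(cum_5yr) {
  if (any(cum_5yr < 0) || any(cum_5yr >= 1))
    stop("cum_5yr must lie in [0, 1)", call. = FALSE)
  1 - (1 - cum_5yr)^(1 / 20)
}

le_cycles <- function(scenario) {
  le <- scenario$life_expectancies
  c(salvage = months_to_cycles(le$post_salvage_months),
    palliative = months_to_cycles(le$post_unresectable_months))
}

eligibility_time <- function(t_dx, cycle, eligibility) {
  if (eligibility == "exact") t_dx else cycle - 1
}

#' Simulate one patient through the surveillance and re-treatment submodel
#'
#' Reference per-patient implementation of the five-state discrete-time Markov
#' loop (no known recurrence; recurrence curatively treated; recurrence
#' palliatively treated; dead due to cancer; dead due to other causes). Within
#' each 3-month cycle events resolve in order: symptomatic interval detection
#' at the continuous symptom-onset time, scheduled surveillance testing at the
#' cycle boundary, then mortality (an assigned cancer death occurring within
#' the cycle takes precedence over the background draw at the boundary). On
#' diagnosis, [salvage_eligible()] decides curative versus palliative
#' re-treatment and the corresponding life expectancy is assigned; cancer
#' death then occurs deterministically at diagnosis time plus life expectancy
#' if within the horizon. Uses R's global random stream ([set.seed()]);
#' [run_scenario()] is the fast whole-cohort equivalent.
#'
#' @param profile a `recurrence_profile` from [assign_recurrence()].
#' @param scenario the [cohort_scenario] the profile was generated under.
#' @return a `patient_outcome` list: `state_path` (per-cycle state), `dx_time`,
#'   `dx_mode`, `salvage`, `death_time`, `death_cause`.
#' @export
simulate_patient <- function(profile, scenario) {
  stopifnot(inherits(profile, "recurrence_profile"),
            inherits(scenario, "cohort_scenario"))
  H <- scenario$horizon_cycles
  p_m <- per_cycle_mortality(scenario$progression$m)
  le <- le_cycles(scenario)
  states <- character(H)
  state <- "no_known_recurrence"
  dx_time <- NA_real_; dx_mode <- NA_character_
  salvage <- FALSE; death_time <- NA_real_; death_cause <- NA_character_
  cancer_death <- Inf

  record_dx <- function(t, mode, cycle) {
    dx_time <<- t; dx_mode <<- mode
    t_elig <- eligibility_time(t, cycle, scenario$eligibility)
    salvage <<- salvage_eligible(profile$site, t_elig, profile$U,
                                 scenario$p_lung_operable)
    state <<- if (salvage) "recurrence_curative" else "recurrence_palliative"
    cancer_death <<- t + if (salvage) le[["salvage"]] else le[["palliative"]]
  }

  for (cycle in seq_len(H)) {
    diagnosed <- state %in% c("recurrence_curative", "recurrence_palliative")
    if (!diagnosed && isTRUE(profile$will_recur) &&
        profile$S > cycle - 1 && profile$S <= cycle) {
      record_dx(profile$S, "symptomatic", cycle)
      diagnosed <- TRUE
    }
    if (!diagnosed) {
      res <- run_surveillance_cycle(profile, cycle, scenario$schedule,
                                    scenario$tests)
      if (!is.null(res$diagnosis))
        record_dx(res$diagnosis$time, res$diagnosis$mode, cycle)
    }
    if (cancer_death <= cycle) {
      death_time <- cancer_death; death_cause <- "cancer"
      state <- "dead_cancer"
    } else if (stats::runif(1) < p_m) {
      death_time <- cycle; death_cause <- "other"
      state <- "dead_other"
    }
    states[cycle] <- state
    if (state %in% c("dead_cancer", "dead_other")) {
      if (cycle < H) states[(cycle + 1):H] <- state
      break
    }
  }
  structure(list(state_path = states, dx_time = dx_time, dx_mode = dx_mode,
                 salvage = salvage, death_time = death_time,
                 death_cause = death_cause),
            class = "patient_outcome")
}

#' Summarize a simulated cohort
#'
#' Computes the seven trial-style outcome targets from per-patient outcomes:
#' overall survival at each whole year (fraction alive at the end of cycle
#' 4k, after that cycle's events), disease-free survival at the horizon
#' (fraction with neither a recurrence diagnosis nor death from any cause),
#' the proportion of all patients undergoing curative salvage surgery, and
#' the split of diagnoses by detection mode. Proportions are on the 0-1
#' scale; the print method and the calibration layer use percentage points.
#'
#' @param outcomes a data.frame of per-patient outcomes as returned in
#'   `run_scenario()$outcomes` (columns `dx_time`, `salvage`, `death_time`,
#'   `dx_mode` at minimum).
#' @param horizon horizon in cycles (default 20).
#' @return an `outcome_summary` list: `dfs5`, `os` (named vector, years
#'   1..horizon/4), `salvage_prop`, `dx_mode_split`, `n`.
#' @export
summarize_cohort <- function(outcomes, horizon = 20L) {
  stopifnot(is.data.frame(outcomes))
  n <- nrow(outcomes)
  if (n == 0) stop("empty cohort", call. = FALSE)
  dead_by <- function(t) !is.na(outcomes$death_time) & outcomes$death_time <= t
  years <- seq_len(horizon %/% 4L)
  os <- vapply(years, function(k) 1 - mean(dead_by(4 * k)), numeric(1))
  names(os) <- paste0("os", years)
  diagnosed <- !is.na(outcomes$dx_time) & outcomes$dx_time <= horizon
  dfs5 <- mean(!diagnosed & !dead_by(horizon))
  mode <- outcomes$dx_mode[diagnosed]
  split <- c(surveillance = mean(mode == "surveillance"),
             symptomatic = mean(mode == "symptomatic"))
  structure(list(dfs5 = dfs5, os = os,
                 salvage_prop = mean(outcomes$salvage),
                 dx_mode_split = split, n = n),
            class = "outcome_summary")
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d patients:\n", x$n))
  cat(sprintf("  DFS at horizon  %5.1f%%\n", 100 * x$dfs5))
  for (k in seq_along(x$os))
    cat(sprintf("  OS year %d       %5.1f%%\n", k, 100 * x$os[k]))
  cat(sprintf("  Salvage surgery %5.1f%%\n", 100 * x$salvage_prop))
  invisible(x)
}

#' Extract the outcome-target vector in percentage points
#'
#' @param summary an `outcome_summary`.
#' @return named numeric vector `dfs5, os1..os5, salvage` on the 0-100 scale.
#' @export
summary_targets <- function(summary) {
  stopifnot(inherits(summary, "outcome_summary"))
  out <- c(dfs5 = summary$dfs5, summary$os, salvage = summary$salvage_prop)
  100 * out
}

engine_args <- function(scenario, seed) {
  mods <- modality_levels()
  sdist <- scenario$site_distribution
  met_code <- match(sdist$met_status, site_met_levels()) - 1L
  detect <- matrix(FALSE, length(mods), nrow(sdist))
  for (j in seq_len(nrow(sdist))) {
    site <- structure(list(local_status = sdist$local_status[j],
                           met_status = sdist$met_status[j]),
                      class = "recurrence_site")
    detect[, j] <- vapply(mods, function(m)
      site_matches_targets(site, scenario$tests[[m]]$targets), TRUE)
  }
  pp <- scenario$progression
  le <- le_cycles(scenario)
  list(n = scenario$n_patients, seed = as.double(seed),
       horizon = scenario$horizon_cycles, p_recur = scenario$p_recur,
       site_prob = sdist$prob, site_met = met_code,
       r_d = pp$r_d, xdu_c = weeks_to_cycles(pp$x_du_weeks), r_u = pp$r_u,
       xds_c = weeks_to_cycles(pp$x_ds_weeks), r_s = pp$r_s,
       sigma_c = weeks_to_cycles(pp$sigma_ds_weeks),
       p_mort_cycle = per_cycle_mortality(pp$m),
       sens = vapply(scenario$tests[mods], `[[`, 1.0, "sensitivity"),
       spec = vapply(scenario$tests[mods], `[[`, 1.0, "specificity"),
       detect = detect,
       schedule = matrix(as.integer(unclass(scenario$schedule)),
                         nrow = scenario$horizon_cycles),
       le_salvage_c = le[["salvage"]], le_palliative_c = le[["palliative"]],
       p_lung_operable = scenario$p_lung_operable,
       exact_eligibility = scenario$eligibility == "exact")
}

#' Run a scenario
#'
#' Simulates the full cohort with the compiled engine and summarizes it.
#' Deterministic given `(scenario, seed)`: every random variate is a pure
#' function of the seed, the patient index, and the draw's identity (cycle
#' and modality), so per-patient histories are bitwise reproducible,
#' unchanged when the cohort grows, and comparable across scenario variants
#' under common random numbers.
#'
#' @param scenario a [cohort_scenario].
#' @param seed integer master seed.
#' @return a list of class `scenario_run`: `summary` (an `outcome_summary`),
#'   `outcomes` (one row per patient: latent profile, diagnosis, salvage,
#'   death), `seed`, `scenario`.
#' @export
run_scenario <- function(scenario, seed) {
  stopifnot(inherits(scenario, "cohort_scenario"), is.numeric(seed),
            length(seed) == 1L, seed >= 0)
  args <- engine_args(scenario, seed)
  raw <- do.call(cpp_run_cohort, args)
  sdist <- scenario$site_distribution
  outcomes <- data.frame(
    patient = raw$patient, will_recur = raw$will_recur,
    local_status = ifelse(is.na(raw$site), NA_character_,
                          sdist$local_status[raw$site]),
    met_status = ifelse(is.na(raw$site), NA_character_,
                        sdist$met_status[raw$site]),
    D = raw$D, U = raw$U, S = raw$S, eps = raw$eps,
    s_clipped = raw$s_clipped, dx_time = raw$dx_time,
    dx_mode = c(NA, "surveillance", "symptomatic")[raw$dx_mode + 1L],
    salvage = raw$salvage, death_time = raw$death_time,
    death_cause = c(NA, "cancer", "other")[raw$death_cause + 1L],
    stringsAsFactors = FALSE)
  structure(list(summary = summarize_cohort(outcomes,
                                            scenario$horizon_cycles),
                 outcomes = outcomes, seed = seed, scenario = scenario),
            class = "scenario_run")
}

#' @export
print.scenario_run <- function(x, ...) {
  cat("Scenario run (seed", x$seed, ")\n")
  print(x$summary)
  invisible(x)
}

#' Export per-patient outcomes and cohort summaries
#'
#' @param run a `scenario_run` from [run_scenario()].
#' @param outcomes_csv,summary_json,summary_csv optional output paths; only
#'   non-`NULL` ones are written.
#' @return invisibly, the run.
#' @export
export_run <- function(run, outcomes_csv = NULL, summary_json = NULL,
                       summary_csv = NULL) {
  stopifnot(inherits(run, "scenario_run"))
  if (!is.null(outcomes_csv))
    utils::write.csv(run$outcomes, outcomes_csv, row.names = FALSE)
  tg <- summary_targets(run$summary)
  if (!is.null(summary_json))
    jsonlite::write_json(as.list(tg), summary_json, auto_unbox = TRUE,
                         digits = NA)
  if (!is.null(summary_csv))
    utils::write.csv(data.frame(target = names(tg), value = unname(tg)),
                     summary_csv, row.names = FALSE)
  invisible(run)
}
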