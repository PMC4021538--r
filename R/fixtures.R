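#' Packaged scenarios and parameter sets
#'
#' The package ships desk-scale fixtures for both arms of the Pietra
#' surveillance trial, bundling each arm's cohort characteristics, testing
#' schedule and observed outcome targets, together with the published final
#' calibrated disease-progression parameters and the calibration starting
#' ranges.
#'
#' @return `fixture_catalog()` returns the available fixture names.
#' @export
fixture_catalog <- function() c("pietra_intensive", "pietra_minimal")

#' @rdname fixture_catalog
#' @param name a fixture name from [fixture_catalog()].
#' @return `load_fixture` returns the [cohort_scenario] (its `targets` field
#'   carries the arm's observed outcomes on the 0-100 scale).
#' @export
load_fixture <- function(name) {
  if (!name %in% fixture_catalog())
    stop("unknown fixture '", name, "'; available: ",
         paste(fixture_catalog(), collapse = ", "), call. = FALSE)
  path <- system.file("extdata", paste0(name, ".yaml"), package = "crcrecur")
  read_scenario(path)
}

#' Final calibrated disease-progression parameters
#'
#' The best-fitting parameter set from the published nine-round grid-search
#' calibration against the intensive follow-up arm: detectability hazard
#' 0.092 per cycle, resectability window 6 weeks growing at 0.11 per cycle,
#' presymptomatic window 17 weeks growing at 0.07 per cycle, symptom-error
#' SD 11 weeks, background five-year mortality 1.6%.
#'
#' @return a [progression_params] object.
#' @export
calibrated_params <- function() {
  progression_params(r_d = 0.092, x_du_weeks = 6, r_u = 0.11,
                     x_ds_weeks = 17, r_s = 0.07, sigma_ds_weeks = 11,
                     m = 0.016)
}

#' Generate a random but valid scenario
#'
#' Draws every scenario field from the supplied ranges; intended for
#' property-based testing. Deterministic given `seed`. Degenerate
#' (zero-width) ranges reproduce the specified value exactly.
#'
#' @param seed integer seed.
#' @param n_patients cohort size.
#' @param horizon_cycles horizon.
#' @param p_recur_range,r_d_range,x_du_range,r_u_range,x_ds_range,r_s_range,sigma_range,m_range
#'   `c(lower, upper)` sampling ranges for the corresponding parameters
#'   (window ranges in weeks).
#' @param visit_density probability that any given (cycle, modality) cell of
#'   the schedule is tested.
#' @return a [cohort_scenario].
#' @export
generate_synthetic_scenario <- function(seed, n_patients = 500L,
                                        horizon_cycles = 20L,
                                        p_recur_range = c(0.1, 0.9),
                                        r_d_range = c(0.05, 0.3),
                                        x_du_range = c(2, 30),
                                        r_u_range = c(0, 0.2),
                                        x_ds_range = c(2, 30),
                                        r_s_range = c(-0.02, 0.2),
                                        sigma_range = c(0, 15),
                                        m_range = c(0, 0.3),
                                        visit_density = 0.3) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  runifr <- function(r) stats::runif(1, r[1], r[2])
  w <- stats::runif(5)
  sdist <- site_distribution(
    local_status = c("locoregional", "anastomotic_only", "none", "none",
                     "none"),
    met_status = c("none", "none", "liver", "lung", "multiple_other"),
    prob = w / sum(w))
  pp <- progression_params(
    r_d = runifr(r_d_range), x_du_weeks = runifr(x_du_range),
    r_u = runifr(r_u_range), x_ds_weeks = runifr(x_ds_range),
    r_s = runifr(r_s_range), sigma_ds_weeks = runifr(sigma_range),
    m = runifr(m_range))
  tests <- default_test_panel()
  for (m in names(tests)) {
    tests[[m]]$sensitivity <- stats::runif(1, 0.3, 1)
    tests[[m]]$specificity <- stats::runif(1, 0.7, 1)
  }
  mat <- matrix(as.integer(stats::runif(horizon_cycles *
                                          length(modality_levels())) <
                             visit_density),
                nrow = horizon_cycles,
                dimnames = list(NULL, modality_levels()))
  cohort_scenario(n_patients = n_patients, p_recur = runifr(p_recur_range),
                  site_distribution = sdist, progression = pp, tests = tests,
                  schedule = schedule_from_matrix(mat),
                  horizon_cycles = horizon_cycles,
                  name = sprintf("synthetic_%d", seed))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Export disease-progression milestones for plotting
#'
#' Samples `n` recurring patients under the given parameters and tabulates
#' their latent milestones ranked from earliest- to latest-recurring, one
#' row per patient — the layout used to scatter-plot D, U and S against
#' patient rank.
#'
#' @param params a [progression_params].
#' @param n number of recurrers (default 20).
#' @param seed integer seed.
#' @param path optional CSV output path.
#' @return a data.frame with columns `rank`, `D_cycles`, `U_cycles`,
#'   `S_cycles`, `D_weeks`, `U_weeks`, `S_weeks`.
#' @export
export_progression_scatter <- function(params, n = 20L, seed = 1L,
                                       path = NULL) {
  stopifnot(inherits(params, "progression_params"), n >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  D <- sort(sample_detectability_time(params$r_d, n))
  U <- unresectability_time(D, params)
  S <- symptom_onset_time(D, params)$S
  df <- data.frame(rank = seq_len(n), D_cycles = D, U_cycles = U,
                   S_cycles = S, D_weeks = cycles_to_weeks(D),
                   U_weeks = cycles_to_weeks(U),
                   S_weeks = cycles_to_weeks(S))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
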