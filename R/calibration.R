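param_names <- function() {
  c("r_d", "x_du_weeks", "r_u", "x_ds_weeks", "r_s", "sigma_ds_weeks", "m")
}

target_names <- function() c("dfs5", "os1", "os2", "os3", "os4", "os5", "salvage")

default_priority <- function() {
  # DFS5 first, then OS5 down to OS3, salvage, and OS2/OS1 last (most subject
  # to small-number noise in the source trial)
  c("dfs5", "os5", "os4", "os3", "salvage", "os2", "os1")
}

#' Starting ranges for grid-search calibration
#'
#' The published initial search intervals for the seven calibrated
#' parameters: detectability hazard 0.05-0.12 per cycle, both baseline
#' windows 1 week to 9 months (39 weeks), presymptomatic-window rate
#' -0.025-0.15, resectability-window rate 0-0.15, symptom-error SD 1 week to
#' 6 months (26 weeks), and background five-year mortality 1-20%.
#'
#' @return named list of `c(lower, upper)` ranges.
#' @export
default_starting_ranges <- function() {
  list(r_d = c(0.05, 0.12), x_du_weeks = c(1, 39), r_u = c(0, 0.15),
       x_ds_weeks = c(1, 39), r_s = c(-0.025, 0.15),
       sigma_ds_weeks = c(1, 26), m = c(0.01, 0.20))
}

#' Calibration specification
#'
#' @param targets named numeric vector of observed outcomes on the 0-100
#'   scale, names `dfs5, os1..os5, salvage`.
#' @param ranges named list of inclusive `c(lower, upper)` intervals per
#'   parameter; defaults to [default_starting_ranges()].
#' @param points_per_param grid points per parameter (scalar or named
#'   vector), between 2 and 8; default 3 (the desk-scale profile).
#' @param priority order in which targets filter candidates.
#' @param tol_primary,tol_fallback elimination thresholds in percentage
#'   points: candidates deviating by more than `tol_primary` are dropped at
#'   each step; if no candidate survives a step, the step is retried at
#'   `tol_fallback`.
#' @param n_patients cohort size per model run.
#' @param max_rounds maximum grid-search rounds.
#' @return a `calibration_spec` list.
#' @export
calibration_spec <- function(targets, ranges = default_starting_ranges(),
                             points_per_param = 3L,
                             priority = default_priority(),
                             tol_primary = 1, tol_fallback = 2,
                             n_patients = 2000L, max_rounds = 3L) {
  targets <- unlist(targets)[target_names()]
  if (anyNA(targets)) stop("targets must cover ", paste(target_names(),
                           collapse = ", "), call. = FALSE)
  stopifnot(setequal(names(ranges), param_names()),
            setequal(priority, target_names()))
  structure(list(targets = targets, ranges = ranges[param_names()],
                 points_per_param = points_per_param, priority = priority,
                 tol_primary = tol_primary, tol_fallback = tol_fallback,
                 n_patients = as.integer(n_patients),
                 max_rounds = as.integer(max_rounds)),
            class = "calibration_spec")
}

#' Build an evenly spaced parameter grid
#'
#' Cartesian product of evenly spaced values over each parameter's inclusive
#' range (endpoints included). A degenerate range (zero width) contributes a
#' single value.
#'
#' @param ranges named list of `c(lower, upper)`.
#' @param points_per_param scalar or named vector of point counts (>= 2,
#'   except for degenerate ranges).
#' @return a data.frame with one column per parameter and one row per
#'   combination; attribute `step` holds each parameter's grid spacing.
#' @export
build_grid <- function(ranges, points_per_param = 3L) {
  if (length(points_per_param) == 1L)
    points_per_param <- stats::setNames(rep(points_per_param,
                                            length(ranges)), names(ranges))
  vals <- lapply(names(ranges), function(p) {
    r <- ranges[[p]]
    if (diff(r) == 0) return(r[1])
    k <- points_per_param[[p]]
    if (k < 2) stop("points_per_param must be >= 2 for ", p, call. = FALSE)
    seq(r[1], r[2], length.out = k)
  })
  names(vals) <- names(ranges)
  grid <- expand.grid(vals, KEEP.OUT.ATTRS = FALSE)
  step <- vapply(vals, function(v)
    if (length(v) > 1) v[2] - v[1] else 0, numeric(1))
  attr(grid, "step") <- step
  grid
}

#' Goodness of fit
#'
#' Unweighted sum of squared differences between predicted and observed
#' values of the seven calibration targets, in percentage points.
#'
#' @param predicted,observed named numeric vectors covering the same targets.
#' @return non-negative scalar.
#' @export
goodness_of_fit <- function(predicted, observed) {
  if (!setequal(names(predicted), names(observed)))
    stop("predicted and observed must cover the same targets", call. = FALSE)
  sum((predicted[names(observed)] - observed)^2)
}

#' Sequential target filtering
#'
#' Applies the priority-ordered elimination rule: for each target in turn,
#' candidates whose predicted value deviates from the observed value by more
#' than `tol_primary` percentage points are dropped; if that leaves none, the
#' step is retried at `tol_fallback`. If even the fallback eliminates every
#' remaining candidate, the step is skipped with a flag (passing survivors
#' through unchanged) rather than aborting.
#'
#' @param predicted matrix or data.frame of predicted targets (columns named
#'   as in [goodness_of_fit()]), one row per candidate.
#' @param observed named numeric vector of observed targets.
#' @param spec a [calibration_spec] (supplies priority and tolerances).
#' @return list with `keep` (logical vector over candidates), `steps`
#'   (data.frame: target, tolerance used, survivors), `flagged` (targets
#'   where even the fallback failed).
#' @export
sequential_filter <- function(predicted, observed, spec) {
  predicted <- as.matrix(predicted)
  keep <- rep(TRUE, nrow(predicted))
  steps <- data.frame(target = character(0), tol = numeric(0),
                      survivors = integer(0))
  flagged <- character(0)
  for (tg in spec$priority) {
    dev <- abs(predicted[, tg] - observed[[tg]])
    for (tol in c(spec$tol_primary, spec$tol_fallback)) {
      cand <- keep & dev <= tol
      if (any(cand)) break
    }
    if (!any(cand)) {
      flagged <- c(flagged, tg)
      warning("no candidate within fallback tolerance for target '", tg,
              "'; step skipped", call. = FALSE)
      cand <- keep
    }
    keep <- cand
    steps <- rbind(steps, data.frame(target = tg, tol = tol,
                                     survivors = sum(keep)))
  }
  list(keep = keep, steps = steps, flagged = flagged)
}

#' Narrow parameter ranges between calibration rounds
#'
#' Each parameter's next-round range spans the surviving values, padded by
#' one previous-round grid step on each side and clipped to the original
#' starting range.
#'
#' @param survivors data.frame of surviving parameter sets.
#' @param step named numeric vector of the previous grid's spacing.
#' @param original named list of the calibration's starting ranges.
#' @return named list of new `c(lower, upper)` ranges.
#' @export
narrow_ranges <- function(survivors, step, original) {
  stopifnot(nrow(survivors) >= 1)
  out <- lapply(names(original), function(p) {
    lo <- min(survivors[[p]]) - step[[p]]
    hi <- max(survivors[[p]]) + step[[p]]
    c(max(lo, original[[p]][1]), min(hi, original[[p]][2]))
  })
  names(out) <- names(original)
  out
}

derive_subseed <- function(master, index) {
  (master + 1013904223 * index) %% 2147483647
}

params_from_row <- function(row) {
  progression_params(r_d = row$r_d, x_du_weeks = row$x_du_weeks,
                     r_u = row$r_u, x_ds_weeks = row$x_ds_weeks,
                     r_s = row$r_s, sigma_ds_weeks = row$sigma_ds_weeks,
                     m = row$m)
}

apply_params <- function(scenario, params) {
  scenario$progression <- params
  scenario
}

#' Iterative grid-search calibration
#'
#' Runs rounds of: build an evenly spaced grid over the current ranges,
#' simulate a cohort for every parameter combination, filter candidates
#' sequentially against the observed targets, and narrow the ranges around
#' the survivors. Rounds stop when the minimum goodness-of-fit across a
#' round's combinations fails to improve on the previous round's (that
#' previous round's result is retained), or when `max_rounds` is reached.
#' The final parameter set is the terminal survivor closest (summed
#' normalized distance, ties broken in parameter order) to the per-parameter
#' midpoints of the final ranges.
#'
#' Each parameter set is simulated with a sub-seed derived from the master
#' seed and the set's index within its round, so calibrations are exactly
#' reproducible.
#'
#' @param spec a [calibration_spec].
#' @param scenario_template a [cohort_scenario] whose progression parameters
#'   are replaced by each candidate set (its `n_patients` is overridden by
#'   the spec's).
#' @param seed integer master seed.
#' @param runner function `(scenario, seed) -> scenario_run`; replaceable
#'   for testing. Defaults to [run_scenario()].
#' @param verbose print per-round progress.
#' @return a `calibration_result`: `rounds` (per-round candidate tables with
#'   predictions, fit, and survival flags), `best_fit_per_round`,
#'   `final_params` ([progression_params]), `final_ranges`,
#'   `termination_reason` (`"no_improvement"` or `"budget"`).
#' @export
calibrate <- function(spec, scenario_template, seed = 1L,
                      runner = run_scenario, verbose = FALSE) {
  stopifnot(inherits(spec, "calibration_spec"),
            inherits(scenario_template, "cohort_scenario"))
  template <- scenario_template
  template$n_patients <- spec$n_patients
  ranges <- spec$ranges
  original <- spec$ranges
  rounds <- list()
  best_fits <- numeric(0)
  terminal <- NULL
  reason <- "budget"

  for (r in seq_len(spec$max_rounds)) {
    grid <- build_grid(ranges, spec$points_per_param)
    step <- attr(grid, "step")
    pred <- matrix(NA_real_, nrow(grid), length(target_names()),
                   dimnames = list(NULL, target_names()))
    for (i in seq_len(nrow(grid))) {
      sc <- apply_params(template, params_from_row(grid[i, ]))
      run <- runner(sc, derive_subseed(seed, i))
      tg <- summary_targets(run$summary)
      pred[i, ] <- tg[target_names()]
    }
    fits <- apply(pred, 1, function(p) goodness_of_fit(p, spec$targets))
    filt <- sequential_filter(pred, spec$targets, spec)
    round_tab <- cbind(grid, as.data.frame(pred), fit = fits,
                       survived = filt$keep)
    rounds[[r]] <- list(table = round_tab, ranges = ranges, step = step,
                        filter_steps = filt$steps, flagged = filt$flagged)
    best_fits[r] <- min(fits)
    if (verbose)
      message(sprintf("round %d: %d combinations, %d survivors, best fit %.2f",
                      r, nrow(grid), sum(filt$keep), best_fits[r]))
    if (r > 1 && best_fits[r] >= best_fits[r - 1]) {
      terminal <- r - 1
      reason <- "no_improvement"
      break
    }
    terminal <- r
    if (r == spec$max_rounds) { reason <- "budget"; break }
    ranges <- narrow_ranges(grid[filt$keep, , drop = FALSE], step, original)
  }

  term <- rounds[[terminal]]
  survivors <- term$table[term$table$survived, param_names(), drop = FALSE]
  final_ranges <- narrow_ranges(survivors, term$step, original)
  mids <- vapply(final_ranges, mean, numeric(1))
  widths <- vapply(final_ranges, diff, numeric(1))
  widths[widths == 0] <- 1
  dist <- as.matrix(sweep(abs(sweep(as.matrix(survivors), 2, mids)), 2,
                          widths, "/"))
  total <- rowSums(dist)
  best <- which(total == min(total))
  if (length(best) > 1) {
    # tie-break parameter by parameter, in canonical parameter order
    for (p in param_names()) {
      d <- dist[best, p]
      best <- best[d == min(d)]
      if (length(best) == 1) break
    }
  }
  final <- params_from_row(survivors[best[1], ])
  structure(list(rounds = rounds, best_fit_per_round = best_fits,
                 final_params = final, final_ranges = final_ranges,
                 termination_reason = reason, terminal_round = terminal),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Grid-search calibration: %d round(s), terminated (%s)\n",
              length(x$rounds), x$termination_reason))
  cat("  best fit per round:",
      paste(sprintf("%.2f", x$best_fit_per_round), collapse = ", "), "\n")
  print(x$final_params)
  invisible(x)
}

#' Write per-round survivor tables as CSV
#'
#' @param result a `calibration_result`.
#' @param dir output directory (created if needed); one
#'   `round_<k>.csv` per round plus `final_params.json`.
#' @export
export_calibration <- function(result, dir) {
  stopifnot(inherits(result, "calibration_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in seq_along(result$rounds))
    utils::write.csv(result$rounds[[r]]$table,
                     file.path(dir, sprintf("round_%d.csv", r)),
                     row.names = FALSE)
  jsonlite::write_json(
    list(final_params = unclass(result$final_params),
         final_ranges = result$final_ranges,
         best_fit_per_round = result$best_fit_per_round,
         termination_reason = result$termination_reason),
    file.path(dir, "final_params.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
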