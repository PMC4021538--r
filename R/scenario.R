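#' Site distribution table
#'
#' Convenience constructor for the categorical distribution over recurrence
#' sites used by a scenario. Rows are (local_status, met_status) outcomes with
#' probabilities summing to one.
#'
#' @param local_status,met_status character vectors (recycled to equal
#'   length) from the site enumerations.
#' @param prob numeric vector of probabilities.
#' @return a data.frame with columns `local_status`, `met_status`, `prob`.
#' @export
site_distribution <- function(local_status, met_status, prob) {
  df <- data.frame(local_status = local_status, met_status = met_status,
                   prob = prob, stringsAsFactors = FALSE)
  validate_site_distribution(df)
  df
}

validate_site_distribution <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("local_status", "met_status", "prob") %in% names(df)))
  if (!all(df$local_status %in% site_local_levels()))
    stop("invalid local_status in site distribution", call. = FALSE)
  if (!all(df$met_status %in% site_met_levels()))
    stop("invalid met_status in site distribution", call. = FALSE)
  if (any(df$local_status == "none" & df$met_status == "none"))
    stop("a recurrence site cannot be none/none", call. = FALSE)
  if (any(df$prob < 0))
    stop("site probabilities must be non-negative", call. = FALSE)
  if (abs(sum(df$prob) - 1) > 1e-6)
    stop("site distribution must sum to 1 (got ", sum(df$prob), ")",
         call. = FALSE)
  invisible(df)
}

default_life_expectancies <- function() {
  list(no_recurrence_years = 20.7, post_salvage_months = 21,
       post_unresectable_months = 8)
}

#' Cohort scenario
#'
#' The complete configuration for one simulated cohort: size, eventual
#' recurrence probability, site distribution, disease-progression parameters,
#' surveillance test panel and schedule, assigned life expectancies, and the
#' time horizon. Durations carry explicit unit suffixes (`_weeks`, `_months`,
#' `_years`, `_cycles`) and are converted to 3-month cycles internally.
#'
#' @param n_patients cohort size.
#' @param p_recur probability of eventual recurrence, in `[0, 1]`.
#' @param site_distribution a data.frame from [site_distribution()].
#' @param progression a [progression_params] object.
#' @param tests named list of [test_characteristics]; defaults to
#'   [default_test_panel()].
#' @param schedule a `surveillance_schedule` matrix from [build_schedule()].
#' @param life_expectancies list with `no_recurrence_years`,
#'   `post_salvage_months`, `post_unresectable_months`.
#' @param horizon_cycles number of 3-month cycles (default 20).
#' @param eligibility how resectability is assessed at diagnosis:
#'   `"cycle_start"` (default) compares the unresectability time U with the
#'   start of the cycle in which the diagnosis occurs, matching the discrete
#'   Markov submodel's cycle-level evaluation of disease state;
#'   `"exact"` compares U with the continuous diagnosis time.
#' @param p_lung_operable operability probability for lung metastases
#'   (default 0.5, half as likely as liver).
#' @param name optional scenario name.
#' @param targets optional named numeric vector/list of observed outcome
#'   targets on the 0-100 scale (`dfs5`, `os1`..`os5`, `salvage`).
#' @return object of class `cohort_scenario`.
#' @export
cohort_scenario <- function(n_patients, p_recur, site_distribution,
                            progression, tests = default_test_panel(),
                            schedule = build_schedule(),
                            life_expectancies = default_life_expectancies(),
                            horizon_cycles = 20L,
                            eligibility = c("cycle_start", "exact"),
                            p_lung_operable = 0.5, name = NULL,
                            targets = NULL) {
  eligibility <- match.arg(eligibility)
  stopifnot(n_patients >= 1, horizon_cycles >= 1)
  if (p_recur < 0 || p_recur > 1)
    stop("p_recur must lie in [0, 1]", call. = FALSE)
  validate_site_distribution(site_distribution)
  stopifnot(inherits(progression, "progression_params"))
  stopifnot(all(modality_levels() %in% names(tests)))
  if (nrow(schedule) != horizon_cycles)
    stop("schedule has ", nrow(schedule), " rows but horizon is ",
         horizon_cycles, " cycles", call. = FALSE)
  if (!identical(colnames(schedule), modality_levels()))
    schedule <- schedule_from_matrix(schedule, horizon_cycles)
  le <- utils::modifyList(default_life_expectancies(),
                          as.list(life_expectancies))
  structure(list(name = name, n_patients = as.integer(n_patients),
                 p_recur = p_recur, site_distribution = site_distribution,
                 progression = progression, tests = tests,
                 schedule = schedule, life_expectancies = le,
                 horizon_cycles = as.integer(horizon_cycles),
                 eligibility = eligibility,
                 p_lung_operable = p_lung_operable, targets = targets),
            class = "cohort_scenario")
}

#' @export
print.cohort_scenario <- function(x, ...) {
  cat("Cohort scenario", if (!is.null(x$name)) paste0("'", x$name, "'"), "\n")
  cat(sprintf("  %d patients, %d cycles (%.1f years), p_recur = %.3f\n",
              x$n_patients, x$horizon_cycles, x$horizon_cycles / 4,
              x$p_recur))
  cat(sprintf("  scheduled tests: %d visits across %d modalities\n",
              sum(x$schedule), sum(colSums(x$schedule) > 0)))
  invisible(x)
}

## ---- configuration I/O -----------------------------------------------------

scenario_to_list <- function(scenario) {
  sch <- scenario$schedule
  sched_cycles <- lapply(colnames(sch), function(m) which(sch[, m] == 1))
  names(sched_cycles) <- colnames(sch)
  sched_cycles <- sched_cycles[vapply(sched_cycles, length, 1L) > 0]
  list(
    name = scenario$name,
    n_patients = scenario$n_patients,
    p_recur = scenario$p_recur,
    horizon_cycles = scenario$horizon_cycles,
    eligibility = scenario$eligibility,
    p_lung_operable = scenario$p_lung_operable,
    site_distribution = lapply(seq_len(nrow(scenario$site_distribution)),
      function(i) as.list(scenario$site_distribution[i, ])),
    progression = unclass(scenario$progression),
    tests = lapply(scenario$tests, function(tc)
      list(sensitivity = tc$sensitivity, specificity = tc$specificity)),
    schedule_cycles = sched_cycles,
    life_expectancies = scenario$life_expectancies,
    targets = scenario$targets
  )
}

scenario_from_list <- function(x) {
  sd <- do.call(rbind, lapply(x$site_distribution, function(r)
    data.frame(local_status = r$local_status, met_status = r$met_status,
               prob = as.numeric(r$prob), stringsAsFactors = FALSE)))
  pp <- do.call(progression_params, lapply(x$progression, as.numeric))
  tests <- default_test_panel()
  for (m in names(x$tests)) {
    tests[[m]] <- test_characteristics(
      m, as.numeric(x$tests[[m]]$sensitivity),
      as.numeric(x$tests[[m]]$specificity),
      targets = x$tests[[m]]$targets)
  }
  horizon <- as.integer(x$horizon_cycles %||% 20L)
  if (!is.null(x$schedule_rules)) {
    sch <- build_schedule(x$schedule_rules, horizon)
  } else {
    mat <- matrix(0L, horizon, length(modality_levels()),
                  dimnames = list(NULL, modality_levels()))
    for (m in names(x$schedule_cycles)) mat[unlist(x$schedule_cycles[[m]]), m] <- 1L
    sch <- schedule_from_matrix(mat)
  }
  cohort_scenario(
    n_patients = as.integer(x$n_patients), p_recur = as.numeric(x$p_recur),
    site_distribution = sd, progression = pp, tests = tests, schedule = sch,
    life_expectancies = x$life_expectancies %||% default_life_expectancies(),
    horizon_cycles = horizon,
    eligibility = x$eligibility %||% "cycle_start",
    p_lung_operable = as.numeric(x$p_lung_operable %||% 0.5),
    name = x$name, targets = x$targets)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write scenario configuration files
#'
#' Scenarios serialize to YAML or JSON (chosen by file extension) mirroring
#' the [cohort_scenario] field names. Schedules are stored compactly as the
#' list of cycles at which each modality is tested (`schedule_cycles`); the
#' visit-rule shorthand accepted by [build_schedule()] may be supplied
#' instead under `schedule_rules`.
#'
#' @param scenario a [cohort_scenario].
#' @param path file path ending in `.yaml`, `.yml`, or `.json`.
#' @return `read_scenario` returns a [cohort_scenario].
#' @export
write_scenario <- function(scenario, path) {
  x <- scenario_to_list(scenario)
  x <- x[!vapply(x, is.null, TRUE)]
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else stop("unsupported scenario file extension: ", path, call. = FALSE)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("no such scenario file: ", path, call. = FALSE)
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else if (grepl("\\.json$", path)) jsonlite::read_json(path)
       else stop("unsupported scenario file extension: ", path, call. = FALSE)
  scenario_from_list(x)
}

## ---- parameter paths (used by the sensitivity module) ----------------------

scenario_get <- function(scenario, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- scenario
  for (k in keys) {
    if (is.null(node[[k]]))
      stop("parameter path not found in scenario: ", path, call. = FALSE)
    node <- node[[k]]
  }
  if (!is.numeric(node) || length(node) != 1L)
    stop("parameter path does not resolve to a scalar: ", path, call. = FALSE)
  node
}

scenario_set <- function(scenario, path, value) {
  scenario_get(scenario, path)  # validates the path
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  scenario[[keys]] <- value
  scenario
}
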