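modality_levels <- function() {
  c("cea", "chest_xray", "ct_hepatic", "ct_other_abdominal",
    "hepatic_ultrasound", "colonoscopy", "clinical_exam")
}

# Which recurrence-site components a modality can truly detect. Site-agnostic
# modalities (CEA, clinical interview/exam) see any recurrence; imaging is
# mapped to its anatomic target. A scheduled CT of abdomen/pelvis is modeled
# as its two performance components (hepatic + other abdominal) administered
# at the same visit.
default_modality_targets <- function() {
  list(
    cea = "any",
    chest_xray = "lung",
    ct_hepatic = "liver",
    ct_other_abdominal = c("locoregional", "multiple_other"),
    hepatic_ultrasound = "liver",
    colonoscopy = c("anastomotic_only", "intraluminal_metachronous"),
    clinical_exam = "any"
  )
}

#' Surveillance-test characteristics
#'
#' @param modality one of `cea`, `chest_xray`, `ct_hepatic`,
#'   `ct_other_abdominal`, `hepatic_ultrasound`, `colonoscopy`,
#'   `clinical_exam`.
#' @param sensitivity,specificity probabilities in `[0, 1]` for the test in
#'   isolation.
#' @param targets character vector of site components this modality can truly
#'   detect (`"any"`, or values from the local/metastatic site enumerations).
#'   Defaults to the modality's standard anatomic mapping.
#' @return an object of class `test_characteristics`.
#' @export
test_characteristics <- function(modality, sensitivity, specificity,
                                 targets = NULL) {
  modality <- match.arg(modality, modality_levels())
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  if (is.null(targets)) targets <- default_modality_targets()[[modality]]
  structure(list(modality = modality, sensitivity = sensitivity,
                 specificity = specificity, targets = targets),
            class = "test_characteristics")
}

#' Default surveillance test panel
#'
#' The seven-modality panel with published single-test performance: CEA
#' (0.64/0.90), chest X-ray (0.76/0.95), CT for hepatic metastases
#' (0.83/0.93), CT for other abdominal disease (0.46/0.98), hepatic
#' ultrasound (0.62/0.85), colonoscopy (0.95/1.00), and clinical
#' interview/examination (0.42/0.95).
#'
#' @return named list of [test_characteristics], one per modality.
#' @export
default_test_panel <- function() {
  perf <- list(cea = c(0.64, 0.90), chest_xray = c(0.76, 0.95),
               ct_hepatic = c(0.83, 0.93), ct_other_abdominal = c(0.46, 0.98),
               hepatic_ultrasound = c(0.62, 0.85), colonoscopy = c(0.95, 1.00),
               clinical_exam = c(0.42, 0.95))
  out <- lapply(names(perf), function(m)
    test_characteristics(m, perf[[m]][1], perf[[m]][2]))
  names(out) <- names(perf)
  out
}

site_matches_targets <- function(site, targets) {
  if ("any" %in% targets) return(TRUE)
  site$local_status %in% targets || site$met_status %in% targets
}

#' Build a surveillance schedule matrix
#'
#' Expands per-modality visit rules into the binary cycle-by-modality matrix
#' the simulator consumes. Each rule is a list of segments
#' `(interval_months, from_month, to_month)`: visits fall at months
#' `from_month, from_month + interval_months, ...` up to `to_month`, anchored
#' to months since surgery (no visit at time zero). All months must be
#' multiples of 3, the model's cycle length.
#'
#' @param rules named list (names = modalities); each element a list of
#'   segments, each segment a list or named numeric vector with entries
#'   `interval_months`, `from_month`, `to_month`. An empty or missing rule
#'   yields an all-zero column.
#' @param horizon_cycles number of 3-month cycles (default 20, i.e. 5 years).
#' @return an integer matrix `horizon_cycles x 7` with 0/1 entries and
#'   modality column names, of class `surveillance_schedule`.
#' @examples
#' # "Every 3 months for 2 years; every 6 months thereafter"
#' sch <- build_schedule(list(cea = list(
#'   list(interval_months = 3, from_month = 3, to_month = 24),
#'   list(interval_months = 6, from_month = 30, to_month = 60))))
#' which(sch[, "cea"] == 1)
#' @export
build_schedule <- function(rules = list(), horizon_cycles = 20L) {
  stopifnot(horizon_cycles >= 1)
  mods <- modality_levels()
  mat <- matrix(0L, nrow = horizon_cycles, ncol = length(mods),
                dimnames = list(NULL, mods))
  for (m in names(rules)) {
    if (!m %in% mods)
      stop("unknown modality in schedule rules: ", m, call. = FALSE)
    for (seg in rules[[m]]) {
      seg <- as.list(seg)
      iv <- seg$interval_months; fr <- seg$from_month; to <- seg$to_month
      if (is.null(iv) || is.null(fr) || is.null(to))
        stop("schedule segment needs interval_months, from_month, to_month",
             call. = FALSE)
      if (any(c(iv, fr, to) %% 3 != 0))
        stop("schedule months must be multiples of 3 (cycle granularity)",
             call. = FALSE)
      months <- seq(fr, to, by = iv)
      cycles <- months / 3
      cycles <- cycles[cycles >= 1 & cycles <= horizon_cycles]
      mat[cycles, m] <- 1L
    }
  }
  structure(mat, class = c("surveillance_schedule", "matrix", "array"))
}

schedule_from_matrix <- function(mat, horizon_cycles = nrow(mat)) {
  mods <- modality_levels()
  stopifnot(is.matrix(mat), all(mat %in% c(0, 1)))
  out <- matrix(0L, nrow = horizon_cycles, ncol = length(mods),
                dimnames = list(NULL, mods))
  cols <- intersect(colnames(mat), mods)
  if (length(cols) == 0 && ncol(mat) == length(mods)) {
    out[, ] <- as.integer(mat)
  } else {
    out[, cols] <- as.integer(mat[, cols])
  }
  structure(out, class = c("surveillance_schedule", "matrix", "array"))
}

#' Read or write a schedule matrix as CSV
#'
#' CSV layout: header row of modality names, one row per cycle, 0/1 entries.
#'
#' @param schedule a `surveillance_schedule` matrix.
#' @param path file path.
#' @return `read_schedule_csv` returns a `surveillance_schedule`.
#' @export
write_schedule_csv <- function(schedule, path) {
  utils::write.csv(as.data.frame(unclass(schedule)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  schedule_from_matrix(as.matrix(df))
}

#' Administer a single surveillance test
#'
#' A test is truly positive with probability `sensitivity` when the patient
#' harbors a recurrence that is detectable (`t >= D`) and whose site the
#' modality targets; otherwise it is positive only through the
#' false-positive channel, with probability `1 - specificity`. Uses R's
#' global random stream.
#'
#' @param test a [test_characteristics].
#' @param profile a `recurrence_profile` (see [assign_recurrence]).
#' @param t current time, in cycles.
#' @return logical: test positive?
#' @export
administer_test <- function(test, profile, t) {
  stopifnot(inherits(test, "test_characteristics"),
            inherits(profile, "recurrence_profile"))
  detectable <- isTRUE(profile$will_recur) && t >= profile$D &&
    site_matches_targets(profile$site, test$targets)
  p <- if (detectable) test$sensitivity else 1 - test$specificity
  stats::runif(1) < p
}

#' Resolve one surveillance cycle
#'
#' Administers every test scheduled for the cycle as independent draws. If
#' any result is positive a single full workup follows within the cycle;
#' workup sensitivity and specificity are treated as 100% combined, so a
#' diagnosis is recorded if and only if the patient has any detectable
#' recurrence (`t >= D`) — regardless of which modality fired. A false
#' positive in a patient whose recurrence is detectable at another site thus
#' still leads to a true diagnosis, while a false positive in a recurrence-
#' free patient is ruled out with no lasting effect.
#'
#' @param profile a `recurrence_profile`.
#' @param cycle cycle index (tests occur at the boundary, time `cycle`).
#' @param schedule a `surveillance_schedule` matrix.
#' @param tests named list of [test_characteristics].
#' @return a list with `tests_administered`, `any_positive`, and `diagnosis`
#'   (`NULL`, or list with `time`, `mode = "surveillance"`).
#' @export
run_surveillance_cycle <- function(profile, cycle, schedule, tests) {
  stopifnot(cycle >= 1, cycle <= nrow(schedule))
  scheduled <- colnames(schedule)[schedule[cycle, ] == 1]
  any_pos <- FALSE
  for (m in scheduled) {
    if (administer_test(tests[[m]], profile, t = cycle)) any_pos <- TRUE
  }
  diagnosis <- NULL
  if (any_pos && isTRUE(profile$will_recur) && cycle >= profile$D)
    diagnosis <- list(time = cycle, mode = "surveillance")
  list(tests_administered = scheduled, any_positive = any_pos,
       diagnosis = diagnosis)
}
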