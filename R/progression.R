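#' Disease-progression parameters
#'
#' Bundles the seven parameters governing the latent natural history of a
#' colorectal-cancer recurrence and group-specific background mortality:
#' an exponential hazard for the onset of test-detectability, two windows
#' (detectability to unresectability, detectability to symptom onset) that
#' widen or narrow linearly with the detectability time, a normally
#' distributed symptom-onset error, and the five-year cumulative probability
#' of death from non-CRC causes.
#'
#' @param r_d hazard rate, per 3-month cycle, at which a recurrence
#'   transitions from undetectable to detectable. Must be positive.
#' @param x_du_weeks baseline (D = 0) width of the resectability window, in
#'   weeks. Must be positive.
#' @param r_u per-cycle rate of change of the resectability window with
#'   increasing detectability time. Non-negative.
#' @param x_ds_weeks baseline (D = 0) width of the presymptomatic window, in
#'   weeks. Must be positive.
#' @param r_s per-cycle rate of change of the presymptomatic window; may be
#'   negative.
#' @param sigma_ds_weeks standard deviation, in weeks, of the normally
#'   distributed symptom-onset error term. Non-negative.
#' @param m five-year cumulative probability of death from non-CRC causes,
#'   in `[0, 1)`.
#' @return an object of class `progression_params` (a named list).
#' @examples
#' progression_params(r_d = 0.092, x_du_weeks = 6, r_u = 0.11,
#'                    x_ds_weeks = 17, r_s = 0.07, sigma_ds_weeks = 11,
#'                    m = 0.016)
#' @export
progression_params <- function(r_d, x_du_weeks, r_u, x_ds_weeks, r_s,
                               sigma_ds_weeks, m) {
  stopifnot(is.numeric(r_d), length(r_d) == 1L)
  if (r_d <= 0) stop("r_d must be positive", call. = FALSE)
  if (x_du_weeks <= 0) stop("x_du_weeks must be positive", call. = FALSE)
  if (x_ds_weeks <= 0) stop("x_ds_weeks must be positive", call. = FALSE)
  if (sigma_ds_weeks < 0) stop("sigma_ds_weeks must be non-negative", call. = FALSE)
  if (r_u < 0) stop("r_u must be non-negative", call. = FALSE)
  if (m < 0 || m >= 1) stop("m must lie in [0, 1)", call. = FALSE)
  structure(list(r_d = r_d, x_du_weeks = x_du_weeks, r_u = r_u,
                 x_ds_weeks = x_ds_weeks, r_s = r_s,
                 sigma_ds_weeks = sigma_ds_weeks, m = m),
            class = "progression_params")
}

#' @export
print.progression_params <- function(x, ...) {
  cat("Disease progression parameters (3-month cycle units for rates):\n")
  cat(sprintf("  r_d      %.4g /cycle   (mean time to detectability %.2f cycles)\n",
              x$r_d, 1 / x$r_d))
  cat(sprintf("  x_du     %.4g weeks    r_u  %.4g /cycle\n", x$x_du_weeks, x$r_u))
  cat(sprintf("  x_ds     %.4g weeks    r_s  %.4g /cycle\n", x$x_ds_weeks, x$r_s))
  cat(sprintf("  sigma_ds %.4g weeks\n", x$sigma_ds_weeks))
  cat(sprintf("  m        %.4g (five-year background mortality)\n", x$m))
  invisible(x)
}

site_local_levels <- function() {
  c("none", "locoregional", "anastomotic_only", "intraluminal_metachronous")
}

site_met_levels <- function() c("none", "liver", "lung", "multiple_other")

#' Anatomic site of a recurrence
#'
#' A recurrence is described by its local tumor status (none, locoregional,
#' anastomotic only, or intraluminal/metachronous) and its metastasis status
#' (none, liver, lung, or multiple/other organs). A recurring patient cannot
#' have both components equal to `"none"`.
#'
#' @param local_status,met_status character scalars from the enumerations
#'   above.
#' @return an object of class `recurrence_site`.
#' @export
recurrence_site <- function(local_status = "none", met_status = "none") {
  local_status <- match.arg(local_status, site_local_levels())
  met_status <- match.arg(met_status, site_met_levels())
  if (local_status == "none" && met_status == "none")
    stop("a recurrence must have a local or a metastatic component", call. = FALSE)
  structure(list(local_status = local_status, met_status = met_status),
            class = "recurrence_site")
}

#' Sample the earliest-detectability time
#'
#' Detectability onset follows a continuous exponential distribution with
#' hazard rate `r_d` per 3-month cycle, producing declining recurrence
#' incidence with time since initial treatment.
#'
#' @param r_d per-cycle hazard rate (> 0).
#' @param n number of draws.
#' @return detectability times in cycles, all positive.
#' @export
sample_detectability_time <- function(r_d, n = 1L) {
  if (!is.numeric(r_d) || length(r_d) != 1L || r_d <= 0)
    stop("r_d must be a positive scalar", call. = FALSE)
  stats::rexp(n, rate = r_d)
}

#' Unresectability time
#'
#' The time U at which a recurrence is no longer amenable to curative salvage
#' surgery: `U = D + x_du * (1 + r_u * D)` with every term in cycles. A
#' positive baseline window and non-negative rate guarantee `U > D`.
#'
#' @param D detectability time(s), in cycles.
#' @param params a [progression_params] object.
#' @return unresectability time(s), in cycles.
#' @export
unresectability_time <- function(D, params) {
  stopifnot(inherits(params, "progression_params"), all(D >= 0))
  D + weeks_to_cycles(params$x_du_weeks) * (1 + params$r_u * D)
}

#' Symptom-onset time
#'
#' The time S at which a recurrence produces symptoms that bring the patient
#' to care between scheduled visits:
#' `S = D + x_ds * (1 + r_s * D) + eps`, `eps ~ Normal(0, sigma_ds)`, all in
#' cycles. Because the error term can push S below D (a symptomatic but
#' not-yet-detectable recurrence, which the model does not admit), S is
#' clipped at D; the realized error draw is returned unmodified.
#'
#' @inheritParams unresectability_time
#' @param eps optional fixed error draw(s) in cycles; when `NULL` the error is
#'   drawn from `Normal(0, sigma_ds)`.
#' @return a list with elements `S` (cycles, `>= D`), `eps` (the realized
#'   draw, cycles) and `clipped` (logical).
#' @export
symptom_onset_time <- function(D, params, eps = NULL) {
  stopifnot(inherits(params, "progression_params"), all(D >= 0))
  sigma <- weeks_to_cycles(params$sigma_ds_weeks)
  if (is.null(eps)) eps <- stats::rnorm(length(D), 0, sigma)
  S <- D + weeks_to_cycles(params$x_ds_weeks) * (1 + params$r_s * D) + eps
  clipped <- S < D
  S[clipped] <- D[clipped]
  list(S = S, eps = eps, clipped = clipped)
}

#' Eligibility for curative salvage surgery
#'
#' A diagnosed recurrence can be salvaged curatively only while still
#' resectable (`t_dx < U`) and only at an operable site: local-only disease
#' and liver metastases are operable; lung metastases are operable with
#' probability `p_lung` (half as likely as liver); metastases to multiple or
#' other sites are inoperable.
#'
#' @param site a [recurrence_site].
#' @param t_dx time at which resectability is assessed, in cycles.
#' @param U unresectability time, in cycles.
#' @param p_lung operability probability for lung metastases.
#' @return logical scalar.
#' @export
salvage_eligible <- function(site, t_dx, U, p_lung = 0.5) {
  stopifnot(inherits(site, "recurrence_site"), t_dx >= 0)
  if (t_dx >= U) return(FALSE)
  switch(site$met_status,
         none = TRUE,
         liver = TRUE,
         lung = stats::runif(1) < p_lung,
         multiple_other = FALSE)
}

#' Assign a latent recurrence profile
#'
#' Draws one patient's complete latent timeline under a scenario: whether the
#' patient will ever recur (probability `p_recur`), the anatomic site, and
#' the continuous-time milestones D (earliest detectability), U
#' (unresectability) and S (symptom onset). Uses R's global random number
#' stream; seed with [set.seed()] for reproducibility.
#'
#' @param scenario a [cohort_scenario].
#' @return an object of class `recurrence_profile` with fields `will_recur`,
#'   and, for recurrers, `site`, `D`, `U`, `S`, `eps`, `s_clipped`.
#' @export
assign_recurrence <- function(scenario) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  will_recur <- stats::runif(1) < scenario$p_recur
  if (!will_recur)
    return(structure(list(will_recur = FALSE), class = "recurrence_profile"))
  sd <- scenario$site_distribution
  k <- findInterval(stats::runif(1), cumsum(sd$prob), left.open = TRUE) + 1L
  k <- min(k, nrow(sd))
  site <- recurrence_site(sd$local_status[k], sd$met_status[k])
  pp <- scenario$progression
  D <- sample_detectability_time(pp$r_d)
  U <- unresectability_time(D, pp)
  so <- symptom_onset_time(D, pp)
  structure(list(will_recur = TRUE, site = site, D = D, U = U, S = so$S,
                 eps = so$eps, s_clipped = so$clipped),
            class = "recurrence_profile")
}
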