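# Independent oracles used across the suite. These deliberately avoid the
# package's simulation path: the diagnosis-time oracle enumerates events by
# brute force from a latent profile, and the salvage-fraction oracle
# integrates the latent-time model numerically.

# Brute-force diagnosis time for perfect tests (sens = spec = 1) and no
# background mortality: the earlier of the symptom-onset time (if within the
# horizon) and the first scheduled cycle boundary >= D at which some
# administered modality targets the patient's site.
oracle_dx_time <- function(will_recur, D, S, local_status, met_status,
                           schedule, tests, horizon = nrow(schedule)) {
  if (!will_recur) return(NA_real_)
  site <- list(local_status = local_status, met_status = met_status)
  match_mod <- function(m) {
    tg <- tests[[m]]$targets
    "any" %in% tg || site$local_status %in% tg || site$met_status %in% tg
  }
  t_surv <- Inf
  for (c in seq_len(horizon)) {
    if (c < D) next
    mods <- colnames(schedule)[schedule[c, ] == 1]
    if (length(mods) && any(vapply(mods, match_mod, TRUE))) {
      t_surv <- c
      break
    }
  }
  t_sym <- if (S <= horizon) S else Inf
  ans <- min(t_surv, t_sym)
  if (is.infinite(ans)) NA_real_ else ans
}

# Numerical integration of the salvage probability in the absence of any
# surveillance, exact resectability comparison: a patient is salvaged iff
# they recur at an operable site, develop symptoms while still resectable
# (S < U), and do so within the horizon. S = D + max(g(D) + eps, 0) with
# eps ~ Normal(0, sigma), so P(S < U and S <= H | D) =
# Phi((min(U - D, H - D) - g(D)) / sigma).
oracle_salvage_integral <- function(scenario) {
  pp <- scenario$progression
  H <- scenario$horizon_cycles
  xdu <- pp$x_du_weeks / 13; xds <- pp$x_ds_weeks / 13
  sigma <- pp$sigma_ds_weeks / 13
  p_cond <- function(d) {
    w <- xdu * (1 + pp$r_u * d)
    g <- xds * (1 + pp$r_s * d)
    lim <- pmin(w, H - d)
    if (sigma > 0) pnorm((lim - g) / sigma) else as.numeric(g < lim)
  }
  dens <- function(d) dexp(d, pp$r_d) * p_cond(d)
  p_dx_resectable <- integrate(dens, 0, H, rel.tol = 1e-9)$value
  op <- ifelse(scenario$site_distribution$met_status == "none", 1,
        ifelse(scenario$site_distribution$met_status == "liver", 1,
        ifelse(scenario$site_distribution$met_status == "lung",
               scenario$p_lung_operable, 0)))
  scenario$p_recur * sum(scenario$site_distribution$prob * op) *
    p_dx_resectable
}

# Compact scenario for unit tests
make_test_scenario <- function(n = 200L, p_recur = 0.4,
                               schedule = build_schedule(),
                               eligibility = "cycle_start", m = 0.016,
                               sigma_ds_weeks = 11) {
  cohort_scenario(
    n_patients = n, p_recur = p_recur,
    site_distribution = site_distribution(
      local_status = c("locoregional", "none", "none"),
      met_status = c("none", "liver", "multiple_other"),
      prob = c(0.5, 0.2, 0.3)),
    progression = progression_params(0.092, 6, 0.11, 17, 0.07,
                                     sigma_ds_weeks, m),
    schedule = schedule, eligibility = eligibility)
}

perfect_panel <- function() {
  tests <- default_test_panel()
  for (m in names(tests)) {
    tests[[m]]$sensitivity <- 1
    tests[[m]]$specificity <- 1
  }
  tests
}
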