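test_that("five-year cumulative mortality converts to the per-cycle probability", {
  expect_equal(per_cycle_mortality(0), 0)
  expect_equal(per_cycle_mortality(0.016), 8.061440e-4, tolerance = 1e-6)
  # validation-group value: 1.6% + 14.0 percentage points
  expect_equal(per_cycle_mortality(0.156), 8.444284e-3, tolerance = 1e-6)
  expect_error(per_cycle_mortality(1), "\\[0, 1\\)")
})

test_that("a symptomatic diagnosis before U leads to salvage and a deterministic cancer death", {
  sc <- make_test_scenario(m = 0)
  prof <- structure(list(
    will_recur = TRUE, site = recurrence_site(met_status = "liver"),
    D = 2.5, U = 40, S = 3.1, eps = 0), class = "recurrence_profile")
  set.seed(1)
  out <- simulate_patient(prof, sc)
  expect_equal(out$dx_time, 3.1)
  expect_equal(out$dx_mode, "symptomatic")
  expect_true(out$salvage)
  # post-salvage life expectancy 21 months = 7 cycles
  expect_equal(out$death_time, 10.1)
  expect_equal(out$death_cause, "cancer")
  expect_equal(out$state_path[4], "recurrence_curative")
  expect_equal(out$state_path[11], "dead_cancer")
})

test_that("diagnosis after U is palliative with an 8-month life expectancy", {
  sc <- make_test_scenario(m = 0)
  prof <- structure(list(
    will_recur = TRUE, site = recurrence_site(met_status = "liver"),
    D = 2.5, U = 3.0, S = 6.5, eps = 0), class = "recurrence_profile")
  set.seed(1)
  out <- simulate_patient(prof, sc)
  expect_equal(out$dx_mode, "symptomatic")
  expect_false(out$salvage)  # cycle of diagnosis starts at 6 > U
  expect_equal(out$death_time, 6.5 + 8 / 3)
})

test_that("a non-recurring patient with no background death stays disease-free", {
  sc <- make_test_scenario(m = 0)
  prof <- structure(list(will_recur = FALSE), class = "recurrence_profile")
  out <- simulate_patient(prof, sc)
  expect_true(all(out$state_path == "no_known_recurrence"))
  expect_true(is.na(out$dx_time))
  expect_true(is.na(out$death_time))
})

test_that("cohort summaries implement the trial outcome definitions", {
  # hand-counted cohort of 10: 2 diagnosed (1 salvaged) and alive at 5y,
  # 1 dead of other causes at cycle 10, 7 event-free
  outcomes <- data.frame(
    dx_time = c(4, 8, rep(NA, 8)),
    dx_mode = c("surveillance", "symptomatic", rep(NA, 8)),
    salvage = c(TRUE, rep(FALSE, 9)),
    death_time = c(NA, NA, 10, rep(NA, 7)),
    death_cause = c(NA, NA, "other", rep(NA, 7)))
  s <- summarize_cohort(outcomes, horizon = 20)
  expect_equal(s$dfs5, 0.7)
  expect_equal(unname(s$os), c(1, 1, 0.9, 0.9, 0.9))
  expect_equal(s$salvage_prop, 0.1)
  expect_equal(unname(s$dx_mode_split), c(0.5, 0.5))
  # a cancer death after diagnosis contributes one DFS event (at diagnosis)
  # and one OS death
  outcomes2 <- data.frame(dx_time = 10, dx_mode = "surveillance",
                          salvage = FALSE, death_time = 19,
                          death_cause = "cancer")
  s2 <- summarize_cohort(outcomes2, horizon = 20)
  expect_equal(s2$dfs5, 0)
  expect_equal(unname(s2$os), c(1, 1, 1, 1, 0))
  expect_error(summarize_cohort(outcomes[0, ]), "empty")
})

test_that("scenario runs are deterministic and stable under cohort growth", {
  sc <- make_test_scenario(n = 500)
  a <- run_scenario(sc, 42)
  b <- run_scenario(sc, 42)
  expect_identical(a$outcomes, b$outcomes)
  expect_identical(summary_targets(a$summary), summary_targets(b$summary))
  # a different seed gives different draws
  expect_false(identical(a$outcomes, run_scenario(sc, 43)$outcomes))
  # growing the cohort leaves earlier patients' histories untouched
  sc2 <- sc; sc2$n_patients <- 800L
  big <- run_scenario(sc2, 42)
  expect_identical(big$outcomes[1:500, ], a$outcomes)
})

test_that("degenerate scenarios produce the expected certainties", {
  sc <- make_test_scenario(n = 300, p_recur = 0, m = 0)
  s <- run_scenario(sc, 7)$summary
  expect_equal(s$dfs5, 1)
  expect_equal(unname(s$os), rep(1, 5))
  expect_equal(s$salvage_prop, 0)
})

test_that("survival invariants hold across random scenarios", {
  for (seed in 1:6) {
    sc <- generate_synthetic_scenario(seed, n_patients = 400L)
    s <- run_scenario(sc, seed + 100)$summary
    expect_lte(s$dfs5, s$os[[5]] + 1e-12)
    expect_true(all(diff(s$os) <= 1e-12))
    run <- run_scenario(sc, seed + 100)$outcomes
    expect_lte(s$salvage_prop, mean(run$will_recur))
    rec <- run[run$will_recur, ]
    expect_true(all(rec$D < rec$U))
    expect_true(all(rec$S >= rec$D))
    # diagnoses only ever occur at or after detectability
    dx <- rec[!is.na(rec$dx_time), ]
    expect_true(all(dx$dx_time >= dx$D | dx$dx_mode == "symptomatic"))
    expect_true(all(dx$dx_time[dx$dx_mode == "surveillance"] >=
                      dx$D[dx$dx_mode == "surveillance"]))
    # no false diagnoses: non-recurrers are never diagnosed
    expect_true(all(is.na(run$dx_time[!run$will_recur])))
  }
})

test_that("salvage declines as test sensitivities are scaled toward zero", {
  sch <- build_schedule(list(
    cea = list(list(interval_months = 3, from_month = 3, to_month = 60))))
  props <- vapply(c(1, 0.5, 0.1, 0), function(f) {
    sc <- make_test_scenario(n = 3000, schedule = sch, m = 0)
    for (m in names(sc$tests)) {
      sc$tests[[m]]$sensitivity <- sc$tests[[m]]$sensitivity * f
      sc$tests[[m]]$specificity <- 1  # isolate the true-positive channel
    }
    run_scenario(sc, 11)$summary$salvage_prop  # paired seed
  }, numeric(1))
  expect_true(all(diff(props) <= 0))
})

test_that("the engine agrees with the per-patient reference implementation on diagnosis logic", {
  # with perfect tests the engine's realized outcomes must match what
  # simulate_patient produces from the same latent profile (the only
  # randomness left is background mortality, switched off here)
  sch <- build_schedule(list(
    cea = list(list(interval_months = 6, from_month = 6, to_month = 60)),
    colonoscopy = list(list(interval_months = 12, from_month = 12,
                            to_month = 60))))
  sc <- make_test_scenario(n = 300, schedule = sch, m = 0)
  sc$tests <- perfect_panel()
  run <- run_scenario(sc, 5)$outcomes
  for (i in which(run$will_recur)) {
    prof <- structure(list(
      will_recur = TRUE,
      site = recurrence_site(run$local_status[i], run$met_status[i]),
      D = run$D[i], U = run$U[i], S = run$S[i], eps = run$eps[i]),
      class = "recurrence_profile")
    ref <- simulate_patient(prof, sc)
    expect_identical(is.na(ref$dx_time), is.na(run$dx_time[i]))
    if (!is.na(ref$dx_time)) {
      expect_equal(ref$dx_time, run$dx_time[i])
      expect_equal(ref$dx_mode, run$dx_mode[i])
      expect_equal(ref$salvage, run$salvage[i])
    }
  }
})
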