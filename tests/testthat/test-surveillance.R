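intensive_rule <- list(
  list(interval_months = 3, from_month = 3, to_month = 24),
  list(interval_months = 6, from_month = 30, to_month = 60))

test_that("visit rules expand to the expected cycle patterns", {
  sch <- build_schedule(list(cea = intensive_rule))
  # every 3 months for 2 years, then every 6 months: cycles 1-8, 10, 12, ..., 20
  expect_identical(which(sch[, "cea"] == 1),
                   as.integer(c(1:8, seq(10, 20, 2))))
  expect_identical(sum(sch[, "cea"]), 14L)
  # yearly rule lands on cycles 4, 8, 12, 16, 20
  yearly <- build_schedule(list(chest_xray = list(
    list(interval_months = 12, from_month = 12, to_month = 60))))
  expect_identical(which(yearly[, "chest_xray"] == 1),
                   as.integer(seq(4, 20, 4)))
  # minimal-arm rule: every 6 months for 1 year, then yearly
  minimal <- build_schedule(list(cea = list(
    list(interval_months = 6, from_month = 6, to_month = 12),
    list(interval_months = 12, from_month = 24, to_month = 60))))
  expect_identical(which(minimal[, "cea"] == 1),
                   as.integer(c(2, 4, 8, 12, 16, 20)))
  # unscheduled modalities give all-zero columns; empty rules an all-zero matrix
  expect_true(all(build_schedule()[, ] == 0))
  expect_true(all(sch[, "colonoscopy"] == 0))
  # sub-cycle intervals are rejected
  expect_error(build_schedule(list(cea = list(
    list(interval_months = 2, from_month = 2, to_month = 12)))),
    "multiples of 3")
})

test_that("schedule matrices round-trip through CSV", {
  sch <- build_schedule(list(cea = intensive_rule, colonoscopy = list(
    list(interval_months = 12, from_month = 12, to_month = 60))))
  path <- withr::local_tempfile(fileext = ".csv")
  write_schedule_csv(sch, path)
  back <- read_schedule_csv(path)
  expect_identical(unclass(back), unclass(sch))
})

test_that("test positivity follows sensitivity for detectable disease and the false-positive channel otherwise", {
  prof_liver <- structure(list(
    will_recur = TRUE, site = recurrence_site(met_status = "liver"),
    D = 2, U = 10, S = 30, eps = 0), class = "recurrence_profile")
  cea <- test_characteristics("cea", 0.64, 0.90)
  set.seed(8)
  n <- 2e4
  pos <- vapply(seq_len(n), function(i) administer_test(cea, prof_liver, t = 5),
                TRUE)
  expect_lt(abs(mean(pos) - 0.64), 3 * sqrt(0.64 * 0.36 / n))
  # perfectly specific test never fires without detectable targeted disease
  colono <- test_characteristics("colonoscopy", 0.95, 1.00)
  none <- structure(list(will_recur = FALSE), class = "recurrence_profile")
  expect_false(any(vapply(1:2000, function(i)
    administer_test(colono, none, t = 5), TRUE)))
  # site mismatch: chest x-ray on a liver-only recurrence uses only the
  # false-positive channel (rate 1 - 0.95)
  cxr <- test_characteristics("chest_xray", 0.76, 0.95)
  pos_cxr <- vapply(seq_len(n), function(i)
    administer_test(cxr, prof_liver, t = 5), TRUE)
  expect_lt(abs(mean(pos_cxr) - 0.05), 3 * sqrt(0.05 * 0.95 / n))
  # not yet detectable (t < D): false-positive channel only
  pos_early <- vapply(seq_len(n), function(i)
    administer_test(cea, prof_liver, t = 1), TRUE)
  expect_lt(abs(mean(pos_early) - 0.10), 3 * sqrt(0.10 * 0.90 / n))
})

test_that("a positive test triggers a workup that diagnoses any detectable recurrence", {
  sch <- build_schedule(list(chest_xray = list(
    list(interval_months = 3, from_month = 3, to_month = 60))))
  tests <- default_test_panel()
  # liver-only recurrence, detectable; chest x-ray forced to always "fire"
  # via specificity 0: the workup, not the x-ray, makes the diagnosis
  tests$chest_xray <- test_characteristics("chest_xray", 0.76, 0)
  prof <- structure(list(
    will_recur = TRUE, site = recurrence_site(met_status = "liver"),
    D = 2, U = 40, S = 40, eps = 0), class = "recurrence_profile")
  set.seed(1)
  res <- run_surveillance_cycle(prof, cycle = 3, schedule = sch, tests = tests)
  expect_true(res$any_positive)
  expect_equal(res$diagnosis, list(time = 3, mode = "surveillance"))
  # same forced positive on a recurrence-free patient: workup rules it out
  none <- structure(list(will_recur = FALSE), class = "recurrence_profile")
  res2 <- run_surveillance_cycle(none, cycle = 3, schedule = sch, tests = tests)
  expect_true(res2$any_positive)
  expect_null(res2$diagnosis)
  # a cycle with no scheduled tests cannot diagnose
  res3 <- run_surveillance_cycle(prof, cycle = 3,
                                 schedule = build_schedule(), tests = tests)
  expect_identical(res3$tests_administered, character(0))
  expect_null(res3$diagnosis)
})

test_that("with perfect specificity and no detectable disease there are no positives", {
  sc <- make_test_scenario(n = 400, p_recur = 0,
                           schedule = build_schedule(list(
                             cea = intensive_rule)))
  for (m in names(sc$tests)) sc$tests[[m]]$specificity <- 1
  run <- run_scenario(sc, 123)
  expect_true(all(is.na(run$outcomes$dx_time)))
  expect_equal(run$summary$salvage_prop, 0)
})

test_that("a denser schedule never delays surveillance diagnosis under common random numbers", {
  base_rules <- list(cea = list(
    list(interval_months = 6, from_month = 6, to_month = 60)))
  dense_rules <- list(
    cea = list(list(interval_months = 3, from_month = 3, to_month = 60)),
    clinical_exam = list(list(interval_months = 3, from_month = 3,
                              to_month = 60)))
  sparse <- make_test_scenario(n = 2000, schedule = build_schedule(base_rules),
                               m = 0)
  dense <- make_test_scenario(n = 2000, schedule = build_schedule(dense_rules),
                              m = 0)
  a <- run_scenario(dense, 99)$outcomes
  b <- run_scenario(sparse, 99)$outcomes
  surv <- function(o) ifelse(!is.na(o$dx_time) & o$dx_mode == "surveillance",
                             o$dx_time, Inf)
  # the dense schedule includes every sparse visit (cycles 2,4,...) plus more,
  # and shared (cycle, modality) draws couple the runs patient by patient
  sym <- function(o) ifelse(!is.na(o$dx_time) & o$dx_mode == "symptomatic",
                            o$dx_time, Inf)
  dx_a <- pmin(surv(a), sym(a)); dx_b <- pmin(surv(b), sym(b))
  expect_true(all(dx_a <= dx_b))
})
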