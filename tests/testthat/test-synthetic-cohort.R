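test_that("generated cohorts respect invariants and are seed-deterministic", {
  cfg <- simulation_config(n_subjects = 100, seed = 1)
  ch <- generate_cohort(cfg)
  expect_equal(nrow(ch$subjects), 100)
  for (d in epic26_domains()) {
    v <- ch$visits[[d]]
    expect_true(all(v[!is.na(v)] >= 0 & v[!is.na(v)] <= 100))
  }
  expect_true(all(ch$subjects$gleason %in% c("<=6", "3+4", "4+3", ">=8"),
                  na.rm = TRUE))
  gh <- ch$subjects$general_health
  expect_true(all(gh[!is.na(gh)] %in% c("Poor", "Fair", "Good", "Very good", "Excellent")))
  expect_true(all(ch$subjects$age_dx > 0 & ch$subjects$age_dx < 120, na.rm = TRUE))
  expect_true(all(ch$subjects$psa >= 0, na.rm = TRUE))

  ch2 <- generate_cohort(cfg)
  expect_identical(ch, ch2)
})

test_that("zero residual noise makes observed scores equal the linear predictor", {
  cfg <- recovery_config(n = 150, seed = 3, residual_sd = 0)
  ch <- generate_cohort(cfg)
  expect_equal(unname(ch$log$clipped_fraction["sexual"]), 0)
  asm <- build_analysis_table(ch$subjects, ch$visits, domains = "sexual")
  tab <- asm$tables$sexual[["12m"]]
  expect_gt(nrow(tab), 100)
  expect_equal(tab$observed, predict_score(ch$truth$sexual, tab), tolerance = 1e-12)
})

test_that("invalid configurations name the offending field", {
  expect_error(simulation_config(n_subjects = 0), "n_subjects")
  expect_error(simulation_config(residual_sd = c(sexual = -1)), "residual_sd")
  expect_error(simulation_config(visit_months = c(0, 12)), "visit_months")
  bad_gl <- c("<=6" = 0.5, "3+4" = 0.6, "4+3" = 0, ">=8" = 0)
  expect_error(simulation_config(covariates = utils::modifyList(
    formals(simulation_config)$covariates |> eval(), list(gleason = bad_gl))),
    "gleason")
})

test_that("MAR masking hits its marginal target and only its scoped fields", {
  cfg <- recovery_config(n = 5000, seed = 9)
  ch <- generate_cohort(cfg)

  ## probability-zero rule leaves everything untouched
  null_out <- apply_missingness(ch$subjects, ch$visits,
                                list(list(field = "psa", intercept = -Inf)),
                                seed = 5)
  expect_identical(null_out$subjects, ch$subjects)
  expect_identical(null_out$visits, ch$visits)

  ## 20% marginal target on PSA, MAR on age: realized within 2 points
  out <- apply_missingness(ch$subjects, ch$visits,
                           list(list(field = "psa", target = 0.2,
                                     slopes = c(age_dx = 0.5))),
                           seed = 5)
  expect_lt(abs(mean(is.na(out$subjects$psa)) - 0.2), 0.02)
  expect_identical(out$visits, ch$visits)

  ## outcome rule scoped to the 12-month visit touches nothing else
  out2 <- apply_missingness(ch$subjects, ch$visits,
                            list(list(field = "sexual", target = 0.15,
                                      scope = 12)),
                            seed = 5)
  expect_identical(out2$subjects, ch$subjects)
  at12 <- out2$visits$scheduled_month == 12
  expect_gt(sum(is.na(out2$visits$sexual[at12])), 0)
  expect_identical(out2$visits$sexual[!at12], ch$visits$sexual[!at12])

  ## determinism
  out3 <- apply_missingness(ch$subjects, ch$visits,
                            list(list(field = "sexual", target = 0.15,
                                      scope = 12)),
                            seed = 5)
  expect_identical(out2, out3)
})

test_that("conditioning on an incompletely observed covariate is rejected as MNAR", {
  ch <- generate_cohort(recovery_config(n = 50, seed = 2))
  ch$subjects$age_dx[3] <- NA
  expect_error(
    apply_missingness(ch$subjects, ch$visits,
                      list(list(field = "psa", target = 0.2,
                                slopes = c(age_dx = 0.5))), seed = 1),
    "MAR")
})

test_that("cohort tables round-trip through CSV with empty-field missing values", {
  cfg <- simulation_config(n_subjects = 60, seed = 4)
  ch <- generate_cohort(cfg)
  dir <- tempfile()
  write_cohort(ch, dir)
  back <- read_cohort(dir)
  expect_equal(back$subjects, ch$subjects)
  expect_equal(back$visits, ch$visits, tolerance = 1e-12)
  expect_identical(back$truth, ch$truth)
})

test_that("default study-scale cohorts resemble the registry summary targets", {
  ch <- generate_cohort(simulation_config(n_subjects = 2000, seed = 11))
  s <- ch$subjects
  expect_lt(abs(mean(s$age_dx, na.rm = TRUE) - 65.4), 1)
  expect_lt(abs(mean(is.na(s$psa)) - 0.20), 0.04)
  expect_lt(abs(mean(is.na(s$general_health)) - 0.55), 0.04)
  base <- ch$visits[ch$visits$scheduled_month == 0, ]
  ## ceiling pile-up: pre-surgery medians of 100 for the three ceiling domains
  for (d in c("urinary_incontinence", "bowel", "hormonal")) {
    expect_equal(stats::median(base[[d]], na.rm = TRUE), 100)
  }
  expect_lt(abs(mean(base$sexual, na.rm = TRUE) - 61.2), 3)
})
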