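## Shared fixture builders, all generated in code.

## Clipping-free parameter-recovery configuration: the generating linear
## predictor stays well inside [0, 100], baselines carry no ceiling mass,
## every questionnaire is returned and nothing is missing, so validating the
## generating model itself is a clean null case.
recovery_model <- function() {
  model_spec("sexual", 47, list(
    months = 0.1, age_dx = -0.3, baseline = 0.5, psa = -0.3,
    gleason = list(ref = "<=6", levels = c("3+4" = -2, "4+3" = -4, ">=8" = -6)),
    general_health = list(ref = "Good",
                          levels = c(Poor = -6, Fair = -3, "Very good" = 2,
                                     Excellent = 4))))
}

recovery_config <- function(n = 2000, seed = 42, residual_sd = 8,
                            missingness = NULL) {
  simulation_config(
    n_subjects = n, seed = seed, domains = "sexual",
    true_models = list(sexual = recovery_model()),
    residual_sd = c(sexual = residual_sd),
    baseline_distribution = list(sexual = list(ceiling_weight = 0, mean = 60, sd = 12)),
    missingness = missingness,
    visit_months = 12, visit_jitter_sd = 1,
    response_prob = 1, baseline_response_prob = 1)
}

## 50-subject cohort with engineered edge cases for assembly/exclusion flow.
## Boundary subjects: S01 age 81 (out), S02 age 80 (in), S03 PSA 50 (out),
## S04 PSA 49.9 (in), S05-S07 adjunct therapy, S08 non-localized, S09 two
## reasons, S10 missing PSA (in). Visit edge cases: S11 months 7.9/16.1
## (outside windows), S12/S13 window edges 8/16, S14 tie 20/28 around 24,
## S15 tie 10/14 around 12, S16 no baseline, S17 missing sexual baseline,
## S18 missing sexual outcome, S19 no visits.
make_edge_cohort <- function() {
  n <- 50
  subjects <- data.frame(
    subject_id = sprintf("S%02d", seq_len(n)),
    age_dx = 65, psa = 6, gleason = "3+4", general_health = "Good",
    race = "White", treatment = "RP", stage_localized = TRUE,
    adt = FALSE, brachytherapy = FALSE, cryoablation = FALSE,
    stringsAsFactors = FALSE)
  subjects$age_dx[1] <- 81
  subjects$age_dx[2] <- 80
  subjects$psa[3] <- 50
  subjects$psa[4] <- 49.9
  subjects$adt[5] <- TRUE
  subjects$brachytherapy[6] <- TRUE
  subjects$cryoablation[7] <- TRUE
  subjects$stage_localized[8] <- FALSE
  subjects$age_dx[9] <- 81; subjects$psa[9] <- 50
  subjects$psa[10] <- NA

  doms <- epic26_domains()
  mk_visit <- function(sid, month, sched, score = 70) {
    v <- data.frame(subject_id = sid, scheduled_month = sched,
                    months_post_surgery = month, stringsAsFactors = FALSE)
    for (d in doms) v[[d]] <- score
    v
  }
  rows <- list()
  for (i in seq_len(n)) {
    sid <- subjects$subject_id[i]
    if (sid == "S19") next                       # no visits at all
    if (sid != "S16") rows[[length(rows) + 1L]] <- mk_visit(sid, 0, 0, 80)
    if (sid == "S11") {
      rows[[length(rows) + 1L]] <- mk_visit(sid, 7.9, 12)
      rows[[length(rows) + 1L]] <- mk_visit(sid, 16.1, 12)
    } else if (sid == "S12") {
      rows[[length(rows) + 1L]] <- mk_visit(sid, 8, 12, 61)
    } else if (sid == "S13") {
      rows[[length(rows) + 1L]] <- mk_visit(sid, 16, 12, 62)
    } else if (sid == "S14") {
      rows[[length(rows) + 1L]] <- mk_visit(sid, 20, 24, 63)
      rows[[length(rows) + 1L]] <- mk_visit(sid, 28, 24, 64)
    } else if (sid == "S15") {
      rows[[length(rows) + 1L]] <- mk_visit(sid, 10, 12, 65)
      rows[[length(rows) + 1L]] <- mk_visit(sid, 14, 12, 66)
    } else {
      v12 <- mk_visit(sid, 12.4, 12)
      v24 <- mk_visit(sid, 24.2, 24)
      if (sid == "S18") v12$sexual <- NA
      rows[[length(rows) + 1L]] <- v12
      rows[[length(rows) + 1L]] <- v24
    }
  }
  visits <- do.call(rbind, rows)
  base_na <- visits$subject_id == "S17" & visits$months_post_surgery == 0
  visits$sexual[base_na] <- NA
  rownames(visits) <- NULL
  list(subjects = subjects, visits = visits)
}

## Small random paired-scores fixture.
make_paired <- function(n = 40, seed = 1) {
  set.seed(seed)
  yhat <- runif(n, 20, 90)
  y <- pmin(100, pmax(0, yhat + rnorm(n, 0, 12)))
  paired_scores(y, yhat)
}
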