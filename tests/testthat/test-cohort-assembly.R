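test_that("exclusion criteria apply at their printed boundaries", {
  co <- make_edge_cohort()
  ex <- apply_exclusions(co$subjects)
  kept <- ex$subjects$subject_id
  reason_of <- function(sid) ex$log$reason[ex$log$subject_id == sid]

  expect_false("S01" %in% kept); expect_equal(reason_of("S01"), "age")    # age 81
  expect_true("S02" %in% kept)                                           # age 80
  expect_false("S03" %in% kept); expect_equal(reason_of("S03"), "psa")   # PSA 50
  expect_true("S04" %in% kept)                                           # PSA 49.9
  expect_equal(reason_of("S05"), "adt")
  expect_equal(reason_of("S06"), "brachytherapy")
  expect_equal(reason_of("S07"), "cryoablation")
  expect_equal(reason_of("S08"), "non_localized")
  expect_setequal(reason_of("S09"), c("age", "psa"))                     # both logged
  expect_true("S10" %in% kept)                                           # missing PSA passes
  expect_equal(nrow(ex$subjects), 50 - 7)   # S09 is one subject, two reasons
})

test_that("the closest in-window visit is selected with earlier-visit tie-break", {
  v <- data.frame(subject_id = "X", scheduled_month = 12,
                  months_post_surgery = c(10, 15), sexual = c(1, 2))
  expect_equal(select_visit(v, 12, c(8, 16))$months_post_surgery, 10)
  v2 <- transform(v, months_post_surgery = c(7, 17))
  expect_null(select_visit(v2, 12, c(8, 16)))
  v3 <- transform(v, months_post_surgery = c(10, 14))   # tie |10-12| = |14-12|
  expect_equal(select_visit(v3, 12, c(8, 16))$months_post_surgery, 10)
})

test_that("assembly drops subjects per domain only and logs one reason each", {
  co <- make_edge_cohort()
  ex <- apply_exclusions(co$subjects)
  asm <- build_analysis_table(ex$subjects, co$visits)
  tab12 <- asm$tables$sexual[["12m"]]

  ## window-edge months 8 and 16 are included (inclusive bounds)
  expect_true(all(c("S12", "S13") %in% tab12$subject_id))
  ## tie at 24m target resolves to the earlier (20-month) visit
  tab24 <- asm$tables$sexual[["24m"]]
  expect_equal(tab24$months_post_surgery[tab24$subject_id == "S14"], 20)
  expect_equal(tab24$observed[tab24$subject_id == "S14"], 63)
  ## tie at 12m resolves to month 10
  expect_equal(tab12$observed[tab12$subject_id == "S15"], 65)
  ## out-of-window and visitless subjects are logged
  dl12 <- asm$drop_log[asm$drop_log$domain == "sexual" & asm$drop_log$timepoint == "12m", ]
  expect_equal(dl12$reason[dl12$subject_id == "S11"], "no_window_visit")
  expect_equal(dl12$reason[dl12$subject_id == "S19"], "no_window_visit")
  expect_equal(dl12$reason[dl12$subject_id == "S16"], "missing_baseline")
  ## per-domain rule: S17 misses only the sexual baseline, S18 only the sexual outcome
  expect_equal(dl12$reason[dl12$subject_id == "S17"], "missing_baseline")
  expect_equal(dl12$reason[dl12$subject_id == "S18"], "missing_outcome")
  for (d in setdiff(epic26_domains(), "sexual")) {
    expect_true(all(c("S17", "S18") %in% asm$tables[[d]][["12m"]]$subject_id))
  }
})

test_that("flow conservation holds for every domain and timepoint", {
  co <- make_edge_cohort()
  ex <- apply_exclusions(co$subjects)
  asm <- build_analysis_table(ex$subjects, co$visits)
  flow <- assembly_flow(asm)
  expect_equal(nrow(flow), length(epic26_domains()) * 2)
  expect_equal(flow$included + flow$no_window_visit + flow$missing_baseline +
                 flow$missing_outcome,
               rep(flow$n_input[1], nrow(flow)))
  ## ... and every retained subject appears exactly once per cell
  for (d in epic26_domains()) {
    for (tp in c("12m", "24m")) {
      dl <- asm$drop_log[asm$drop_log$domain == d & asm$drop_log$timepoint == tp, ]
      ids <- c(asm$tables[[d]][[tp]]$subject_id, dl$subject_id)
      expect_setequal(ids, ex$subjects$subject_id)
      expect_equal(anyDuplicated(ids), 0L)
    }
  }
})

test_that("assembly is order-independent over input rows", {
  co <- make_edge_cohort()
  ex <- apply_exclusions(co$subjects)
  asm1 <- build_analysis_table(ex$subjects, co$visits)
  set.seed(1)
  shuf_s <- ex$subjects[sample(nrow(ex$subjects)), ]
  shuf_v <- co$visits[sample(nrow(co$visits)), ]
  asm2 <- build_analysis_table(shuf_s, shuf_v)
  for (d in epic26_domains()) {
    for (tp in c("12m", "24m")) {
      t1 <- asm1$tables[[d]][[tp]]
      t2 <- asm2$tables[[d]][[tp]]
      t1 <- t1[order(t1$subject_id), ]; rownames(t1) <- NULL
      t2 <- t2[order(t2$subject_id), ]; rownames(t2) <- NULL
      expect_equal(t1, t2)
    }
  }
})

test_that("duplicate (subject, month) visit rows are rejected with ids", {
  co <- make_edge_cohort()
  dup <- co$visits[co$visits$subject_id == "S20" & co$visits$scheduled_month == 12, ]
  visits <- rbind(co$visits, dup)
  ex <- apply_exclusions(co$subjects)
  expect_error(build_analysis_table(ex$subjects, visits), "S20")
})

test_that("assembly windows must bracket their targets", {
  expect_error(assembly_config(target_months = 12, windows = list("12" = c(13, 16))),
               "window")
})
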