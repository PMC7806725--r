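cfg <- toy_htn_config()

adult <- function(pid = "P1") ev_row(pid, 0, "measurement", "age", 50)

test_that("HTN pair rule: worked examples", {
  # 150/95 day 0 and 145/92 day 30 -> one DP at day 30
  ev <- rbind(adult(), bp_rows("P1", 0, 150, 95), bp_rows("P1", 30, 145, 92))
  dps <- extract_decision_points(build_timelines(ev), cfg,
                                 drop_missing_outcome = FALSE)
  expect_equal(nrow(dps), 1)
  expect_equal(dps$index_date, as.Date("2015-01-31"))

  # second reading controlled -> zero DPs
  ev <- rbind(adult(), bp_rows("P1", 0, 150, 95), bp_rows("P1", 30, 135, 85))
  expect_equal(nrow(extract_decision_points(build_timelines(ev), cfg,
                                 drop_missing_outcome = FALSE)), 0)

  # pair separated by 400 days -> zero DPs
  ev <- rbind(adult(), bp_rows("P1", 0, 150, 95), bp_rows("P1", 400, 150, 95))
  expect_equal(nrow(extract_decision_points(build_timelines(ev), cfg,
                                 drop_missing_outcome = FALSE)), 0)

  # age 17 at qualifying date -> zero DPs
  ev <- rbind(ev_row("P1", 0, "measurement", "age", 17),
              bp_rows("P1", 0, 150, 95), bp_rows("P1", 30, 145, 92))
  expect_equal(nrow(extract_decision_points(build_timelines(ev), cfg,
                                 drop_missing_outcome = FALSE)), 0)

  # DBP alone can trigger: 135/95 pairs are uncontrolled
  ev <- rbind(adult(), bp_rows("P1", 0, 135, 95), bp_rows("P1", 30, 135, 92))
  expect_equal(nrow(extract_decision_points(build_timelines(ev), cfg,
                                 drop_missing_outcome = FALSE)), 1)
})

test_that("pregnancy and refill exclusions apply", {
  base <- rbind(adult(), bp_rows("P1", 0, 150, 95),
                bp_rows("P1", 30, 145, 92))
  ev <- rbind(base, ev_row("P1", 10, "diagnosis", "pregnancy_dx"))
  dps <- suppressMessages(extract_decision_points(build_timelines(ev), cfg,
                                 drop_missing_outcome = FALSE))
  expect_equal(nrow(dps), 0)
  # pregnancy marker long before the window does not exclude
  ev <- rbind(base, ev_row("P1", -400, "diagnosis", "pregnancy_dx"))
  expect_equal(nrow(extract_decision_points(build_timelines(ev), cfg,
                                 drop_missing_outcome = FALSE)), 1)
  # a refill-only encounter date is not a DP
  ev <- rbind(adult(),
              bp_rows("P1", 0, 150, 95),
              ev_row("P1", 30, "measurement", "sbp", 145),
              ev_row("P1", 30, "measurement", "dbp", 92),
              ev_row("P1", 30, "encounter", "refill"))
  expect_equal(nrow(extract_decision_points(build_timelines(ev), cfg,
                                 drop_missing_outcome = FALSE)), 0)
})

test_that("diagnosis_then_lab rule follows most-recent-lab-in-window logic", {
  t2dm <- read_disease_config(system.file("extdata/config/t2dm.yaml",
                                          package = "pcto"))
  mk <- function(...) build_timelines(rbind(adult(), ...))
  # wide-period copy of the shipped config
  t2dm$study_period <- as.Date(c("2014-01-01", "2020-12-31"))
  # dx day 0; encounter day 100 with hba1c 8.0 at day 60 -> DP
  ev <- mk(ev_row("P1", 0, "diagnosis", "t2dm_dx"),
           ev_row("P1", 60, "measurement", "hba1c", 8.0),
           ev_row("P1", 100, "encounter", "office_visit"))
  dps <- extract_decision_points(ev, t2dm, drop_missing_outcome = FALSE)
  expect_equal(format(dps$index_date), "2015-04-11")
  # most recent lab normal (6.5 after the 8.0) -> no DP
  ev <- mk(ev_row("P1", 0, "diagnosis", "t2dm_dx"),
           ev_row("P1", 60, "measurement", "hba1c", 8.0),
           ev_row("P1", 90, "measurement", "hba1c", 6.5),
           ev_row("P1", 100, "encounter", "office_visit"))
  expect_equal(nrow(extract_decision_points(ev, t2dm,
                                            drop_missing_outcome = FALSE)),
               0)
  # abnormal lab outside the 365-day lookback -> no DP
  ev <- mk(ev_row("P1", 0, "diagnosis", "t2dm_dx"),
           ev_row("P1", 60, "measurement", "hba1c", 8.0),
           ev_row("P1", 500, "encounter", "office_visit"))
  expect_equal(nrow(extract_decision_points(ev, t2dm,
                                            drop_missing_outcome = FALSE)),
               0)
  # encounters before/on the diagnosis date never qualify
  ev <- mk(ev_row("P1", 50, "diagnosis", "t2dm_dx"),
           ev_row("P1", 40, "measurement", "hba1c", 8.0),
           ev_row("P1", 45, "encounter", "office_visit"))
  expect_equal(nrow(extract_decision_points(ev, t2dm,
                                            drop_missing_outcome = FALSE)),
               0)
})

test_that("extraction matches the brute-force enumeration on random timelines", {
  set.seed(31)
  t2dm <- read_disease_config(system.file("extdata/config/t2dm.yaml",
                                          package = "pcto"))
  t2dm$study_period <- as.Date(c("2014-01-01", "2020-12-31"))
  hl <- read_disease_config(system.file("extdata/config/hl.yaml",
                                        package = "pcto"))
  hl$study_period <- as.Date(c("2014-01-01", "2020-12-31"))
  configs <- list(htn = cfg, t2dm = t2dm, hl = hl)
  for (rule in names(configs)) {
    ev <- rbindlist(lapply(sprintf("%s%02d", rule, 1:12),
                           random_timeline_events, rule = rule))
    tl <- build_timelines(ev)
    dps <- extract_decision_points(tl, configs[[rule]],
                                   drop_missing_outcome = FALSE)
    for (pid in tl$patients) {
      expect_equal(dps[patient_id == pid]$index_date,
                   bf_dp_dates(ev, pid, configs[[rule]]),
                   info = paste(rule, pid))
    }
  }
})

test_that("raising the uncontrolled threshold never increases the DP count", {
  set.seed(17)
  ev <- rbindlist(lapply(sprintf("m%02d", 1:10), random_timeline_events,
                         rule = "htn"))
  tl <- build_timelines(ev)
  counts <- sapply(c(140, 150, 160, 180), function(thr) {
    c2 <- toy_htn_config()
    c2$analytes[[1]]$threshold <- thr
    nrow(extract_decision_points(tl, c2, drop_missing_outcome = FALSE))
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("treatment decisions compare active sets across the buffer", {
  base <- rbind(adult(), bp_rows("P1", 0, 150, 95),
                bp_rows("P1", 30, 145, 92))
  dp <- as.Date("2015-01-31")
  # no medication events -> no_change
  dec <- detect_treatment_decision(build_timelines(base), "P1", dp, cfg)
  expect_equal(dec$label, "no_change")
  expect_equal(dec$n_meds_after, 0)
  # start 5 days after DP (buffer 14) -> ACEI_Lisinopril+
  ev <- rbind(base, ev_row("P1", 35, "medication", "lisinopril",
                           action = "start"))
  dec <- detect_treatment_decision(build_timelines(ev), "P1", dp, cfg)
  expect_equal(dec$label, "ACEI_Lisinopril+")
  expect_equal(dec$n_meds_after, 1)
  # start outside the buffer is invisible
  ev <- rbind(base, ev_row("P1", 50, "medication", "lisinopril",
                           action = "start"))
  expect_equal(detect_treatment_decision(build_timelines(ev), "P1", dp,
                                         cfg)$label, "no_change")
  # within-class switch -> sorted join
  ev <- rbind(base,
              ev_row("P1", -100, "medication", "glyburide",
                     action = "start"),
              ev_row("P1", 32, "medication", "glyburide", action = "stop"),
              ev_row("P1", 33, "medication", "glipizide",
                     action = "start"))
  dec <- detect_treatment_decision(build_timelines(ev), "P1", dp, cfg)
  expect_equal(dec$label,
               "Sulfonylurea_Glipizide+|Sulfonylurea_Glyburide-")
  expect_equal(dec$n_meds_after, 1)
  # ingredients outside the treatment universe are ignored
  ev <- rbind(base, ev_row("P1", 35, "medication", "st_johns_wort",
                           action = "start"))
  expect_equal(detect_treatment_decision(build_timelines(ev), "P1", dp,
                                         cfg)$label, "no_change")
})

test_that("outcome windows depend on the decision label", {
  dp <- as.Date("2015-01-31")
  base <- rbind(adult(), bp_rows("P1", 0, 150, 95),
                bp_rows("P1", 30, 145, 92))
  # no change, controlled BP at day 60 after DP -> controlled
  ev <- rbind(base, bp_rows("P1", 90, 130, 80))
  expect_equal(determine_outcome(build_timelines(ev), "P1", dp,
                                 "no_change", cfg), "controlled")
  # treatment changed: day-7 reading ignored (window starts at 14)
  ev <- rbind(base, bp_rows("P1", 37, 150, 85), bp_rows("P1", 60, 135, 80))
  expect_equal(determine_outcome(build_timelines(ev), "P1", dp,
                                 "ACEI_Lisinopril+", cfg), "controlled")
  # same readings under no_change: day-7 reading counts and is uncontrolled
  expect_equal(determine_outcome(build_timelines(ev), "P1", dp,
                                 "no_change", cfg), "not_controlled")
  # no follow-up measurement in window -> missing
  expect_equal(determine_outcome(build_timelines(base), "P1", dp,
                                 "no_change", cfg), "missing")
})

test_that("one DP per patient-date; decision labels partition the DPs", {
  ws <- small_world(n_patients = 40, seed = 13)
  dps <- extract_decision_points(ws$tl, ws$dcfg)
  expect_equal(anyDuplicated(dps[, .(patient_id, index_date)]), 0)
  expect_true(all(nchar(dps$decision_label) > 0))
  expect_true(all(dps$outcome %in% c("controlled", "not_controlled")))
})

test_that("split_train_score is disjoint, exhaustive and seed-deterministic", {
  dps <- data.table(dp_id = sprintf("d%03d", 1:100))
  sp <- split_train_score(dps, 30, seed = 5)
  expect_equal(nrow(sp$train), 30)
  expect_equal(nrow(sp$score), 70)
  expect_length(intersect(sp$train$dp_id, sp$score$dp_id), 0)
  expect_setequal(c(sp$train$dp_id, sp$score$dp_id), dps$dp_id)
  sp2 <- split_train_score(dps, 30, seed = 5)
  expect_identical(sp, sp2)
  sp0 <- split_train_score(dps, 0, seed = 5)
  expect_equal(nrow(sp0$train), 0)
  expect_equal(nrow(sp0$score), 100)
})
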