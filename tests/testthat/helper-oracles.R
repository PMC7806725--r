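# Independent oracles and fixture builders shared across test files.
# Oracles deliberately use brute force / base R paths that do not share code
# with the implementation they check.

suppressMessages(library(data.table))

# --- fixture builders --------------------------------------------------------

# quick event-row builder; day offsets from 2015-01-01
ev_row <- function(pid, day, kind, code, value = NA_real_,
                   action = NA_character_) {
  data.table(patient_id = pid, event_date = as.Date("2015-01-01") + day,
             event_kind = kind, code = code, value = value,
             unit = NA_character_, action = action)
}

bp_rows <- function(pid, day, sbp, dbp) {
  rbind(ev_row(pid, day, "measurement", "sbp", sbp),
        ev_row(pid, day, "measurement", "dbp", dbp),
        ev_row(pid, day, "encounter", "office_visit"))
}

# minimal HTN-style disease config over a toy universe
toy_universe <- data.frame(
  code = c("lisinopril", "hydrochlorothiazide", "glyburide", "glipizide"),
  ingredient = c("Lisinopril", "Hydrochlorothiazide", "Glyburide",
                 "Glipizide"),
  class = c("ACEI", "Thiazide", "Sulfonylurea", "Sulfonylurea"))

toy_htn_config <- function(...) {
  disease_config(
    disease = "HTN",
    study_period = as.Date(c("2014-01-01", "2020-12-31")),
    dp_rule = "consecutive_uncontrolled_pair",
    analytes = list(list(code = "sbp", op = ">=", threshold = 140),
                    list(code = "dbp", op = ">=", threshold = 90)),
    treatment_universe = toy_universe, ...)
}

# standard small synthetic world used by several pipeline tests
small_world <- function(n_patients = 120, seed = 42, ...) {
  cfg <- sim_config(n_patients = n_patients, seed = seed, ...)
  sim <- simulate_population(cfg)
  tl <- build_timelines(sim$events)
  dcfg <- htn_config_for_sim(cfg)
  list(cfg = cfg, sim = sim, tl = tl, dcfg = dcfg)
}

# random event timelines exercising all extraction rules (ages, pregnancy,
# refills, diagnoses, labs, BP pairs); used by the brute-force DP check
random_timeline_events <- function(pid, rule = "htn") {
  n_vis <- sample(3:12, 1)
  days <- sort(sample(0:1200, n_vis))
  rows <- list(ev_row(pid, 0, "measurement", "age",
                      sample(c(15, 25, 45, 70), 1)))
  if (runif(1) < 0.3)
    rows <- c(rows, list(ev_row(pid, sample(0:1200, 1), "diagnosis",
                                "pregnancy_dx")))
  if (rule != "htn" && runif(1) < 0.8)
    rows <- c(rows, list(ev_row(pid, sample(0:300, 1), "diagnosis",
                                if (rule == "t2dm") "t2dm_dx" else "hl_dx")))
  for (d in days) {
    refill <- runif(1) < 0.2
    rows <- c(rows, list(ev_row(pid, d, "encounter",
                                if (refill) "refill" else "office_visit")))
    if (rule == "htn") {
      rows <- c(rows, list(
        ev_row(pid, d, "measurement", "sbp", sample(c(120, 138, 145, 170), 1)),
        ev_row(pid, d, "measurement", "dbp", sample(c(70, 88, 92, 105), 1))))
    } else if (runif(1) < 0.7) {
      code <- if (rule == "t2dm") "hba1c" else "ldl"
      val <- if (rule == "t2dm") sample(c(6.0, 6.9, 7.0, 8.5), 1)
             else sample(c(100, 130, 131, 180), 1)
      # labs sometimes on non-encounter days
      lab_day <- max(0, d - sample(0:100, 1))
      rows <- c(rows, list(ev_row(pid, lab_day, "measurement", code, val)))
    }
  }
  rbindlist(rows)
}

# --- brute-force decision-point oracle --------------------------------------

# Re-derives DP index dates for one patient from raw events by direct
# enumeration of the rules; no shared code with extract_decision_points().
bf_dp_dates <- function(events, pid, config) {
  ev <- events[patient_id == pid]
  in_period <- function(d) d >= config$study_period[1] &
    d <= config$study_period[2]
  enc <- ev[event_kind == "encounter"]
  usable_date <- function(d) {
    e <- enc[event_date == d]
    nrow(e) == 0 || any(!(e$code %in% config$refill_codes))
  }
  age_ok <- function(d) {
    a <- ev[event_kind == "measurement" & code == config$age_code &
              event_date <= d]
    nrow(a) > 0 &&
      a$value[order(a$event_date)][nrow(a)] >= config$min_age
  }
  preg_ok <- function(d) {
    p <- ev[event_kind == "diagnosis" & code %in% config$pregnancy_codes]
    !any(p$event_date >= d - config$pregnancy_exclusion_days &
           p$event_date <= d)
  }
  cand <- as.Date(character())
  if (config$dp_rule == "consecutive_uncontrolled_pair") {
    codes <- sapply(config$analytes, `[[`, "code")
    m <- ev[event_kind == "measurement" & code %in% codes,
            .(value = mean(value)), by = .(event_date, code)]
    dates <- sort(unique(m$event_date))
    dates <- dates[vapply(dates, function(d)
      all(codes %in% m$code[m$event_date == d]), logical(1))]
    unc <- vapply(dates, function(d) {
      any(sapply(config$analytes, function(a) {
        v <- m$value[m$event_date == d & m$code == a$code]
        if (a$op == ">=") v >= a$threshold else v > a$threshold
      }))
    }, logical(1))
    if (length(dates) >= 2)
      for (k in 2:length(dates)) {
        gap <- as.integer(dates[k] - dates[k - 1])
        if (unc[k] && unc[k - 1] && gap >= 1 &&
            gap <= config$max_separation_days &&
            usable_date(dates[k]))
          cand <- c(cand, dates[k])
      }
  } else {
    dx <- ev[event_kind == "diagnosis" & code %in% config$diagnosis_codes]
    if (nrow(dx)) {
      idx <- min(dx$event_date)
      labs <- ev[event_kind == "measurement" & code == config$lab$code,
                 .(value = mean(value)), by = event_date]
      for (d in sort(unique(enc$event_date[!(enc$code %in%
                                               config$refill_codes)]))) {
        d <- as.Date(d, origin = "1970-01-01")
        if (d <= idx) next
        inw <- labs[event_date >= d - config$lookback_days &
                      event_date <= d]
        if (!nrow(inw)) next
        v <- inw$value[which.max(inw$event_date)]
        hit <- if (config$lab$op == ">=") v >= config$lab$threshold
               else v > config$lab$threshold
        if (hit) cand <- c(cand, d)
      }
    }
  }
  cand <- unique(cand[in_period(cand)])
  sort(cand[vapply(cand, age_ok, logical(1)) &
              vapply(cand, preg_ok, logical(1))])
}

# --- misc oracles ------------------------------------------------------------

# chi-squared 2x2 via stats::chisq.test (independent of chisq2x2)
bf_chisq <- function(a, b, c, d, correct = FALSE) {
  suppressWarnings(stats::chisq.test(matrix(c(a, b, c, d), 2,
                                            byrow = TRUE),
                                     correct = correct))
}

# element-wise quadratic form oracle for the learned distance
bf_quadform_distance <- function(W, a, b) {
  M <- W %*% t(W)
  d <- a - b
  acc <- 0
  for (i in seq_along(d)) for (j in seq_along(d))
    acc <- acc + unname(d[i] * M[i, j] * d[j])
  sqrt(acc)
}

random_orthonormal <- function(p, d) {
  qr.Q(qr(matrix(rnorm(p * p), p, p)))[, seq_len(d), drop = FALSE]
}
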