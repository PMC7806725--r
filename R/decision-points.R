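#' Extract clinical decision points from patient timelines
#'
#' A decision point (DP) is an encounter date at which the disease is
#' measurably uncontrolled, so a treatment change is warranted.  For each DP
#' the observed treatment decision (medication starts/stops within a buffer,
#' restricted to the configured treatment universe), the follow-up outcome
#' (controlled / not_controlled / missing) and the post-decision medication
#' count are recorded.  One patient may contribute many DPs; at most one DP
#' per patient per date.
#'
#' Exclusions: age below `config$min_age` at the DP (or unknown age),
#' pregnancy marker within `pregnancy_exclusion_days` before the DP, refill
#' encounters, index dates outside the study period.
#'
#' @param timelines A [build_timelines()] result.
#' @param config A [disease_config()].
#' @param drop_missing_outcome Drop DPs with no qualifying follow-up
#'   measurement (default `TRUE`; they are counted in the report either
#'   way).
#' @return `data.table` with columns `dp_id`, `patient_id`, `index_date`,
#'   `decision_label`, `outcome`, `n_meds_after`; attribute `"report"`
#'   holds extraction counts.
#' @export
extract_decision_points <- function(timelines, config,
                                    drop_missing_outcome = TRUE) {
  stopifnot(inherits(timelines, "pcto_timelines"),
            inherits(config, "pcto_disease_config"))
  report <- c(candidates = 0L, excluded_age = 0L, excluded_pregnancy = 0L,
              missing_outcome = 0L)
  rows <- list()
  for (pid in timelines$patients) {
    pd <- patient_data(timelines, pid, config)
    cand <- switch(config$dp_rule,
                   consecutive_uncontrolled_pair = dp_dates_pair(pd, config),
                   diagnosis_then_lab = dp_dates_lab(pd, config))
    cand <- cand[cand >= config$study_period[1] &
                   cand <= config$study_period[2]]
    cand <- unique(cand)
    report["candidates"] <- report["candidates"] + length(cand)
    if (!length(cand)) next
    ok_age <- vapply(cand, function(d) {
      a <- age_at(pd, d, config$age_code)
      !is.na(a) && a >= config$min_age
    }, logical(1))
    report["excluded_age"] <- report["excluded_age"] + sum(!ok_age)
    cand <- cand[ok_age]
    if (length(cand) && length(config$pregnancy_codes)) {
      ok_preg <- vapply(cand, function(d)
        !any(pd$preg_dates >= d - config$pregnancy_exclusion_days &
               pd$preg_dates <= d), logical(1))
      report["excluded_pregnancy"] <-
        report["excluded_pregnancy"] + sum(!ok_preg)
      cand <- cand[ok_preg]
    }
    for (d in cand) {
      d <- as.Date(d, origin = "1970-01-01")
      dec <- decision_at(pd, d, config)
      out <- outcome_at(pd, d, dec$label, config)
      rows[[length(rows) + 1]] <- list(
        patient_id = pid, index_date = d, decision_label = dec$label,
        outcome = out, n_meds_after = dec$n_meds_after)
    }
  }
  dps <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(patient_id = character(),
                           index_date = as.Date(character()),
                           decision_label = character(),
                           outcome = character(), n_meds_after = integer())
  report["missing_outcome"] <- sum(dps$outcome == "missing")
  if (drop_missing_outcome) dps <- dps[outcome != "missing"]
  dps[, dp_id := paste0(patient_id, "@", format(index_date))]
  data.table::setcolorder(dps, c("dp_id", "patient_id", "index_date",
                                 "decision_label", "outcome",
                                 "n_meds_after"))
  data.table::setattr(dps, "report", report)
  dps[]
}

# Per-patient working set: plain vectors for speed inside extraction loops.
patient_data <- function(timelines, pid, config) {
  ev <- timelines$events[.(pid)]
  iv <- timelines$intervals[patient_id == pid]
  meas <- ev[event_kind == "measurement"]
  enc <- ev[event_kind == "encounter"]
  dx <- ev[event_kind == "diagnosis"]
  pd <- list(
    pid = pid,
    meas = meas,
    enc_dates = unique(enc$event_date),
    enc_ok_dates = unique(enc$event_date[!(enc$code %in%
                                             config$refill_codes)]),
    dx = dx,
    preg_dates = dx$event_date[dx$code %in% config$pregnancy_codes],
    intervals = iv)
  pd$readings <- reading_table(pd, config$analytes)  # built once per patient
  pd
}

# TRUE when date d counts as a usable (non-refill) encounter date: either a
# non-refill encounter is recorded on d, or no encounter record exists at
# all on d (measurement-only sources).
encounter_ok <- function(pd, d) {
  !(d %in% pd$enc_dates) | (d %in% pd$enc_ok_dates)
}

# Reading table for a set of analyte comparisons: one row per date on which
# *all* analyte codes were measured; per (date, code) values averaged.
# uncontrolled = any comparison holds.
reading_table <- function(pd, analytes) {
  codes <- vapply(analytes, `[[`, "", "code")
  m <- pd$meas[code %in% codes,
               .(value = mean(value)), by = .(event_date, code)]
  if (!nrow(m)) return(NULL)
  w <- data.table::dcast(m, event_date ~ code, value.var = "value")
  w <- w[complete.cases(w)]
  if (!nrow(w)) return(NULL)
  data.table::setorder(w, event_date)
  unc <- rep(FALSE, nrow(w))
  for (a in analytes) {
    v <- w[[a$code]]
    unc <- unc | (if (a$op == ">=") v >= a$threshold else v > a$threshold)
  }
  w[, uncontrolled := unc]
  w
}

dp_dates_pair <- function(pd, config) {
  w <- pd$readings
  if (is.null(w) || nrow(w) < 2) return(as.Date(character()))
  d <- w$event_date; u <- w$uncontrolled
  k <- seq_len(nrow(w))[-1]
  gap <- as.integer(d[k] - d[k - 1])
  hit <- u[k] & u[k - 1] & gap >= 1 & gap <= config$max_separation_days
  cand <- d[k][hit]
  cand[encounter_ok(pd, cand)]
}

dp_dates_lab <- function(pd, config) {
  if (!length(pd$dx$event_date)) return(as.Date(character()))
  dxd <- pd$dx$event_date[pd$dx$code %in% config$diagnosis_codes]
  if (!length(dxd)) return(as.Date(character()))
  index0 <- min(dxd)
  enc <- pd$enc_ok_dates[pd$enc_ok_dates > index0]
  if (!length(enc)) return(as.Date(character()))
  labs <- pd$meas[code == config$lab$code,
                  .(value = mean(value)), by = event_date]
  data.table::setorder(labs, event_date)
  ok <- vapply(enc, function(d) {
    inw <- labs[event_date >= d - config$lookback_days & event_date <= d]
    if (!nrow(inw)) return(FALSE)
    v <- inw$value[which.max(as.integer(inw$event_date))]
    if (config$lab$op == ">=") v >= config$lab$threshold
    else v > config$lab$threshold
  }, logical(1))
  sort(enc[ok])
}

age_at <- function(pd, d, age_code) {
  a <- pd$meas[code == age_code & event_date <= d]
  if (!nrow(a)) return(NA_real_)
  a$value[which.max(as.integer(a$event_date))]
}

active_universe <- function(pd, d, universe_codes) {
  iv <- pd$intervals
  if (!nrow(iv)) return(character())
  sel <- iv$code %in% universe_codes & iv$start <= d &
    (is.na(iv$stop) | iv$stop > d)
  unique(iv$code[sel])
}

decision_token <- function(config, code, suffix) {
  tu <- config$treatment_universe
  i <- match(code, tu$code)
  paste0(tu$class[i], "_", tu$ingredient[i], suffix)
}

decision_at <- function(pd, d, config) {
  ucodes <- config$treatment_universe$code
  before <- active_universe(pd, d - 1, ucodes)
  after <- active_universe(pd, d + config$decision_buffer_days, ucodes)
  adds <- setdiff(after, before)
  drops <- setdiff(before, after)
  toks <- c(vapply(adds, decision_token, "", config = config, suffix = "+"),
            vapply(drops, decision_token, "", config = config, suffix = "-"))
  label <- if (!length(toks)) "no_change"
           else paste(sort(unname(toks)), collapse = "|")
  list(label = label, n_meds_after = length(after))
}

outcome_at <- function(pd, d, decision_label, config) {
  fu <- config$followup
  n_min <- if (decision_label != "no_change") fu$changed_min_days
           else fu$min_days
  w <- pd$readings
  if (is.null(w)) return("missing")
  off <- as.integer(w$event_date - d)
  inw <- which(off >= n_min & off <= fu$max_days)
  if (!length(inw)) return("missing")
  first <- inw[which.min(off[inw])]
  if (w$uncontrolled[first]) "not_controlled" else "controlled"
}

#' Observed treatment decision at a decision point
#'
#' Compares the set of active treatment-universe ingredients on the day
#' before the DP with the set active `decision_buffer_days` after it.
#' Additions emit `"{Class}_{Ingredient}+"`, removals
#' `"{Class}_{Ingredient}-"`; tokens are sorted and joined with `"|"`; an
#' empty delta is `"no_change"`.
#'
#' @param timelines A [build_timelines()] result.
#' @param patient_id Patient identifier.
#' @param dp_date Index date.
#' @param config A [disease_config()].
#' @return List with `label` and `n_meds_after` (active universe
#'   medications at `dp_date + decision_buffer_days`).
#' @export
detect_treatment_decision <- function(timelines, patient_id, dp_date,
                                      config) {
  pd <- patient_data(timelines, patient_id, config)
  decision_at(pd, as.Date(dp_date), config)
}

#' Follow-up outcome for a decision point
#'
#' The first qualifying follow-up measurement between `N` and
#' `followup$max_days` days after the DP decides the outcome, where `N` is
#' `followup$changed_min_days` when the treatment changed and
#' `followup$min_days` otherwise.  The measurement is controlled when no
#' configured analyte comparison holds; no measurement in the window yields
#' `"missing"`.
#'
#' @inheritParams detect_treatment_decision
#' @param decision_label The already-determined decision label (the window
#'   start depends on it).
#' @return `"controlled"`, `"not_controlled"` or `"missing"`.
#' @export
determine_outcome <- function(timelines, patient_id, dp_date,
                              decision_label, config) {
  pd <- patient_data(timelines, patient_id, config)
  outcome_at(pd, as.Date(dp_date), decision_label, config)
}

#' Split decision points into training and scoring sets
#'
#' Uniform random split without replacement; disjoint and exhaustive;
#' deterministic given `seed`.
#'
#' @param dps DP table from [extract_decision_points()].
#' @param n_train Number of training rows (`< nrow(dps)`).
#' @param seed Integer seed.
#' @return List with `train` and `score` data.tables.
#' @export
split_train_score <- function(dps, n_train, seed = 1) {
  stopifnot(n_train >= 0, n_train < nrow(dps))
  idx <- with_rng(seed, sample.int(nrow(dps), n_train))
  list(train = dps[sort(idx)], score = dps[setdiff(seq_len(nrow(dps)),
                                                   sort(idx))])
}
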