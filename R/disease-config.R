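#' Disease-specific decision-point configuration
#'
#' Encodes the clinical criteria that define decision points (DPs), observed
#' treatment decisions and follow-up outcomes for one chronic disease.
#' Three ready-made configurations transcribing standard criteria for
#' hypertension, type 2 diabetes and hyperlipidemia ship with the package
#' (`system.file("extdata/config", c("htn.yaml","t2dm.yaml","hl.yaml"),
#' package = "pcto")`).
#'
#' Two DP rules are supported:
#' \describe{
#'   \item{`consecutive_uncontrolled_pair`}{two consecutive uncontrolled
#'     readings of the configured analytes separated by 1 to
#'     `max_separation_days` days; the second reading's date is the DP
#'     (hypertension: SBP >= 140 or DBP >= 90).}
#'   \item{`diagnosis_then_lab`}{every non-refill encounter after the
#'     earliest qualifying diagnosis whose most recent lab value within
#'     `lookback_days` is abnormal (T2DM: HbA1c >= 7.0 within 365 d;
#'     hyperlipidemia: LDL > 130 within 420 d).}
#' }
#'
#' A *reading* is uncontrolled when **any** configured analyte comparison
#' holds; a follow-up measurement is *controlled* when **none** holds.
#'
#' @param disease Label.
#' @param study_period Length-2 `Date` vector; index dates must fall inside.
#' @param dp_rule `"consecutive_uncontrolled_pair"` or
#'   `"diagnosis_then_lab"`.
#' @param analytes List of `list(code=, op=, threshold=)` comparisons
#'   (`op` one of `">="`, `">"`) defining "uncontrolled" for both DP
#'   detection (pair rule) and the follow-up outcome.
#' @param max_separation_days Pair rule: maximum days between the two
#'   readings.
#' @param diagnosis_codes,lab,lookback_days Lab rule: qualifying diagnosis
#'   codes; `lab = list(code=, op=, threshold=)`; lookback window in days.
#' @param min_age Minimum age in years at the DP.
#' @param age_code Measurement code holding age in years.
#' @param pregnancy_codes,pregnancy_exclusion_days Diagnosis codes marking
#'   pregnancy and the exclusion window before the DP.
#' @param refill_codes Encounter codes treated as refill encounters
#'   (excluded from DP detection).
#' @param decision_buffer_days Days after the DP within which medication
#'   changes count as the observed treatment decision.
#' @param followup List `min_days`, `max_days`, `changed_min_days`: the
#'   follow-up window starts at `changed_min_days` when treatment changed,
#'   else at `min_days`.
#' @param treatment_universe `data.frame(code, ingredient, class)` of
#'   clinically acceptable medications; only these enter decision labels.
#' @param filter_variables Character names of baseline variables requiring
#'   exact match during precision-cohort filtering.
#' @return Object of class `pcto_disease_config`.
#' @export
disease_config <- function(disease,
                           study_period,
                           dp_rule = c("consecutive_uncontrolled_pair",
                                       "diagnosis_then_lab"),
                           analytes,
                           max_separation_days = 365,
                           diagnosis_codes = character(),
                           lab = NULL,
                           lookback_days = 365,
                           min_age = 18,
                           age_code = "age",
                           pregnancy_codes = "pregnancy_dx",
                           pregnancy_exclusion_days = 365,
                           refill_codes = "refill",
                           decision_buffer_days = 14,
                           followup = list(min_days = 1, max_days = 365,
                                           changed_min_days = 14),
                           treatment_universe,
                           filter_variables = character()) {
  dp_rule <- match.arg(dp_rule)
  study_period <- as.Date(study_period)
  stopifnot(length(study_period) == 2, study_period[1] <= study_period[2],
            length(analytes) >= 1,
            followup$min_days < followup$max_days,
            is.data.frame(treatment_universe),
            nrow(treatment_universe) >= 1,
            all(c("code", "ingredient", "class") %in%
                  names(treatment_universe)))
  for (a in analytes) stopifnot(a$op %in% c(">=", ">"),
                                is.numeric(a$threshold))
  if (dp_rule == "diagnosis_then_lab") {
    stopifnot(length(diagnosis_codes) >= 1, !is.null(lab),
              lab$op %in% c(">=", ">"))
  }
  followup$changed_min_days <- followup$changed_min_days %||%
    followup$min_days
  structure(list(
    disease = disease, study_period = study_period, dp_rule = dp_rule,
    analytes = analytes, max_separation_days = max_separation_days,
    diagnosis_codes = diagnosis_codes, lab = lab,
    lookback_days = lookback_days, min_age = min_age, age_code = age_code,
    pregnancy_codes = pregnancy_codes,
    pregnancy_exclusion_days = pregnancy_exclusion_days,
    refill_codes = refill_codes,
    decision_buffer_days = decision_buffer_days, followup = followup,
    treatment_universe = data.table::as.data.table(treatment_universe),
    filter_variables = filter_variables), class = "pcto_disease_config")
}

#' Read a disease configuration from YAML or JSON
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return A [disease_config()].
#' @export
read_disease_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  tu <- data.table::rbindlist(lapply(x$treatment_universe, as.list))
  disease_config(
    disease = x$disease,
    study_period = as.Date(unlist(x$study_period)),
    dp_rule = x$dp_rule,
    analytes = x$analytes,
    max_separation_days = x$max_separation_days %||% 365,
    diagnosis_codes = unlist(x$diagnosis_codes) %||% character(),
    lab = x$lab,
    lookback_days = x$lookback_days %||% 365,
    min_age = x$min_age %||% 18,
    age_code = x$age_code %||% "age",
    pregnancy_codes = unlist(x$pregnancy_codes) %||% "pregnancy_dx",
    pregnancy_exclusion_days = x$pregnancy_exclusion_days %||% 365,
    refill_codes = unlist(x$refill_codes) %||% "refill",
    decision_buffer_days = x$decision_buffer_days %||% 14,
    followup = x$followup,
    treatment_universe = tu,
    filter_variables = unlist(x$filter_variables) %||% character())
}

#' Hypertension configuration matching the synthetic generator
#'
#' Convenience constructor: the shipped `htn.yaml` uses a 2004--2018 study
#' period; this helper widens the period to cover a [sim_config()]
#' simulation and takes its treatment universe from the simulated
#' treatments.
#'
#' @param sim A [sim_config()] (defaults to `sim_config()`).
#' @param ... Overrides passed to [disease_config()].
#' @return A [disease_config()].
#' @export
htn_config_for_sim <- function(sim = sim_config(), ...) {
  tu <- data.table::rbindlist(lapply(sim$treatments, function(t)
    list(code = t$code, ingredient = t$ingredient, class = t$class)))
  args <- list(
    disease = "HTN",
    study_period = c(sim$start_date, sim$start_date + sim$horizon_days),
    dp_rule = "consecutive_uncontrolled_pair",
    analytes = list(
      list(code = "sbp", op = ">=",
           threshold = sim$control_thresholds$primary_ge),
      list(code = sim$secondary$code, op = ">=",
           threshold = sim$control_thresholds$secondary_ge)),
    max_separation_days = 365,
    treatment_universe = tu)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(disease_config, args)
}
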