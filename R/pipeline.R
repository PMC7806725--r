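#' Default variable templates for a disease configuration
#'
#' A generic template set mirroring the guideline-derived variables of a
#' chronic-disease workflow: one active-medication indicator per
#' treatment-universe ingredient, age (demographic) plus an age-60
#' indicator, an ever-diagnosed flag per supplied diagnosis code, and the
#' latest baseline value of each outcome analyte over the past 12 months.
#'
#' @param config A [disease_config()].
#' @param diagnosis_flags Named character vector: variable name ->
#'   diagnosis code for `diagnosis_ever` flags.
#' @return List of [variable_template()]s.
#' @export
default_variable_templates <- function(config,
                                       diagnosis_flags = c(
                                         dm = "dm_dx",
                                         disease_dx = "htn_dx")) {
  tu <- config$treatment_universe
  tpl <- lapply(seq_len(nrow(tu)), function(i)
    variable_template(paste0("med_", tu$code[i]), "medication_active",
                      codes = tu$code[i]))
  tpl <- c(tpl, list(
    variable_template("age", "demographic", codes = config$age_code,
                      window = "all_history"),
    variable_template("age60", "lab_latest_flag", codes = config$age_code,
                      window = "all_history", op = ">=", threshold = 60)))
  for (nm in names(diagnosis_flags))
    tpl <- c(tpl, list(variable_template(nm, "diagnosis_ever",
                                         codes = diagnosis_flags[[nm]],
                                         window = "all_history")))
  for (a in config$analytes)
    tpl <- c(tpl, list(variable_template(paste0(a$code, "_baseline"),
                                         "lab_latest_value",
                                         codes = a$code,
                                         window = "past_12m")))
  tpl
}

#' Assemble decision points and variable matrices for analysis
#'
#' Convenience wrapper: extracts DPs, constructs the variable matrix, drops
#' incomplete rows, and splits columns into exact-match filter variables
#' (per `config$filter_variables`, defaulting to the active-medication
#' indicators plus `age60` when unspecified) and the baseline variables
#' used by the similarity model.
#'
#' @param timelines A [build_timelines()] result.
#' @param config A [disease_config()].
#' @param templates Variable templates (default
#'   [default_variable_templates()]).
#' @param max_dps Optional cap: uniform subsample of DPs (seeded) to bound
#'   desk-scale runtime.
#' @param seed Seed for the optional subsample.
#' @return List with `dps`, `X` (all variables), `baseline_X`, `filter_X`,
#'   `filter_variables`, `baseline_variables`, `templates`.
#' @export
build_analysis_dataset <- function(timelines, config,
                                   templates =
                                     default_variable_templates(config),
                                   max_dps = Inf, seed = 1) {
  dps <- extract_decision_points(timelines, config)
  if (nrow(dps) > max_dps) {
    keep <- with_rng(seed, sort(sample.int(nrow(dps), max_dps)))
    dps <- dps[keep]
  }
  X <- construct_variables(timelines, dps, templates)
  dps <- dps[dp_id %in% X$dp_id]
  tnames <- vapply(templates, `[[`, "", "name")
  fvars <- config$filter_variables
  if (!length(fvars))
    fvars <- intersect(c(grep("^med_", tnames, value = TRUE), "age60"),
                       tnames)
  fvars <- intersect(fvars, names(X))
  bvars <- setdiff(tnames, fvars)
  list(dps = dps, X = X,
       baseline_X = X[, c("dp_id", bvars), with = FALSE],
       filter_X = X[, c("dp_id", fvars), with = FALSE],
       filter_variables = fvars, baseline_variables = bvars,
       templates = templates)
}

#' One-call personalized options report for an index DP
#'
#' Builds the precision cohort and runs the options analysis.
#'
#' @param model A `pcto_lsml`.
#' @param index_dp_id Index DP id.
#' @param ds Dataset list from [build_analysis_dataset()].
#' @param min_group_size,alpha Passed to [compare_outcomes()].
#' @param ... Passed to [build_precision_cohort()].
#' @return List with `cohort` and `report` (NULL when insufficient).
#' @export
pcto_report <- function(model, index_dp_id, ds, min_group_size = 30,
                        alpha = 0.05, ...) {
  cohort <- build_precision_cohort(model, index_dp_id, ds$dps,
                                   ds$baseline_X, ds$filter_X, ...)
  if (cohort$insufficient) return(list(cohort = cohort, report = NULL))
  members <- ds$dps[dp_id %in% cohort$member_ids]
  list(cohort = cohort,
       report = compare_outcomes(members, min_group_size = min_group_size,
                                 alpha = alpha,
                                 index_dp_id = index_dp_id))
}
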