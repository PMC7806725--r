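#' Configure a synthetic EHR simulation
#'
#' Describes a synthetic population of chronic-disease patients whose visit
#' streams, control measurements (an SBP analogue with a paired, correlated
#' DBP analogue), confounded treatment-initiation policy and heterogeneous
#' treatment effects are all known, so that the full pipeline can be tested
#' against ground truth.
#'
#' The generative model at each visit is
#' `measure = baseline_measure_mean + b_i + s_i - sum(active effects) + noise`
#' where `b_i ~ N(0, baseline_measure_sd)` is idiosyncratic patient-level
#' variation invisible to the treatment policy and `s_i ~ N(0, severity_sd)`
#' is latent severity that the policy *can* condition on (the source of
#' confounding).  The paired secondary analyte loads with `secondary$loading`
#' on the same patient-level terms with independent visit noise.
#'
#' @param n_patients Number of patients.
#' @param horizon_days Observation horizon in days from each patient's first
#'   visit (day 0).
#' @param visit_rate Mean inter-visit gap in days (geometric gaps, min 1).
#' @param baseline_measure_mean,baseline_measure_sd Population mean of the
#'   control measure and SD of the per-patient idiosyncratic offset.
#' @param severity_sd SD of the per-patient latent severity offset.
#' @param noise_sd Per-measurement noise SD.
#' @param secondary List describing the paired analyte: `code`, `mean`,
#'   `loading`, `noise_sd`.
#' @param control_thresholds Named list `primary_ge`, `secondary_ge`: a visit
#'   is *uncontrolled* when primary >= `primary_ge` or secondary >=
#'   `secondary_ge`.
#' @param treatments List of treatments, each a list with `code`,
#'   `ingredient`, `class`, `effect_size` (reduction of the control measure)
#'   and optional `modifiers` (list of `list(predicate=, effect=)`,
#'   predicates over covariates).
#' @param policy List of rules `list(predicate=, prob=)` evaluated in order
#'   over covariates plus `severity`; the first matching rule gives the
#'   per-uncontrolled-visit probability of initiating each inactive
#'   treatment.
#' @param stop_prob Per-visit discontinuation probability of each active
#'   treatment (produces "stop" decision labels).
#' @param covariates Named list of static patient attributes:
#'   `list(type="binary", p=)` or `list(type="continuous", mean=, sd=,
#'   min=, max=)`.  Continuous covariates are emitted as day-0 measurement
#'   events, binary ones as day-0 diagnosis events (`<name>_dx`).
#' @param pregnancy_rate Probability that a patient with `age < 45` gets one
#'   `pregnancy_dx` diagnosis at a uniformly random day.
#' @param truth_subgroups Character vector of covariate predicates for which
#'   ground-truth control probabilities are tabulated.
#' @param start_date Calendar date of day 0.
#' @param seed Integer seed; all randomness flows from it.
#' @return An object of class `pcto_sim_config`.
#' @export
sim_config <- function(n_patients = 1000,
                       horizon_days = 1095,
                       visit_rate = 30,
                       baseline_measure_mean = 150,
                       baseline_measure_sd = 8,
                       severity_sd = 8,
                       noise_sd = 6,
                       secondary = list(code = "dbp", mean = 86,
                                        loading = 0.5, noise_sd = 4),
                       control_thresholds = list(primary_ge = 140,
                                                 secondary_ge = 90),
                       treatments = default_treatments(),
                       policy = default_policy(),
                       stop_prob = 0.05,
                       covariates = default_covariates(),
                       pregnancy_rate = 0.05,
                       truth_subgroups = c("TRUE", "age >= 60", "age < 60",
                                           "dm == 1", "dm == 0"),
                       start_date = as.Date("2010-01-01"),
                       seed = 1) {
  stopifnot(n_patients >= 0, horizon_days > 0, visit_rate >= 1,
            baseline_measure_sd >= 0, severity_sd >= 0, noise_sd > 0,
            secondary$noise_sd > 0, length(treatments) >= 1,
            stop_prob >= 0, stop_prob <= 1)
  for (r in policy)
    stopifnot(is.character(r$predicate), r$prob >= 0, r$prob <= 1)
  cfg <- structure(as.list(environment()), class = "pcto_sim_config")
  cfg
}

#' @rdname sim_config
#' @export
default_treatments <- function() list(
  list(code = "lisinopril", ingredient = "Lisinopril", class = "ACEI",
       effect_size = 12,
       modifiers = list(list(predicate = "dm == 1", effect = -6))),
  list(code = "hydrochlorothiazide", ingredient = "Hydrochlorothiazide",
       class = "Thiazide", effect_size = 9, modifiers = list()),
  list(code = "amlodipine", ingredient = "Amlodipine", class = "CCB",
       effect_size = 7,
       modifiers = list(list(predicate = "age >= 60", effect = 6))))

#' @rdname sim_config
#' @export
default_policy <- function() list(
  list(predicate = "severity > 5", prob = 0.35),
  list(predicate = "TRUE", prob = 0.12))

#' @rdname sim_config
#' @export
default_covariates <- function() list(
  age = list(type = "continuous", mean = 62, sd = 12, min = 25, max = 90),
  dm = list(type = "binary", p = 0.3))

eval_predicate <- function(predicate, env_list) {
  isTRUE(eval(parse(text = predicate), envir = env_list,
              enclos = baseenv()))
}

# total effect of treatment `trt` for a patient with covariates `cov_list`
treatment_effect <- function(trt, cov_list) {
  e <- trt$effect_size
  for (m in trt$modifiers %||% list())
    if (eval_predicate(m$predicate, cov_list)) e <- e + m$effect
  e
}

draw_covariates <- function(config) {
  n <- config$n_patients
  out <- data.table::data.table(
    patient_id = sprintf("P%05d", seq_len(max(n, 0))))
  if (n == 0) {
    for (nm in names(config$covariates)) out[, (nm) := numeric(0)]
    return(out)
  }
  for (nm in names(config$covariates)) {
    cv <- config$covariates[[nm]]
    x <- if (cv$type == "binary") rbinom(n, 1, cv$p)
         else pmin(pmax(rnorm(n, cv$mean, cv$sd),
                        cv$min %||% -Inf), cv$max %||% Inf)
    out[, (nm) := x]
  }
  out
}

#' Simulate a synthetic EHR population
#'
#' Generates an event table in the canonical schema (see [event-tables])
#' plus a ground-truth object.  Deterministic given `config$seed`;
#' `n_patients = 0` yields an empty table.
#'
#' Per patient: geometric inter-visit gaps with mean `visit_rate` (min 1
#' day); at each visit the primary and secondary analytes are measured; if
#' the visit is uncontrolled, a disease diagnosis (`htn_dx`) is recorded on
#' first occurrence and each inactive treatment is initiated with the
#' policy probability (policy rules can see latent severity, which is how
#' confounding is planted); each active treatment is discontinued with
#' probability `stop_prob` per visit.
#'
#' @param config A [sim_config()].
#' @return List with `events` (event data.table) and `truth`
#'   (class `pcto_ground_truth`: per-patient latent offsets, covariates,
#'   subgroup-by-treatment true control probabilities, the policy).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "pcto_sim_config"))
  with_rng(config$seed, simulate_population_impl(config))
}

simulate_population_impl <- function(config) {
  cov <- draw_covariates(config)
  n <- config$n_patients
  empty <- data.table::data.table(
    patient_id = character(), event_date = as.Date(character()),
    event_kind = character(), code = character(), value = numeric(),
    unit = character(), action = character())
  truth <- structure(list(config = config, covariates = cov,
                          severity = setNames(numeric(0), character(0)),
                          baseline = setNames(numeric(0), character(0)),
                          control_prob = truth_control_table(config, cov)),
                     class = "pcto_ground_truth")
  if (n == 0) return(list(events = empty, truth = truth))

  b <- rnorm(n, 0, config$baseline_measure_sd)
  s <- rnorm(n, 0, config$severity_sd)
  names(b) <- names(s) <- cov$patient_id
  sec <- config$secondary
  thr <- config$control_thresholds
  trts <- config$treatments
  per_patient <- vector("list", n)

  for (i in seq_len(n)) {
    pid <- cov$patient_id[i]
    cl <- c(as.list(cov[i, -"patient_id"]), list(severity = s[i]))
    eff <- vapply(trts, treatment_effect, numeric(1), cov_list = cl)
    p_init <- 0
    for (r in config$policy)
      if (eval_predicate(r$predicate, cl)) { p_init <- r$prob; break }

    n_gap <- max(2L, ceiling(config$horizon_days / config$visit_rate * 2) + 5L)
    gaps <- 1 + rgeom(n_gap, 1 / config$visit_rate)
    while (sum(gaps) < config$horizon_days)
      gaps <- c(gaps, 1 + rgeom(n_gap, 1 / config$visit_rate))
    days <- c(0, cumsum(gaps))
    days <- days[days <= config$horizon_days]
    nv <- length(days)

    active <- rep(FALSE, length(trts))
    dxed <- FALSE
    pr1 <- pr2 <- numeric(nv)
    med_day <- integer(0); med_code <- character(0); med_act <- character(0)
    dx_day <- integer(0); dx_code <- character(0)

    for (v in seq_len(nv)) {
      tot_eff <- sum(eff[active])
      pr1[v] <- config$baseline_measure_mean + b[i] + s[i] - tot_eff +
        rnorm(1, 0, config$noise_sd)
      pr2[v] <- sec$mean + sec$loading * (b[i] + s[i] - tot_eff) +
        rnorm(1, 0, sec$noise_sd)
      uncontrolled <- pr1[v] >= thr$primary_ge || pr2[v] >= thr$secondary_ge
      # stops first (a treatment stopped today cannot restart today)
      was_active <- active
      for (t in which(was_active)) {
        if (runif(1) < config$stop_prob) {
          active[t] <- FALSE
          med_day <- c(med_day, days[v]); med_code <- c(med_code, trts[[t]]$code)
          med_act <- c(med_act, "stop")
        }
      }
      if (uncontrolled) {
        if (!dxed) {
          dx_day <- c(dx_day, days[v]); dx_code <- c(dx_code, "htn_dx")
          dxed <- TRUE
        }
        for (t in which(!was_active)) {
          if (runif(1) < p_init) {
            active[t] <- TRUE
            med_day <- c(med_day, days[v])
            med_code <- c(med_code, trts[[t]]$code)
            med_act <- c(med_act, "start")
          }
        }
      }
    }

    # static day-0 covariate events
    cont <- names(config$covariates)[vapply(config$covariates,
                                            function(x) x$type == "continuous",
                                            logical(1))]
    bin <- setdiff(names(config$covariates), cont)
    bin_on <- bin[vapply(bin, function(nm) cl[[nm]] == 1, logical(1))]
    preg_day <- integer(0)
    if (!is.null(cl$age) && cl$age < 45 &&
        runif(1) < config$pregnancy_rate)
      preg_day <- sample.int(config$horizon_days, 1)

    v_day <- c(days, days, med_day, dx_day,
               rep(0L, length(cont)), rep(0L, length(bin_on)), preg_day,
               days)
    v_kind <- c(rep("measurement", 2 * nv),
                rep("medication", length(med_act)),
                rep("diagnosis", length(dx_day)),
                rep("measurement", length(cont)),
                rep("diagnosis", length(bin_on)),
                rep("diagnosis", length(preg_day)),
                rep("encounter", nv))
    v_code <- c(rep("sbp", nv), rep(sec$code, nv), med_code, dx_code,
                cont,
                if (length(bin_on)) paste0(bin_on, "_dx") else character(0),
                rep("pregnancy_dx", length(preg_day)),
                rep("office_visit", nv))
    v_value <- c(round(pr1, 1), round(pr2, 1),
                 rep(NA_real_, length(med_code) + length(dx_code)),
                 as.numeric(unlist(cl[cont], use.names = FALSE)),
                 rep(NA_real_, length(bin_on) + length(preg_day) + nv))
    v_action <- c(rep(NA_character_, 2 * nv), med_act,
                  rep(NA_character_, length(dx_day) + length(cont) +
                        length(bin_on) + length(preg_day) + nv))
    lens <- c(length(v_day), length(v_kind), length(v_code),
              length(v_value), length(v_action))
    if (length(unique(lens)) != 1)
      stop("internal length mismatch for ", pid, ": ",
           paste(lens, collapse = "/"),
           " nv=", nv, " med=", length(med_code), " dx=", length(dx_code),
           " cont=", length(cont), " bin=", length(bin_on),
           " preg=", length(preg_day))
    per_patient[[i]] <- data.table::data.table(
      patient_id = pid, day = v_day, event_kind = v_kind, code = v_code,
      value = v_value, action = v_action)
  }

  ev <- data.table::rbindlist(per_patient)
  ev[, event_date := config$start_date + day]
  ev[, `:=`(day = NULL, unit = NA_character_)]
  data.table::setcolorder(ev, EVENT_COLS)
  data.table::setorder(ev, patient_id, event_date, event_kind, code,
                       action, na.last = TRUE)
  truth$severity <- s
  truth$baseline <- b
  list(events = ev[], truth = truth)
}

med_act_kind <- function(acts) rep("medication", length(acts))

# Exact control probability under permanent use of one treatment (or none),
# for a patient with combined latent offset u = b + s and effect e:
#   P(primary < thr1  and  secondary < thr2)
# integrated over u ~ N(0, sqrt(sb^2 + ss^2)) by trapezoidal quadrature
# (visit noises of the two analytes are independent given u).
control_prob_for_effect <- function(config, e) {
  su <- sqrt(config$baseline_measure_sd^2 + config$severity_sd^2)
  thr <- config$control_thresholds
  sec <- config$secondary
  if (su < 1e-12) {
    u <- 0; w <- 1
  } else {
    u <- seq(-6 * su, 6 * su, length.out = 801)
    w <- dnorm(u, 0, su)
    w <- w / sum(w)
  }
  p1 <- pnorm((thr$primary_ge - config$baseline_measure_mean - u + e) /
                config$noise_sd)
  p2 <- pnorm((thr$secondary_ge - sec$mean - sec$loading * (u - e)) /
                sec$noise_sd)
  sum(w * p1 * p2)
}

truth_control_table <- function(config, cov) {
  rows <- list()
  labels <- c("no_change", vapply(config$treatments, `[[`, "", "code"))
  for (g in config$truth_subgroups) {
    if (nrow(cov)) {
      in_g <- vapply(seq_len(nrow(cov)), function(i)
        eval_predicate(g, as.list(cov[i, -"patient_id"])), logical(1))
    } else in_g <- logical(0)
    if (!any(in_g)) next
    sub <- cov[in_g]
    for (ti in seq_along(labels)) {
      probs <- vapply(seq_len(nrow(sub)), function(i) {
        cl <- as.list(sub[i, -"patient_id"])
        e <- if (ti == 1) 0
             else treatment_effect(config$treatments[[ti - 1]], cl)
        control_prob_for_effect(config, e)
      }, numeric(1))
      rows[[length(rows) + 1]] <- data.table::data.table(
        subgroup = g, treatment = labels[ti], prob = mean(probs),
        n_patients = nrow(sub))
    }
  }
  if (!length(rows))
    return(data.table::data.table(subgroup = character(),
                                  treatment = character(), prob = numeric(),
                                  n_patients = integer()))
  data.table::rbindlist(rows)
}

#' Rank treatment options by true control probability
#'
#' Oracle for parameter-recovery tests: orders the configured treatments
#' (plus `"no_change"`) by their ground-truth expected control probability
#' within a covariate subgroup, preserving ties as groups.
#'
#' @param truth A `pcto_ground_truth` from [simulate_population()].
#' @param subgroup A covariate predicate string (e.g. `"age >= 60"`); must
#'   match at least one simulated patient.
#' @param tol Probabilities closer than `tol` are tied.
#' @return List of character vectors: tie groups in decreasing order of
#'   true control probability.
#' @export
truth_option_ranking <- function(truth, subgroup = "TRUE", tol = 1e-9) {
  cfg <- truth$config
  cov <- truth$covariates
  sg <- subgroup   # avoid data.table column-name capture in i
  tab <- truth$control_prob[subgroup == sg]
  if (!nrow(tab)) {
    in_g <- vapply(seq_len(nrow(cov)), function(i)
      eval_predicate(subgroup, as.list(cov[i, -"patient_id"])), logical(1))
    if (!any(in_g)) stop("subgroup matches no simulated patient: ", subgroup)
    cfg2 <- cfg; cfg2$truth_subgroups <- subgroup
    tab <- truth_control_table(cfg2, cov)
  }
  tab <- tab[order(-tab$prob)]
  groups <- list(); cur <- tab$treatment[1]; last <- tab$prob[1]
  for (k in seq_len(nrow(tab))[-1]) {
    if (abs(tab$prob[k] - last) <= tol) cur <- c(cur, tab$treatment[k])
    else { groups[[length(groups) + 1]] <- cur; cur <- tab$treatment[k] }
    last <- tab$prob[k]
  }
  groups[[length(groups) + 1]] <- cur
  groups
}

#' Serialize ground truth alongside a simulated event table
#'
#' @param truth A `pcto_ground_truth`.
#' @param path JSON output path.
#' @export
write_ground_truth <- function(truth, path) {
  out <- list(severity = as.list(truth$severity),
              baseline = as.list(truth$baseline),
              covariates = truth$covariates,
              control_prob = truth$control_prob,
              policy = truth$config$policy,
              seed = truth$config$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
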