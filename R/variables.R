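#' Baseline variable templates
#'
#' A template describes how one baseline variable is constructed from a
#' patient's record over a window ending at the DP index date.  Windows
#' follow common chronic-disease practice: the past 12 months, past 14
#' months, or all available history.
#'
#' @param name Unique variable name.
#' @param source One of `"medication_active"` (ingredient interval covers
#'   the index date), `"diagnosis_ever"`, `"diagnosis_recent"`,
#'   `"lab_latest_value"` (most recent value in window; missing if none),
#'   `"lab_latest_flag"` (most recent value compared against `threshold`),
#'   `"demographic"` (latest measurement over all history, e.g. age).
#' @param codes Character vector of event codes the variable summarizes.
#' @param window `"past_12m"` (365 d), `"past_14m"` (425 d) or
#'   `"all_history"`; ignored for `medication_active` (point-in-time) and
#'   `demographic`.
#' @param op,threshold For `lab_latest_flag`: comparison (`">="`/`">"`) and
#'   threshold.
#' @return Object of class `pcto_variable_template`.
#' @export
variable_template <- function(name, source, codes,
                              window = "past_12m",
                              op = ">=", threshold = NA_real_) {
  source <- match.arg(source, c("medication_active", "diagnosis_ever",
                                "diagnosis_recent", "lab_latest_value",
                                "lab_latest_flag", "demographic"))
  window <- match.arg(window, c("past_12m", "past_14m", "all_history"))
  if (source == "lab_latest_flag") stopifnot(is.finite(threshold))
  structure(list(name = name, source = source, codes = codes,
                 window = window, op = op, threshold = threshold),
            class = "pcto_variable_template")
}

window_days <- function(window)
  switch(window, past_12m = 365, past_14m = 425, all_history = Inf)

#' Construct the DP-by-variable baseline matrix
#'
#' One row per decision point, one column per template.  DPs with any
#' missing value (e.g. no lab result in the window) are dropped and
#' counted; only complete rows are retained.
#'
#' @param timelines A [build_timelines()] result.
#' @param dps DP table from [extract_decision_points()].
#' @param templates List of [variable_template()]s (unique names).
#' @return `data.table` with `dp_id` plus one numeric column per variable;
#'   attribute `"dropped"` holds the ids of DPs removed for missingness.
#' @export
construct_variables <- function(timelines, dps, templates) {
  nms <- vapply(templates, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate template names")
  ev <- timelines$events
  iv <- timelines$intervals
  out <- data.table::data.table(dp_id = dps$dp_id)
  dpt <- data.table::data.table(patient_id = dps$patient_id,
                                index_date = dps$index_date)
  for (tpl in templates) {
    out[, (tpl$name) := template_column(tpl, dpt, ev, iv)]
  }
  keep <- complete.cases(out)
  dropped <- out$dp_id[!keep]
  if (length(dropped))
    message(length(dropped), " DP(s) dropped for missing variable values")
  res <- out[keep]
  data.table::setattr(res, "dropped", dropped)
  res[]
}

template_column <- function(tpl, dpt, ev, iv) {
  n <- nrow(dpt)
  win <- window_days(tpl$window)
  vapply(seq_len(n), function(k) {
    pid <- dpt$patient_id[k]; d <- dpt$index_date[k]
    switch(tpl$source,
      medication_active = {
        sel <- iv$patient_id == pid & iv$code %in% tpl$codes &
          iv$start <= d & (is.na(iv$stop) | iv$stop > d)
        as.numeric(any(sel))
      },
      diagnosis_ever = {
        e <- ev[.(pid)][event_kind == "diagnosis" & code %in% tpl$codes &
                          event_date <= d]
        as.numeric(nrow(e) > 0)
      },
      diagnosis_recent = {
        e <- ev[.(pid)][event_kind == "diagnosis" & code %in% tpl$codes &
                          event_date <= d & event_date >= d - win]
        as.numeric(nrow(e) > 0)
      },
      lab_latest_value = latest_value(ev, pid, tpl$codes, d, win),
      demographic = latest_value(ev, pid, tpl$codes, d, Inf),
      lab_latest_flag = {
        v <- latest_value(ev, pid, tpl$codes, d, win)
        if (is.na(v)) NA_real_
        else as.numeric(if (tpl$op == ">=") v >= tpl$threshold
                        else v > tpl$threshold)
      })
  }, numeric(1))
}

latest_value <- function(ev, pid, codes, d, win) {
  e <- ev[.(pid)][event_kind == "measurement" & code %in% codes &
                    event_date <= d]
  if (is.finite(win)) e <- e[event_date >= d - win]
  if (!nrow(e)) return(NA_real_)
  e <- e[event_date == max(event_date)]
  mean(e$value)
}

#' Stability selection with L1-regularized logistic regression
#'
#' Fits `n_models` L1-penalized logistic regressions, each on an
#' independent uniform subsample (without replacement) of
#' `floor(subsample_frac * n)` rows, and counts for each variable how many
#' models give it a nonzero coefficient.  Variables selected by at least
#' `threshold` of the models are flagged stable.  Columns are z-scored
#' inside each resample so the penalty is scale-free; columns constant in
#' the full matrix are never selectable (frequency 0, with a warning).
#'
#' @param X Numeric matrix or data.table (a `dp_id` column is ignored).
#' @param y Binary outcome vector (two classes required), e.g.
#'   `outcome == "controlled"`.
#' @param n_models,subsample_frac,threshold Operating point; defaults 200
#'   models on 75\% subsamples with a 150/200 stability threshold.
#' @param l1_strength Penalty `lambda` passed to [glmnet::glmnet()];
#'   `NULL` chooses it via [choose_l1_strength()].
#' @param target_vars Desired final variable count used when choosing the
#'   penalty (mean nonzero count per model is steered to about twice this).
#' @param seed Integer seed (subsampling keys off row index).
#' @return `data.table` (class `pcto_stability`) with `name`, `frequency`,
#'   `selected`, `cluster` (NA until [correlate_and_cluster()] is applied);
#'   attributes record the operating point.
#' @export
stability_select <- function(X, y, n_models = 200, subsample_frac = 0.75,
                             threshold = 150, l1_strength = NULL,
                             target_vars = 10, seed = 1) {
  X <- as_variable_matrix(X)
  y <- as.integer(as.factor(y)) - 1L
  n <- nrow(X); p <- ncol(X)
  if (length(unique(y)) < 2) stop("outcome y is constant")
  if (n < 20) stop("need at least 20 rows for stability selection")
  const <- apply(X, 2, function(col) sd(col) == 0)
  if (any(const))
    warning("constant column(s) never selectable: ",
            paste(colnames(X)[const], collapse = ", "))
  if (is.null(l1_strength))
    l1_strength <- choose_l1_strength(X[, !const, drop = FALSE], y,
                                      target_vars = target_vars)
  m_rows <- floor(subsample_frac * n)
  freq <- setNames(integer(p), colnames(X))
  with_rng(seed, {
    for (m in seq_len(n_models)) {
      rows <- sample.int(n, m_rows)
      Xi <- X[rows, !const, drop = FALSE]
      mu <- colMeans(Xi); sdv <- apply(Xi, 2, sd); sdv[sdv == 0] <- 1
      Xi <- scale(Xi, center = mu, scale = sdv)
      beta <- l1_coefs(Xi, y[rows], l1_strength)
      nz <- abs(beta) > 1e-8
      freq[colnames(Xi)[nz]] <- freq[colnames(Xi)[nz]] + 1L
    }
  })
  res <- data.table::data.table(name = colnames(X),
                                frequency = unname(freq),
                                selected = unname(freq) >= threshold,
                                cluster = NA_integer_)
  data.table::setattr(res, "n_models", n_models)
  data.table::setattr(res, "threshold", threshold)
  data.table::setattr(res, "l1_strength", l1_strength)
  data.table::setattr(res, "class",
                      c("pcto_stability", class(res)))
  res[]
}

# Lasso-logistic coefficients at one penalty value; fitted along a short
# descending lambda path for glmnet stability, coefficients taken at the
# target value.
l1_coefs <- function(X, y, lambda) {
  lmax <- max(abs(crossprod(X, y - mean(y)))) / length(y)
  path <- sort(unique(c(exp(seq(log(max(lmax, lambda * 1.001)),
                                log(lambda), length.out = 15)), lambda)),
               decreasing = TRUE)
  fit <- glmnet::glmnet(X, y, family = "binomial", lambda = path,
                        standardize = FALSE)
  j <- which.min(abs(fit$lambda - lambda))
  as.numeric(fit$beta[, j])
}

#' Choose the L1 penalty for stability selection
#'
#' Picks, from glmnet's default lambda path on the full matrix, the penalty
#' whose number of nonzero coefficients is closest to
#' `2 * target_vars` (stability selection then thins this candidate pool).
#' The grid and choice are reported via `message()`.
#'
#' @inheritParams stability_select
#' @return The chosen lambda.
#' @export
choose_l1_strength <- function(X, y, target_vars = 10) {
  X <- as_variable_matrix(X)
  Xs <- scale(X)
  Xs[, apply(X, 2, sd) == 0] <- 0
  fit <- glmnet::glmnet(Xs, y, family = "binomial", nlambda = 50)
  nz <- fit$df
  k <- which.min(abs(nz - 2 * target_vars))
  message("l1_strength grid search: lambda = ",
          signif(fit$lambda[k], 4), " (", nz[k],
          " nonzero coefficients, target ", 2 * target_vars, ")")
  fit$lambda[k]
}

as_variable_matrix <- function(X) {
  if (data.table::is.data.table(X) || is.data.frame(X)) {
    X <- data.table::as.data.table(X)
    if ("dp_id" %in% names(X)) X <- X[, -"dp_id"]
    X <- as.matrix(X)
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  X
}

#' Cluster correlated candidate variables
#'
#' Single-linkage clusters on `|Pearson r| >= r_threshold`, emitted as a
#' review report: the final adjudication of correlated variables is a human
#' step, so the pipeline outputs clusters and accepts an approved-variable
#' list (see [read_approved_variables()]).
#'
#' @param X DP-by-variable matrix restricted to candidate variables
#'   (at least two).
#' @param r_threshold Absolute correlation at or above which two variables
#'   are linked.
#' @return Named integer vector of cluster ids.
#' @export
correlate_and_cluster <- function(X, r_threshold = 0.8) {
  X <- as_variable_matrix(X)
  if (ncol(X) < 2) stop("need at least 2 candidate variables")
  r <- suppressWarnings(abs(cor(X)))
  r[is.na(r)] <- 0
  d <- as.dist(1 - r)
  h <- hclust(d, method = "single")
  cutree(h, h = 1 - r_threshold)
}

#' Read an approved-variable list
#'
#' One variable name per line; blank lines and `#` comments ignored.  When
#' supplied, the pipeline proceeds with exactly this list instead of the
#' automatic stable set.
#'
#' @param path Text file path.
#' @return Character vector of variable names.
#' @export
read_approved_variables <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}
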