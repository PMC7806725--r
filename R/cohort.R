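#' Exact-match filtering of cohort candidates
#'
#' Keeps the scoring DPs whose filter-variable vector is identical to the
#' index DP's; the index DP itself is always excluded (leave-one-out
#' contract).
#'
#' @param index_dp_id Id of the index DP.
#' @param filter_X `data.table` with `dp_id` plus the filter-variable
#'   columns, covering the index DP and all scoring DPs.
#' @return Character vector of candidate dp_ids (possibly empty, which
#'   downstream reports as an insufficient cohort).
#' @export
filter_candidates <- function(index_dp_id, filter_X) {
  stopifnot("dp_id" %in% names(filter_X))
  i <- match(index_dp_id, filter_X$dp_id)
  if (is.na(i)) stop("index DP not present in filter table: ", index_dp_id)
  cols <- setdiff(names(filter_X), "dp_id")
  if (!length(cols)) return(setdiff(filter_X$dp_id, index_dp_id))
  keep <- rep(TRUE, nrow(filter_X))
  for (cl in cols) keep <- keep & (filter_X[[cl]] == filter_X[[cl]][i])
  keep[i] <- FALSE
  filter_X$dp_id[keep]
}

#' Similarity scores for filtered candidates
#'
#' Raw learned distances to the index DP, normalized by the 99th percentile
#' of the candidate distances and capped at 1, so scores live in `[0, 1]`
#' with 0 = identical to the index patient.  The p99 normalizer (rather
#' than the max) keeps thresholds stable against a single distant outlier.
#' Score order always equals raw-distance order.
#'
#' @param model A `pcto_lsml`.
#' @param index Named numeric vector: the index DP's baseline variables.
#' @param candidates Matrix/data.table of candidate baseline rows (a
#'   `dp_id` column is ignored).
#' @return Numeric scores in `[0, 1]`, one per candidate row.
#' @export
score_candidates <- function(model, index, candidates) {
  raw <- lsml_distances(model, index, candidates)
  p99 <- unname(quantile(raw, 0.99, type = 7))
  if (p99 == 0) {
    warning("all candidates identical to the index DP; scores set to 0")
    return(rep(0, length(raw)))
  }
  pmin(raw / p99, 1)
}

#' Standardized bias of one covariate between decision groups
#'
#' `(mean(no_change) - mean(change)) / sd(change)`: the covariate-balance
#' diagnostic comparing the "no treatment change" and "treatment change"
#' groups, scaled by the treated-group standard deviation.  An exactly
#' equal pair of means gives 0 regardless of the spread (so exact-matched
#' filter variables are exactly balanced); otherwise a zero treated-group
#' SD yields `NA` with a warning (covariate skipped).
#'
#' @param x Numeric covariate values.
#' @param change Logical: `TRUE` for the treatment-change group.
#' @return Scalar standardized bias (signed).
#' @export
standardized_bias <- function(x, change) {
  stopifnot(length(x) == length(change), any(change), any(!change))
  num <- mean(x[!change]) - mean(x[change])
  if (num == 0) return(0)
  s <- sd(x[change])
  if (is.na(s) || s == 0) {
    warning("treated-group sd is 0; covariate skipped")
    return(NA_real_)
  }
  num / s
}

#' Covariate-balance report for a cohort
#'
#' @param X Matrix/data.table of balance covariates (rows = cohort
#'   members).
#' @param change Logical vector (treatment change vs no change).
#' @param aggregate `"max"` (default, conservative) or `"mean"` of the
#'   absolute per-covariate biases.
#' @return List with `per_covariate` (named numeric), `aggregate`,
#'   `n_change`, `n_no_change`.
#' @export
balance_report <- function(X, change, aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  X <- as_variable_matrix(X)
  if (!any(change) || !any(!change))
    return(list(per_covariate = setNames(rep(NA_real_, ncol(X)),
                                         colnames(X)),
                aggregate = NA_real_,
                n_change = sum(change), n_no_change = sum(!change)))
  per <- vapply(seq_len(ncol(X)), function(j)
    suppressWarnings(standardized_bias(X[, j], change)), numeric(1))
  names(per) <- colnames(X)
  agg <- if (all(is.na(per))) NA_real_
         else if (aggregate == "max") max(abs(per), na.rm = TRUE)
         else mean(abs(per), na.rm = TRUE)
  list(per_covariate = per, aggregate = agg,
       n_change = sum(change), n_no_change = sum(!change))
}

#' Select the similarity-score threshold for a precision cohort
#'
#' Evaluates cohort size and aggregate covariate balance at each threshold
#' of a score-quantile grid (ascending) and selects the largest threshold
#' whose cohort has at least `min_cohort` members and aggregate balance at
#' most `balance_max`.  If no threshold achieves the balance bound, the
#' minimum-balance threshold among those with sufficient size is chosen and
#' the cohort flagged balance-violating; if no threshold reaches
#' `min_cohort`, the result is flagged insufficient.
#'
#' @param scores Normalized scores from [score_candidates()].
#' @param candidate_ids dp_ids aligned with `scores`.
#' @param X Balance covariates aligned with `scores` (the baseline
#'   variables entering the similarity model; exact-matched filter
#'   variables are constant and contribute 0).
#' @param change Logical: treatment-change indicator per candidate.
#' @param grid Score quantiles to scan (default `seq(0.05, 1, 0.05)`).
#' @param min_cohort Minimum acceptable cohort size.
#' @param balance_max Maximum acceptable aggregate balance.
#' @param aggregate Passed to [balance_report()].
#' @param index_dp_id Stored on the result for bookkeeping.
#' @return Object of class `pcto_cohort`: `member_ids`, `threshold`,
#'   `balance` (the final [balance_report()]), `balance_profile`
#'   (`data.table` of threshold, size, balance), `insufficient`,
#'   `balance_violating`, `n_candidates`, `scores` (named by dp_id).
#' @export
select_threshold <- function(scores, candidate_ids, X, change,
                             grid = seq(0.05, 1, by = 0.05),
                             min_cohort = 100, balance_max = 0.1,
                             aggregate = "max", index_dp_id = NA_character_) {
  X <- as_variable_matrix(X)
  stopifnot(length(scores) == length(candidate_ids),
            nrow(X) == length(scores), length(change) == length(scores))
  thr <- unname(quantile(scores, sort(grid), type = 7))
  prof <- data.table::data.table(quantile = sort(grid), threshold = thr,
                                 size = NA_integer_, balance = NA_real_)
  reports <- vector("list", length(thr))
  for (k in seq_along(thr)) {
    inc <- scores <= thr[k]
    prof$size[k] <- sum(inc)
    rep_k <- balance_report(X[inc, , drop = FALSE], change[inc],
                            aggregate = aggregate)
    reports[[k]] <- rep_k
    prof$balance[k] <- rep_k$aggregate
  }
  eligible <- prof$size >= min_cohort
  ok <- eligible & !is.na(prof$balance) & prof$balance <= balance_max
  insufficient <- !any(eligible)
  violating <- FALSE
  if (insufficient) {
    pick <- NA_integer_
  } else if (any(ok)) {
    pick <- max(which(ok))
  } else {
    cand <- which(eligible & !is.na(prof$balance))
    pick <- if (length(cand)) cand[which.min(prof$balance[cand])]
            else max(which(eligible))
    violating <- TRUE
  }
  members <- if (is.na(pick)) character() else
    candidate_ids[scores <= thr[pick]]
  structure(list(
    index_dp_id = index_dp_id,
    n_candidates = length(scores),
    scores = setNames(scores, candidate_ids),
    threshold = if (is.na(pick)) NA_real_ else thr[pick],
    member_ids = members,
    balance = if (is.na(pick)) NULL else reports[[pick]],
    balance_profile = prof,
    insufficient = insufficient,
    balance_violating = violating), class = "pcto_cohort")
}

#' @export
print.pcto_cohort <- function(x, ...) {
  cat("<pcto_cohort> index=", x$index_dp_id, ": ", x$n_candidates,
      " candidates -> ", length(x$member_ids), " members",
      if (x$insufficient) " [insufficient]",
      if (x$balance_violating) " [balance violating]",
      "\n", sep = "")
  if (!is.null(x$balance))
    cat("  threshold=", signif(x$threshold, 3), ", balance=",
        signif(x$balance$aggregate, 3), "\n", sep = "")
  invisible(x)
}

#' Build the precision cohort for an index decision point
#'
#' Runs the full funnel: exact-match filter, similarity scoring, threshold
#' selection under the covariate-balance constraint.
#'
#' @param model A `pcto_lsml`.
#' @param index_dp_id Index DP id.
#' @param dps DP table covering the scoring set (and the index DP).
#' @param baseline_X `data.table` with `dp_id` + baseline variables (the
#'   similarity model's variables).
#' @param filter_X `data.table` with `dp_id` + filter variables.
#' @param ... Passed to [select_threshold()] (`min_cohort`, `balance_max`,
#'   `grid`, `aggregate`).
#' @return A `pcto_cohort`.
#' @export
build_precision_cohort <- function(model, index_dp_id, dps, baseline_X,
                                   filter_X, ...) {
  cand_ids <- filter_candidates(index_dp_id, filter_X)
  if (!length(cand_ids))
    return(structure(list(index_dp_id = index_dp_id, n_candidates = 0L,
                          scores = numeric(), threshold = NA_real_,
                          member_ids = character(), balance = NULL,
                          balance_profile = NULL, insufficient = TRUE,
                          balance_violating = FALSE),
                     class = "pcto_cohort"))
  bm <- as_variable_matrix(baseline_X)
  rownames(bm) <- baseline_X$dp_id
  index_vec <- bm[index_dp_id, ]
  cand_X <- bm[cand_ids, , drop = FALSE]
  scores <- score_candidates(model, index_vec, cand_X)
  change <- dps$decision_label[match(cand_ids, dps$dp_id)] != "no_change"
  select_threshold(scores, cand_ids, cand_X, change,
                   index_dp_id = index_dp_id, ...)
}
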