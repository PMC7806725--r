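#' Leave-one-out evaluation over the scoring set
#'
#' Each scoring DP in turn plays the index patient: it is removed, a
#' precision cohort is built from the remaining scoring DPs, the
#' treatment-options analysis is run, and summary flags are recorded.
#' Per-DP computations are independent (no shared mutable state), so the
#' result is identical regardless of processing order.
#'
#' Two variants of the medication-complexity flags are recorded:
#' `better_fewer/same/more` consider only significantly-better options,
#' while `comparable_fewer/same/more` consider tested options whose control
#' rate is at least the baseline's (comparable-or-better outcomes).
#'
#' @param dps Scoring DP table.
#' @param baseline_X,filter_X `data.table`s (`dp_id` + columns) covering
#'   all scoring DPs.
#' @param model A `pcto_lsml`.
#' @param dp_ids Subset of dp_ids to evaluate (default: all rows of
#'   `dps`).
#' @param min_group_size,alpha Passed to [compare_outcomes()].
#' @param ... Passed to [build_precision_cohort()] /
#'   [select_threshold()] (`min_cohort`, `balance_max`, ...).
#' @return `data.table` of LOOCV records: `dp_id`, `filter_key`,
#'   `cohort_size`, `insufficient`, `has_better`,
#'   `better_fewer/same/more`, `comparable_fewer/same/more`.
#' @export
loocv_run <- function(dps, baseline_X, filter_X, model,
                      dp_ids = dps$dp_id, min_group_size = 30,
                      alpha = 0.05, ...) {
  stopifnot(nrow(dps) > 0)
  fcols <- setdiff(names(filter_X), "dp_id")
  fkey <- if (length(fcols))
    apply(as_variable_matrix(filter_X), 1, paste, collapse = "|")
  else rep("", nrow(filter_X))
  names(fkey) <- filter_X$dp_id

  recs <- lapply(dp_ids, function(id) {
    rec <- list(dp_id = id, filter_key = unname(fkey[id]),
                cohort_size = 0L, insufficient = TRUE, has_better = FALSE,
                better_fewer = FALSE, better_same = FALSE,
                better_more = FALSE, comparable_fewer = FALSE,
                comparable_same = FALSE, comparable_more = FALSE)
    cohort <- tryCatch(
      build_precision_cohort(model, id, dps, baseline_X, filter_X, ...),
      error = function(e) NULL)
    if (is.null(cohort) || cohort$insufficient) return(rec)
    members <- dps[dp_id %in% cohort$member_ids]
    if (!nrow(members)) return(rec)
    rep_i <- compare_outcomes(members, min_group_size = min_group_size,
                              alpha = alpha, index_dp_id = id)
    rec$cohort_size <- length(cohort$member_ids)
    rec$insufficient <- FALSE
    rows <- rep_i$rows
    better <- rows[rows$tested & rows$significant &
                     rows$direction == "better", ]
    rec$has_better <- nrow(better) > 0
    rec$better_fewer <- any(better$med_delta == "fewer")
    rec$better_same <- any(better$med_delta == "same")
    rec$better_more <- any(better$med_delta == "more")
    comp <- rows[rows$tested & rows$diff_vs_baseline >= 0, ]
    rec$comparable_fewer <- any(comp$med_delta == "fewer")
    rec$comparable_same <- any(comp$med_delta == "same")
    rec$comparable_more <- any(comp$med_delta == "more")
    rec
  })
  data.table::rbindlist(recs)
}

#' Aggregate LOOCV records by filter-variable cohort
#'
#' Summarizes, per exact-match filter cohort: DP count, percentage of DPs
#' with at least one significantly better option, and the
#' medication-complexity percentages.  Cohorts with fewer than `min_pool`
#' DPs are pooled into an `"other"` row (long-tail behaviour); rows are
#' sorted by size with a cumulative-coverage column, and an overall
#' `"TOTAL"` row is appended.
#'
#' @param records Output of [loocv_run()].
#' @param min_pool Pool threshold (default 5).
#' @return `data.table` with `filter_key`, `n`, `pct_has_better`,
#'   `pct_better_fewer/same/more`, `cumulative_coverage` (percent of all
#'   DPs in this row and the larger ones).
#' @export
aggregate_by_filter_cohort <- function(records, min_pool = 5) {
  stopifnot(nrow(records) > 0)
  recs <- data.table::copy(data.table::as.data.table(records))
  sizes <- recs[, .N, by = filter_key]
  small <- sizes$filter_key[sizes$N < min_pool]
  if (length(small) && length(small) < nrow(sizes))
    recs[filter_key %in% small, filter_key := "other"]
  agg <- recs[, .(
    n = .N,
    pct_has_better = 100 * mean(has_better),
    pct_better_fewer = 100 * mean(better_fewer),
    pct_better_same = 100 * mean(better_same),
    pct_better_more = 100 * mean(better_more)), by = filter_key]
  data.table::setorder(agg, -n)
  agg[, cumulative_coverage := 100 * cumsum(n) / sum(n)]
  total <- data.table::data.table(
    filter_key = "TOTAL", n = nrow(recs),
    pct_has_better = 100 * mean(recs$has_better),
    pct_better_fewer = 100 * mean(recs$better_fewer),
    pct_better_same = 100 * mean(recs$better_same),
    pct_better_more = 100 * mean(recs$better_more),
    cumulative_coverage = 100)
  data.table::rbindlist(list(agg, total))
}
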