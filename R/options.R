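#' Pearson chi-squared statistic for a 2x2 table
#'
#' Closed form `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, optionally with
#' Yates continuity correction.  Any all-zero margin yields statistic 0 and
#' p-value 1 with a warning.
#'
#' @param a,b First row (e.g. option: controlled, not controlled).
#' @param c,d Second row (baseline: controlled, not controlled).
#' @param correct Apply Yates continuity correction (default `FALSE`;
#'   plain Pearson is the reference analysis).
#' @return List with `statistic` and `p_value` (1 df).
#' @export
chisq2x2 <- function(a, b, c, d, correct = FALSE) {
  n <- a + b + c + d
  m <- c(a + b, c + d, a + c, b + d)
  if (any(m == 0)) {
    warning("chi-squared with an all-zero margin; p = 1")
    return(list(statistic = 0, p_value = 1))
  }
  num <- abs(a * d - b * c)
  if (correct) num <- max(0, num - n / 2)
  stat <- n * num^2 / prod(m)
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Group cohort members by observed treatment decision
#'
#' @param members DP table rows for the cohort members.
#' @return Named list of data.tables, an exact partition by
#'   `decision_label`.
#' @export
group_by_decision <- function(members) {
  stopifnot(nrow(members) > 0)
  split(members, by = "decision_label")
}

#' Treatment-options report for a precision cohort
#'
#' Groups the cohort's DPs by observed treatment decision and compares each
#' option's follow-up control rate against the `"no_change"` baseline with
#' a 2x2 Pearson chi-squared test, Bonferroni-corrected over the `m`
#' comparisons actually performed (groups with at least `min_group_size`
#' DPs).  Option medication complexity is the rounded median of members'
#' post-decision medication counts, reported relative to baseline as
#' fewer/same/more.
#'
#' @param members DP table rows of the cohort members (columns
#'   `decision_label`, `outcome`, `n_meds_after`).
#' @param min_group_size Smallest group that is significance-tested;
#'   smaller groups are reported untested.
#' @param alpha Family-wise error target (per-test threshold `alpha / m`,
#'   strict inequality).
#' @param correct Continuity correction, passed to [chisq2x2()].
#' @param index_dp_id Bookkeeping.
#' @return Object of class `pcto_options_report`: `rows` (one per decision
#'   label: `n`, `pct_controlled`, `diff_vs_baseline`, `chi2_stat`,
#'   `p_value`, `tested`, `significant`, `direction`, `n_meds`,
#'   `med_delta`), `m`, `cohort_size`, `no_baseline` flag.
#' @export
compare_outcomes <- function(members, min_group_size = 30, alpha = 0.05,
                             correct = FALSE, index_dp_id = NA_character_) {
  members <- data.table::as.data.table(members)
  groups <- group_by_decision(members)
  labels <- names(groups)
  no_baseline <- !("no_change" %in% labels)
  base <- if (no_baseline) NULL else groups[["no_change"]]
  base_pct <- if (no_baseline) NA_real_
              else 100 * mean(base$outcome == "controlled")
  base_meds <- if (no_baseline) NA_real_
               else round_half_away(median(base$n_meds_after))

  option_labels <- setdiff(labels, "no_change")
  testable <- option_labels[vapply(option_labels, function(l)
    nrow(groups[[l]]), integer(1)) >= min_group_size]
  m <- if (no_baseline) 0L else length(testable)

  rows <- data.table::rbindlist(lapply(labels, function(l) {
    g <- groups[[l]]
    n <- nrow(g)
    ctrl <- sum(g$outcome == "controlled")
    pct <- 100 * ctrl / n
    n_meds <- round_half_away(median(g$n_meds_after))
    is_base <- l == "no_change"
    tested <- !is_base && !no_baseline && l %in% testable && m > 0
    if (tested) {
      ts <- chisq2x2(ctrl, n - ctrl,
                     sum(base$outcome == "controlled"),
                     nrow(base) - sum(base$outcome == "controlled"),
                     correct = correct)
      stat <- ts$statistic; p <- ts$p_value
      sig <- p < alpha / m
    } else {
      stat <- NA_real_; p <- NA_real_; sig <- FALSE
    }
    diff <- if (is_base || no_baseline) if (is_base) 0 else NA_real_
            else pct - base_pct
    direction <- if (is_base || is.na(diff)) "equal"
                 else if (diff > 0) "better"
                 else if (diff < 0) "worse" else "equal"
    med_delta <- if (is_base || no_baseline) "same"
                 else if (n_meds < base_meds) "fewer"
                 else if (n_meds > base_meds) "more" else "same"
    data.table::data.table(
      decision_label = l, n = n, pct_controlled = pct,
      diff_vs_baseline = diff, chi2_stat = stat, p_value = p,
      tested = tested, significant = sig, direction = direction,
      n_meds = n_meds, med_delta = med_delta)
  }))
  data.table::setorder(rows, -n)
  structure(list(index_dp_id = index_dp_id, rows = rows, m = m,
                 cohort_size = nrow(members),
                 baseline_pct = base_pct, baseline_n_meds = base_meds,
                 no_baseline = no_baseline, alpha = alpha),
            class = "pcto_options_report")
}

#' @export
print.pcto_options_report <- function(x, ...) {
  cat("<pcto_options_report> cohort of ", x$cohort_size, " DPs, ",
      nrow(x$rows), " decision group(s), m = ", x$m, " tested",
      if (x$no_baseline) " [no baseline]", "\n", sep = "")
  print(x$rows[, .(decision_label, n,
                   pct_controlled = round(pct_controlled, 1),
                   diff = round(diff_vs_baseline, 1),
                   p_value = signif(p_value, 3), significant, direction,
                   med_delta)])
  invisible(x)
}

#' Serialize an options report
#'
#' @param report A `pcto_options_report`.
#' @param path JSON output path.
#' @export
write_options_report <- function(report, path) {
  out <- list(index_dp_id = report$index_dp_id,
              cohort_size = report$cohort_size, m = report$m,
              no_baseline = report$no_baseline, rows = report$rows)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Sankey-serializable structure for an options report
#'
#' Nodes: one initial node, one per treatment option, plus `controlled` /
#' `not_controlled` terminals.  Link widths are DP counts (initial ->
#' option = group size, option -> outcome = controlled split), so widths
#' leaving the initial node sum to the cohort size.  Option color classes:
#' `gray` baseline, `dark_green`/`light_green` significant/nonsignificant
#' better, `dark_red`/`light_red` worse.  Labels are
#' `"{decision_label} ({pct}%)"`.
#'
#' @param report A `pcto_options_report`.
#' @return List with `nodes` and `links`, directly JSON-serializable.
#' @export
to_sankey <- function(report) {
  rows <- report$rows
  color_of <- function(k) {
    if (rows$decision_label[k] == "no_change") return("gray")
    dir <- rows$direction[k]
    if (dir == "better") {
      if (rows$significant[k]) "dark_green" else "light_green"
    } else if (dir == "worse") {
      if (rows$significant[k]) "dark_red" else "light_red"
    } else "gray"
  }
  nodes <- data.table::data.table(
    id = c("initial", rows$decision_label, "controlled", "not_controlled"),
    label = c("precision cohort",
              sprintf("%s (%s%%)", rows$decision_label,
                      formatC(rows$pct_controlled, digits = 1,
                              format = "f")),
              "controlled", "not controlled"),
    color = c("black", vapply(seq_len(nrow(rows)), color_of, ""),
              "green", "red"))
  ctrl_n <- round_half_away(rows$n * rows$pct_controlled / 100)
  links <- data.table::rbindlist(list(
    data.table::data.table(source = "initial",
                           target = rows$decision_label, value = rows$n),
    data.table::data.table(source = rows$decision_label,
                           target = "controlled", value = ctrl_n),
    data.table::data.table(source = rows$decision_label,
                           target = "not_controlled",
                           value = rows$n - ctrl_n)))
  list(nodes = nodes, links = links[value > 0 | source == "initial"])
}
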