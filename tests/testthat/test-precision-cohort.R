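test_that("filter_candidates keeps exact matches and excludes the index", {
  fX <- data.table(dp_id = c("i", "a", "b", "c", "d"),
                   age60 = c(1, 1, 1, 0, 1),
                   on_acei = c(1, 1, 0, 1, 1))
  expect_setequal(filter_candidates("i", fX), c("a", "d"))
  # no candidate matches -> empty set
  fX2 <- data.table(dp_id = c("i", "a"), age60 = c(1, 0))
  expect_length(filter_candidates("i", fX2), 0)
  # all match -> everything but the index
  fX3 <- data.table(dp_id = c("i", "a", "b"), age60 = c(1, 1, 1))
  expect_setequal(filter_candidates("i", fX3), c("a", "b"))
  expect_error(filter_candidates("zz", fX), "zz")
})

test_that("score_candidates: p99 normalization, capping and order preservation", {
  m <- lsml_model(diag(2), variables = c("x", "y"))
  idx <- c(x = 0, y = 0)
  # identical candidate scores 0
  cand <- rbind(c(0, 0), c(1, 0), c(2, 0))
  colnames(cand) <- c("x", "y")
  sc <- score_candidates(m, idx, cand)
  expect_equal(sc[1], 0)
  # two candidates with raw distances 1 and 2 -> p99 ~ 2 -> 0.5, 1.0
  cand2 <- rbind(c(1, 0), c(2, 0)); colnames(cand2) <- c("x", "y")
  sc2 <- score_candidates(m, idx, cand2)
  expect_equal(sc2, c(1 / 1.99, 1), tolerance = 0.02)
  expect_true(all(sc2 <= 1))
  # ranking by score equals ranking by brute-force raw distance
  set.seed(23)
  cand3 <- matrix(rnorm(200), ncol = 2,
                  dimnames = list(NULL, c("x", "y")))
  raw <- apply(cand3, 1, function(r) sqrt(sum(r^2)))
  expect_equal(order(score_candidates(m, idx, cand3)), order(raw))
  # all-identical candidates -> all zero with warning
  cand4 <- rbind(c(0, 0), c(0, 0)); colnames(cand4) <- c("x", "y")
  expect_warning(sc4 <- score_candidates(m, idx, cand4), "identical")
  expect_equal(sc4, c(0, 0))
})

test_that("standardized_bias matches hand and brute-force arithmetic", {
  # identical means -> 0
  expect_equal(standardized_bias(c(1, 2, 3, 1, 2, 3),
                                 c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)),
               0)
  # means 0.5 vs 0.3, sd_change 0.4 -> |bias| = 0.5
  x <- c(0.1, 0.5)                       # change group: mean .3, sd ~.283
  x <- c(0.3 + 0.4 * c(-1, 1) / sqrt(2)) # exact sd 0.4
  g <- c(TRUE, TRUE, FALSE, FALSE)
  xx <- c(x, 0.5, 0.5)
  expect_equal(abs(standardized_bias(xx, g)), 0.5)
  # 6-row toy table vs direct arithmetic
  v <- c(2, 4, 9, 1, 7, 5); ch <- c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE)
  expect_equal(standardized_bias(v, ch),
               (mean(v[!ch]) - mean(v[ch])) / sd(v[ch]))
  # constant treated covariate with differing means -> NA + warning
  expect_warning(b <- standardized_bias(c(1, 1, 2, 3), c(TRUE, TRUE,
                                                         FALSE, FALSE)),
                 "sd is 0")
  expect_true(is.na(b))
})

test_that("select_threshold follows the grid rule", {
  # construct scores/covariate so that balance grows with the threshold
  set.seed(24)
  n <- 400
  scores <- sort(runif(n))
  conf <- scores * 2 + rnorm(n, 0, 0.1)    # drifts with score
  change <- rbinom(n, 1, 0.5) == 1
  X <- cbind(conf = conf)
  ids <- sprintf("c%03d", seq_len(n))
  ch <- select_threshold(scores, ids, X, change, min_cohort = 50,
                         balance_max = 0.5)
  expect_s3_class(ch, "pcto_cohort")
  expect_false(ch$insufficient)
  expect_true(all(ch$scores[ch$member_ids] <= ch$threshold))
  expect_lte(ch$balance$aggregate, 0.5)
  # profile sizes are non-decreasing in threshold
  expect_true(all(diff(ch$balance_profile$size) >= 0))
  # all thresholds satisfy a loose bound -> full candidate set selected
  ch2 <- select_threshold(scores, ids, X, change, min_cohort = 50,
                          balance_max = 100)
  expect_equal(length(ch2$member_ids), n)
  # impossible balance bound -> min-balance eligible threshold, flagged
  ch3 <- select_threshold(scores, ids, X, change, min_cohort = 50,
                          balance_max = 1e-6)
  expect_true(ch3$balance_violating)
  expect_gte(length(ch3$member_ids), 50)
  prof <- ch3$balance_profile
  eligible <- prof[size >= 50 & !is.na(balance)]
  expect_equal(ch3$balance$aggregate, min(eligible$balance))
  # insufficient candidates
  ch4 <- select_threshold(scores[1:10], ids[1:10], X[1:10, , drop = FALSE],
                          change[1:10], min_cohort = 50)
  expect_true(ch4$insufficient)
  expect_length(ch4$member_ids, 0)
})

test_that("cohort membership is deterministic and filter bias is exactly 0", {
  ws <- small_world(n_patients = 150, seed = 27)
  ds <- build_analysis_dataset(ws$tl, ws$dcfg, max_dps = 800)
  sp <- split_train_score(ds$dps, 300, seed = 1)
  tr <- ds$baseline_X[dp_id %in% sp$train$dp_id]
  y <- sp$train$outcome[match(tr$dp_id, sp$train$dp_id)] == "controlled"
  model <- train_lsml(tr, y)
  ids <- sp$score$dp_id
  sub <- function(X) X[dp_id %in% ids]
  # pick an index DP from the largest filter cohort
  fkey <- apply(as.matrix(sub(ds$filter_X)[, -1]), 1, paste, collapse = "|")
  idx <- ids[fkey == names(sort(table(fkey), decreasing = TRUE))[1]][1]
  c1 <- build_precision_cohort(model, idx, sp$score, sub(ds$baseline_X),
                               sub(ds$filter_X), min_cohort = 30)
  c2 <- build_precision_cohort(model, idx, sp$score, sub(ds$baseline_X),
                               sub(ds$filter_X), min_cohort = 30)
  expect_identical(c1$member_ids, c2$member_ids)
  expect_identical(c1$threshold, c2$threshold)
  expect_false(c1$insufficient)
  # members match the index on every filter variable -> bias exactly 0
  fX <- sub(ds$filter_X)
  mem <- fX[dp_id %in% c1$member_ids]
  for (cl in setdiff(names(fX), "dp_id"))
    expect_true(all(mem[[cl]] == fX[dp_id == idx][[cl]]))
  members <- sp$score[dp_id %in% c1$member_ids]
  ch <- members$decision_label != "no_change"
  if (any(ch) && any(!ch))
    for (cl in setdiff(names(mem), "dp_id"))
      expect_equal(suppressWarnings(standardized_bias(mem[[cl]], ch)), 0)
})
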