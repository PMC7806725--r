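test_that("construct_variables fills each template source correctly", {
  ev <- rbind(
    ev_row("P1", 0, "measurement", "age", 67),
    ev_row("P1", 100, "medication", "lisinopril", action = "start"),
    ev_row("P1", 150, "diagnosis", "dm_dx"),
    ev_row("P1", 170, "measurement", "hba1c", 8.1),
    bp_rows("P1", 180, 150, 95), bp_rows("P1", 200, 150, 95),
    ev_row("P2", 0, "measurement", "age", 40),
    bp_rows("P2", 180, 150, 95), bp_rows("P2", 200, 150, 95))
  tl <- build_timelines(ev)
  dps <- data.table(dp_id = c("P1@x", "P2@x"),
                    patient_id = c("P1", "P2"),
                    index_date = as.Date("2015-01-01") + 200)
  tpl <- list(
    variable_template("on_acei", "medication_active", "lisinopril"),
    variable_template("age", "demographic", "age"),
    variable_template("dm_ever", "diagnosis_ever", "dm_dx",
                      window = "all_history"),
    variable_template("dm_recent", "diagnosis_recent", "dm_dx",
                      window = "past_12m"),
    variable_template("a1c", "lab_latest_value", "hba1c",
                      window = "past_12m"),
    variable_template("a1c_high", "lab_latest_flag", "hba1c",
                      window = "past_12m", op = ">=", threshold = 7))
  X <- suppressMessages(construct_variables(tl, dps, tpl))
  # P2 has no hba1c -> dropped for missingness
  expect_equal(X$dp_id, "P1@x")
  expect_equal(attr(X, "dropped"), "P2@x")
  expect_equal(X$on_acei, 1)     # open interval covers index date
  expect_equal(X$age, 67)
  expect_equal(X$dm_ever, 1)
  expect_equal(X$dm_recent, 1)   # 50 days before index
  expect_equal(X$a1c, 8.1)       # lab 30 days before index, in window
  expect_equal(X$a1c_high, 1)
})

test_that("window boundaries: lab outside past_12m is missing", {
  ev <- rbind(ev_row("P1", 0, "measurement", "hba1c", 9.0),
              ev_row("P1", 400, "encounter", "office_visit"))
  tl <- build_timelines(ev)
  dps <- data.table(dp_id = "P1@x", patient_id = "P1",
                    index_date = as.Date("2015-01-01") + 400)
  tpl12 <- list(variable_template("a1c", "lab_latest_value", "hba1c",
                                  window = "past_12m"))
  tpl14 <- list(variable_template("a1c", "lab_latest_value", "hba1c",
                                  window = "past_14m"))
  expect_equal(nrow(suppressMessages(
    construct_variables(tl, dps, tpl12))), 0)        # 400 > 365
  expect_equal(construct_variables(tl, dps, tpl14)$a1c, 9.0)  # 400 <= 425
})

test_that("stability selection separates informative from noise variables", {
  set.seed(21)
  n <- 800; p_noise <- 12
  X <- matrix(rnorm(n * (3 + p_noise)), n)
  colnames(X) <- c(paste0("inf", 1:3), paste0("noise", 1:p_noise))
  eta <- X[, 1] - X[, 2] + X[, 3]
  y <- rbinom(n, 1, plogis(eta))
  st <- suppressMessages(stability_select(X, y, n_models = 100,
                                          threshold = 75, target_vars = 3,
                                          seed = 3))
  expect_true(all(st[name %in% paste0("inf", 1:3)]$selected))
  expect_gte(mean(!st[grepl("noise", name)]$selected), 0.8)
  expect_true(all(st$frequency >= 0 & st$frequency <= 100))
})

test_that("stability selection input contracts", {
  X <- matrix(rnorm(100 * 3), 100)
  expect_error(stability_select(X, rep(1, 100)), "constant")
  expect_error(stability_select(X[1:10, ], rbinom(10, 1, 0.5),
                                l1_strength = 0.05), "20 rows")
  Xc <- cbind(X, const = 1)
  colnames(Xc) <- c("a", "b", "c", "const")
  y <- rbinom(100, 1, plogis(X[, 1]))
  expect_warning(st <- stability_select(Xc, y, n_models = 20,
                                        threshold = 15,
                                        l1_strength = 0.05, seed = 1),
                 "const")
  expect_equal(st[name == "const"]$frequency, 0)
})

test_that("subsample_frac = 1 makes all models identical (frequency 0 or n_models)", {
  set.seed(5)
  X <- matrix(rnorm(200 * 6), 200)
  colnames(X) <- paste0("v", 1:6)
  y <- rbinom(200, 1, plogis(2 * X[, 1]))
  st <- suppressMessages(stability_select(X, y, n_models = 25,
                                          subsample_frac = 1,
                                          threshold = 20, seed = 2))
  expect_true(all(st$frequency %in% c(0L, 25L)))
})

test_that("frequencies are invariant to column order", {
  set.seed(6)
  X <- matrix(rnorm(300 * 5), 300)
  colnames(X) <- paste0("v", 1:5)
  y <- rbinom(300, 1, plogis(X[, 1] - X[, 4]))
  st1 <- stability_select(X, y, n_models = 30, threshold = 20,
                          l1_strength = 0.03, seed = 7)
  perm <- c(4, 2, 5, 1, 3)
  st2 <- stability_select(X[, perm], y, n_models = 30, threshold = 20,
                          l1_strength = 0.03, seed = 7)
  expect_equal(st1[order(name)]$frequency, st2[order(name)]$frequency)
})

test_that("stronger penalty never increases selection frequencies (trend)", {
  set.seed(8)
  X <- matrix(rnorm(400 * 6), 400)
  colnames(X) <- paste0("v", 1:6)
  y <- rbinom(400, 1, plogis(X[, 1]))
  freqs <- sapply(c(0.01, 0.05, 0.15), function(lam)
    sum(stability_select(X, y, n_models = 25, threshold = 20,
                         l1_strength = lam, seed = 4)$frequency))
  expect_true(all(diff(freqs) <= 0))
})

test_that("correlate_and_cluster single-linkage matches the worked example", {
  set.seed(9)
  n <- 1000
  z <- rnorm(n)
  # chain a-b and b-c above the threshold, a-c below it
  x1 <- z + 0.35 * rnorm(n)
  x2 <- z + 0.35 * rnorm(n)
  x3 <- scale(x2)[, 1] + 0.62 * rnorm(n)
  X <- cbind(a = x1, b = x2, c = x3)
  r <- abs(cor(X))
  # single linkage: a-b and b-c linked at 0.8 -> one cluster despite r(a,c)
  expect_gte(r["a", "b"], 0.8)
  expect_gte(r["b", "c"], 0.8)
  expect_lt(r["a", "c"], 0.8)
  cl <- correlate_and_cluster(X, r_threshold = 0.8)
  expect_equal(length(unique(cl)), 1)
  # brute-force single-linkage check: transitive closure of the r >= 0.8
  # graph has one component
  g <- r >= 0.8
  reach <- g
  for (k in 1:3) reach <- reach | (reach %*% g > 0)
  expect_true(all(reach))

  # identical columns share a cluster; independent noise does not
  Y <- cbind(p = z, q = z, r = rnorm(n), s = rnorm(n))
  cl2 <- correlate_and_cluster(Y, r_threshold = 0.8)
  expect_equal(cl2[["p"]], cl2[["q"]])
  expect_equal(length(unique(cl2)), 3)
  expect_error(correlate_and_cluster(X[, 1, drop = FALSE]), "2 candidate")
})

test_that("approved-variable list overrides the automatic selection", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# reviewed 2020-01-01", "age", "", "sbp_baseline"), f)
  expect_equal(read_approved_variables(f), c("age", "sbp_baseline"))
})
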