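# build a per-survey component frame directly (no MCMC) for bin logic tests
ps_row <- function(person, survey, date, m = 0, a = 0, v = 0) {
  data.frame(person_id = person, survey_id = survey,
             survey_date = as.Date(date), mean_rt = m, rt_adjustment = a,
             log_resid_var = v, n_records = 10)
}

test_that("lag bins follow the half-year interval scheme with closed lower bin", {
  test_date <- as.Date("2023-01-01")
  # day offsets giving lags of exactly 0, 0.3011, 0.5, 0.50103, 6.4012 and
  # 6.6995 years (182.625 days = exactly half of 365.25)
  days <- c(0, 110, 182.625, 183, 2338, 2447)
  ps <- do.call(rbind, lapply(seq_along(days), function(i)
    ps_row("P1", sprintf("S%d", i), test_date - days[i], m = i)))
  sc <- data.frame(person_id = "P1", test_name = "t", score = 55,
                   test_date = test_date)
  bins <- assign_lag_bins(ps, sc)
  # expectations: 0 -> bin 1, 0.3 -> 1, 0.5 -> 1 (boundary closed),
  # 0.501 -> 2, 6.40 -> 13, 6.70 -> dropped
  expect_equal(sort(unique(bins$lag_bin)), c(1L, 2L, 13L))
  expect_equal(sum(bins$n_surveys_in_bin), 5L)  # the 6.7-year survey is gone
  b1 <- bins[bins$lag_bin == 1, ]
  expect_equal(b1$n_surveys_in_bin, 3L)
  expect_equal(b1$mean_rt, mean(c(1, 2, 3)))    # averages within the bin
})

test_that("persons with no pre-test surveys are omitted and counted", {
  test_date <- as.Date("2023-01-01")
  ps <- rbind(ps_row("P1", "S1", "2022-10-01", m = 1),
              ps_row("P2", "S1", "2023-06-01", m = 2))  # after the test
  sc <- data.frame(person_id = c("P1", "P2"), test_name = "t",
                   score = c(50, 60), test_date = test_date)
  bins <- assign_lag_bins(ps, sc)
  expect_equal(unique(bins$person_id), "P1")
  expect_equal(attr(bins, "n_omitted_persons"), 1L)
})

test_that("three surveys in one bin average to the direct mean", {
  test_date <- as.Date("2023-01-01")
  ps <- rbind(ps_row("P1", "S1", test_date - 36, m = 2.1, a = 0.9, v = -1.2),
              ps_row("P1", "S2", test_date - 73, m = 2.5, a = 1.1, v = -1.6),
              ps_row("P1", "S3", test_date - 146, m = 2.9, a = 1.3, v = -2.0))
  sc <- data.frame(person_id = "P1", test_name = "t", score = 55,
                   test_date = test_date)
  bins <- assign_lag_bins(ps, sc)
  expect_equal(nrow(bins), 1L)
  expect_equal(bins$mean_rt, mean(c(2.1, 2.5, 2.9)))
  expect_equal(bins$rt_adjustment, mean(c(0.9, 1.1, 1.3)))
  expect_equal(bins$n_surveys_in_bin, 3L)
})

test_that("cluster-robust SEs match a brute-force sandwich on a fixed toy", {
  set.seed(51)
  G <- 50
  d <- do.call(rbind, lapply(1:G, function(g) {
    nb <- sample(1:3, 1)
    data.frame(person_id = sprintf("P%02d", g), lag_bin = seq_len(nb),
               mean_rt = rnorm(nb), rt_adjustment = rnorm(nb),
               log_resid_var = rnorm(nb),
               n_surveys_in_bin = 1, lag_lo = (seq_len(nb) - 1) * 0.5,
               lag_hi = seq_len(nb) * 0.5)
  }))
  sc <- data.frame(person_id = sprintf("P%02d", 1:G), test_name = "t",
                   score = rnorm(G, 50, 10))
  class(d) <- c("lag_bins", "data.frame")
  res <- lag_moderator_regression(d, sc)
  fit <- res$model
  X <- model.matrix(fit)
  e <- residuals(fit)
  cl <- res$cluster
  # brute force: per-cluster score sums
  meat <- matrix(0, ncol(X), ncol(X))
  for (g in unique(cl)) {
    sg <- colSums(X[cl == g, , drop = FALSE] * e[cl == g])
    meat <- meat + tcrossprod(sg)
  }
  B <- solve(crossprod(X))
  V <- B %*% meat %*% B * G / (G - 1)
  expect_equal(unname(res$vcov), unname(V), tolerance = 1e-8,
               ignore_attr = TRUE)
  if (requireNamespace("sandwich", quietly = TRUE)) {
    V2 <- sandwich::vcovCL(fit, cluster = cl, type = "HC0", cadjust = FALSE)
    expect_equal(unname(res$vcov * (G - 1) / G), unname(V2),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("with one observation per cluster the sandwich reduces to HC0 x n/(n-1)", {
  set.seed(52)
  n <- 60
  x <- rnorm(n)
  y <- 1 + 0.5 * x + rnorm(n)
  fit <- lm(y ~ x)
  V <- rtscale:::vcov_cluster(fit, cluster = seq_len(n), cadjust = TRUE)
  X <- model.matrix(fit)
  e <- residuals(fit)
  B <- solve(crossprod(X))
  hc0 <- B %*% t(X) %*% diag(e^2) %*% X %*% B
  expect_equal(unname(V), unname(hc0 * n / (n - 1)), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("a single lag bin reduces exactly to the cross-sectional regression", {
  set.seed(53)
  p <- generate_panel(panel_config(n_persons = 300, n_surveys = 1,
                                   items_per_survey = 2, seed = 54))
  comp <- true_components(p)
  d <- data.frame(person_id = comp$person_id, lag_bin = 1L,
                  mean_rt = comp$mean_rt, rt_adjustment = comp$rt_adjustment,
                  log_resid_var = comp$log_resid_var, n_surveys_in_bin = 1,
                  lag_lo = 0, lag_hi = 0.5)
  class(d) <- c("lag_bins", "data.frame")
  res <- lag_moderator_regression(d, p$scores)
  ref <- regress_components(p$scores, comp)
  for (cp in c("mean_rt", "rt_adjustment", "log_resid_var")) {
    expect_equal(res$per_bin$beta[res$per_bin$component == cp],
                 ref$coefficients$beta[ref$coefficients$term == cp],
                 tolerance = 1e-10)
  }
  expect_true(all(is.na(res$tests$interaction_F)))
})

test_that("stacking conserves rows and no person repeats within a bin", {
  set.seed(55)
  test_date <- as.Date("2023-06-01")
  ps <- do.call(rbind, lapply(1:20, function(i)
    do.call(rbind, lapply(1:6, function(s)
      ps_row(sprintf("P%02d", i), sprintf("S%d", s),
             test_date - s * 70, m = rnorm(1))))))
  sc <- data.frame(person_id = sprintf("P%02d", 1:20), test_name = "t",
                   score = rnorm(20, 50, 10), test_date = test_date)
  bins <- assign_lag_bins(ps, sc)
  expect_false(any(duplicated(bins[, c("person_id", "lag_bin")])))
  expect_equal(sum(bins$n_surveys_in_bin), nrow(ps))
})

test_that("max_stable_lag applies the consecutive-interval rule", {
  mk <- function(ci_lo, ci_hi) {
    data.frame(component = "mean_rt", lag_bin = seq_along(ci_lo),
               lag_lo = (seq_along(ci_lo) - 1) * 0.5,
               lag_hi = seq_along(ci_lo) * 0.5,
               beta = (ci_lo + ci_hi) / 2, se = 1, t = 1, p = 0.5,
               ci_lo = ci_lo, ci_hi = ci_hi, n = 100)
  }
  # all 13 bins exclude zero -> full 6.5-year span
  expect_equal(unname(max_stable_lag(mk(rep(0.1, 13), rep(0.3, 13)))), 6.5)
  # bins 1-2 exclude, bin 3 includes, bin 4 excludes -> 1.0 year
  expect_equal(unname(max_stable_lag(mk(c(0.1, 0.1, -0.1, 0.1),
                                        c(0.3, 0.3, 0.1, 0.3)))), 1.0)
  # first bin includes zero -> 0
  expect_equal(unname(max_stable_lag(mk(c(-0.1, 0.2), c(0.1, 0.4)))), 0)
  # negative-side exclusion counts too, and a missing bin breaks the run
  pb <- mk(c(-0.4, -0.4, -0.4), c(-0.1, -0.1, -0.1))
  pb$lag_bin <- c(1L, 2L, 4L)
  expect_equal(unname(max_stable_lag(pb)), 1.0)
})

test_that("effect sizes are classified by the .10/.30/.50 conventions", {
  expect_equal(classify_effect_size(c(0.50, -0.30, 0.10, 0.05, -0.75)),
               c("large", "medium", "small", "negligible", "large"))
  expect_error(classify_effect_size(NA_real_))
})

test_that("a lag-limited effect concentrates max_stable_lag at the cutoff", {
  set.seed(56)
  hits <- integer(0)
  for (rep in 1:50) {
    G <- 600
    u <- rnorm(G)
    score <- 50 + 10 * (0.4 * u + rnorm(G, 0, sqrt(1 - 0.16)))
    d <- do.call(rbind, lapply(1:8, function(b) {
      eff <- if (b <= 4) u else rnorm(G)    # signal dies after bin 4
      data.frame(person_id = sprintf("P%03d", 1:G), lag_bin = b,
                 mean_rt = eff + rnorm(G, 0, 0.5),
                 rt_adjustment = rnorm(G), log_resid_var = rnorm(G),
                 n_surveys_in_bin = 1, lag_lo = (b - 1) * 0.5,
                 lag_hi = b * 0.5)
    }))
    class(d) <- c("lag_bins", "data.frame")
    sc <- data.frame(person_id = sprintf("P%03d", 1:G), test_name = "t",
                     score = score)
    res <- lag_moderator_regression(d, sc)
    hits <- c(hits, max_stable_lag(res)["mean_rt"])
  }
  mode_lag <- as.numeric(names(sort(table(hits), decreasing = TRUE))[1])
  expect_equal(mode_lag, 2.0)
})

test_that("per-survey fits tag components by survey and skip small surveys", {
  p <- generate_panel(panel_config(n_persons = 60, n_surveys = 3,
                                   items_per_survey = 25,
                                   tau = diag(c(0.16, 0.04, 0.25)),
                                   seed = 57))
  cl <- log_records(p)
  ti <- ti_truth(p)
  spec <- ls_spec(chains = 2, iterations = 1200, burn_in = 600, seed = 5)
  ps <- fit_per_survey_components(cl, ti, spec)
  expect_setequal(unique(ps$survey_id), c("S01", "S02", "S03"))
  expect_equal(nrow(ps), 180L)
  for (s in unique(ps$survey_id)) {
    sub <- ps[ps$survey_id == s, ]
    truth <- p$person_truth$alpha[match(sub$person_id,
                                        p$person_truth$person_id)]
    expect_gte(cor(sub$mean_rt, truth), 0.8)
  }
  expect_warning(
    fit_per_survey_components(cl, ti, spec, min_items = 26),
    "skipped")
})

test_that("a survey with a single TI value is fitted without the slope", {
  set.seed(58)
  persons <- sprintf("P%02d", 1:30)
  recA <- do.call(rbind, lapply(sprintf("A%02d", 1:12), function(it)
    data.frame(person_id = persons, item_id = it, survey_id = "SA",
               survey_date = as.Date("2021-01-01"),
               log_rt = rnorm(30, 2.3 + (match(it, sprintf("A%02d", 1:12)) - 6) / 10, 0.4))))
  recB <- do.call(rbind, lapply(sprintf("B%02d", 1:12), function(it)
    data.frame(person_id = persons, item_id = it, survey_id = "SB",
               survey_date = as.Date("2021-03-01"),
               log_rt = rnorm(30, 2.5, 0.4))))
  ti <- data.frame(item_id = c(sprintf("A%02d", 1:12), sprintf("B%02d", 1:12)),
                   ti_log = c(2.3 + ((1:12) - 6) / 10, rep(2.5, 12)),
                   ti_se = 0)
  ti$ti_centered <- ti$ti_log - log(10)
  spec <- ls_spec(chains = 2, iterations = 800, burn_in = 400, seed = 6)
  ps <- fit_per_survey_components(rbind(recA, recB), ti, spec)
  expect_true("SB" %in% attr(ps, "slope_omitted"))
  expect_true(all(is.na(ps$rt_adjustment[ps$survey_id == "SB"])))
  expect_true(all(is.finite(ps$rt_adjustment[ps$survey_id == "SA"])))
})
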