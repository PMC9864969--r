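test_that("a single standardized predictor's beta equals the Pearson correlation", {
  set.seed(41)
  n <- 200
  comp <- data.frame(person_id = sprintf("P%03d", 1:n),
                     mean_rt = rnorm(n))
  scores <- data.frame(person_id = comp$person_id, test_name = "t",
                       score = 0.4 * comp$mean_rt + rnorm(n))
  fit <- regress_components(scores, comp)
  r <- cor(comp$mean_rt, scores$score)
  beta <- fit$coefficients$beta[fit$coefficients$term == "mean_rt"]
  expect_equal(beta, r, tolerance = 1e-10)
})

test_that("F, t and R-squared match a from-scratch linear-algebra computation", {
  set.seed(42)
  n <- 40
  comp <- data.frame(person_id = sprintf("P%02d", 1:n),
                     mean_rt = rnorm(n), rt_adjustment = rnorm(n),
                     log_resid_var = rnorm(n))
  scores <- data.frame(person_id = comp$person_id, test_name = "t",
                       score = with(comp, -0.3 * mean_rt + 0.5 * rt_adjustment)
                       + rnorm(n))
  fit <- regress_components(scores, comp)
  z <- function(v) (v - mean(v)) / sd(v)
  X <- cbind(1, z(comp$mean_rt), z(comp$rt_adjustment), z(comp$log_resid_var))
  y <- z(scores$score)
  b <- solve(crossprod(X), crossprod(X, y))
  e <- y - X %*% b
  s2 <- sum(e^2) / (n - 4)
  se <- sqrt(diag(s2 * solve(crossprod(X))))
  tval <- as.numeric(b) / se
  R2 <- 1 - sum(e^2) / sum((y - mean(y))^2)
  Fval <- (R2 / 3) / ((1 - R2) / (n - 4))
  expect_equal(fit$coefficients$beta, as.numeric(b), tolerance = 1e-8)
  expect_equal(fit$coefficients$t, tval, tolerance = 1e-8)
  expect_equal(fit$r_squared, R2, tolerance = 1e-8)
  expect_equal(fit$F, Fval, tolerance = 1e-8)
})

test_that("a score built as an exact linear function of one component gives r = 1", {
  comp <- data.frame(person_id = sprintf("P%02d", 1:30),
                     mean_rt = seq(-1, 1, length.out = 30))
  scores <- data.frame(person_id = comp$person_id, test_name = "t",
                       score = 50 - 7 * comp$mean_rt)
  ct <- correlate_components(comp, scores)
  expect_equal(ct$r[ct$component == "mean_rt"], -1, tolerance = 1e-12)
  # zero-variance component is reported as an error entry, not a crash
  comp$mean_rt <- 1
  ct2 <- correlate_components(comp, scores)
  expect_true(is.na(ct2$r[ct2$component == "mean_rt"]))
  expect_match(ct2$error[ct2$component == "mean_rt"], "zero variance")
})

test_that("permuting a component against scores destroys the association", {
  set.seed(43)
  p <- generate_panel(panel_config(n_persons = 400, n_surveys = 1,
                                   items_per_survey = 2, seed = 44))
  comp <- true_components(p)
  hits <- 0L
  for (i in 1:100) {
    perm <- comp
    perm$rt_adjustment <- sample(perm$rt_adjustment)
    ct <- correlate_components(perm[, c("person_id", "rt_adjustment")],
                               p$scores)
    if (ct$p > 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 89L)   # binomial(100, .95) 1% lower bound
})

test_that("pure-noise covariates leave component betas essentially unchanged", {
  set.seed(45)
  p <- generate_panel(panel_config(n_persons = 3000, n_surveys = 1,
                                   items_per_survey = 2, seed = 46))
  comp <- true_components(p)
  base <- regress_components(p$scores, comp)
  covs <- data.frame(person_id = comp$person_id,
                     noise1 = rnorm(nrow(comp)), noise2 = rnorm(nrow(comp)))
  full <- regress_components(p$scores, comp, covariates = covs)
  expect_gte(full$r_squared, base$r_squared - 1e-12)
  idx <- match(c("mean_rt", "rt_adjustment", "log_resid_var"),
               base$coefficients$term)
  idx2 <- match(c("mean_rt", "rt_adjustment", "log_resid_var"),
                full$coefficients$term)
  expect_lt(max(abs(full$coefficients$beta[idx2] -
                      base$coefficients$beta[idx])), 0.02)
})

test_that("collinear designs are rejected naming the offending columns", {
  comp <- data.frame(person_id = sprintf("P%02d", 1:20),
                     mean_rt = rnorm(20))
  comp$rt_adjustment <- comp$mean_rt          # exact collinearity
  scores <- data.frame(person_id = comp$person_id, test_name = "t",
                       score = rnorm(20))
  expect_error(regress_components(scores, comp), "rt_adjustment")
})

test_that("identical groups show no moderation", {
  set.seed(47)
  n <- 120
  base <- data.frame(person_id = sprintf("A%03d", 1:n),
                     mean_rt = rnorm(n), rt_adjustment = rnorm(n),
                     log_resid_var = rnorm(n))
  dup <- base
  dup$person_id <- sprintf("B%03d", 1:n)
  comp <- rbind(base, dup)
  sc <- data.frame(person_id = comp$person_id, test_name = "t",
                   score = rep(0.4 * base$rt_adjustment + rnorm(n), 2))
  age <- data.frame(person_id = comp$person_id,
                    age = rep(c(30, 50), each = n))
  mod <- moderated_regression(sc, comp, age, cut = 40)
  expect_lt(max(abs(mod$differences$t)), 1e-8)
})

test_that("a doubled older-group effect is detected by the interaction test", {
  p <- generate_panel(panel_config(n_persons = 2000, n_surveys = 1,
                                   items_per_survey = 2,
                                   age_moderation = 2, seed = 48))
  mod <- moderated_regression(p$scores, true_components(p),
                              p$demographics[, c("person_id", "age")])
  d <- mod$differences
  expect_lt(d$p[d$component == "mean_rt"], 0.05)
  old <- mod$group_betas[mod$group_betas$group == "older", ]
  young <- mod$group_betas[mod$group_betas$group == "younger", ]
  expect_gt(abs(old$beta[old$component == "mean_rt"]),
            abs(young$beta[young$component == "mean_rt"]))
})

test_that("without moderation the interaction test holds its size", {
  rejections <- 0L
  for (i in 1:50) {
    p <- generate_panel(panel_config(n_persons = 500, n_surveys = 1,
                                     items_per_survey = 2,
                                     age_moderation = 1, seed = 1000 + i))
    mod <- moderated_regression(p$scores, true_components(p),
                                p$demographics[, c("person_id", "age")])
    if (mod$differences$p[mod$differences$component == "mean_rt"] < 0.05)
      rejections <- rejections + 1L
  }
  expect_lte(rejections, qbinom(0.995, 50, 0.05))
})

test_that("degenerate groups are rejected", {
  comp <- data.frame(person_id = sprintf("P%02d", 1:20), mean_rt = rnorm(20),
                     rt_adjustment = rnorm(20), log_resid_var = rnorm(20))
  sc <- data.frame(person_id = comp$person_id, test_name = "t",
                   score = rnorm(20))
  age <- data.frame(person_id = comp$person_id, age = rep(30, 20))
  expect_error(moderated_regression(sc, comp, age), "non-empty")
})
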