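#' Correlate person RT components with cognitive scores
#'
#' Pearson correlations (with two-sided p-values) between each RT component
#' and each cognitive test score, matched on `person_id` pairwise-complete.
#'
#' @param components A [extract_person_components()] data frame (or any
#'   frame with `person_id` plus component columns).
#' @param scores Data frame with `person_id`, `test_name`, `score`.
#' @return Data frame with `component`, `test_name`, `r`, `p`, `n`, and an
#'   `error` column flagging undefined correlations (zero variance).
#' @export
correlate_components <- function(components, scores) {
  comps <- intersect(c("mean_rt", "rt_adjustment", "log_resid_var"),
                     names(components))
  out <- list()
  for (tn in unique(scores$test_name)) {
    sc <- scores[scores$test_name == tn, ]
    m <- merge(components, sc, by = "person_id")
    for (cp in comps) {
      x <- m[[cp]]; y <- m$score
      ok <- is.finite(x) & is.finite(y)
      x <- x[ok]; y <- y[ok]
      if (length(x) < 3L || sd(x) < 1e-12 || sd(y) < 1e-12) {
        out[[length(out) + 1L]] <- data.frame(
          component = cp, test_name = tn, r = NA_real_, p = NA_real_,
          n = length(x), error = "undefined (zero variance or n < 3)")
      } else {
        ct <- cor.test(x, y)
        out[[length(out) + 1L]] <- data.frame(
          component = cp, test_name = tn, r = unname(ct$estimate),
          p = ct$p.value, n = length(x), error = NA_character_)
      }
    }
  }
  do.call(rbind, out)
}

#' Standardized multiple regression of a cognitive score on RT components
#'
#' Ordinary least squares on the z-scored outcome and z-scored RT
#' components (standardization uses the analysis subsample of listwise
#' complete cases), so component coefficients are standardized betas.
#' Categorical demographic covariates, if supplied, enter as unstandardized
#' indicator contrasts; continuous covariates (age) are z-scored.
#'
#' @param scores Data frame with `person_id`, `test_name`, `score`.
#' @param components Person components data frame.
#' @param covariates Optional demographics data frame keyed by `person_id`;
#'   all its non-key columns are entered as covariates.
#' @param test Which `test_name` to analyze (default: the first present).
#' @return An object of class `"rt_regression"`: a list with `coefficients`
#'   (term, beta, se, t, p), `F`, `df1`, `df2`, `p`, `r_squared`, `n`, the
#'   underlying `lm` fit, and the outcome name.
#' @export
regress_components <- function(scores, components, covariates = NULL,
                               test = NULL) {
  test <- test %||% scores$test_name[1]
  sc <- scores[scores$test_name == test, c("person_id", "score")]
  m <- merge(components, sc, by = "person_id")
  comps <- intersect(c("mean_rt", "rt_adjustment", "log_resid_var"),
                     names(components))
  comps <- comps[vapply(comps, function(cp) any(is.finite(m[[cp]])), TRUE)]
  if (!is.null(covariates)) m <- merge(m, covariates, by = "person_id")
  covs <- if (is.null(covariates)) character(0)
  else setdiff(names(covariates), "person_id")
  m <- m[complete.cases(m[, c("score", comps, covs)]), ]
  if (nrow(m) <= length(comps) + length(covs) + 1L)
    stop("too few complete cases for regression", call. = FALSE)

  m$score_z <- zscore(m$score)
  for (cp in comps) m[[cp]] <- zscore(m[[cp]])
  for (cv in covs) {
    if (is.numeric(m[[cv]])) m[[cv]] <- zscore(m[[cv]])
    else m[[cv]] <- factor(m[[cv]])
  }
  fm <- as.formula(paste("score_z ~", paste(c(comps, covs), collapse = " + ")))
  fit <- lm(fm, data = m)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("singular design; collinear terms: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  structure(list(
    outcome = test,
    coefficients = data.frame(term = rownames(ct), beta = ct[, 1],
                              se = ct[, 2], t = ct[, 3], p = ct[, 4],
                              row.names = NULL),
    components = comps,
    F = unname(sm$fstatistic[1]),
    df1 = unname(sm$fstatistic[2]), df2 = unname(sm$fstatistic[3]),
    p = pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
           lower.tail = FALSE),
    r_squared = sm$r.squared,
    n = nrow(m),
    model = fit), class = "rt_regression")
}

#' @export
print.rt_regression <- function(x, ...) {
  cat(sprintf("Regression of %s on RT components (n = %d)\n", x$outcome, x$n))
  print(transform(x$coefficients, beta = round(beta, 3), se = round(se, 3),
                  t = round(t, 2), p = signif(p, 3)), row.names = FALSE)
  cat(sprintf("F(%d, %d) = %.2f, R^2 = %.3f, p = %.3g\n", x$df1, x$df2,
              x$F, x$r_squared, x$p))
  invisible(x)
}

#' Age-moderated regression of cognitive scores on RT components
#'
#' Tests whether component-score relationships differ between younger
#' (below `cut` years) and older (at or above `cut`) respondents, using a
#' single model with group-by-component interactions. Within-group
#' standardized betas come from the group-specific (cell-means)
#' parameterization of the same fit; the interaction t statistics are the
#' group-difference tests. Outcome and components are z-scored over the
#' full analysis sample so betas are comparable across groups.
#'
#' @param scores Data frame with `person_id`, `test_name`, `score`.
#' @param components Person components data frame.
#' @param age Either a numeric vector aligned with `components$person_id`
#'   or a data frame with `person_id` and `age` columns.
#' @param cut Age cut in years (default 40).
#' @param test Which `test_name` to analyze.
#' @return An object of class `"rt_moderation"`: list with `group_betas`
#'   (component, group, beta, se, t, p), `differences` (component,
#'   difference t and p), `F`, `r_squared`, `n_young`, `n_old`.
#' @export
moderated_regression <- function(scores, components, age, cut = 40,
                                 test = NULL) {
  test <- test %||% scores$test_name[1]
  if (is.data.frame(age)) {
    agedf <- age[, c("person_id", "age")]
  } else {
    agedf <- data.frame(person_id = components$person_id, age = age)
  }
  sc <- scores[scores$test_name == test, c("person_id", "score")]
  m <- merge(merge(components, sc, by = "person_id"), agedf, by = "person_id")
  comps <- intersect(c("mean_rt", "rt_adjustment", "log_resid_var"),
                     names(components))
  comps <- comps[vapply(comps, function(cp) any(is.finite(m[[cp]])), TRUE)]
  m <- m[complete.cases(m[, c("score", "age", comps)]), ]
  m$group <- factor(ifelse(m$age >= cut, "older", "younger"),
                    levels = c("younger", "older"))
  n_y <- sum(m$group == "younger"); n_o <- sum(m$group == "older")
  if (n_y == 0L || n_o == 0L)
    stop("both age groups must be non-empty at cut ", cut, call. = FALSE)
  if (min(n_y, n_o) < length(comps) + 2L)
    stop("a group has too few observations for the moderation model",
         call. = FALSE)
  m$score_z <- zscore(m$score)
  for (cp in comps) m[[cp]] <- zscore(m[[cp]])

  rhs <- paste(comps, collapse = " + ")
  fit_int <- lm(as.formula(paste("score_z ~ group * (", rhs, ")")), data = m)
  fit_cell <- lm(as.formula(paste("score_z ~ 0 + group + group:(", rhs, ")")),
                 data = m)
  sm_i <- summary(fit_int)$coefficients
  sm_c <- summary(fit_cell)$coefficients

  gb <- do.call(rbind, lapply(comps, function(cp) {
    rows <- paste0("group", c("younger", "older"), ":", cp)
    data.frame(component = cp, group = c("younger", "older"),
               beta = sm_c[rows, 1], se = sm_c[rows, 2],
               t = sm_c[rows, 3], p = sm_c[rows, 4], row.names = NULL)
  }))
  dif <- do.call(rbind, lapply(comps, function(cp) {
    row <- paste0("groupolder:", cp)
    data.frame(component = cp, estimate = sm_i[row, 1], t = sm_i[row, 3],
               p = sm_i[row, 4], row.names = NULL)
  }))
  sm <- summary(fit_int)
  structure(list(
    outcome = test, group_betas = gb, differences = dif,
    F = unname(sm$fstatistic[1]),
    df1 = unname(sm$fstatistic[2]), df2 = unname(sm$fstatistic[3]),
    r_squared = sm$r.squared,
    n_young = n_y, n_old = n_o, cut = cut,
    model = fit_int), class = "rt_moderation")
}

#' @export
print.rt_moderation <- function(x, ...) {
  cat(sprintf("Age-moderated regression of %s (cut %g y): n = %d / %d\n",
              x$outcome, x$cut, x$n_young, x$n_old))
  print(transform(x$group_betas, beta = round(beta, 3), t = round(t, 2)),
        row.names = FALSE)
  cat("Group differences (interaction t):\n")
  print(transform(x$differences, estimate = round(estimate, 3),
                  t = round(t, 2), p = signif(p, 3)), row.names = FALSE)
  invisible(x)
}
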