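#' Fit the location-scale model separately for each survey
#'
#' Estimates the (expanded) location-scale model on each survey's records
#' alone, producing per-survey person component estimates for the lagged
#' analysis. Time intensities are reused from the global
#' [estimate_time_intensities()] fit (two-stage procedure). Surveys with
#' fewer than `min_items` items or fewer than `min_persons` persons are
#' skipped with a warning; a survey whose items share a single TI value
#' cannot identify the TI slope and is fitted without it (its
#' `rt_adjustment` is reported as NA and the survey is flagged).
#'
#' @param records Clean RT records (`person_id`, `item_id`, `survey_id`,
#'   `survey_date`, `log_rt`).
#' @param ti Global `"time_intensity"` table.
#' @param spec An [ls_spec()]; survey s is fitted with seed
#'   `spec$seed + s` so identical data and seeds give identical estimates.
#' @param min_items Minimum items per survey (default 10).
#' @param min_persons Minimum persons per survey (default 10).
#' @return Data frame of per-survey components: `person_id`, `survey_id`,
#'   `survey_date`, `mean_rt`, `rt_adjustment`, `log_resid_var`,
#'   `n_records`, with attributes `skipped` and `slope_omitted`.
#' @export
fit_per_survey_components <- function(records, ti, spec = ls_spec(),
                                      min_items = 10, min_persons = 10) {
  surveys <- sort(unique(records$survey_id))
  out <- list()
  skipped <- character(0)
  slope_omitted <- character(0)
  for (s in seq_along(surveys)) {
    sv <- surveys[s]
    rs <- records[records$survey_id == sv, ]
    n_items <- length(unique(rs$item_id))
    n_pers <- length(unique(rs$person_id))
    if (n_items < min_items || n_pers < min_persons) {
      skipped <- c(skipped, sv)
      next
    }
    spec_s <- spec
    spec_s$seed <- spec$seed + s
    tic <- ti$ti_centered[match(unique(rs$item_id), ti$item_id)]
    expanded <- length(unique(rs$item_id)) >= 2 && sd(tic) > 1e-10
    fit <- if (expanded) fit_expanded_location_scale(rs, ti, spec_s)
    else fit_location_scale(rs, spec_s)
    if (!expanded) slope_omitted <- c(slope_omitted, sv)
    pc <- suppressWarnings(extract_person_components(fit))
    dates <- rs$survey_date[match(pc$person_id, rs$person_id)]
    out[[sv]] <- data.frame(person_id = pc$person_id, survey_id = sv,
                            survey_date = dates,
                            mean_rt = pc$mean_rt,
                            rt_adjustment = pc$rt_adjustment,
                            log_resid_var = pc$log_resid_var,
                            n_records = pc$n_records)
  }
  if (length(skipped))
    warning("surveys skipped (below minimum size): ",
            paste(skipped, collapse = ", "), call. = FALSE)
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  attr(res, "skipped") <- skipped
  attr(res, "slope_omitted") <- slope_omitted
  res
}

#' Assign per-survey components to half-year lag bins
#'
#' Computes, per person, the lag in years between each survey and that
#' person's cognitive test date (`(test_date - survey_date) / 365.25`),
#' drops surveys after the test or more than `max_lag` years before it,
#' maps lags to half-year bins (bin k covers `(0.5(k-1), 0.5k]` years,
#' bin 1 closed at 0), and averages each component within person x bin.
#'
#' @param per_survey Per-survey components from
#'   [fit_per_survey_components()].
#' @param scores Data frame with `person_id`, `test_name`, `test_date`.
#' @param bin_width Bin width in years (default 0.5).
#' @param max_lag Maximum lag retained in years (default 6.5).
#' @param test Which `test_name`'s date to use.
#' @return Data frame of class `"lag_bins"`: `person_id`, `lag_bin`,
#'   `lag_lo`, `lag_hi`, component averages, `n_surveys_in_bin`; attribute
#'   `n_omitted_persons` counts persons with no pre-test surveys.
#' @export
assign_lag_bins <- function(per_survey, scores, bin_width = 0.5,
                            max_lag = 6.5, test = NULL) {
  test <- test %||% scores$test_name[1]
  sc <- scores[scores$test_name == test, c("person_id", "test_date")]
  m <- merge(per_survey, sc, by = "person_id")
  m$lag_years <- as.numeric(m$test_date - m$survey_date) / 365.25
  n_before <- length(unique(m$person_id))
  m <- m[m$lag_years >= 0 & m$lag_years <= max_lag, ]
  n_omitted <- n_before - length(unique(m$person_id))
  m$lag_bin <- pmax(1L, as.integer(ceiling(m$lag_years / bin_width - 1e-9)))

  agg <- aggregate(m[, c("mean_rt", "rt_adjustment", "log_resid_var")],
                   by = list(person_id = m$person_id, lag_bin = m$lag_bin),
                   FUN = function(v) mean(v, na.rm = TRUE))
  cnt <- aggregate(list(n_surveys_in_bin = m$survey_id),
                   by = list(person_id = m$person_id, lag_bin = m$lag_bin),
                   FUN = length)
  out <- merge(agg, cnt, by = c("person_id", "lag_bin"))
  out$lag_lo <- (out$lag_bin - 1L) * bin_width
  out$lag_hi <- out$lag_bin * bin_width
  out <- out[order(out$person_id, out$lag_bin), ]
  rownames(out) <- NULL
  attr(out, "n_omitted_persons") <- n_omitted
  class(out) <- c("lag_bins", "data.frame")
  out
}

#' Lag-as-moderator regression with cluster-robust standard errors
#'
#' Stacks one row per person x lag bin (the cognitive score repeated across
#' a person's rows) and regresses the z-scored score on the z-scored RT
#' components, lag bin (categorical), and component-by-bin interactions,
#' parameterized cell-means style so each coefficient is directly the
#' component's standardized beta within one bin. Because the outcome
#' repeats within persons, standard errors come from a cluster-robust
#' sandwich estimator with clusters = persons (CR0 meat with a `G/(G-1)`
#' small-sample factor); per-bin confidence intervals use t(G-1) quantiles
#' and the component-by-lag interaction is a cluster-robust Wald F test.
#'
#' @param bins A `"lag_bins"` data frame.
#' @param scores Data frame with `person_id`, `test_name`, `score`.
#' @param test Which `test_name` to analyze.
#' @param conf_level Confidence level for per-bin CIs (default 0.95).
#' @param cadjust Apply the `G/(G-1)` small-sample factor (default TRUE).
#' @param min_clusters Bins with fewer persons are excluded with a warning.
#' @return Object of class `"lag_regression"`: `per_bin` (component,
#'   lag_bin, lag_lo, lag_hi, beta, se, t, p, ci_lo, ci_hi, n), `tests`
#'   (per component: main-effect F and interaction F with df and p),
#'   `n_persons`, `n_rows`, the `lm` fit and robust `vcov`.
#' @export
lag_moderator_regression <- function(bins, scores, test = NULL,
                                     conf_level = 0.95, cadjust = TRUE,
                                     min_clusters = 2) {
  test <- test %||% scores$test_name[1]
  sc <- scores[scores$test_name == test, c("person_id", "score")]
  m <- merge(as.data.frame(bins), sc, by = "person_id")
  comps <- c("mean_rt", "rt_adjustment", "log_resid_var")
  comps <- comps[vapply(comps, function(cp) any(is.finite(m[[cp]])), TRUE)]
  m <- m[complete.cases(m[, c("score", comps)]), ]

  bin_sizes <- tapply(m$person_id, m$lag_bin, function(p) length(unique(p)))
  bad <- names(bin_sizes)[bin_sizes < min_clusters]
  if (length(bad)) {
    warning("lag bins excluded (fewer than ", min_clusters, " persons): ",
            paste(bad, collapse = ", "), call. = FALSE)
    m <- m[!(m$lag_bin %in% as.integer(bad)), ]
  }
  if (!nrow(m)) stop("no usable lag bins", call. = FALSE)
  used_bins <- sort(unique(m$lag_bin))

  # outcome standardized over persons, components over stacked rows
  pers <- m[!duplicated(m$person_id), ]
  mu_y <- mean(pers$score); sd_y <- sd(pers$score)
  if (!is.finite(sd_y) || sd_y < 1e-12)
    stop("outcome has zero variance", call. = FALSE)
  m$score_z <- (m$score - mu_y) / sd_y
  for (cp in comps) m[[cp]] <- zscore(m[[cp]])

  # cell-means design built explicitly (valid even with a single bin):
  # one dummy per bin plus per-bin component slopes
  bin_cols <- paste0("bin", used_bins)
  for (b in used_bins) m[[paste0("bin", b)]] <- as.numeric(m$lag_bin == b)
  slope_cols <- character(0)
  for (cp in comps) for (b in used_bins) {
    cn <- paste0("bin", b, "_", cp)
    m[[cn]] <- m[[paste0("bin", b)]] * m[[cp]]
    slope_cols <- c(slope_cols, cn)
  }
  fit <- lm(score_z ~ 0 + ., data = m[, c("score_z", bin_cols, slope_cols)])
  V <- vcov_cluster(fit, m$person_id, cadjust = cadjust)
  G <- attr(V, "n_clusters")
  cf <- coef(fit)
  tq <- qt(1 - (1 - conf_level) / 2, G - 1)

  per_bin <- list()
  bin_width <- if ("lag_hi" %in% names(m))
    (m$lag_hi - m$lag_lo)[1] else 0.5
  for (cp in comps) for (b in used_bins) {
    nm <- paste0("bin", b, "_", cp)
    est <- cf[nm]; se <- sqrt(V[nm, nm])
    per_bin[[length(per_bin) + 1L]] <- data.frame(
      component = cp, lag_bin = b,
      lag_lo = (b - 1L) * bin_width, lag_hi = b * bin_width,
      beta = unname(est), se = se, t = unname(est / se),
      p = 2 * pt(abs(est / se), G - 1, lower.tail = FALSE),
      ci_lo = unname(est - tq * se), ci_hi = unname(est + tq * se),
      n = sum(m$lag_bin == b))
  }
  per_bin <- do.call(rbind, per_bin)

  tests <- list()
  B <- length(used_bins)
  for (cp in comps) {
    idx <- match(paste0("bin", used_bins, "_", cp), names(cf))
    Rm <- matrix(0, 1, length(cf))
    Rm[1, idx] <- 1 / B                       # average slope = 0
    main <- wald_test(cf, V, Rm, df2 = G - 1)
    inter <- NULL
    if (B >= 2) {
      Ri <- matrix(0, B - 1, length(cf))
      for (r in seq_len(B - 1)) {
        Ri[r, idx[1]] <- 1
        Ri[r, idx[r + 1]] <- -1               # slope equality across bins
      }
      inter <- wald_test(cf, V, Ri, df2 = G - 1)
    }
    tests[[cp]] <- data.frame(
      component = cp,
      main_F = main$F, main_df1 = main$df1, main_df2 = main$df2,
      main_p = main$p,
      interaction_F = inter$F %||% NA_real_,
      interaction_df1 = inter$df1 %||% NA_real_,
      interaction_df2 = inter$df2 %||% NA_real_,
      interaction_p = inter$p %||% NA_real_)
  }
  structure(list(
    outcome = test,
    per_bin = per_bin,
    tests = do.call(rbind, c(tests, make.row.names = FALSE)),
    n_persons = G, n_rows = nrow(m),
    conf_level = conf_level,
    cluster = m$person_id,
    model = fit, vcov = V), class = "lag_regression")
}

#' @export
print.lag_regression <- function(x, ...) {
  cat(sprintf("Lag-as-moderator regression of %s: %d persons, %d rows\n",
              x$outcome, x$n_persons, x$n_rows))
  print(transform(x$per_bin, beta = round(beta, 3), se = round(se, 3),
                  t = round(t, 2), p = signif(p, 2),
                  ci_lo = round(ci_lo, 3), ci_hi = round(ci_hi, 3)),
        row.names = FALSE)
  cat("Component tests (cluster-robust Wald):\n")
  print(x$tests, row.names = FALSE)
  invisible(x)
}

#' Maximum stable lag per RT component
#'
#' The longest run of consecutive half-year lag bins, starting at bin 1,
#' whose confidence intervals all exclude zero; reported in years
#' (`0.5 * k` for a run of k bins). A missing bin breaks the run; if the
#' first bin's CI includes zero the result is 0.
#'
#' @param result A `"lag_regression"` object or its `per_bin` data frame.
#' @param bin_width Bin width in years (default 0.5).
#' @return Named numeric vector of years, one entry per component.
#' @export
max_stable_lag <- function(result, bin_width = 0.5) {
  pb <- if (inherits(result, "lag_regression")) result$per_bin else result
  comps <- unique(pb$component)
  out <- setNames(numeric(length(comps)), comps)
  for (cp in comps) {
    d <- pb[pb$component == cp, ]
    d <- d[order(d$lag_bin), ]
    k <- 0L
    repeat {
      row <- d[d$lag_bin == k + 1L, ]
      if (nrow(row) != 1L) break
      if (!(row$ci_lo > 0 || row$ci_hi < 0)) break
      k <- k + 1L
    }
    out[cp] <- k * bin_width
  }
  out
}

#' Classify a standardized coefficient by conventional effect size
#'
#' Thresholds on the absolute value: >= .50 large, >= .30 medium,
#' >= .10 small, otherwise negligible.
#'
#' @param value Numeric vector of standardized coefficients.
#' @return Character vector of classifications.
#' @export
classify_effect_size <- function(value) {
  stopifnot(all(is.finite(value)))
  a <- abs(value)
  ifelse(a >= 0.50, "large",
         ifelse(a >= 0.30, "medium",
                ifelse(a >= 0.10, "small", "negligible")))
}

#' Plot standardized coefficients against lag bin
#'
#' One panel per RT component: per-bin standardized betas with their
#' confidence intervals, against the lag (years before the cognitive
#' test).
#'
#' @param result A `"lag_regression"` object.
#' @param file Optional PNG path; when given the plot is written there.
#' @return Invisibly, the `per_bin` table.
#' @export
plot_lag_coefficients <- function(result, file = NULL) {
  pb <- result$per_bin
  comps <- unique(pb$component)
  if (!is.null(file)) grDevices::png(file, width = 900, height = 320)
  op <- graphics::par(mfrow = c(1, length(comps)), mar = c(4, 4, 2, 1))
  on.exit({ graphics::par(op); if (!is.null(file)) grDevices::dev.off() })
  for (cp in comps) {
    d <- pb[pb$component == cp, ]
    mid <- (d$lag_lo + d$lag_hi) / 2
    plot(mid, d$beta, ylim = range(c(d$ci_lo, d$ci_hi, 0)),
         xlab = "lag before test (years)", ylab = "standardized beta",
         main = cp, pch = 19)
    graphics::segments(mid, d$ci_lo, mid, d$ci_hi)
    graphics::abline(h = 0, lty = 2)
  }
  invisible(pb)
}
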