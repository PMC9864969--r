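#' Configuration for the synthetic survey RT panel
#'
#' Bundles and validates all parameters of the synthetic panel generator.
#' Defaults emulate a web panel in which respondents answer batteries of
#' survey items every two months over several years, with log response times
#' (natural log of seconds) generated from a mixed-effects location-scale
#' model: person random effects on mean log RT, on the slope linking log RT
#' to item time intensity (TI), and on the log residual variance.
#'
#' The default fixed intercept (2.33 log seconds) and TI distribution (mean
#' 2.29 log seconds, truncated to 1.14-4.04) match the marginal summaries
#' typical of such panels; `omega` defaults to -1.66 so that the implied
#' marginal SD of pooled log RT is close to 0.79.
#'
#' @param n_persons Number of persons.
#' @param n_surveys Number of surveys per person.
#' @param items_per_survey Items in each survey.
#' @param survey_interval_days Days between consecutive surveys (default 60,
#'   i.e. roughly two-month intervals).
#' @param gamma00 Fixed intercept: expected log RT (log seconds) for an item
#'   with TI equal to the 10-second reference.
#' @param gamma10 Fixed slope of log RT on centered TI (unitless).
#' @param omega Intercept of the log residual variance.
#' @param tau 3x3 covariance matrix of the person random effects
#'   (u0 = mean, u1 = TI slope, u2 = log residual variance). Must be
#'   symmetric positive semidefinite. The default has SDs (0.4, 0.2, 0.5)
#'   with correlations cor(u0,u1) = 0.25 and cor(u1,u2) = 0.14, which makes
#'   the default cognitive-score coefficients and `r2_cog` mutually
#'   consistent (see Details).
#' @param ti_mean,ti_sd Mean and SD (log seconds) of the item TI
#'   distribution before truncation.
#' @param ti_range Length-2 truncation bounds for TI (log seconds).
#' @param beta_cog Length-3 vector of standardized effects of (u0, u1, u2)
#'   on the cognitive score.
#' @param r2_cog Proportion of cognitive-score variance explained by the
#'   latent RT components.
#' @param contamination_rate Fraction of RT records replaced by extreme
#'   outliers (seconds multiplied by Uniform(10, 50)). Must be < 0.1.
#' @param age_moderation Multiplier applied to the u0 effect on the
#'   cognitive score for persons aged 40+ (1 = no moderation).
#' @param test_name Name of the generated cognitive test.
#' @param start_date Calendar date at which panel entry begins; entries are
#'   staggered uniformly over the following two years.
#' @param seed Integer seed; the generator is fully reproducible given the
#'   seed and configuration.
#'
#' @details The cognitive score for person j is
#' `50 + 10 * (sum_k beta_cog[k] * z_kj + e_j)` where `z_kj = u_kj /
#' sqrt(tau[k,k])` are the population-standardized latents and the noise
#' variance is chosen so that the latent signal explains exactly `r2_cog` of
#' the score variance. When `beta_cog' R beta_cog` (with R the latent
#' correlation matrix) equals `r2_cog` — as under the defaults — the true
#' standardized regression coefficients equal `beta_cog` exactly; otherwise
#' they are scaled by `sqrt(r2_cog / (beta_cog' R beta_cog))`.
#'
#' @return A validated list of class `"panel_config"`.
#' @export
panel_config <- function(n_persons = 200,
                         n_surveys = 12,
                         items_per_survey = 25,
                         survey_interval_days = 60,
                         gamma00 = 2.33,
                         gamma10 = 1.0,
                         omega = -1.66,
                         tau = default_tau(),
                         ti_mean = 2.29,
                         ti_sd = 0.5,
                         ti_range = c(1.14, 4.04),
                         beta_cog = c(-0.28, 0.50, -0.15),
                         r2_cog = 0.26,
                         contamination_rate = 0,
                         age_moderation = 1,
                         test_name = "number_series",
                         start_date = as.Date("2016-01-01"),
                         seed = 1L) {
  cfg <- list(n_persons = as.integer(n_persons),
              n_surveys = as.integer(n_surveys),
              items_per_survey = as.integer(items_per_survey),
              survey_interval_days = as.integer(survey_interval_days),
              gamma00 = gamma00, gamma10 = gamma10, omega = omega,
              tau = tau, ti_mean = ti_mean, ti_sd = ti_sd,
              ti_range = ti_range, beta_cog = beta_cog, r2_cog = r2_cog,
              contamination_rate = contamination_rate,
              age_moderation = age_moderation, test_name = test_name,
              start_date = as.Date(start_date), seed = as.integer(seed))
  validate_panel_config(cfg)
  class(cfg) <- "panel_config"
  cfg
}

#' Default person random-effect covariance matrix
#'
#' Variances (0.16, 0.04, 0.25) for (mean log RT, TI slope, log residual
#' variance) with cor(u0,u1) = 0.25 and cor(u1,u2) = 0.14.
#' @return A 3x3 covariance matrix.
#' @export
default_tau <- function() {
  sds <- c(0.4, 0.2, 0.5)
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.25
  R[2, 3] <- R[3, 2] <- 0.14
  diag(sds) %*% R %*% diag(sds)
}

validate_panel_config <- function(cfg) {
  stopifnot(cfg$n_persons >= 0, cfg$n_surveys >= 1, cfg$items_per_survey >= 1,
            cfg$survey_interval_days >= 1)
  check_psd(cfg$tau, "tau")
  if (nrow(cfg$tau) != 3L)
    stop("'tau' must be 3x3 (mean, slope, log residual variance)", call. = FALSE)
  if (cfg$contamination_rate < 0 || cfg$contamination_rate >= 0.1)
    stop("'contamination_rate' must be in [0, 0.1)", call. = FALSE)
  if (cfg$r2_cog < 0 || cfg$r2_cog > 1)
    stop("'r2_cog' must be in [0, 1]", call. = FALSE)
  if (length(cfg$ti_range) != 2L || cfg$ti_range[1] >= cfg$ti_range[2])
    stop("'ti_range' must be increasing bounds", call. = FALSE)
  if (length(cfg$beta_cog) != 3L)
    stop("'beta_cog' must have length 3", call. = FALSE)
  invisible(TRUE)
}

# Truncated-normal draws by inverse-CDF; degenerate sd = 0 returns the mean.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd < 1e-12) return(rep(mean, n))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# Demographic marginals of a large US internet panel (proportions).
demographic_marginals <- function() {
  list(
    age = list(breaks = list(c(18, 34), c(35, 44), c(45, 54), c(55, 64),
                             c(65, 74), c(75, 90)),
               prob = c(0.2063, 0.2061, 0.1801, 0.1955, 0.1482, 0.0637)),
    gender = list(levels = c("man", "woman"), prob = c(0.4112, 0.5888)),
    race_ethnicity = list(levels = c("non_hispanic_white", "hispanic",
                                     "other_mixed"),
                          prob = c(0.6361, 0.1778, 0.1860)),
    education = list(levels = c("hs_or_less", "some_college", "college_grad"),
                     prob = c(0.2327, 0.3745, 0.3928)),
    income = list(levels = c("lt25k", "25_50k", "50_75k", "75_100k",
                             "ge100k"),
                  prob = c(0.2064, 0.2204, 0.1863, 0.1333, 0.2536)))
}

#' Generate a synthetic survey response-time panel
#'
#' Simulates a persons-by-items-by-surveys panel from the expanded
#' location-scale generative model. For each person j a triple
#' `(u0j, u1j, u2j)` is drawn from MVN(0, tau); for each item i a time
#' intensity `TI_i` is drawn from a truncated normal; then
#' `log RT_ij = gamma00 + u0j + (gamma10 + u1j) * (TI_i - ln 10) + r_ij`
#' with `r_ij ~ N(0, exp(omega + u2j))`, and `RT` in seconds is
#' `exp(log RT)`. Cognitive scores are linear functions of the standardized
#' latents on a T-score metric (mean 50, SD 10); see [panel_config()].
#'
#' Panel entry is staggered uniformly over the first two years; each person
#' then completes every survey at `survey_interval_days` spacing, and takes
#' the cognitive test 1-60 days after their final survey (all persons
#' complete at least five surveys before testing whenever
#' `n_surveys >= 5`). A `contamination_rate` fraction of records has the
#' recorded seconds multiplied by Uniform(10, 50), mimicking respondents
#' stepping away from the screen.
#'
#' @param config A [panel_config()] object.
#' @return A list of class `"synthetic_panel"` with elements `rt_records`
#'   (person_id, item_id, survey_id, survey_date, rt_seconds, contaminated),
#'   `items` (item metadata with `single_page` and `open_ended` flags),
#'   `item_truth` (true TIs), `person_truth` (true u's, alpha, beta,
#'   sigma2), `scores`, `demographics`, `survey_dates`, and the `config`.
#' @export
generate_panel <- function(config = panel_config()) {
  validate_panel_config(config)
  set.seed(config$seed)
  J <- config$n_persons
  S <- config$n_surveys
  I <- config$items_per_survey * S
  if (J == 0L) return(empty_panel(config))
  person_id <- sprintf("P%04d", seq_len(J))
  item_id <- sprintf("I%04d", seq_len(I))
  survey_of_item <- sprintf("S%02d", rep(seq_len(S), each = config$items_per_survey))
  survey_id <- sprintf("S%02d", seq_len(S))

  # person latents
  u <- MASS::mvrnorm(J, mu = rep(0, 3), Sigma = config$tau)
  u <- matrix(u, nrow = J)
  alpha <- config$gamma00 + u[, 1]
  beta <- config$gamma10 + u[, 2]
  sigma2 <- exp(config$omega + u[, 3])

  # item time intensities (log seconds), truncated normal
  ti_true <- rtruncnorm(I, config$ti_mean, config$ti_sd,
                        config$ti_range[1], config$ti_range[2])
  ti_c <- ti_true - log(10)

  # survey calendar: staggered entry, then fixed spacing
  entry <- config$start_date + floor(runif(J, 0, 730))
  survey_dates <- data.frame(
    person_id = rep(person_id, each = S),
    survey_id = rep(survey_id, J),
    survey_date = rep(entry, each = S) +
      rep((seq_len(S) - 1L) * config$survey_interval_days, J))

  # response times: every person answers every item of every survey
  n_rec <- J * I
  pidx <- rep(seq_len(J), each = I)
  iidx <- rep(seq_len(I), J)
  mu_log <- alpha[pidx] + beta[pidx] * ti_c[iidx]
  log_rt <- mu_log + rnorm(n_rec, 0, sqrt(sigma2[pidx]))
  rt_seconds <- exp(log_rt)
  contaminated <- if (config$contamination_rate > 0)
    rbinom(n_rec, 1L, config$contamination_rate) else integer(n_rec)
  if (any(contaminated == 1L)) {
    k <- which(contaminated == 1L)
    rt_seconds[k] <- rt_seconds[k] * runif(length(k), 10, 50)
  }
  rec_date <- survey_dates$survey_date[
    match(paste(person_id[pidx], survey_of_item[iidx]),
          paste(survey_dates$person_id, survey_dates$survey_id))]
  rt_records <- data.frame(
    person_id = person_id[pidx],
    item_id = item_id[iidx],
    survey_id = survey_of_item[iidx],
    survey_date = rec_date,
    rt_seconds = rt_seconds,
    contaminated = contaminated)

  # demographics
  dm <- demographic_marginals()
  band <- sample(seq_along(dm$age$prob), J, TRUE, dm$age$prob)
  age <- vapply(band, function(b) {
    r <- dm$age$breaks[[b]]
    r[1] + floor(runif(1, 0, r[2] - r[1] + 1))
  }, 0)
  demographics <- data.frame(
    person_id = person_id,
    age = age,
    gender = sample(dm$gender$levels, J, TRUE, dm$gender$prob),
    race_ethnicity = sample(dm$race_ethnicity$levels, J, TRUE,
                            dm$race_ethnicity$prob),
    education = sample(dm$education$levels, J, TRUE, dm$education$prob),
    income = sample(dm$income$levels, J, TRUE, dm$income$prob))

  # cognitive scores: T-score metric, latents standardized by population SD
  tau_d <- diag(config$tau)
  z <- sapply(1:3, function(k)
    if (tau_d[k] > 1e-12) u[, k] / sqrt(tau_d[k]) else rep(0, J))
  z <- matrix(z, nrow = J)
  bmat <- matrix(rep(config$beta_cog, each = J), nrow = J)
  if (config$age_moderation != 1)
    bmat[age >= 40, 1] <- bmat[age >= 40, 1] * config$age_moderation
  signal <- rowSums(bmat * z)
  # population signal variance under the unmoderated coefficients
  sdv <- sqrt(tau_d)
  Rlat <- diag(3)
  ok <- sdv > 1e-12
  if (all(ok)) Rlat <- diag(1 / sdv) %*% config$tau %*% diag(1 / sdv)
  v_s <- as.numeric(t(config$beta_cog) %*% Rlat %*% config$beta_cog)
  if (!any(ok)) v_s <- 0
  noise_var <- if (config$r2_cog == 0) 1
  else if (config$r2_cog == 1) 0
  else v_s * (1 - config$r2_cog) / config$r2_cog
  if (config$r2_cog == 0) signal <- signal * 0
  score <- 50 + 10 * (signal + rnorm(J, 0, sqrt(noise_var)))

  test_date <- entry + (S - 1L) * config$survey_interval_days +
    1L + floor(runif(J, 0, 60))
  scores <- data.frame(person_id = person_id,
                       test_name = config$test_name,
                       score = score,
                       test_date = test_date)

  structure(list(
    rt_records = rt_records,
    items = data.frame(item_id = item_id, survey_id = survey_of_item,
                       single_page = 1L, open_ended = 0L),
    item_truth = data.frame(item_id = item_id, ti_true = ti_true,
                            ti_true_centered = ti_c),
    person_truth = data.frame(person_id = person_id,
                              u0 = u[, 1], u1 = u[, 2], u2 = u[, 3],
                              alpha = alpha, beta = beta, sigma2 = sigma2,
                              log_resid_var = config$omega + u[, 3]),
    scores = scores,
    demographics = demographics,
    survey_dates = survey_dates,
    config = config), class = "synthetic_panel")
}

# Zero-person panel: every table present with its full header, zero rows.
empty_panel <- function(config) {
  S <- config$n_surveys
  I <- config$items_per_survey * S
  item_id <- sprintf("I%04d", seq_len(I))
  survey_of_item <- sprintf("S%02d", rep(seq_len(S), each = config$items_per_survey))
  chr <- character(0); num <- numeric(0); int <- integer(0)
  dt <- as.Date(character(0))
  structure(list(
    rt_records = data.frame(person_id = chr, item_id = chr, survey_id = chr,
                            survey_date = dt, rt_seconds = num,
                            contaminated = int),
    items = data.frame(item_id = item_id, survey_id = survey_of_item,
                       single_page = 1L, open_ended = 0L),
    item_truth = data.frame(item_id = item_id,
                            ti_true = rep(NA_real_, I),
                            ti_true_centered = rep(NA_real_, I)),
    person_truth = data.frame(person_id = chr, u0 = num, u1 = num, u2 = num,
                              alpha = num, beta = num, sigma2 = num,
                              log_resid_var = num),
    scores = data.frame(person_id = chr, test_name = chr, score = num,
                        test_date = dt),
    demographics = data.frame(person_id = chr, age = num, gender = chr,
                              race_ethnicity = chr, education = chr,
                              income = chr),
    survey_dates = data.frame(person_id = chr, survey_id = chr,
                              survey_date = dt),
    config = config), class = "synthetic_panel")
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat(sprintf("Synthetic RT panel: %d persons, %d surveys, %d items, %d records\n",
              x$config$n_persons, x$config$n_surveys, nrow(x$items),
              nrow(x$rt_records)))
  invisible(x)
}

#' Write a synthetic panel to a directory of CSV files
#'
#' Emits `rt_records.csv`, `items.csv`, `scores.csv`, `demographics.csv`,
#' `survey_dates.csv`, `truth/person_truth.csv`, `truth/item_truth.csv`,
#' and the generating configuration as `config.yaml`. Dates are ISO-8601.
#' The files round-trip losslessly through [read_panel()].
#'
#' @param panel A `"synthetic_panel"` object.
#' @param directory Output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_panel <- function(panel, directory) {
  stopifnot(inherits(panel, "synthetic_panel"))
  dir.create(file.path(directory, "truth"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(directory))
    stop("cannot create directory: ", directory, call. = FALSE)
  files <- c(rt_records = "rt_records.csv", items = "items.csv",
             scores = "scores.csv", demographics = "demographics.csv",
             survey_dates = "survey_dates.csv")
  for (nm in names(files))
    write.csv(panel[[nm]], file.path(directory, files[nm]), row.names = FALSE)
  write.csv(panel$person_truth, file.path(directory, "truth", "person_truth.csv"),
            row.names = FALSE)
  write.csv(panel$item_truth, file.path(directory, "truth", "item_truth.csv"),
            row.names = FALSE)
  cfg <- panel$config
  cfg$tau <- as.numeric(cfg$tau)
  cfg$start_date <- as.character(cfg$start_date)
  yaml::write_yaml(unclass(cfg), file.path(directory, "config.yaml"))
  invisible(c(file.path(directory, files),
              file.path(directory, "truth",
                        c("person_truth.csv", "item_truth.csv")),
              file.path(directory, "config.yaml")))
}

#' Read a panel previously written by [write_panel()]
#'
#' @param directory Directory containing the panel CSV files.
#' @return A list of class `"synthetic_panel"`.
#' @export
read_panel <- function(directory) {
  rd <- function(f, date_cols = character(0)) {
    path <- file.path(directory, f)
    if (!file.exists(path)) stop("missing panel file: ", path, call. = FALSE)
    d <- read.csv(path, stringsAsFactors = FALSE)
    for (dc in intersect(date_cols, names(d))) d[[dc]] <- as.Date(d[[dc]])
    d
  }
  cfg <- yaml::read_yaml(file.path(directory, "config.yaml"))
  cfg$tau <- matrix(unlist(cfg$tau), 3, 3)
  cfg$start_date <- as.Date(cfg$start_date)
  cfg <- do.call(panel_config, cfg[setdiff(names(cfg), NULL)])
  structure(list(
    rt_records = rd("rt_records.csv", "survey_date"),
    items = rd("items.csv"),
    item_truth = rd(file.path("truth", "item_truth.csv")),
    person_truth = rd(file.path("truth", "person_truth.csv")),
    scores = rd("scores.csv", "test_date"),
    demographics = rd("demographics.csv"),
    survey_dates = rd("survey_dates.csv", "survey_date"),
    config = cfg), class = "synthetic_panel")
}
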