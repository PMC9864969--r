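#' Estimate item time intensities from log response times
#'
#' Fits the cross-classified random-effects model
#' `log RT_ij = mu + p_j + q_i + e_ij` with `p_j ~ N(0, sigma_p^2)` (person),
#' `q_i ~ N(0, sigma_q^2)` (item) and `e_ij ~ N(0, sigma_e^2)`, and returns
#' per-item time intensities `ti_log = mu + EB(q_i)` on the log-seconds
#' scale, where EB is the empirical-Bayes (posterior mean) item effect. The
#' time intensity is the RT analogue of item difficulty: the latent expected
#' log time an item requires.
#'
#' Two estimators are provided. `method = "mcmc"` (default) is a fully
#' conjugate Gibbs sampler with diffuse priors (flat on `mu`, inverse-gamma
#' (0.001, 0.001) on the three variances), deterministic given `seed`.
#' `method = "reml"` profiles the model through [lme4::lmer()] and uses the
#' conditional modes (equal to conditional means here) as EB estimates; it
#' is faster and serves as a cross-check.
#'
#' Time intensities are centered at a 10-second reference
#' (`ti_centered = ti_log - ln(reference_seconds)`), so that downstream
#' model intercepts read as the predicted log RT for a 10-second item.
#'
#' @param records Data frame with `person_id`, `item_id`, `log_rt`.
#' @param method `"mcmc"` or `"reml"`.
#' @param reference_seconds Centering reference in seconds (default 10).
#' @param iterations,burn_in MCMC length (kept draws = iterations - burn_in).
#' @param seed Integer seed for the MCMC path.
#' @param flag_min_obs Items with fewer observations are flagged
#'   (`flagged = TRUE`); their TIs are retained but carry high SE.
#' @return A data frame of class `"time_intensity"` with columns `item_id`,
#'   `ti_log`, `ti_centered`, `ti_se`, `n_obs`, `flagged`, and attributes
#'   `mu`, `varcomp` (sigma_p2, sigma_q2, sigma_e2) and `method`.
#' @export
estimate_time_intensities <- function(records,
                                      method = c("mcmc", "reml"),
                                      reference_seconds = 10,
                                      iterations = 2000, burn_in = 1000,
                                      seed = 1L, flag_min_obs = 10) {
  method <- match.arg(method)
  stopifnot(all(c("person_id", "item_id", "log_rt") %in% names(records)))
  items <- sort(unique(records$item_id))
  persons <- unique(records$person_id)
  if (length(items) < 2L)
    stop("at least 2 items are required to estimate time intensities",
         call. = FALSE)
  if (length(persons) < 2L)
    stop("at least 2 persons are required", call. = FALSE)
  comp <- bipartite_components(records$person_id, records$item_id)
  if (max(comp) > 1L)
    stop(sprintf(paste0("person-item design is disconnected ",
                        "(%d components); time intensities are not ",
                        "comparable across components"), max(comp)),
         call. = FALSE)

  y <- records$log_rt
  pf <- factor(records$person_id, levels = persons)
  itf <- factor(records$item_id, levels = items)
  pidx <- as.integer(pf)
  iidx <- as.integer(itf)
  n_obs <- as.integer(table(itf))

  if (method == "reml") {
    fit <- lme4::lmer(y ~ 1 + (1 | pf) + (1 | itf), REML = TRUE)
    mu <- as.numeric(lme4::fixef(fit)[1])
    re <- lme4::ranef(fit, condVar = TRUE)
    qhat <- re$itf[items, 1]
    cv <- as.numeric(attr(re$itf, "postVar"))
    mu_var <- as.numeric(vcov(fit)[1, 1])
    ti_log <- mu + qhat
    ti_se <- sqrt(cv + mu_var)
    vc <- lme4::VarCorr(fit)
    varcomp <- c(sigma_p2 = as.numeric(vc$pf),
                 sigma_q2 = as.numeric(vc$itf),
                 sigma_e2 = attr(vc, "sc")^2)
  } else {
    g <- ti_gibbs(y, pidx, iidx, length(persons), length(items),
                  iterations, burn_in, seed)
    mu <- g$mu
    ti_log <- g$ti_mean
    ti_se <- g$ti_sd
    varcomp <- g$varcomp
  }

  out <- data.frame(item_id = items,
                    ti_log = ti_log,
                    ti_centered = ti_log - log(reference_seconds),
                    ti_se = ti_se,
                    n_obs = n_obs,
                    flagged = n_obs < flag_min_obs)
  rownames(out) <- NULL
  attr(out, "mu") <- mu
  attr(out, "varcomp") <- varcomp
  attr(out, "method") <- method
  class(out) <- c("time_intensity", "data.frame")
  out
}

# Conjugate Gibbs sampler for the crossed random-intercept model.
ti_gibbs <- function(y, pidx, iidx, J, I, iterations, burn_in, seed) {
  set.seed(seed)
  n <- length(y)
  np <- tabulate(pidx, J)
  ni <- tabulate(iidx, I)
  mu <- mean(y)
  p <- as.numeric(rowsum(y - mu, pidx)[, 1] / np)
  q <- rep(0, I)
  s2e <- var(y - mu - p[pidx])
  if (!is.finite(s2e) || s2e < 1e-8) s2e <- 1e-4
  s2p <- max(var(p), 1e-4)
  s2q <- 0.1
  a0 <- b0 <- 0.001
  keep <- iterations - burn_in
  ti_sum <- ti_sum2 <- rep(0, I)
  mu_sum <- 0
  vc_sum <- c(0, 0, 0)
  for (it in seq_len(iterations)) {
    # person effects
    rp <- rowsum(y - mu - q[iidx], pidx)[, 1]
    prec <- np / s2e + 1 / s2p
    p <- rnorm(J, (rp / s2e) / prec, sqrt(1 / prec))
    # item effects
    ri <- rowsum(y - mu - p[pidx], iidx)[, 1]
    prec <- ni / s2e + 1 / s2q
    q <- rnorm(I, (ri / s2e) / prec, sqrt(1 / prec))
    # grand mean (flat prior)
    r <- y - p[pidx] - q[iidx]
    mu <- rnorm(1, mean(r), sqrt(s2e / n))
    # variances
    ss <- sum((r - mu)^2)
    s2e <- 1 / stats::rgamma(1, a0 + n / 2, b0 + ss / 2)
    s2p <- 1 / stats::rgamma(1, a0 + J / 2, b0 + sum(p^2) / 2)
    s2q <- 1 / stats::rgamma(1, a0 + I / 2, b0 + sum(q^2) / 2)
    if (it > burn_in) {
      ti <- mu + q
      ti_sum <- ti_sum + ti
      ti_sum2 <- ti_sum2 + ti^2
      mu_sum <- mu_sum + mu
      vc_sum <- vc_sum + c(s2p, s2q, s2e)
    }
  }
  ti_mean <- ti_sum / keep
  ti_var <- pmax(ti_sum2 / keep - ti_mean^2, 0)
  list(mu = mu_sum / keep, ti_mean = ti_mean, ti_sd = sqrt(ti_var),
       varcomp = setNames(vc_sum / keep,
                          c("sigma_p2", "sigma_q2", "sigma_e2")))
}

#' Re-center time intensities at a reference duration
#'
#' @param ti A `"time_intensity"` data frame.
#' @param reference_seconds Positive reference duration in seconds.
#' @return The input with `ti_centered = ti_log - ln(reference_seconds)`.
#' @export
center_ti <- function(ti, reference_seconds = 10) {
  if (!is.numeric(reference_seconds) || reference_seconds <= 0)
    stop("'reference_seconds' must be positive", call. = FALSE)
  ti$ti_centered <- ti$ti_log - log(reference_seconds)
  ti
}
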