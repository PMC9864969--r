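#' Sampler settings for the location-scale models
#'
#' @param chains Number of MCMC chains (>= 2 so that the potential scale
#'   reduction (PSR) convergence diagnostic is defined).
#' @param iterations Total iterations per chain.
#' @param burn_in Iterations discarded per chain (adaptation happens here).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer seed; chain c uses `seed + c`.
#' @param fixed_effect_var Prior variance of the normal priors on the fixed
#'   effects (gamma00, gamma10, omega). Default 1e6 (diffuse).
#' @param tau_prior_df,tau_prior_scale Inverse-Wishart prior on the random
#'   effect covariance tau; defaults are df = dim + 1 and identity scale.
#' @param psr_threshold Convergence flag threshold on the largest PSR
#'   (default 1.05).
#' @param adapt_target Target Metropolis acceptance rate for the adaptive
#'   random-walk steps (default 0.44, the scalar-update optimum).
#' @return A list of class `"ls_spec"`.
#' @export
ls_spec <- function(chains = 2, iterations = 4000, burn_in = iterations / 2,
                    thin = 1, seed = 1L, fixed_effect_var = 1e6,
                    tau_prior_df = NULL, tau_prior_scale = NULL,
                    psr_threshold = 1.05, adapt_target = 0.44) {
  stopifnot(iterations > burn_in, chains >= 2, thin >= 1)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed),
                 fixed_effect_var = fixed_effect_var,
                 tau_prior_df = tau_prior_df,
                 tau_prior_scale = tau_prior_scale,
                 psr_threshold = psr_threshold,
                 adapt_target = adapt_target), class = "ls_spec")
}

# Per-person sufficient statistics for y = a + b*x + e models.
# With no covariate, x is identically 0 and the b-terms vanish.
ls_suff <- function(records, x = NULL) {
  persons <- unique(records$person_id)
  pf <- factor(records$person_id, levels = persons)
  y <- records$log_rt
  if (is.null(x)) x <- rep(0, length(y))
  M <- rowsum(cbind(1, x, x^2, y, y^2, x * y), pf)
  list(persons = persons, J = length(persons),
       n = M[, 1], Sx = M[, 2], Sxx = M[, 3],
       Sy = M[, 4], Syy = M[, 5], Sxy = M[, 6])
}

# Residual sum of squares per person given person-level (a, b).
ls_ss <- function(st, a, b) {
  pmax(st$Syy - 2 * a * st$Sy - 2 * b * st$Sxy + a^2 * st$n +
         2 * a * b * st$Sx + b^2 * st$Sxx, 0)
}

#' Fit the multilevel location-scale model
#'
#' Fits, by Metropolis-within-Gibbs sampling, the two-level model
#' `log RT_ij = alpha_j + r_ij` with `r_ij ~ N(0, sigma_j^2)`,
#' `alpha_j = gamma00 + u0j`, `log(sigma_j^2) = omega + u1j`, and
#' `(u0j, u1j) ~ MVN(0, tau)`. The model carries random effects on both the
#' person mean ("location") and the log of the person residual variance
#' ("scale"), so individual differences in average log RT and in
#' intraindividual RT variability are estimated jointly.
#'
#' The sampler uses conjugate normal updates for `gamma00` and for
#' `u0j | sigma_j^2`, adaptive random-walk Metropolis updates (targeting
#' ~0.44 acceptance, adaptation frozen after burn-in) for the scale effects
#' `u1j` and `omega`, translation moves that exchange location between the
#' fixed effects and the random-effect means (a mixing device; the
#' likelihood is invariant, so only the priors enter the acceptance ratio),
#' and a conjugate inverse-Wishart update for `tau`. Priors are
#' `N(0, fixed_effect_var)` on fixed effects and inverse-Wishart
#' (identity scale, df = dim + 1) on `tau`. Results are deterministic given
#' `spec$seed`.
#'
#' @param records Data frame with `person_id` and `log_rt`.
#' @param spec An [ls_spec()] object.
#' @return An object of class `"location_scale_fit"`; see
#'   [extract_person_components()] for the person-level summaries. Fields
#'   include posterior means `gamma00`, `omega`, `tau`, per-chain `draws`
#'   matrices, per-parameter `psr`, and `converged`.
#' @export
fit_location_scale <- function(records, spec = ls_spec()) {
  ls_check_records(records)
  st <- ls_suff(records, x = NULL)
  ls_mcmc(st, expanded = FALSE, spec = spec)
}

#' Fit the expanded location-scale model with a time-intensity slope
#'
#' Expands [fit_location_scale()] with a person-specific slope on centered
#' item time intensity (TI): `log RT_ij = alpha_j + beta_j * TIc_i + r_ij`,
#' `beta_j = gamma10 + u1j`, `log(sigma_j^2) = omega + u2j`, and a 3x3
#' random-effect covariance `tau`. The slope separates *systematic RT
#' adjustments* (calibration of speed to item demands) from *residual RT
#' variability* (the remaining person-specific noise level), and the
#' intercept becomes the person's predicted log RT for an item at the TI
#' centering reference (10 seconds).
#'
#' TIs enter as fixed, known covariates from a prior
#' [estimate_time_intensities()] step (two-stage procedure; TI uncertainty
#' is not propagated).
#'
#' @param records Data frame with `person_id`, `item_id`, `log_rt`.
#' @param ti A `"time_intensity"` data frame covering every item observed.
#' @param spec An [ls_spec()] object.
#' @return A `"location_scale_fit"` object with `gamma10` and 3x3 `tau`.
#' @export
fit_expanded_location_scale <- function(records, ti, spec = ls_spec()) {
  ls_check_records(records)
  miss <- setdiff(unique(records$item_id), ti$item_id)
  if (length(miss))
    stop("no time intensity for items: ",
         paste(utils::head(miss, 10), collapse = ", "), call. = FALSE)
  x <- ti$ti_centered[match(records$item_id, ti$item_id)]
  if (sd(x) < 1e-10) {
    if (max(abs(x)) < 1e-10) {
      # TI fixed at the centering reference carries no slope information:
      # the model reduces exactly to the basic location-scale model
      warning("all ti_centered are zero; the TI slope is unidentified ",
              "and the model reduces to the basic location-scale model",
              call. = FALSE)
      return(fit_location_scale(records, spec))
    }
    stop("ti_centered is constant; the TI slope is unidentified",
         call. = FALSE)
  }
  st <- ls_suff(records, x = x)
  ls_mcmc(st, expanded = TRUE, spec = spec)
}

ls_check_records <- function(records) {
  stopifnot(all(c("person_id", "log_rt") %in% names(records)))
  if (length(unique(records$person_id)) < 2L)
    stop("at least 2 persons are required (tau is unidentified otherwise)",
         call. = FALSE)
  if (var(records$log_rt) < 1e-12)
    stop("all log RTs are identical; residual variance is degenerate",
         call. = FALSE)
  invisible(TRUE)
}

# Core sampler. `st` holds per-person sufficient statistics; `expanded`
# switches between the 2-dim (Eq-1 style) and 3-dim random-effect models.
ls_mcmc <- function(st, expanded, spec) {
  J <- st$J
  d <- if (expanded) 3L else 2L    # (u0[, u1], u_scale)
  nu0 <- spec$tau_prior_df %||% (d + 1)
  Psi <- spec$tau_prior_scale %||% diag(d)
  v0 <- spec$fixed_effect_var
  n_keep <- (spec$iterations - spec$burn_in) %/% spec$thin

  par_names <- c("gamma00", if (expanded) "gamma10", "omega",
                 vech_labels(d))
  chains <- vector("list", spec$chains)
  acc <- numeric(spec$chains)
  # person posterior accumulators (pooled over chains)
  a_sum <- a_sum2 <- b_sum <- b_sum2 <- v_sum <- v_sum2 <- rep(0, J)

  # data-driven starting values
  ybar <- st$Sy / st$n
  s2j <- ls_ss(st, ybar, 0) / pmax(st$n - 1, 1)
  s2j <- pmax(s2j, 1e-3)
  if (expanded) {
    sxx_c <- st$Sxx - st$Sx^2 / st$n
    sxy_c <- st$Sxy - st$Sx * st$Sy / st$n
    b_ols <- ifelse(sxx_c > 1e-8, sxy_c / sxx_c, 0)
  }

  for (ch in seq_len(spec$chains)) {
    set.seed(spec$seed + ch)
    shift <- 0.15 * (ch - (spec$chains + 1) / 2)
    gamma00 <- mean(ybar) + shift
    gamma10 <- if (expanded) mean(b_ols) + shift else 0
    omega <- mean(log(s2j)) + shift
    U <- matrix(0, J, d)
    U[, 1] <- ybar - mean(ybar)
    if (expanded) U[, 2] <- b_ols - mean(b_ols)
    U[, d] <- log(s2j) - mean(log(s2j))
    tau <- crossprod(U) / J + diag(0.05, d)

    step_u <- rep(0.5, J)          # RW step for scale effects
    step_w <- 0.1                  # RW step for omega
    step_t <- rep(0.1, d)          # translation-move steps
    acc_n <- acc_d <- 0
    draws <- matrix(NA_real_, n_keep, length(par_names),
                    dimnames = list(NULL, par_names))
    krow <- 0L

    for (it in seq_len(spec$iterations)) {
      adapting <- it <= spec$burn_in
      rate <- min(0.1, 5 / sqrt(it))
      Ti <- solve(tau)

      # --- location effects u_loc | u_scale (conjugate normal) ---
      us <- U[, d]
      vj <- exp(omega + us)
      if (expanded) {
        bvec <- tau[1:2, d]; cc <- tau[d, d]
        m_loc <- outer(us / cc, bvec)                 # J x 2
        S <- tau[1:2, 1:2] - tcrossprod(bvec) / cc
        Q <- solve(S)
        Sz <- st$Sy - gamma00 * st$n - gamma10 * st$Sx
        Szx <- st$Sxy - gamma00 * st$Sx - gamma10 * st$Sxx
        p11 <- st$n / vj + Q[1, 1]
        p12 <- st$Sx / vj + Q[1, 2]
        p22 <- st$Sxx / vj + Q[2, 2]
        h1 <- Sz / vj + Q[1, 1] * m_loc[, 1] + Q[1, 2] * m_loc[, 2]
        h2 <- Szx / vj + Q[1, 2] * m_loc[, 1] + Q[2, 2] * m_loc[, 2]
        det <- p11 * p22 - p12^2
        s11 <- p22 / det; s12 <- -p12 / det; s22 <- p11 / det
        mu1 <- s11 * h1 + s12 * h2
        mu2 <- s12 * h1 + s22 * h2
        L11 <- sqrt(s11); L21 <- s12 / L11
        L22 <- sqrt(pmax(s22 - L21^2, 1e-12))
        z1 <- rnorm(J); z2 <- rnorm(J)
        U[, 1] <- mu1 + L11 * z1
        U[, 2] <- mu2 + L21 * z1 + L22 * z2
      } else {
        m0 <- (tau[1, d] / tau[d, d]) * us
        v_c <- tau[1, 1] - tau[1, d]^2 / tau[d, d]
        Sz <- st$Sy - gamma00 * st$n
        prec <- st$n / vj + 1 / v_c
        U[, 1] <- rnorm(J, (Sz / vj + m0 / v_c) / prec, sqrt(1 / prec))
      }

      # --- scale effects u_scale | u_loc (adaptive RW Metropolis) ---
      a <- gamma00 + U[, 1]
      b <- if (expanded) gamma10 + U[, 2] else rep(0, J)
      SS <- ls_ss(st, a, b)
      A <- tau[-d, -d, drop = FALSE]
      bv <- tau[-d, d]
      Ainvb <- solve(A, bv)
      m2 <- as.numeric(U[, -d, drop = FALSE] %*% Ainvb)
      s2c <- max(tau[d, d] - sum(bv * Ainvb), 1e-10)
      us <- U[, d]
      lt <- function(u) -st$n / 2 * (omega + u) - SS / (2 * exp(omega + u)) -
        (u - m2)^2 / (2 * s2c)
      prop <- us + step_u * rnorm(J)
      lacc <- lt(prop) - lt(us)
      ok <- log(runif(J)) < lacc
      us[ok] <- prop[ok]
      U[, d] <- us
      if (adapting)
        step_u <- step_u * exp(rate * (as.numeric(ok) - spec$adapt_target))
      acc_n <- acc_n + sum(ok); acc_d <- acc_d + J

      # --- fixed effects gamma | u (conjugate) ---
      vj <- exp(omega + us)
      if (expanded) {
        Szu <- st$Sy - U[, 1] * st$n - U[, 2] * st$Sx
        Szxu <- st$Sxy - U[, 1] * st$Sx - U[, 2] * st$Sxx
        p11 <- sum(st$n / vj) + 1 / v0
        p12 <- sum(st$Sx / vj)
        p22 <- sum(st$Sxx / vj) + 1 / v0
        h <- c(sum(Szu / vj), sum(Szxu / vj))
        P <- matrix(c(p11, p12, p12, p22), 2, 2)
        Sig <- solve(P)
        g <- as.numeric(MASS::mvrnorm(1, Sig %*% h, Sig))
        gamma00 <- g[1]; gamma10 <- g[2]
      } else {
        Szu <- st$Sy - U[, 1] * st$n
        prec <- sum(st$n / vj) + 1 / v0
        gamma00 <- rnorm(1, sum(Szu / vj) / prec, sqrt(1 / prec))
      }

      # --- omega | rest (adaptive RW Metropolis) ---
      a <- gamma00 + U[, 1]
      b <- if (expanded) gamma10 + U[, 2] else rep(0, J)
      SS <- ls_ss(st, a, b)
      ltw <- function(w) sum(-st$n / 2 * (w + us) - SS / (2 * exp(w + us))) -
        w^2 / (2 * v0)
      wp <- omega + step_w * rnorm(1)
      ok1 <- log(runif(1)) < ltw(wp) - ltw(omega)
      if (ok1) omega <- wp
      if (adapting) step_w <- step_w * exp(rate * (ok1 - spec$adapt_target))

      # --- translation moves: shift mass between fixed effects and u ---
      # likelihood-invariant; acceptance ratio involves only the priors
      fx <- c(gamma00, if (expanded) gamma10, omega)
      for (k in seq_len(d)) {
        delta <- step_t[k] * rnorm(1)
        dlp <- delta * as.numeric(Ti[k, , drop = FALSE] %*% colSums(U)) -
          J * delta^2 * Ti[k, k] / 2 +
          (fx[k]^2 - (fx[k] + delta)^2) / (2 * v0)
        okk <- log(runif(1)) < dlp
        if (okk) {
          U[, k] <- U[, k] - delta
          fx[k] <- fx[k] + delta
        }
        if (adapting) step_t[k] <- step_t[k] * exp(rate * (okk - spec$adapt_target))
      }
      gamma00 <- fx[1]
      if (expanded) gamma10 <- fx[2]
      omega <- fx[length(fx)]
      us <- U[, d]

      # --- tau | u (conjugate inverse-Wishart) ---
      tau <- rinvwishart(nu0 + J, Psi + crossprod(U))

      if (!adapting && (it - spec$burn_in) %% spec$thin == 0L) {
        krow <- krow + 1L
        draws[krow, ] <- c(gamma00, if (expanded) gamma10, omega, vech(tau))
        aj <- gamma00 + U[, 1]
        bj <- if (expanded) gamma10 + U[, 2] else rep(NA_real_, J)
        lv <- omega + U[, d]
        a_sum <- a_sum + aj; a_sum2 <- a_sum2 + aj^2
        if (expanded) { b_sum <- b_sum + bj; b_sum2 <- b_sum2 + bj^2 }
        v_sum <- v_sum + lv; v_sum2 <- v_sum2 + lv^2
      }
    }
    chains[[ch]] <- draws[seq_len(krow), , drop = FALSE]
    acc[ch] <- acc_n / acc_d
  }

  nk <- sum(vapply(chains, nrow, 0L))
  post_mean <- colMeans(do.call(rbind, chains))
  psr <- psr_matrix(chains)
  pm_sd <- function(s, s2) sqrt(pmax(s2 / nk - (s / nk)^2, 0))
  person <- data.frame(
    person_id = st$persons,
    mean_rt = a_sum / nk, mean_rt_sd = pm_sd(a_sum, a_sum2),
    rt_adjustment = if (expanded) b_sum / nk else NA_real_,
    rt_adjustment_sd = if (expanded) pm_sd(b_sum, b_sum2) else NA_real_,
    log_resid_var = v_sum / nk, log_resid_var_sd = pm_sd(v_sum, v_sum2),
    n_records = as.numeric(st$n))

  tau_hat <- unvech(post_mean[vech_labels(d)], d)
  structure(list(
    model = if (expanded) "expanded_location_scale" else "location_scale",
    expanded = expanded,
    gamma00 = unname(post_mean["gamma00"]),
    gamma10 = if (expanded) unname(post_mean["gamma10"]) else NULL,
    omega = unname(post_mean["omega"]),
    tau = tau_hat,
    draws = chains,
    psr = psr,
    converged = all(psr < spec$psr_threshold, na.rm = TRUE),
    accept_rate = mean(acc),
    person = person,
    n_persons = J,
    n_records = sum(st$n),
    spec = spec), class = "location_scale_fit")
}

#' @export
print.location_scale_fit <- function(x, ...) {
  cat(sprintf("%s fit: %d persons, %d records\n", x$model, x$n_persons,
              x$n_records))
  cat(sprintf("  gamma00 = %.3f%s, omega = %.3f\n", x$gamma00,
              if (x$expanded) sprintf(", gamma10 = %.3f", x$gamma10) else "",
              x$omega))
  cat("  tau:\n")
  print(round(x$tau, 4))
  cat(sprintf("  max PSR = %.3f (%s)\n", max(x$psr, na.rm = TRUE),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Extract person-level RT components from a fitted model
#'
#' Returns the posterior means and SDs of each person's latent RT
#' components: `mean_rt` (`alpha_j`; under the expanded model, the
#' predicted log RT for an item at the 10-second TI reference),
#' `rt_adjustment` (`beta_j`, expanded model only), and `log_resid_var`
#' (`omega + u_scale,j`, the log of the person's residual RT variance).
#'
#' @param fit A `"location_scale_fit"` object.
#' @return A data frame, one row per person, with components, their
#'   posterior SDs, and `n_records`. If the fit did not converge a warning
#'   is attached and emitted, but extraction still proceeds.
#' @export
extract_person_components <- function(fit) {
  stopifnot(inherits(fit, "location_scale_fit"))
  out <- fit$person
  if (!fit$converged) {
    warning("fit flagged as non-converged (max PSR = ",
            round(max(fit$psr, na.rm = TRUE), 3),
            "); component estimates may be unreliable", call. = FALSE)
    attr(out, "converged") <- FALSE
  } else attr(out, "converged") <- TRUE
  class(out) <- c("person_components", "data.frame")
  out
}
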