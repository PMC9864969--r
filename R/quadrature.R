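#' Marginal log-likelihood of a location-scale model by adaptive quadrature
#'
#' Evaluates, person by person, the integrated likelihood of the
#' (expanded) location-scale model at fixed parameter values, integrating
#' the 2- or 3-dimensional person random effects out by adaptive
#' Gauss-Hermite quadrature (nodes centered at each person's conditional
#' posterior mode and scaled by the local curvature). This is an
#' independent, sampler-free route to the likelihood, intended for small
#' data sets and for validating the MCMC fits.
#'
#' When `tau` is exactly zero the integral collapses and the closed-form
#' product of normal densities is returned.
#'
#' @param records Data frame with `person_id`, `log_rt` and (when `ti` is
#'   supplied) `item_id`.
#' @param params List with `gamma00`, `omega`, `tau` (2x2 or 3x3) and,
#'   for the expanded model, `gamma10`.
#' @param ti Optional `"time_intensity"` table; supplying it selects the
#'   expanded model and requires 3x3 `tau`.
#' @param nodes Gauss-Hermite nodes per dimension (default 15).
#' @return The marginal log-likelihood (a scalar).
#' @export
marginal_loglik_quadrature <- function(records, params, ti = NULL,
                                       nodes = 15) {
  tau <- params$tau
  check_psd(tau, "tau")
  expanded <- !is.null(ti)
  d <- nrow(tau)
  if (expanded && d != 3L) stop("expanded model requires 3x3 tau", call. = FALSE)
  if (!expanded && d != 2L) stop("basic model requires 2x2 tau", call. = FALSE)
  x <- NULL
  if (expanded) {
    miss <- setdiff(unique(records$item_id), ti$item_id)
    if (length(miss)) stop("no time intensity for some items", call. = FALSE)
    x <- ti$ti_centered[match(records$item_id, ti$item_id)]
  }
  st <- ls_suff(records, x = x)
  g00 <- params$gamma00
  g10 <- if (expanded) params$gamma10 else 0
  omega <- params$omega

  # per-person log-likelihood at a matrix of random-effect values (K x d)
  ll_j <- function(j, U) {
    a <- g00 + U[, 1]
    b <- if (expanded) g10 + U[, 2] else 0
    v <- exp(omega + U[, d])
    stj <- list(n = st$n[j], Sx = st$Sx[j], Sxx = st$Sxx[j], Sy = st$Sy[j],
                Syy = st$Syy[j], Sxy = st$Sxy[j])
    SS <- stj$Syy - 2 * a * stj$Sy - 2 * b * stj$Sxy + a^2 * stj$n +
      2 * a * b * stj$Sx + b^2 * stj$Sxx
    -stj$n / 2 * log(2 * pi * v) - SS / (2 * v)
  }

  if (max(abs(tau)) < 1e-12)
    return(sum(vapply(seq_len(st$J),
                      function(j) ll_j(j, matrix(0, 1, d)), 0)))

  Tinv <- solve(tau)
  ldt <- determinant(tau, logarithm = TRUE)$modulus
  lprior <- function(U) -d / 2 * log(2 * pi) - 0.5 * as.numeric(ldt) -
    0.5 * rowSums((U %*% Tinv) * U)

  gh <- pracma::gaussHermite(nodes)
  grid <- as.matrix(expand.grid(rep(list(seq_len(nodes)), d)))
  Tn <- matrix(gh$x[grid], ncol = d)
  logw <- rowSums(matrix(log(gh$w[grid]), ncol = d)) + rowSums(Tn^2)

  total <- 0
  for (j in seq_len(st$J)) {
    f <- function(u) {
      u <- matrix(u, 1, d)
      -(ll_j(j, u) + lprior(u))
    }
    opt <- optim(rep(0, d), f, method = "BFGS")
    H <- stats::optimHess(opt$par, f)
    Sig <- tryCatch(solve(H), error = function(e) diag(d))
    ev <- eigen(Sig, symmetric = TRUE)
    ev$values <- pmax(ev$values, 1e-10)
    L <- ev$vectors %*% diag(sqrt(ev$values), d)
    Uj <- matrix(opt$par, nrow(Tn), d, byrow = TRUE) +
      sqrt(2) * Tn %*% t(L)
    lg <- ll_j(j, Uj) + lprior(Uj)
    lv <- logw + lg
    m <- max(lv)
    total <- total + (d / 2 * log(2) + 0.5 * sum(log(ev$values)) +
                        m + log(sum(exp(lv - m))))
  }
  total
}

#' Maximum marginal likelihood estimation by quadrature
#'
#' Direct maximization of [marginal_loglik_quadrature()] over the fixed
#' effects and the random-effect covariance (parameterized by its log-
#' Cholesky factor), using Nelder-Mead. Intended for small data sets as an
#' independent check on the MCMC sampler: with diffuse priors, posterior
#' means of the fixed effects should sit close to these point estimates.
#'
#' @inheritParams marginal_loglik_quadrature
#' @param nodes Gauss-Hermite nodes per dimension (default 9; estimation
#'   re-finds each person's mode at every objective evaluation).
#' @param maxit Maximum Nelder-Mead iterations.
#' @return List with `gamma00`, `gamma10` (expanded only), `omega`, `tau`,
#'   `loglik`, and the optimizer convergence code.
#' @export
mml_estimate <- function(records, ti = NULL, nodes = 9, maxit = 600) {
  expanded <- !is.null(ti)
  d <- if (expanded) 3L else 2L
  x <- NULL
  if (expanded) x <- ti$ti_centered[match(records$item_id, ti$item_id)]
  st <- ls_suff(records, x = x)
  ybar <- st$Sy / st$n
  s2j <- pmax(ls_ss(st, ybar, 0) / pmax(st$n - 1, 1), 1e-3)

  # theta = (gamma00 [, gamma10], omega, log-chol tau)
  nfix <- if (expanded) 3L else 2L
  pack_tau <- function(theta) {
    L <- matrix(0, d, d)
    k <- nfix
    for (i in seq_len(d)) for (j in seq_len(i)) {
      k <- k + 1L
      L[i, j] <- if (i == j) exp(theta[k]) else theta[k]
    }
    tcrossprod(L)
  }
  start <- c(mean(ybar), if (expanded) 0.8, mean(log(s2j)),
             rep(0, d * (d + 1) / 2))
  ltau0 <- rep(0, d * (d + 1) / 2)
  k <- 0L
  for (i in seq_len(d)) for (j in seq_len(i)) {
    k <- k + 1L
    if (i == j) ltau0[k] <- log(0.3)
  }
  start[(nfix + 1):length(start)] <- ltau0

  negll <- function(theta) {
    params <- list(gamma00 = theta[1],
                   gamma10 = if (expanded) theta[2] else NULL,
                   omega = theta[nfix], tau = pack_tau(theta))
    -marginal_loglik_quadrature(records, params, ti = ti, nodes = nodes)
  }
  opt <- optim(start, negll, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-9))
  for (round in 1:3) {            # restart until the simplex converges
    if (opt$convergence == 0) break
    opt <- optim(opt$par, negll, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-9))
  }
  list(gamma00 = opt$par[1],
       gamma10 = if (expanded) opt$par[2] else NULL,
       omega = opt$par[nfix],
       tau = pack_tau(opt$par),
       loglik = -opt$value,
       convergence = opt$convergence)
}
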