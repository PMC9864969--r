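# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-stage random seed from a run seed
#'
#' A single run seed fans out deterministically to one seed per pipeline
#' stage so each stage is individually reproducible. Stage seeds stay below
#' `.Machine$integer.max`.
#'
#' @param seed Integer run seed.
#' @param stage Integer stage index (0, 1, 2, ...).
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stage))
  as.integer((abs(seed) + 10007 * (stage + 1)) %% (.Machine$integer.max - 1L)) + 1L
}

# Check a covariance matrix is symmetric positive semidefinite.
check_psd <- function(m, name = deparse(substitute(m)), tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(sprintf("'%s' must be a square matrix", name), call. = FALSE)
  if (max(abs(m - t(m))) > tol)
    stop(sprintf("'%s' must be symmetric", name), call. = FALSE)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(1, max(abs(ev))))
    stop(sprintf("'%s' is not positive semidefinite (min eigenvalue %.3g)",
                 name, min(ev)), call. = FALSE)
  invisible(TRUE)
}

# z-score a vector; zero-variance input is an error unless allow_const.
zscore <- function(x, allow_const = FALSE) {
  s <- sd(x)
  if (!is.finite(s) || s < 1e-12) {
    if (allow_const) return(rep(0, length(x)))
    stop("cannot standardize a zero-variance variable", call. = FALSE)
  }
  (x - mean(x)) / s
}

# Potential scale reduction factor (Gelman-Rubin) for one parameter.
# `draws` is a list of numeric vectors, one per chain, equal length.
psr_factor <- function(draws) {
  m <- length(draws)
  n <- length(draws[[1]])
  if (m < 2L || n < 2L) return(NA_real_)
  means <- vapply(draws, mean, 0)
  vars <- vapply(draws, var, 0)
  W <- mean(vars)
  B <- n * var(means)
  if (W < 1e-300) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# PSR for every column of per-chain draw matrices.
psr_matrix <- function(chain_mats) {
  p <- ncol(chain_mats[[1]])
  out <- vapply(seq_len(p), function(j) {
    psr_factor(lapply(chain_mats, function(m) m[, j]))
  }, 0)
  names(out) <- colnames(chain_mats[[1]])
  out
}

# Connected components of the person-item bipartite graph, by union-find.
# Returns an integer vector of component labels for the union of ids.
bipartite_components <- function(person, item) {
  pid <- paste0("p:", person)
  iid <- paste0("i:", item)
  ids <- unique(c(pid, iid))
  parent <- seq_along(ids)
  idx <- setNames(seq_along(ids), ids)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  pi <- idx[pid]
  ii <- idx[iid]
  for (k in seq_along(pi)) {
    a <- find(pi[k]); b <- find(ii[k])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_along(ids), find, 0L)
  comp <- match(roots, unique(roots))
  names(comp) <- ids
  comp
}

# Cluster-robust (sandwich) covariance for an OLS fit.
# CR0 meat with a G/(G-1) small-sample factor (optional).
vcov_cluster <- function(model, cluster, cadjust = TRUE) {
  X <- model.matrix(model)
  e <- residuals(model)
  cluster <- as.character(cluster)
  stopifnot(length(cluster) == nrow(X))
  Xe <- X * e
  scores <- rowsum(Xe, group = cluster)      # per-cluster score sums
  meat <- crossprod(as.matrix(scores))
  bread <- chol2inv(qr.R(qr(X)))             # (X'X)^{-1}
  G <- nrow(scores)
  V <- bread %*% meat %*% bread
  if (cadjust) V <- V * G / (G - 1)
  dimnames(V) <- list(colnames(X), colnames(X))
  attr(V, "n_clusters") <- G
  V
}

# Wald test of R theta = r with covariance V; F statistic with df (q, df2).
wald_test <- function(coefs, V, R, r = rep(0, nrow(R)), df2) {
  q <- nrow(R)
  d <- as.numeric(R %*% coefs - r)
  W <- as.numeric(t(d) %*% solve(R %*% V %*% t(R), d))
  Fstat <- W / q
  list(F = Fstat, df1 = q, df2 = df2, p = pf(Fstat, q, df2, lower.tail = FALSE))
}

# Draw from an inverse-Wishart(df, scale) via rWishart on the inverse scale.
rinvwishart <- function(df, scale) {
  solve(rWishart(1, df, solve(scale))[, , 1])
}

# Half-vectorization labels for a symmetric matrix ("tau00", "tau10", ...).
vech_labels <- function(d, prefix = "tau") {
  lab <- character(0)
  for (i in seq_len(d)) for (j in seq_len(i))
    lab <- c(lab, sprintf("%s%d%d", prefix, i - 1, j - 1))
  lab
}

vech <- function(m) {
  d <- nrow(m)
  out <- numeric(0)
  for (i in seq_len(d)) for (j in seq_len(i)) out <- c(out, m[i, j])
  out
}

unvech <- function(v, d) {
  m <- matrix(0, d, d)
  k <- 1L
  for (i in seq_len(d)) for (j in seq_len(i)) {
    m[i, j] <- m[j, i] <- v[k]
    k <- k + 1L
  }
  m
}
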