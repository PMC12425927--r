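# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: brute-force double loops, recursive permutation
# enumeration, and a grid search over the restricted likelihood.

# Restricted log-likelihood evaluated from the textbook definition
# (independent of the package's chol-based implementation).
oracle_reml_loglik <- function(y, X, V) {
  Vi <- solve(V)
  A <- t(X) %*% Vi %*% X
  beta <- solve(A, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * (log(det(V)) + log(det(A)) + t(r) %*% Vi %*% r))
}

# Coarse grid search maximizing the same restricted likelihood over
# (tau2_study, tau2_obs); returns the best grid point and its GLS mean.
oracle_grid_reml <- function(yi, vi, study, tau2_grid) {
  X <- matrix(1, length(yi), 1)
  studies <- unique(study)
  Z <- outer(study, studies, "==") * 1
  best <- list(ll = -Inf)
  for (ts in tau2_grid) {
    for (to in tau2_grid) {
      V <- ts * tcrossprod(Z) + diag(to + vi, length(yi))
      ll <- oracle_reml_loglik(yi, X, V)
      if (ll > best$ll) {
        Vi <- solve(V)
        mu <- sum(Vi %*% yi) / sum(Vi)
        best <- list(ll = ll, tau2_study = ts, tau2_obs = to, mu = mu)
      }
    }
  }
  best
}

# All permutations of a vector, recursively (independent of the package's
# iterative enumerator).
oracle_perms <- function(v) {
  if (length(v) <= 1L) return(matrix(v, nrow = 1))
  out <- NULL
  for (i in seq_along(v)) {
    sub <- oracle_perms(v[-i])
    out <- rbind(out, cbind(v[i], sub, deparse.level = 0))
  }
  out
}

# Kendall tau-b by explicit pair counting with tie correction.
oracle_tau_b <- function(x, y) {
  n <- length(x)
  S <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      S <- S + sign(x[j] - x[i]) * sign(y[j] - y[i])
    }
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  S / sqrt((n0 - n1) * (n0 - n2))
}

# Euclidean distance matrix by explicit double loop.
oracle_euclid <- function(xy) {
  n <- nrow(xy)
  m <- matrix(0, n, n)
  for (i in 1:n) {
    for (j in 1:n) {
      m[i, j] <- sqrt(sum((xy[i, ] - xy[j, ])^2))
    }
  }
  m
}

# Mantel r computed independently (explicit vectors and stats::cor on
# manually extracted triangles).
oracle_mantel_r <- function(a, b) {
  n <- nrow(a)
  va <- vb <- numeric(0)
  for (j in 1:(n - 1)) {
    for (i in (j + 1):n) {
      va <- c(va, a[i, j])
      vb <- c(vb, b[i, j])
    }
  }
  cor(va, vb)
}

# A small deterministic study database used by I/O tests.
make_tiny_db <- function() {
  spec <- synthetic_spec(seed = 123L, n_studies = 5L, obs_per_study = 3L)
  generate_observations(spec)
}

strip_attrs <- function(df) {
  attributes(df) <- attributes(df)[c("names", "row.names", "class")]
  df
}
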