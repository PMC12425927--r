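# Publication-bias diagnostics: Rosenthal fail-safe number with the
# 5n + 10 robustness rule, and the Begg-type Kendall rank-correlation test.

#' Rosenthal fail-safe number
#'
#' The number of hypothetical null (zero-effect) studies that would have to
#' be added before the Stouffer-combined one-tailed p-value of the observed
#' effects rises above `alpha`:
#' `N_fs = floor((sum z_i)^2 / z_alpha^2 - k)`, floored at 0, with
#' `z_i = y_i / sqrt(v_i)` and `z_alpha` the one-tailed critical value.
#'
#' @param yi effect sizes (or an effect-size data frame with columns
#'   `lnrr`, `variance`).
#' @param vi sampling variances, all strictly positive.
#' @param alpha one-tailed significance level (default 0.05).
#' @return Integer fail-safe number (>= 0).
#' @export
failsafe_rosenthal <- function(yi, vi = NULL, alpha = 0.05) {
  if (is.data.frame(yi)) { vi <- yi$variance; yi <- yi$lnrr }
  k <- length(yi)
  if (k < 1L) stop("failsafe_rosenthal: need at least one effect")
  if (any(vi <= 0)) stop("failsafe_rosenthal: all variances must be > 0")
  z <- yi / sqrt(vi)
  z_alpha <- qnorm(1 - alpha)
  n_fs <- floor(sum(z)^2 / z_alpha^2 - k)
  max(0L, as.integer(n_fs))
}

#' Begg-type Kendall rank-correlation test for publication bias
#'
#' Kendall's tau between the variance-standardized deviates from the
#' fixed-effect pooled mean and the sampling variances.  With
#' `w_i = 1/v_i`, the pooled mean is `ybar = sum(w y)/sum(w)` and the
#' standardized deviate is `(y_i - ybar)/sqrt(v_i - 1/sum(w))`.  A
#' correlation between deviate and variance indicates small-study
#' (publication) bias.  The two-sided p-value is exact (full enumeration of
#' the permutation distribution of tau) for `k <= 8`; otherwise a normal
#' approximation of the concordance statistic S with continuity correction
#' and tie correction is used.
#'
#' @inheritParams failsafe_rosenthal
#' @return List with elements `tau` and `p`.
#' @export
kendall_tau_test <- function(yi, vi = NULL) {
  if (is.data.frame(yi)) { vi <- yi$variance; yi <- yi$lnrr }
  k <- length(yi)
  if (k < 3L) stop("kendall_tau_test: need at least 3 effects")
  if (any(vi <= 0)) stop("kendall_tau_test: all variances must be > 0")
  w <- 1 / vi
  ybar <- sum(w * yi) / sum(w)
  vstar <- vi - 1 / sum(w)
  vstar[vstar < 0] <- 0   # guard rounding; analytically vi >= 1/sum(w)
  ti <- (yi - ybar) / sqrt(pmax(vstar, .Machine$double.eps))
  tau <- kendall_tau_b(ti, vi)
  if (k <= 8L) {
    perms <- all_permutations(k)
    taus <- apply(perms, 1, function(pm) kendall_tau_b(ti, vi[pm]))
    p <- mean(abs(taus) >= abs(tau) - 1e-12)
  } else {
    p <- kendall_normal_p(ti, vi)
  }
  list(tau = tau, p = p)
}

# tau-b: tie-corrected Kendall correlation (matches stats::cor method "kendall")
kendall_tau_b <- function(x, y) {
  cor(x, y, method = "kendall")
}

# Normal approximation for the two-sided Kendall test: S with tie-corrected
# variance and continuity correction.
kendall_normal_p <- function(x, y) {
  n <- length(x)
  S <- 0
  for (i in seq_len(n - 1)) {
    S <- S + sum(sign(x[-seq_len(i)] - x[i]) * sign(y[-seq_len(i)] - y[i]))
  }
  tie_term <- function(v) {
    t <- table(v)
    t <- t[t > 1]
    c(sum(t * (t - 1) * (2 * t + 5)),
      sum(t * (t - 1) * (t - 2)),
      sum(t * (t - 1)))
  }
  tx <- tie_term(x); ty <- tie_term(y)
  var_S <- (n * (n - 1) * (2 * n + 5) - tx[1] - ty[1]) / 18 +
    tx[2] * ty[2] / (9 * n * (n - 1) * (n - 2)) +
    tx[3] * ty[3] / (2 * n * (n - 1))
  if (var_S <= 0) return(1)
  z <- (S - sign(S)) / sqrt(var_S)
  2 * pnorm(-abs(z))
}

# All permutations of 1:n as an n! x n matrix (row-wise), n small.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (pos in seq_len(n)) {
    for (r in seq_len(nrow(sub))) {
      perm <- integer(n)
      perm[pos] <- n
      perm[-pos] <- sub[r, ]
      out[row, ] <- perm
      row <- row + 1L
    }
  }
  out
}

#' Publication-bias report for a set of effects
#'
#' Combines the Rosenthal fail-safe number with the 5n + 10 robustness rule
#' (robust when `N_fs > 5k + 10`) and, when `k >= 3`, the Begg-type Kendall
#' rank test.
#'
#' @inheritParams failsafe_rosenthal
#' @return Object of class `sbi_bias`: `failsafe_n`, `n_obs`, `threshold`,
#'   `robust`, `kendall_tau`, `p_kendall`.
#' @export
bias_report <- function(yi, vi = NULL, alpha = 0.05) {
  if (is.data.frame(yi)) { vi <- yi$variance; yi <- yi$lnrr }
  k <- length(yi)
  n_fs <- failsafe_rosenthal(yi, vi, alpha)
  threshold <- 5L * k + 10L
  kend <- if (k >= 3L) kendall_tau_test(yi, vi) else list(tau = NA_real_, p = NA_real_)
  out <- list(failsafe_n = n_fs, n_obs = k, threshold = threshold,
              robust = n_fs > threshold,
              kendall_tau = kend$tau, p_kendall = kend$p)
  class(out) <- "sbi_bias"
  out
}

#' @export
print.sbi_bias <- function(x, ...) {
  cat("Publication-bias report\n")
  cat(sprintf("  fail-safe N = %d (threshold 5n+10 = %d) -> %s\n",
              x$failsafe_n, x$threshold,
              if (x$robust) "robust" else "not robust"))
  if (!is.na(x$kendall_tau)) {
    cat(sprintf("  Kendall tau = %.4f, p = %.4g\n", x$kendall_tau, x$p_kendall))
  }
  invisible(x)
}
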