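# Study-nested multilevel random-effects pooling.
#
# Model: y_ij = x_ij' beta + b_i + u_ij + e_ij with
#   b_i  ~ N(0, tau2_study)   (study-level intercept, shared within study)
#   u_ij ~ N(0, tau2_obs)     (observation-level heterogeneity)
#   e_ij ~ N(0, v_ij)         (known sampling variance of the lnRR)
# Marginal covariance V = tau2_study * ZZ' + tau2_obs * I + diag(v).
# Variance components are estimated by REML via Fisher scoring with
# step-halving and projection onto tau2 >= 0.

# Restricted log-likelihood (up to an additive constant).
reml_loglik <- function(y, X, V) {
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  Vi <- chol2inv(ch)
  U <- Vi %*% X
  A <- crossprod(X, U)
  Ai <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Ai)) return(-Inf)
  beta <- Ai %*% crossprod(U, y)
  r <- y - X %*% beta
  ld_V <- 2 * sum(log(diag(ch)))
  ld_A <- determinant(A, logarithm = TRUE)$modulus[1]
  as.numeric(-0.5 * (ld_V + ld_A + crossprod(r, Vi %*% r)))
}

# One REML fit with fixed design X; returns estimates and diagnostics.
# 'estimate' flags which of (tau2_study, tau2_obs) are free.
reml_fit_engine <- function(y, vi, X, Z, tau2, estimate,
                            reltol = 1e-8, maxit = 200L) {
  k <- length(y)
  G <- list(study = tcrossprod(Z), obs = diag(k))
  build_V <- function(tau2) {
    tau2["study"] * G$study + tau2["obs"] * G$obs + diag(vi, k)
  }
  ll <- reml_loglik(y, X, build_V(tau2))
  if (!is.finite(ll)) stop("multilevel fit: restricted likelihood not finite at start")
  converged <- FALSE
  iter <- 0L
  grad_norm <- NA_real_
  while (iter < maxit) {
    iter <- iter + 1L
    V <- build_V(tau2)
    ch <- chol(V)
    Vi <- chol2inv(ch)
    U <- Vi %*% X
    A <- crossprod(X, U)
    Ai <- solve(A)
    beta <- Ai %*% crossprod(U, y)
    r <- as.numeric(y - X %*% beta)
    Py <- as.numeric(Vi %*% r)
    free <- names(tau2)[estimate]
    # active-set: a component at 0 whose score pushes it negative stays fixed
    M <- lapply(G[free], function(g) Vi %*% g)
    W <- lapply(G[free], function(g) crossprod(U, g))   # p x k
    score <- vapply(seq_along(free), function(j) {
      g <- G[[free[j]]]
      tr_P_g <- sum(diag(M[[j]])) - sum(Ai * (W[[j]] %*% U))
      -0.5 * tr_P_g + 0.5 * sum(Py * (g %*% Py))
    }, numeric(1))
    names(score) <- free
    active <- !(tau2[free] <= 0 & score < 0)
    grad_norm <- sqrt(sum(score[active]^2))
    if (!any(active)) { converged <- TRUE; break }
    fa <- free[active]
    nf <- length(fa)
    info <- matrix(0, nf, nf, dimnames = list(fa, fa))
    idx <- match(fa, free)
    WU <- lapply(W, function(w) w %*% U)               # p x p
    for (a in seq_len(nf)) {
      for (b in a:nf) {
        ja <- idx[a]; jb <- idx[b]
        # I_ab = 0.5 tr(P G_a P G_b) with P = Vi - U Ai U'
        t1 <- sum(M[[ja]] * t(M[[jb]]))
        c1 <- sum(diag(Ai %*% (W[[jb]] %*% (M[[ja]] %*% U))))
        c2 <- sum(diag(Ai %*% (W[[ja]] %*% (M[[jb]] %*% U))))
        t3 <- sum(diag((Ai %*% WU[[ja]]) %*% (Ai %*% WU[[jb]])))
        info[a, b] <- info[b, a] <- 0.5 * (t1 - c1 - c2 + t3)
      }
    }
    step <- tryCatch(solve(info, score[fa]), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      step <- score[fa] / max(diag(info), 1e-8)
    }
    # step-halving with projection onto the non-negative orthant
    improved <- FALSE
    fac <- 1
    for (h in 1:30) {
      cand <- tau2
      cand[fa] <- pmax(tau2[fa] + fac * step, 0)
      ll_new <- reml_loglik(y, X, build_V(cand))
      if (is.finite(ll_new) && ll_new > ll - 1e-12) {
        improved <- TRUE
        break
      }
      fac <- fac / 2
    }
    if (!improved) { converged <- TRUE; break }  # no uphill direction left
    delta <- ll_new - ll
    tau2 <- cand
    ll <- ll_new
    if (abs(delta) < reltol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop("multilevel REML did not converge in ", maxit,
         " iterations (last tau2 = [", paste(signif(tau2, 6), collapse = ", "),
         "], gradient norm = ", signif(grad_norm, 6), ")")
  }
  tau2[tau2 < 1e-12] <- 0   # report an exact boundary zero, not an epsilon
  V <- build_V(tau2)
  Vi <- chol2inv(chol(V))
  U <- Vi %*% X
  A <- crossprod(X, U)
  Ai <- solve(A)
  beta <- as.numeric(Ai %*% crossprod(U, y))
  list(beta = beta, vcov = Ai, tau2 = tau2, loglik = ll,
       iterations = iter, grad_norm = grad_norm)
}

#' Fit the study-nested multilevel random-effects model
#'
#' Pools lnRR effect sizes with known sampling variances under a model with
#' a study-level random intercept and an observation-level random effect,
#' estimated by REML (Fisher scoring, step-halving, variance components
#' projected onto `>= 0`; convergence tolerance 1e-8 on the restricted
#' log-likelihood, at most 200 iterations).  Inference on the pooled mean is
#' Wald-type: `ci = mu +/- z_(1-alpha/2) * se`.
#'
#' Degenerate designs are handled explicitly: a single effect returns
#' `(mu = y, se = sqrt(v), tau2 = 0)`; when every study contributes exactly
#' one observation the two variance components are confounded and the
#' heterogeneity is reported as `tau2_study` with `tau2_obs` fixed at 0.
#'
#' @param yi numeric vector of effect sizes, or an effect-size data frame
#'   from [compute_effect_sizes()] (columns `lnrr`, `variance`, `study_id`).
#' @param vi sampling variances (ignored when `yi` is a data frame).
#' @param study study identifiers; `NULL` treats every effect as its own study.
#' @param mods optional factor/character moderator: fits one mean per level.
#' @param fix_tau2_study,fix_tau2_obs optionally fix a variance component
#'   (e.g. at 0) instead of estimating it.
#' @param level confidence level (default 0.95).
#' @param reltol,maxit REML convergence controls.
#' @return Object of class `sbi_meta`: pooled estimate(s) `b` with
#'   covariance, `mu`/`se`/`ci_low`/`ci_high`/`z`/`p` (intercept-only fits),
#'   variance components `tau2_study`, `tau2_obs`, counts `k`/`n_studies`,
#'   and the Cochran heterogeneity statistic `Q_total` with `df_Q`.
#' @export
fit_multilevel_re <- function(yi, vi = NULL, study = NULL, mods = NULL,
                              fix_tau2_study = NULL, fix_tau2_obs = NULL,
                              level = 0.95, reltol = 1e-8, maxit = 200L) {
  if (is.data.frame(yi)) {
    eff <- yi
    stopifnot(all(c("lnrr", "variance") %in% names(eff)))
    if (is.null(study) && "study_id" %in% names(eff)) study <- eff$study_id
    vi <- eff$variance
    yi <- eff$lnrr
  }
  k <- length(yi)
  if (k == 0L) stop("fit_multilevel_re: no effect sizes")
  if (length(vi) != k) stop("fit_multilevel_re: yi and vi lengths differ")
  if (any(!is.finite(yi)) || any(!is.finite(vi)) || any(vi < 0)) {
    stop("fit_multilevel_re: effects must be finite with non-negative variances")
  }
  if (is.null(study)) study <- as.character(seq_len(k))
  study <- as.character(study)
  zcrit <- qnorm(1 - (1 - level) / 2)

  if (!is.null(mods)) {
    if (!is.factor(mods)) mods <- factor(mods)
    if (nlevels(mods) < 2L) stop("fit_multilevel_re: moderator needs >= 2 levels")
    if (any(table(mods) == 0L)) stop("fit_multilevel_re: empty moderator level")
    X <- stats::model.matrix(~ 0 + mods)
    colnames(X) <- levels(mods)
  } else {
    X <- matrix(1, k, 1, dimnames = list(NULL, "intrcpt"))
  }
  p <- ncol(X)
  if (k <= p) {
    if (k == 1L && p == 1L) {
      out <- list(b = yi, vcov_b = matrix(vi, 1, 1), mu = yi, se = sqrt(vi),
                  ci_low = yi - zcrit * sqrt(vi), ci_high = yi + zcrit * sqrt(vi),
                  z = if (vi > 0) yi / sqrt(vi) else NA_real_,
                  p = if (vi > 0) 2 * pnorm(-abs(yi / sqrt(vi))) else NA_real_,
                  tau2_study = 0, tau2_obs = 0, k = 1L, n_studies = 1L,
                  Q_total = 0, df_Q = 0L, loglik_reml = NA_real_,
                  iterations = 0L, level = level, mods = NULL, yi = yi, vi = vi,
                  study = study)
      class(out) <- "sbi_meta"
      return(out)
    }
    stop("fit_multilevel_re: k must exceed the number of fixed effects")
  }

  studies <- unique(study)
  Z <- outer(study, studies, "==") * 1
  singleton <- all(colSums(Z) == 1L)

  tau2 <- c(study = NA_real_, obs = NA_real_)
  estimate <- c(study = TRUE, obs = TRUE)
  if (!is.null(fix_tau2_study)) { tau2["study"] <- fix_tau2_study; estimate["study"] <- FALSE }
  if (!is.null(fix_tau2_obs)) { tau2["obs"] <- fix_tau2_obs; estimate["obs"] <- FALSE }
  if (singleton && estimate[["study"]] && estimate[["obs"]]) {
    # one obs per study: ZZ' = I, components confounded -> single component
    tau2["obs"] <- 0
    estimate["obs"] <- FALSE
  }
  init <- max((var(yi) - mean(vi)) / 2, 0.1 * var(yi), 1e-6)
  if (!is.finite(init)) init <- 1e-6
  tau2[is.na(tau2)] <- init
  # all-zero variances with fixed tau2 = 0 would make V singular
  if (all(tau2[!estimate] == 0) && !any(estimate) && any(vi == 0)) {
    stop("fit_multilevel_re: zero marginal variance")
  }

  fit <- reml_fit_engine(yi, vi, X, Z, tau2, estimate, reltol, maxit)

  se_b <- sqrt(diag(fit$vcov))
  z_b <- fit$beta / se_b
  p_b <- 2 * pnorm(-abs(z_b))
  # Cochran Q about the fixed-effect (1/v weighted) fit with the same design
  wfe <- 1 / pmax(vi, .Machine$double.eps)
  XtW <- t(X * wfe)
  beta_fe <- solve(XtW %*% X, XtW %*% yi)
  Q_total <- sum(wfe * (yi - as.numeric(X %*% beta_fe))^2)

  out <- list(
    b = setNames(fit$beta, colnames(X)), vcov_b = fit$vcov,
    mu = if (is.null(mods)) unname(fit$beta[1]) else NA_real_,
    se = if (is.null(mods)) unname(se_b[1]) else NA_real_,
    ci_low = if (is.null(mods)) unname(fit$beta[1] - zcrit * se_b[1]) else NA_real_,
    ci_high = if (is.null(mods)) unname(fit$beta[1] + zcrit * se_b[1]) else NA_real_,
    z = if (is.null(mods)) unname(z_b[1]) else NA_real_,
    p = if (is.null(mods)) unname(p_b[1]) else NA_real_,
    se_b = setNames(se_b, colnames(X)),
    tau2_study = unname(fit$tau2["study"]), tau2_obs = unname(fit$tau2["obs"]),
    k = k, n_studies = length(studies),
    Q_total = Q_total, df_Q = k - p,
    loglik_reml = fit$loglik, iterations = fit$iterations,
    level = level, mods = mods, yi = yi, vi = vi, study = study
  )
  class(out) <- "sbi_meta"
  out
}

#' @export
print.sbi_meta <- function(x, ...) {
  cat("Multilevel random-effects meta-analysis\n")
  cat(sprintf("  k = %d observations, %d studies\n", x$k, x$n_studies))
  cat(sprintf("  tau2 (study) = %.5f, tau2 (obs) = %.5f\n",
              x$tau2_study, x$tau2_obs))
  if (is.null(x$mods)) {
    cat(sprintf("  pooled lnRR = %.4f (SE %.4f), %d%% CI [%.4f, %.4f], z = %.3f, p = %.4g\n",
                x$mu, x$se, round(100 * x$level), x$ci_low, x$ci_high, x$z, x$p))
  } else {
    tab <- data.frame(level = names(x$b), estimate = x$b, se = x$se_b)
    print(tab, row.names = FALSE)
  }
  cat(sprintf("  Q_total = %.3f (df = %d)\n", x$Q_total, x$df_Q))
  invisible(x)
}

#' Significance by the confidence-interval zero-crossing rule
#'
#' An effect is called significant when its confidence interval does not
#' cross zero.
#'
#' @param est `sbi_meta` object (or any list with `ci_low`, `ci_high`).
#' @return Logical.
#' @export
is_significant <- function(est) {
  if (is.na(est$ci_low) || is.na(est$ci_high)) return(NA)
  est$ci_low > 0 || est$ci_high < 0
}

#' Subgroup analysis with the omnibus moderator test
#'
#' Fits the multilevel model with one pooled mean per moderator level and
#' tests the joint hypothesis that all level means are equal with a Wald
#' chi-square statistic (Q_M, df = levels - 1).
#'
#' @param effects effect-size data frame or numeric `yi`.
#' @param moderator categorical moderator, one value per effect.
#' @inheritParams fit_multilevel_re
#' @return Object of class `sbi_subgroup`: `moderator`, per-level estimate
#'   `table`, `QM`, `df`, `p_QM`, and the underlying `fit`.
#' @export
fit_subgroup <- function(effects, moderator, vi = NULL, study = NULL,
                         level = 0.95, ...) {
  moderator_name <- deparse(substitute(moderator))[1]
  mods <- factor(moderator)
  if (nlevels(mods) < 2L) stop("fit_subgroup: moderator must have >= 2 observed levels")
  fit <- fit_multilevel_re(effects, vi = vi, study = study, mods = mods,
                           level = level, ...)
  L <- length(fit$b)
  # contrasts: each level minus the first; equality of all means
  C <- cbind(-1, diag(L - 1))
  est <- as.numeric(C %*% fit$b)
  Sc <- C %*% fit$vcov_b %*% t(C)
  QM <- as.numeric(crossprod(est, solve(Sc, est)))
  df <- L - 1L
  zcrit <- qnorm(1 - (1 - level) / 2)
  tab <- data.frame(
    level = names(fit$b),
    k = as.integer(table(fit$mods)[names(fit$b)]),
    mu = unname(fit$b),
    se = unname(fit$se_b),
    ci_low = unname(fit$b - zcrit * fit$se_b),
    ci_high = unname(fit$b + zcrit * fit$se_b),
    stringsAsFactors = FALSE
  )
  tab$significant <- tab$ci_low > 0 | tab$ci_high < 0
  out <- list(moderator = moderator_name, table = tab, QM = QM, df = df,
              p_QM = pchisq(QM, df, lower.tail = FALSE), fit = fit)
  class(out) <- "sbi_subgroup"
  out
}

#' @export
print.sbi_subgroup <- function(x, ...) {
  cat("Subgroup analysis (", x$moderator, ")\n", sep = "")
  print(x$table, row.names = FALSE)
  cat(sprintf("  QM = %.3f (df = %d), p = %.4g\n", x$QM, x$df, x$p_QM))
  invisible(x)
}

#' Single-step post hoc pairwise comparisons between moderator levels
#'
#' All pairwise differences between level means, with single-step adjusted
#' p-values from the max-|z| distribution of the joint normal of the
#' contrasts (the Tukey-style family-wise correction used after a
#' significant omnibus test).  The max-|z| tail probability is approximated
#' by seeded Monte-Carlo draws from the contrast distribution; with a single
#' contrast the adjusted p equals the unadjusted two-sided p exactly.  If
#' the contrast covariance is not positive definite the adjustment falls
#' back to Bonferroni with a warning.
#'
#' @param sub `sbi_subgroup` object from [fit_subgroup()].
#' @param n_draws Monte-Carlo sample size (default 100000).
#' @param seed integer seed for the draws.
#' @return Data frame: `level_a`, `level_b`, `difference`, `se`, `z`,
#'   `p` (unadjusted), `p_adj`.
#' @export
posthoc_pairwise <- function(sub, n_draws = 100000L, seed = 1L) {
  stopifnot(inherits(sub, "sbi_subgroup"))
  b <- sub$fit$b
  S <- sub$fit$vcov_b
  L <- length(b)
  pairs <- combn(L, 2)
  C <- matrix(0, ncol(pairs), L)
  for (j in seq_len(ncol(pairs))) {
    C[j, pairs[2, j]] <- 1
    C[j, pairs[1, j]] <- -1
  }
  diffs <- as.numeric(C %*% b)
  Sc <- C %*% S %*% t(C)
  se <- sqrt(diag(Sc))
  z <- diffs / se
  p_raw <- 2 * pnorm(-abs(z))
  m <- length(z)
  if (m == 1L) {
    p_adj <- p_raw
  } else {
    Rc <- Sc / tcrossprod(se)
    draws <- tryCatch({
      old <- get_rng_state()
      on.exit(restore_rng_state(old), add = TRUE)
      set.seed(as.integer(seed))
      MASS::mvrnorm(n_draws, mu = rep(0, m), Sigma = Rc)
    }, error = function(e) NULL)
    if (is.null(draws)) {
      warning("posthoc_pairwise: singular contrast covariance; Bonferroni fallback")
      p_adj <- pmin(1, m * p_raw)
    } else {
      maxz <- apply(abs(draws), 1, max)
      p_adj <- vapply(abs(z), function(zz) mean(maxz >= zz), numeric(1))
      p_adj <- pmax(p_adj, p_raw)   # single-step adjustment never below raw
    }
  }
  data.frame(
    level_a = names(b)[pairs[1, ]],
    level_b = names(b)[pairs[2, ]],
    difference = diffs, se = se, z = z, p = p_raw, p_adj = p_adj,
    stringsAsFactors = FALSE
  )
}

# Save/restore the global RNG so seeded helpers do not disturb user streams.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
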