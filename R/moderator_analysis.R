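# Continuous-moderator analyses: weighted meta-regression with AIC/BIC
# model selection and quadratic turning points, Mantel / partial Mantel
# permutation tests, and permutation-based moderator importance from a
# tree ensemble.

#' Weighted meta-regression of lnRR on a continuous moderator
#'
#' Weighted least squares of the effect sizes on `x` (linear) or on `x` and
#' `x^2` (quadratic) with weights `1/(v_i + tau2)`, where `tau2` is the
#' total heterogeneity (`tau2_study + tau2_obs`) from a preliminary
#' intercept-only multilevel fit.  The same `tau2` is reused across
#' candidate forms so their AIC/BIC are comparable.  Rows with missing `x`
#' are dropped (count reported via `message()`).
#'
#' @param yi effect sizes, or an effect-size data frame (columns `lnrr`,
#'   `variance`, `study_id`).
#' @param x continuous moderator values, one per effect.
#' @param vi sampling variances (ignored when `yi` is a data frame).
#' @param study study ids for the preliminary heterogeneity fit.
#' @param form `"linear"` or `"quadratic"`.
#' @param tau2 optionally supply the heterogeneity instead of estimating it.
#' @return Object of class `sbi_metareg`: `form`, `coefficients`
#'   (`intercept`, `b1`[, `b2`]), `vcov`, weighted `R2`, model Wald
#'   `p_model`, `AIC`, `BIC` (Gaussian likelihood with known variances
#'   `v + tau2`), `k`, `tau2`.
#' @export
meta_regression <- function(yi, x, vi = NULL, study = NULL,
                            form = c("linear", "quadratic"), tau2 = NULL) {
  form <- match.arg(form)
  if (is.data.frame(yi)) {
    if (is.null(study) && "study_id" %in% names(yi)) study <- yi$study_id
    vi <- yi$variance
    yi <- yi$lnrr
  }
  keep <- is.finite(x)
  if (any(!keep)) {
    message("meta_regression: dropping ", sum(!keep), " row(s) with missing x")
    yi <- yi[keep]; vi <- vi[keep]; x <- x[keep]
    if (!is.null(study)) study <- study[keep]
  }
  k <- length(yi)
  n_coef <- if (form == "linear") 2L else 3L
  if (k < n_coef + 1L) stop("meta_regression: need at least ", n_coef + 1L, " rows")
  if (form == "quadratic" && length(unique(x)) < 3L) {
    stop("meta_regression: constant or two-valued x cannot support a quadratic")
  }
  if (length(unique(x)) < 2L) stop("meta_regression: x is constant")
  if (is.null(tau2)) {
    pre <- fit_multilevel_re(yi, vi, study)
    tau2 <- pre$tau2_study + pre$tau2_obs
  }
  w <- 1 / (vi + tau2)
  X <- if (form == "linear") cbind(intercept = 1, b1 = x) else
    cbind(intercept = 1, b1 = x, b2 = x^2)
  XtW <- t(X * w)
  A <- XtW %*% X
  beta <- solve(A, XtW %*% yi)
  V <- solve(A)
  fitted <- as.numeric(X %*% beta)
  res <- yi - fitted
  ybar_w <- sum(w * yi) / sum(w)
  R2 <- 1 - sum(w * res^2) / sum(w * (yi - ybar_w)^2)
  R2 <- min(max(R2, 0), 1)
  # omnibus Wald test of the slope coefficient(s)
  sl <- seq.int(2L, n_coef)
  Vs <- V[sl, sl, drop = FALSE]
  chi <- as.numeric(crossprod(beta[sl], solve(Vs, beta[sl])))
  p_model <- pchisq(chi, length(sl), lower.tail = FALSE)
  sigma2 <- vi + tau2
  logLik <- -0.5 * sum(log(2 * pi * sigma2) + res^2 / sigma2)
  out <- list(
    form = form,
    coefficients = setNames(as.numeric(beta), colnames(X)),
    vcov = V, R2 = R2, chi2 = chi, p_model = p_model,
    AIC = -2 * logLik + 2 * n_coef,
    BIC = -2 * logLik + n_coef * log(k),
    logLik = logLik, k = k, tau2 = tau2, x = x, yi = yi, w = w
  )
  class(out) <- "sbi_metareg"
  out
}

#' @export
print.sbi_metareg <- function(x, ...) {
  cat(sprintf("Weighted meta-regression (%s), k = %d\n", x$form, x$k))
  print(round(x$coefficients, 6))
  cat(sprintf("  R2 = %.4f, chi2 = %.3f, p = %.4g, AIC = %.2f, BIC = %.2f\n",
              x$R2, x$chi2, x$p_model, x$AIC, x$BIC))
  invisible(x)
}

#' Select a regression form by information criteria
#'
#' Returns the candidate fit with the lowest AIC; ties are broken by lower
#' BIC, then by fewer parameters.  All candidates must be fitted to the
#' same rows (`k` must agree).
#'
#' @param fits list of `sbi_metareg` objects on identical data.
#' @return The selected `sbi_metareg`.
#' @export
select_model <- function(fits) {
  if (inherits(fits, "sbi_metareg")) return(fits)
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, logical(1), "sbi_metareg")))
  if (length(fits) == 1L) return(fits[[1]])
  ks <- vapply(fits, `[[`, numeric(1), "k")
  if (length(unique(ks)) != 1L) stop("select_model: candidates fitted to different data (k mismatch)")
  aic <- vapply(fits, `[[`, numeric(1), "AIC")
  bic <- vapply(fits, `[[`, numeric(1), "BIC")
  npar <- vapply(fits, function(f) length(f$coefficients), numeric(1))
  ord <- order(aic, bic, npar)
  fits[[ord[1]]]
}

#' Vertex, roots, and positive interval of a fitted quadratic
#'
#' For a quadratic fit `y = intercept + b1 x + b2 x^2` (b2 != 0): the vertex
#' `x = -b1/(2 b2)` and its fitted value, the real roots of `fitted = 0`,
#' and the open interval of `x` where the fitted lnRR is positive (for a
#' concave fit with two roots, the interval between them).
#'
#' @param fit `sbi_metareg` with `form = "quadratic"`.
#' @return Object of class `quadratic_summary`: `vertex_x`, `vertex_y`,
#'   `roots` (numeric vector of length 0-2, increasing), `positive_interval`
#'   (length-2 numeric or NULL when the fitted curve is nowhere positive).
#' @export
quadratic_summary <- function(fit) {
  stopifnot(inherits(fit, "sbi_metareg"))
  if (fit$form != "quadratic") stop("quadratic_summary: fit is not quadratic; use the linear form directly")
  cf <- fit$coefficients
  a <- cf[["b2"]]; b <- cf[["b1"]]; c0 <- cf[["intercept"]]
  if (a == 0) stop("quadratic_summary: b2 = 0; refit with form = 'linear'")
  vertex_x <- -b / (2 * a)
  vertex_y <- c0 + b * vertex_x + a * vertex_x^2
  disc <- b^2 - 4 * a * c0
  roots <- if (disc > 0) sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a)) else
    if (disc == 0) -b / (2 * a) else numeric(0)
  positive_interval <- NULL
  if (a < 0) {
    if (length(roots) == 2L) positive_interval <- roots
    # disc <= 0 with a < 0: curve never positive
  } else {
    # convex: positive outside the roots (unbounded); report NULL unless
    # the curve is everywhere positive, which has no finite interval either
    positive_interval <- NULL
  }
  out <- list(vertex_x = unname(vertex_x), vertex_y = unname(vertex_y),
              roots = unname(roots), positive_interval = unname(positive_interval),
              concave = a < 0)
  class(out) <- "quadratic_summary"
  out
}

#' @export
print.quadratic_summary <- function(x, ...) {
  cat(sprintf("Quadratic summary: vertex at x = %.6f (fitted y = %.6f), %s\n",
              x$vertex_x, x$vertex_y, if (x$concave) "maximum" else "minimum"))
  if (length(x$roots)) cat("  roots:", paste(signif(x$roots, 6), collapse = ", "), "\n")
  if (!is.null(x$positive_interval)) {
    cat(sprintf("  fitted lnRR > 0 on (%.6f, %.6f)\n",
                x$positive_interval[1], x$positive_interval[2]))
  } else cat("  fitted lnRR nowhere positive on a bounded interval\n")
  invisible(x)
}

lower_triangle <- function(m) m[lower.tri(m)]

check_dist_matrix <- function(m, name) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop(name, " must be a square matrix")
  if (max(abs(m - t(m))) > 1e-8) stop(name, " must be symmetric")
  if (max(abs(diag(m))) > 1e-8) stop(name, " must have a zero diagonal")
  invisible(m)
}

#' Mantel permutation test between two distance matrices
#'
#' The Mantel statistic r is the Pearson correlation of the strictly lower
#' triangles.  The one-sided p-value permutes the rows and columns of
#' `dist_b` jointly.  With `exhaustive = TRUE` (feasible for small n) all
#' `n!` relabelings are enumerated and `p = #{r_perm >= r_obs}/n!`; otherwise
#' `n_perm` seeded random permutations are drawn and the add-one estimator
#' `p = (1 + #{r_perm >= r_obs})/(1 + n_perm)` is used, which can never be
#' exactly zero.
#'
#' @param dist_a,dist_b symmetric distance matrices with zero diagonals,
#'   same dimension >= 4.
#' @param n_perm number of random permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @param exhaustive enumerate all relabelings instead of sampling.
#' @return List with `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(dist_a, dist_b, n_perm = 999L, seed = 1L,
                        exhaustive = FALSE) {
  check_dist_matrix(dist_a, "dist_a")
  check_dist_matrix(dist_b, "dist_b")
  n <- nrow(dist_a)
  if (n != nrow(dist_b)) stop("mantel_test: dimension mismatch")
  if (n < 4L) stop("mantel_test: need at least 4 samples")
  va <- lower_triangle(dist_a)
  vb <- lower_triangle(dist_b)
  if (sd(va) == 0 || sd(vb) == 0) stop("mantel_test: constant distance triangle")
  r_obs <- cor(va, vb)
  if (exhaustive) {
    perms <- all_permutations(n)
    rs <- apply(perms, 1, function(pm) cor(va, lower_triangle(dist_b[pm, pm])))
    p <- mean(rs >= r_obs - 1e-12)
    n_used <- nrow(perms)
  } else {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
    hits <- 0L
    for (i in seq_len(n_perm)) {
      pm <- sample.int(n)
      if (cor(va, lower_triangle(dist_b[pm, pm])) >= r_obs - 1e-12) hits <- hits + 1L
    }
    p <- (1 + hits) / (1 + n_perm)
    n_used <- n_perm
  }
  list(r = r_obs, p = p, n_perm = n_used)
}

#' Partial Mantel test controlling for a third distance matrix
#'
#' Correlates the residuals of the `dist_a` and `dist_b` triangles after
#' linear regression on the `dist_c` triangle; significance by joint
#' row/column permutation of `dist_b`, re-residualizing the permuted
#' triangle each time.
#'
#' @inheritParams mantel_test
#' @param dist_c conditioning distance matrix.
#' @return List with `r`, `p`, `n_perm`.
#' @export
partial_mantel_test <- function(dist_a, dist_b, dist_c, n_perm = 999L,
                                seed = 1L, exhaustive = FALSE) {
  check_dist_matrix(dist_a, "dist_a")
  check_dist_matrix(dist_b, "dist_b")
  check_dist_matrix(dist_c, "dist_c")
  n <- nrow(dist_a)
  if (n != nrow(dist_b) || n != nrow(dist_c)) stop("partial_mantel_test: dimension mismatch")
  if (n < 4L) stop("partial_mantel_test: need at least 4 samples")
  va <- lower_triangle(dist_a)
  vc <- lower_triangle(dist_c)
  if (sd(va) == 0 || sd(vc) == 0) stop("partial_mantel_test: constant distance triangle")
  resid_on <- function(y, x) y - (cov(y, x) / var(x)) * (x - mean(x)) - mean(y)
  ra <- resid_on(va, vc)
  if (sd(ra) == 0) stop("partial_mantel_test: dist_a fully explained by dist_c")
  stat <- function(dm) {
    vb <- lower_triangle(dm)
    if (sd(vb) == 0) return(NA_real_)
    rb <- resid_on(vb, vc)
    # a matrix fully explained by the conditioning matrix has no residual
    # signal left: the partial correlation is 0 by convention
    if (sd(rb) < 1e-12) return(0)
    cor(ra, rb)
  }
  r_obs <- stat(dist_b)
  if (is.na(r_obs)) stop("partial_mantel_test: constant distance triangle")
  if (exhaustive) {
    perms <- all_permutations(n)
    rs <- apply(perms, 1, function(pm) stat(dist_b[pm, pm]))
    p <- mean(rs >= r_obs - 1e-12)
    n_used <- nrow(perms)
  } else {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
    hits <- 0L
    for (i in seq_len(n_perm)) {
      pm <- sample.int(n)
      if (stat(dist_b[pm, pm]) >= r_obs - 1e-12) hits <- hits + 1L
    }
    p <- (1 + hits) / (1 + n_perm)
    n_used <- n_perm
  }
  list(r = r_obs, p = p, n_perm = n_used)
}

#' Moderator importance from a tree ensemble
#'
#' Fits a random-forest regressor of the response on the candidate
#' moderators (seeded) on a training split, then measures each moderator's
#' importance as the mean increase in out-of-sample squared error when its
#' column is permuted in the held-out split (`n_shuffle` seeded
#' permutations).  Predictors that add nothing get importance near 0;
#' permutation importance is comparable across mixed-type predictors,
#' unlike impurity importance.
#'
#' @param data data frame of complete cases (rows with missing values are
#'   dropped; a predictor that is missing everywhere is dropped with a
#'   warning).
#' @param response name of the response column (e.g. the lnRR of a trait).
#' @param predictors character vector of >= 2 predictor columns.
#' @param seed integer seed (forest and permutations).
#' @param n_shuffle permutations per predictor (default 10).
#' @param holdout fraction of rows held out for the error measurement.
#' @param num_trees forest size (default 500).
#' @return Data frame with columns `predictor`, `importance` (increase in
#'   held-out MSE), sorted by decreasing importance.
#' @export
moderator_importance <- function(data, response, predictors, seed = 1L,
                                 n_shuffle = 10L, holdout = 0.3,
                                 num_trees = 500L) {
  stopifnot(is.data.frame(data), response %in% names(data))
  predictors <- setdiff(predictors, response)
  if (length(predictors) < 1L) stop("moderator_importance: no predictors")
  all_missing <- predictors[vapply(predictors, function(p) all(is.na(data[[p]])), logical(1))]
  if (length(all_missing)) {
    warning("moderator_importance: dropping all-missing predictor(s) ",
            paste(all_missing, collapse = ", "))
    predictors <- setdiff(predictors, all_missing)
  }
  if (length(predictors) < 2L) stop("moderator_importance: need >= 2 usable predictors")
  d <- data[, c(response, predictors), drop = FALSE]
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) < 20L) stop("moderator_importance: need >= 20 complete rows")
  for (p in predictors) if (is.character(d[[p]])) d[[p]] <- factor(d[[p]])

  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  n <- nrow(d)
  test_idx <- sample.int(n, max(2L, round(holdout * n)))
  train <- d[-test_idx, , drop = FALSE]
  test <- d[test_idx, , drop = FALSE]
  fml <- stats::as.formula(paste(response, "~", paste(predictors, collapse = "+")))
  rf <- ranger::ranger(fml, data = train, num.trees = num_trees,
                       seed = as.integer(seed), num.threads = 1L)
  base_mse <- mean((predict(rf, data = test, num.threads = 1L)$predictions -
                      test[[response]])^2)
  imp <- vapply(predictors, function(p) {
    incr <- numeric(n_shuffle)
    for (s in seq_len(n_shuffle)) {
      shuffled <- test
      shuffled[[p]] <- shuffled[[p]][sample.int(nrow(shuffled))]
      mse <- mean((predict(rf, data = shuffled, num.threads = 1L)$predictions -
                     shuffled[[response]])^2)
      incr[s] <- mse - base_mse
    }
    mean(incr)
  }, numeric(1))
  out <- data.frame(predictor = predictors, importance = unname(imp),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance), , drop = FALSE]
  rownames(out) <- NULL
  out
}
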