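# Meta-regression, model selection, quadratic summaries, Mantel tests,
# and tree-ensemble moderator importance.

test_that("noise-free linear data are recovered exactly", {
  x <- seq(0, 1, length.out = 10)
  y <- 2 * x + 1
  fit <- meta_regression(y, x, vi = rep(0.01, 10), tau2 = 0)
  expect_equal(unname(fit$coefficients), c(1, 2), tolerance = 1e-10)
  expect_equal(fit$R2, 1)
})

test_that("noise-free quadratic data recover the planted vertex", {
  x <- seq(-1, 1, length.out = 12)
  y <- -(x - 0.212)^2 + 0.05
  fit <- meta_regression(y, x, vi = rep(0.01, 12), form = "quadratic", tau2 = 0)
  expect_equal(unname(fit$coefficients[["b2"]]), -1, tolerance = 1e-10)
  qs <- quadratic_summary(fit)
  expect_equal(qs$vertex_x, 0.212, tolerance = 1e-10)
  expect_equal(qs$vertex_y, 0.05, tolerance = 1e-10)
})

test_that("weighted fits match the closed-form normal equations", {
  set.seed(80)
  x <- runif(30); vi <- runif(30, 0.01, 0.05)
  y <- 0.3 - 0.5 * x + 0.8 * x^2 + rnorm(30, 0, 0.1)
  tau2 <- 0.02
  fit <- meta_regression(y, x, vi = vi, form = "quadratic", tau2 = tau2)
  W <- diag(1 / (vi + tau2))
  X <- cbind(1, x, x^2)
  beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y)
  expect_equal(unname(fit$coefficients), as.numeric(beta), tolerance = 1e-10)
  expect_equal(unname(fit$vcov), unname(solve(t(X) %*% W %*% X)),
               tolerance = 1e-10)
})

test_that("rows with missing x are dropped and degenerate designs rejected", {
  x <- c(1, 2, 3, NA, 5, 6)
  y <- x; y[4] <- 99
  expect_message(fit <- meta_regression(y, x, vi = rep(0.01, 6), tau2 = 0),
                 "dropping 1")
  expect_equal(fit$k, 5)
  expect_error(meta_regression(y[1:4], rep(1, 4), vi = rep(0.01, 4), tau2 = 0),
               "constant")
  expect_error(meta_regression(y, rep(c(1, 2), 3), vi = rep(0.01, 6),
                               form = "quadratic", tau2 = 0), "quadratic")
})

test_that("quadratic weighted R2 is at least the nested linear R2", {
  set.seed(81)
  for (i in 1:8) {
    x <- runif(25); vi <- runif(25, 0.01, 0.05)
    y <- rnorm(25, 0.2 * x, 0.15)
    fl <- meta_regression(y, x, vi = vi, form = "linear", tau2 = 0.01)
    fq <- meta_regression(y, x, vi = vi, form = "quadratic", tau2 = 0.01)
    expect_gte(fq$R2, fl$R2 - 1e-12)
  }
})

test_that("model selection prefers the true linear form and applies tie rules", {
  set.seed(82)
  wins <- 0L
  for (i in 1:50) {
    x <- runif(40); vi <- rep(0.02, 40)
    y <- 0.1 + 0.4 * x + rnorm(40, 0, sqrt(vi))
    fits <- list(meta_regression(y, x, vi = vi, form = "linear", tau2 = 0),
                 meta_regression(y, x, vi = vi, form = "quadratic", tau2 = 0))
    if (select_model(fits)$form == "linear") wins <- wins + 1L
  }
  expect_gte(wins, 45L)   # >= 90% of replicates

  f1 <- fits[[1]]; f2 <- fits[[2]]
  f2$AIC <- f1$AIC               # forced AIC tie -> lower BIC wins
  expect_identical(select_model(list(f1, f2))$form,
                   if (f1$BIC <= f2$BIC) "linear" else "quadratic")
  expect_identical(select_model(list(f1))$form, "linear")
  f3 <- f2; f3$k <- 10
  expect_error(select_model(list(f1, f3)), "k mismatch")
})

test_that("quadratic summary finds roots matching a bisection oracle", {
  bisect <- function(f, lo, hi, tol = 1e-12) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }
  set.seed(83)
  for (i in 1:10) {
    a <- -runif(1, 0.5, 3); v <- runif(1, -1, 1); h <- runif(1, 0.05, 2)
    # construct y = a (x - v)^2 + h: concave with two real roots
    x <- seq(v - 3, v + 3, length.out = 15)
    y <- a * (x - v)^2 + h
    fit <- meta_regression(y, x, vi = rep(0.01, 15), form = "quadratic", tau2 = 0)
    qs <- quadratic_summary(fit)
    f <- function(z) a * (z - v)^2 + h
    r1 <- bisect(f, v - 3 - sqrt(h / -a), v)
    r2 <- bisect(f, v, v + 3 + sqrt(h / -a))
    expect_equal(qs$roots, c(r1, r2), tolerance = 1e-6)
    expect_equal(qs$positive_interval, c(r1, r2), tolerance = 1e-6)
    # the vertex is the argmax of the fitted curve
    cf <- fit$coefficients
    fitted_at <- function(z) cf[[1]] + cf[[2]] * z + cf[[3]] * z^2
    eps <- 1e-4
    expect_gte(fitted_at(qs$vertex_x), fitted_at(qs$vertex_x + eps))
    expect_gte(fitted_at(qs$vertex_x), fitted_at(qs$vertex_x - eps))
  }
})

test_that("quadratic summary handles no-root and misuse cases", {
  x <- seq(-1, 1, length.out = 10)
  y <- -(x^2) - 0.5                         # concave, always negative
  fit <- meta_regression(y, x, vi = rep(0.01, 10), form = "quadratic", tau2 = 0)
  qs <- quadratic_summary(fit)
  expect_length(qs$roots, 0)
  expect_null(qs$positive_interval)
  expect_lt(qs$vertex_y, 0)
  lin <- meta_regression(y, x, vi = rep(0.01, 10), form = "linear", tau2 = 0)
  expect_error(quadratic_summary(lin), "not quadratic")
})

test_that("mantel r is 1 against itself and matches an independent r", {
  set.seed(84)
  xy <- matrix(rnorm(20), 10, 2)
  a <- as.matrix(dist(xy))
  res <- mantel_test(a, a, n_perm = 99, seed = 1)
  expect_equal(res$r, 1)
  b <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
  expect_equal(mantel_test(a, b, n_perm = 9, seed = 1)$r, oracle_mantel_r(a, b),
               tolerance = 1e-12)
})

test_that("exhaustive mantel p equals enumeration over all relabelings", {
  set.seed(85)
  a <- as.matrix(dist(matrix(rnorm(10), 5, 2)))
  b <- as.matrix(dist(matrix(rnorm(10), 5, 2)))
  res <- mantel_test(a, b, exhaustive = TRUE)
  perms <- oracle_perms(1:5)
  r_obs <- oracle_mantel_r(a, b)
  rs <- apply(perms, 1, function(pm) oracle_mantel_r(a, b[pm, pm]))
  expect_equal(res$p, mean(rs >= r_obs - 1e-12), tolerance = 1e-12)
  expect_equal(res$n_perm, 120)
})

test_that("mantel r is invariant to increasing linear transforms of dist_b", {
  set.seed(86)
  a <- as.matrix(dist(matrix(rnorm(16), 8, 2)))
  b <- as.matrix(dist(matrix(rnorm(16), 8, 2)))
  r0 <- mantel_test(a, b, n_perm = 9, seed = 1)$r
  b2 <- 3.7 * b       # common positive rescaling (zero diagonal preserved)
  expect_equal(mantel_test(a, b2, n_perm = 9, seed = 1)$r, r0, tolerance = 1e-12)
})

test_that("mantel p-values use the add-one estimator and control type I", {
  set.seed(87)
  a <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
  b <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
  res <- mantel_test(a, b, n_perm = 99, seed = 5)
  expect_gte(res$p, 1 / 100)        # can never be exactly zero
  rejections <- 0L
  for (i in 1:100) {
    aa <- as.matrix(dist(matrix(rnorm(16), 8, 2)))
    bb <- as.matrix(dist(matrix(rnorm(16), 8, 2)))
    if (mantel_test(aa, bb, n_perm = 99, seed = i)$p < 0.05) {
      rejections <- rejections + 1L
    }
  }
  expect_lte(rejections, 12L)       # ~5% expected under the null
})

test_that("partial mantel behaves at the two analytic poles", {
  set.seed(88)
  a <- as.matrix(dist(matrix(rnorm(24), 12, 2)))
  b <- 0.7 * a + as.matrix(dist(matrix(rnorm(24), 12, 2)))
  diag(b) <- 0
  cc <- as.matrix(dist(matrix(rnorm(24), 12, 2)))   # unrelated conditioner
  pm <- partial_mantel_test(a, b, cc, n_perm = 99, seed = 1)
  m <- mantel_test(a, b, n_perm = 99, seed = 1)
  expect_equal(pm$r, m$r, tolerance = 0.15)         # ~ simple r
  # fully explained: dist_b equals the conditioning matrix
  expect_equal(partial_mantel_test(a, cc, cc, n_perm = 9, seed = 1)$r, 0)
  # small instance against the explicit residual-regression oracle
  lt <- function(m) m[lower.tri(m)]
  res_on <- function(y, x) residuals(lm(y ~ x))
  r_orc <- cor(res_on(lt(a), lt(cc)), res_on(lt(b), lt(cc)))
  expect_equal(pm$r, r_orc, tolerance = 1e-10)
})

test_that("moderator importance ranks a planted signal first", {
  set.seed(89)
  firsts <- 0L
  for (rep in 1:15) {
    n <- 120
    d <- data.frame(A = runif(n), B = runif(n), C = runif(n), D = runif(n))
    d$y <- 2 * d$A + rnorm(n, 0, 0.1)
    imp <- moderator_importance(d, "y", c("A", "B", "C", "D"), seed = rep)
    if (imp$predictor[1] == "A") firsts <- firsts + 1L
  }
  expect_gte(firsts, 14L)
})

test_that("pure-noise responses give no dominant predictor", {
  set.seed(90)
  n <- 100
  d <- data.frame(A = runif(n), B = runif(n), C = runif(n))
  d$y <- rnorm(n)
  imp <- moderator_importance(d, "y", c("A", "B", "C"), seed = 3)
  # no predictor should explain a meaningful share of the response variance
  expect_lt(max(imp$importance), 0.5 * var(d$y))
})

test_that("moderator importance input contracts hold", {
  n <- 30
  d <- data.frame(A = runif(n), B = NA_real_, y = rnorm(n))
  expect_error(suppressWarnings(moderator_importance(d, "y", c("A", "B"))),
               ">= 2")
  d$C <- runif(n)
  expect_warning(imp <- moderator_importance(d, "y", c("A", "B", "C"), seed = 1),
                 "all-missing")
  expect_setequal(imp$predictor, c("A", "C"))
  expect_error(moderator_importance(d[1:10, ], "y", c("A", "C")), "20 complete")
})
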