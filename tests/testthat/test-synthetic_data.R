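# The seeded study-database generator with known truth.

test_that("noise-free generator reproduces mu_true exactly", {
  spec <- synthetic_spec(seed = 5L, n_studies = 6L, obs_per_study = 3L,
                         mu_true = c(shannon = 0.05), tau_study = 0,
                         sigma_obs = 0, moderator_levels = list(),
                         sd_missing_rate = 0)
  db <- generate_observations(spec)
  lnrr <- log(db$mean_treat / db$mean_ctrl)
  expect_equal(lnrr, rep(0.05, nrow(db)), tolerance = 1e-12)
})

test_that("the generator is deterministic and prefix-stable in n_studies", {
  spec <- synthetic_spec(seed = 17L, n_studies = 8L, obs_per_study = 3L)
  a <- generate_observations(spec)
  b <- generate_observations(spec)
  expect_identical(strip_attrs(a), strip_attrs(b))
  # adding studies must not reshuffle the draws of earlier studies
  spec_small <- synthetic_spec(seed = 17L, n_studies = 5L, obs_per_study = 3L)
  small <- generate_observations(spec_small)
  expect_identical(strip_attrs(small), strip_attrs(a[1:15, ]))
})

test_that("generated lnRRs average to mu_true over many observations", {
  spec <- synthetic_spec(seed = 99L, n_studies = 2500L, obs_per_study = 4L,
                         mu_true = c(shannon = 0.05), moderator_levels = list(),
                         sd_missing_rate = 0)
  db <- generate_observations(spec)
  expect_equal(nrow(db), 10000L)
  lnrr <- log(db$mean_treat / db$mean_ctrl)
  # observed lnRR = theta + sampling noise from the two arms
  se_mean <- sd(lnrr) / sqrt(length(lnrr))
  expect_lt(abs(mean(lnrr) - 0.05), 3 * se_mean)
})

test_that("moderator shifts move the affected subgroup's mean effect", {
  spec <- synthetic_spec(seed = 41L, n_studies = 400L, obs_per_study = 2L,
                         mu_true = c(shannon = 0.02),
                         moderator_levels = list(
                           n_source = c(mineral = 0, mixed = 0.3)),
                         tau_study = 0.02, sigma_obs = 0.01,
                         sd_missing_rate = 0)
  db <- generate_observations(spec)
  lnrr <- log(db$mean_treat / db$mean_ctrl)
  gap <- mean(lnrr[db$n_source == "mixed"]) - mean(lnrr[db$n_source == "mineral"])
  expect_equal(gap, 0.3, tolerance = 0.05)
})

test_that("generated databases pass validation and the density filter", {
  spec <- synthetic_spec(seed = 7L, n_studies = 12L, obs_per_study = 3L)
  db <- generate_observations(spec)
  expect_equal(nrow(validation_report(db)), 0L)
  expect_equal(nrow(suppressMessages(filter_rdt(db))), nrow(db))
  expect_true(all(db$rdt >= 1 & db$rdt <= 2))
  expect_true(all(db$is_final_year))
})

test_that("sd masking hits roughly the configured rate", {
  spec <- synthetic_spec(seed = 23L, n_studies = 500L, obs_per_study = 2L,
                         sd_missing_rate = 0.3)
  db <- generate_observations(spec)
  rate <- mean(is.na(c(db$sd_treat, db$sd_ctrl)))
  expect_lt(abs(rate - 0.3), 0.03)
})

test_that("imputed databases pool close to the complete-data estimate", {
  spec_full <- synthetic_spec(seed = 61L, n_studies = 30L, obs_per_study = 3L,
                              mu_true = c(shannon = 0.05),
                              moderator_levels = list(), sd_missing_rate = 0)
  spec_miss <- synthetic_spec(seed = 61L, n_studies = 30L, obs_per_study = 3L,
                              mu_true = c(shannon = 0.05),
                              moderator_levels = list(), sd_missing_rate = 0.3)
  fit_of <- function(spec) {
    db <- impute_sd(generate_observations(spec))
    fit_multilevel_re(compute_effect_sizes(db))
  }
  f1 <- fit_of(spec_full); f2 <- fit_of(spec_miss)
  expect_lt(abs(f1$mu - f2$mu), f1$se)
})

test_that("ordination clouds respect the configured geometry", {
  # symmetric null: no separation, equal dispersion
  base <- list(n_per_group = 40L, centroid_separation = 0,
               dispersion_ctrl = 1, dispersion_treat = 1)
  vals <- vapply(1:20, function(s) {
    spec <- synthetic_spec(seed = s, ordination = base)
    lnrr_beta(summarize_distances(generate_ordination(spec)))
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.03)

  # doubled treatment dispersion -> lnrr_beta near ln 2 at large n
  spec2 <- synthetic_spec(seed = 3L, ordination = list(
    n_per_group = 500L, centroid_separation = 0,
    dispersion_ctrl = 1, dispersion_treat = 2))
  d2 <- summarize_distances(generate_ordination(spec2))
  expect_lt(abs(lnrr_beta(d2) - log(2)), 0.06)

  # wide separation -> strongly positive between_within structure ratio
  spec3 <- synthetic_spec(seed = 4L, ordination = list(
    n_per_group = 30L, centroid_separation = 10,
    dispersion_ctrl = 1, dispersion_treat = 1))
  d3 <- summarize_distances(generate_ordination(spec3))
  expect_gt(lnrr_structure(d3, "between_within"), 1)
  expect_error(generate_ordination(
    synthetic_spec(seed = 1, ordination = modifyList(base, list(n_per_group = 1L)))),
    ">= 2")
})

test_that("yield pairs follow the quadratic link and are recoverable", {
  spec <- synthetic_spec(seed = 19L, quad_noise_sd = 0)
  s <- seq(-0.2, 0.6, length.out = 25)
  y <- generate_yield_pairs(spec, s)
  q <- spec$quad_link
  expect_equal(y, q[["a"]] * s^2 + q[["b"]] * s + q[["c"]], tolerance = 1e-12)
  fit <- meta_regression(y, s, vi = rep(0.01, 25), form = "quadratic", tau2 = 0)
  expect_equal(unname(fit$coefficients), unname(q[c("c", "b", "a")]),
               tolerance = 1e-8)
  # with noise, the fitted vertex stays within its standard error
  spec2 <- synthetic_spec(seed = 20L, quad_noise_sd = 0.02)
  y2 <- generate_yield_pairs(spec2, s)
  fit2 <- meta_regression(y2, s, vi = rep(1e-4, 25), form = "quadratic",
                          tau2 = 0.02^2)
  qs2 <- quadratic_summary(fit2)
  v_true <- -q[["b"]] / (2 * q[["a"]])
  # delta-method SE of -b1/(2 b2)
  cf <- fit2$coefficients; V <- fit2$vcov
  gr <- c(0, -1 / (2 * cf[["b2"]]), cf[["b1"]] / (2 * cf[["b2"]]^2))
  se_v <- sqrt(drop(t(gr) %*% V %*% gr))
  expect_lt(abs(qs2$vertex_x - v_true), 3 * se_v + 0.02)
  # the vertex maximizes the mean response among probed values
  y_clean <- generate_yield_pairs(spec, c(v_true, v_true + 0.1, v_true - 0.1))
  expect_true(which.max(y_clean) == 1L)
})

test_that("invalid specs are rejected", {
  expect_error(synthetic_spec(sd_missing_rate = 1.5))
  expect_error(synthetic_spec(mu_true = c(oddtrait = 0.1)))
  expect_error(synthetic_spec(moderator_levels = list(n_source = c(guano = 1))))
  expect_error(synthetic_spec(tau_study = -0.1))
})
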