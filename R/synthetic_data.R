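# Seeded synthetic study databases with known truth.
#
# The generator emulates the structure of the real intercropping database:
# study-nested observations with between-study heterogeneity, lognormal
# control means so all means are positive by construction, treatment means
# consistent with a target lnRR, moderator level shifts, a quadratic
# covariate -> effect link for the yield/diversity relationship, and
# two-group 2D ordination clouds with controllable separation/dispersion.
# One stream per (spec, study) index, so adding studies never reshuffles
# the draws of earlier ones.

# Deterministic 32-bit sub-seed for unit 'i' of a spec-level seed.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + (i + 1) * 1299721) %% 2147483629)
}

#' Parameterization of a synthetic study database
#'
#' Bundles every knob of the simulator.  Defaults describe a database of
#' the size and effect structure typical of published soybean-intercropping
#' syntheses: 89 studies contributing a few observations each, trait-level
#' true lnRRs of a few percent for alpha-diversity, a large positive
#' structure shift, a near-zero yield response, moderate between-study
#' heterogeneity, and arm CVs around 15% with 4 replicates per arm.
#'
#' @param seed integer master seed; a fixed seed yields byte-identical data.
#' @param n_studies number of studies (articles).
#' @param obs_per_study observations contributed by each study.
#' @param mu_true named vector: true lnRR per trait (names from [sbi_traits()]).
#' @param tau_study between-study SD of the study intercept (lnRR units).
#' @param sigma_obs SD of the observation-level heterogeneity.
#' @param cv_arm target within-arm coefficient of variation.
#' @param n_per_arm replicates per arm.
#' @param moderator_levels named list: for each categorical moderator, a
#'   named numeric vector of additive lnRR shifts per level (levels drawn
#'   uniformly).  The default shifts are deviation-coded (mean zero) so the
#'   trait-level estimand stays `mu_true`; their ordering (mixed > organic >
#'   mineral nitrogen) mirrors the subgroup pattern typical of fertilizer
#'   regimes.
#' @param quad_link numeric `c(a, b, c)`: yield lnRR as a quadratic in the
#'   Shannon lnRR.  The default has roots at 0.008 and 0.401 (yield
#'   advantage inside that Shannon-response window) and is concave.
#' @param quad_noise_sd SD of the noise around the quadratic link.
#' @param nfr_range range (kg N/ha) of the nitrogen application rate.
#' @param sd_missing_rate probability that a reported arm SD is masked.
#' @param ordination list `n_per_group`, `centroid_separation`,
#'   `dispersion_ctrl`, `dispersion_treat` for [generate_ordination()].
#' @return Object of class `sbi_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_studies = 89L,
                           obs_per_study = 4L,
                           mu_true = c(shannon = 0.036, chao1 = 0.034,
                                       richness = 0.102, beta_diversity = -0.098,
                                       structure = 0.741, yield = -0.020),
                           tau_study = 0.05,
                           sigma_obs = 0.03,
                           cv_arm = 0.15,
                           n_per_arm = 4L,
                           moderator_levels = list(
                             n_source = c(mineral = -0.03, organic = 0,
                                          mixed = 0.05, none = -0.02)),
                           quad_link = c(a = -1, b = 0.409, c = -0.003272),
                           quad_noise_sd = 0.02,
                           nfr_range = c(0, 300),
                           sd_missing_rate = 0.1,
                           ordination = list(n_per_group = 6L,
                                             centroid_separation = 2,
                                             dispersion_ctrl = 1,
                                             dispersion_treat = 1)) {
  stopifnot(
    length(seed) == 1L, is.finite(seed),
    n_studies >= 1L, obs_per_study >= 1L,
    length(mu_true) >= 1L, !is.null(names(mu_true)),
    all(names(mu_true) %in% sbi_traits()),
    tau_study >= 0, sigma_obs >= 0, cv_arm >= 0, n_per_arm >= 1L,
    length(quad_link) == 3L, quad_noise_sd >= 0,
    length(nfr_range) == 2L, nfr_range[1] <= nfr_range[2],
    sd_missing_rate >= 0, sd_missing_rate <= 1,
    ordination$n_per_group >= 2L,
    ordination$centroid_separation >= 0,
    ordination$dispersion_ctrl > 0, ordination$dispersion_treat > 0
  )
  for (mn in names(moderator_levels)) {
    if (!mn %in% names(sbi_enum_levels())) stop("unknown moderator: ", mn)
    if (!all(names(moderator_levels[[mn]]) %in% sbi_enum_levels()[[mn]])) {
      stop("unknown level(s) for moderator ", mn)
    }
  }
  spec <- list(seed = as.integer(seed), n_studies = as.integer(n_studies),
               obs_per_study = as.integer(obs_per_study), mu_true = mu_true,
               tau_study = tau_study, sigma_obs = sigma_obs, cv_arm = cv_arm,
               n_per_arm = as.integer(n_per_arm),
               moderator_levels = moderator_levels,
               quad_link = setNames(as.numeric(quad_link), c("a", "b", "c")),
               quad_noise_sd = quad_noise_sd, nfr_range = nfr_range,
               sd_missing_rate = sd_missing_rate, ordination = ordination)
  class(spec) <- "sbi_spec"
  spec
}

#' Generate a synthetic study-observation database
#'
#' Per study i, a study intercept `b_i ~ N(0, tau_study^2)` is drawn; each
#' observation then has true effect `theta = mu_true[trait] + moderator
#' shifts + b_i + N(0, sigma_obs^2)`, a lognormal control mean
#' (`meanlog = 1`, `sdlog = 0.3`), treatment mean `x_c * exp(theta)`, and
#' arm SDs `cv_arm * mean`, perturbed by +/-10% and masked missing at
#' `sd_missing_rate`.  Moderators are seeded categorical draws, covariates
#' seeded uniforms over field-realistic ranges, and RDT is drawn in [1, 2]
#' (replacement-to-additive designs) so the generated database passes the
#' density filter unchanged.
#'
#' @param spec `sbi_spec` object.
#' @return Validated observation data frame ([sbi_schema()] columns) with a
#'   `"truth"` attribute carrying the per-row true effect `theta`.
#' @export
generate_observations <- function(spec) {
  stopifnot(inherits(spec, "sbi_spec"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)

  lev <- sbi_enum_levels()
  traits <- names(spec$mu_true)
  rows <- vector("list", spec$n_studies * spec$obs_per_study)
  theta_all <- numeric(length(rows))
  r <- 0L
  for (i in seq_len(spec$n_studies)) {
    set.seed(derive_seed(spec$seed, i))
    b_i <- rnorm(1, 0, spec$tau_study)
    for (j in seq_len(spec$obs_per_study)) {
      r <- r + 1L
      trait <- if (length(traits) == 1L) traits else sample(traits, 1L)
      cats <- lapply(setNames(nm = setdiff(names(lev), "trait")), function(cn) {
        if (cn %in% names(spec$moderator_levels)) {
          sample(names(spec$moderator_levels[[cn]]), 1L)
        } else {
          sample(lev[[cn]], 1L)
        }
      })
      shift <- if (length(spec$moderator_levels)) {
        sum(vapply(names(spec$moderator_levels), function(mn)
          spec$moderator_levels[[mn]][[cats[[mn]]]], numeric(1)))
      } else 0
      theta <- spec$mu_true[[trait]] + shift + b_i + rnorm(1, 0, spec$sigma_obs)
      x_c <- rlnorm(1, meanlog = 1, sdlog = 0.3)
      x_t <- x_c * exp(theta)
      sd_t <- spec$cv_arm * x_t * runif(1, 0.9, 1.1)
      sd_c <- spec$cv_arm * x_c * runif(1, 0.9, 1.1)
      miss_t <- runif(1) < spec$sd_missing_rate
      miss_c <- runif(1) < spec$sd_missing_rate
      theta_all[r] <- theta
      rows[[r]] <- data.frame(
        schema_version = SBI_SCHEMA_VERSION,
        study_id = sprintf("study_%03d", i),
        obs_id = sprintf("obs_%03d_%02d", i, j),
        trait = trait,
        taxon_group = cats$taxon_group,
        mean_treat = x_t, mean_ctrl = x_c,
        sd_treat = if (miss_t) NA_real_ else sd_t,
        sd_ctrl = if (miss_c) NA_real_ else sd_c,
        n_treat = spec$n_per_arm, n_ctrl = spec$n_per_arm,
        n_source = cats$n_source, n_timing = cats$n_timing,
        companion_type = cats$companion_type, system = cats$system,
        condition = cats$condition, compartment = cats$compartment,
        strip = cats$strip,
        map_mm = runif(1, 300, 2000), mat_c = runif(1, 2, 25),
        duration_yr = sample(1:10, 1L),
        nfr_kg_ha = runif(1, spec$nfr_range[1], spec$nfr_range[2]),
        rdt = runif(1, 1, 2), prdt = runif(1, 0.3, 1),
        phi = runif(1, 4.5, 8.5), soci = runif(1, 5, 40),
        tni = runif(1, 0.5, 3),
        rows_soybean = sample(2:6, 1L), dist_soybean_m = runif(1, 0.2, 1),
        is_final_year = TRUE,
        stringsAsFactors = FALSE
      )
    }
  }
  db <- do.call(rbind, rows)
  db <- validate_observations(db)
  stopifnot(nrow(validation_report(db)) == 0L)
  attr(db, "truth") <- theta_all
  db
}

#' Generate a two-group 2D ordination cloud
#'
#' Control samples are bivariate normal around the origin with isotropic SD
#' `dispersion_ctrl`; treatment samples around `(centroid_separation, 0)`
#' with SD `dispersion_treat`.
#'
#' @param spec `sbi_spec` object (fields under `spec$ordination`).
#' @param obs_id identifier attached to the generated set.
#' @return Ordination data frame (see [validate_ordination()]).
#' @export
generate_ordination <- function(spec, obs_id = "synthetic_ord") {
  stopifnot(inherits(spec, "sbi_spec"))
  o <- spec$ordination
  if (o$n_per_group < 2L) stop("generate_ordination: n_per_group must be >= 2")
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(derive_seed(spec$seed, 0L))
  n <- o$n_per_group
  ord <- data.frame(
    obs_id = obs_id,
    sample_id = c(sprintf("c%02d", seq_len(n)), sprintf("t%02d", seq_len(n))),
    group = rep(c("control", "treatment"), each = n),
    axis1 = c(rnorm(n, 0, o$dispersion_ctrl),
              rnorm(n, o$centroid_separation, o$dispersion_treat)),
    axis2 = c(rnorm(n, 0, o$dispersion_ctrl),
              rnorm(n, 0, o$dispersion_treat)),
    method = "PCoA",
    stringsAsFactors = FALSE
  )
  validate_ordination(ord)
}

#' Generate yield lnRRs linked quadratically to Shannon lnRRs
#'
#' `y = a s^2 + b s + c + N(0, quad_noise_sd^2)` with `(a, b, c)` from
#' `spec$quad_link`, emulating the unimodal yield/diversity dose-response.
#'
#' @param spec `sbi_spec` object.
#' @param shannon_lnrr numeric vector of Shannon effect sizes.
#' @return Numeric vector of yield lnRRs, same length.
#' @export
generate_yield_pairs <- function(spec, shannon_lnrr) {
  stopifnot(inherits(spec, "sbi_spec"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(derive_seed(spec$seed, 999983L))
  q <- spec$quad_link
  q[["a"]] * shannon_lnrr^2 + q[["b"]] * shannon_lnrr + q[["c"]] +
    rnorm(length(shannon_lnrr), 0, spec$quad_noise_sd)
}
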