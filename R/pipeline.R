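# Pipeline orchestration: the full analysis flow (filters -> effect sizes
# -> pooling -> subgroups -> bias -> meta-regression -> ordination) driven
# by a single validated configuration, with deterministic seeded outputs.

RUN_CONFIG_KEYS <- c("input", "db", "ordination", "ordination_path", "spec",
                     "traits", "moderators", "covariates", "convention",
                     "cv_pool", "alpha", "n_perm", "seed", "out_dir")

#' Build and validate a pipeline configuration
#'
#' @param input path to a study-observation CSV (alternative to `db`).
#' @param db in-memory observation data frame (alternative to `input`).
#' @param ordination in-memory ordination data frame.
#' @param ordination_path path to an ordination-coordinate CSV.
#' @param spec optional [synthetic_spec()] for [run_simulate()].
#' @param traits traits to analyze (default all of [sbi_traits()]).
#' @param moderators categorical moderators for [run_subgroups()].
#' @param covariates continuous covariates for [run_modreg()].
#' @param convention lnRRs convention (see [lnrr_structure()]).
#' @param cv_pool CV pooling stratum for [impute_sd()].
#' @param alpha significance level.
#' @param n_perm permutations for Mantel-type tests.
#' @param seed master seed for every stochastic stage.
#' @param out_dir optional directory; when set, each stage writes its CSV
#'   report there with a header comment carrying the config hash and seed.
#' @param ... rejected: any unknown key is a fatal error naming the key.
#' @return Object of class `sbi_config`.
#' @export
run_config <- function(input = NULL, db = NULL, ordination = NULL,
                       ordination_path = NULL, spec = NULL,
                       traits = sbi_traits(),
                       moderators = c("taxon_group", "n_source", "n_timing",
                                      "companion_type", "system", "condition",
                                      "compartment", "strip"),
                       covariates = c("nfr_kg_ha", "map_mm", "mat_c",
                                      "duration_yr", "phi", "soci", "tni"),
                       convention = c("between_within", "as_printed"),
                       cv_pool = c("trait_arm", "global"),
                       alpha = 0.05, n_perm = 999L, seed = 1L,
                       out_dir = NULL, ...) {
  extra <- list(...)
  if (length(extra)) {
    stop("run_config: unknown configuration key(s): ",
         paste(names(extra), collapse = ", "))
  }
  convention <- match.arg(convention)
  cv_pool <- match.arg(cv_pool)
  stopifnot(alpha > 0, alpha < 1, n_perm >= 1)
  if (!all(traits %in% sbi_traits())) {
    stop("run_config: unknown trait(s): ",
         paste(setdiff(traits, sbi_traits()), collapse = ", "))
  }
  known_cols <- sbi_schema()
  if (!all(moderators %in% known_cols)) {
    stop("run_config: moderator(s) not in the schema: ",
         paste(setdiff(moderators, known_cols), collapse = ", "))
  }
  if (!all(covariates %in% known_cols)) {
    stop("run_config: covariate(s) not in the schema: ",
         paste(setdiff(covariates, known_cols), collapse = ", "))
  }
  cfg <- list(input = input, db = db, ordination = ordination,
              ordination_path = ordination_path, spec = spec,
              traits = traits, moderators = moderators,
              covariates = covariates, convention = convention,
              cv_pool = cv_pool, alpha = alpha, n_perm = as.integer(n_perm),
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "sbi_config"
  cfg
}

# FNV-1a hash of the configuration (stable across sessions).
config_hash <- function(config) {
  stable <- config[setdiff(names(config), c("db", "ordination", "out_dir"))]
  txt <- paste(deparse(stable), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# Write a report CSV with a provenance comment line.
write_report <- function(df, name, config) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  path <- file.path(config$out_dir, paste0(name, ".csv"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# sbimeta report=%s config_hash=%s seed=%d",
                     name, config_hash(config), config$seed), con)
  write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}

# Load, filter and imputation-complete the database of a config.
prepare_database <- function(config) {
  db <- config$db
  if (is.null(db)) {
    if (is.null(config$input)) stop("config has neither 'db' nor 'input'")
    db <- read_observations(config$input)
  } else {
    db <- validate_observations(db)
  }
  db <- filter_rdt(db)
  db <- select_final_year(db)
  if (nrow(db) > 0L) db <- impute_sd(db, pool = config$cv_pool)
  db
}

empty_overall_row <- function(trait) {
  data.frame(trait = trait, k = 0L, n_studies = 0L, mu = NA_real_,
             se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
             tau2_study = NA_real_, tau2_obs = NA_real_, z = NA_real_,
             p = NA_real_, significant = NA, obs_ids = "",
             stringsAsFactors = FALSE)
}

#' Overall pooled effects per trait
#'
#' Runs the full per-trait flow: density and final-year filters, SD
#' imputation, lnRR effect sizes, multilevel pooling, and the CI
#' zero-crossing significance call.  Traits without observations yield a
#' `k = 0` row and a warning.
#'
#' @param config `sbi_config` from [run_config()].
#' @return Data frame, one row per trait, with a provenance column
#'   `obs_ids`.  Written to `overall.csv` under `out_dir` when set.
#' @export
run_overall <- function(config) {
  stopifnot(inherits(config, "sbi_config"))
  db <- prepare_database(config)
  rows <- lapply(config$traits, function(tr) {
    sub <- db[db$trait == tr, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning("run_overall: no observations for trait '", tr, "'")
      return(empty_overall_row(tr))
    }
    eff <- compute_effect_sizes(sub)
    if (nrow(eff) == 0L) return(empty_overall_row(tr))
    fit <- fit_multilevel_re(eff, level = 1 - config$alpha)
    data.frame(trait = tr, k = fit$k, n_studies = fit$n_studies,
               mu = unname(fit$mu), se = unname(fit$se),
               ci_low = unname(fit$ci_low), ci_high = unname(fit$ci_high),
               tau2_study = fit$tau2_study, tau2_obs = fit$tau2_obs,
               z = unname(fit$z), p = unname(fit$p),
               significant = is_significant(fit),
               obs_ids = paste(eff$obs_id, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  write_report(out, "overall", config)
  out
}

#' Subgroup analyses per trait and moderator
#'
#' For every trait x moderator pair with at least two observed levels:
#' per-level pooled estimates, the omnibus Q_M test, and single-step post
#' hoc pairwise comparisons (seeded from `config$seed`).  Moderators with a
#' single observed level are skipped with a warning.
#'
#' @param config `sbi_config`.
#' @return List with data frames `subgroups` (per-level rows, Q_M columns)
#'   and `posthoc` (pairwise comparisons).  Written to `subgroups.csv` /
#'   `posthoc.csv` when `out_dir` is set.
#' @export
run_subgroups <- function(config) {
  stopifnot(inherits(config, "sbi_config"))
  db <- prepare_database(config)
  sub_rows <- list()
  ph_rows <- list()
  for (tr in config$traits) {
    dtr <- db[db$trait == tr, , drop = FALSE]
    if (nrow(dtr) == 0L) next
    eff <- compute_effect_sizes(dtr)
    dtr <- dtr[dtr$obs_id %in% eff$obs_id, , drop = FALSE]
    for (mod in config$moderators) {
      vals <- dtr[[mod]]
      ok <- !is.na(vals)
      lev_obs <- unique(vals[ok])
      if (length(lev_obs) < 2L || sum(ok) < 4L) {
        warning("run_subgroups: skipping ", tr, " x ", mod,
                " (fewer than two observed levels)")
        next
      }
      sg <- tryCatch(
        fit_subgroup(eff[ok, , drop = FALSE], moderator = vals[ok],
                     level = 1 - config$alpha),
        error = function(e) {
          warning("run_subgroups: ", tr, " x ", mod, " failed: ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(sg)) next
      tab <- sg$table
      tab <- cbind(data.frame(trait = tr, moderator = mod,
                              stringsAsFactors = FALSE),
                   tab,
                   data.frame(QM = sg$QM, df = sg$df, p_QM = sg$p_QM,
                              obs_ids = paste(eff$obs_id[ok], collapse = ";"),
                              stringsAsFactors = FALSE))
      sub_rows[[length(sub_rows) + 1L]] <- tab
      ph <- posthoc_pairwise(sg, seed = config$seed)
      ph_rows[[length(ph_rows) + 1L]] <-
        cbind(data.frame(trait = tr, moderator = mod, stringsAsFactors = FALSE), ph)
    }
  }
  subgroups <- if (length(sub_rows)) do.call(rbind, sub_rows) else NULL
  posthoc <- if (length(ph_rows)) do.call(rbind, ph_rows) else NULL
  write_report(subgroups, "subgroups", config)
  write_report(posthoc, "posthoc", config)
  list(subgroups = subgroups, posthoc = posthoc)
}

#' Publication-bias diagnostics per trait
#'
#' Rosenthal fail-safe N with the 5n + 10 robustness rule, plus the
#' Begg-type Kendall rank test where at least three effects exist.
#'
#' @param config `sbi_config`.
#' @return Data frame, one row per trait with >= 1 effect.  Written to
#'   `bias.csv` when `out_dir` is set.
#' @export
run_bias <- function(config) {
  stopifnot(inherits(config, "sbi_config"))
  db <- prepare_database(config)
  rows <- list()
  for (tr in config$traits) {
    eff <- compute_effect_sizes(db[db$trait == tr, , drop = FALSE])
    if (nrow(eff) == 0L) next
    br <- bias_report(eff, alpha = config$alpha)
    rows[[length(rows) + 1L]] <- data.frame(
      trait = tr, k = br$n_obs, failsafe_n = br$failsafe_n,
      threshold = br$threshold, robust = br$robust,
      kendall_tau = br$kendall_tau, p_kendall = br$p_kendall,
      obs_ids = paste(eff$obs_id, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else NULL
  write_report(out, "bias", config)
  out
}

#' Continuous-moderator meta-regressions per trait
#'
#' For every trait x covariate pair, fits the linear and quadratic weighted
#' meta-regressions, selects by AIC/BIC ([select_model()]), and extracts the
#' vertex / roots / positive interval when the quadratic wins.
#'
#' @param config `sbi_config`.
#' @return Data frame, one row per trait x covariate.  Written to
#'   `modreg.csv` when `out_dir` is set.
#' @export
run_modreg <- function(config) {
  stopifnot(inherits(config, "sbi_config"))
  db <- prepare_database(config)
  rows <- list()
  for (tr in config$traits) {
    dtr <- db[db$trait == tr, , drop = FALSE]
    if (nrow(dtr) == 0L) next
    eff <- compute_effect_sizes(dtr)
    dtr <- dtr[match(eff$obs_id, dtr$obs_id), , drop = FALSE]
    for (cv in config$covariates) {
      x <- dtr[[cv]]
      fits <- tryCatch(suppressMessages(list(
        meta_regression(eff, x, form = "linear"),
        meta_regression(eff, x, form = "quadratic"))),
        error = function(e) NULL)
      if (is.null(fits)) next
      best <- select_model(fits)
      qs <- if (best$form == "quadratic") quadratic_summary(best) else NULL
      cf <- best$coefficients
      rows[[length(rows) + 1L]] <- data.frame(
        trait = tr, covariate = cv, form = best$form, k = best$k,
        intercept = cf[["intercept"]], b1 = cf[["b1"]],
        b2 = if (best$form == "quadratic") cf[["b2"]] else NA_real_,
        R2 = best$R2, p_model = best$p_model,
        AIC = best$AIC, BIC = best$BIC,
        AIC_linear = fits[[1]]$AIC, AIC_quadratic = fits[[2]]$AIC,
        vertex_x = if (!is.null(qs)) qs$vertex_x else NA_real_,
        vertex_y = if (!is.null(qs)) qs$vertex_y else NA_real_,
        root_low = if (!is.null(qs) && length(qs$roots) == 2L) qs$roots[1] else NA_real_,
        root_high = if (!is.null(qs) && length(qs$roots) == 2L) qs$roots[2] else NA_real_,
        obs_ids = paste(eff$obs_id, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else NULL
  write_report(out, "modreg", config)
  out
}

#' Ordination-derived beta-diversity and structure response ratios
#'
#' For every ordination set (grouped by `obs_id`) in the configured
#' coordinate table: within/between mean Euclidean distances, lnRRb, and
#' lnRRs under both conventions.
#'
#' @param config `sbi_config` with `ordination` or `ordination_path` set.
#' @return Data frame, one row per ordination set.  Written to
#'   `ordination.csv` when `out_dir` is set.
#' @export
run_ordination <- function(config) {
  stopifnot(inherits(config, "sbi_config"))
  ord <- config$ordination
  if (is.null(ord)) {
    if (is.null(config$ordination_path)) stop("config has no ordination table")
    ord <- read_ordination(config$ordination_path)
  } else {
    ord <- validate_ordination(ord)
  }
  rows <- lapply(unique(ord$obs_id), function(oid) {
    os <- ord[ord$obs_id == oid, , drop = FALSE]
    d <- summarize_distances(os)
    data.frame(
      obs_id = oid, method = os$method[1],
      n_ctrl = d$n_ctrl, n_treat = d$n_treat,
      d_within_ctrl = d$d_within_ctrl, d_within_treat = d$d_within_treat,
      d_between = d$d_between,
      lnrr_beta = if (length(d$degenerate)) NA_real_ else lnrr_beta(d),
      lnrr_structure = lnrr_structure(d, config$convention),
      lnrr_structure_as_printed = if (d$d_within_treat > 0)
        lnrr_structure(d, "as_printed") else NA_real_,
      lnrr_structure_between_within = if (d$d_between > 0)
        lnrr_structure(d, "between_within") else NA_real_,
      degenerate = paste(d$degenerate, collapse = ";"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  write_report(out, "ordination", config)
  out
}

#' Generate a synthetic database (and ordination set) from the config's spec
#'
#' @param config `sbi_config` with `spec` set to a [synthetic_spec()].
#' @return List with `db` (observation data frame) and `ordination`.  When
#'   `out_dir` is set, writes `simulated_observations.csv` and
#'   `simulated_ordination.csv`.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "sbi_config"))
  if (is.null(config$spec)) stop("run_simulate: config$spec is not set")
  db <- generate_observations(config$spec)
  ord <- generate_ordination(config$spec)
  if (!is.null(config$out_dir)) {
    if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
    write_observations(db, file.path(config$out_dir, "simulated_observations.csv"))
    write.csv(ord, file.path(config$out_dir, "simulated_ordination.csv"),
              row.names = FALSE, na = "")
  }
  list(db = db, ordination = ord)
}

#' Run every pipeline stage and collect the report tables
#'
#' @param config `sbi_config`.
#' @return Named list: `overall`, `subgroups`, `posthoc`, `bias`, `modreg`,
#'   and (when an ordination table is configured) `ordination`.
#' @export
run_report <- function(config) {
  stopifnot(inherits(config, "sbi_config"))
  sg <- run_subgroups(config)
  out <- list(
    overall = run_overall(config),
    subgroups = sg$subgroups,
    posthoc = sg$posthoc,
    bias = run_bias(config),
    modreg = run_modreg(config)
  )
  if (!is.null(config$ordination) || !is.null(config$ordination_path)) {
    out$ordination <- run_ordination(config)
  }
  out
}
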