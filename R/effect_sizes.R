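# lnRR effect sizes, sampling variances, CV-based SD imputation, and the
# relative planting-density metrics RDT / pRDT.

#' Log response ratio
#'
#' lnRR = ln(x_t) - ln(x_c), the effect-size metric for all mean-valued
#' traits: treatment (intercropping) mean over control (monoculture) mean on
#' the natural-log scale.
#'
#' @param x_t treatment-arm mean(s), strictly positive.
#' @param x_c control-arm mean(s), strictly positive.
#' @return Numeric vector of lnRR values.
#' @export
log_response_ratio <- function(x_t, x_c) {
  if (any(!is.finite(x_t)) || any(x_t <= 0)) {
    stop("log_response_ratio: treatment mean must be positive and finite")
  }
  if (any(!is.finite(x_c)) || any(x_c <= 0)) {
    stop("log_response_ratio: control mean must be positive and finite")
  }
  log(x_t) - log(x_c)
}

#' Sampling variance of the log response ratio
#'
#' v = s_t^2 / (n_t x_t^2) + s_c^2 / (n_c x_c^2): the sum of the two
#' squared-coefficient-of-variation-over-n terms.  Depends on the arms only
#' through their CVs and sample sizes, so it is invariant to rescaling a
#' trait's units.
#'
#' @param s_t,s_c arm standard deviations (>= 0).
#' @param n_t,n_c arm sample sizes (>= 1).
#' @param x_t,x_c arm means (> 0).
#' @return Numeric vector of sampling variances.
#' @export
lnrr_variance <- function(s_t, n_t, x_t, s_c, n_c, x_c) {
  if (any(!is.finite(s_t)) || any(s_t < 0) || any(!is.finite(s_c)) || any(s_c < 0)) {
    stop("lnrr_variance: standard deviations must be non-negative")
  }
  if (any(!is.finite(n_t)) || any(n_t < 1) || any(!is.finite(n_c)) || any(n_c < 1)) {
    stop("lnrr_variance: sample sizes must be >= 1")
  }
  if (any(!is.finite(x_t)) || any(x_t <= 0) || any(!is.finite(x_c)) || any(x_c <= 0)) {
    stop("lnrr_variance: means must be positive")
  }
  s_t^2 / (n_t * x_t^2) + s_c^2 / (n_c * x_c^2)
}

#' Relative density total (RDT) of a two-species intercrop
#'
#' RDT = d1_ic/d1_sc + d2_ic/d2_sc, where d*_ic are the component densities
#' in the intercrop (plants per unit area of the whole intercrop) and d*_sc
#' the corresponding sole-crop densities.  RDT = 1 is a replacement design;
#' RDT > 1 an additive design.
#'
#' @param d1_ic,d2_ic intercrop densities of species 1 and 2.
#' @param d1_sc,d2_sc sole-crop densities of species 1 and 2.
#' @return Numeric RDT value(s).
#' @export
compute_rdt <- function(d1_ic, d1_sc, d2_ic, d2_sc) {
  dens <- c(d1_ic, d1_sc, d2_ic, d2_sc)
  if (any(!is.finite(dens)) || any(dens <= 0)) {
    stop("compute_rdt: all densities must be positive")
  }
  d1_ic / d1_sc + d2_ic / d2_sc
}

#' Plant relative density total (pRDT) of the soybean component
#'
#' pRDT = d_ic / d_sc: soybean density in the intercrop relative to its
#' sole-crop density.
#'
#' @param d_ic soybean density in the intercrop.
#' @param d_sc soybean density in the sole crop.
#' @return Numeric ratio(s).
#' @export
compute_prdt <- function(d_ic, d_sc) {
  if (any(!is.finite(c(d_ic, d_sc))) || any(c(d_ic, d_sc) <= 0)) {
    stop("compute_prdt: densities must be positive")
  }
  d_ic / d_sc
}

#' Impute missing arm standard deviations from average coefficients of variation
#'
#' For observations reporting a mean but no SD, the SD is estimated as the
#' reported mean times the average coefficient of variation (CV = sd/mean) of
#' the observations that do report SDs.  By default the average CV is pooled
#' per trait and per arm (treatment CVs separately from control CVs within
#' each trait), which prevents scale contamination across traits; `pool =
#' "global"` averages over all reported CVs instead.  Reported SDs are never
#' modified, and re-running the imputation is a no-op.
#'
#' @param db observation data frame.
#' @param pool `"trait_arm"` (default) or `"global"` CV pooling stratum.
#' @return `db` with SDs filled in and logical columns `sd_treat_imputed`,
#'   `sd_ctrl_imputed` marking the imputed entries.
#' @export
impute_sd <- function(db, pool = c("trait_arm", "global")) {
  pool <- match.arg(pool)
  if (!"sd_treat_imputed" %in% names(db)) {
    db$sd_treat_imputed <- rep(FALSE, nrow(db))
  }
  if (!"sd_ctrl_imputed" %in% names(db)) {
    db$sd_ctrl_imputed <- rep(FALSE, nrow(db))
  }
  if (nrow(db) == 0L) return(db)

  cv_t <- db$sd_treat / db$mean_treat
  cv_c <- db$sd_ctrl / db$mean_ctrl
  strata <- if (pool == "trait_arm") db$trait else rep("all", nrow(db))

  fill <- function(sd_col, mean_col, cv_own, cv_other, flag_col) {
    miss <- is.na(db[[sd_col]])
    if (!any(miss)) return()
    for (st in unique(strata[miss])) {
      in_st <- strata == st
      cvs <- if (pool == "trait_arm") cv_own[in_st] else c(cv_own[in_st], cv_other[in_st])
      cvs <- cvs[!is.na(cvs)]
      if (length(cvs) == 0L) {
        stop("impute_sd: no reported SDs to estimate a CV in stratum '", st,
             "' (", sd_col, ")")
      }
      rows <- which(miss & in_st)
      db[[sd_col]][rows] <<- db[[mean_col]][rows] * mean(cvs)
      db[[flag_col]][rows] <<- TRUE
    }
  }
  fill("sd_treat", "mean_treat", cv_t, cv_c, "sd_treat_imputed")
  fill("sd_ctrl", "mean_ctrl", cv_c, cv_t, "sd_ctrl_imputed")
  db
}

#' Build the lnRR effect-size table from a study database
#'
#' Computes the lnRR and its sampling variance for every observation.  Rows
#' still missing an SD after [impute_sd()] (i.e. whole strata without any
#' reported SD) are dropped with a warning, since they cannot enter a
#' variance-weighted fit.
#'
#' @param db observation data frame (ideally after [filter_rdt()],
#'   [select_final_year()] and [impute_sd()]).
#' @return Data frame with columns `obs_id`, `study_id`, `trait`, `lnrr`,
#'   `variance`, `imputed_sd`.
#' @export
compute_effect_sizes <- function(db) {
  if (nrow(db) == 0L) {
    return(data.frame(obs_id = character(0), study_id = character(0),
                      trait = character(0), lnrr = numeric(0),
                      variance = numeric(0), imputed_sd = logical(0)))
  }
  usable <- !is.na(db$sd_treat) & !is.na(db$sd_ctrl)
  if (any(!usable)) {
    warning("compute_effect_sizes: dropping ", sum(!usable),
            " observation(s) without reported or imputable SDs")
    db <- db[usable, , drop = FALSE]
  }
  imput_t <- if ("sd_treat_imputed" %in% names(db)) db$sd_treat_imputed else FALSE
  imput_c <- if ("sd_ctrl_imputed" %in% names(db)) db$sd_ctrl_imputed else FALSE
  data.frame(
    obs_id = db$obs_id,
    study_id = db$study_id,
    trait = db$trait,
    lnrr = log_response_ratio(db$mean_treat, db$mean_ctrl),
    variance = lnrr_variance(db$sd_treat, db$n_treat, db$mean_treat,
                             db$sd_ctrl, db$n_ctrl, db$mean_ctrl),
    imputed_sd = as.logical(imput_t | imput_c),
    stringsAsFactors = FALSE
  )
}
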