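# Study-observation database: schema, validated CSV I/O, filters.
#
# One row = one paired monoculture (control) vs intercropping (treatment)
# measurement of a microbial community trait or yield, plus the management,
# site and density metadata used downstream as moderators and covariates.
# Missing values are a single sentinel: NA in memory, empty field on disk.

SBI_SCHEMA_VERSION <- 1L

#' Trait and moderator level sets of the study database
#'
#' The fixed vocabulary of the observation table.  `sbi_traits()` returns the
#' response traits; `sbi_enum_levels()` the admissible levels of every
#' categorical column.
#'
#' @return `sbi_traits()`: character vector of trait names.
#'   `sbi_enum_levels()`: named list of character vectors.
#' @export
sbi_traits <- function() {
  c("shannon", "chao1", "richness", "beta_diversity", "structure", "yield")
}

#' @rdname sbi_traits
#' @export
sbi_enum_levels <- function() {
  list(
    trait          = sbi_traits(),
    taxon_group    = c("bacteria", "fungi", "special_fungi", "unspecified"),
    n_source       = c("mineral", "organic", "mixed", "none"),
    n_timing       = c("basal", "topdressing", "none"),
    companion_type = c("legume", "non_legume"),
    system         = c("soy_maize", "non_soy_maize"),
    condition      = c("pot", "field"),
    compartment    = c("rhizosphere", "bulk"),
    strip          = c("soybean", "non_soybean")
  )
}

# Canonical column order; the header is fixed and case-sensitive, and the
# schema_version column guards against dialect drift.
sbi_schema <- function() {
  c("schema_version", "study_id", "obs_id", "trait", "taxon_group",
    "mean_treat", "mean_ctrl", "sd_treat", "sd_ctrl", "n_treat", "n_ctrl",
    "n_source", "n_timing", "companion_type", "system", "condition",
    "compartment", "strip",
    "map_mm", "mat_c", "duration_yr", "nfr_kg_ha", "rdt", "prdt",
    "phi", "soci", "tni", "rows_soybean", "dist_soybean_m", "is_final_year")
}

sbi_numeric_cols <- function() {
  c("mean_treat", "mean_ctrl", "sd_treat", "sd_ctrl",
    "map_mm", "mat_c", "duration_yr", "nfr_kg_ha", "rdt", "prdt",
    "phi", "soci", "tni", "rows_soybean", "dist_soybean_m")
}

empty_observation_db <- function() {
  db <- as.data.frame(setNames(rep(list(character(0)), length(sbi_schema())),
                               sbi_schema()), stringsAsFactors = FALSE)
  db$schema_version <- integer(0)
  for (col in sbi_numeric_cols()) db[[col]] <- numeric(0)
  db$n_treat <- integer(0)
  db$n_ctrl <- integer(0)
  db$is_final_year <- logical(0)
  db
}

#' Validate a study-observation table
#'
#' Checks each row of an observation table against the schema: positive arm
#' means, non-negative SDs, arm sizes >= 1, known enum levels, and obs_id
#' uniqueness.  Offending rows are dropped; the reasons are collected in a
#' validation report attached as the `"validation"` attribute (a data frame
#' with columns `row`, `field`, `reason`).
#'
#' @param db data frame with the columns of [sbi_schema()].
#' @return The accepted rows, with the validation report attached.
#' @export
validate_observations <- function(db) {
  schema <- sbi_schema()
  if (!identical(names(db), schema)) {
    missing <- setdiff(schema, names(db))
    extra <- setdiff(names(db), schema)
    stop("observation table header does not match the schema",
         if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")))
  }
  n <- nrow(db)
  report <- list()
  bad <- rep(FALSE, n)
  flag <- function(rows, field, reason) {
    rows <- which(rows)
    if (length(rows)) {
      report[[length(report) + 1L]] <<- data.frame(
        row = rows, field = field, reason = reason, stringsAsFactors = FALSE)
      bad[rows] <<- TRUE
    }
  }

  if (n == 0L) {
    attr(db, "validation") <- data.frame(row = integer(0), field = character(0),
                                         reason = character(0))
    return(db)
  }

  for (col in sbi_numeric_cols()) db[[col]] <- as.numeric(db[[col]])
  db$n_treat <- suppressWarnings(as.integer(db$n_treat))
  db$n_ctrl <- suppressWarnings(as.integer(db$n_ctrl))
  db$is_final_year <- as.logical(db$is_final_year)
  db$schema_version <- suppressWarnings(as.integer(db$schema_version))

  flag(is.na(db$schema_version) | db$schema_version != SBI_SCHEMA_VERSION,
       "schema_version", "unsupported schema version")
  flag(is.na(db$study_id) | db$study_id == "", "study_id", "missing study_id")
  flag(is.na(db$obs_id) | db$obs_id == "", "obs_id", "missing obs_id")
  flag(duplicated(db$obs_id), "obs_id", "duplicate obs_id")
  flag(is.na(db$mean_treat) | db$mean_treat <= 0, "mean_treat", "non-positive mean")
  flag(is.na(db$mean_ctrl) | db$mean_ctrl <= 0, "mean_ctrl", "non-positive mean")
  flag(!is.na(db$sd_treat) & db$sd_treat < 0, "sd_treat", "negative SD")
  flag(!is.na(db$sd_ctrl) & db$sd_ctrl < 0, "sd_ctrl", "negative SD")
  flag(is.na(db$n_treat) | db$n_treat < 1L, "n_treat", "arm size below 1")
  flag(is.na(db$n_ctrl) | db$n_ctrl < 1L, "n_ctrl", "arm size below 1")
  flag(is.na(db$is_final_year), "is_final_year", "missing final-year flag")
  for (col in names(sbi_enum_levels())) {
    lev <- sbi_enum_levels()[[col]]
    missing_ok <- !(col %in% c("trait"))
    bad_level <- !is.na(db[[col]]) & db[[col]] != "" & !(db[[col]] %in% lev)
    if (!missing_ok) bad_level <- bad_level | is.na(db[[col]]) | db[[col]] == ""
    flag(bad_level, col, "unknown enum level")
    db[[col]][!is.na(db[[col]]) & db[[col]] == ""] <- NA_character_
  }

  report <- if (length(report)) do.call(rbind, report) else
    data.frame(row = integer(0), field = character(0), reason = character(0))
  report <- report[order(report$row), , drop = FALSE]
  rownames(report) <- NULL
  out <- db[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "validation") <- report
  out
}

#' Read a study-observation table from CSV
#'
#' Reads a UTF-8, RFC-4180 CSV with the fixed header of [sbi_schema()].
#' Rows failing validation are dropped and reported (see
#' [validate_observations()]); file order is preserved for the accepted rows.
#'
#' @param path path to the CSV file.
#' @return Validated observation data frame with a `"validation"` attribute.
#' @seealso [write_observations()]
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("cannot read observation table: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  na.strings = "", check.names = FALSE, fileEncoding = "UTF-8")
  validate_observations(raw)
}

#' Write a study-observation table to CSV
#'
#' Inverse of [read_observations()]: missing values become empty fields, so
#' write-then-read is the identity on valid databases.
#'
#' @param db validated observation data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(db, path) {
  out <- db[, sbi_schema(), drop = FALSE]
  # 17 significant digits so doubles survive the text round trip exactly
  for (col in sbi_numeric_cols()) {
    v <- out[[col]]
    out[[col]] <- ifelse(is.na(v), NA_character_, sprintf("%.17g", v))
  }
  write.csv(out, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Return the validation report of a database
#'
#' @param db observation data frame returned by [read_observations()] or
#'   [validate_observations()].
#' @return Data frame with columns `row`, `field`, `reason`.
#' @export
validation_report <- function(db) {
  rep <- attr(db, "validation")
  if (is.null(rep)) {
    rep <- data.frame(row = integer(0), field = character(0), reason = character(0))
  }
  rep
}

#' Exclude sub-replacement intercropping designs
#'
#' Drops observations whose relative density total (RDT) is known and below
#' 1; an RDT of 1 is a replacement design, above 1 an additive design.  Rows
#' with missing RDT are retained: the exclusion is by measured density, not
#' by missingness.
#'
#' @param db observation data frame.
#' @return Filtered data frame; the number of removals is reported via
#'   `message()`.
#' @export
filter_rdt <- function(db) {
  drop <- !is.na(db$rdt) & db$rdt < 1
  if (any(drop)) {
    message("filter_rdt: removed ", sum(drop), " observation(s) with RDT < 1")
  }
  out <- db[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "validation") <- attr(db, "validation")
  out
}

#' Keep only each study's final-year observations
#'
#' Within each study, keeps the rows flagged `is_final_year`; a study with no
#' flagged row keeps all its rows and triggers a warning, so no study is
#' silently lost.
#'
#' @param db observation data frame.
#' @return Filtered data frame.
#' @export
select_final_year <- function(db) {
  if (nrow(db) == 0L) return(db)
  keep <- rep(TRUE, nrow(db))
  unflagged <- character(0)
  for (sid in unique(db$study_id)) {
    idx <- which(db$study_id == sid)
    if (any(db$is_final_year[idx])) {
      keep[idx] <- db$is_final_year[idx]
    } else {
      unflagged <- c(unflagged, sid)
    }
  }
  if (length(unflagged)) {
    warning("select_final_year: no final-year flag in study(ies) ",
            paste(unflagged, collapse = ", "), "; keeping all their rows")
  }
  out <- db[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "validation") <- attr(db, "validation")
  out
}
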