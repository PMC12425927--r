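# Ordination-derived response ratios: 2D sample coordinates from published
# NMDS / PCA / PCoA / RDA plots are reduced to within- and between-group mean
# Euclidean distances, from which one-dimensional beta-diversity (lnRRb) and
# community-structure (lnRRs) response ratios are computed.

ORDINATION_METHODS <- c("NMDS", "PCA", "PCoA", "RDA")

#' Read an ordination-coordinate table from CSV
#'
#' Expected columns: `obs_id`, `sample_id`, `group` (`control` /
#' `treatment`), `axis1`, `axis2`, `method` (NMDS, PCA, PCoA or RDA).  Only
#' the first two ordination axes are used throughout.
#'
#' @param path path to the CSV file.
#' @return Data frame of sample coordinates.
#' @export
read_ordination <- function(path) {
  if (!file.exists(path)) stop("cannot read ordination table: ", path)
  ord <- read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                  fileEncoding = "UTF-8")
  validate_ordination(ord)
}

#' Validate an ordination-coordinate table
#'
#' @param ord data frame with columns `obs_id`, `sample_id`, `group`,
#'   `axis1`, `axis2`, `method`.
#' @return The validated data frame (invisibly unchanged apart from type
#'   coercion of the axes).
#' @export
validate_ordination <- function(ord) {
  needed <- c("obs_id", "sample_id", "group", "axis1", "axis2", "method")
  if (!all(needed %in% names(ord))) {
    stop("ordination table must have columns: ", paste(needed, collapse = ", "))
  }
  ord$axis1 <- as.numeric(ord$axis1)
  ord$axis2 <- as.numeric(ord$axis2)
  if (any(!is.finite(ord$axis1)) || any(!is.finite(ord$axis2))) {
    stop("ordination coordinates must be finite")
  }
  if (!all(ord$group %in% c("control", "treatment"))) {
    stop("ordination group must be 'control' or 'treatment'")
  }
  if (!all(ord$method %in% ORDINATION_METHODS)) {
    stop("ordination method must be one of ", paste(ORDINATION_METHODS, collapse = ", "))
  }
  if (anyDuplicated(ord[, c("obs_id", "sample_id")])) {
    stop("sample_id must be unique within an ordination set")
  }
  for (g in c("control", "treatment")) {
    if (sum(ord$group == g) < 2L) stop("need >= 2 samples per group (", g, ")")
  }
  ord
}

#' Pairwise Euclidean distances between ordination samples
#'
#' Distance between samples i and j on the first two ordination axes:
#' sqrt((axis1_i - axis1_j)^2 + (axis2_i - axis2_j)^2).
#'
#' @param ord ordination data frame (see [validate_ordination()]).
#' @return Symmetric distance matrix with zero diagonal, dimnames =
#'   sample ids.
#' @export
pairwise_euclidean <- function(ord) {
  if (nrow(ord) < 2L) stop("pairwise_euclidean: need at least 2 samples")
  xy <- cbind(ord$axis1, ord$axis2)
  rownames(xy) <- ord$sample_id
  as.matrix(dist(xy, method = "euclidean"))
}

#' Within- and between-group mean ordination distances
#'
#' Mean pairwise Euclidean distances over the three index sets: control
#' pairs (D_c), treatment pairs (D_t), and control-treatment pairs (D_b),
#' each unordered pair counted once.  A degenerate group (all points
#' coincident) yields a within-distance of exactly 0 and is flagged.
#'
#' @param ord ordination data frame with >= 2 samples per group.
#' @return Object of class `structure_distances`: list with
#'   `d_within_ctrl`, `d_within_treat`, `d_between`, `n_ctrl`, `n_treat`,
#'   `degenerate` (character vector of flagged groups).
#' @export
summarize_distances <- function(ord) {
  ord <- validate_ordination(ord)
  dm <- pairwise_euclidean(ord)
  ctrl <- which(ord$group == "control")
  trt <- which(ord$group == "treatment")
  mean_pairs <- function(idx) {
    sub <- dm[idx, idx, drop = FALSE]
    mean(sub[lower.tri(sub)])
  }
  res <- list(
    d_within_ctrl = mean_pairs(ctrl),
    d_within_treat = mean_pairs(trt),
    d_between = mean(dm[ctrl, trt]),
    n_ctrl = length(ctrl),
    n_treat = length(trt)
  )
  res$degenerate <- c(
    if (res$d_within_ctrl == 0) "control",
    if (res$d_within_treat == 0) "treatment"
  )
  class(res) <- "structure_distances"
  res
}

#' @export
print.structure_distances <- function(x, ...) {
  cat("Ordination distance summary\n")
  cat(sprintf("  D_c (within control,   n=%d): %.4f\n", x$n_ctrl, x$d_within_ctrl))
  cat(sprintf("  D_t (within treatment, n=%d): %.4f\n", x$n_treat, x$d_within_treat))
  cat(sprintf("  D_b (between groups)        : %.4f\n", x$d_between))
  if (length(x$degenerate)) {
    cat("  degenerate group(s):", paste(x$degenerate, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Beta-diversity log response ratio from ordination distances
#'
#' lnRRb = ln(D_t) - ln(D_c): the log ratio of within-treatment to
#' within-control mean dispersion.  Positive values mean intercropping
#' increased the spread of samples in ordination space.
#'
#' @param d `structure_distances` object from [summarize_distances()].
#' @return Numeric lnRRb.
#' @export
lnrr_beta <- function(d) {
  stopifnot(inherits(d, "structure_distances"))
  if (d$d_within_treat <= 0 || d$d_within_ctrl <= 0) {
    stop("lnrr_beta: undefined for zero within-group distance")
  }
  log(d$d_within_treat) - log(d$d_within_ctrl)
}

#' Community-structure log response ratio from ordination distances
#'
#' Two conventions are supported.  The default, `"between_within"`, is
#' lnRRs = ln(D_b / ((D_c + D_t)/2)): between-group separation relative to
#' the mean within-group dispersion.  It is ~0 for coincident groups and
#' grows without bound as the group centroids separate, so it can express
#' the positive structure shifts this statistic is meant to capture.  The
#' `"as_printed"` convention, lnRRs = ln(D_t / (D_c + D_t)), is retained for
#' auditability; note it is bounded above by 0 for positive distances.
#'
#' @param d `structure_distances` object.
#' @param convention `"between_within"` (default) or `"as_printed"`.
#' @return Numeric lnRRs.
#' @export
lnrr_structure <- function(d, convention = c("between_within", "as_printed")) {
  stopifnot(inherits(d, "structure_distances"))
  convention <- match.arg(convention)
  tot <- d$d_within_ctrl + d$d_within_treat
  if (tot <= 0) stop("lnrr_structure: undefined for zero within-group distances")
  if (convention == "as_printed") {
    if (d$d_within_treat <= 0) stop("lnrr_structure: zero within-treatment distance")
    log(d$d_within_treat) - log(tot)
  } else {
    if (d$d_between <= 0) stop("lnrr_structure: zero between-group distance")
    log(d$d_between) - log(tot / 2)
  }
}
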