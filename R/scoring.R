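#' CSI-score weight vector
#'
#' Constructs and validates the six non-negative integer coefficients of the
#' CSI-score equation. The published default is
#' `CSI = 1*C_extent + 2*C_grade + 1*S_extent + 2*S_grade + 1*I_extent +
#' 1*I_grade`.
#'
#' @param w Numeric vector of six non-negative integers, in the order
#'   `c_extent, c_grade, s_extent, s_grade, i_extent, i_grade`.
#' @return A named integer vector of class `"csi_weights"`.
#' @examples
#' csi_weights()            # the published weights (1, 2, 1, 2, 1, 1)
#' csi_weights(rep(1, 6))
#' @export
csi_weights <- function(w = c(1, 2, 1, 2, 1, 1)) {
  w <- as.numeric(w)
  if (length(w) != 6L || anyNA(w) || any(w < 0) || any(w != round(w)))
    stop_validation("weights must be six non-negative integers")
  structure(as.integer(w), names = CSI_COMPONENT_NAMES, class = "csi_weights")
}

#' Compute the CSI-score
#'
#' Integer dot product of the six score components with a weight vector.
#' Scores are exact integers end to end; no floating point enters the scoring
#' path.
#'
#' @param components A `csi_components` vector, a named numeric vector, or a
#'   matrix / data frame with the six component columns (one row per
#'   patient).
#' @param weights A [csi_weights()] vector (default: published weights).
#' @return Integer score(s); under the default weights the attainable range
#'   is 0 to 22.
#' @examples
#' csi_score(c(1, 0, 2, 2, 0, 0))  # 7
#' csi_score(c(3, 3, 3, 3, 1, 3))  # 22
#' @export
csi_score <- function(components, weights = csi_weights()) {
  weights <- csi_weights(weights)
  x <- component_matrix(components)
  validate_components(x)
  as.integer(x %*% weights)
}

component_matrix <- function(components) {
  if (is.data.frame(components)) {
    missing <- setdiff(CSI_COMPONENT_NAMES, names(components))
    if (length(missing))
      stop_validation(paste0("missing component column(s): ",
                             paste(missing, collapse = ", ")))
    x <- as.matrix(components[CSI_COMPONENT_NAMES])
  } else if (is.matrix(components)) {
    x <- components
    if (!is.null(colnames(x)) && all(CSI_COMPONENT_NAMES %in% colnames(x)))
      x <- x[, CSI_COMPONENT_NAMES, drop = FALSE]
    if (ncol(x) != 6L) stop_validation("component matrix must have 6 columns")
  } else {
    if (length(components) != 6L)
      stop_validation("components must have 6 entries")
    x <- matrix(as.numeric(components), nrow = 1L,
                dimnames = list(NULL, CSI_COMPONENT_NAMES))
  }
  storage.mode(x) <- "integer"
  x
}

validate_components <- function(x) {
  ext <- x[, c(1L, 3L, 5L), drop = FALSE]
  grd <- x[, c(2L, 4L, 6L), drop = FALSE]
  if (anyNA(x) || any(x < 0L) || any(ext[, 1:2] > 3L) || any(grd > 3L))
    stop_validation("component scales must lie in 0..3")
  if (any(ext[, 3L] > 1L))
    stop_validation("i_extent must be 0 or 1 (only ostial IMA stenosis is scored)")
  if (any(grd > 0L & ext == 0L))
    stop_validation("a positive grade requires a lesion (extent > 0)")
  invisible(x)
}

#' Enumerate all admissible component profiles
#'
#' Every six-tuple of scales satisfying the structural constraints: extent
#' and grade in `0:3` for CA and SMA, IMA extent in `0:1`, and for each
#' vessel a positive grade requires a lesion (`grade > 0` implies
#' `extent > 0`). There are `13 * 13 * 5 = 845` such profiles.
#'
#' @return Integer matrix with one admissible profile per row.
#' @export
admissible_components <- function() {
  per_vessel <- function(max_extent) {
    ext <- integer(0); grd <- integer(0)
    for (e in 0:max_extent) {
      g <- if (e == 0L) 0L else 0:3
      ext <- c(ext, rep(e, length(g))); grd <- c(grd, g)
    }
    cbind(ext, grd)
  }
  ca <- per_vessel(3L); sma <- per_vessel(3L); ima <- per_vessel(1L)
  idx <- expand.grid(i = seq_len(nrow(ima)), s = seq_len(nrow(sma)),
                     c = seq_len(nrow(ca)))
  out <- cbind(ca[idx$c, , drop = FALSE], sma[idx$s, , drop = FALSE],
               ima[idx$i, , drop = FALSE])
  colnames(out) <- CSI_COMPONENT_NAMES
  out
}

#' Attainable score range under a weight vector
#'
#' Minimum and maximum CSI-score over all admissible component profiles
#' (brute-force enumeration). Under the published weights the range is
#' 0 to 22, the maximum attained at full-extent occlusion of all three
#' vessels, `(3, 3, 3, 3, 1, 3)`.
#'
#' @param weights A [csi_weights()] vector.
#' @return Integer vector `c(min, max)`.
#' @examples
#' score_range()            # 0 22
#' score_range(rep(1, 6))   # 0 16
#' @export
score_range <- function(weights = csi_weights()) {
  s <- csi_score(admissible_components(), weights)
  c(min = min(s), max = max(s))
}

#' Dichotomize a score into low/high risk groups
#'
#' @param score Integer score(s), >= 0.
#' @param cutoff Cut-off; `high` iff `score >= cutoff`. Default 8, the
#'   Youden-optimal cut-off of the published derivation.
#' @return Factor with levels `low`, `high`.
#' @examples
#' classify_risk(c(7, 8))  # low, high
#' @export
classify_risk <- function(score, cutoff = 8) {
  if (any(is.na(score)) || any(score < 0))
    stop_validation("scores must be non-negative")
  factor(ifelse(score >= cutoff, "high", "low"), levels = c("low", "high"))
}

#' Score subgroup binning for stratified reports
#'
#' Bins a score into the five reporting subgroups 0-3, 4-7, 8-11, 12-15
#' and >15.
#'
#' @param score Integer score(s) within the attainable range.
#' @param max_score Upper bound of the attainable range (default 22).
#' @return Factor with levels `"0-3"`, `"4-7"`, `"8-11"`, `"12-15"`, `">15"`.
#' @examples
#' score_subgroup(c(0, 15, 16))
#' @export
score_subgroup <- function(score, max_score = 22) {
  if (any(is.na(score)) || any(score < 0) || any(score > max_score))
    stop_validation(sprintf("score outside the attainable range [0, %d]", max_score))
  cut(score, breaks = c(-0.5, 3.5, 7.5, 11.5, 15.5, max_score + 0.5),
      labels = c("0-3", "4-7", "8-11", "12-15", ">15"))
}
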