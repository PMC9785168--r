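#' ROC operating points over observed cut-offs
#'
#' One operating point per distinct observed score value, using the decision
#' rule "positive iff score >= cutoff". Sensitivity and specificity are
#' computed by direct counting; the table is sorted by cut-off ascending.
#'
#' @param scores Numeric scores.
#' @param labels Logical (or 0/1) labels, `TRUE` = positive.
#' @return Data frame with columns `cutoff`, `sensitivity`, `specificity`,
#'   `youden_j`.
#' @examples
#' roc_points(c(8, 9, 10, 1, 2, 8), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
#' @export
roc_points <- function(scores, labels) {
  labels <- check_labeled(scores, labels)
  cuts <- sort(unique(scores))
  pos <- scores[labels]; neg <- scores[!labels]
  sens <- vapply(cuts, function(ct) mean(pos >= ct), numeric(1))
  spec <- vapply(cuts, function(ct) mean(neg < ct), numeric(1))
  data.frame(cutoff = cuts, sensitivity = sens, specificity = spec,
             youden_j = sens + spec - 1)
}

#' Youden-optimal cut-off
#'
#' Selects, among the distinct observed score values, the cut-off maximising
#' Youden's index `J = sensitivity + specificity - 1` under the rule
#' "positive iff score >= cutoff". Ties in J are broken toward the smallest
#' cut-off, so the result is deterministic.
#'
#' @inheritParams roc_points
#' @return An object of class `"csi_cutoff"`: a list with `cutoff`,
#'   `sensitivity`, `specificity`, `youden_j`.
#' @examples
#' youden_cutoff(c(8, 9, 10, 1, 2, 8), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
#' @export
youden_cutoff <- function(scores, labels) {
  pts <- roc_points(scores, labels)
  # tolerance guards against float noise in sens + spec - 1; the first
  # candidate within it is the smallest tying cut-off
  best <- which(pts$youden_j >= max(pts$youden_j) - 1e-9)[1L]
  structure(as.list(pts[best, , drop = FALSE]), class = "csi_cutoff")
}

#' @export
print.csi_cutoff <- function(x, ...) {
  cat(sprintf("Youden-optimal cut-off: %s (J = %.3f; sensitivity %.1f%%, specificity %.1f%%)\n",
              format(x$cutoff), x$youden_j,
              100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}
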