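#' Grid search for score weights maximising the rank-based AUC
#'
#' Evaluates [auc_rank()] of the weighted component score for every weight
#' vector in the Cartesian grid (default `{0,1,2,3}` per coefficient, 4096
#' candidates, which contains the published solution). The maximiser is
#' selected deterministically: highest AUC, then minimal coefficient sum,
#' then lexicographically smallest vector. All candidates within `tol` of
#' the best AUC are returned as ties.
#'
#' @param components Matrix or data frame of the six component columns, one
#'   row per patient (see [csi_components()]).
#' @param labels Logical (or 0/1) labels, `TRUE` = positive.
#' @param grid Integer vector of admissible values per coefficient
#'   (default `0:3`), or a list of six such vectors.
#' @param tol Numeric tolerance for AUC ties (default `1e-9`).
#' @return An object of class `"csi_grid"`: a list with `best_weights`
#'   ([csi_weights()]), `best_auc`, `n_candidates`, and `ties` (matrix of
#'   all tying weight vectors, in lexicographic order).
#' @examples
#' comp <- admissible_components()[c(1, 100, 400, 800), ]
#' grid_search_weights(comp, c(FALSE, FALSE, TRUE, TRUE), grid = 0:1)
#' @export
grid_search_weights <- function(components, labels, grid = 0:3, tol = 1e-9) {
  x <- component_matrix(components)
  labels <- check_labeled(seq_len(nrow(x)), labels)
  if (!is.list(grid)) grid <- rep(list(sort(unique(as.integer(grid)))), 6L)
  if (length(grid) != 6L || any(!lengths(grid)))
    stop_validation("grid must be a non-empty value set per coefficient")
  # candidates in lexicographic order over (w1, ..., w6)
  W <- as.matrix(expand.grid(rev(grid), KEEP.OUT.ATTRS = FALSE))[, 6:1, drop = FALSE]
  colnames(W) <- CSI_COMPONENT_NAMES
  n_pos <- sum(labels); n_neg <- sum(!labels)
  S <- x %*% t(W)                      # n_patients x n_candidates
  R <- apply(S, 2L, rank)              # midranks per candidate
  if (is.null(dim(R))) R <- matrix(R, ncol = ncol(S))
  auc <- (colSums(R[labels, , drop = FALSE]) - n_pos * (n_pos + 1) / 2) /
    (n_pos * n_neg)
  best_auc <- max(auc)
  tie_idx <- which(auc >= best_auc - tol)
  ties <- W[tie_idx, , drop = FALSE]
  # tie-break: minimal coefficient sum, then lexicographic (row order of W
  # is already lexicographic, so the first minimal-sum row wins)
  pick <- tie_idx[order(rowSums(ties))[1L]]
  structure(list(
    best_weights = csi_weights(W[pick, ]),
    best_auc = auc[pick],
    n_candidates = nrow(W),
    ties = ties
  ), class = "csi_grid")
}

#' @export
print.csi_grid <- function(x, ...) {
  cat(sprintf("Grid search over %d weight vectors\n", x$n_candidates))
  cat(sprintf("  best AUC %.3f at weights (%s); %d tie(s)\n",
              x$best_auc, paste(x$best_weights, collapse = ", "),
              nrow(x$ties)))
  invisible(x)
}
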