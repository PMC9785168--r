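#' Fit the CSI-score to a labelled cohort
#'
#' The central estimator: given a labelled cohort, derives the score weights
#' by exhaustive grid search maximising the tie-aware rank-based AUC
#' ([grid_search_weights()]), computes every patient's score, selects the
#' Youden-optimal cut-off ([youden_cutoff()]) and attaches the
#' Brunner-Munzel confidence interval for the AUC ([bm_confint()]). With
#' `weights` supplied the search is skipped and the given equation is
#' evaluated as-is (e.g. to validate the published weights `(1, 2, 1, 2, 1,
#' 1)` on a new cohort); with `cutoff` supplied the dichotomization point is
#' fixed instead of estimated.
#'
#' @param data Data frame holding one row per patient: either the six
#'   component columns (`c_extent`, ..., `i_grade`) or the wide measurement
#'   schema of [read_cohort()], plus the label column.
#' @param label Name of the logical label column (default `"cmi_label"`,
#'   `TRUE` = CMI).
#' @param weights Optional fixed [csi_weights()]; `NULL` (default) derives
#'   them by grid search.
#' @param grid Value set per coefficient for the grid search (default
#'   `0:3`).
#' @param cutoff Optional fixed cut-off; `NULL` (default) selects the
#'   Youden-optimal one.
#' @param level Confidence level for the AUC interval (default 0.95).
#' @param absent_vessel_policy Passed to [score_patients()].
#' @return An object of class `"csi_fit"`, a list with elements `weights`,
#'   `auc` (`csi_auc`), `cutoff` (`csi_cutoff`), `roc` (data frame),
#'   `grid` (`csi_grid` or `NULL`), `scored` (the scored cohort table),
#'   `n`, `n_pos`, `n_neg`, `level`, `call`. Methods: `print`, `summary`,
#'   `coef` (the weights), `predict` (scores / risk groups / subgroups for
#'   new data), `fitted` (in-sample scores), `plot` (ROC curve).
#' @examples
#' cohort <- simulate_cohort(150, seed = 7)
#' fit <- csi_fit(cohort)
#' summary(fit)
#' coef(fit)
#' head(predict(fit, type = "risk"))
#' @export
csi_fit <- function(data, label = "cmi_label", weights = NULL, grid = 0:3,
                    cutoff = NULL, level = 0.95,
                    absent_vessel_policy = c("zero", "missing")) {
  cl <- match.call()
  data <- as.data.frame(data)
  if (is.null(data[[label]]))
    stop_validation(sprintf("label column '%s' not found", label))
  if (is.null(data$patient_id))
    data$patient_id <- sprintf("P%04d", seq_len(nrow(data)))
  scored <- score_patients(data, weights = weights %||% csi_weights(),
                           cutoff = cutoff %||% 8,
                           absent_vessel_policy = absent_vessel_policy)
  labels <- as.logical(data[[label]])
  if (nrow(scored) != nrow(data))  # absent-vessel policy dropped patients
    labels <- labels[data$patient_id %in% scored$patient_id]
  if (anyNA(labels)) stop_validation("label column contains NA")
  comp <- component_matrix(scored[CSI_COMPONENT_NAMES])

  gs <- NULL
  if (is.null(weights)) {
    gs <- grid_search_weights(comp, labels, grid = grid)
    weights <- gs$best_weights
  } else {
    weights <- csi_weights(weights)
  }
  scores <- csi_score(comp, weights)
  auc <- bm_confint(scores, labels, level = level)
  roc <- roc_points(scores, labels)
  if (is.null(cutoff)) {
    cut_res <- youden_cutoff(scores, labels)
  } else {
    pts <- roc
    at <- which(pts$cutoff == cutoff)
    cut_res <- if (length(at)) {
      structure(as.list(pts[at[1L], , drop = FALSE]), class = "csi_cutoff")
    } else {
      sens <- mean(scores[labels] >= cutoff)
      spec <- mean(scores[!labels] < cutoff)
      structure(list(cutoff = cutoff, sensitivity = sens, specificity = spec,
                     youden_j = sens + spec - 1), class = "csi_cutoff")
    }
  }
  scored$csi_score <- scores
  scored$risk_group <- classify_risk(scores, cut_res$cutoff)
  scored$subgroup <- score_subgroup(scores,
                                    max_score = max(score_range(weights)[["max"]],
                                                    max(scores)))
  scored$cmi_label <- labels

  structure(list(
    weights = weights, auc = auc, cutoff = cut_res, roc = roc, grid = gs,
    scored = scored, n = length(labels), n_pos = sum(labels),
    n_neg = sum(!labels), level = level, call = cl
  ), class = "csi_fit")
}

#' @export
print.csi_fit <- function(x, ...) {
  cat("CSI-score fit\n")
  cat("  call: ", deparse(x$call), "\n", sep = "")
  w <- x$weights
  cat(sprintf("  score = %d*C_extent + %d*C_grade + %d*S_extent + %d*S_grade + %d*I_extent + %d*I_grade%s\n",
              w[1], w[2], w[3], w[4], w[5], w[6],
              if (is.null(x$grid)) " (fixed)" else " (grid search)"))
  cat(sprintf("  n = %d (%d positive, %d negative); AUC %.3f; cut-off %s\n",
              x$n, x$n_pos, x$n_neg, x$auc$auc, format(x$cutoff$cutoff)))
  invisible(x)
}

#' @export
summary.csi_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.csi_fit")
}

#' @export
print.summary.csi_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  print(f$auc)
  print(f$cutoff)
  if (!is.null(f$grid)) print(f$grid)
  tab <- table(f$scored$risk_group, f$scored$cmi_label)
  cat("  risk group vs label:\n")
  print(tab)
  invisible(x)
}

#' @export
coef.csi_fit <- function(object, ...) object$weights

#' @export
fitted.csi_fit <- function(object, ...) object$scored$csi_score

#' Predict scores, risk groups or subgroups from a CSI-score fit
#'
#' @param object A [csi_fit()] object.
#' @param newdata Optional data frame (component columns or wide measurement
#'   schema); defaults to the training cohort.
#' @param type `"score"` (default), `"risk"`, `"subgroup"`, or `"table"`
#'   (the full scored table).
#' @param ... Unused.
#' @return Integer scores, a low/high factor, a subgroup factor, or the
#'   scored data frame.
#' @export
predict.csi_fit <- function(object, newdata = NULL,
                            type = c("score", "risk", "subgroup", "table"),
                            ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    scored <- object$scored
  } else {
    scored <- score_patients(as.data.frame(newdata),
                             weights = object$weights,
                             cutoff = object$cutoff$cutoff)
  }
  switch(type,
         score = scored$csi_score,
         risk = scored$risk_group,
         subgroup = scored$subgroup,
         table = scored)
}

#' Plot the ROC curve of a CSI-score fit
#'
#' Base-graphics ROC curve (sensitivity against 1 - specificity over the
#' observed cut-offs), with the selected cut-off marked.
#'
#' @param x A [csi_fit()] object.
#' @param ... Passed to [plot()].
#' @export
plot.csi_fit <- function(x, ...) {
  r <- x$roc[order(-x$roc$cutoff), ]
  fpr <- c(0, 1 - r$specificity, 1)
  tpr <- c(0, r$sensitivity, 1)
  plot(fpr, tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "1 - specificity", ylab = "Sensitivity",
       main = sprintf("CSI-score ROC (AUC %.3f)", x$auc$auc), ...)
  abline(0, 1, lty = 3, col = "grey50")
  at <- x$roc$cutoff == x$cutoff$cutoff
  points(1 - x$roc$specificity[at], x$roc$sensitivity[at], pch = 19)
  text(1 - x$roc$specificity[at], x$roc$sensitivity[at],
       labels = sprintf("cut-off %s", format(x$cutoff$cutoff)), pos = 4)
  invisible(x)
}
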