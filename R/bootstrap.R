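#' Bootstrap the discriminative performance of a score
#'
#' Resamples patients (score and label jointly) with replacement, of the
#' same size as the cohort, and recomputes the rank-based AUC per resample.
#' Resamples missing a class carry no AUC and are skipped and counted;
#' `n_reps_effective` reports how many resamples contributed. The summary
#' gives the mean, minimum and maximum of the resampled AUCs and a
#' percentile confidence interval. With `stratified = TRUE`, resampling is
#' done within each class, so every resample retains both classes.
#'
#' @param scores Numeric scores.
#' @param labels Logical (or 0/1) labels, `TRUE` = positive.
#' @param n_reps Number of bootstrap resamples (default 100000).
#' @param seed Optional integer seed; with a fixed seed the summary is
#'   bit-reproducible.
#' @param level Confidence level of the percentile interval (default 0.95).
#' @param stratified Resample within class instead of over the whole cohort.
#' @return An object of class `"csi_boot"`: a list with `mean_auc`,
#'   `min_auc`, `max_auc`, `sd_auc`, `ci_low`, `ci_high`, `level`,
#'   `n_reps`, `n_reps_effective`, `point_auc`.
#' @examples
#' s <- c(10, 9, 8, 3, 2, 1); l <- rep(c(TRUE, FALSE), each = 3)
#' bootstrap_auc(s, l, n_reps = 200, seed = 1)
#' @export
bootstrap_auc <- function(scores, labels, n_reps = 100000, seed = NULL,
                          level = 0.95, stratified = FALSE) {
  labels <- check_labeled(scores, labels)
  if (n_reps < 1) stop_validation("n_reps must be at least 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(scores)
  pos_idx <- which(labels); neg_idx <- which(!labels)
  n_pos_all <- length(pos_idx); n_neg_all <- length(neg_idx)
  aucs <- rep(NA_real_, n_reps)
  for (b in seq_len(n_reps)) {
    if (stratified) {
      idx <- c(pos_idx[sample.int(n_pos_all, n_pos_all, replace = TRUE)],
               neg_idx[sample.int(n_neg_all, n_neg_all, replace = TRUE)])
    } else {
      idx <- sample.int(n, n, replace = TRUE)
    }
    l <- labels[idx]
    n_pos <- sum(l)
    if (n_pos == 0L || n_pos == n) next  # single-class resample: skipped
    r <- rank(scores[idx])
    aucs[b] <- (sum(r[l]) - n_pos * (n_pos + 1) / 2) / (n_pos * (n - n_pos))
  }
  aucs <- aucs[!is.na(aucs)]
  if (!length(aucs))
    stop_degenerate("all bootstrap resamples were single-class; use a larger cohort or stratified resampling")
  ci <- unname(quantile(aucs, c((1 - level) / 2, (1 + level) / 2)))
  structure(list(
    mean_auc = mean(aucs), min_auc = min(aucs), max_auc = max(aucs),
    sd_auc = stats::sd(aucs),
    ci_low = ci[1L], ci_high = ci[2L], level = level,
    n_reps = n_reps, n_reps_effective = length(aucs),
    point_auc = auc_rank(scores, labels)
  ), class = "csi_boot")
}

#' @export
print.csi_boot <- function(x, ...) {
  cat(sprintf("Bootstrap AUC over %d resamples (%d effective)\n",
              x$n_reps, x$n_reps_effective))
  cat(sprintf("  mean %.3f, min %.3f, max %.3f; %d%% percentile CI %.3f-%.3f\n",
              x$mean_auc, x$min_auc, x$max_auc, round(100 * x$level),
              x$ci_low, x$ci_high))
  cat(sprintf("  point estimate on the full cohort: %.3f\n", x$point_auc))
  invisible(x)
}
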