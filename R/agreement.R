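#' Percent agreement between two raters
#'
#' Counts exact equality of the two parallel score sequences. The percentage
#' is returned unrounded; rounding happens only at the presentation layer
#' (see [write_report()]).
#'
#' @param rater1,rater2 Parallel integer score sequences.
#' @return List with `n_agree`, `n_total`, `percent_agreement`.
#' @examples
#' percent_agreement(c(1, 2, 3), c(1, 2, 4))
#' @export
percent_agreement <- function(rater1, rater2) {
  if (length(rater1) != length(rater2))
    stop_validation("rater sequences must have equal length")
  if (!length(rater1)) stop_validation("need at least one rated case")
  n_agree <- sum(rater1 == rater2)
  list(n_agree = n_agree, n_total = length(rater1),
       percent_agreement = 100 * n_agree / length(rater1))
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` over the
#' exact score categories, treated as nominal (unweighted) by default —
#' matching the percent-agreement framing where only identical scores count.
#' The confidence interval uses the large-sample standard error of
#' Fleiss, Cohen and Everitt with a normal quantile. Linear or quadratic
#' agreement weights are available but off by default.
#'
#' @param rater1,rater2 Parallel integer score sequences.
#' @param level Confidence level (default 0.95).
#' @param weighting `"unweighted"` (default), `"linear"` or `"quadratic"`.
#' @return An object of class `"csi_kappa"`: a list with `kappa`, `se`,
#'   `ci_low`, `ci_high`, `level`, `p_observed`, `p_expected`, `n_agree`,
#'   `n_total`, `percent_agreement`, `weighting`.
#' @examples
#' r1 <- rep(c(0, 0, 1, 1), c(20, 5, 10, 15))
#' r2 <- rep(c(0, 1, 0, 1), c(20, 5, 10, 15))
#' cohen_kappa(r1, r2)  # kappa 0.40
#' @export
cohen_kappa <- function(rater1, rater2, level = 0.95,
                        weighting = c("unweighted", "linear", "quadratic")) {
  weighting <- match.arg(weighting)
  if (length(rater1) != length(rater2))
    stop_validation("rater sequences must have equal length")
  n <- length(rater1)
  cats <- sort(unique(c(rater1, rater2)))
  k <- length(cats)
  if (k < 2L)
    stop_degenerate("kappa is undefined: fewer than 2 distinct categories observed")
  tab <- table(factor(rater1, levels = cats), factor(rater2, levels = cats))
  p <- tab / n
  pr <- rowSums(p); pc <- colSums(p)
  w <- switch(weighting,
    unweighted = diag(k),
    linear = 1 - abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1),
    quadratic = 1 - (outer(seq_len(k), seq_len(k), "-") / (k - 1))^2)
  p_o <- sum(w * p)
  p_e <- sum(w * outer(pr, pc))
  if (1 - p_e < .Machine$double.eps)
    stop_degenerate("kappa is undefined: expected agreement is 1 (both raters effectively constant)")
  kap <- (p_o - p_e) / (1 - p_e)
  # Fleiss-Cohen-Everitt large-sample variance of weighted kappa
  w_row <- as.vector(w %*% pc)   # average weight of row category i
  w_col <- as.vector(pr %*% w)   # average weight of column category j
  term <- sum(p * (w * (1 - p_e) -
                     outer(w_row, w_col, "+") * (1 - p_o))^2)
  var_k <- (term - (p_o * p_e - 2 * p_e + p_o)^2) / (n * (1 - p_e)^4)
  se <- sqrt(max(0, var_k))
  z <- qnorm((1 + level) / 2)
  agree <- percent_agreement(rater1, rater2)
  structure(list(
    kappa = kap, se = se,
    ci_low = max(-1, kap - z * se), ci_high = min(1, kap + z * se),
    level = level, p_observed = p_o, p_expected = p_e,
    n_agree = agree$n_agree, n_total = agree$n_total,
    percent_agreement = agree$percent_agreement,
    weighting = weighting
  ), class = "csi_kappa")
}

#' @export
print.csi_kappa <- function(x, ...) {
  cat(sprintf("Inter-rater agreement: %d of %d cases (%.1f%%)\n",
              x$n_agree, x$n_total, x$percent_agreement))
  cat(sprintf("  Cohen's kappa (%s): %.3f (%d%% CI %.3f-%.3f)\n",
              x$weighting, x$kappa, round(100 * x$level),
              x$ci_low, x$ci_high))
  invisible(x)
}
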