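#' Two-by-two cross-tabulation of risk group against a binary attribute
#'
#' Reproduces the "n (%)" style summary tables: counts of a binary patient
#' attribute (e.g. CMI, invasive treatment, death) within each risk group,
#' percentages within group, and a p-value from Pearson's chi-square test
#' (without continuity correction), replaced by Fisher's exact test whenever
#' any expected cell count falls below 5.
#'
#' @param group Factor or vector defining the two groups (e.g. the output of
#'   [classify_risk()]); the first level forms the first row.
#' @param attribute Logical (or 0/1) per-patient attribute.
#' @return An object of class `"csi_crosstab"`: a list with `counts` (2x2
#'   matrix, groups in rows), `n_group`, `percent` (attribute-positive
#'   percentage per group), `expected`, `test` (`"pearson"` or `"fisher"`),
#'   `p_value`.
#' @examples
#' grp <- rep(c("low", "high"), c(100, 142))
#' cmi <- c(rep(c(TRUE, FALSE), c(11, 89)), rep(c(TRUE, FALSE), c(98, 44)))
#' csi_crosstab(grp, cmi)
#' @export
csi_crosstab <- function(group, attribute) {
  if (length(group) != length(attribute))
    stop_validation("group and attribute must have equal length")
  if (!is.factor(group)) group <- factor(group)
  group <- droplevels(group)
  attribute <- as.logical(attribute)
  if (nlevels(group) != 2L)
    stop_validation("group must have exactly two observed levels")
  if (anyNA(attribute))
    stop_validation("attribute must be binary without NA")
  counts <- table(group, factor(attribute, levels = c(TRUE, FALSE)))
  counts <- matrix(as.integer(counts), nrow = 2L,
                   dimnames = list(levels(group), c("yes", "no")))
  if (any(rowSums(counts) == 0L) || any(colSums(counts) == 0L))
    stop_degenerate("degenerate 2x2 table: an empty margin leaves the test undefined")
  n_group <- rowSums(counts)
  expected <- outer(n_group, colSums(counts)) / sum(counts)
  if (any(expected < 5)) {
    test <- "fisher"
    p <- fisher.test(counts)$p.value
  } else {
    test <- "pearson"
    p <- chisq.test(counts, correct = FALSE)$p.value
  }
  structure(list(
    counts = counts, n_group = n_group,
    percent = 100 * counts[, "yes"] / n_group,
    expected = expected, test = test, p_value = p
  ), class = "csi_crosstab")
}

#' @export
print.csi_crosstab <- function(x, ...) {
  cat("2x2 cross-tabulation (attribute-positive, n (%))\n")
  for (g in rownames(x$counts))
    cat(sprintf("  %-8s %d (%.0f)\n", g, x$counts[g, "yes"], x$percent[g]))
  cat(sprintf("  p = %s (%s)\n",
              format.pval(x$p_value, digits = 3, eps = 0.001),
              if (x$test == "pearson") "Pearson chi-square" else "Fisher exact"))
  invisible(x)
}
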