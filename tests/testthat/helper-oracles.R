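# Independent oracles, deliberately naive: pairwise counting for the AUC and
# exhaustive candidate search for the Youden cut-off.

brute_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

oracle_youden <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  best_j <- -Inf; best_cut <- NA
  for (ct in sort(unique(scores))) {
    j <- mean(pos >= ct) + mean(neg < ct) - 1
    if (j > best_j + 1e-12) { best_j <- j; best_cut <- ct }
  }
  list(cutoff = best_cut, youden_j = best_j)
}

# worked lesion examples: per-patient measurement tables
fig_measurements <- function(which) {
  switch(which,
    A = data.frame(
      vessel = c("CA", "SMA", "IMA"),
      reach = c("ostial", "proximal", "none"),
      percent = c(40, 73, NA),
      occluded = FALSE, absent = FALSE),
    B = data.frame(
      vessel = c("CA", "SMA", "IMA"),
      reach = c("ostial", "proximal", "ostial"),
      percent = c(56, 77, 45),
      occluded = FALSE, absent = FALSE),
    C = data.frame(
      vessel = c("CA", "SMA", "IMA"),
      reach = c("extended", "extended", "ostial"),
      percent = NA_real_,
      occluded = TRUE, absent = FALSE))
}

random_valid_measurements <- function() {
  reach <- sample(c("none", "ostial", "proximal", "extended"), 3, replace = TRUE)
  reach[3] <- sample(c("none", "ostial"), 1)
  d_norm <- round(runif(3, 4, 9), 2)
  pct <- runif(3, 0, 99)
  occ <- runif(3) < 0.15
  data.frame(
    vessel = c("CA", "SMA", "IMA"),
    reach = reach,
    d_sten = round(d_norm * (1 - pct / 100), 3),
    d_norm = d_norm,
    percent = NA_real_,
    occluded = occ,
    absent = FALSE)
}
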