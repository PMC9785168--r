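#' Simulate a synthetic suspected-CMI cohort
#'
#' Generates per-patient visceral-artery lesion measurements with the
#' qualitative structure of a suspected chronic-mesenteric-ischemia (CMI)
#' referral cohort: a latent severity drawn from a two-component Gaussian
#' mixture (diseased vs non-diseased subpopulations), per-vessel lesion
#' reach and percent stenosis increasing stochastically with severity (more
#' affected vessels, greater reach, higher grade, eventually occlusion; IMA
#' lesions are ostial only), physiologic reference diameters, and a binary
#' CMI label.
#'
#' Labels come from the latent severity, not from the score itself
#' (`label_model = "logistic"`, the default), so the derived AUC is below 1
#' and cut-off estimation is a genuine statistical task; the logistic centre
#' is solved numerically so the expected label prevalence equals
#' `cmi_prevalence`. The `"threshold"` mode labels patients by
#' `true_score >= threshold_cutoff` and exists as an oracle for exact
#' weight-recovery tests.
#'
#' All randomness flows from `seed` through per-stage sub-seeds (severity,
#' lesions, labels), so each stage is independently reproducible.
#'
#' @param n_patients Number of patients (>= 2).
#' @param cmi_prevalence Mixture weight of the diseased component and target
#'   label prevalence (default 0.45).
#' @param seed Integer seed (required for reproducibility).
#' @param label_model `"logistic"` (default) or `"threshold"`.
#' @param logistic_slope Slope of the label model on the severity scale
#'   (default 1.5); larger values make labels more deterministic in severity.
#' @param threshold_cutoff Score cut-off used by the `"threshold"` label
#'   model (default 8).
#' @param severity_location_cmi,severity_location_non Locations of the two
#'   severity mixture components (defaults 2.2 and 0.2, standard-normal
#'   scale).
#' @param severity_sd Within-component severity SD (default 1).
#' @param vessel_sd SD of the per-vessel deviation from patient severity
#'   (default 0.7).
#' @param reach_thresholds Increasing thresholds on the per-vessel scale for
#'   ostial / proximal / extended reach.
#' @param pct_mid,pct_scale Location and scale of the logistic map from the
#'   per-vessel scale to percent stenosis.
#' @param occ_mid,occ_scale Location and scale of the occlusion probability.
#' @param absent_rate Per-vessel probability of an anatomic-variant absent
#'   vessel (default 0).
#' @param weights Weights used for `true_score` (default published weights).
#' @return Data frame with one row per patient: `patient_id`,
#'   `latent_severity`, the wide measurement schema
#'   (`{ca,sma,ima}_{reach,d_sten_mm,d_norm_mm,percent,occluded,absent}`),
#'   the six true component columns, `true_score`, and `cmi_label`.
#' @examples
#' cohort <- simulate_cohort(100, seed = 1)
#' table(cohort$cmi_label)
#' @export
simulate_cohort <- function(n_patients, cmi_prevalence = 0.45, seed = 1,
                            label_model = c("logistic", "threshold"),
                            logistic_slope = 1.5, threshold_cutoff = 8,
                            severity_location_cmi = 2.2,
                            severity_location_non = 0.2,
                            severity_sd = 1, vessel_sd = 0.7,
                            reach_thresholds = c(-0.15, 1.35, 2.7),
                            pct_mid = 1.1, pct_scale = 0.8,
                            occ_mid = 3.3, occ_scale = 0.55,
                            absent_rate = 0,
                            weights = csi_weights()) {
  label_model <- match.arg(label_model)
  if (n_patients < 2) stop_validation("n_patients must be at least 2")
  if (cmi_prevalence <= 0 || cmi_prevalence >= 1)
    stop_validation("cmi_prevalence must lie strictly between 0 and 1")
  if (is.unsorted(reach_thresholds, strictly = TRUE) ||
      length(reach_thresholds) != 3L)
    stop_validation("reach_thresholds must be three strictly increasing values")
  weights <- csi_weights(weights)

  set.seed(as.integer(seed))
  sub_seed <- sample.int(.Machine$integer.max - 1L, 3L)

  # stage 1: latent severity from the two-component mixture
  set.seed(sub_seed[1L])
  diseased <- runif(n_patients) < cmi_prevalence
  severity <- rnorm(n_patients,
                    mean = ifelse(diseased, severity_location_cmi,
                                  severity_location_non),
                    sd = severity_sd)

  # stage 2: per-vessel lesions, monotone in severity
  set.seed(sub_seed[2L])
  cohort <- data.frame(patient_id = sprintf("P%04d", seq_len(n_patients)),
                       latent_severity = severity)
  comp <- matrix(0L, n_patients, 6L, dimnames = list(NULL, CSI_COMPONENT_NAMES))
  for (i in seq_along(CSI_VESSELS)) {
    v <- CSI_VESSELS[i]
    u <- severity + rnorm(n_patients, 0, vessel_sd)
    reach_i <- findInterval(u, reach_thresholds)        # 0..3
    if (v == "IMA") reach_i <- pmin(reach_i, 1L)        # ostial only
    pct <- 100 * plogis((u - pct_mid) / pct_scale)
    occluded <- reach_i > 0L &
      runif(n_patients) < plogis((u - occ_mid) / occ_scale)
    pct[reach_i == 0L] <- 0
    pct[occluded] <- 100
    absent <- runif(n_patients) < absent_rate
    reach_i[absent] <- 0L
    pct[absent] <- 0; occluded[absent] <- FALSE
    d_norm <- round(runif(n_patients, 5, 9), 2)
    d_sten <- d_norm * (1 - pct / 100)
    reach <- CSI_REACH_LEVELS[reach_i + 1L]
    has_lesion <- reach_i > 0L & !absent
    p <- tolower(v)
    cohort[[paste0(p, "_reach")]] <- reach
    cohort[[paste0(p, "_d_sten_mm")]] <- ifelse(has_lesion, d_sten, NA_real_)
    cohort[[paste0(p, "_d_norm_mm")]] <- ifelse(has_lesion, d_norm, NA_real_)
    cohort[[paste0(p, "_percent")]] <- NA_real_
    cohort[[paste0(p, "_occluded")]] <- occluded
    cohort[[paste0(p, "_absent")]] <- absent
    comp[, 2L * i - 1L] <- ifelse(absent, 0L, extent_class(reach, v))
    comp[, 2L * i] <- ifelse(has_lesion, grade_class(pct, occluded), 0L)
  }
  cohort <- cbind(cohort, as.data.frame(comp))
  cohort$true_score <- csi_score(comp, weights)

  # stage 3: labels
  set.seed(sub_seed[3L])
  if (label_model == "threshold") {
    cohort$cmi_label <- cohort$true_score >= threshold_cutoff
  } else {
    centre <- solve_logistic_centre(
      cmi_prevalence, logistic_slope,
      severity_location_cmi, severity_location_non, severity_sd)
    cohort$cmi_label <-
      runif(n_patients) < plogis(logistic_slope * (severity - centre))
  }
  cohort
}

# expected label prevalence under severity ~ mixture, label ~ logistic
solve_logistic_centre <- function(prev, slope, mu1, mu0, sd) {
  e_logis <- function(mu, centre) {
    integrate(function(z) plogis(slope * (mu + sd * z - centre)) * dnorm(z),
              -Inf, Inf)$value
  }
  f <- function(centre)
    prev * e_logis(mu1, centre) + (1 - prev) * e_logis(mu0, centre) - prev
  uniroot(f, lower = mu0 - 20 / max(slope, 0.05),
          upper = mu1 + 20 / max(slope, 0.05))$root
}

#' Simulate two raters scoring the same cohort
#'
#' Rater 1 returns the true scores. Rater 2 re-reads a Bernoulli
#' (`disagreement_rate`) subset of patients with one reading error: the
#' grade class of one randomly chosen vessel is shifted by one level (the
#' shift direction is flipped at the scale boundary, and a grade appearing
#' on a lesion-free vessel also raises its extent to ostial so the profile
#' stays admissible), then the patient is rescored.
#'
#' @param cohort A cohort from [simulate_cohort()] (needs the six component
#'   columns).
#' @param disagreement_rate Probability that a patient is mis-read
#'   (default 0.17, i.e. an expected 83% agreement).
#' @param seed Integer seed.
#' @param weights Weights used for rescoring.
#' @return List with integer vectors `rater1` and `rater2`.
#' @examples
#' cohort <- simulate_cohort(50, seed = 1)
#' r <- simulate_raters(cohort, disagreement_rate = 0.17, seed = 2)
#' mean(r$rater1 == r$rater2)
#' @export
simulate_raters <- function(cohort, disagreement_rate = 0.17, seed = 1,
                            weights = csi_weights()) {
  if (disagreement_rate < 0 || disagreement_rate > 1)
    stop_validation("disagreement_rate must lie in [0, 1]")
  comp <- component_matrix(cohort[CSI_COMPONENT_NAMES])
  weights <- csi_weights(weights)
  n <- nrow(comp)
  set.seed(as.integer(seed))
  perturb <- runif(n) < disagreement_rate
  vessel <- sample.int(3L, n, replace = TRUE)
  up <- sample(c(-1L, 1L), n, replace = TRUE)
  comp2 <- comp
  for (i in which(perturb)) {
    gcol <- 2L * vessel[i]
    g <- comp2[i, gcol]
    shift <- up[i]
    if (g + shift < 0L || g + shift > 3L) shift <- -shift
    comp2[i, gcol] <- g + shift
    if (comp2[i, gcol] > 0L && comp2[i, gcol - 1L] == 0L)
      comp2[i, gcol - 1L] <- 1L  # rater 2 saw a mild lesion
  }
  list(rater1 = csi_score(comp, weights), rater2 = csi_score(comp2, weights))
}
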