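#' Score a cohort of patients from raw lesion measurements
#'
#' Applies the lesion classification and the score to every patient of a
#' wide-schema measurement table (one row per patient, per-vessel columns
#' `{ca,sma,ima}_{reach,d_sten_mm,d_norm_mm,percent,occluded,absent}` — see
#' [read_cohort()]), or passes through component columns if the table
#' already contains them.
#'
#' @param data Data frame in the wide measurement schema or with the six
#'   component columns.
#' @param weights A [csi_weights()] vector.
#' @param cutoff Risk-group cut-off (default 8).
#' @param absent_vessel_policy `"zero"` (default): an absent vessel
#'   contributes `(0, 0)` and the patient is flagged; `"missing"`: patients
#'   with an absent vessel are dropped with a message.
#' @return Data frame with `patient_id`, the six component columns,
#'   `csi_score`, `risk_group`, `subgroup`, `flags`, and `cmi_label` if
#'   present in the input.
#' @examples
#' cohort <- simulate_cohort(20, seed = 1)
#' head(score_patients(cohort[!grepl("^c_|^s_|^i_|true", names(cohort))]))
#' @export
score_patients <- function(data, weights = csi_weights(), cutoff = 8,
                           absent_vessel_policy = c("zero", "missing")) {
  absent_vessel_policy <- match.arg(absent_vessel_policy)
  data <- as.data.frame(data)
  n <- nrow(data)
  if (!n) stop_validation("empty cohort")
  if (is.null(data$patient_id)) data$patient_id <- sprintf("P%04d", seq_len(n))

  if (all(CSI_COMPONENT_NAMES %in% names(data))) {
    comp <- component_matrix(data[CSI_COMPONENT_NAMES])
    validate_components(comp)
    flags <- rep("", n)
  } else {
    comp <- matrix(0L, n, 6L, dimnames = list(NULL, CSI_COMPONENT_NAMES))
    flags <- character(n)
    for (r in seq_len(n)) {
      m <- wide_row_measurements(data[r, , drop = FALSE])
      cc <- withCallingHandlers(
        tryCatch(csi_components(m), error = function(e) {
          stop_validation(sprintf("row %d (patient %s): %s", r,
                                  data$patient_id[r], conditionMessage(e)))
        }),
        warning = function(w) {
          invokeRestart("muffleWarning")
        })
      comp[r, ] <- as.integer(cc)
      flags[r] <- paste(attr(cc, "flags"), collapse = ";")
    }
  }
  out <- data.frame(patient_id = data$patient_id, as.data.frame(comp))
  out$csi_score <- csi_score(comp, weights)
  out$risk_group <- classify_risk(out$csi_score, cutoff)
  out$subgroup <- score_subgroup(out$csi_score,
                                 max_score = score_range(weights)[["max"]])
  out$flags <- flags
  if (!is.null(data$cmi_label)) out$cmi_label <- as.logical(data$cmi_label)
  if (absent_vessel_policy == "missing") {
    drop <- grepl("absent:", out$flags)
    if (any(drop)) {
      message(sprintf("dropping %d patient(s) with an absent vessel (absent_vessel_policy = 'missing')",
                      sum(drop)))
      out <- out[!drop, , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  out
}

# reshape one wide-schema row into the three-row per-vessel layout
wide_row_measurements <- function(row) {
  get <- function(p, suffix, default = NA) {
    col <- paste0(p, suffix)
    if (col %in% names(row)) row[[col]] else default
  }
  data.frame(
    vessel = CSI_VESSELS,
    reach = vapply(c("ca", "sma", "ima"), function(p) {
      r <- get(p, "_reach", "none")
      if (is.na(r) || !nzchar(as.character(r))) "none" else as.character(r)
    }, character(1)),
    d_sten = vapply(c("ca", "sma", "ima"), function(p)
      as.numeric(get(p, "_d_sten_mm")), numeric(1)),
    d_norm = vapply(c("ca", "sma", "ima"), function(p)
      as.numeric(get(p, "_d_norm_mm")), numeric(1)),
    percent = vapply(c("ca", "sma", "ima"), function(p)
      as.numeric(get(p, "_percent")), numeric(1)),
    occluded = vapply(c("ca", "sma", "ima"), function(p)
      isTRUE(as.logical(get(p, "_occluded", FALSE))), logical(1)),
    absent = vapply(c("ca", "sma", "ima"), function(p)
      isTRUE(as.logical(get(p, "_absent", FALSE))), logical(1))
  )
}
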