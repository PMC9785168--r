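COHORT_VESSEL_COLS <- as.vector(outer(
  c("ca", "sma", "ima"),
  c("_reach", "_d_sten_mm", "_d_norm_mm", "_percent", "_occluded", "_absent"),
  paste0))

#' Read and validate a cohort measurement table
#'
#' Reads the wide measurement CSV (UTF-8, header required; one row per
#' patient, columns `patient_id`, optional `cmi_label`, and per vessel
#' `{ca,sma,ima}_reach`, `_d_sten_mm`, `_d_norm_mm`, `_percent`,
#' `_occluded`, `_absent`). Empty diameter cells are allowed where
#' `_percent` substitutes for them and vice versa. All rows are validated;
#' if any row is invalid the reader fails with a line-numbered report of
#' every problem found.
#'
#' @param path Path to the CSV file.
#' @param require_label Require the `cmi_label` column (default `FALSE`).
#' @return Validated data frame in the wide schema.
#' @export
read_cohort <- function(path, require_label = FALSE) {
  if (!file.exists(path)) stop_validation(paste0("file not found: ", path))
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  missing <- setdiff(c("patient_id", COHORT_VESSEL_COLS), names(df))
  # reach columns are mandatory; measurement columns may be absent entirely
  hard_missing <- missing[grepl("_reach$|^patient_id$", missing)]
  if (length(hard_missing))
    stop_validation(paste0("missing required column(s): ",
                           paste(hard_missing, collapse = ", ")))
  for (col in setdiff(missing, hard_missing)) df[[col]] <- NA
  if (require_label && is.null(df$cmi_label))
    stop_validation("missing required column: cmi_label")

  errors <- character(0)
  if (anyDuplicated(df$patient_id)) {
    dup <- unique(df$patient_id[duplicated(df$patient_id)])
    errors <- c(errors, paste0("duplicate patient_id: ",
                               paste(dup, collapse = ", ")))
  }
  for (p in c("ca", "sma", "ima")) {
    for (col in paste0(p, c("_occluded", "_absent"))) {
      v <- df[[col]]
      if (!is.logical(v)) {
        parsed <- parse_flag(v)
        if (anyNA(parsed) && !all(is.na(v[is.na(parsed)])))
          errors <- c(errors, sprintf(
            "column %s: unparseable flag value(s) in row(s) %s", col,
            paste(which(is.na(parsed) & !is.na(v)), collapse = ", ")))
        df[[col]] <- parsed
      }
      df[[col]][is.na(df[[col]])] <- FALSE
    }
    vessel <- toupper(p)
    reach <- df[[paste0(p, "_reach")]]
    reach[is.na(reach)] <- "none"
    bad <- !reach %in% CSI_REACH_LEVELS
    if (any(bad))
      errors <- c(errors, sprintf(
        "row %s: unknown %s reach '%s'",
        which(bad), vessel, reach[bad]))
    df[[paste0(p, "_reach")]] <- reach
    ds <- suppressWarnings(as.numeric(df[[paste0(p, "_d_sten_mm")]]))
    dn <- suppressWarnings(as.numeric(df[[paste0(p, "_d_norm_mm")]]))
    pc <- suppressWarnings(as.numeric(df[[paste0(p, "_percent")]]))
    has_lesion <- reach != "none" & !df[[paste0(p, "_absent")]]
    occ <- df[[paste0(p, "_occluded")]]
    no_measure <- has_lesion & !occ & is.na(pc) & (is.na(ds) | is.na(dn))
    if (any(no_measure))
      errors <- c(errors, sprintf(
        "row %d: vessel %s has a lesion but neither percent nor both diameters",
        which(no_measure), vessel))
    bad_diam <- !is.na(ds) & !is.na(dn) & (dn <= 0 | ds < 0 | ds > dn)
    if (any(bad_diam))
      errors <- c(errors, sprintf(
        "row %d: vessel %s has invalid diameters (d_sten %s, d_norm %s; need 0 <= d_sten <= d_norm, d_norm > 0)",
        which(bad_diam), vessel, format(ds[bad_diam]), format(dn[bad_diam])))
    bad_pct <- !is.na(pc) & (pc < 0 | pc > 100)
    if (any(bad_pct))
      errors <- c(errors, sprintf(
        "row %d: vessel %s percent stenosis outside [0, 100] (%s)",
        which(bad_pct), vessel, format(pc[bad_pct])))
    df[[paste0(p, "_d_sten_mm")]] <- ds
    df[[paste0(p, "_d_norm_mm")]] <- dn
    df[[paste0(p, "_percent")]] <- pc
  }
  if (!is.null(df$cmi_label)) df$cmi_label <- parse_flag(df$cmi_label)
  if (length(errors))
    stop_validation(paste0("invalid cohort file '", path, "':\n  ",
                           paste(errors, collapse = "\n  ")))
  df
}

parse_flag <- function(v) {
  if (is.logical(v)) return(v)
  s <- toupper(trimws(as.character(v)))
  out <- rep(NA, length(v))
  out[s %in% c("TRUE", "T", "1", "YES", "Y")] <- TRUE
  out[s %in% c("FALSE", "F", "0", "NO", "N")] <- FALSE
  out
}

#' Write a cohort or scored table to CSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @export
write_cohort <- function(x, path) {
  write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write an analysis report deterministically
#'
#' Serializes a named list of results (scalars, vectors, data frames, or the
#' package's result objects, which are unclassed) with sorted keys and fixed
#' decimal places: AUC-, kappa-, sensitivity-, specificity- and
#' Youden-scale values to 3 decimals, percentages to 1 decimal. Identical
#' results always produce byte-identical files. The `text` format mirrors
#' the clinical "n (%)" table style for cross-tabulations.
#'
#' @param results Named list.
#' @param path Output path.
#' @param format `"json"` (default), `"csv"` (flattened key/value pairs) or
#'   `"text"`.
#' @export
write_report <- function(results, path, format = c("json", "csv", "text")) {
  format <- match.arg(format)
  prepared <- prepare_report(results)
  if (format == "json") {
    jsonlite::write_json(prepared, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  } else if (format == "csv") {
    flat <- flatten_report(prepared)
    write.csv(data.frame(key = names(flat), value = unlist(flat, use.names = FALSE)),
              path, row.names = FALSE)
  } else {
    writeLines(text_report(prepared), path)
  }
  invisible(path)
}

round_for_report <- function(name, value) {
  if (!is.numeric(value)) return(value)
  lname <- tolower(name)
  if (grepl("percent|agreement_pct|^pct", lname)) return(round(value, 1))
  if (grepl("auc|kappa|ci_|sens|spec|youden|^se$|p_value|p_obs|p_exp", lname))
    return(round(value, 3))
  value
}

prepare_report <- function(x, name = "") {
  if (inherits(x, c("csi_auc", "csi_cutoff", "csi_boot", "csi_kappa",
                    "csi_grid", "csi_crosstab")))
    x <- lapply(unclass(x), identity)
  if (inherits(x, "csi_weights")) x <- as.list(unclass(x))
  if (is.data.frame(x)) {
    x <- x[, sort(names(x)), drop = FALSE]
    for (nm in names(x)) x[[nm]] <- round_for_report(nm, x[[nm]])
    return(x)
  }
  if (is.list(x)) {
    if (!is.null(names(x))) x <- x[order(names(x))]
    return(lapply(seq_along(x), function(i)
      prepare_report(x[[i]], names(x)[i] %||% "")) |>
        stats::setNames(names(x)))
  }
  if (is.matrix(x)) return(as.data.frame(x))
  if (is.factor(x)) return(as.character(x))
  round_for_report(name, x)
}

flatten_report <- function(x, prefix = "") {
  if (is.data.frame(x)) x <- as.list(x)
  if (is.list(x)) {
    out <- list()
    for (nm in names(x)) {
      key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
      out <- c(out, flatten_report(x[[nm]], key))
    }
    return(out)
  }
  stats::setNames(list(paste(format(x, trim = TRUE), collapse = ";")), prefix)
}

text_report <- function(x) {
  flat <- flatten_report(x)
  sprintf("%s: %s", names(flat), unlist(flat, use.names = FALSE))
}

#' Read a YAML run configuration
#'
#' A single YAML file drives the command-line pipeline; CLI flags override
#' file values. Recognised fields: `weights` (six integers), `cutoff`,
#' `grid` (two integers, lower and upper bound), `level`, `n_reps`, `seed`,
#' `absent_vessel_policy`, `input`, `output`.
#'
#' @param path Path to the YAML file.
#' @return Named list of configuration values, validated.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop_validation("reading config files requires the 'yaml' package")
  if (!file.exists(path)) stop_validation(paste0("config not found: ", path))
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$weights)) cfg$weights <- csi_weights(cfg$weights)
  if (!is.null(cfg$cutoff) && (!is.numeric(cfg$cutoff) || cfg$cutoff < 0))
    stop_validation("config: cutoff must be a non-negative number")
  if (!is.null(cfg$level) && (cfg$level <= 0 || cfg$level >= 1))
    stop_validation("config: level must lie in (0, 1)")
  if (!is.null(cfg$seed) && cfg$seed != round(cfg$seed))
    stop_validation("config: seed must be an integer")
  if (!is.null(cfg$absent_vessel_policy) &&
      !cfg$absent_vessel_policy %in% c("zero", "missing"))
    stop_validation("config: absent_vessel_policy must be 'zero' or 'missing'")
  cfg
}
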