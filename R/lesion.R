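#' Percent diameter stenosis from luminal diameters
#'
#' Computes the percent stenosis `(1 - d_stenosis / d_normal) * 100` from the
#' residual lumen diameter at the lesion and the estimated normal luminal
#' diameter at the same level. For a vessel with generalized calcification the
#' narrowest diameter is used as `d_stenosis` upstream; no separate pathway is
#' needed here.
#'
#' @param d_stenosis Residual lumen diameter at the stenosis, in mm (>= 0).
#' @param d_normal Estimated normal luminal diameter, in mm (> 0).
#' @param vessel Optional vessel name(s) used in error messages.
#' @return Numeric vector of percent stenosis values in `[0, 100]`.
#' @examples
#' percent_stenosis(3, 5)   # 40
#' percent_stenosis(0, 5)   # 100, total occlusion
#' @export
percent_stenosis <- function(d_stenosis, d_normal, vessel = NULL) {
  if (length(d_stenosis) != length(d_normal))
    stop_validation("d_stenosis and d_normal must have equal length")
  bad_norm <- !is.na(d_normal) & d_normal <= 0
  bad_sten <- !is.na(d_stenosis) & !is.na(d_normal) &
    (d_stenosis < 0 | d_stenosis > d_normal)
  if (any(bad_norm) || any(bad_sten)) {
    i <- which(bad_norm | bad_sten)[1L]
    where <- if (!is.null(vessel)) paste0(" (vessel ", vessel[min(i, length(vessel))], ")") else ""
    stop_validation(sprintf(
      "invalid measurement%s: need d_normal > 0 and 0 <= d_stenosis <= d_normal, got d_stenosis=%s, d_normal=%s",
      where, format(d_stenosis[i]), format(d_normal[i])))
  }
  100 * (1 - d_stenosis / d_normal)
}

#' Stenosis grade scale (0-3)
#'
#' Maps a percent stenosis to the four-level grade scale: 0 for 0-50%, 1 for
#' 51-70%, 2 for 71-99%, and 3 for occlusion. The printed integer bands are
#' extended to continuous measurements as half-open intervals: grade 0 iff
#' percent <= 50, grade 1 iff 50 < percent <= 70, grade 2 iff
#' 70 < percent < 100. An `occluded` flag (or percent exactly 100) always
#' yields grade 3.
#'
#' @param percent Percent stenosis in `[0, 100]`. May be `NA` when
#'   `occluded` is `TRUE`.
#' @param occluded Logical; `TRUE` marks complete occlusion and dominates any
#'   measured percent.
#' @return Integer vector of grades in `0:3`.
#' @examples
#' grade_class(40, FALSE)  # 0
#' grade_class(73, FALSE)  # 2
#' grade_class(20, TRUE)   # 3
#' @export
grade_class <- function(percent, occluded = FALSE) {
  n <- max(length(percent), length(occluded))
  percent <- rep_len(percent, n)
  occluded <- rep_len(occluded, n)
  chk <- !is.na(percent) & (percent < 0 | percent > 100)
  if (any(chk))
    stop_validation(sprintf("percent stenosis outside [0, 100]: %s",
                            format(percent[which(chk)[1L]])))
  if (any(is.na(percent) & !occluded))
    stop_validation("percent stenosis is NA for a non-occluded lesion")
  g <- integer(n)
  p <- ifelse(occluded, 100, percent)
  g[p > 50] <- 1L
  g[p > 70] <- 2L
  g[p >= 100 | occluded] <- 3L
  g
}

#' Lesion extent scale (0-3)
#'
#' Maps the lesion reach category to the extent scale: none = 0, ostial = 1
#' (within 10 mm of the aortic lumen), proximal = 2 (up to the first SMA
#' branch / CA bifurcation), extended = 3 (beyond those landmarks). For the
#' IMA only ostial stenosis is scored: any non-none reach is capped at 1 with
#' a warning, to avoid over-weighting a vessel whose distal branches are hard
#' to evaluate.
#'
#' @param reach Character vector of reach categories
#'   (`"none"`, `"ostial"`, `"proximal"`, `"extended"`).
#' @param vessel Vessel identifier(s), one of `"CA"`, `"SMA"`, `"IMA"`.
#' @return Integer vector of extent values (`0:3`; `0:1` for the IMA).
#' @examples
#' extent_class("ostial", "CA")    # 1
#' extent_class("extended", "SMA") # 3
#' @export
extent_class <- function(reach, vessel) {
  n <- max(length(reach), length(vessel))
  reach <- rep_len(as.character(reach), n)
  vessel <- rep_len(toupper(as.character(vessel)), n)
  if (any(!vessel %in% CSI_VESSELS))
    stop_validation(sprintf("unknown vessel '%s' (expected CA, SMA or IMA)",
                            vessel[which(!vessel %in% CSI_VESSELS)[1L]]))
  m <- match(reach, CSI_REACH_LEVELS)
  if (anyNA(m))
    stop_validation(sprintf(
      "unknown reach category '%s' for vessel %s (expected none/ostial/proximal/extended)",
      reach[which(is.na(m))[1L]], vessel[which(is.na(m))[1L]]))
  ext <- m - 1L
  cap <- vessel == "IMA" & ext > 1L
  if (any(cap)) {
    warning(sprintf("IMA reach beyond ostial in %d record(s); extent capped at 1 (only ostial IMA stenosis is scored)",
                    sum(cap)), call. = FALSE)
    ext[cap] <- 1L
  }
  ext
}

#' Score components from per-vessel lesion measurements
#'
#' Converts one patient's three vessel measurements into the six scale
#' variables `(C_extent, C_grade, S_extent, S_grade, I_extent, I_grade)`.
#' Exactly one row per vessel is required. Grade uses the measured diameters,
#' or `percent` directly when diameters are unavailable. An absent vessel
#' (anatomic variant) contributes `(0, 0)` and is flagged in the
#' `"absent_vessels"` attribute.
#'
#' @param measurements A data frame with one row per vessel and columns
#'   `vessel` (`CA`/`SMA`/`IMA`), `reach`, `d_sten`, `d_norm`, `percent`,
#'   `occluded`, `absent`. `percent` may substitute for the diameters.
#' @return A named integer vector of the six components (class
#'   `"csi_components"`), with attributes `absent_vessels` and `flags`.
#' @examples
#' m <- data.frame(
#'   vessel = c("CA", "SMA", "IMA"),
#'   reach = c("ostial", "proximal", "none"),
#'   d_sten = c(3, NA, NA), d_norm = c(5, NA, NA),
#'   percent = c(NA, 73, NA),
#'   occluded = FALSE, absent = FALSE)
#' csi_components(m)  # (1, 0, 2, 2, 0, 0)
#' @export
csi_components <- function(measurements) {
  m <- as.data.frame(measurements)
  for (col in c("d_sten", "d_norm", "percent"))
    if (is.null(m[[col]])) m[[col]] <- NA_real_
  for (col in c("occluded", "absent"))
    if (is.null(m[[col]])) m[[col]] <- FALSE
  m$occluded[is.na(m$occluded)] <- FALSE
  m$absent[is.na(m$absent)] <- FALSE
  m$vessel <- toupper(as.character(m$vessel))
  if (nrow(m) != 3L || !setequal(m$vessel, CSI_VESSELS) || anyDuplicated(m$vessel))
    stop_validation("measurements must contain exactly one row per vessel (CA, SMA, IMA)")
  m <- m[match(CSI_VESSELS, m$vessel), , drop = FALSE]

  out <- integer(6L)
  flags <- character(0)
  absent <- character(0)
  for (i in seq_len(3L)) {
    v <- m$vessel[i]
    if (isTRUE(m$absent[i])) {
      absent <- c(absent, v)
      flags <- c(flags, paste0("absent:", v))
      next  # contributes (0, 0)
    }
    reach <- as.character(m$reach[i])
    if (is.na(reach) || !nzchar(reach)) reach <- "none"
    ext <- extent_class(reach, v)
    if (v == "IMA" && reach %in% c("proximal", "extended"))
      flags <- c(flags, "ima_capped")
    if (ext == 0L) next  # no lesion -> grade 0
    pct <- m$percent[i]
    if (is.na(pct) && !m$occluded[i])
      pct <- percent_stenosis(m$d_sten[i], m$d_norm[i], vessel = v)
    if (!is.na(pct) && (pct < 0 || pct > 100))
      stop_validation(sprintf("percent stenosis outside [0, 100] for vessel %s", v))
    occ <- isTRUE(m$occluded[i])
    if (!occ && !is.na(pct) && pct >= 100) {
      warning(sprintf("vessel %s: percent stenosis 100 with occluded = FALSE; treated as occlusion (grade 3)", v),
              call. = FALSE)
      occ <- TRUE
    }
    out[2L * i - 1L] <- ext
    out[2L * i] <- grade_class(pct, occ)
  }
  names(out) <- CSI_COMPONENT_NAMES
  structure(out, class = "csi_components",
            absent_vessels = absent, flags = unique(flags))
}
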