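# Per-study dose arithmetic. All functions are pure, vectorised, and keep
# full numeric precision; rounding is left to the presentation layer.

check_positive <- function(x, name, strict = TRUE) {
  bad <- if (strict) !is.finite(x) | x <= 0 else !is.finite(x) | x < 0
  if (any(bad)) {
    stop(sprintf("`%s` must be %s and finite (offending value at position %d: %s)",
                 name, if (strict) "strictly positive" else "non-negative",
                 which(bad)[1], format(x[which(bad)[1]])), call. = FALSE)
  }
  invisible(x)
}

#' Effective diameter of an elliptical cross-section
#'
#' The effective diameter is the diameter of the circle with the same area as
#' the (approximately elliptical) patient cross-section, computed as the
#' geometric mean of the anterior-posterior and lateral dimensions measured at
#' the most extensive cross-sectional slice:
#' \eqn{D_{eff} = \sqrt{AP \times LAT}}.
#'
#' @param ap Anterior-posterior dimension in cm (strictly positive).
#' @param lat Lateral dimension in cm (strictly positive).
#' @return Effective diameter in cm. Vectorised over both arguments.
#' @examples
#' effective_diameter(25, 36) # 30 cm
#' @export
effective_diameter <- function(ap, lat) {
  check_positive(ap, "ap")
  check_positive(lat, "lat")
  sqrt(ap * lat)
}

#' Size-specific dose estimate
#'
#' \eqn{SSDE = CTDI_{vol} \times k}, where k is the phantom-to-patient size
#' conversion factor (see [lookup_k()]).
#'
#' @param ctdi_vol Volume CT dose index in mGy (non-negative), referenced to
#'   the standard phantom.
#' @param k Dimensionless size conversion factor (strictly positive).
#' @return SSDE in mGy.
#' @export
ssde <- function(ctdi_vol, k) {
  check_positive(ctdi_vol, "ctdi_vol", strict = FALSE)
  check_positive(k, "k")
  ctdi_vol * k
}

#' Size-specific dose-length product
#'
#' Applies the same size conversion factor used for SSDE to the whole-scan
#' dose-length product: \eqn{DLP_{ss} = DLP \times k}. By construction
#' `dlp_ss(dlp, k) / dlp == ssde(c, k) / c == k` for any record.
#'
#' @param dlp Dose-length product in mGy.cm (non-negative).
#' @inheritParams ssde
#' @return Size-adjusted dose-length product in mGy.cm.
#' @export
dlp_ss <- function(dlp, k) {
  check_positive(dlp, "dlp", strict = FALSE)
  check_positive(k, "k")
  dlp * k
}

#' Effective dose from a dose-length product
#'
#' \eqn{ED = DLP \times f} with a protocol-specific conversion coefficient
#' f in mSv/(mGy.cm); the chest value is 0.014 (AAPM Report 96).
#'
#' @inheritParams dlp_ss
#' @param f_factor Conversion coefficient in mSv/(mGy.cm); default 0.014
#'   (chest). Resolve by protocol name with [lookup_f()].
#' @return Effective dose in mSv.
#' @examples
#' effective_dose(286.51) # 4.011 mSv
#' @export
effective_dose <- function(dlp, f_factor = 0.014) {
  check_positive(dlp, "dlp", strict = FALSE)
  check_positive(f_factor, "f_factor")
  dlp * f_factor
}

#' Scan-length change between topogram and diagnostic scan
#'
#' Compares the planned (topogram) scan length against the acquired diagnostic
#' scan length. A positive delta means the diagnostic scan was extended beyond
#' the planned range (over-ranging); a negative delta means it was shortened.
#' "unchanged" requires exact mm equality.
#'
#' @param topogram_mm Topogram (scout) length in mm (strictly positive).
#' @param diagnostic_mm Diagnostic scan length in mm (strictly positive).
#' @return A tibble with columns `delta_mm`, `delta_pct` (percent of the
#'   topogram length) and `category` (factor: shortened / unchanged /
#'   extended).
#' @export
scan_length_change <- function(topogram_mm, diagnostic_mm) {
  check_positive(topogram_mm, "topogram_mm")
  check_positive(diagnostic_mm, "diagnostic_mm")
  delta <- diagnostic_mm - topogram_mm
  tibble::tibble(
    delta_mm = delta,
    delta_pct = 100 * delta / topogram_mm,
    category = factor(
      ifelse(delta < 0, "shortened", ifelse(delta > 0, "extended", "unchanged")),
      levels = c("shortened", "unchanged", "extended")
    )
  )
}
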