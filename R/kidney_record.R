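#' One kidney's dose estimates under one acquisition condition
#'
#' Holds the WKP-derived absorbed dose and the SV-derived doses of a single
#' kidney for one (SV volume, Gaussian filter) condition, plus the
#' ground-truth dose when the record comes from simulation.
#'
#' @param patient_id Opaque patient identifier (string).
#' @param kidney_side \code{"left"} or \code{"right"}.
#' @param filter_sigma_mm Gaussian post-filter sigma in mm (0 = unfiltered).
#' @param sv_volume_ml SV volume in ml (e.g. 2.0 or 0.6).
#' @param wkp_dose_gy WKP absorbed dose in Gy, \code{> 0}.
#' @param sv_doses_gy Ordered numeric vector of SV absorbed doses in Gy, all
#'   \code{> 0}, non-empty (typically length 5).
#' @param true_dose_gy Optional ground-truth dose in Gy (\code{NA} for real
#'   data; set by the synthetic-cohort generator).
#' @return An object of class \code{"kidney_record"}.
#' @export
kidney_record <- function(patient_id, kidney_side, filter_sigma_mm,
                          sv_volume_ml, wkp_dose_gy, sv_doses_gy,
                          true_dose_gy = NA_real_) {
  kidney_side <- match.arg(kidney_side, c("left", "right"))
  stopifnot(length(patient_id) == 1L,
            is.numeric(filter_sigma_mm), length(filter_sigma_mm) == 1L,
            filter_sigma_mm >= 0,
            is.numeric(sv_volume_ml), length(sv_volume_ml) == 1L,
            sv_volume_ml > 0,
            is.numeric(wkp_dose_gy), length(wkp_dose_gy) == 1L,
            is.numeric(sv_doses_gy),
            is.numeric(true_dose_gy), length(true_dose_gy) == 1L)
  if (!length(sv_doses_gy))
    stop("'sv_doses_gy' must contain at least one SV dose")
  if (!is.finite(wkp_dose_gy) || wkp_dose_gy <= 0)
    stop("'wkp_dose_gy' must be strictly positive")
  if (any(!is.finite(sv_doses_gy)) || any(sv_doses_gy <= 0))
    stop("all SV doses must be strictly positive")
  if (!is.na(true_dose_gy) && true_dose_gy <= 0)
    stop("'true_dose_gy' must be strictly positive when given")
  structure(
    list(patient_id = as.character(patient_id), kidney_side = kidney_side,
         filter_sigma_mm = filter_sigma_mm, sv_volume_ml = sv_volume_ml,
         wkp_dose_gy = wkp_dose_gy, sv_doses_gy = as.numeric(sv_doses_gy),
         true_dose_gy = true_dose_gy),
    class = "kidney_record"
  )
}

#' @export
print.kidney_record <- function(x, ...) {
  cat(sprintf("Kidney record: patient %s, %s kidney, GF %g mm, SV %g ml\n",
              x$patient_id, x$kidney_side, x$filter_sigma_mm, x$sv_volume_ml))
  cat(sprintf("  WKP dose: %.3f Gy; %d SV doses: %s Gy\n",
              x$wkp_dose_gy, length(x$sv_doses_gy),
              paste(sprintf("%.3f", x$sv_doses_gy), collapse = ", ")))
  if (!is.na(x$true_dose_gy))
    cat(sprintf("  true dose: %.3f Gy\n", x$true_dose_gy))
  invisible(x)
}

# Stratum label of a record: the (SV volume, filter sigma) condition.
record_stratum <- function(rec) {
  sprintf("v%g_f%g", rec$sv_volume_ml, rec$filter_sigma_mm)
}

#' Split records into (SV volume, filter) strata
#'
#' @param records List of \code{\link{kidney_record}} objects.
#' @return Named list of record lists, one per condition, named
#'   \code{"v<volume>_f<filter>"}, in order of first appearance.
#' @export
split_records <- function(records) {
  stopifnot(is.list(records), all(vapply(records, inherits, TRUE, "kidney_record")))
  keys <- vapply(records, record_stratum, "")
  split(records, factor(keys, levels = unique(keys)))
}
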