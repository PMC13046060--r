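#' Configuration of a synthetic dosimetry cohort
#'
#' Full recipe for a simulated study: cohort sizes, the true-dose
#' distribution, and per-condition noise parameters. True doses are
#' log-normal (doses are positive and right-skewed), parameterized by the
#' median and the log-scale sd; the defaults (median 3.76 Gy, log-sd 0.33)
#' put the central 95% of doses at roughly 2-7.2 Gy.
#'
#' @param n_patients Number of patients (default 18).
#' @param kidneys_per_patient Kidneys per patient (default 2).
#' @param svs_per_kidney SVs placed per kidney (default 5).
#' @param dose_median_gy Median of the true-dose distribution, Gy.
#' @param dose_log_sigma Log-normal shape (sd of log dose).
#' @param conditions Named list mapping condition labels
#'   (\code{"v<volume>_f<filter>"}) to \code{\link{noise_params}}; each entry
#'   must also carry attributes or be accompanied by the parallel lists
#'   \code{sv_volume_ml} and \code{filter_sigma_mm} below.
#' @param sv_volumes_ml,filter_sigmas_mm Numeric vectors parallel to
#'   \code{conditions} giving each condition's SV volume and filter sigma.
#' @param seed Integer RNG seed for \code{\link{generate_cohort}}.
#' @return An object of class \code{"cohort_config"}.
#' @seealso \code{\link{default_config}} for the calibrated study emulation.
#' @export
cohort_config <- function(n_patients = 18L, kidneys_per_patient = 2L,
                          svs_per_kidney = 5L, dose_median_gy = 3.76,
                          dose_log_sigma = 0.33, conditions,
                          sv_volumes_ml, filter_sigmas_mm, seed = 1L) {
  stopifnot(n_patients >= 1, kidneys_per_patient >= 1, svs_per_kidney >= 1,
            dose_median_gy > 0, dose_log_sigma > 0,
            is.list(conditions), length(conditions) >= 1L,
            all(vapply(conditions, inherits, TRUE, "noise_params")),
            length(sv_volumes_ml) == length(conditions),
            length(filter_sigmas_mm) == length(conditions),
            all(sv_volumes_ml > 0), all(filter_sigmas_mm >= 0),
            length(seed) == 1L, is.finite(seed))
  structure(
    list(n_patients = as.integer(n_patients),
         kidneys_per_patient = as.integer(kidneys_per_patient),
         svs_per_kidney = as.integer(svs_per_kidney),
         dose_median_gy = dose_median_gy, dose_log_sigma = dose_log_sigma,
         conditions = conditions,
         sv_volumes_ml = as.numeric(sv_volumes_ml),
         filter_sigmas_mm = as.numeric(filter_sigmas_mm),
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "Cohort config: %d patients x %d kidneys, %d SVs/kidney, %d conditions\n",
    x$n_patients, x$kidneys_per_patient, x$svs_per_kidney,
    length(x$conditions)))
  cat(sprintf("  true dose ~ lognormal(median %.2f Gy, log-sd %.2f); seed %d\n",
              x$dose_median_gy, x$dose_log_sigma, x$seed))
  invisible(x)
}

#' Invert the precision curve for the noise magnitudes
#'
#' Solves the first-order precision formula for \code{(sigma_sv,
#' sigma_wkp)} given the single-SV precision U(1) and the asymptotic plateau
#' U(infinity), both in percent, at a given SV-WKP correlation (independent
#' SVs assumed). Since \code{U(1)^2 - U(inf)^2 = sigma_sv^2} regardless of
#' rho, \code{sigma_sv} follows directly; \code{sigma_wkp} then solves
#' \code{sigma_wkp^2 - 2 rho sigma_sv sigma_wkp = (U(inf)/100)^2}.
#'
#' @param single_sv_precision U(1) in percent.
#' @param plateau U(infinity) in percent.
#' @param rho SV-WKP noise correlation (default 0).
#' @return A list with \code{sigma_sv} and \code{sigma_wkp} (fractions).
#' @examples
#' calibrate_sigmas(11.82, 7.27)  # sigma_sv 0.0932, sigma_wkp 0.0727
#' @export
calibrate_sigmas <- function(single_sv_precision, plateau, rho = 0) {
  stopifnot(is.numeric(single_sv_precision), is.numeric(plateau),
            is.numeric(rho), abs(rho) <= 1)
  if (plateau < 0 || single_sv_precision <= plateau)
    stop("infeasible pair: need single-SV precision > plateau >= 0")
  s1 <- single_sv_precision / 100
  pinf <- plateau / 100
  sigma_sv <- sqrt(s1^2 - pinf^2)
  disc <- rho^2 * sigma_sv^2 + pinf^2
  sigma_wkp <- rho * sigma_sv + sqrt(disc)
  if (sigma_wkp < 0) stop("no real solution for sigma_wkp")
  list(sigma_sv = sigma_sv, sigma_wkp = sigma_wkp)
}

#' Study-calibrated default cohort configuration
#'
#' The reference simulation conditions: 18 patients x 2 kidneys x 5 SVs,
#' true doses log-normal with median 3.76 Gy, and ten (SV volume, filter)
#' conditions - SV volumes 2 ml and 0.6 ml crossed with Gaussian filter
#' sigmas 0, 3, 4, 5, 6 mm. Each condition's noise magnitudes are obtained
#' by \code{\link{calibrate_sigmas}} from the per-filter single-SV
#' precisions (2 ml: 11.82, 11.41, 11.38, 11.29, 11.40 percent; 0.6 ml:
#' 13.13, 12.30, 12.11, 12.07, 12.24 percent) and the plateau precisions
#' (7.27 and 6.92 percent), with rho = 0 as the conservative assumption for
#' the unknown SV-WKP noise correlation. The multiplicative SV bias is 1.12
#' (2 ml) and 1.23 (0.6 ml), the unfiltered normalization factors.
#'
#' @param seed RNG seed stored in the config (default 1).
#' @return A \code{\link{cohort_config}}.
#' @export
default_config <- function(seed = 1L) {
  filters <- c(0, 3, 4, 5, 6)
  singles <- list(`2` = c(11.82, 11.41, 11.38, 11.29, 11.40),
                  `0.6` = c(13.13, 12.30, 12.11, 12.07, 12.24))
  plateaus <- c(`2` = 7.27, `0.6` = 6.92)
  biases <- c(`2` = 1.12, `0.6` = 1.23)
  conds <- list(); vols <- numeric(); fsig <- numeric()
  for (vol in c("2", "0.6")) {
    for (i in seq_along(filters)) {
      sig <- calibrate_sigmas(singles[[vol]][i], plateaus[[vol]], rho = 0)
      conds[[sprintf("v%s_f%g", vol, filters[i])]] <-
        noise_params(sig$sigma_sv, sig$sigma_wkp, rho_sv_wkp = 0,
                     rho_sv_sv = 0, bias = biases[[vol]])
      vols <- c(vols, as.numeric(vol))
      fsig <- c(fsig, filters[i])
    }
  }
  cohort_config(conditions = conds, sv_volumes_ml = vols,
                filter_sigmas_mm = fsig, seed = seed)
}

#' Generate a synthetic cohort of kidney records
#'
#' Draws one true dose per kidney from the configured log-normal (shared
#' across all conditions of that kidney, as in a real study where every
#' filter setting re-processes the same acquisition), then simulates the SV
#' and WKP dose estimates independently for each condition via
#' \code{\link{simulate_kidney_measurement}}. Fully reproducible from
#' \code{config$seed}; seeds the global RNG stream.
#'
#' @param config A \code{\link{cohort_config}}.
#' @return A list of \code{\link{kidney_record}} objects (one per kidney and
#'   condition) with \code{true_dose_gy} filled in, ordered by patient,
#'   kidney, then condition.
#' @examples
#' cohort <- generate_cohort(default_config(seed = 42))
#' length(cohort)  # 36 kidneys x 10 conditions = 360
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n_kid <- config$n_patients * config$kidneys_per_patient
  mu <- log(config$dose_median_gy)
  true_doses <- stats::rlnorm(n_kid, meanlog = mu, sdlog = config$dose_log_sigma)
  sides <- c("left", "right")
  records <- vector("list", n_kid * length(config$conditions))
  idx <- 0L
  for (p in seq_len(config$n_patients)) {
    for (s in seq_len(config$kidneys_per_patient)) {
      kid <- (p - 1L) * config$kidneys_per_patient + s
      for (ci in seq_along(config$conditions)) {
        sim <- simulate_kidney_measurement(true_doses[kid],
                                           config$conditions[[ci]],
                                           config$svs_per_kidney)
        idx <- idx + 1L
        records[[idx]] <- kidney_record(
          patient_id = sprintf("P%02d", p),
          kidney_side = sides[(s - 1L) %% 2L + 1L],
          filter_sigma_mm = config$filter_sigmas_mm[ci],
          sv_volume_ml = config$sv_volumes_ml[ci],
          wkp_dose_gy = sim$wkp_dose, sv_doses_gy = sim$sv_doses,
          true_dose_gy = true_doses[kid])
      }
    }
  }
  records
}
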