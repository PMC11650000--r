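#' Specify a synthetic EEG/MEG cohort
#'
#' Collects every generative parameter for [simulate_subject()] and
#' [simulate_cohort()].  Each region's signal is the sum of a 1/f^chi
#' aperiodic background (unit SD), a narrowband alpha oscillation
#' (Gaussian-bandpass-filtered noise centred on the subject's drawn peak
#' frequency, SD `alpha_amplitude` times the region's topography weight) and
#' white measurement noise of SD `noise_sd`, all in background-SD units.
#'
#' Controls draw their alpha peak from N(`alpha_peak_mean_control`,
#' `alpha_peak_sd`) and patients from N(`alpha_peak_mean_patient`,
#' `alpha_peak_sd`); draws are clipped to [4, 14] Hz so the slow (6-9 Hz)
#' and fast (10-11 Hz) bands stay meaningful.  The default peaks (10.5 Hz
#' controls, 8 Hz patients) are synthetic choices that straddle the two
#' bands; they are not estimates from any clinical cohort.
#'
#' @param n_controls,n_patients Cohort sizes (>= 0, at least one subject in
#'   total for [simulate_cohort()]).
#' @param patient_laterality_fractions Named numeric `c(left=, right=)`
#'   summing to 1; the left-TLE count is `round(left * n_patients)`.
#' @param fs Sampling rate in Hz; must exceed 95 Hz so the 1-47.5 Hz
#'   analysis band sits below Nyquist.  EEG convention 250, MEG 600.
#' @param duration Recording length in seconds.
#' @param n_regions Even region count, split half/half by hemisphere
#'   (default 68).
#' @param aperiodic_exponent Slope chi of the 1/f^chi background power.
#' @param alpha_peak_mean_control,alpha_peak_mean_patient,alpha_peak_sd
#'   Alpha peak frequency distribution per group, Hz.
#' @param alpha_bandwidth Full width at half power of the oscillator, Hz.
#' @param alpha_amplitude Oscillator SD at a weight-1 region, in units of
#'   the background SD.
#' @param alpha_amplitude_topography Optional non-negative weight per
#'   region; default: the posterior-dominant linear taper of
#'   [dk68_parcellation()].
#' @param noise_sd White measurement-noise SD, background-SD units.
#' @param seed Integer master seed; per-subject substreams are derived from
#'   it deterministically.
#' @param modality `"EEG"` or `"MEG"` (metadata only).
#' @return An object of class `cohort_spec`.
#' @examples
#' spec <- cohort_spec(n_controls = 3, n_patients = 2, duration = 10)
#' @export
cohort_spec <- function(n_controls = 20L, n_patients = 20L,
                        patient_laterality_fractions = c(left = 0.5, right = 0.5),
                        fs = 250, duration = 60, n_regions = 68L,
                        aperiodic_exponent = 1,
                        alpha_peak_mean_control = 10.5,
                        alpha_peak_mean_patient = 8,
                        alpha_peak_sd = 0.5,
                        alpha_bandwidth = 2,
                        alpha_amplitude = 0.5,
                        alpha_amplitude_topography = NULL,
                        noise_sd = 0.2,
                        seed = 1L,
                        modality = c("EEG", "MEG")) {
  spec <- list(n_controls = as.integer(n_controls),
               n_patients = as.integer(n_patients),
               patient_laterality_fractions = patient_laterality_fractions,
               fs = fs, duration = duration,
               n_regions = as.integer(n_regions),
               aperiodic_exponent = aperiodic_exponent,
               alpha_peak_mean_control = alpha_peak_mean_control,
               alpha_peak_mean_patient = alpha_peak_mean_patient,
               alpha_peak_sd = alpha_peak_sd,
               alpha_bandwidth = alpha_bandwidth,
               alpha_amplitude = alpha_amplitude,
               alpha_amplitude_topography = alpha_amplitude_topography,
               noise_sd = noise_sd, seed = as.integer(seed),
               modality = match.arg(modality))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
}

#' Validate a cohort specification
#'
#' Checks every generative invariant and fails naming the offending field.
#'
#' @param spec A [cohort_spec()].
#' @return The validated spec, invisibly usable in pipelines.
#' @export
validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  chk <- function(ok, field, why)
    if (!ok) stop("invalid cohort_spec field '", field, "': ", why,
                  call. = FALSE)
  chk(spec$n_controls >= 0L, "n_controls", "must be >= 0")
  chk(spec$n_patients >= 0L, "n_patients", "must be >= 0")
  fr <- spec$patient_laterality_fractions
  chk(length(fr) == 2L && all(fr >= 0) && abs(sum(fr) - 1) <= 1e-9,
      "patient_laterality_fractions", "two non-negative values summing to 1")
  chk(is.numeric(spec$fs) && spec$fs > 2 * 47.5, "fs",
      "must exceed 95 Hz so the 1-47.5 Hz analysis band is below Nyquist")
  chk(spec$duration > 0, "duration", "must be positive (seconds)")
  chk(spec$n_regions >= 2L && spec$n_regions %% 2L == 0L, "n_regions",
      "must be an even count >= 2")
  chk(spec$aperiodic_exponent >= 0, "aperiodic_exponent", "must be >= 0")
  for (f in c("alpha_peak_mean_control", "alpha_peak_mean_patient"))
    chk(spec[[f]] > 1 && spec[[f]] < spec$fs / 2, f,
        "mean alpha peak must lie inside (1, fs/2) Hz")
  chk(spec$alpha_peak_sd >= 0, "alpha_peak_sd", "must be >= 0")
  chk(spec$alpha_bandwidth > 0, "alpha_bandwidth", "must be positive (Hz)")
  chk(spec$alpha_amplitude >= 0, "alpha_amplitude", "must be >= 0")
  if (!is.null(spec$alpha_amplitude_topography)) {
    chk(length(spec$alpha_amplitude_topography) == spec$n_regions,
        "alpha_amplitude_topography", "one weight per region required")
    chk(all(spec$alpha_amplitude_topography >= 0),
        "alpha_amplitude_topography", "weights must be non-negative")
  }
  chk(spec$noise_sd >= 0, "noise_sd", "must be >= 0")
  chk(is.finite(spec$seed), "seed", "must be a finite integer")
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d controls + %d patients, %s @ %g Hz, %g s\n",
              x$n_controls, x$n_patients, x$modality, x$fs, x$duration))
  cat(sprintf("  alpha peaks: control %.1f Hz, patient %.1f Hz (sd %.2f), 1/f^%.2g\n",
              x$alpha_peak_mean_control, x$alpha_peak_mean_patient,
              x$alpha_peak_sd, x$aperiodic_exponent))
  invisible(x)
}
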