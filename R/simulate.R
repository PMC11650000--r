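# Run `expr` under a private Mersenne-Twister stream seeded with `seed`,
# restoring the caller's RNG state afterwards so simulation is pure.
with_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# deterministic per-subject substream seed, independent of subject order
subject_seed <- function(master, i) {
  as.integer((as.double(master) %% 2147483647 * 48271 + i * 16807) %% 2147483647)
}

# Draw the two-sided Hermitian-symmetric spectrum of a zero-mean Gaussian
# process with amplitude response gain(f): independent complex-normal bins
# (DC zero, Nyquist real), each column standardised via Parseval so the
# time-domain sample SD is exactly 1.  Columns are regions.
draw_spectrum <- function(n, n_cols, gain, scale = rep(1, n_cols)) {
  n_half <- (n - 1) %/% 2                    # strictly positive, non-Nyquist
  idx <- which(gain[2:(n_half + 1)] > 1e-12) # skip numerically dead bins
  m <- length(idx)
  g <- gain[1 + idx]
  re <- matrix(stats::rnorm(m * n_cols), nrow = m) * g
  im <- matrix(stats::rnorm(m * n_cols), nrow = m) * g
  ny <- if (n %% 2 == 0 && gain[n / 2 + 1] > 1e-12)
    stats::rnorm(n_cols) * gain[n / 2 + 1] else rep(0, n_cols)
  # Parseval: sample variance (n-1 denominator) of the inverse transform
  v <- (2 * (colSums(re * re) + colSums(im * im)) + ny * ny) /
    n^2 * n / (n - 1)
  v[v == 0] <- 1
  s <- matrix(scale / sqrt(v), nrow = m, ncol = n_cols, byrow = TRUE)
  Z <- matrix(0i, nrow = n, ncol = n_cols)
  H <- complex(real = re * s, imaginary = im * s)
  Z[1 + idx, ] <- H
  Z[n + 1 - idx, ] <- Conj(H)
  if (n %% 2 == 0) Z[n / 2 + 1, ] <- ny * scale / sqrt(v)
  Z
}

# two-sided frequency axis for an n-point FFT at sampling rate fs
fft_freqs <- function(n, fs) {
  k <- 0:(n - 1)
  pmin(k, n - k) * fs / n
}

#' Simulate one subject's region-level recording
#'
#' Generates a [recording()] whose regions each carry an aperiodic 1/f^chi
#' background, a narrowband alpha oscillation at the subject's drawn peak
#' frequency (amplitude scaled by the region's topography weight) and white
#' measurement noise.  The drawn peak is stored in the recording's
#' provenance so recovery tests can check it.
#'
#' @param spec A [cohort_spec()].
#' @param group `"control"`, `"left_TLE"` or `"right_TLE"`.
#' @param seed Integer substream seed; defaults to the spec's master seed.
#' @param subject_id Identifier for the returned recording.
#' @return A [recording()] of `spec$duration * spec$fs` samples per region.
#' @examples
#' rec <- simulate_subject(cohort_spec(duration = 8), "control")
#' @export
simulate_subject <- function(spec, group = c("control", "left_TLE", "right_TLE"),
                             seed = spec$seed, subject_id = "s01") {
  validate_cohort_spec(spec)
  group <- match.arg(group)
  parc <- dk68_parcellation(spec$n_regions)
  w <- spec$alpha_amplitude_topography
  if (is.null(w)) w <- parc$weight
  n <- round(spec$duration * spec$fs)
  nr <- spec$n_regions
  peak_mean <- if (group == "control") spec$alpha_peak_mean_control
               else spec$alpha_peak_mean_patient

  with_rng(seed, {
    peak <- stats::rnorm(1, peak_mean, spec$alpha_peak_sd)
    peak <- min(max(peak, 4), 14)          # keep slow/fast bands meaningful

    f <- fft_freqs(n, spec$fs)
    # 1/f^chi amplitude, floored below 0.5 Hz; DC removed
    ap_gain <- ifelse(f == 0, 0, pmax(f, 0.5)^(-spec$aperiodic_exponent / 2))
    Z <- draw_spectrum(n, nr, ap_gain)        # unit-SD background

    sigma_f <- spec$alpha_bandwidth / 2.355   # FWHM -> Gaussian SD
    osc_gain <- exp(-(f - peak)^2 / (2 * sigma_f^2))
    osc_gain[f == 0] <- 0
    Z <- Z + draw_spectrum(n, nr, osc_gain,
                           scale = spec$alpha_amplitude * w)

    x <- Re(stats::mvfft(Z, inverse = TRUE)) / n
    if (spec$noise_sd > 0)
      x <- x + matrix(stats::rnorm(n * nr, sd = spec$noise_sd), nrow = n)

    recording(t(x), fs = spec$fs,
              region_labels = parc$label, hemisphere = parc$hemisphere,
              subject_id = subject_id, group = group,
              modality = spec$modality,
              provenance = list(alpha_peak_hz = peak, seed = as.integer(seed)))
  })
}

#' Simulate a full control + patient cohort
#'
#' Draws `n_controls` control subjects and `n_patients` TLE patients
#' (laterality split by `patient_laterality_fractions`, left count
#' `round(left_fraction * n_patients)`).  Each subject uses a substream
#' derived deterministically from `spec$seed`, so the cohort is reproducible
#' and independent of generation order.
#'
#' @param spec A [cohort_spec()] with `n_controls + n_patients >= 1`.
#' @return A list with `recordings` (list of [recording()]) and `provenance`
#'   (data.frame: subject_id, group, laterality, drawn_peak_hz, seed).
#' @examples
#' coh <- simulate_cohort(cohort_spec(n_controls = 2, n_patients = 1,
#'                                    duration = 8))
#' coh$provenance
#' @export
simulate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  n_tot <- spec$n_controls + spec$n_patients
  if (n_tot < 1L) stop("cohort must contain at least one subject")
  n_left <- as.integer(round(spec$patient_laterality_fractions[["left"]] *
                             spec$n_patients))
  groups <- c(rep("control", spec$n_controls),
              rep("left_TLE", n_left),
              rep("right_TLE", spec$n_patients - n_left))
  ids <- sprintf("%s%03d", ifelse(groups == "control", "con", "pat"),
                 seq_len(n_tot))
  recs <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    recs[[i]] <- simulate_subject(spec, groups[i],
                                  seed = subject_seed(spec$seed, i),
                                  subject_id = ids[i])
  }
  prov <- data.frame(
    subject_id = ids, group = groups,
    laterality = vapply(recs, rec_laterality, character(1)),
    drawn_peak_hz = vapply(recs, function(r) r$provenance$alpha_peak_hz,
                           numeric(1)),
    seed = vapply(recs, function(r) r$provenance$seed, integer(1)),
    stringsAsFactors = FALSE)
  list(recordings = recs, provenance = prov)
}
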