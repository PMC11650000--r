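#' Canonical slow/fast alpha band definitions
#'
#' Shipped constants: slow alpha 6-9 Hz and fast alpha 10-11 Hz.  Band
#' edges are inclusive on bin centres, so at the default 0.5 Hz resolution
#' the slow band covers 7 bins (6.0-9.0) and the fast band 3 bins
#' (10.0-11.0); 9.5 Hz belongs to neither, mirroring the deliberate gap
#' between the two bands.
#'
#' @param name Band name.
#' @param f_lo,f_hi Band edges in Hz, `0 < f_lo <= f_hi`.
#' @return A `band_definition` object.
#' @export
band_definition <- function(name, f_lo, f_hi) {
  if (!(f_lo > 0 && f_lo <= f_hi))
    stop("band edges must satisfy 0 < f_lo <= f_hi")
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi,
                 edge_rule = "inclusive"), class = "band_definition")
}

#' @rdname band_definition
#' @export
slow_alpha_band <- function() band_definition("slow_alpha", 6, 9)

#' @rdname band_definition
#' @export
fast_alpha_band <- function() band_definition("fast_alpha", 10, 11)

#' Welch power spectral density
#'
#' Averaged Hann-tapered periodograms over sliding windows (default 2-s
#' windows with 1-s overlap, giving 0.5 Hz resolution).  One-sided density
#' scaling: summing `power * df` over the grid approximates the signal
#' variance.  Segments are not detrended, so DC power is retained in the
#' lowest bins.
#'
#' @param rec A [recording()].
#' @param window_s Window length, seconds.
#' @param overlap_s Overlap between consecutive windows, seconds
#'   (`0 <= overlap_s < window_s`).
#' @return A `power_spectrum`: list with `freqs` (Hz), `power` (region x
#'   frequency matrix), `fs`, `df`, `normalized = FALSE`, plus the
#'   recording's region and subject metadata.
#' @export
welch_psd <- function(rec, window_s = 2, overlap_s = 1) {
  stopifnot(inherits(rec, "recording"))
  if (!(overlap_s >= 0 && overlap_s < window_s))
    stop("need 0 <= overlap_s < window_s")
  n <- ncol(rec$data)
  nper <- round(window_s * rec$fs)
  if (n < 2 * nper)
    stop("recording too short for Welch: need >= ", 2 * nper,
         " samples (2 windows), got ", n)
  step <- nper - round(overlap_s * rec$fs)
  starts <- seq(1L, n - nper + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nper - 1)) / nper)   # periodic Hann
  U <- sum(w^2)
  nfreq <- nper %/% 2 + 1L
  nr <- nrow(rec$data)
  # stack all (segment, region) windows as columns of one matrix: a single
  # mvfft call covers the whole recording
  segs <- matrix(0, nrow = nper, ncol = length(starts) * nr)
  k <- 0L
  for (s in starts) {
    seg <- t(rec$data[, s:(s + nper - 1L), drop = FALSE]) * w
    segs[, (k * nr + 1L):((k + 1L) * nr)] <- seg
    k <- k + 1L
  }
  X <- stats::mvfft(segs)[seq_len(nfreq), , drop = FALSE]
  P <- Mod(X)^2 / (rec$fs * U)
  scale2 <- rep(2, nfreq); scale2[1] <- 1
  if (nper %% 2 == 0) scale2[nfreq] <- 1      # Nyquist bin not doubled
  P <- P * scale2
  # average over segments per region
  dim(P) <- c(nfreq * nr, length(starts))
  pow <- matrix(rowMeans(P), nrow = nfreq)    # frequency x region
  pow <- t(pow)
  rownames(pow) <- rec$region_labels
  structure(list(freqs = (seq_len(nfreq) - 1L) * rec$fs / nper,
                 power = pow, fs = rec$fs, df = rec$fs / nper,
                 normalized = FALSE, norm_band = NULL,
                 region_labels = rec$region_labels,
                 hemisphere = rec$hemisphere,
                 subject_id = rec$subject_id, group = rec$group,
                 modality = rec$modality,
                 laterality = rec_laterality(rec)),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %s (%s): %d regions x %d bins, df = %g Hz%s\n",
              x$subject_id, x$group, nrow(x$power), length(x$freqs), x$df,
              if (x$normalized)
                sprintf(", relative over %g-%g Hz",
                        x$norm_band[1], x$norm_band[2]) else ""))
  invisible(x)
}

# indices of bins whose centres fall inside [f_lo, f_hi], edges inclusive
band_bins <- function(freqs, f_lo, f_hi, tol = 1e-9) {
  which(freqs >= f_lo - tol & freqs <= f_hi + tol)
}

#' Sum-to-one relative power
#'
#' Divides each region's power by its total over the normalization band, so
#' band powers become proportions.  Bins outside the band are zeroed.  The
#' default band (1, 47.5) Hz matches the analysis bandpass.
#'
#' @param ps An unnormalized `power_spectrum` from [welch_psd()].
#' @param norm_band Length-2 numeric, Hz.
#' @return The normalized `power_spectrum` (`normalized = TRUE`).
#' @export
relative_power <- function(ps, norm_band = c(1, 47.5)) {
  stopifnot(inherits(ps, "power_spectrum"))
  if (isTRUE(ps$normalized))
    stop("spectrum is already normalized; relative_power cannot be applied twice")
  bins <- band_bins(ps$freqs, norm_band[1], norm_band[2])
  if (!length(bins)) stop("no frequency bins inside the normalization band")
  tot <- rowSums(ps$power[, bins, drop = FALSE])
  if (any(tot <= 0))
    stop("zero total power inside the normalization band for region(s): ",
         paste(ps$region_labels[tot <= 0], collapse = ", "))
  out <- ps
  pw <- matrix(0, nrow = nrow(ps$power), ncol = ncol(ps$power),
               dimnames = dimnames(ps$power))
  pw[, bins] <- ps$power[, bins, drop = FALSE] / tot
  out$power <- pw
  out$normalized <- TRUE
  out$norm_band <- as.numeric(norm_band)
  out
}

#' Relative band power per region
#'
#' Sums relative power over the bins whose centres fall inside the band
#' (edges inclusive).
#'
#' @param ps A normalized `power_spectrum`.
#' @param band A [band_definition()], contained in the normalization band.
#' @return Named numeric vector, one proportion per region.
#' @export
band_power <- function(ps, band) {
  stopifnot(inherits(ps, "power_spectrum"), inherits(band, "band_definition"))
  if (!isTRUE(ps$normalized))
    stop("band_power expects a normalized spectrum; call relative_power() first")
  if (band$f_lo < ps$norm_band[1] - 1e-9 || band$f_hi > ps$norm_band[2] + 1e-9)
    stop("band ", band$name, " (", band$f_lo, "-", band$f_hi,
         " Hz) lies outside the normalization band")
  bins <- band_bins(ps$freqs, band$f_lo, band$f_hi)
  rowSums(ps$power[, bins, drop = FALSE])
}

#' Cohort-level global band power curve
#'
#' For each frequency bin in `f_range`: the mean relative power over all
#' subjects and regions, with a normal-approximation 95% confidence
#' interval across subjects (each subject first averaged across its
#' regions; CI = mean +/- 1.96 SEM).
#'
#' @param spectra List of normalized `power_spectrum` objects sharing one
#'   frequency grid.
#' @param f_range Length-2 numeric, Hz (default 1-20).
#' @return data.frame: `freq`, `mean`, `ci_lo`, `ci_hi`, `n_subjects`.
#' @export
global_band_power <- function(spectra, f_range = c(1, 20)) {
  stopifnot(length(spectra) >= 1)
  f0 <- spectra[[1]]$freqs
  for (ps in spectra) {
    stopifnot(inherits(ps, "power_spectrum"))
    if (!isTRUE(ps$normalized)) stop("all spectra must be normalized")
    if (length(ps$freqs) != length(f0) || any(abs(ps$freqs - f0) > 1e-9))
      stop("spectra do not share a common frequency grid")
  }
  bins <- band_bins(f0, f_range[1], f_range[2])
  # per-subject curve: mean across regions
  subj <- t(vapply(spectra,
                   function(ps) colMeans(ps$power[, bins, drop = FALSE]),
                   numeric(length(bins))))
  m <- colMeans(subj)
  n <- nrow(subj)
  sem <- if (n > 1) apply(subj, 2, stats::sd) / sqrt(n) else rep(0, ncol(subj))
  data.frame(freq = f0[bins], mean = m,
             ci_lo = m - 1.96 * sem, ci_hi = m + 1.96 * sem,
             n_subjects = n)
}

# argmax of the log-spectrum detrended by a log-log 1/f fit (fit over
# fit_range excluding the alpha neighbourhood), searched within peak_range.
# Internal oracle used by peak-recovery checks and summary().
estimate_alpha_peak <- function(ps, region = 1L, peak_range = c(6, 13),
                                fit_range = c(2, 40), exclude = c(5, 15)) {
  p <- ps$power[region, ]
  f <- ps$freqs
  fit_idx <- which(f >= fit_range[1] & f <= fit_range[2] &
                   !(f >= exclude[1] & f <= exclude[2]) & p > 0)
  co <- stats::coef(stats::lm(log10(p[fit_idx]) ~ log10(f[fit_idx])))
  pk_idx <- band_bins(f, peak_range[1], peak_range[2])
  resid <- log10(pmax(p[pk_idx], 1e-300)) - (co[1] + co[2] * log10(f[pk_idx]))
  f[pk_idx][which.max(resid)]
}
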