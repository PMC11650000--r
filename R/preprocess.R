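# replace the data matrix of a recording, keeping metadata; fs may change
update_rec <- function(rec, data, fs = rec$fs) {
  recording(data, fs = fs, region_labels = rec$region_labels,
            hemisphere = rec$hemisphere, subject_id = rec$subject_id,
            group = rec$group, modality = rec$modality,
            provenance = rec$provenance)
}

#' Zero-phase bandpass filter
#'
#' Forward-backward (zero-phase) 4th-order Butterworth bandpass applied per
#' region.  The default 1-47.5 Hz band is the conventional broadband
#' analysis window for resting-state EEG/MEG.
#'
#' @param rec A [recording()].
#' @param f_lo,f_hi Passband edges in Hz, `0 < f_lo < f_hi < fs/2`.
#' @return A filtered copy of the recording (same shape, fs, labels).
#' @export
bandpass_filter <- function(rec, f_lo = 1, f_hi = 47.5) {
  stopifnot(inherits(rec, "recording"))
  if (!(f_lo > 0 && f_lo < f_hi && f_hi < rec$fs / 2))
    stop("bandpass edges must satisfy 0 < f_lo < f_hi < fs/2 (fs = ",
         rec$fs, " Hz)")
  bf <- signal::butter(4, c(f_lo, f_hi) / (rec$fs / 2), type = "pass")
  out <- t(apply(rec$data, 1, function(x) signal::filtfilt(bf, x)))
  update_rec(rec, out)
}

#' Resample a recording
#'
#' Polyphase anti-aliased resampling to `fs_target` (downsampling only;
#' bandpass first so the retained band sits below the new Nyquist).  The
#' duration is preserved to within one output sample.
#'
#' @param rec A [recording()].
#' @param fs_target Target sampling rate in Hz, `<= rec$fs`.
#' @return The resampled recording with its `fs` field updated.
#' @export
resample_recording <- function(rec, fs_target) {
  stopifnot(inherits(rec, "recording"))
  if (fs_target > rec$fs)
    stop("upsampling is not supported (fs_target ", fs_target,
         " > fs ", rec$fs, ")")
  if (fs_target == rec$fs) return(rec)
  # rational approximation of the rate ratio
  frac <- .rat(fs_target / rec$fs)
  n_out <- floor(ncol(rec$data) * fs_target / rec$fs)
  out <- t(apply(rec$data, 1, function(x)
    signal::resample(x, frac$p, frac$q)[seq_len(n_out)]))
  update_rec(rec, out, fs = fs_target)
}

# continued-fraction rational approximation p/q of a ratio in (0, 1]
.rat <- function(r, tol = 1e-9, max_q = 10000L) {
  q <- 1:max_q
  p <- round(r * q)
  ok <- which(p >= 1 & abs(p / q - r) < tol)
  if (!length(ok)) stop("cannot express resampling ratio ", r,
                        " as a small rational")
  list(p = p[ok[1]], q = q[ok[1]])
}

#' Epoch selection policy
#'
#' @param mode `"first"` (take the initial segment) or `"min_variance"`
#'   (scan 1-s steps and take the window minimising the mean across regions
#'   of per-region variance — an automated stand-in for manual selection of
#'   the most artefact-free segment).
#' @param duration Epoch length in seconds (convention: 60 for EEG, 70 for
#'   MEG).
#' @return An `epoch_policy` object for [select_epoch()].
#' @export
epoch_policy <- function(mode = c("first", "min_variance"), duration = 60) {
  mode <- match.arg(mode)
  if (duration <= 0) stop("epoch duration must be positive")
  structure(list(mode = mode, duration = duration), class = "epoch_policy")
}

#' Select a contiguous analysis epoch
#'
#' @param rec A [recording()].
#' @param policy An [epoch_policy()]; `policy$duration` must not exceed the
#'   recording length.
#' @return The recording restricted to the selected epoch.
#' @export
select_epoch <- function(rec, policy = epoch_policy()) {
  stopifnot(inherits(rec, "recording"), inherits(policy, "epoch_policy"))
  n_win <- round(policy$duration * rec$fs)
  n <- ncol(rec$data)
  if (n_win > n)
    stop("recording (", n / rec$fs, " s) shorter than requested epoch (",
         policy$duration, " s)")
  start <- if (policy$mode == "first" || n_win == n) 1L else {
    step <- round(rec$fs)                  # 1-second scan steps
    starts <- seq(1L, n - n_win + 1L, by = step)
    score <- vapply(starts, function(s) {
      seg <- rec$data[, s:(s + n_win - 1L), drop = FALSE]
      mean(apply(seg, 1, stats::var))
    }, numeric(1))
    starts[which.min(score)]               # which.min: earliest tie wins
  }
  update_rec(rec, rec$data[, start:(start + n_win - 1L), drop = FALSE])
}

#' Sign-flip averaging of source signals within regions
#'
#' Source orientations on opposite sulcal walls give within-region signals
#' of arbitrary polarity; naive averaging cancels them.  Each source is
#' multiplied by the sign of its correlation with the region's first
#' principal direction (zero correlation counts as +1), then sources are
#' averaged.  The result is finally flipped, if needed, so it correlates
#' non-negatively with the region's lowest-index unflipped source.
#'
#' @param sources Numeric matrix, source-signals x samples.
#' @param region_assignment Region id per source (any atomic vector).
#' @return Matrix region x samples, rows ordered by first appearance of each
#'   region id, row names set to the region ids.
#' @export
signflip_average <- function(sources, region_assignment) {
  sources <- as.matrix(sources)
  if (length(region_assignment) != nrow(sources))
    stop("region_assignment length must equal number of source rows")
  ids <- unique(region_assignment)
  out <- matrix(NA_real_, nrow = length(ids), ncol = ncol(sources),
                dimnames = list(as.character(ids), NULL))
  for (j in seq_along(ids)) {
    idx <- which(region_assignment == ids[j])
    if (!length(idx)) stop("empty region: ", ids[j])
    S <- sources[idx, , drop = FALSE]
    if (length(idx) == 1L) { out[j, ] <- S[1, ]; next }
    # first principal direction of the source covariance
    v1 <- eigen(stats::cov(t(S)), symmetric = TRUE)$vectors[, 1]
    pc <- drop(v1 %*% S)
    flips <- vapply(seq_len(nrow(S)), function(i) {
      r <- suppressWarnings(stats::cor(S[i, ], pc))
      if (is.na(r) || r == 0) 1 else sign(r)
    }, numeric(1))
    avg <- colMeans(S * flips)
    r0 <- suppressWarnings(stats::cor(avg, S[1, ]))
    if (!is.na(r0) && r0 < 0) avg <- -avg   # global sign convention
    out[j, ] <- avg
  }
  out
}
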