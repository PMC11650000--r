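#' Construct a region-level recording
#'
#' A `recording` holds one subject's region-of-interest time series: a
#' regions x samples matrix together with the sampling rate, region labels,
#' hemisphere membership and subject metadata.  This is the exchange unit of
#' the whole pipeline.
#'
#' @param data Numeric matrix, regions x samples, all values finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param region_labels Character vector, one label per row of `data`.
#' @param hemisphere Character vector ("left"/"right") per region.
#' @param subject_id Subject identifier string.
#' @param group One of `"control"`, `"left_TLE"`, `"right_TLE"`.
#' @param modality `"EEG"` or `"MEG"`.
#' @param provenance Optional named list of generation metadata (e.g. the
#'   drawn alpha peak frequency of a synthetic subject).
#' @return An object of class `recording`.
#' @seealso [simulate_subject()], [read_recording()]
#' @export
recording <- function(data, fs, region_labels, hemisphere,
                      subject_id = "s01", group = "control",
                      modality = "EEG", provenance = list()) {
  data <- as.matrix(data)
  if (!is.numeric(data) || !all(is.finite(data)))
    stop("recording data must be a finite numeric matrix")
  if (length(region_labels) != nrow(data))
    stop("region_labels length (", length(region_labels),
         ") != data row count (", nrow(data), ")")
  if (length(hemisphere) != nrow(data))
    stop("hemisphere length (", length(hemisphere),
         ") != data row count (", nrow(data), ")")
  if (!all(hemisphere %in% c("left", "right")))
    stop("hemisphere entries must be 'left' or 'right'")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar (Hz)")
  group <- match.arg(group, c("control", "left_TLE", "right_TLE"))
  modality <- match.arg(modality, c("EEG", "MEG"))
  rownames(data) <- region_labels
  structure(list(subject_id = as.character(subject_id), group = group,
                 modality = modality, fs = fs, data = data,
                 region_labels = as.character(region_labels),
                 hemisphere = as.character(hemisphere),
                 provenance = provenance),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s  group=%s  modality=%s\n",
              x$subject_id, x$group, x$modality))
  cat(sprintf("  %d regions x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (!is.null(x$provenance$alpha_peak_hz))
    cat(sprintf("  injected alpha peak: %.2f Hz\n",
                x$provenance$alpha_peak_hz))
  invisible(x)
}

# seizure-focus laterality for a recording: "left"/"right" or NA for controls
rec_laterality <- function(rec) {
  switch(rec$group, left_TLE = "left", right_TLE = "right", NA_character_)
}

rec_duration <- function(rec) ncol(rec$data) / rec$fs
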