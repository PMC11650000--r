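# shared fixture builders (all generated in code, no stored data)

# cohort spec at the study's Monte-Carlo conditions: default generative
# parameters, 20-s epochs
mc_spec <- function(seed, null = FALSE, ...) {
  cohort_spec(n_controls = 20, n_patients = 20, duration = 20,
              alpha_peak_mean_patient = if (null) 10.5 else 8,
              seed = seed, ...)
}

# construct a power_spectrum object directly from a power matrix, for
# arithmetic-level unit tests that do not need a real Welch estimate
toy_spectrum <- function(power, freqs, normalized = FALSE,
                         norm_band = NULL, subject_id = "toy",
                         group = "control", hemisphere = NULL) {
  power <- as.matrix(power)
  labels <- rownames(power)
  if (is.null(labels)) labels <- paste0("r", seq_len(nrow(power)))
  if (is.null(hemisphere))
    hemisphere <- rep(c("left", "right"), length.out = nrow(power))
  structure(list(freqs = freqs, power = power, fs = 2 * max(freqs),
                 df = diff(freqs[1:2]), normalized = normalized,
                 norm_band = norm_band, region_labels = labels,
                 hemisphere = hemisphere, subject_id = subject_id,
                 group = group, modality = "EEG",
                 laterality = switch(group, left_TLE = "left",
                                     right_TLE = "right", NA_character_)),
            class = "power_spectrum")
}

# build an alpha_ratio_table directly from a subject x region value matrix
toy_ratio_table <- function(values, groups,
                            hemisphere = rep(c("left", "right"),
                                             each = ncol(values) / 2),
                            laterality = NULL) {
  values <- as.matrix(values)
  if (is.null(laterality))
    laterality <- ifelse(groups == "left_TLE", "left",
                         ifelse(groups == "right_TLE", "right", NA))
  structure(list(
    values = values,
    subjects = data.frame(
      subject_id = sprintf("s%02d", seq_len(nrow(values))),
      group = groups, modality = "EEG", laterality = laterality,
      stringsAsFactors = FALSE),
    regions = data.frame(label = paste0("r", seq_len(ncol(values))),
                         hemisphere = hemisphere, stringsAsFactors = FALSE),
    floored = matrix(FALSE, nrow(values), ncol(values)),
    slow = slow_alpha_band(), fast = fast_alpha_band(),
    log_base = "natural"), class = "alpha_ratio_table")
}

# sinusoid recording helper
sine_recording <- function(freq, fs = 250, duration = 60, n_regions = 2,
                           amplitude = 1) {
  t <- (seq_len(round(duration * fs)) - 1) / fs
  x <- amplitude * sin(2 * pi * freq * t)
  recording(matrix(rep(x, each = n_regions), nrow = n_regions),
            fs = fs,
            region_labels = paste0("r", seq_len(n_regions)),
            hemisphere = rep(c("left", "right"),
                             length.out = n_regions))
}
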