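#' Write a recording as TSV plus JSON sidecar
#'
#' The tabular exchange format: a TSV whose first column is `time_s` and
#' remaining columns are one region each (header = region labels), plus a
#' JSON sidecar at `<path>.json` carrying fs, subject metadata and the
#' hemisphere map.  Text-based so fixtures stay diffable and
#' language-neutral.
#'
#' @param rec A [recording()].
#' @param path Output TSV path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  df <- data.frame((seq_len(ncol(rec$data)) - 1) / rec$fs,
                   t(rec$data), check.names = FALSE)
  names(df) <- c("time_s", rec$region_labels)
  utils::write.table(format(df, digits = 12, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(fs = rec$fs, subject_id = rec$subject_id, group = rec$group,
               modality = rec$modality,
               laterality = rec_laterality(rec),
               hemisphere = as.list(stats::setNames(rec$hemisphere,
                                                    rec$region_labels)),
               provenance = rec$provenance)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a recording from the tabular format
#'
#' @param path TSV path written by [write_recording()] (sidecar expected at
#'   `<path>.json`).
#' @param format `"tabular"`; `"edf"` is reserved for an optional European
#'   Data Format reader and errors when no EDF backend is installed.
#' @return A validated [recording()].
#' @export
read_recording <- function(path, format = c("tabular", "edf")) {
  format <- match.arg(format)
  if (format == "edf")
    stop("EDF input requires an optional EDF reader backend, which is not ",
         "installed; use the tabular format")
  if (!file.exists(path)) stop("recording file not found: ", path)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing JSON sidecar: expected ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  if (names(df)[1] != "time_s" && names(df)[1] != "sample")
    stop("malformed header in ", path,
         ": first column must be 'time_s' or 'sample', got '",
         names(df)[1], "'")
  if (!all(vapply(df, is.numeric, logical(1)))) {
    bad <- names(df)[!vapply(df, is.numeric, logical(1))]
    stop("non-numeric cells in column(s): ", paste(bad, collapse = ", "))
  }
  if (names(df)[1] == "time_s" && nrow(df) > 1) {
    fs_obs <- 1 / stats::median(diff(df$time_s))
    if (abs(fs_obs - meta$fs) / meta$fs > 0.001)
      stop("fs mismatch: sidecar says ", meta$fs, " Hz but sample spacing ",
           "implies ", signif(fs_obs, 6), " Hz")
  }
  labels <- names(df)[-1]
  hemi <- unlist(meta$hemisphere)[labels]
  if (any(is.na(hemi)))
    stop("sidecar hemisphere map is missing region(s): ",
         paste(labels[is.na(hemi)], collapse = ", "))
  recording(t(as.matrix(df[, -1, drop = FALSE])), fs = meta$fs,
            region_labels = labels, hemisphere = unname(hemi),
            subject_id = meta$subject_id, group = meta$group,
            modality = meta$modality,
            provenance = if (length(meta$provenance)) meta$provenance
                         else list())
}

#' Pipeline run configuration
#'
#' Collates every analysis parameter with modality-aware defaults: EEG runs
#' at 250 Hz with 60-s epochs, MEG at 600 Hz with 70-s epochs; both use a
#' 1-47.5 Hz bandpass and normalization band, 2-s/1-s Welch windows, and
#' the 6-9 / 10-11 Hz slow/fast alpha bands.
#'
#' @param modality `"EEG"` or `"MEG"`.
#' @param fs_target Analysis sampling rate (Hz).
#' @param bandpass Length-2 numeric, Hz.
#' @param epoch An [epoch_policy()].
#' @param welch_window_s,welch_overlap_s Welch parameters, seconds.
#' @param norm_band Normalization band, Hz.
#' @param slow,fast [band_definition()]s.
#' @param t_variant `"student"` or `"welch"`.
#' @param seed Integer seed used when the pipeline simulates its input.
#' @param output_dir Where [run_pipeline()] writes artifacts.
#' @return A validated `run_config` object.
#' @export
run_config <- function(modality = c("EEG", "MEG"),
                       fs_target = NULL, bandpass = c(1, 47.5),
                       epoch = NULL, welch_window_s = 2, welch_overlap_s = 1,
                       norm_band = c(1, 47.5),
                       slow = slow_alpha_band(), fast = fast_alpha_band(),
                       t_variant = "student", seed = 1L,
                       output_dir = tempfile("alphaslow_run_")) {
  modality <- match.arg(modality)
  if (is.null(fs_target)) fs_target <- if (modality == "EEG") 250 else 600
  if (is.null(epoch))
    epoch <- epoch_policy("first", if (modality == "EEG") 60 else 70)
  stopifnot(inherits(epoch, "epoch_policy"),
            inherits(slow, "band_definition"),
            inherits(fast, "band_definition"))
  if (!(bandpass[1] > 0 && bandpass[1] < bandpass[2] &&
        bandpass[2] < fs_target / 2))
    stop("invalid run_config field 'bandpass': need 0 < lo < hi < fs_target/2")
  if (!(welch_overlap_s >= 0 && welch_overlap_s < welch_window_s))
    stop("invalid run_config field 'welch': need 0 <= overlap < window")
  structure(list(modality = modality, fs_target = fs_target,
                 bandpass = bandpass, epoch = epoch,
                 welch_window_s = welch_window_s,
                 welch_overlap_s = welch_overlap_s,
                 norm_band = norm_band, slow = slow, fast = fast,
                 t_variant = t_variant, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

# serialize an alpha_ratio_table to long-form TSV
write_ratio_table <- function(table, path) {
  long <- expand.grid(region = table$regions$label,
                      subject = table$subjects$subject_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ord <- match(long$subject, table$subjects$subject_id)
  long <- data.frame(subject = long$subject,
                     group = table$subjects$group[ord],
                     laterality = table$subjects$laterality[ord],
                     region = long$region,
                     hemisphere = table$regions$hemisphere[
                       match(long$region, table$regions$label)],
                     log_ratio = as.vector(t(table$values))[
                       seq_len(nrow(long))])
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

write_stats_tsv <- function(results, path) {
  df <- do.call(rbind, lapply(results, function(r)
    data.frame(test_name = r$test_name, comparison = r$comparison,
               statistic = r$statistic,
               df = paste(signif(r$df, 8), collapse = "/"),
               p_raw = r$p_value, p_adjusted = r$p_adjusted,
               m = r$m_corrections, effect_size = r$effect_size,
               n = paste(r$n_per_group, collapse = "/"),
               degenerate = r$degenerate)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full alpha-slowing pipeline and write its artifacts
#'
#' End-to-end driver: obtain recordings (from a [cohort_spec()] by
#' simulation, or from a directory of tabular recordings), preprocess
#' (bandpass, resample, epoch), estimate relative spectra, build the alpha
#' ratio table, run the cohort statistics and the ROC biomarker evaluation,
#' and write TSV/JSON artifacts plus a manifest (config echo, seed, package
#' version, row counts, md5 checksums).  Identical config and seed give
#' identical artifacts.
#'
#' @param config A [run_config()].
#' @param input A [cohort_spec()] or a directory containing `*.tsv`
#'   recordings with sidecars.
#' @return An [alpha_slowing()] fit, invisibly, with
#'   `attr(, "output_dir")` and `attr(, "manifest")` set.
#' @export
run_pipeline <- function(config, input) {
  stopifnot(inherits(config, "run_config"))
  if (inherits(input, "cohort_spec")) {
    coh <- simulate_cohort(input)
    recs <- coh$recordings
    prov <- coh$provenance
  } else {
    files <- sort(list.files(input, pattern = "\\.tsv$", full.names = TRUE))
    if (!length(files))
      stop("no .tsv recordings found in input directory: ", input)
    recs <- lapply(files, read_recording)
    prov <- NULL
  }
  fit <- alpha_slowing(recs, config = config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  if (!is.null(prov))
    utils::write.table(prov, out("provenance.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  write_ratio_table(fit$ratio_table, out("alpha_ratio.tsv"))
  write_stats_tsv(c(fit$hemisphere_tests, fit$region_tests),
                  out("stats.tsv"))
  utils::write.table(
    data.frame(threshold = fit$biomarker$roc$thresholds,
               fpr = fit$biomarker$roc$fpr, tpr = fit$biomarker$roc$tpr),
    out("roc.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  for (g in names(fit$global_power))
    utils::write.table(fit$global_power[[g]],
                       out(sprintf("global_power_%s.tsv", g)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(auc = fit$biomarker$roc$auc,
         n_pos = fit$biomarker$roc$n_pos, n_neg = fit$biomarker$roc$n_neg,
         t_stat = fit$biomarker$t_test$statistic,
         p = fit$biomarker$t_test$p_value,
         group_means = as.list(fit$biomarker$group_means)),
    out("summary.json"), auto_unbox = TRUE, digits = NA)
  files_written <- sort(list.files(config$output_dir))
  manifest <- list(
    package_version = as.character(utils::packageVersion("alphaslow")),
    seed = config$seed,
    config = list(modality = config$modality, fs_target = config$fs_target,
                  bandpass = config$bandpass,
                  epoch = unclass(config$epoch),
                  welch = c(config$welch_window_s, config$welch_overlap_s),
                  norm_band = config$norm_band,
                  slow = c(config$slow$f_lo, config$slow$f_hi),
                  fast = c(config$fast$f_lo, config$fast$f_hi),
                  t_variant = config$t_variant),
    n_subjects = nrow(fit$ratio_table$values),
    n_regions = ncol(fit$ratio_table$values),
    checksums = as.list(tools::md5sum(
      file.path(config$output_dir, files_written))))
  names(manifest$checksums) <- files_written
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  attr(fit, "output_dir") <- config$output_dir
  attr(fit, "manifest") <- manifest
  invisible(fit)
}
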