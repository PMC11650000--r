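#' Slow/fast alpha power log ratio
#'
#' `log(slow / fast)` per region, natural log.  Positive values mean
#' relatively more slow alpha — i.e. alpha slowing, read as deviation from
#' health.  Powers are floored at `eps` before division so degenerate
#' zero-power inputs stay finite; floored entries are flagged in the
#' `"floored"` attribute.
#'
#' @param slow,fast Non-negative per-region power vectors of equal length.
#' @param eps Flooring constant (default 1e-12).
#' @return Numeric vector of log ratios with attribute `floored` (logical).
#' @export
alpha_log_ratio <- function(slow, fast, eps = 1e-12) {
  if (length(slow) != length(fast))
    stop("slow and fast power vectors must have equal length")
  if (any(slow < 0) || any(fast < 0))
    stop("band powers must be non-negative")
  floored <- slow < eps | fast < eps
  r <- log(pmax(slow, eps) / pmax(fast, eps))
  attr(r, "floored") <- floored
  r
}

#' Subject x region alpha power ratio table
#'
#' Computes the slow/fast alpha log ratio for every subject and region of a
#' cohort — the study's central derived dataset.
#'
#' @param spectra List of normalized `power_spectrum` objects (one per
#'   subject) sharing a frequency grid.
#' @param slow,fast [band_definition()]s (defaults 6-9 and 10-11 Hz).
#' @param eps Zero-power floor passed to [alpha_log_ratio()].
#' @return An `alpha_ratio_table`: list with `values` (subject x region
#'   matrix of natural-log ratios), `subjects` (data.frame: subject_id,
#'   group, modality, laterality), `regions` (data.frame: label,
#'   hemisphere), `floored` (logical matrix), and the band definitions.
#' @export
alpha_ratio_table <- function(spectra, slow = slow_alpha_band(),
                              fast = fast_alpha_band(), eps = 1e-12) {
  stopifnot(length(spectra) >= 1)
  labels <- spectra[[1]]$region_labels
  vals <- matrix(NA_real_, nrow = length(spectra), ncol = length(labels),
                 dimnames = list(vapply(spectra, `[[`, "", "subject_id"),
                                 labels))
  fl <- matrix(FALSE, nrow = nrow(vals), ncol = ncol(vals))
  for (i in seq_along(spectra)) {
    ps <- spectra[[i]]
    if (!identical(ps$region_labels, labels))
      stop("spectra have inconsistent region labels")
    r <- alpha_log_ratio(band_power(ps, slow), band_power(ps, fast), eps = eps)
    vals[i, ] <- r
    fl[i, ] <- attr(r, "floored")
  }
  structure(list(
    values = vals,
    subjects = data.frame(
      subject_id = vapply(spectra, `[[`, "", "subject_id"),
      group = vapply(spectra, `[[`, "", "group"),
      modality = vapply(spectra, `[[`, "", "modality"),
      laterality = vapply(spectra, function(s)
        if (is.null(s$laterality)) NA_character_ else s$laterality, ""),
      stringsAsFactors = FALSE),
    regions = data.frame(label = labels,
                         hemisphere = spectra[[1]]$hemisphere,
                         stringsAsFactors = FALSE),
    floored = fl, slow = slow, fast = fast, log_base = "natural"),
    class = "alpha_ratio_table")
}

#' @export
print.alpha_ratio_table <- function(x, ...) {
  cat(sprintf("<alpha_ratio_table> %d subjects x %d regions (%s over %s, natural log)\n",
              nrow(x$values), ncol(x$values), x$slow$name, x$fast$name))
  print(table(x$subjects$group))
  invisible(x)
}

#' Per-subject hemispheric mean log ratio
#'
#' Averages the log ratio over one hemisphere's regions per subject.
#' `"ipsilateral"`/`"contralateral"` resolve against each patient's
#' seizure-focus laterality and are undefined for controls.
#'
#' @param table An [alpha_ratio_table()].
#' @param side `"left"`, `"right"`, `"ipsilateral"` or `"contralateral"`.
#' @return Named per-subject numeric vector.
#' @export
hemisphere_mean <- function(table,
                            side = c("left", "right", "ipsilateral",
                                     "contralateral")) {
  stopifnot(inherits(table, "alpha_ratio_table"))
  side <- match.arg(side)
  hemi <- table$regions$hemisphere
  if (side %in% c("left", "right")) {
    resolved <- rep(side, nrow(table$values))
  } else {
    lat <- table$subjects$laterality
    bad <- which(is.na(lat))
    if (length(bad))
      stop("ipsilateral/contralateral undefined for subjects without ",
           "laterality (controls): ",
           paste(table$subjects$subject_id[bad], collapse = ", "))
    resolved <- if (side == "ipsilateral") lat
                else ifelse(lat == "left", "right", "left")
  }
  out <- vapply(seq_len(nrow(table$values)), function(i)
    mean(table$values[i, hemi == resolved[i]]), numeric(1))
  names(out) <- table$subjects$subject_id
  out
}

#' Per-subject global mean log ratio
#'
#' Unweighted mean over all regions — the subject-level biomarker score.
#'
#' @param table An [alpha_ratio_table()].
#' @return Named per-subject numeric vector.
#' @export
global_mean_ratio <- function(table) {
  stopifnot(inherits(table, "alpha_ratio_table"))
  if (any(!is.finite(table$values)))
    stop("ratio table contains non-finite values")
  out <- rowMeans(table$values)
  names(out) <- table$subjects$subject_id
  out
}

#' Band-edge sensitivity sweep
#'
#' Recomputes the cohort separation for every (slow, fast) band pair of a
#' grid: per pair, the alpha ratio table is rebuilt, subjects' global mean
#' ratios formed, and the patient-vs-control unpaired t statistic computed
#' (positive t = patients have more slow alpha).  Overlapping pairs are
#' computed but flagged with a warning in the output.
#'
#' @param spectra List of normalized `power_spectrum` objects with group
#'   metadata (at least 2 controls and 2 patients).
#' @param slow_grid,fast_grid Lists of [band_definition()]s.
#' @param variant t-test variant, `"student"` or `"welch"`.
#' @return data.frame: slow_lo, slow_hi, fast_lo, fast_hi, t_stat, p,
#'   overlap (logical).
#' @export
band_sensitivity <- function(spectra, slow_grid, fast_grid,
                             variant = "student") {
  grid <- expand.grid(si = seq_along(slow_grid), fi = seq_along(fast_grid))
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(k) {
    sb <- slow_grid[[grid$si[k]]]; fb <- fast_grid[[grid$fi[k]]]
    overlap <- sb$f_hi >= fb$f_lo && fb$f_hi >= sb$f_lo
    if (overlap)
      warning("slow band ", sb$f_lo, "-", sb$f_hi, " overlaps fast band ",
              fb$f_lo, "-", fb$f_hi, " Hz", call. = FALSE)
    tab <- alpha_ratio_table(spectra, slow = sb, fast = fb)
    gm <- global_mean_ratio(tab)
    is_pat <- tab$subjects$group != "control"
    tt <- unpaired_t(gm[is_pat], gm[!is_pat], variant = variant)
    data.frame(slow_lo = sb$f_lo, slow_hi = sb$f_hi,
               fast_lo = fb$f_lo, fast_hi = fb$f_hi,
               t_stat = tt$statistic, p = tt$p_value, overlap = overlap)
  }))
  out
}
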