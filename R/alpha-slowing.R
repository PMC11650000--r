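#' Fit the alpha-slowing analysis to a cohort of recordings
#'
#' The package's central entry point.  Takes a cohort of region-level
#' recordings (or a [cohort_spec()], which is simulated first), runs the
#' conditioning and spectral stages, and returns one object holding the
#' study's derived quantities:
#'
#' 1. preprocess — zero-phase 1-47.5 Hz bandpass, downsampling to the
#'    modality's analysis rate, epoch selection;
#' 2. spectral — Welch relative power (2-s windows, 1-s overlap,
#'    sum-to-one over the normalization band);
#' 3. alpha ratio — per-region log(slow/fast) alpha power;
#' 4. statistics — hemisphere-level unpaired and region-paired t-tests
#'    with Bonferroni correction, plus normality checks of the
#'    subject-level means;
#' 5. biomarker — ROC of the per-subject global mean ratio.
#'
#' @param x List of [recording()]s or a [cohort_spec()].
#' @param config A [run_config()]; its modality defaults are taken from the
#'   first recording when not supplied.
#' @param ... Unused.
#' @return An object of class `alpha_slowing` with components
#'   `ratio_table`, `spectra`, `global_power` (per group),
#'   `hemisphere_tests`, `region_tests`, `normality`, `biomarker`,
#'   `config`.
#' @examples
#' \donttest{
#' spec <- cohort_spec(n_controls = 4, n_patients = 4, duration = 12)
#' fit <- alpha_slowing(spec)
#' summary(fit)
#' }
#' @export
alpha_slowing <- function(x, config = NULL, ...) {
  if (inherits(x, "cohort_spec")) x <- simulate_cohort(x)$recordings
  stopifnot(is.list(x), length(x) >= 1,
            all(vapply(x, inherits, logical(1), "recording")))
  if (is.null(config))
    config <- run_config(modality = x[[1]]$modality, seed = 1L)
  spectra <- lapply(x, function(rec) {
    rec <- bandpass_filter(rec, config$bandpass[1], config$bandpass[2])
    if (rec$fs > config$fs_target)
      rec <- resample_recording(rec, config$fs_target)
    if (rec_duration(rec) > config$epoch$duration + 1e-9)
      rec <- select_epoch(rec, config$epoch)
    relative_power(welch_psd(rec, config$welch_window_s,
                             config$welch_overlap_s),
                   norm_band = config$norm_band)
  })
  tab <- alpha_ratio_table(spectra, slow = config$slow, fast = config$fast)
  grp <- tab$subjects$group
  gp <- list()
  if (any(grp == "control"))
    gp$control <- global_band_power(spectra[grp == "control"])
  if (any(grp != "control"))
    gp$patient <- global_band_power(spectra[grp != "control"])
  has_both <- sum(grp == "control") >= 2 && sum(grp != "control") >= 2
  hem <- reg <- NULL
  norm <- biom <- NULL
  if (has_both) {
    hem <- cohort_comparison(tab, "hemisphere", variant = config$t_variant)
    reg <- cohort_comparison(tab, "region")
    biom <- evaluate_biomarker(tab, variant = config$t_variant)
    gm <- global_mean_ratio(tab)
    norm <- list()
    for (g in c("control", "patient")) {
      v <- if (g == "control") gm[grp == "control"] else gm[grp != "control"]
      if (length(v) >= 8) {
        norm[[paste0(g, "_anderson_darling")]] <-
          normality_test(v, "anderson_darling")
        norm[[paste0(g, "_lilliefors")]] <-
          normality_test(v, "lilliefors", n_mc = 2000L,
                         mc_seed = config$seed)
      }
    }
  }
  structure(list(ratio_table = tab, spectra = spectra, global_power = gp,
                 hemisphere_tests = hem, region_tests = reg,
                 normality = norm, biomarker = biom, config = config),
            class = "alpha_slowing")
}

#' @export
print.alpha_slowing <- function(x, ...) {
  tb <- table(x$ratio_table$subjects$group)
  cat(sprintf("<alpha_slowing> %d subjects (%s), %d regions, %s\n",
              nrow(x$ratio_table$values),
              paste(names(tb), tb, sep = "=", collapse = ", "),
              ncol(x$ratio_table$values), x$config$modality))
  if (!is.null(x$biomarker)) print(x$biomarker)
  invisible(x)
}

#' @describeIn alpha_slowing Group-level summary: hemispheric and global
#'   mean log ratios, test battery, normality checks and AUC.
#' @param object,... An `alpha_slowing` fit.
#' @export
summary.alpha_slowing <- function(object, ...) {
  x <- object
  out <- list(coef = coef(x),
              hemisphere_tests = x$hemisphere_tests,
              region_tests = x$region_tests,
              normality = x$normality,
              auc = if (!is.null(x$biomarker)) x$biomarker$roc$auc else NA)
  class(out) <- "summary.alpha_slowing"
  out
}

#' @export
print.summary.alpha_slowing <- function(x, ...) {
  cat("Alpha slowing analysis summary\n")
  cat("Global mean log ratio (slow/fast alpha):\n")
  print(round(x$coef, 4))
  if (!is.null(x$hemisphere_tests)) {
    cat("\nSubject-level hemisphere comparisons (Bonferroni m = 2):\n")
    for (tt in x$hemisphere_tests) print(tt)
    cat("\nRegion-paired comparisons:\n")
    for (tt in x$region_tests) print(tt)
  }
  if (!is.null(x$normality) && length(x$normality)) {
    cat("\nNormality of subject-level means:\n")
    for (nm in names(x$normality))
      cat(sprintf("  %s: statistic %.4f, p = %.3g\n", nm,
                  x$normality[[nm]]$statistic, x$normality[[nm]]$p_value))
  }
  if (!is.na(x$auc)) cat(sprintf("\nBiomarker AUC: %.4f\n", x$auc))
  invisible(x)
}

#' @describeIn alpha_slowing Named coefficients: per-group mean of the
#'   subject-level global mean log ratio and their difference.
#' @export
coef.alpha_slowing <- function(object, ...) {
  gm <- global_mean_ratio(object$ratio_table)
  is_pat <- object$ratio_table$subjects$group != "control"
  c(control_mean = mean(gm[!is_pat]),
    patient_mean = if (any(is_pat)) mean(gm[is_pat]) else NA_real_,
    difference = if (any(is_pat)) mean(gm[is_pat]) - mean(gm[!is_pat])
                 else NA_real_)
}

#' @describeIn alpha_slowing Two-panel base-graphics display: group global
#'   band power curves with 95% CI, and the biomarker ROC curve.
#' @export
plot.alpha_slowing <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, if (is.null(x$biomarker)) 1 else 2))
  on.exit(graphics::par(op))
  gp <- x$global_power
  ylim <- range(unlist(lapply(gp, function(g) c(g$ci_lo, g$ci_hi))))
  cols <- c(control = "steelblue", patient = "firebrick")
  first <- TRUE
  for (g in names(gp)) {
    if (first) {
      graphics::plot(gp[[g]]$freq, gp[[g]]$mean, type = "l", col = cols[g],
                     ylim = ylim, xlab = "Frequency (Hz)",
                     ylab = "Relative power",
                     main = "Global band power (mean, 95% CI)")
      first <- FALSE
    } else graphics::lines(gp[[g]]$freq, gp[[g]]$mean, col = cols[g])
    graphics::polygon(c(gp[[g]]$freq, rev(gp[[g]]$freq)),
                      c(gp[[g]]$ci_lo, rev(gp[[g]]$ci_hi)),
                      col = grDevices::adjustcolor(cols[g], alpha.f = 0.2),
                      border = NA)
  }
  graphics::legend("topright", legend = names(gp), col = cols[names(gp)],
                   lty = 1, bty = "n")
  if (!is.null(x$biomarker)) plot(x$biomarker$roc)
  invisible(x)
}
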