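new_test_result <- function(test_name, statistic, df, p_value,
                            effect_size = NA_real_, n = integer(0),
                            correction = "none", m_corrections = NA_integer_,
                            p_adjusted = NA_real_, degenerate = FALSE,
                            comparison = NA_character_) {
  structure(list(test_name = test_name, comparison = comparison,
                 statistic = statistic, df = df, p_value = p_value,
                 effect_size = effect_size, n_per_group = n,
                 correction = correction, m_corrections = m_corrections,
                 p_adjusted = p_adjusted, degenerate = degenerate),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s%s\n", x$test_name,
              if (!is.na(x$comparison)) paste0(" [", x$comparison, "]") else ""))
  cat(sprintf("  statistic = %.4g, df = %s, p = %.4g%s\n", x$statistic,
              paste(signif(x$df, 6), collapse = "/"), x$p_value,
              if (!is.na(x$p_adjusted))
                sprintf(" (adjusted %.4g, %s m=%d)", x$p_adjusted,
                        x$correction, x$m_corrections) else ""))
  if (!is.na(x$effect_size))
    cat(sprintf("  Cohen's d = %.3f, n = %s\n", x$effect_size,
                paste(x$n_per_group, collapse = "/")))
  if (x$degenerate) cat("  WARNING: degenerate (zero-variance) case\n")
  invisible(x)
}

#' Unpaired two-sample t-test
#'
#' Two-sided t-test between independent samples.  Sign convention:
#' positive statistic when `mean(a) > mean(b)`.  Cohen's d with pooled SD
#' is always reported.  Zero pooled variance with unequal means returns the
#' boundary p = 0 with a degenerate flag instead of raising, so cohort
#' sweeps never abort.
#'
#' @param a,b Numeric vectors, each of length >= 2, finite.
#' @param variant `"student"` (equal-variance, default) or `"welch"`.
#' @return A `test_result`.
#' @export
unpaired_t <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs n >= 2")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("inputs must be finite")
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  d <- if (sp2 > 0) (mean(a) - mean(b)) / sqrt(sp2) else NA_real_
  name <- sprintf("unpaired t (%s)", variant)
  # same near-constancy criterion as stats::t.test, returned as a flagged
  # boundary case instead of an error so cohort sweeps never abort
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  if (se <= 10 * .Machine$double.eps * max(abs(mean(a)), abs(mean(b)))) {
    if (abs(mean(a) - mean(b)) <= se)
      return(new_test_result(name, 0, na + nb - 2, 1, effect_size = 0,
                             n = c(na, nb), degenerate = TRUE))
    return(new_test_result(name, sign(mean(a) - mean(b)) * Inf,
                           na + nb - 2, 0, n = c(na, nb), degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = (variant == "student"))
  new_test_result(name, unname(tt$statistic), unname(tt$parameter),
                  tt$p.value, effect_size = d, n = c(na, nb))
}

#' Paired t-test
#'
#' Two-sided t-test on position-paired differences (df = n - 1); in the
#' region-wise use the pairing unit is the region (34 per hemisphere) and
#' each entry is a cohort's per-region mean log ratio.  Zero-variance
#' differences return boundary p-values (1 if the mean difference is also
#' zero, else 0) with a degenerate flag.
#'
#' @param x,y Paired numeric vectors of equal length >= 2.
#' @return A `test_result`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  if (length(x) < 2) stop("need n >= 2 pairs")
  d <- x - y
  n <- length(d)
  m <- mean(d); s <- stats::sd(d)
  dz <- m / s
  if (s == 0 || s / sqrt(n) <= 10 * .Machine$double.eps * abs(m)) {
    if (m == 0)
      return(new_test_result("paired t", 0, n - 1, 1, effect_size = 0,
                             n = n, degenerate = TRUE))
    return(new_test_result("paired t", sign(m) * Inf, n - 1, 0,
                           n = n, degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  new_test_result("paired t", unname(tt$statistic), unname(tt$parameter),
                  tt$p.value, effect_size = dz, n = n)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction (df = 1) — the convention that reproduces
#' standard demographic sex-ratio comparisons.
#'
#' @param tab 2x2 matrix of non-negative integer counts, all margins > 0.
#' @return A `test_result` (no effect size).
#' @export
chi_square_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("a 2x2 count table is required")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("all table margins must be positive")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  new_test_result("chi-square (2x2, uncorrected)", unname(ct$statistic),
                  unname(ct$parameter), ct$p.value,
                  n = as.integer(colSums(tab)))
}

#' Bonferroni correction
#'
#' `p_adj = min(1, m * p)`, order-preserving; `m` may exceed the number of
#' p-values supplied (partial family).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param m Family size, `>= length(p)` (default `length(p)`).
#' @return Adjusted p-values, capped at 1.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (m < length(p)) stop("family size m (", m,
                          ") smaller than number of tests (", length(p), ")")
  pmin(1, m * p)
}

# Lilliefors statistic: max KS distance between the ECDF and the normal
# CDF with estimated mean/SD
lilliefors_stat <- function(x) {
  n <- length(x)
  z <- stats::pnorm(sort(x), mean(x), stats::sd(x))
  i <- seq_len(n)
  max(pmax(i / n - z, z - (i - 1) / n))
}

#' Normality tests (Anderson-Darling, Lilliefors)
#'
#' Anderson-Darling uses the small-sample-adjusted approximation with
#' estimated mean and SD (via `nortest::ad.test`).  Lilliefors computes
#' the composite-null Kolmogorov-Smirnov statistic and a seeded
#' Monte-Carlo p-value: `n_mc` standard-normal samples of the same size,
#' p = (1 + #{D* >= D}) / (n_mc + 1).
#'
#' @param x Numeric sample, n >= 8.
#' @param test `"anderson_darling"` or `"lilliefors"`.
#' @param n_mc Monte-Carlo replicates for the Lilliefors null (default
#'   10000).
#' @param mc_seed Seed for the Monte-Carlo null stream.
#' @return A `test_result`.
#' @export
normality_test <- function(x, test = c("anderson_darling", "lilliefors"),
                           n_mc = 10000L, mc_seed = 1L) {
  test <- match.arg(test)
  if (length(x) < 8) stop("normality tests require n >= 8")
  if (test == "anderson_darling") {
    at <- nortest::ad.test(x)
    return(new_test_result("Anderson-Darling normality",
                           unname(at$statistic), NA_real_, at$p.value,
                           n = length(x)))
  }
  D <- lilliefors_stat(x)
  n <- length(x)
  null_D <- with_rng(mc_seed, {
    sims <- matrix(stats::rnorm(n * n_mc), nrow = n)
    apply(sims, 2, lilliefors_stat)
  })
  p <- (1 + sum(null_D >= D)) / (n_mc + 1)
  new_test_result("Lilliefors normality (Monte-Carlo)", D, NA_real_, p,
                  n = n)
}

#' Cohort comparison battery
#'
#' Dispatches the study's group comparisons on an [alpha_ratio_table()]:
#'
#' * `level = "hemisphere"` — per hemisphere, an unpaired t-test between
#'   control and patient subjects' hemispheric mean log ratios (Bonferroni
#'   family m = 2; sign convention patients minus controls).
#' * `level = "region"` — per hemisphere, one paired t-test across that
#'   hemisphere's regions, pairing the control cohort's per-region mean
#'   with the patient cohort's per-region mean (df = regions - 1).
#'
#' In both cases Bonferroni uses m = the number of comparisons in the
#' family actually run (2 hemispheres); m is recorded in every result.
#'
#' @param table An [alpha_ratio_table()].
#' @param level `"hemisphere"` (subject-level, default) or `"region"`
#'   (region-paired).
#' @param patient_groups Which groups form the patient cohort.
#' @param variant Unpaired t-test variant.
#' @return List of `test_result`s with adjusted p-values and the family
#'   size recorded.
#' @export
cohort_comparison <- function(table, level = c("hemisphere", "region"),
                              patient_groups = c("left_TLE", "right_TLE"),
                              variant = "student") {
  stopifnot(inherits(table, "alpha_ratio_table"))
  level <- match.arg(level)
  grp <- table$subjects$group
  is_pat <- grp %in% patient_groups
  is_con <- grp == "control"
  if (!any(is_pat) || !any(is_con))
    stop("both a control and a patient cohort are required")
  hemis <- c("left", "right")
  if (level == "hemisphere") {
    res <- lapply(hemis, function(h) {
      hm <- hemisphere_mean(table, h)
      tt <- unpaired_t(hm[is_pat], hm[is_con], variant = variant)
      tt$comparison <- sprintf("patients vs controls, %s hemisphere (subject-level)", h)
      tt
    })
  } else {
    res <- lapply(hemis, function(h) {
      idx <- table$regions$hemisphere == h
      con_mean <- colMeans(table$values[is_con, idx, drop = FALSE])
      pat_mean <- colMeans(table$values[is_pat, idx, drop = FALSE])
      tt <- paired_t(con_mean, pat_mean)
      tt$comparison <- sprintf("controls vs patients, %s hemisphere (%d region pairs)",
                               h, sum(idx))
      tt
    })
  }
  m <- length(res)
  padj <- bonferroni(vapply(res, `[[`, numeric(1), "p_value"), m = m)
  for (i in seq_along(res)) {
    res[[i]]$correction <- "bonferroni"
    res[[i]]$m_corrections <- m
    res[[i]]$p_adjusted <- padj[i]
  }
  res
}
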