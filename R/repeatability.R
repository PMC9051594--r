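# Test-retest repeatability statistics: within-subject coefficient of
# variation (wCV), repeatability coefficient (RC = 1.96 * sqrt(2) * wCV),
# bootstrap confidence intervals, Bland-Altman agreement, intraclass
# correlation, Pearson correlation, and the RC-vs-SUVmax stratification.

#' Paired test-retest samples
#'
#' Builds the long-format table of paired measurements consumed by the
#' repeatability estimators: one row per subject (or lesion) and metric,
#' with the value from each of the two scans. Reader-swap designs are
#' expressed purely through `reader_tag` (e.g. `"R1,R2"` for scan 1 read by
#' reader 1 against scan 2 read by reader 2); no special code path exists.
#'
#' @param subject_id Vector of subject (or lesion) identifiers.
#' @param a,b Non-negative measurements from scan A and scan B.
#' @param metric_name,reader_tag Metadata columns (recycled).
#' @return Data frame with columns `subject_id`, `a`, `b`, `metric_name`,
#'   `reader_tag`.
#' @export
paired_samples <- function(subject_id, a, b, metric_name = "value",
                           reader_tag = NA_character_) {
  if (length(a) != length(b) || length(a) != length(subject_id))
    stop("subject_id, a and b must have equal length")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("paired values must be finite")
  if (any(a < 0) || any(b < 0))
    stop("paired values must be non-negative")
  data.frame(subject_id = subject_id, a = as.numeric(a), b = as.numeric(b),
             metric_name = metric_name, reader_tag = reader_tag)
}

# per-pair squared relative difference terms; both-zero pairs per policy
.wcv_terms <- function(pairs, zero_policy = c("exclude_both_zero", "error")) {
  zero_policy <- match.arg(zero_policy)
  a <- pairs$a; b <- pairs$b
  zero <- (a + b) == 0
  if (any(zero) && zero_policy == "error")
    stop(sprintf("%d pair(s) with a = b = 0; wCV term undefined", sum(zero)))
  a <- a[!zero]; b <- b[!zero]
  if (!length(a))
    stop("no usable pairs: all pairs are zero on both scans")
  list(terms = (a - b)^2 / (2 * ((a + b) / 2)^2), n_excluded = sum(zero))
}

#' Within-subject coefficient of variation
#'
#' The relative test-retest variability pooled over subjects:
#' `wCV = sqrt( mean_i [ (a_i - b_i)^2 / (2 * ((a_i + b_i)/2)^2) ] )`.
#' Subjects measured zero on both scans (no detectable disease on either
#' visit) contribute an undefined 0/0 term and are excluded by default, with
#' their count available from [repeatability()]. A single-sided zero
#' (`a = 0, b > 0`) is a finite term (value 2) and is retained.
#'
#' @param pairs A [paired_samples()] data frame (columns `a`, `b`).
#' @param zero_policy `"exclude_both_zero"` (default) or `"error"`.
#' @return wCV as a fraction (multiply by 100 for percent).
#' @export
wcv <- function(pairs, zero_policy = c("exclude_both_zero", "error")) {
  t <- .wcv_terms(pairs, zero_policy)
  sqrt(mean(t$terms))
}

#' Repeatability coefficient
#'
#' `RC = 1.96 * sqrt(2) * wCV`: the smallest relative change between two
#' scans that exceeds measurement variability with 95% probability.
#'
#' @param wcv_value wCV as a non-negative fraction.
#' @return RC as a fraction.
#' @export
rc <- function(wcv_value) {
  if (any(wcv_value < 0, na.rm = TRUE)) stop("wCV must be non-negative")
  1.96 * sqrt(2) * wcv_value
}

#' Bootstrap percentile confidence interval for wCV or RC
#'
#' Resamples subjects (rows of `pairs`, after the zero-pair policy) with
#' replacement and returns the percentile interval of the statistic over
#' `n_boot` replicates. Deterministic under `seed` and bit-reproducible.
#'
#' @param pairs A [paired_samples()] data frame.
#' @param statistic `"wcv"` or `"rc"`.
#' @param n_boot Number of replicates (default 1000).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @param zero_policy See [wcv()].
#' @return Numeric length-2 `(low, high)`.
#' @export
bootstrap_ci <- function(pairs, statistic = c("wcv", "rc"), n_boot = 1000L,
                         seed = 1L, level = 0.95,
                         zero_policy = c("exclude_both_zero", "error")) {
  statistic <- match.arg(statistic)
  t <- .wcv_terms(pairs, zero_policy)$terms
  n <- length(t)
  if (n < 2L) stop("at least 2 usable pairs are required for a bootstrap CI")
  est <- .with_seed(seed, {
    idx <- sample.int(n, n * n_boot, replace = TRUE)
    sqrt(rowMeans(matrix(t[idx], nrow = n_boot)))
  })
  if (statistic == "rc") est <- rc(est)
  alpha <- (1 - level) / 2
  stats::quantile(est, c(alpha, 1 - alpha), names = FALSE, type = 7)
}

#' Full repeatability estimate for one metric
#'
#' Point estimates and bootstrap CIs for wCV and RC in one call.
#'
#' @inheritParams bootstrap_ci
#' @return List of class `repeatability_estimate`: `wcv`, `rc`, `wcv_ci_low`,
#'   `wcv_ci_high`, `rc_ci_low`, `rc_ci_high`, `n_subjects`,
#'   `n_excluded_zero_pairs`, `n_boot`, `seed`.
#' @export
repeatability <- function(pairs, n_boot = 1000L, seed = 1L, level = 0.95,
                          zero_policy = c("exclude_both_zero", "error")) {
  t <- .wcv_terms(pairs, zero_policy)
  w <- sqrt(mean(t$terms))
  ci <- if (length(t$terms) >= 2L)
    bootstrap_ci(pairs, "wcv", n_boot, seed, level, zero_policy)
  else c(NA_real_, NA_real_)
  structure(list(wcv = w, rc = rc(w),
                 wcv_ci_low = ci[1], wcv_ci_high = ci[2],
                 rc_ci_low = rc(max(ci[1], 0)), rc_ci_high = rc(max(ci[2], 0)),
                 n_subjects = length(t$terms),
                 n_excluded_zero_pairs = t$n_excluded,
                 n_boot = n_boot, seed = seed, level = level),
            class = "repeatability_estimate")
}

#' @export
print.repeatability_estimate <- function(x, ...) {
  cat(sprintf("wCV %.1f%% | RC %.1f%% (%.0f%% CI %.1f-%.1f%%) | n = %d (%d zero pair(s) excluded)\n",
              100 * x$wcv, 100 * x$rc, 100 * x$level,
              100 * x$rc_ci_low, 100 * x$rc_ci_high,
              x$n_subjects, x$n_excluded_zero_pairs))
  invisible(x)
}

#' Bland-Altman agreement
#'
#' Absolute (not percent) differences between scans: `d = b - a` by default
#' (scan 2 minus scan 1), bias = mean difference, 95% limits of agreement
#' `bias +/- 1.96 * sd(d)`, and a normal-approximation CI for the bias
#' (`bias +/- 1.96 * sd(d) / sqrt(n)`).
#'
#' @param pairs A [paired_samples()] data frame (>= 2 rows).
#' @param sign `"b_minus_a"` (default) or `"a_minus_b"`.
#' @return List of class `bland_altman_result`: `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `bias_ci_low`, `bias_ci_high`, `n`, `sign`.
#' @export
bland_altman <- function(pairs, sign = c("b_minus_a", "a_minus_b")) {
  sign <- match.arg(sign)
  if (nrow(pairs) < 2L) stop("at least 2 pairs are required")
  d <- if (sign == "b_minus_a") pairs$b - pairs$a else pairs$a - pairs$b
  bias <- mean(d)
  s <- stats::sd(d)
  n <- length(d)
  structure(list(bias = bias, sd_diff = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 bias_ci_low = bias - 1.96 * s / sqrt(n),
                 bias_ci_high = bias + 1.96 * s / sqrt(n),
                 n = n, sign = sign),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("Bland-Altman (%s): bias %.3f (95%% CI %.3f to %.3f), LoA %.3f to %.3f, n = %d\n",
              x$sign, x$bias, x$bias_ci_low, x$bias_ci_high,
              x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Intraclass correlation coefficient
#'
#' Single-measure two-way ICC from the two-way ANOVA mean squares of a
#' subjects-by-raters table. The default variant is absolute agreement
#' (ICC(A,1)); `"consistency"` gives ICC(C,1), which ignores a constant
#' rater offset. Because the variant matters (a constant offset gives
#' consistency 1 but agreement < 1), the variant is always carried in the
#' result. The F test of the subject effect (`MSR/MSE`) provides the
#' p-value.
#'
#' @param ratings Numeric matrix or data frame, subjects in rows, raters
#'   (scans or readers) in columns; >= 2 subjects and >= 2 columns.
#' @param variant `"agreement"` (default) or `"consistency"`.
#' @return List of class `icc_result`: `value`, `variant`, `n_subjects`,
#'   `n_raters`, `f`, `p`.
#' @export
icc <- function(ratings, variant = c("agreement", "consistency")) {
  variant <- match.arg(variant)
  M <- as.matrix(ratings)
  storage.mode(M) <- "double"
  n <- nrow(M); k <- ncol(M)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 raters")
  if (any(!is.finite(M))) stop("ratings must be finite")
  rowm <- rowMeans(M); colm <- colMeans(M); g <- mean(M)
  MSR <- k * sum((rowm - g)^2) / (n - 1)
  MSC <- n * sum((colm - g)^2) / (k - 1)
  MSE <- sum((M - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + g)^2) /
    ((n - 1) * (k - 1))
  if (MSR <= .Machine$double.eps * max(1, g^2))
    stop("zero between-subject variance; ICC undefined")
  val <- if (variant == "agreement") {
    (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  } else {
    (MSR - MSE) / (MSR + (k - 1) * MSE)
  }
  f <- if (MSE > 0) MSR / MSE else Inf
  p <- if (is.finite(f)) stats::pf(f, n - 1, (n - 1) * (k - 1), lower.tail = FALSE) else 0
  lab <- if (variant == "agreement")
    "two-way, absolute agreement, single measure (ICC(A,1))"
  else "two-way, consistency, single measure (ICC(C,1))"
  structure(list(value = val, variant = lab, n_subjects = n, n_raters = k,
                 f = f, p = p),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC %.4f [%s], n = %d x %d, p = %.3g\n",
              x$value, x$variant, x$n_subjects, x$n_raters, x$p))
  invisible(x)
}

#' Pearson correlation and R-squared
#'
#' Pearson correlation with the two-sided t-transform p-value, optionally on
#' a log10-log10 scale (non-positive entries are dropped before taking logs,
#' e.g. zero-burden patients in a tumor-volume-vs-PSA correlation).
#'
#' @param x,y Numeric vectors.
#' @param log_log Apply log10 to both after dropping non-positive pairs.
#' @return List: `r`, `r2`, `p`, `n`, `log_log`.
#' @export
correlation_r2 <- function(x, y, log_log = FALSE) {
  ok <- is.finite(x) & is.finite(y)
  if (log_log) ok <- ok & x > 0 & y > 0
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("at least 3 usable pairs are required")
  if (log_log) { x <- log10(x); y <- log10(y) }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
       p = ct$p.value, n = length(x), log_log = log_log)
}

#' RC as a function of the lesion SUVmax stratum
#'
#' Exploratory profile of repeatability against lesion avidity: for each
#' threshold in `start, start + step, ...`, lesions are stratified by their
#' SUVmax (mean of the two scans' SUVmax) and wCV/RC computed within the
#' stratum. `mode = "below"` keeps lesions with SUVmax below the threshold
#' (thresholding in as published), `mode = "above"` keeps lesions at or
#' above it (discarding low-avidity lesions); both interpretations are
#' offered because low-SUVmax lesions are the ones expected to repeat worst.
#' Strata with fewer than `min_n` usable lesions are flagged `low_n`.
#'
#' @param pairs A [paired_samples()] data frame of per-lesion values.
#' @param suv_max Numeric vector, one SUVmax per row of `pairs` (a matrix or
#'   data frame with the per-scan SUVmax in two columns is averaged).
#' @param start First threshold (default 1).
#' @param step Threshold increment (default 5).
#' @param mode `"below"` or `"above"`.
#' @param min_n Minimum stratum size before flagging (default 3).
#' @param zero_policy See [wcv()].
#' @return Data frame: `threshold`, `n`, `wcv`, `rc`, `low_n`.
#' @export
rc_suvmax_profile <- function(pairs, suv_max, start = 1, step = 5,
                              mode = c("below", "above"), min_n = 3L,
                              zero_policy = c("exclude_both_zero", "error")) {
  mode <- match.arg(mode)
  if (nrow(pairs) == 0L) stop("empty input")
  if (is.matrix(suv_max) || is.data.frame(suv_max))
    suv_max <- rowMeans(as.matrix(suv_max))
  if (length(suv_max) != nrow(pairs))
    stop("suv_max must align with pairs")
  thresholds <- seq(start, max(suv_max) + step, by = step)
  rows <- lapply(thresholds, function(th) {
    keep <- if (mode == "below") suv_max < th else suv_max >= th
    sub <- pairs[keep, , drop = FALSE]
    w <- tryCatch(wcv(sub, zero_policy), error = function(e) NA_real_)
    nn <- if (nrow(sub)) length(.wcv_terms0(sub)) else 0L
    data.frame(threshold = th, n = nn, wcv = w,
               rc = if (is.na(w)) NA_real_ else rc(w),
               low_n = nn < min_n)
  })
  do.call(rbind, rows)
}

.wcv_terms0 <- function(pairs) {
  keep <- (pairs$a + pairs$b) > 0
  which(keep)
}
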