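#' Build a 2x2 confusion table
#'
#' Cross-tabulates predicted against truth labels keyed by an identifier
#' (sample, or sample x gene). Both inputs must cover exactly the same keys.
#'
#' @param predicted,truth Data frames with a key column (`key`, or the
#'   column named by `key_col`) and a logical `positive` column.
#' @param key_col Name of the key column (default `"key"`).
#' @return A list of class `confusion_table` with counts `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
#' @examples
#' pred <- tibble::tibble(key = letters[1:4], positive = c(TRUE, TRUE, FALSE, FALSE))
#' truth <- tibble::tibble(key = letters[1:4], positive = c(TRUE, FALSE, FALSE, TRUE))
#' confusion_counts(pred, truth)
confusion_counts <- function(predicted, truth, key_col = "key") {
  p <- as_tibble(predicted)
  t <- as_tibble(truth)
  for (df in list(p, t)) {
    if (!all(c(key_col, "positive") %in% names(df))) {
      abort(sprintf("inputs need columns '%s' and 'positive'", key_col))
    }
  }
  pk <- p[[key_col]]
  tk <- t[[key_col]]
  if (anyDuplicated(pk) || anyDuplicated(tk)) {
    abort("duplicate keys in predicted or truth")
  }
  off <- c(setdiff(pk, tk), setdiff(tk, pk))
  if (length(off) > 0) {
    abort(sprintf("key mismatch between predicted and truth: %s",
                  paste(off, collapse = ", ")))
  }
  t <- t[match(pk, tk), ]
  confusion_table(
    tp = sum(p$positive & t$positive),
    fp = sum(p$positive & !t$positive),
    tn = sum(!p$positive & !t$positive),
    fn = sum(!p$positive & t$positive)
  )
}

#' Construct a confusion table from counts
#'
#' @param tp,fp,tn,fn Nonnegative counts.
#' @return A list of class `confusion_table`.
#' @export
confusion_table <- function(tp = 0, fp = 0, tn = 0, fn = 0) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) abort("confusion counts must be nonnegative")
  structure(as.list(counts), class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("<confusion_table> TP %s  FP %s  TN %s  FN %s\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' @export
tidy.confusion_table <- function(x, ...) {
  tibble(tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn)
}

#' @export
glance.confusion_table <- function(x, ...) {
  tibble(
    sensitivity = if (x$tp + x$fn > 0) sensitivity(x) else NA_real_,
    specificity = if (x$tn + x$fp > 0) specificity(x) else NA_real_,
    n = x$tp + x$fp + x$tn + x$fn
  )
}

#' Analytical sensitivity
#'
#' `100 * TP / (TP + FN)`, the true-positive rate as a percentage.
#'
#' @param t A `confusion_table`.
#' @return Percentage in `[0, 100]` at full precision (see
#'   [printed_percent()] for display formatting).
#' @export
#' @examples
#' sensitivity(confusion_table(tp = 252, fn = 2))
sensitivity <- function(t) {
  stopifnot(inherits(t, "confusion_table"))
  if (t$tp + t$fn == 0) abort("sensitivity undefined: TP + FN = 0")
  100 * t$tp / (t$tp + t$fn)
}

#' Analytical specificity
#'
#' `100 * TN / (TN + FP)`, the true-negative rate as a percentage.
#' Validation of targeted panels often uses a base-pair denominator
#' (interrogated bases x samples); see [bp_denominator()].
#'
#' @param t A `confusion_table`.
#' @return Percentage in `[0, 100]` at full precision.
#' @export
specificity <- function(t) {
  stopifnot(inherits(t, "confusion_table"))
  if (t$tn + t$fp == 0) abort("specificity undefined: TN + FP = 0")
  100 * t$tn / (t$tn + t$fp)
}

#' Discordance rate
#'
#' @param n_discordant,n_total Counts; `n_total` must be positive.
#' @return Percentage `100 * n_discordant / n_total`.
#' @export
#' @examples
#' discordance_rate(3, 104)
discordance_rate <- function(n_discordant, n_total) {
  if (n_total <= 0) abort("`n_total` must be positive")
  100 * n_discordant / n_total
}

#' Base-pair specificity denominator
#'
#' Interrogated-region size times number of samples: the true-negative
#' denominator used to express variant-calling specificity over a panel
#' footprint.
#'
#' @param region_bp Interrogated bases per sample.
#' @param n_samples Number of samples.
#' @return `region_bp * n_samples`.
#' @export
#' @examples
#' bp_denominator(477945, 58)
bp_denominator <- function(region_bp, n_samples) {
  region_bp * n_samples
}

#' Binomial confidence interval for a proportion
#'
#' Two-sided interval for `successes / n`, as percentages. Clopper-Pearson
#' (exact beta-quantile) is the default; Wilson score is available.
#'
#' @param successes,n Counts with `0 <= successes <= n`, `n > 0`.
#' @param level Confidence level (default 0.95).
#' @param method `"clopper_pearson"` (default) or `"wilson"`.
#' @return Tibble with `estimate`, `conf_low`, `conf_high` (percent).
#' @export
#' @examples
#' proportion_ci(252, 254)
proportion_ci <- function(successes, n, level = 0.95,
                          method = c("clopper_pearson", "wilson")) {
  method <- match.arg(method)
  if (n <= 0) abort("`n` must be positive")
  if (successes < 0 || successes > n) abort("`successes` must lie in [0, n]")
  alpha <- 1 - level
  p <- successes / n
  if (method == "clopper_pearson") {
    lo <- if (successes == 0) 0 else qbeta(alpha / 2, successes, n - successes + 1)
    hi <- if (successes == n) 1 else qbeta(1 - alpha / 2, successes + 1, n - successes)
  } else {
    z <- qnorm(1 - alpha / 2)
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    lo <- max(0, centre - half)
    hi <- min(1, centre + half)
  }
  tibble(estimate = 100 * p, conf_low = 100 * lo, conf_high = 100 * hi)
}

#' Format a percentage the way a validation report prints it
#'
#' Clinical validation reports are not uniform in how they round: some cells
#' are rounded half-up, others truncated toward zero (e.g. a specificity of
#' 99.999996% printed as 99.99%, not 100.00%). `printed_percent` applies a
#' stated convention so reproduced tables match their source digit for
#' digit.
#'
#' @param x Percentage at full precision.
#' @param digits Printed decimal places.
#' @param rounding `"round"` (half-up) or `"floor"` (truncate toward zero).
#' @return Numeric value at the printed precision.
#' @export
#' @examples
#' printed_percent(99.999996, 2, "floor")
#' printed_percent(123 / 124 * 100, 1, "round")
printed_percent <- function(x, digits = 2, rounding = c("round", "floor")) {
  rounding <- match.arg(rounding)
  scale <- 10^digits
  if (rounding == "floor") {
    floor(x * scale) / scale
  } else {
    floor(x * scale + 0.5) / scale
  }
}

#' The assay validation confusion counts
#'
#' Confusion counts of the four validation datasets (somatic and germline
#' SNV/indel detection, MSI, LOH) as printed in the assay's validation
#' summary, with the display convention (decimal places and rounding
#' direction) each printed figure used. These counts are inputs to the
#' concordance arithmetic, not outputs of this package.
#'
#' @return Tibble with columns `metric`, `kind` (sensitivity/specificity),
#'   `a` (TP or TN), `b` (FN or FP), `digits`, `rounding`.
#' @export
validation_counts <- function() {
  readr::read_tsv(system.file("extdata", "validation_counts.tsv",
                              package = "lynchmmr"),
                  show_col_types = FALSE)
}

#' Reproduce the assay validation metric table
#'
#' Recomputes every printed validation percentage from its confusion counts
#' via [sensitivity()] / [specificity()], together with the value at the
#' printed precision and a Clopper-Pearson 95% interval (reported for
#' reference only; the source intervals were derived with an unstated
#' method and are not reproduced).
#'
#' @return Tibble with `metric`, `value` (full precision), `printed`
#'   (display precision), `conf_low`, `conf_high`.
#' @export
#' @examples
#' validation_metrics()
validation_metrics <- function() {
  vc <- validation_counts()
  purrr::pmap_dfr(vc, function(metric, kind, a, b, digits, rounding) {
    ct <- if (kind == "sensitivity") {
      confusion_table(tp = a, fn = b)
    } else {
      confusion_table(tn = a, fp = b)
    }
    value <- if (kind == "sensitivity") sensitivity(ct) else specificity(ct)
    ci <- proportion_ci(a, a + b)
    tibble(metric = metric, kind = kind,
           value = value,
           printed = printed_percent(value, digits, rounding),
           conf_low = ci$conf_low, conf_high = ci$conf_high)
  })
}
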