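#' Test one microsatellite marker for instability
#'
#' Compares tumor and normal read-length histograms at one homopolymer
#' marker with a Pearson chi-square homogeneity test. Length categories are
#' built from the pooled histograms with a 0.5 pseudocount; categories with
#' pooled counts below 5 are merged into their nearest neighbor so the
#' chi-square approximation holds at panel depths. A marker is *covered*
#' when both histograms reach `min_reads` spanning reads, and *unstable*
#' (expanded) when it is covered and the test rejects at `alpha`.
#'
#' @param tumor_hist,normal_hist Named numeric vectors: read counts keyed by
#'   supported tract length (nt), e.g. `c("20" = 180, "19" = 20)`.
#' @param min_reads Minimum spanning reads per histogram (default 20).
#' @param alpha Per-site significance level (default 0.05). No per-site
#'   multiple-testing correction is applied; aggregation happens at the
#'   panel level through the 20% unstable-fraction rule.
#' @param marker_id Optional marker label carried into the result.
#' @return One-row tibble: `marker_id`, `covered`, `unstable`, `p_value`,
#'   `tumor_reads`, `normal_reads`.
#' @export
#' @examples
#' norm <- c("20" = 200)
#' tum <- c("20" = 100, "17" = 100)
#' site_instability_test(tum, norm)
site_instability_test <- function(tumor_hist, normal_hist, min_reads = 20,
                                  alpha = 0.05, marker_id = NA_character_) {
  clean <- function(h) {
    h <- h[h > 0]
    if (length(h) == 0) return(h)
    lens <- as.integer(names(h))
    if (anyNA(lens) || any(lens <= 0)) {
      abort("histograms must be keyed by positive tract lengths")
    }
    h
  }
  tumor_hist <- clean(tumor_hist)
  normal_hist <- clean(normal_hist)
  t_total <- sum(tumor_hist)
  n_total <- sum(normal_hist)
  covered <- t_total >= min_reads && n_total >= min_reads
  if (!covered) {
    return(tibble(marker_id = marker_id, covered = FALSE, unstable = FALSE,
                  p_value = NA_real_, tumor_reads = t_total,
                  normal_reads = n_total))
  }

  lens <- sort(unique(c(as.integer(names(tumor_hist)),
                        as.integer(names(normal_hist)))))
  t_cnt <- setNames(rep(0, length(lens)), lens)
  n_cnt <- t_cnt
  t_cnt[names(tumor_hist)] <- tumor_hist
  n_cnt[names(normal_hist)] <- normal_hist

  # merge sparse pooled categories into the nearest neighbor (left fold)
  pooled <- t_cnt + n_cnt
  while (length(pooled) > 1 && any(pooled < 5)) {
    i <- which(pooled < 5)[1]
    j <- if (i == 1) 2 else i - 1
    t_cnt[j] <- t_cnt[j] + t_cnt[i]
    n_cnt[j] <- n_cnt[j] + n_cnt[i]
    pooled[j] <- pooled[j] + pooled[i]
    t_cnt <- t_cnt[-i]; n_cnt <- n_cnt[-i]; pooled <- pooled[-i]
  }

  if (length(pooled) < 2) {
    p <- 1
  } else {
    m <- rbind(tumor = t_cnt + 0.5, normal = n_cnt + 0.5)
    p <- suppressWarnings(chisq.test(m, correct = FALSE)$p.value)
    if (is.na(p)) p <- 1
  }
  tibble(marker_id = marker_id, covered = TRUE, unstable = p < alpha,
         p_value = p, tumor_reads = t_total, normal_reads = n_total)
}

#' Test every marker of a sample for instability
#'
#' Tidy wrapper over [site_instability_test()]: takes a long histogram table
#' and returns one row per marker.
#'
#' @param hist_df Data frame with columns `marker_id`, `origin`
#'   (`"tumor"`/`"normal"`), `length`, `read_count`.
#' @param min_reads,alpha See [site_instability_test()].
#' @return Tibble of per-marker results.
#' @export
msi_test_sites <- function(hist_df, min_reads = 20, alpha = 0.05) {
  hist_df <- as_tibble(hist_df)
  needed <- c("marker_id", "origin", "length", "read_count")
  miss <- setdiff(needed, names(hist_df))
  if (length(miss) > 0) {
    abort(sprintf("`hist_df` is missing column(s): %s", paste(miss, collapse = ", ")))
  }
  hist_df |>
    group_by(.data$marker_id) |>
    dplyr::group_modify(function(d, key) {
      to_hist <- function(o) {
        dd <- d[d$origin == o, ]
        setNames(dd$read_count, dd$length)
      }
      site_instability_test(to_hist("tumor"), to_hist("normal"),
                            min_reads = min_reads, alpha = alpha) |>
        select(-"marker_id")
    }) |>
    ungroup()
}

#' Classify panel MSI status
#'
#' The sample *Fails* when fewer than `min_covered_sites` markers have
#' coverage; otherwise it is *High* when the unstable fraction of covered
#' markers is at least `high_fraction` (inclusive), else *Stable*.
#'
#' @param sites Tibble of per-marker results ([msi_test_sites()]).
#' @param crit An [msi_criteria()].
#' @return A list of class `msi_panel_result`: `n_covered`, `n_unstable`,
#'   `unstable_fraction`, `status`.
#' @export
#' @examples
#' sites <- tibble::tibble(covered = rep(TRUE, 40),
#'                         unstable = rep(c(TRUE, FALSE), c(8, 32)))
#' classify_msi_panel(sites)
classify_msi_panel <- function(sites, crit = msi_criteria()) {
  sites <- as_tibble(sites)
  n_covered <- sum(sites$covered)
  n_unstable <- sum(sites$unstable & sites$covered)
  frac <- if (n_covered > 0) n_unstable / n_covered else NA_real_
  status <- if (n_covered < crit$min_covered_sites) {
    "Failed"
  } else if (frac >= crit$high_fraction) {
    "High"
  } else {
    "Stable"
  }
  structure(list(n_covered = n_covered, n_unstable = n_unstable,
                 unstable_fraction = frac, status = status),
            class = "msi_panel_result")
}

#' @export
print.msi_panel_result <- function(x, ...) {
  cat(sprintf("<msi_panel_result> %s (%d/%d covered markers unstable%s)\n",
              x$status, x$n_unstable, x$n_covered,
              if (is.na(x$unstable_fraction)) ""
              else sprintf(" = %.1f%%", 100 * x$unstable_fraction)))
  invisible(x)
}

#' @export
glance.msi_panel_result <- function(x, ...) {
  tibble(status = x$status, n_covered = x$n_covered,
         n_unstable = x$n_unstable, unstable_fraction = x$unstable_fraction)
}

#' Bethesda five-marker classification
#'
#' The Promega mononucleotide panel rule: MSI-High with two or more
#' unstable markers, MSI-Low with exactly one, MSS with none.
#'
#' @param marker_calls Logical vector of length 5 (unstable flags for
#'   NR-21, BAT-26, BAT-25, NR-24, MONO-27), optionally named.
#' @return `"MSI-H"`, `"MSI-L"` or `"MSS"`.
#' @export
#' @examples
#' classify_promega(c(TRUE, TRUE, FALSE, FALSE, FALSE))
classify_promega <- function(marker_calls) {
  if (length(marker_calls) != 5 || !is.logical(marker_calls) ||
      anyNA(marker_calls)) {
    abort("`marker_calls` must be 5 non-missing logical marker flags")
  }
  n <- sum(marker_calls)
  if (n >= 2) "MSI-H" else if (n == 1) "MSI-L" else "MSS"
}
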