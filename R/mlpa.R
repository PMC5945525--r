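#' Normalize MS-MLPA probe signals to per-island methylation ratios
#'
#' Each probe's raw ratio is digested / undigested signal. Ratios are
#' normalized by the mean raw ratio of the reference probes (probes without
#' an HhaI site, whose signal should survive digestion unchanged), then
#' averaged per CpG island. Because HhaI cannot cut methylated DNA, the
#' normalized ratio approximates the methylated fraction at the island: 0
#' for fully unmethylated (fully digested), 1 for fully methylated.
#'
#' @param signals Data frame with columns `probe_id`, `island_id` (one of
#'   the promoter islands, or `"reference"`), `digested`, `undigested`.
#' @return Named numeric vector of island ratios.
#' @export
#' @examples
#' sig <- tibble::tibble(
#'   probe_id = c("r1", "r2", "p1", "p2"),
#'   island_id = c("reference", "reference", "island_1", "island_2"),
#'   digested = c(1000, 980, 400, 20), undigested = c(1000, 1020, 1000, 1000))
#' normalize_probe_ratios(sig)
normalize_probe_ratios <- function(signals) {
  s <- as_tibble(signals)
  needed <- c("probe_id", "island_id", "digested", "undigested")
  miss <- setdiff(needed, names(s))
  if (length(miss) > 0) {
    abort(sprintf("`signals` is missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (any(s$digested < 0) || any(s$undigested < 0)) {
    abort("signal intensities must be nonnegative")
  }
  dropped <- s$undigested == 0
  if (any(dropped)) {
    warn(sprintf("dropping probe(s) with zero undigested signal: %s",
                 paste(s$probe_id[dropped], collapse = ", ")))
    s <- s[!dropped, ]
  }
  refs <- filter(s, .data$island_id == "reference")
  if (nrow(refs) == 0) abort("no reference probes present")
  s <- mutate(s, raw_ratio = .data$digested / .data$undigested)
  ref_mean <- mean(s$raw_ratio[s$island_id == "reference"])
  if (ref_mean <= 0) abort("reference probes have zero mean ratio")
  islands <- s |>
    filter(.data$island_id != "reference") |>
    group_by(.data$island_id) |>
    summarise(ratio = mean(.data$raw_ratio) / ref_mean, .groups = "drop")
  setNames(islands$ratio, islands$island_id)
}

#' Call MLH1 promoter methylation from island ratios
#'
#' Methylated when any single island reaches the single-island threshold
#' (0.30) or at least two islands reach the multi-island threshold (0.15).
#'
#' @param island_ratios Named numeric vector from
#'   [normalize_probe_ratios()].
#' @param th An [mlpa_thresholds()].
#' @return A list of class `methylation_result`: `island_ratios`,
#'   `methylated`, `rule_fired` (`single_island`, `multi_island` or
#'   `none`).
#' @export
#' @examples
#' call_mlh1_methylation(c(i1 = 0.35, i2 = 0.02, i3 = 0.02, i4 = 0.02, i5 = 0.02))
call_mlh1_methylation <- function(island_ratios, th = mlpa_thresholds()) {
  if (length(island_ratios) == 0) abort("no island ratios supplied")
  if (any(island_ratios < 0)) abort("island ratios must be nonnegative")
  single <- any(island_ratios >= th$single_island_min)
  multi <- sum(island_ratios >= th$multi_island_min) >= 2
  rule <- if (single) "single_island" else if (multi) "multi_island" else "none"
  structure(list(island_ratios = island_ratios,
                 methylated = single || multi,
                 rule_fired = rule),
            class = "methylation_result")
}

#' @export
print.methylation_result <- function(x, ...) {
  cat(sprintf("<methylation_result> %s (rule: %s)\n",
              if (x$methylated) "methylated" else "unmethylated", x$rule_fired))
  print(round(x$island_ratios, 3))
  invisible(x)
}

#' @export
tidy.methylation_result <- function(x, ...) {
  tibble(island_id = names(x$island_ratios),
         ratio = unname(x$island_ratios))
}

#' @export
glance.methylation_result <- function(x, ...) {
  tibble(methylated = x$methylated, rule_fired = x$rule_fired,
         max_ratio = max(x$island_ratios))
}
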