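#' Select informative SNPs for allelic-imbalance analysis
#'
#' An informative SNP is germline-heterozygous (normal B-allele frequency
#' inside the het window) and adequately covered in both samples. Adds
#' `normal_baf`, `tumor_baf` and the mirrored deviation
#' `|tumor_baf - 0.5|`.
#'
#' @param sites Data frame of paired counts (`tumor_ref`, `tumor_alt`,
#'   `normal_ref`, `normal_alt`, plus any identifier columns).
#' @param p A [loh_params()].
#' @return Tibble of retained SNPs (possibly empty).
#' @export
select_informative_snps <- function(sites, p = loh_params()) {
  sites <- as_tibble(sites)
  sites |>
    mutate(tumor_depth = .data$tumor_ref + .data$tumor_alt,
           normal_depth = .data$normal_ref + .data$normal_alt,
           normal_baf = vaf_of(.data$normal_alt, .data$normal_ref),
           tumor_baf = vaf_of(.data$tumor_alt, .data$tumor_ref)) |>
    filter(.data$tumor_depth >= p$min_site_depth,
           .data$normal_depth >= p$min_site_depth,
           .data$normal_baf >= p$het_baf_low,
           .data$normal_baf <= p$het_baf_high) |>
    mutate(mirrored_dev = abs(.data$tumor_baf - 0.5))
}

# one-sided exact binomial p for |k - n/2| at p = 0.5 (mirrored statistic)
mirrored_binom_p <- function(alt, depth) {
  k <- pmax(alt, depth - alt)
  pbinom(k - 1, depth, 0.5, lower.tail = FALSE)
}

#' Call loss of heterozygosity for one gene
#'
#' A gene is in LOH when (i) at least `min_informative_snps` informative
#' SNPs are available, (ii) the median mirrored BAF deviation reaches the
#' imbalance threshold, and (iii) an aggregate allelic-imbalance test
#' rejects at `alpha`. The aggregate test combines per-SNP exact binomial
#' tests of the mirrored tumor counts against 0.5 by Stouffer's method.
#' Under copy-neutral LOH the estimated affected cell fraction is twice the
#' median deviation (clipped to `[0, 1]`); for deletion LOH the same
#' deviation arises at lower affected fraction, so the estimate is a lower
#' bound.
#'
#' @param snps Tibble from [select_informative_snps()].
#' @param p A [loh_params()].
#' @param gene Optional gene label; `PMS2` results carry a pseudogene
#'   caution in `warning`.
#' @return One-row tibble: `gene`, `n_informative`, `imbalance_stat`,
#'   `p_value`, `loh`, `est_affected_fraction`, `reason`, `warning`.
#' @export
call_gene_loh <- function(snps, p = loh_params(), gene = NA_character_) {
  snps <- as_tibble(snps)
  n <- nrow(snps)
  warn_txt <- if (identical(gene, "PMS2")) {
    "PMS2 allelic imbalance may be confounded by pseudogene reads"
  } else {
    NA_character_
  }
  if (n < p$min_informative_snps) {
    return(tibble(gene = gene, n_informative = n,
                  imbalance_stat = NA_real_, p_value = NA_real_,
                  loh = FALSE, est_affected_fraction = NA_real_,
                  reason = "insufficient_snps", warning = warn_txt))
  }
  stat <- median(snps$mirrored_dev)
  pvals <- pmin(pmax(mirrored_binom_p(snps$tumor_alt,
                                      snps$tumor_alt + snps$tumor_ref),
                     1e-300), 1 - 1e-15)
  z <- sum(qnorm(pvals, lower.tail = FALSE)) / sqrt(n)
  p_comb <- pnorm(z, lower.tail = FALSE)
  loh <- stat >= p$imbalance_threshold && p_comb < p$alpha
  tibble(gene = gene, n_informative = n,
         imbalance_stat = stat, p_value = p_comb, loh = loh,
         est_affected_fraction = min(1, max(0, 2 * stat)),
         reason = if (loh) "allelic_imbalance" else "no_imbalance",
         warning = warn_txt)
}

#' Call LOH across the Lynch genes of one case
#'
#' Groups a paired-count table by gene (assigning genes from the panel when
#' absent), restricts to the five Lynch genes, and applies
#' [select_informative_snps()] + [call_gene_loh()] per gene.
#'
#' @param sites Paired-count data frame with or without a `gene` column.
#' @param panel A [load_panel()] result, used when `gene` is missing.
#' @param p A [loh_params()].
#' @return Tibble with one row per Lynch gene present in `sites`.
#' @export
call_loh_by_gene <- function(sites, panel = NULL, p = loh_params()) {
  sites <- as_tibble(sites)
  if (!"gene" %in% names(sites)) {
    if (is.null(panel)) abort("`sites` has no `gene` column and no panel was given")
    sites <- assign_genes(sites, panel)
  }
  sites <- filter(sites, .data$gene %in% lynch_genes())
  purrr::map_dfr(sort(unique(sites$gene)), function(g) {
    snps <- select_informative_snps(filter(sites, .data$gene == g), p)
    call_gene_loh(snps, p, gene = g)
  })
}

#' Coarse gene-level copy-number estimate from depth ratios
#'
#' Normalizes per-interval mean depths by each sample's panel-wide median,
#' takes the per-gene median tumor/normal ratio, and reports
#' `round(2 * ratio)` as the copy-number estimate. The estimate is not
#' purity-adjusted: at 50% purity a true 4-copy gene has expected
#' normalized ratio (0.5 x 4 + 0.5 x 2) / 2 = 1.5 and rounds to 3.
#'
#' @param depth_profile Data frame with one row per panel interval:
#'   `gene`, `tumor_depth`, `normal_depth` (mean depths).
#' @return Tibble: `gene`, `depth_ratio`, `cn_estimate`.
#' @export
estimate_gene_copy_number <- function(depth_profile) {
  d <- as_tibble(depth_profile)
  needed <- c("gene", "tumor_depth", "normal_depth")
  miss <- setdiff(needed, names(d))
  if (length(miss) > 0) {
    abort(sprintf("`depth_profile` is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  skipped <- d$normal_depth <= 0
  if (any(skipped)) {
    warn(sprintf("skipping %d interval(s) with zero normal depth", sum(skipped)))
    d <- d[!skipped, ]
  }
  if (nrow(d) == 0) abort("no usable intervals: all normal depths are zero")
  t_med <- median(d$tumor_depth)
  n_med <- median(d$normal_depth)
  if (t_med <= 0 || n_med <= 0) abort("panel-wide median depth is zero")
  d |>
    mutate(ratio = (.data$tumor_depth / t_med) / (.data$normal_depth / n_med)) |>
    group_by(.data$gene) |>
    summarise(depth_ratio = median(.data$ratio), .groups = "drop") |>
    mutate(cn_estimate = round(2 * .data$depth_ratio))
}
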