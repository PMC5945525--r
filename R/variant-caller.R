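#' Normalize a variant to its minimal left-aligned representation
#'
#' Trims shared trailing bases, then shared leading bases (keeping at least
#' one base on each allele and shifting `pos` right for each leading base
#' removed), so equivalent indel spellings deduplicate deterministically.
#'
#' @param pos 1-based position.
#' @param ref,alt Allele strings.
#' @return List with `pos`, `ref`, `alt`.
#' @export
#' @examples
#' normalize_variant(100, "CAG", "CG")
normalize_variant <- function(pos, ref, alt) {
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]
    a <- a[-1]
    pos <- pos + 1
  }
  list(pos = pos, ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

vaf_of <- function(alt, ref) {
  depth <- alt + ref
  ifelse(depth > 0, alt / depth, NA_real_)
}

#' Call one paired tumor/normal site
#'
#' Applies the somatic/germline threshold cascade to a single observation.
#' A site below the caller floor (tumor VAF < 1% or coverage below 6x
#' tumor / 4x normal) yields no call. Otherwise the origin is `germline`
#' when the normal VAF reaches the het-ratio floor (10%), `somatic` when
#' the normal VAF is below the contamination ceiling (2%), and `ambiguous`
#' in between. Somatic candidates below the reporting VAF additionally face
#' a one-sided Fisher exact test of tumor against normal counts as a guard
#' against noise at the detection limit. Report-level shortfalls (tumor
#' < 100x, normal < 10x, VAF < 5%) set flags instead of dropping the call.
#'
#' @param obs One observation: list or one-row data frame with `chrom`,
#'   `pos`, `ref`, `alt`, `tumor_ref`, `tumor_alt`, `normal_ref`,
#'   `normal_alt` and optionally `q_score`, `gene`.
#' @param th A [lynch_thresholds()].
#' @return A one-row tibble (the call) or `NULL` when no call is made.
#' @export
#' @examples
#' obs <- list(chrom = "sim1", pos = 1000, ref = "A", alt = "T",
#'             tumor_ref = 354, tumor_alt = 20, normal_ref = 200,
#'             normal_alt = 0, q_score = 60)
#' call_site(obs, lynch_thresholds())
call_site <- function(obs, th = lynch_thresholds()) {
  counts <- c(obs$tumor_ref, obs$tumor_alt, obs$normal_ref, obs$normal_alt)
  if (any(is.na(counts)) || any(counts < 0)) {
    abort(sprintf("negative or missing read counts at %s:%s", obs$chrom, obs$pos))
  }
  t_depth <- obs$tumor_ref + obs$tumor_alt
  n_depth <- obs$normal_ref + obs$normal_alt
  if (t_depth == 0) return(NULL)
  t_vaf <- obs$tumor_alt / t_depth
  n_vaf <- if (n_depth > 0) obs$normal_alt / n_depth else 0

  if (t_vaf < th$caller_min_vaf) return(NULL)
  if (t_depth < th$caller_min_tumor_cov || n_depth < th$caller_min_normal_cov) {
    return(NULL)
  }

  flags <- character(0)
  if (t_depth < th$report_min_tumor_cov) flags <- c(flags, "low_tumor_coverage")
  if (n_depth < th$report_min_normal_cov) flags <- c(flags, "low_normal_coverage")
  if (t_vaf < th$report_min_vaf) flags <- c(flags, "below_reporting_vaf")

  somatic_p <- NA_real_
  if (n_vaf >= th$germline_min_het_ratio) {
    origin <- "germline"
  } else if (n_vaf < th$somatic_max_normal_vaf) {
    origin <- "somatic"
    if (t_vaf < th$report_min_vaf) {
      somatic_p <- fisher.test(
        matrix(c(obs$tumor_alt, obs$tumor_ref, obs$normal_alt, obs$normal_ref),
               nrow = 2),
        alternative = "greater")$p.value
      if (somatic_p > th$somatic_fisher_alpha) {
        origin <- "ambiguous"
        flags <- c(flags, "ambiguous_origin")
      }
    }
  } else {
    origin <- "ambiguous"
    flags <- c(flags, "ambiguous_origin")
  }

  is_reportable <- length(flags) == 0 && origin != "ambiguous"
  tibble(
    chrom = as.character(obs$chrom), pos = as.integer(obs$pos),
    ref = as.character(obs$ref), alt = as.character(obs$alt),
    gene = if (is.null(obs$gene)) NA_character_ else as.character(obs$gene),
    origin = origin,
    tumor_vaf = t_vaf, normal_vaf = n_vaf,
    tumor_depth = as.integer(t_depth), normal_depth = as.integer(n_depth),
    q_score = if (is.null(obs$q_score)) NA_real_ else as.numeric(obs$q_score),
    somatic_p = somatic_p,
    flags = paste(flags, collapse = ";"),
    reportable = is_reportable
  )
}

#' Call somatic and germline variants on paired counts
#'
#' Per-site application of [call_site()] over a table of paired tumor/normal
#' allele counts, in deterministic (chrom, pos, alt) order. Every emitted
#' call has exactly one origin (`somatic`, `germline` or `ambiguous`);
#' reportable calls carry no flags.
#'
#' @param sites Data frame of observations; see [call_site()] for columns.
#' @param th A [lynch_thresholds()].
#' @param panel Optional [load_panel()] result used to fill the `gene`
#'   column by position.
#' @return Tibble of calls (possibly zero rows) with class
#'   `lynch_variant_calls`.
#' @export
call_paired_variants <- function(sites, th = lynch_thresholds(), panel = NULL) {
  sites <- as_tibble(sites)
  needed <- c("chrom", "pos", "ref", "alt",
              "tumor_ref", "tumor_alt", "normal_ref", "normal_alt")
  miss <- setdiff(needed, names(sites))
  if (length(miss) > 0) {
    abort(sprintf("`sites` is missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (nrow(sites) > 0) {
    key <- paste(sites$chrom, sites$pos, sites$alt)
    if (anyDuplicated(key)) {
      abort(sprintf("duplicate site(s): %s",
                    paste(unique(key[duplicated(key)]), collapse = ", ")))
    }
  }
  if (!is.null(panel)) sites <- assign_genes(sites, panel)
  sites <- arrange(sites, .data$chrom, .data$pos, .data$alt)
  calls <- purrr::map_dfr(seq_len(nrow(sites)),
                          function(i) call_site(as.list(sites[i, ]), th) %||% tibble())
  if (nrow(calls) == 0) {
    calls <- call_site(list(chrom = "x", pos = 1L, ref = "A", alt = "T",
                            tumor_ref = 100L, tumor_alt = 100L,
                            normal_ref = 50L, normal_alt = 50L), th)[0, ]
  }
  class(calls) <- c("lynch_variant_calls", class(calls))
  calls
}

#' Filter germline calls for reporting
#'
#' Retains germline calls with Phred quality >= 30, normal coverage >= 10x
#' and het ratio (normal VAF) >= 10%.
#'
#' @param calls Tibble of calls from [call_paired_variants()].
#' @param th A [lynch_thresholds()].
#' @return Filtered tibble of germline calls.
#' @export
filter_germline_variants <- function(calls, th = lynch_thresholds()) {
  calls |>
    filter(.data$origin == "germline",
           !is.na(.data$q_score), .data$q_score >= th$germline_min_q,
           .data$normal_depth >= th$germline_min_cov,
           .data$normal_vaf >= th$germline_min_het_ratio)
}

#' Per-sample QC coverage metrics
#'
#' Computes the fraction of targeted bases at or above each coverage tier
#' (10x through 1000x), the mean target coverage, and the number of
#' "noloco" regions -- maximal runs of consecutive bases below the 20x
#' germline floor. A sample fails QC with more than 10 nolocos.
#'
#' @param depths Integer vector: one read depth per targeted base.
#' @param th A [lynch_thresholds()].
#' @return A list of class `qc_report` (see [tidy.qc_report()]).
#' @export
#' @examples
#' qc_coverage_metrics(c(rep(25, 50), rep(5, 10), rep(25, 40)))
qc_coverage_metrics <- function(depths, th = lynch_thresholds()) {
  if (length(depths) == 0) abort("empty depth vector")
  if (any(is.na(depths)) || any(depths < 0)) abort("depths must be nonnegative")
  tiers <- c(10, 20, 50, 100, 200, 500, 1000)
  pct <- vapply(tiers, function(k) mean(depths >= k), numeric(1))
  names(pct) <- paste0(tiers, "x")
  r <- rle(depths < th$noloco_cov)
  noloco <- sum(r$values)
  structure(list(mean_target_coverage = mean(depths),
                 pct_bases_at = pct,
                 noloco_count = noloco,
                 qc_pass = noloco <= th$max_nolocos,
                 n_bases = length(depths)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> mean coverage %.1fx over %d bases; %d noloco(s); QC %s\n",
              x$mean_target_coverage, x$n_bases, x$noloco_count,
              if (x$qc_pass) "pass" else "FAIL"))
  print(round(x$pct_bases_at, 4))
  invisible(x)
}

#' Tidy a QC report
#'
#' @param x A `qc_report`.
#' @param ... Unused.
#' @return Tibble with one row per coverage tier.
#' @export
tidy.qc_report <- function(x, ...) {
  tibble(tier = names(x$pct_bases_at), fraction = unname(x$pct_bases_at))
}

#' @export
glance.qc_report <- function(x, ...) {
  tibble(mean_target_coverage = x$mean_target_coverage,
         noloco_count = x$noloco_count, qc_pass = x$qc_pass,
         n_bases = x$n_bases)
}
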