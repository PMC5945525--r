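#' Variant-calling and reporting thresholds
#'
#' Assembles the threshold set used by the paired variant caller and the
#' sample-level QC metrics. Defaults are the validated assay settings:
#' a 1% caller-level variant-frequency floor with 6x/4x tumor/normal
#' caller coverage, report-level minima of 100x tumor coverage, 10x normal
#' coverage and 5% variant frequency, germline filters of Q >= 30, 10x
#' coverage and >= 10% het ratio, no/low-coverage ("noloco") regions below
#' 20x with samples failing above 10 nolocos, and a 20% minimum tumor
#' cellularity.
#'
#' @param caller_min_vaf Caller-level minimum tumor variant allele fraction.
#' @param caller_min_tumor_cov,caller_min_normal_cov Caller-level coverage
#'   floors (reads) below which a site is not evaluated at all.
#' @param report_min_tumor_cov,report_min_normal_cov Report-level coverage
#'   minima; calls below them are flagged, not reported.
#' @param report_min_vaf Report-level tumor VAF floor (the ~5% practical
#'   limit of detection).
#' @param somatic_max_normal_vaf Maximum normal-sample VAF compatible with a
#'   somatic origin; tolerates tumor-in-normal contamination.
#' @param germline_min_q Minimum Phred-scaled variant quality for germline
#'   reporting.
#' @param germline_min_cov Minimum normal-sample coverage for germline
#'   reporting.
#' @param germline_min_het_ratio Minimum normal VAF ("het ratio") for a
#'   germline call.
#' @param noloco_cov Coverage below which a base belongs to a noloco region.
#' @param max_nolocos Maximum number of noloco regions before a sample fails
#'   QC.
#' @param min_tumor_cellularity Minimum acceptable tumor-cell fraction of a
#'   specimen.
#' @param somatic_fisher_alpha Significance level of the one-sided Fisher
#'   exact guard applied to putative somatic calls below `report_min_vaf`.
#'
#' @return A list of class `lynch_thresholds`.
#' @export
#' @examples
#' th <- lynch_thresholds()
#' th$report_min_tumor_cov
lynch_thresholds <- function(caller_min_vaf = 0.01,
                             caller_min_tumor_cov = 6,
                             caller_min_normal_cov = 4,
                             report_min_tumor_cov = 100,
                             report_min_normal_cov = 10,
                             report_min_vaf = 0.05,
                             somatic_max_normal_vaf = 0.02,
                             germline_min_q = 30,
                             germline_min_cov = 10,
                             germline_min_het_ratio = 0.10,
                             noloco_cov = 20,
                             max_nolocos = 10,
                             min_tumor_cellularity = 0.20,
                             somatic_fisher_alpha = 0.05) {
  th <- list(
    caller_min_vaf = caller_min_vaf,
    caller_min_tumor_cov = caller_min_tumor_cov,
    caller_min_normal_cov = caller_min_normal_cov,
    report_min_tumor_cov = report_min_tumor_cov,
    report_min_normal_cov = report_min_normal_cov,
    report_min_vaf = report_min_vaf,
    somatic_max_normal_vaf = somatic_max_normal_vaf,
    germline_min_q = germline_min_q,
    germline_min_cov = germline_min_cov,
    germline_min_het_ratio = germline_min_het_ratio,
    noloco_cov = noloco_cov,
    max_nolocos = max_nolocos,
    min_tumor_cellularity = min_tumor_cellularity,
    somatic_fisher_alpha = somatic_fisher_alpha
  )
  fracs <- c("caller_min_vaf", "report_min_vaf", "somatic_max_normal_vaf",
             "germline_min_het_ratio", "min_tumor_cellularity",
             "somatic_fisher_alpha")
  for (f in fracs) {
    if (th[[f]] < 0 || th[[f]] > 1) {
      abort(sprintf("threshold `%s` must lie in [0, 1], got %s", f, th[[f]]))
    }
  }
  if (th$caller_min_vaf >= th$report_min_vaf) {
    abort("`caller_min_vaf` must be below `report_min_vaf`")
  }
  structure(th, class = "lynch_thresholds")
}

#' Panel-level microsatellite-instability criteria
#'
#' A sample fails MSI analysis when fewer than `min_covered_sites` markers
#' have adequate coverage; otherwise it is MSI-High when at least
#' `high_fraction` of covered markers are expanded (unstable), else Stable.
#'
#' @param min_covered_sites Minimum markers with coverage (default 35).
#' @param high_fraction Unstable-site fraction at or above which the panel
#'   is MSI-High (default 0.20; the comparison is inclusive).
#' @return A list of class `msi_criteria`.
#' @export
msi_criteria <- function(min_covered_sites = 35, high_fraction = 0.20) {
  if (high_fraction <= 0 || high_fraction >= 1) {
    abort("`high_fraction` must lie strictly between 0 and 1")
  }
  structure(list(min_covered_sites = min_covered_sites,
                 high_fraction = high_fraction),
            class = "msi_criteria")
}

#' Loss-of-heterozygosity calling parameters
#'
#' @param het_baf_low,het_baf_high Normal-sample B-allele-frequency window
#'   defining an informative (germline heterozygous) SNP.
#' @param min_informative_snps Minimum informative SNPs for a gene-level call.
#' @param min_site_depth Minimum tumor and normal depth per SNP (reads).
#' @param imbalance_threshold Minimum median mirrored BAF deviation
#'   |tumor BAF - 0.5| for an LOH call. The default 0.125 sits between the
#'   expected deviation of copy-neutral LOH at 20% purity (0.10) and at 30%
#'   purity (0.15), placing the detection limit at ~30% affected fraction.
#' @param alpha Significance level for the aggregate allelic-imbalance test.
#' @return A list of class `loh_params`.
#' @export
loh_params <- function(het_baf_low = 0.30, het_baf_high = 0.70,
                       min_informative_snps = 5, min_site_depth = 50,
                       imbalance_threshold = 0.125, alpha = 0.05) {
  if (!(het_baf_low < 0.5 && 0.5 < het_baf_high)) {
    abort("heterozygous BAF window must contain 0.5")
  }
  if (imbalance_threshold <= 0 || imbalance_threshold >= 0.5) {
    abort("`imbalance_threshold` must lie in (0, 0.5)")
  }
  structure(list(het_baf_low = het_baf_low, het_baf_high = het_baf_high,
                 min_informative_snps = min_informative_snps,
                 min_site_depth = min_site_depth,
                 imbalance_threshold = imbalance_threshold, alpha = alpha),
            class = "loh_params")
}

#' MS-MLPA methylation-ratio thresholds
#'
#' A promoter is called methylated when a single CpG island reaches
#' `single_island_min` or when multiple (>= 2) islands reach
#' `multi_island_min`.
#'
#' @param single_island_min Ratio calling methylation from one island (0.30).
#' @param multi_island_min Ratio calling methylation from multiple islands
#'   (0.15).
#' @param n_islands Number of promoter CpG islands assayed (5 for MLH1).
#' @return A list of class `mlpa_thresholds`.
#' @export
mlpa_thresholds <- function(single_island_min = 0.30,
                            multi_island_min = 0.15,
                            n_islands = 5) {
  if (multi_island_min >= single_island_min) {
    abort("`multi_island_min` must be below `single_island_min`")
  }
  structure(list(single_island_min = single_island_min,
                 multi_island_min = multi_island_min,
                 n_islands = n_islands),
            class = "mlpa_thresholds")
}

#' Override threshold objects from a YAML configuration
#'
#' Reads a YAML file whose top-level keys may include `thresholds`,
#' `msi_criteria`, `loh_params` and `mlpa_thresholds`; each maps field names
#' to replacement values. Unknown fields are an error.
#'
#' @param path Path to a YAML file.
#' @return Named list with elements `thresholds`, `msi_criteria`,
#'   `loh_params`, `mlpa_thresholds`.
#' @export
config_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  build <- function(ctor, overrides, what) {
    overrides <- overrides %||% list()
    known <- names(formals(ctor))
    bad <- setdiff(names(overrides), known)
    if (length(bad) > 0) {
      abort(sprintf("unknown %s field(s): %s", what,
                    paste(bad, collapse = ", ")))
    }
    do.call(ctor, overrides)
  }
  list(
    thresholds = build(lynch_thresholds, cfg$thresholds, "thresholds"),
    msi_criteria = build(msi_criteria, cfg$msi_criteria, "msi_criteria"),
    loh_params = build(loh_params, cfg$loh_params, "loh_params"),
    mlpa_thresholds = build(mlpa_thresholds, cfg$mlpa_thresholds,
                            "mlpa_thresholds")
  )
}

validate_bed_lines <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("BED file '%s' contains no intervals", path))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    ok <- length(f) >= 3 &&
      !is.na(suppressWarnings(as.integer(f[2]))) &&
      !is.na(suppressWarnings(as.integer(f[3]))) &&
      as.integer(f[2]) < as.integer(f[3])
    if (!ok) {
      abort(sprintf("malformed BED line %d in '%s': %s", i, path, lines[[i]]))
    }
  }
  invisible(length(lines))
}

#' Load a panel definition
#'
#' Reads a panel directory containing `panel.bed` (targeted regions with the
#' gene symbol in the BED name column; 0-based half-open coordinates) and
#' `markers.tsv` (homopolymer marker definitions: `marker_id`, `chrom`,
#' `pos`, `repeat_unit`, `reference_length`). Overlapping intervals are
#' merged per gene, so the reported footprint is the length of the interval
#' union.
#'
#' @param panel_dir Directory with `panel.bed` and `markers.tsv`.
#' @return A list of class `lynch_panel` with elements `genes` (character),
#'   `regions` (tibble: gene, chrom, start, end, width; 1-based inclusive),
#'   `markers` (tibble), `total_bp` (merged panel footprint) and
#'   `germline_reportable_bp` (merged footprint of the five Lynch genes).
#' @export
#' @examples
#' panel <- default_panel()
#' panel$total_bp
load_panel <- function(panel_dir) {
  bed_path <- file.path(panel_dir, "panel.bed")
  marker_path <- file.path(panel_dir, "markers.tsv")
  if (!file.exists(bed_path)) abort(sprintf("no panel.bed under '%s'", panel_dir))
  if (!file.exists(marker_path)) abort(sprintf("no markers.tsv under '%s'", panel_dir))

  validate_bed_lines(bed_path)
  gr <- rtracklayer::import(bed_path, format = "BED")
  if (is.null(gr$name) || anyNA(gr$name)) {
    abort("panel.bed must carry the gene symbol in the BED name column")
  }
  per_gene <- GenomicRanges::reduce(GenomicRanges::split(gr, gr$name))
  regions <- purrr::map_dfr(names(per_gene), function(g) {
    r <- per_gene[[g]]
    tibble(gene = g,
           chrom = as.character(GenomicRanges::seqnames(r)),
           start = GenomicRanges::start(r),
           end = GenomicRanges::end(r),
           width = GenomicRanges::width(r))
  }) |> arrange(.data$chrom, .data$start)

  total_bp <- sum(GenomicRanges::width(GenomicRanges::reduce(gr, ignore.strand = TRUE)))

  markers <- readr::read_tsv(marker_path, show_col_types = FALSE,
                             col_types = readr::cols(
                               marker_id = readr::col_character(),
                               chrom = readr::col_character(),
                               pos = readr::col_integer(),
                               repeat_unit = readr::col_character(),
                               reference_length = readr::col_integer()
                             ))
  bad_len <- markers$reference_length < 12 | markers$reference_length > 27
  if (any(bad_len)) {
    abort(sprintf("marker repeat length outside 12-27 nt: %s",
                  paste(markers$marker_id[bad_len], collapse = ", ")))
  }

  genes <- sort(unique(regions$gene))
  missing_lynch <- setdiff(lynch_genes(), genes)
  if (length(missing_lynch) > 0) {
    abort(sprintf("panel is missing Lynch gene(s): %s",
                  paste(missing_lynch, collapse = ", ")))
  }
  lynch_bp <- sum(regions$width[regions$gene %in% lynch_genes()])

  structure(list(genes = genes,
                 regions = regions,
                 markers = markers,
                 total_bp = total_bp,
                 germline_reportable_bp = lynch_bp),
            class = "lynch_panel")
}

#' @export
print.lynch_panel <- function(x, ...) {
  cat(sprintf("<lynch_panel> %d genes, %d intervals, %s bp merged footprint\n",
              length(x$genes), nrow(x$regions),
              format(x$total_bp, big.mark = ",")))
  cat(sprintf("  germline reportable (Lynch genes): %s bp\n",
              format(x$germline_reportable_bp, big.mark = ",")))
  cat(sprintf("  markers: %d (%d Promega mononucleotide markers)\n",
              nrow(x$markers),
              sum(x$markers$marker_id %in% promega_marker_ids())))
  invisible(x)
}

#' The bundled synthetic default panel
#'
#' A 39-gene panel on a synthetic contig, sized to the validated assay's
#' footprint (477,945 bp merged exonic target; 45,810 bp germline-reportable
#' Lynch-gene region) with 40 homopolymer markers of 12-20 nt plus the five
#' Promega mononucleotide markers (NR-21, BAT-26, BAT-25, NR-24, MONO-27;
#' 21-27 nt). Coordinates are synthetic: the panel reproduces the assay's
#' geometry, not real genome positions.
#'
#' @return A `lynch_panel`.
#' @export
default_panel <- function() {
  load_panel(system.file("extdata", "lynch_panel", package = "lynchmmr"))
}

#' Promega mononucleotide marker names
#' @return Character vector of the five marker ids.
#' @export
promega_marker_ids <- function() {
  c("NR-21", "BAT-26", "BAT-25", "NR-24", "MONO-27")
}

#' Merged panel footprint in base pairs
#'
#' @param panel A `lynch_panel`.
#' @param genes Optional gene subset; default all panel genes.
#' @return Integer number of merged target bases.
#' @export
panel_bp <- function(panel, genes = NULL) {
  stopifnot(inherits(panel, "lynch_panel"))
  r <- panel$regions
  if (!is.null(genes)) r <- filter(r, .data$gene %in% genes)
  sum(r$width)
}

#' Assign panel genes to genomic sites
#'
#' Adds (or fills) a `gene` column on a site table by overlap with the panel
#' intervals. Sites outside every interval get `NA`.
#'
#' @param sites Data frame with `chrom` and 1-based `pos` columns.
#' @param panel A `lynch_panel`.
#' @return The input as a tibble with a `gene` column.
#' @export
assign_genes <- function(sites, panel) {
  stopifnot(inherits(panel, "lynch_panel"))
  sites <- as_tibble(sites)
  q <- GenomicRanges::GRanges(sites$chrom,
                              IRanges::IRanges(sites$pos, sites$pos))
  s <- GenomicRanges::GRanges(panel$regions$chrom,
                              IRanges::IRanges(panel$regions$start,
                                               panel$regions$end))
  hit <- GenomicRanges::findOverlaps(q, s, select = "first")
  sites$gene <- panel$regions$gene[hit]
  sites
}
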