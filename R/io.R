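paired_count_cols <- c("chrom", "pos", "ref", "alt",
                       "tumor_ref", "tumor_alt", "normal_ref", "normal_alt")

#' Read paired tumor/normal allele counts
#'
#' Accepts either a TSV with columns `chrom`, `pos`, `ref`, `alt`,
#' `tumor_ref`, `tumor_alt`, `normal_ref`, `normal_alt` (optional
#' `q_score`, `gene`) or a VCF with two samples (tumor first, normal
#' second) carrying `AD` allele-depth fields. Multi-allelic VCF records are
#' decomposed into one observation per alternate allele; indels are
#' normalized to their minimal left-aligned representation. Rows are
#' returned in deterministic (chrom, pos, alt) order with 1-based
#' positions.
#'
#' @param path Path to a `.tsv`/`.txt` or `.vcf` file.
#' @return Tibble of observations.
#' @export
parse_paired_counts <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    return(parse_paired_vcf(path))
  }
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(paired_count_cols, names(df))
  if (length(miss) > 0) {
    abort(sprintf("'%s' is missing column(s): %s", path,
                  paste(miss, collapse = ", ")))
  }
  for (col in c("pos", "tumor_ref", "tumor_alt", "normal_ref", "normal_alt")) {
    v <- df[[col]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) | num %% 1 != 0)
    if (length(bad) > 0) {
      abort(sprintf("non-integer `%s` at line %d of '%s'", col,
                    bad[1] + 1L, path))
    }
    df[[col]] <- as.integer(v)
  }
  norm <- purrr::pmap(list(df$pos, df$ref, df$alt), normalize_variant)
  df$pos <- vapply(norm, `[[`, integer(1), "pos")
  df$ref <- vapply(norm, `[[`, character(1), "ref")
  df$alt <- vapply(norm, `[[`, character(1), "alt")
  arrange(df, .data$chrom, .data$pos, .data$alt)
}

parse_paired_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(ad) || ncol(ad) < 2) {
    abort(sprintf("'%s' must contain tumor and normal samples with AD fields", path))
  }
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  rows <- purrr::map_dfr(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    t_ad <- as.integer(strsplit(ad[i, 1], ",", fixed = TRUE)[[1]])
    n_ad <- as.integer(strsplit(ad[i, 2], ",", fixed = TRUE)[[1]])
    purrr::map_dfr(seq_along(alts), function(j) {
      nv <- normalize_variant(as.integer(fix$POS[i]), fix$REF[i], alts[j])
      tibble(chrom = fix$CHROM[i], pos = nv$pos, ref = nv$ref, alt = nv$alt,
             tumor_ref = t_ad[1], tumor_alt = t_ad[j + 1],
             normal_ref = n_ad[1], normal_alt = n_ad[j + 1],
             q_score = qual[i])
    })
  })
  arrange(rows, .data$chrom, .data$pos, .data$alt)
}

#' Write paired counts to TSV
#'
#' Inverse of [parse_paired_counts()]; a write/read round trip is the
#' identity on the required columns.
#'
#' @param sites Observation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paired_counts <- function(sites, path) {
  readr::write_tsv(as_tibble(sites), path, progress = FALSE)
  invisible(path)
}

#' Write variant calls as a minimal VCF
#'
#' Serializes calls with `ORIGIN` and `FLAGS` INFO tags plus the paired
#' VAFs; intended for interoperability, not as a lossless container (use
#' the TSV writer for round trips).
#'
#' @param calls Tibble from [call_paired_variants()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=lynchmmr-%s",
            as.character(utils::packageVersion("lynchmmr"))),
    "##INFO=<ID=ORIGIN,Number=1,Type=String,Description=\"Variant origin: somatic, germline or ambiguous\">",
    "##INFO=<ID=FLAGS,Number=.,Type=String,Description=\"Report-level flags\">",
    "##INFO=<ID=TVAF,Number=1,Type=Float,Description=\"Tumor variant allele fraction\">",
    "##INFO=<ID=NVAF,Number=1,Type=Float,Description=\"Normal variant allele fraction\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- purrr::map_chr(seq_len(nrow(calls)), function(i) {
    x <- calls[i, ]
    info <- sprintf("ORIGIN=%s;TVAF=%.4f;NVAF=%.4f%s", x$origin,
                    x$tumor_vaf, x$normal_vaf,
                    if (nzchar(x$flags)) paste0(";FLAGS=", x$flags) else "")
    sprintf("%s\t%d\t.\t%s\t%s\t%s\t%s\t%s", x$chrom, x$pos, x$ref, x$alt,
            if (is.na(x$q_score)) "." else format(x$q_score),
            if (x$reportable) "PASS" else "flagged", info)
  })
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write or read a marker histogram table
#'
#' Long format: `marker_id`, `origin` (tumor/normal), `length`,
#' `read_count`.
#'
#' @param hist_df Histogram tibble.
#' @param path File path.
#' @return `path` (write) or tibble (read).
#' @export
write_histograms <- function(hist_df, path) {
  readr::write_tsv(as_tibble(hist_df), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_histograms
#' @export
read_histograms <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(c("marker_id", "origin", "length", "read_count"), names(df))
  if (length(miss) > 0) {
    abort(sprintf("'%s' is missing column(s): %s", path,
                  paste(miss, collapse = ", ")))
  }
  df
}

fixture_md5 <- c(
  msi_table1 = "47ff19740e63866d4a7e6fa9046c16f8",
  loh_table2 = "e4691a203ac3c8e013d9716dc8735e7c"
)

#' Load a packaged validation-table fixture
#'
#' The two validation cohorts ship as frozen transcriptions:
#' `msi_table1` -- 104 tumor specimens with the 40-site and 45-site NGS
#' MSI classifications and the Promega reference result; `loh_table2` --
#' 155 gene regions (31 sequencing runs x 5 Lynch genes) with array-based
#' and NGS copy-number/LOH states, verbatim cells, notes, and an
#' `annotation` column marking cells whose printed value contradicts the
#' accompanying narrative. Files are checksum-pinned; a mismatch is an
#' error.
#'
#' @param name `"msi_table1"` or `"loh_table2"`.
#' @return Tibble.
#' @export
#' @examples
#' nrow(load_table_fixture("msi_table1"))
load_table_fixture <- function(name) {
  if (!name %in% names(fixture_md5)) {
    abort(sprintf("unknown fixture '%s' (expected %s)", name,
                  paste(names(fixture_md5), collapse = " or ")))
  }
  path <- system.file("extdata", paste0(name, ".tsv"), package = "lynchmmr")
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, unname(fixture_md5[name]))) {
    abort(sprintf("fixture '%s' failed its checksum (%s); fixtures are frozen",
                  name, sum))
  }
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  na = character())
}

#' Replay the MSI validation cohort against the reference method
#'
#' Scores an NGS MSI column of the `msi_table1` fixture against the
#' Promega reference (High = positive).
#'
#' @param column `"msi_45"` (default) or `"msi_40"`.
#' @return List: `confusion` (a `confusion_table`), `n`, `n_discordant`,
#'   `discordance_pct`.
#' @export
#' @examples
#' replay_msi_table("msi_40")$discordance_pct
replay_msi_table <- function(column = c("msi_45", "msi_40")) {
  column <- match.arg(column)
  tab <- load_table_fixture("msi_table1")
  pred <- tibble(key = tab$sample_id, positive = tab[[column]] == "High")
  truth <- tibble(key = tab$sample_id, positive = tab$promega == "High")
  ct <- confusion_counts(pred, truth)
  nd <- sum(tab[[column]] != tab$promega)
  list(confusion = ct, n = nrow(tab), n_discordant = nd,
       discordance_pct = discordance_rate(nd, nrow(tab)))
}

#' Replay the LOH validation cohort against the array reference
#'
#' Scores the NGS LOH calls of the `loh_table2` fixture against the
#' array-based truth over all 155 gene regions. With `corrected = TRUE`
#' (default) the annotation column is applied: cells whose printed state
#' contradicts the narrative (the heterogeneous ~20%-LOH sample recorded
#' as three false negatives, and two cells conflicting with the single
#' reported false positive) are scored as negative NGS calls.
#'
#' @param corrected Apply fixture annotations (default `TRUE`).
#' @return List with `confusion` (a `confusion_table`) and `n`.
#' @export
replay_loh_table <- function(corrected = TRUE) {
  tab <- load_table_fixture("loh_table2")
  ngs <- tab$ngs_loh
  if (corrected) {
    ngs <- ngs & !(tab$annotation %in%
                     c("ngs_cell_contradicts_note_false_negative",
                       "ngs_plus_contradicts_single_fp_summary"))
  }
  key <- paste(tab$run_id, tab$gene, sep = ":")
  ct <- confusion_counts(tibble(key = key, positive = ngs),
                         tibble(key = key, positive = tab$oncoscan_loh))
  list(confusion = ct, n = nrow(tab))
}

#' Build a case report
#'
#' Stable, serializable summary of one case: module outputs, QC, the tool
#' version and the configuration used (the reproducibility contract).
#'
#' @param sample_id Sample identifier.
#' @param variant_calls,msi,loh,methylation,scenario,qc Module outputs
#'   (any may be `NULL`).
#' @param config Configuration echo (list).
#' @return A list of class `case_report`.
#' @export
build_case_report <- function(sample_id, variant_calls = NULL, msi = NULL,
                              loh = NULL, methylation = NULL,
                              scenario = NULL, qc = NULL, config = list()) {
  structure(list(
    sample_id = sample_id,
    tool_version = as.character(utils::packageVersion("lynchmmr")),
    variant_calls = if (is.null(variant_calls)) NULL else as_tibble(variant_calls),
    msi = if (is.null(msi)) NULL else glance(msi),
    loh = if (is.null(loh)) NULL else as_tibble(loh),
    methylation = if (is.null(methylation)) NULL else
      list(islands = tidy(methylation), call = glance(methylation)),
    scenario = if (is.null(scenario)) NULL else
      list(call = glance(scenario), evidence = scenario$evidence),
    qc = if (is.null(qc)) NULL else glance(qc),
    config = config
  ), class = "case_report")
}

#' Write / read a case report as JSON
#'
#' @param report A `case_report`.
#' @param path JSON path.
#' @return `path` (write); a `case_report` (read).
#' @export
write_case_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_case_report
#' @export
read_case_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("variant_calls", "loh")) {
    if (!is.null(x[[f]])) x[[f]] <- as_tibble(x[[f]])
  }
  structure(x, class = "case_report")
}

#' @export
print.case_report <- function(x, ...) {
  cat(sprintf("<case_report> %s (lynchmmr %s)\n", x$sample_id, x$tool_version))
  if (!is.null(x$scenario)) {
    cat(sprintf("  scenario %s: %s\n", x$scenario$call$scenario,
                x$scenario$call$diagnosis))
  }
  if (!is.null(x$msi)) cat(sprintf("  MSI: %s\n", x$msi$status))
  invisible(x)
}
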