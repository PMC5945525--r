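# shared fixture builders: everything is generated in code at test time

obs_row <- function(tumor_ref, tumor_alt, normal_ref, normal_alt,
                    chrom = "sim1", pos = 1000L, ref = "A", alt = "T",
                    q_score = 60, gene = NA_character_) {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                 tumor_ref = tumor_ref, tumor_alt = tumor_alt,
                 normal_ref = normal_ref, normal_alt = normal_alt,
                 q_score = q_score, gene = gene)
}

# independent reimplementation of the somatic/germline threshold cascade,
# used as the brute-force oracle for call_paired_variants
cascade_oracle <- function(sites, th = lynch_thresholds()) {
  out <- list()
  for (i in seq_len(nrow(sites))) {
    x <- as.list(sites[i, ])
    td <- x$tumor_ref + x$tumor_alt
    nd <- x$normal_ref + x$normal_alt
    if (td == 0) next
    tv <- x$tumor_alt / td
    nv <- if (nd > 0) x$normal_alt / nd else 0
    if (tv < th$caller_min_vaf) next
    if (td < th$caller_min_tumor_cov || nd < th$caller_min_normal_cov) next
    if (nv >= th$germline_min_het_ratio) {
      origin <- "germline"
    } else if (nv < th$somatic_max_normal_vaf) {
      origin <- "somatic"
      if (tv < th$report_min_vaf) {
        p <- stats::fisher.test(matrix(c(x$tumor_alt, x$tumor_ref,
                                         x$normal_alt, x$normal_ref), 2),
                                alternative = "greater")$p.value
        if (p > th$somatic_fisher_alpha) origin <- "ambiguous"
      }
    } else {
      origin <- "ambiguous"
    }
    reportable <- origin != "ambiguous" &&
      td >= th$report_min_tumor_cov && nd >= th$report_min_normal_cov &&
      tv >= th$report_min_vaf
    out[[length(out) + 1]] <- tibble::tibble(
      chrom = x$chrom, pos = x$pos, alt = x$alt,
      origin = origin, reportable = reportable)
  }
  dplyr::bind_rows(out)
}

random_sites <- function(n, seed) {
  set.seed(seed)
  td <- rpois(n, sample(c(5, 50, 300, 600), n, replace = TRUE))
  nd <- rpois(n, sample(c(3, 20, 200, 500), n, replace = TRUE))
  tv <- sample(c(0, 0.005, 0.02, 0.04, 0.06, 0.25, 0.5), n, replace = TRUE)
  nv <- sample(c(0, 0.001, 0.05, 0.15, 0.5), n, replace = TRUE)
  ta <- rbinom(n, td, tv)
  na <- rbinom(n, nd, nv)
  tibble::tibble(chrom = "sim1", pos = seq_len(n) * 10L,
                 ref = "A", alt = "T",
                 tumor_ref = td - ta, tumor_alt = ta,
                 normal_ref = nd - na, normal_alt = na,
                 q_score = 60)
}

# minimal panel written to a temp directory (for load_panel contract tests)
write_toy_panel <- function(dir,
                            bed = c("sim1\t0\t100\tMLH1",
                                    "sim1\t50\t150\tMLH1",
                                    "sim1\t200\t220\tMSH2"),
                            markers = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(bed, file.path(dir, "panel.bed"))
  if (markers) {
    readr::write_tsv(
      tibble::tibble(marker_id = c("HP01", "BAT-26"), chrom = "sim1",
                     pos = c(10L, 210L), repeat_unit = "A",
                     reference_length = c(15L, 26L)),
      file.path(dir, "markers.tsv"))
  }
  dir
}

variant_tbl <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(gene = r[[1]], variant = r[[2]], classification = r[[3]])
  }))
}

loh_tbl <- function(genes, loh = TRUE) {
  tibble::tibble(gene = genes, loh = loh)
}

# the molecular profiles of the published patient cases, as fixtures
patient_profiles <- function() {
  list(
    patient_1 = list(
      profile = case_profile(
        germline_variants = variant_tbl(list("PMS2", "EX6_9del", "pathogenic")),
        somatic_variants = variant_tbl(list("PMS2", "p.Y268*", "pathogenic")),
        msi_status = "High", ihc_absent = "PMS2"),
      scenario = "A", diagnosis = "lynch_confirmed", gene = "PMS2",
      ihc = TRUE),
    patient_2 = list(
      profile = case_profile(
        germline_variants = variant_tbl(list("MSH2", "c.942+3A>T", "pathogenic")),
        somatic_variants = variant_tbl(list("MSH2", "p.R711*", "pathogenic")),
        gene_loh = loh_tbl("MSH2"), msi_status = "High",
        ihc_absent = c("MSH2", "MSH6")),
      scenario = "B", diagnosis = "lynch_confirmed", gene = "MSH2",
      ihc = TRUE),
    patient_3 = list(
      profile = case_profile(
        somatic_variants = variant_tbl(list("MLH1", "c.461delA", "pathogenic")),
        gene_loh = loh_tbl("MLH1"), ihc_absent = c("MLH1", "PMS2")),
      scenario = "C", diagnosis = "lynch_ruled_out_double_somatic",
      gene = "MLH1", ihc = TRUE),
    patient_4 = list(
      profile = case_profile(
        somatic_variants = variant_tbl(
          list("PMS2", "p.Q288*", "pathogenic"),
          list("PMS2", "p.H701R", "likely_pathogenic")),
        ihc_absent = "PMS2"),
      scenario = "D", diagnosis = "lynch_ruled_out_double_somatic",
      gene = "PMS2", ihc = TRUE),
    patient_5 = list(
      profile = case_profile(
        germline_variants = variant_tbl(list("MSH6", "p.R976C", "VUS")),
        somatic_variants = variant_tbl(list("MSH6", "p.E118*", "pathogenic")),
        msi_status = "High", ihc_absent = "MSH6"),
      scenario = "E", diagnosis = "vus_upgrade_candidate", gene = "MSH6",
      ihc = TRUE),
    patient_6 = list(
      profile = case_profile(
        germline_variants = variant_tbl(list("MSH6", "p.T767I", "VUS")),
        somatic_variants = variant_tbl(list("MSH6", "c.3261delC", "pathogenic")),
        ihc_absent = "MSH6"),
      scenario = "E", diagnosis = "vus_upgrade_candidate", gene = "MSH6",
      ihc = TRUE),
    patient_7 = list(
      profile = case_profile(
        somatic_variants = variant_tbl(
          list("MSH6", "c.3261dupC", "pathogenic"),
          list("MLH1", "p.E679*", "pathogenic")),
        gene_loh = loh_tbl("MLH1"), msi_status = "High",
        ihc_absent = c("MLH1", "PMS2")),
      scenario = "C", diagnosis = "lynch_ruled_out_double_somatic",
      gene = "MLH1", ihc = TRUE),
    patient_8_methylation = list(
      profile = case_profile(
        gene_loh = loh_tbl("MLH1"), msi_status = "High",
        mlh1_methylated = TRUE, ihc_absent = c("MLH1", "PMS2")),
      scenario = "G", diagnosis = "sporadic_methylation", gene = "MLH1",
      ihc = TRUE),
    patient_9_boland = list(
      profile = case_profile(
        germline_variants = variant_tbl(
          list("MSH2", "EX1_7inv", "pathogenic")),
        somatic_variants = variant_tbl(
          list("MSH2", "p.R389*", "pathogenic"),
          list("MSH6", "c.3261delC", "pathogenic"),
          list("MSH6", "c.2561_2563delAGA", "VUS")),
        ihc_absent = c("MSH2", "MSH6")),
      scenario = "A", diagnosis = "lynch_confirmed", gene = "MSH2",
      ihc = TRUE)
  )
}
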