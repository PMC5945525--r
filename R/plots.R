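#' Plot an LOH detection-rate sweep
#'
#' Detection rate against tumor purity with the 95% detection target; the
#' limit of detection is the smallest purity on the grid reaching the
#' target.
#'
#' @param object A [loh_detection_sweep()] result.
#' @param target Detection target drawn as a reference line (default
#'   0.95).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.loh_sweep <- function(object, target = 0.95, ...) {
  lod <- loh_lod(object, target)
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$purity, y = .data$detection_rate)) +
    ggplot2::geom_hline(yintercept = target, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "tumor purity (affected cell fraction)",
                  y = "LOH detection rate",
                  title = "Copy-neutral LOH detection by tumor purity",
                  subtitle = if (is.na(lod)) "target not reached on grid"
                  else sprintf("limit of detection: %.0f%% purity", 100 * lod)) +
    ggplot2::theme_minimal()
  if (!is.na(lod)) {
    p <- p + ggplot2::geom_vline(xintercept = lod, linetype = "dotted",
                                 colour = "grey40")
  }
  p
}

#' Plot tumor and normal B-allele frequencies along the panel
#'
#' Mirrors the allelic-imbalance evidence the LOH caller consumes: at a
#' gene in LOH the tumor BAFs of germline-het SNPs split away from 0.5.
#'
#' @param sites Paired-count tibble with a `gene` column.
#' @param genes Optional gene subset (default the five Lynch genes).
#' @return A ggplot.
#' @export
plot_baf_profile <- function(sites, genes = lynch_genes()) {
  d <- as_tibble(sites) |>
    filter(.data$gene %in% genes) |>
    mutate(tumor = vaf_of(.data$tumor_alt, .data$tumor_ref),
           normal = vaf_of(.data$normal_alt, .data$normal_ref)) |>
    tidyr::pivot_longer(c("tumor", "normal"), names_to = "sample",
                        values_to = "baf")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$baf,
                                  colour = .data$sample)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::facet_wrap(~gene, scales = "free_x") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "position", y = "B-allele frequency") +
    ggplot2::theme_minimal()
}

#' Plot tumor vs normal read-length histograms for markers
#'
#' @param hist_df Long histogram tibble (`marker_id`, `origin`, `length`,
#'   `read_count`).
#' @param markers Marker ids to show (default the Promega five).
#' @return A ggplot.
#' @export
plot_marker_histograms <- function(hist_df, markers = promega_marker_ids()) {
  d <- filter(as_tibble(hist_df), .data$marker_id %in% markers)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$length, y = .data$read_count,
                                  fill = .data$origin)) +
    ggplot2::geom_col(position = "identity", alpha = 0.5) +
    ggplot2::facet_wrap(~marker_id, scales = "free") +
    ggplot2::labs(x = "supported tract length (nt)", y = "reads") +
    ggplot2::theme_minimal()
}
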