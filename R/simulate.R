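#' Simulation configuration for a paired tumor/normal case
#'
#' Collects every knob of the paired-cohort simulator. Defaults emulate the
#' validated assay's study conditions: panel mean depth ~500x (the depth
#' tier the assay tracks for tumor samples), specimens at or above the 20%
#' cellularity floor (default purity 0.5, a typical FFPE tumor fraction),
#' 20 informative SNPs per Lynch gene, and microsatellite stutter growing
#' with tract length.
#'
#' @param seed Integer seed; every simulated quantity is reproducible from
#'   `(config, seed)`.
#' @param purity Tumor-cell fraction in `[0, 1]`.
#' @param mean_depth Mean sequencing depth (reads); per-site depths are
#'   Poisson.
#' @param n_snps_per_gene Germline-het SNPs simulated per Lynch gene.
#' @param gene_states Named character vector mapping genes to
#'   `"diploid"`, `"cn_loh"`, `"deletion_loh"` or `"gain"`; unlisted genes
#'   are diploid.
#' @param somatic_events Data frame (`gene`, `classification`, optional
#'   `vaf`); without `vaf` the VAF follows from purity and the gene state.
#' @param germline_events Data frame (`gene`, `classification`).
#' @param msi_status `"High"` or `"Stable"`.
#' @param unstable_site_fraction Fraction of markers rendered unstable in
#'   an MSI-High tumor (default 0.6, the typical majority of mononucleotide
#'   tracts affected in MMR-deficient tumors).
#' @param stutter_rate Per-nucleotide slippage rate; the double-geometric
#'   stutter decay is `stutter_rate * reference_length`.
#' @param instability_shift Somatic deletion size (nt) at unstable markers.
#' @param slip_per_nt Per-read, per-nucleotide somatic slippage probability
#'   at unstable markers; the unstable read fraction is
#'   `purity * min(1, slip_per_nt * reference_length)`, making longer
#'   tracts more sensitive.
#' @param mlh1_methylation_level Methylated fraction at the MLH1 promoter.
#' @param base_error Per-read background error rate.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, purity = 0.5, mean_depth = 500,
                              n_snps_per_gene = 20,
                              gene_states = character(0),
                              somatic_events = NULL, germline_events = NULL,
                              msi_status = "Stable",
                              unstable_site_fraction = 0.6,
                              stutter_rate = 0.01, instability_shift = 3,
                              slip_per_nt = 0.03,
                              mlh1_methylation_level = 0.02,
                              base_error = 0.001) {
  if (purity < 0 || purity > 1) abort("`purity` must lie in [0, 1]")
  probs <- c(unstable_site_fraction, stutter_rate, slip_per_nt,
             mlh1_methylation_level, base_error)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (!msi_status %in% c("High", "Stable")) {
    abort("`msi_status` must be High or Stable")
  }
  ok_states <- c("diploid", "cn_loh", "deletion_loh", "gain")
  if (length(gene_states) > 0 && !all(gene_states %in% ok_states)) {
    abort(sprintf("gene states must be one of: %s",
                  paste(ok_states, collapse = ", ")))
  }
  empty_ev <- tibble(gene = character(0), classification = character(0),
                     vaf = numeric(0))
  fix_ev <- function(e) {
    if (is.null(e)) return(empty_ev)
    e <- as_tibble(e)
    if (!"vaf" %in% names(e)) e$vaf <- NA_real_
    if (!"variant" %in% names(e)) e$variant <- NA_character_
    e
  }
  structure(list(seed = as.integer(seed), purity = purity,
                 mean_depth = mean_depth,
                 n_snps_per_gene = n_snps_per_gene,
                 gene_states = gene_states,
                 somatic_events = fix_ev(somatic_events),
                 germline_events = fix_ev(germline_events),
                 msi_status = msi_status,
                 unstable_site_fraction = unstable_site_fraction,
                 stutter_rate = stutter_rate,
                 instability_shift = instability_shift,
                 slip_per_nt = slip_per_nt,
                 mlh1_methylation_level = mlh1_methylation_level,
                 base_error = base_error),
            class = "simulation_config")
}

#' Expected tumor B-allele frequency of a germline-het site
#'
#' Standard tumor-mixture algebra: the normal contribution carries one
#' alternate and one reference copy, the tumor contribution
#' `alt_copies` / `ref_copies`.
#'
#' @param alt_copies,ref_copies Tumor copy numbers of the alternate and
#'   reference allele (not both zero).
#' @param purity Tumor-cell fraction.
#' @return Expected BAF in `[0, 1]`.
#' @export
#' @examples
#' expected_baf(2, 0, 0.3) # copy-neutral LOH at 30% purity -> 0.65
expected_baf <- function(alt_copies, ref_copies, purity) {
  if (purity < 0 || purity > 1) abort("`purity` must lie in [0, 1]")
  if (alt_copies < 0 || ref_copies < 0 || alt_copies + ref_copies == 0) {
    abort("copy numbers must be nonnegative and not both zero")
  }
  (purity * alt_copies + (1 - purity)) /
    (purity * (alt_copies + ref_copies) + 2 * (1 - purity))
}

#' Expected somatic VAF from purity and copy state
#'
#' @param purity Tumor-cell fraction.
#' @param multiplicity Mutated copies per tumor cell.
#' @param total_cn Total tumor copy number at the locus.
#' @return Expected VAF.
#' @export
expected_somatic_vaf <- function(purity, multiplicity = 1, total_cn = 2) {
  purity * multiplicity / (purity * total_cn + 2 * (1 - purity))
}

state_copies <- function(state) {
  switch(state,
         diploid = c(alt = 1, ref = 1),
         cn_loh = c(alt = 2, ref = 0),
         deletion_loh = c(alt = 1, ref = 0),
         gain = c(alt = 2, ref = 1),
         abort(sprintf("unknown gene state '%s'", state)))
}

with_error <- function(p, e) p * (1 - e) + (1 - p) * e

#' Simulate paired allele counts at one site
#'
#' Depth is Poisson around `mean_depth`; alternate counts are binomial at
#' the mixture-expected BAF folded with the background error rate. The
#' normal sample is always diploid germline. Uses the current RNG stream;
#' seed upstream for reproducibility.
#'
#' @param genotype `"het"` or `"hom_ref"` (germline genotype).
#' @param gene_state Tumor copy state (see [simulation_config()]).
#' @param cfg A [simulation_config()].
#' @return One-row tibble with `tumor_ref`, `tumor_alt`, `normal_ref`,
#'   `normal_alt`.
#' @export
simulate_site_counts <- function(genotype = c("het", "hom_ref"),
                                 gene_state = "diploid",
                                 cfg = simulation_config()) {
  genotype <- match.arg(genotype)
  t_depth <- rpois(1, cfg$mean_depth)
  n_depth <- rpois(1, cfg$mean_depth)
  if (genotype == "het") {
    cp <- state_copies(gene_state)
    p_t <- expected_baf(cp["alt"], cp["ref"], cfg$purity)
    p_n <- 0.5
  } else {
    p_t <- 0
    p_n <- 0
  }
  t_alt <- rbinom(1, t_depth, with_error(p_t, cfg$base_error))
  n_alt <- rbinom(1, n_depth, with_error(p_n, cfg$base_error))
  tibble(tumor_ref = t_depth - t_alt, tumor_alt = t_alt,
         normal_ref = n_depth - n_alt, normal_alt = n_alt)
}

# double-geometric stutter offsets: P(d) proportional to rho^|d|
rstutter <- function(n, rho) {
  if (rho <= 0) return(rep(0L, n))
  mag <- rgeom(n, 1 - rho)
  sign <- sample(c(-1L, 1L), n, replace = TRUE)
  mag * sign
}

#' Simulate tumor and normal read-length histograms at a marker
#'
#' Stable reads scatter around the reference tract length with a symmetric
#' double-geometric stutter whose decay is `stutter_rate *
#' reference_length`, so longer tracts produce wider histograms. At an
#' unstable marker a purity-weighted fraction of tumor reads -- `purity *
#' min(1, slip_per_nt * reference_length)`, growing with tract length --
#' additionally carries a somatic deletion of `instability_shift`
#' nucleotides.
#'
#' @param reference_length Tract length of the marker (nt).
#' @param unstable Is the marker somatically unstable in this tumor?
#' @param cfg A [simulation_config()].
#' @return List with named count vectors `tumor_hist`, `normal_hist`.
#' @export
simulate_homopolymer_histogram <- function(reference_length, unstable = FALSE,
                                           cfg = simulation_config()) {
  rho <- min(0.95, cfg$stutter_rate * reference_length)
  draw <- function(n, shift_frac) {
    if (n == 0) return(setNames(integer(0), character(0)))
    len <- reference_length + rstutter(n, rho)
    if (shift_frac > 0) {
      hit <- runif(n) < shift_frac
      len[hit] <- len[hit] - cfg$instability_shift
    }
    len <- pmax(len, 1L)
    tab <- table(len)
    setNames(as.integer(tab), names(tab))
  }
  n_t <- rpois(1, cfg$mean_depth)
  n_n <- rpois(1, cfg$mean_depth)
  shift_frac <- if (unstable) {
    cfg$purity * min(1, cfg$slip_per_nt * reference_length)
  } else {
    0
  }
  list(tumor_hist = draw(n_t, shift_frac), normal_hist = draw(n_n, 0))
}

#' Simulate a complete paired tumor/normal case
#'
#' Emits every input the analysis modules consume -- paired SNP allele
#' counts per Lynch gene, somatic and germline variant sites, homopolymer
#' histograms for all panel markers, and MS-MLPA probe signals -- plus the
#' generating truth. Identical `(config, seed)` reproduce the case
#' exactly.
#'
#' @param cfg A [simulation_config()].
#' @param panel A [load_panel()] result (default the bundled panel).
#' @return A list of class `simulated_case`: `sites` (paired counts with
#'   `gene`, `role`, `q_score`), `histograms` (long tibble), `mlpa`
#'   (probe signals), `truth`.
#' @export
simulate_case <- function(cfg = simulation_config(), panel = default_panel()) {
  stopifnot(inherits(cfg, "simulation_config"))
  bad <- setdiff(c(cfg$somatic_events$gene, cfg$germline_events$gene,
                   names(cfg$gene_states)),
                 panel$genes)
  if (length(bad) > 0) {
    abort(sprintf("event/state gene(s) absent from panel: %s",
                  paste(unique(bad), collapse = ", ")))
  }
  set.seed(cfg$seed)

  state_of <- function(g) {
    if (g %in% names(cfg$gene_states)) cfg$gene_states[[g]] else "diploid"
  }
  region1 <- function(g) {
    r <- panel$regions[panel$regions$gene == g, ][1, ]
    r
  }

  # intronic het SNP backbone across the Lynch genes
  snp_sites <- purrr::map_dfr(lynch_genes(), function(g) {
    r <- region1(g)
    purrr::map_dfr(seq_len(cfg$n_snps_per_gene), function(i) {
      counts <- simulate_site_counts("het", state_of(g), cfg)
      tibble(chrom = r$chrom, pos = r$start + i - 1L,
             ref = "A", alt = "G", gene = g, role = "snp",
             q_score = 99) |>
        dplyr::bind_cols(counts)
    })
  })

  event_sites <- function(events, germline) {
    if (nrow(events) == 0) return(NULL)
    purrr::map_dfr(seq_len(nrow(events)), function(i) {
      ev <- events[i, ]
      r <- region1(ev$gene)
      t_depth <- rpois(1, cfg$mean_depth)
      n_depth <- rpois(1, cfg$mean_depth)
      if (germline) {
        p_t <- expected_baf(
          state_copies(state_of(ev$gene))["alt"],
          state_copies(state_of(ev$gene))["ref"], cfg$purity)
        p_n <- 0.5
      } else {
        p_t <- if (is.na(ev$vaf)) expected_somatic_vaf(cfg$purity) else ev$vaf
        p_n <- 0
      }
      t_alt <- rbinom(1, t_depth, with_error(p_t, cfg$base_error))
      n_alt <- rbinom(1, n_depth, with_error(p_n, cfg$base_error))
      tibble(chrom = r$chrom,
             pos = r$end - (if (germline) 100L else 300L) - i,
             ref = "C", alt = "T", gene = ev$gene,
             role = if (germline) "germline_event" else "somatic_event",
             q_score = 99,
             tumor_ref = t_depth - t_alt, tumor_alt = t_alt,
             normal_ref = n_depth - n_alt, normal_alt = n_alt)
    })
  }
  sites <- bind_rows(snp_sites,
                     event_sites(cfg$germline_events, TRUE),
                     event_sites(cfg$somatic_events, FALSE))

  markers <- panel$markers
  unstable <- rep(FALSE, nrow(markers))
  if (cfg$msi_status == "High") {
    n_unst <- round(cfg$unstable_site_fraction * nrow(markers))
    unstable[sample.int(nrow(markers), n_unst)] <- TRUE
  }
  histograms <- purrr::map_dfr(seq_len(nrow(markers)), function(i) {
    h <- simulate_homopolymer_histogram(markers$reference_length[i],
                                        unstable[i], cfg)
    bind_rows(
      tibble(marker_id = markers$marker_id[i], origin = "tumor",
             length = as.integer(names(h$tumor_hist)),
             read_count = unname(h$tumor_hist)),
      tibble(marker_id = markers$marker_id[i], origin = "normal",
             length = as.integer(names(h$normal_hist)),
             read_count = unname(h$normal_hist))
    )
  })

  islands <- paste0("island_", 1:5)
  mlpa <- bind_rows(
    purrr::map_dfr(islands, function(isl) {
      und <- rpois(2, 1000)
      meth <- pmin(1, pmax(0, cfg$mlh1_methylation_level +
                             rnorm(2, 0, 0.01)))
      tibble(probe_id = paste0(isl, "_p", 1:2), island_id = isl,
             digested = round(und * meth), undigested = und)
    }),
    {
      und <- rpois(3, 1000)
      tibble(probe_id = paste0("ref_p", 1:3), island_id = "reference",
             digested = und + round(rnorm(3, 0, 10)), undigested = und)
    }
  )

  truth <- list(config = cfg,
                gene_states = setNames(
                  vapply(lynch_genes(), state_of, character(1)),
                  lynch_genes()),
                marker_unstable = setNames(unstable, markers$marker_id),
                msi_status = cfg$msi_status,
                mlh1_methylated = cfg$mlh1_methylation_level >= 0.15)
  structure(list(sites = sites, histograms = histograms, mlpa = mlpa,
                 truth = truth),
            class = "simulated_case")
}

#' @export
print.simulated_case <- function(x, ...) {
  cat(sprintf("<simulated_case> %d sites, %d markers, purity %.2f, MSI %s\n",
              nrow(x$sites), length(unique(x$histograms$marker_id)),
              x$truth$config$purity, x$truth$msi_status))
  invisible(x)
}

#' Simulate a validation cohort
#'
#' Draws cases from named conditions in stated proportions, with a derived
#' seed per case so streams are independent and the whole cohort is
#' reproducible from one seed.
#'
#' @param n_cases Number of cases.
#' @param mix Named proportions over `names(conditions)`; must sum to 1.
#' @param conditions Named list of [simulation_config()] override lists.
#' @param template Base [simulation_config()] arguments (list).
#' @param seed Cohort seed.
#' @param panel Panel passed to [simulate_case()].
#' @return Tibble with `case_id`, `condition` and a `case` list-column of
#'   `simulated_case` objects.
#' @export
simulate_validation_cohort <- function(n_cases, mix, conditions,
                                       template = list(), seed = 1L,
                                       panel = default_panel()) {
  if (n_cases <= 0) abort("`n_cases` must be positive")
  if (abs(sum(mix) - 1) > 1e-8) abort("`mix` proportions must sum to 1")
  if (!setequal(names(mix), names(conditions))) {
    abort("`mix` and `conditions` must share names")
  }
  set.seed(seed)
  labels <- sample(names(mix), n_cases, replace = TRUE, prob = unname(mix))
  case_seeds <- sample.int(.Machine$integer.max - 1L, n_cases)
  purrr::map_dfr(seq_len(n_cases), function(i) {
    args <- modifyList(template, conditions[[labels[i]]])
    args$seed <- case_seeds[i]
    cfg <- do.call(simulation_config, args)
    tibble(case_id = sprintf("case_%03d", i), condition = labels[i],
           case = list(simulate_case(cfg, panel = panel)))
  })
}

#' Copy-neutral LOH detection-rate sweep over tumor purity
#'
#' For each purity, simulates `n_reps` replicates of a gene with
#' copy-neutral LOH (`n_snps` informative het SNPs at Poisson `depth`),
#' calls LOH on each, and records the detection rate. Used to locate the
#' assay's limit of detection.
#'
#' @param purities Purity grid (default 0.10-0.50 in 0.05 steps).
#' @param n_reps Replicates per purity (default 200).
#' @param n_snps Informative SNPs per replicate (default 20).
#' @param depth Mean depth (default 500).
#' @param p A [loh_params()].
#' @param base_error Background error rate.
#' @param seed Seed for the whole sweep.
#' @return Tibble of class `loh_sweep`: `purity`, `n_reps`,
#'   `detection_rate`.
#' @export
#' @examples
#' sw <- loh_detection_sweep(purities = c(0.2, 0.3), n_reps = 20, seed = 1)
#' loh_lod(sw)
loh_detection_sweep <- function(purities = seq(0.10, 0.50, by = 0.05),
                                n_reps = 200, n_snps = 20, depth = 500,
                                p = loh_params(), base_error = 0.001,
                                seed = 1L) {
  set.seed(seed)
  res <- purrr::map_dfr(purities, function(f) {
    baf <- with_error(expected_baf(2, 0, f), base_error)
    hits <- vapply(seq_len(n_reps), function(r) {
      t_depth <- rpois(n_snps, depth)
      n_depth <- rpois(n_snps, depth)
      sites <- tibble(
        tumor_alt = rbinom(n_snps, t_depth, baf),
        normal_alt = rbinom(n_snps, n_depth, with_error(0.5, base_error))
      )
      sites$tumor_ref <- t_depth - sites$tumor_alt
      sites$normal_ref <- n_depth - sites$normal_alt
      snps <- select_informative_snps(sites, p)
      call_gene_loh(snps, p)$loh
    }, logical(1))
    tibble(purity = f, n_reps = n_reps, detection_rate = mean(hits))
  })
  class(res) <- c("loh_sweep", class(res))
  res
}

#' Limit of detection from a purity sweep
#'
#' @param sweep A [loh_detection_sweep()] result.
#' @param target Required detection rate (default 0.95).
#' @return Smallest purity on the grid reaching `target`, or `NA` if none.
#' @export
loh_lod <- function(sweep, target = 0.95) {
  ok <- sweep$purity[sweep$detection_rate >= target]
  if (length(ok) == 0) NA_real_ else min(ok)
}
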