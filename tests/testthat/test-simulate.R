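test_that("expected BAF follows tumor-mixture algebra", {
  for (f in c(0, 0.3, 0.7, 1)) expect_equal(expected_baf(1, 1, f), 0.5)
  expect_equal(expected_baf(2, 0, 1.0), 1.0)
  expect_equal(expected_baf(2, 0, 0.3), 0.65)   # mirrored deviation 0.15
  expect_equal(expected_baf(1, 0, 0.5), (0.5 + 0.5) / (0.5 + 1))
  expect_error(expected_baf(1, 1, 1.5), "\\[0, 1\\]")
  expect_error(expected_baf(0, 0, 0.5), "both zero")

  expect_equal(expected_somatic_vaf(0.5), 0.25)
  expect_equal(expected_somatic_vaf(1.0), 0.5)
})

test_that("simulated site counts match their analytic expectations", {
  cfg <- simulation_config(seed = 1, purity = 0.3, mean_depth = 500,
                           base_error = 0)
  set.seed(101)
  draws <- purrr::map_dfr(1:1000, ~simulate_site_counts("het", "diploid", cfg))
  baf <- draws$tumor_alt / (draws$tumor_alt + draws$tumor_ref)
  expect_lt(abs(mean(baf) - 0.5), 0.02)

  set.seed(102)
  pure <- purrr::map_dfr(1:200, ~simulate_site_counts(
    "het", "cn_loh", simulation_config(purity = 1, base_error = 0)))
  baf_pure <- pure$tumor_alt / (pure$tumor_alt + pure$tumor_ref)
  expect_true(all(baf_pure %in% c(0, 1) | baf_pure > 0.99 | baf_pure < 0.01))

  set.seed(103)
  mixed <- purrr::map_dfr(1:1000, ~simulate_site_counts("het", "cn_loh", cfg))
  dev <- abs(mixed$tumor_alt / (mixed$tumor_alt + mixed$tumor_ref) - 0.5)
  expect_lt(abs(mean(dev) - 0.15), 0.01)   # matches the expected_baf oracle
})

test_that("stutter model widens with tract length and vanishes at rate zero", {
  cfg0 <- simulation_config(seed = 5, stutter_rate = 0)
  set.seed(5)
  h <- simulate_homopolymer_histogram(15, unstable = FALSE, cfg0)
  expect_identical(names(h$normal_hist), "15")
  expect_identical(names(h$tumor_hist), "15")

  # double-geometric variance grows with the length-scaled rate
  spread <- function(len, seed) {
    set.seed(seed)
    cfg <- simulation_config(stutter_rate = 0.01, mean_depth = 2000)
    h <- simulate_homopolymer_histogram(len, unstable = FALSE, cfg)
    lens <- rep(as.integer(names(h$normal_hist)), h$normal_hist)
    stats::var(lens)
  }
  expect_gt(spread(27, 7), spread(12, 7))

  # a fully clonal unstable marker produces a bimodal, rejected histogram
  set.seed(6)
  cfg <- simulation_config(purity = 1, instability_shift = 3)
  hu <- simulate_homopolymer_histogram(27, unstable = TRUE, cfg)
  expect_true(site_instability_test(hu$tumor_hist, hu$normal_hist)$unstable)
})

test_that("case simulation is deterministic and truth-consistent", {
  cfg <- simulation_config(seed = 99, purity = 0.5, msi_status = "High",
                           gene_states = c(MSH2 = "cn_loh"),
                           somatic_events = tibble::tibble(
                             gene = "MSH2", classification = "pathogenic"))
  a <- simulate_case(cfg, panel = default_panel())
  b <- simulate_case(cfg, panel = default_panel())
  expect_identical(a$sites, b$sites)
  expect_identical(a$histograms, b$histograms)
  expect_identical(a$mlpa, b$mlpa)

  c2 <- simulate_case(simulation_config(seed = 100, msi_status = "High"),
                      panel = default_panel())
  expect_false(identical(a$histograms, c2$histograms))

  expect_error(simulate_case(simulation_config(
    somatic_events = tibble::tibble(gene = "NOT_A_GENE",
                                    classification = "pathogenic"))),
    "absent from panel")
})

test_that("an all-default diploid MSS case is molecularly quiet end to end", {
  case <- simulate_case(simulation_config(seed = 12), panel = default_panel())
  calls <- call_paired_variants(case$sites)
  expect_equal(sum(calls$origin == "somatic"), 0)
  loh <- call_loh_by_gene(case$sites, panel = default_panel())
  expect_false(any(loh$loh))
  msi <- classify_msi_panel(msi_test_sites(case$histograms))
  expect_equal(msi$status, "Stable")
})

test_that("a germline-plus-somatic configuration round-trips to a Lynch diagnosis", {
  cfg <- simulation_config(
    seed = 14, purity = 0.5, msi_status = "High",
    germline_events = tibble::tibble(gene = "PMS2", variant = "EX6_9del",
                                     classification = "pathogenic"),
    somatic_events = tibble::tibble(gene = "PMS2", variant = "p.Y268*",
                                    classification = "pathogenic"))
  case <- simulate_case(cfg, panel = default_panel())
  calls <- call_paired_variants(case$sites, panel = default_panel())
  events <- dplyr::inner_join(
    calls, dplyr::select(case$sites, chrom, pos, role), by = c("chrom", "pos"))
  germ <- dplyr::filter(events, role == "germline_event")
  som <- dplyr::filter(events, role == "somatic_event")
  expect_equal(nrow(germ), 1)
  expect_equal(germ$origin, "germline")
  expect_equal(som$origin, "somatic")

  profile <- case_profile(
    germline_variants = tibble::tibble(gene = germ$gene, variant = "EX6_9del",
                                       classification = "pathogenic"),
    somatic_variants = tibble::tibble(gene = som$gene, variant = "p.Y268*",
                                      classification = "pathogenic"),
    gene_loh = dplyr::select(
      call_loh_by_gene(case$sites, panel = default_panel()), gene, loh),
    msi_status = classify_msi_panel(msi_test_sites(case$histograms))$status)
  call <- classify_scenario(profile)
  expect_equal(call$scenario, "A")
  expect_equal(call$diagnosis, "lynch_confirmed")
  expect_equal(call$affected_gene, "PMS2")
})

test_that("cohort simulation respects mix proportions and per-case seeds", {
  conditions <- list(msi_high = list(msi_status = "High", purity = 0.6),
                     mss = list(msi_status = "Stable"))
  one <- simulate_validation_cohort(1, c(msi_high = 1, mss = 0), conditions,
                                    seed = 2)
  expect_equal(nrow(one), 1)
  expect_s3_class(one$case[[1]], "simulated_case")

  expect_error(simulate_validation_cohort(
    4, c(msi_high = 0.7, mss = 0.7), conditions), "sum to 1")

  coh <- simulate_validation_cohort(6, c(msi_high = 0.5, mss = 0.5),
                                    conditions, seed = 3)
  coh2 <- simulate_validation_cohort(6, c(msi_high = 0.5, mss = 0.5),
                                     conditions, seed = 3)
  expect_identical(purrr::map(coh$case, "sites"), purrr::map(coh2$case, "sites"))
  # distinct cases draw from independent streams
  expect_false(identical(coh$case[[1]]$histograms, coh$case[[2]]$histograms))
})

test_that("a scaled MSI validation cohort is recovered with high sensitivity", {
  conditions <- list(msi_high = list(msi_status = "High", purity = 0.6),
                     mss = list(msi_status = "Stable", purity = 0.6))
  coh <- simulate_validation_cohort(30, c(msi_high = 0.5, mss = 0.5),
                                    conditions, seed = 8)
  status <- purrr::map_chr(coh$case, function(cs) {
    classify_msi_panel(msi_test_sites(cs$histograms))$status
  })
  truth <- purrr::map_chr(coh$case, ~.x$truth$msi_status)
  high <- truth == "High"
  expect_gte(sum(high), 5)
  expect_gte(mean(status[high] == "High"), 0.95)
  expect_gte(mean(status[!high] == "Stable"), 0.95)
})
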