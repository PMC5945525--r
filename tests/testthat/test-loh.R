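loh_sim_sites <- function(n_snps, baf, depth = 500) {
  td <- rpois(n_snps, depth)
  nd <- rpois(n_snps, depth)
  ta <- rbinom(n_snps, td, baf)
  na <- rbinom(n_snps, nd, 0.5)
  tibble::tibble(tumor_ref = td - ta, tumor_alt = ta,
                 normal_ref = nd - na, normal_alt = na)
}

test_that("informative-SNP selection applies the het window and depth floor", {
  p <- loh_params()
  sites <- tibble::tibble(
    tumor_ref = c(250, 475, 15, 250),
    tumor_alt = c(250, 25, 15, 250),
    normal_ref = c(250, 250, 250, 275),
    normal_alt = c(250, 250, 250, 225)
  )
  kept <- select_informative_snps(sites, p)
  # site 2 is homozygous-like in normal? no: normal 0.5; tumor hom -- still kept
  # site 3 fails the tumor depth floor (30 < 50)
  expect_equal(nrow(kept), 3)
  expect_true(all(kept$normal_baf >= 0.3 & kept$normal_baf <= 0.7))

  hom <- tibble::tibble(tumor_ref = 250, tumor_alt = 250,
                        normal_ref = 475, normal_alt = 25)  # normal BAF 0.05
  expect_equal(nrow(select_informative_snps(hom, p)), 0)
})

test_that("gene-level LOH call combines median imbalance and aggregate binomial test", {
  p <- loh_params()
  # perfectly balanced tumor BAFs: no LOH, affected fraction 0
  bal <- select_informative_snps(
    tibble::tibble(tumor_ref = rep(250, 20), tumor_alt = rep(250, 20),
                   normal_ref = rep(250, 20), normal_alt = rep(250, 20)), p)
  call <- call_gene_loh(bal, p, gene = "MLH1")
  expect_false(call$loh)
  expect_equal(call$est_affected_fraction, 0)

  # complete allelic loss: alternating BAF 0.05 / 0.95
  lost <- select_informative_snps(
    tibble::tibble(tumor_ref = rep(c(475, 25), 10),
                   tumor_alt = rep(c(25, 475), 10),
                   normal_ref = rep(250, 20), normal_alt = rep(250, 20)), p)
  call <- call_gene_loh(lost, p, gene = "MSH2")
  expect_true(call$loh)
  expect_gte(call$est_affected_fraction, 0.9 - 1e-9)
  expect_lte(call$est_affected_fraction, 1.0)

  # below the informative-SNP floor: reason, no call
  few <- select_informative_snps(
    tibble::tibble(tumor_ref = rep(25, 3), tumor_alt = rep(475, 3),
                   normal_ref = rep(250, 3), normal_alt = rep(250, 3)), p)
  call <- call_gene_loh(few, p, gene = "MSH6")
  expect_false(call$loh)
  expect_equal(call$reason, "insufficient_snps")

  # PMS2 calls carry the pseudogene caution
  expect_match(call_gene_loh(bal, p, gene = "PMS2")$warning, "pseudogene")
})

test_that("LOH calls are invariant under BAF mirroring", {
  set.seed(13)
  p <- loh_params()
  sites <- loh_sim_sites(20, baf = 0.65)
  mirrored <- dplyr::mutate(sites, tmp = tumor_ref, tumor_ref = tumor_alt,
                            tumor_alt = tmp, tmp = NULL)
  a <- call_gene_loh(select_informative_snps(sites, p), p)
  b <- call_gene_loh(select_informative_snps(mirrored, p), p)
  expect_equal(a$loh, b$loh)
  expect_equal(a$imbalance_stat, b$imbalance_stat)
  expect_equal(a$p_value, b$p_value)
})

test_that("affected-fraction estimate recovers simulated purity within 0.05", {
  set.seed(29)
  p <- loh_params()
  for (f in seq(0.4, 1.0, by = 0.2)) {
    est <- vapply(1:60, function(i) {
      sites <- loh_sim_sites(20, baf = expected_baf(2, 0, f))
      call_gene_loh(select_informative_snps(sites, p), p)$est_affected_fraction
    }, numeric(1))
    expect_lt(abs(mean(est) - f), 0.05)
  }
})

test_that("no-LOH simulations stay below the nominal false-positive rate", {
  set.seed(37)
  p <- loh_params()
  fp <- vapply(1:200, function(i) {
    sites <- loh_sim_sites(20, baf = 0.5)
    call_gene_loh(select_informative_snps(sites, p), p)$loh
  }, logical(1))
  expect_lte(mean(fp), p$alpha)
})

test_that("detection crosses its limit between 20% and 30% purity", {
  sw <- loh_detection_sweep(purities = c(0.20, 0.30), n_reps = 100, seed = 41)
  expect_lt(sw$detection_rate[sw$purity == 0.20], 0.5)
  expect_gte(sw$detection_rate[sw$purity == 0.30], 0.95)
})

test_that("per-gene wrapper assigns genes from the panel and calls each Lynch gene", {
  panel <- default_panel()
  cfg <- simulation_config(seed = 3, purity = 0.6,
                           gene_states = c(MLH1 = "cn_loh"))
  case <- simulate_case(cfg, panel = panel)
  res <- call_loh_by_gene(case$sites, panel = panel)
  expect_setequal(res$gene, lynch_genes())
  expect_true(res$loh[res$gene == "MLH1"])
  expect_false(any(res$loh[res$gene != "MLH1"]))
  expect_error(call_loh_by_gene(dplyr::select(case$sites, -gene)),
               "no panel")
})

test_that("depth-ratio copy-number estimates reproduce mixture arithmetic", {
  prof <- tibble::tibble(gene = rep(c("MLH1", "MSH2"), each = 5),
                         tumor_depth = rep(500, 10),
                         normal_depth = rep(500, 10))
  est <- estimate_gene_copy_number(prof)
  expect_true(all(est$depth_ratio == 1))
  expect_true(all(est$cn_estimate == 2))

  # one gene uniformly 1.5x after normalization: CN 3
  prof2 <- prof
  prof2$tumor_depth[prof2$gene == "MLH1"] <- 750
  # keep the panel-wide median anchored by many diploid intervals
  prof2 <- dplyr::bind_rows(prof2,
                            tibble::tibble(gene = "APC",
                                           tumor_depth = rep(500, 20),
                                           normal_depth = rep(500, 20)))
  est2 <- estimate_gene_copy_number(prof2)
  expect_equal(est2$cn_estimate[est2$gene == "MLH1"], 3)

  # purity 0.5, true CN 4: expected ratio (0.5*4 + 0.5*2)/2 = 1.5 -> naive CN 3
  mix_ratio <- (0.5 * 4 + 0.5 * 2) / 2
  prof3 <- dplyr::bind_rows(
    tibble::tibble(gene = "MSH6", tumor_depth = 500 * mix_ratio,
                   normal_depth = 500),
    tibble::tibble(gene = "APC", tumor_depth = rep(500, 20),
                   normal_depth = rep(500, 20)))
  est3 <- estimate_gene_copy_number(prof3)
  expect_equal(est3$cn_estimate[est3$gene == "MSH6"], 3)

  # zero-depth intervals are skipped with a warning; all-zero is an error
  prof4 <- tibble::tibble(gene = "MLH1", tumor_depth = c(500, 500),
                          normal_depth = c(500, 0))
  expect_warning(estimate_gene_copy_number(prof4), "zero normal depth")
  expect_error(suppressWarnings(estimate_gene_copy_number(
    tibble::tibble(gene = "MLH1", tumor_depth = 500, normal_depth = 0))),
    "no usable")
})

test_that("replaying the LOH validation cohort reproduces its printed splits", {
  verbatim <- replay_loh_table(corrected = FALSE)
  expect_equal(verbatim$n, 155)
  expect_equal(verbatim$confusion$tp, 31)
  expect_equal(verbatim$confusion$fp, 3)

  # with annotation-corrected cells: 1 false positive, 3 false negatives
  r <- replay_loh_table(corrected = TRUE)
  ct <- r$confusion
  expect_equal(ct$fn, 3)
  expect_equal(ct$fp, 1)
  expect_equal(ct$tn, 123)
  # the printed specificity split (123 of 124 negatives) reproduces exactly
  expect_equal(printed_percent(specificity(ct), 1), 99.2)
  # excluding the heterogeneous sample leaves no false negatives
  tab <- load_table_fixture("loh_table2")
  keep <- !grepl("^BR14_26", tab$run_id)
  ngs <- tab$ngs_loh & !(tab$annotation %in%
          c("ngs_cell_contradicts_note_false_negative",
            "ngs_plus_contradicts_single_fp_summary"))
  expect_equal(sum(tab$oncoscan_loh[keep] & !ngs[keep]), 0)
})
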