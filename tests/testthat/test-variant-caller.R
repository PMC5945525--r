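test_that("single-site cascade reproduces the validated discordant-call behavior", {
  th <- lynch_thresholds()
  # low-frequency somatic variant at ample coverage: reportable, unflagged
  deep <- call_site(obs_row(354, 20, 300, 0), th)   # VAF 5.35% at 374x
  expect_equal(deep$origin, "somatic")
  expect_identical(deep$flags, "")
  expect_true(deep$reportable)

  # same VAF at 98x: called somatic but flagged, not reportable
  shallow <- call_site(obs_row(92, 6, 300, 0), th)  # VAF 6.1% at 98x
  expect_equal(shallow$origin, "somatic")
  expect_match(shallow$flags, "low_tumor_coverage")
  expect_false(shallow$reportable)

  # textbook germline heterozygote
  het <- call_site(obs_row(150, 150, 120, 110), th)
  expect_equal(het$origin, "germline")
  expect_true(het$reportable)

  # below the 1% caller floor: no call at all
  expect_null(call_site(obs_row(995, 5, 500, 0), th))
  # zero tumor depth: skipped
  expect_null(call_site(obs_row(0, 0, 500, 0), th))
  # caller coverage floor (6x tumor / 4x normal)
  expect_null(call_site(obs_row(3, 2, 500, 250), th))
  expect_null(call_site(obs_row(200, 100, 2, 1), th))
  # intermediate normal VAF: surfaced as ambiguous, never silently assigned
  amb <- call_site(obs_row(250, 250, 475, 25), th)  # normal VAF 5%
  expect_equal(amb$origin, "ambiguous")
  expect_match(amb$flags, "ambiguous_origin")
  # negative counts are a validation error
  expect_error(call_site(obs_row(-1, 10, 100, 0), th), "negative")
})

test_that("the three discordant validation sites yield exactly one reportable somatic call", {
  sites <- dplyr::bind_rows(
    obs_row(354, 20, 300, 0, pos = 100L),  # deep low-VAF call: resolves
    obs_row(92, 6, 300, 0, pos = 200L),    # 98x: insufficient coverage
    obs_row(0, 0, 300, 0, pos = 300L)      # uncovered region
  )
  calls <- call_paired_variants(sites)
  expect_equal(sum(calls$reportable), 1)
  expect_equal(calls$origin[calls$reportable], "somatic")
})

test_that("paired calling is a deterministic per-site map with validated edge handling", {
  expect_equal(nrow(call_paired_variants(random_sites(0, 1))), 0)
  dup <- dplyr::bind_rows(obs_row(100, 100, 100, 100, pos = 5L),
                          obs_row(200, 200, 200, 200, pos = 5L))
  expect_error(call_paired_variants(dup), "duplicate")
  expect_error(call_paired_variants(tibble::tibble(chrom = "x", pos = 1)),
               "missing column")

  sites <- random_sites(300, seed = 11)
  a <- call_paired_variants(sites)
  b <- call_paired_variants(sites[sample(nrow(sites)), ])
  expect_identical(a, b)  # order-insensitive, deterministic output order
})

test_that("caller matches a brute-force reimplementation of the threshold cascade", {
  for (seed in c(7, 23)) {
    sites <- random_sites(500, seed = seed)
    got <- call_paired_variants(sites)[, c("chrom", "pos", "alt", "origin",
                                           "reportable")]
    want <- cascade_oracle(sites) |> dplyr::arrange(chrom, pos, alt)
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("every call has exactly one origin and flags gate reportability", {
  calls <- call_paired_variants(random_sites(400, seed = 5))
  expect_true(all(calls$origin %in% c("somatic", "germline", "ambiguous")))
  expect_true(all(!calls$reportable | calls$flags == ""))
  expect_true(all(!calls$reportable | calls$origin != "ambiguous"))
})

test_that("raising the reporting VAF floor never adds reportable calls", {
  sites <- random_sites(400, seed = 9)
  key <- function(calls) paste(calls$chrom, calls$pos, calls$alt)[calls$reportable]
  base <- key(call_paired_variants(sites, lynch_thresholds()))
  for (v in c(0.08, 0.15, 0.30)) {
    higher <- key(call_paired_variants(sites, lynch_thresholds(report_min_vaf = v)))
    expect_true(all(higher %in% base))
  }
})

test_that("simulated somatic variants at reportable VAF and depth are recovered", {
  set.seed(42)
  n <- 2000
  depth_t <- rpois(n, 500)
  depth_n <- rpois(n, 500)
  vaf <- runif(n, 0.05, 0.50)
  alt_t <- rbinom(n, depth_t, vaf)
  alt_n <- rbinom(n, depth_n, 0.001)
  sites <- tibble::tibble(chrom = "sim1", pos = seq_len(n) * 10L, ref = "A",
                          alt = "T", tumor_ref = depth_t - alt_t,
                          tumor_alt = alt_t, normal_ref = depth_n - alt_n,
                          normal_alt = alt_n, q_score = 60)
  calls <- call_paired_variants(sites)
  recovered <- sum(calls$origin == "somatic")
  expect_gte(recovered / n, 0.99)
  expect_equal(sum(calls$origin == "germline"), 0)

  # 20 clonal somatic events at VAF 0.25 among diploid het background
  set.seed(43)
  bg <- random_sites(480, seed = 17)
  ev_t <- rpois(20, 500); ev_n <- rpois(20, 500)
  ev_alt <- rbinom(20, ev_t, 0.25)
  events <- tibble::tibble(chrom = "sim2", pos = seq_len(20) * 10L, ref = "A",
                           alt = "T", tumor_ref = ev_t - ev_alt,
                           tumor_alt = ev_alt, normal_ref = ev_n,
                           normal_alt = 0L, q_score = 60)
  calls <- call_paired_variants(dplyr::bind_rows(bg, events))
  ev_calls <- dplyr::filter(calls, chrom == "sim2")
  expect_equal(nrow(ev_calls), 20)
  expect_true(all(ev_calls$origin == "somatic"))
})

test_that("germline report filter applies the Q30 / 10x / 10% het-ratio rule", {
  th <- lynch_thresholds()
  calls <- call_paired_variants(dplyr::bind_rows(
    obs_row(150, 150, 100, 100, pos = 10L, q_score = 29),   # Q 29: removed
    obs_row(150, 150, 100, 100, pos = 20L, q_score = 30),   # kept
    obs_row(150, 150, 5, 4, pos = 30L, q_score = 60),       # normal 9x: removed
    obs_row(150, 150, 90, 10, pos = 40L, q_score = 60),     # het ratio 10%: kept
    obs_row(150, 150, 91, 9, pos = 50L, q_score = 60)       # het ratio 9%: ambiguous band
  ), th)
  kept <- filter_germline_variants(calls, th)
  expect_setequal(kept$pos, c(20L, 40L))
})

test_that("QC coverage metrics count tier fractions and noloco runs", {
  qc <- qc_coverage_metrics(rep(600L, 1000))
  expect_true(all(qc$pct_bases_at[c("10x", "20x", "50x", "100x", "200x", "500x")] == 1))
  expect_equal(unname(qc$pct_bases_at["1000x"]), 0)
  expect_equal(qc$noloco_count, 0)
  expect_true(qc$qc_pass)

  # direct-count oracle: one sub-20x run of 10 bases out of 100
  qc2 <- qc_coverage_metrics(c(rep(25L, 50), rep(5L, 10), rep(25L, 40)))
  expect_equal(qc2$noloco_count, 1)
  expect_equal(unname(qc2$pct_bases_at["20x"]), 0.9)

  # 11 disjoint low-coverage runs fail the sample
  depths <- rep(c(rep(30L, 10), rep(5L, 3)), 11)
  qc3 <- qc_coverage_metrics(depths)
  expect_equal(qc3$noloco_count, 11)
  expect_false(qc3$qc_pass)

  # tier fractions are non-increasing
  set.seed(1)
  qc4 <- qc_coverage_metrics(rpois(5000, 150))
  expect_true(all(diff(qc4$pct_bases_at) <= 0))

  expect_error(qc_coverage_metrics(integer(0)), "empty")
})

test_that("variant normalization left-aligns and trims minimal representation", {
  expect_equal(normalize_variant(100, "CAG", "CG"),
               list(pos = 100, ref = "CA", alt = "C"))
  expect_equal(normalize_variant(100, "ATT", "AGT"),
               list(pos = 101, ref = "T", alt = "G"))
  expect_equal(normalize_variant(100, "A", "T"),
               list(pos = 100, ref = "A", alt = "T"))
})
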