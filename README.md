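# lynchmmr

Paired tumor/normal targeted-panel analysis for the molecular work-up of
suspected Lynch syndrome.

When immunohistochemistry shows loss of a mismatch-repair (MMR) protein or a
tumor is microsatellite unstable, the clinical question is whether the defect
is inherited (Lynch syndrome: a germline mutation in *MLH1*, *MSH2*, *MSH6*,
*PMS2*, or an *EPCAM* 3'-deletion, plus a somatic second hit) or purely
somatic (two acquired hits, or *MLH1* promoter hypermethylation). Sequencing
tumor and blood in parallel answers it in one step. `lynchmmr` implements the
computational core of such an assay as a tested, tidyverse-native R package:

- **Paired variant calling** — somatic vs germline origin from tumor/normal
  allele counts via a threshold cascade (1% caller VAF floor at 6x/4x
  coverage; report level 100x tumor / 10x normal / 5% VAF; germline filters
  Q ≥ 30, ≥ 10x, het ratio ≥ 10%), with per-sample coverage QC ("noloco"
  regions below 20x; more than 10 fails the sample).
- **MSI classification** — per-marker chi-square homogeneity tests on tumor
  vs normal homopolymer read-length histograms over 45 markers (40 panel
  homopolymers of 12–20 nt plus the five Promega markers NR-21, BAT-26,
  BAT-25, NR-24, MONO-27 at 21–27 nt); a sample fails below 35 covered
  markers and is MSI-High at ≥ 20% unstable markers. The Bethesda
  five-marker rule (≥ 2 unstable = MSI-H) is included for the reference
  method.
- **LOH detection** — per Lynch gene, allelic imbalance at germline-het
  (primarily intronic) SNPs: median mirrored B-allele-frequency deviation
  |BAF − 0.5| ≥ 0.125 plus a Stouffer-combined exact binomial test, with a
  copy-neutral affected-fraction estimate of twice the median deviation and
  a coarse depth-ratio copy-number estimate.
- **MS-MLPA interpretation** — *MLH1* promoter methylation ratios from
  digested/undigested probe signals, normalized to HhaI-site-free reference
  probes; methylated at ≥ 0.30 on one CpG island or ≥ 0.15 on multiple.
- **Two-hit scenario interpretation** — combines all evidence per gene into
  the scenario archetypes A–H (germline + somatic, germline + LOH, double
  somatic, VUS + somatic, methylation + LOH, …) and a diagnosis:
  `lynch_confirmed`, `lynch_ruled_out_double_somatic`,
  `sporadic_methylation`, `vus_upgrade_candidate`, or `inconclusive`, with
  IHC concordance checking against the MLH1/PMS2 and MSH2/MSH6 heterodimer
  loss patterns.
- **Validation statistics** — confusion tables, sensitivity/specificity
  (including base-pair denominators), discordance rates, Clopper–Pearson /
  Wilson intervals, and the packaged validation cohort fixtures (104-sample
  MSI concordance; 155-region LOH concordance).
- **Seeded simulator** — paired allele counts under purity/copy-state
  mixtures, length-dependent homopolymer stutter, somatic/germline events,
  and MLPA signals, with full truth labels, so every stage is testable at
  desk scale.

## Worked example

Simulate a tumor at 45% purity carrying a germline *MSH2* mutation with
copy-neutral LOH as the second hit plus a later somatic hit, then run the
full interpretation:

```r
library(lynchmmr)
library(dplyr)

panel <- default_panel()
cfg <- simulation_config(
  seed = 11, purity = 0.45, msi_status = "High",
  gene_states = c(MSH2 = "cn_loh"),
  germline_events = tibble(gene = "MSH2", classification = "pathogenic"),
  somatic_events  = tibble(gene = "MSH2", classification = "pathogenic"))
case <- simulate_case(cfg, panel = panel)

loh <- call_loh_by_gene(case$sites, panel = panel)
select(loh, gene, n_informative, imbalance_stat, loh, est_affected_fraction)
#>   gene  n_informative imbalance_stat loh   est_affected_fraction
#> 1 EPCAM            20         0.0153 FALSE                0.0306
#> 2 MLH1             20         0.0162 FALSE                0.0324
#> 3 MSH2             21         0.222  TRUE                 0.443
#> 4 MSH6             20         0.0227 FALSE                0.0454
#> 5 PMS2             20         0.0143 FALSE                0.0285

msi <- classify_msi_panel(msi_test_sites(case$histograms))
msi
#> <msi_panel_result> High (27/45 covered markers unstable = 60.0%)

profile <- case_profile(
  germline_variants = tibble(gene = "MSH2", variant = "c.942+3A>T",
                             classification = "pathogenic"),
  somatic_variants  = tibble(gene = "MSH2", variant = "p.R711*",
                             classification = "pathogenic"),
  gene_loh = select(loh, gene, loh),
  msi_status = msi$status,
  ihc_absent = c("MSH2", "MSH6"))
classify_scenario(profile)
#> <scenario_call> scenario B (lynch_confirmed), affected gene MSH2
#>   - germline MSH2 c.942+3A>T (pathogenic)
#>   - somatic MSH2 p.R711* (pathogenic)
#>   - LOH in MSH2
#>   - MSI status: High
#>   - IHC concordant: absent {MSH2, MSH6} matches a MSH2 defect
```

The LOH caller flags only *MSH2*, its affected-fraction estimate (0.443)
recovers the simulated purity, the MSI classifier calls the tumor High, and
the interpreter assembles scenario B — a germline mutation with LOH as the
second hit — confirming Lynch syndrome, concordant with the IHC pattern.

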