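---
title: "Methods: paired tumor/normal analysis for Lynch syndrome MMR testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired tumor/normal analysis for Lynch syndrome MMR testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lynchmmr)
```

`lynchmmr` reimplements the computational core of a paired tumor/normal
targeted-panel assay for mismatch-repair (MMR) deficiency: somatic/germline
variant differentiation, NGS microsatellite-instability (MSI)
classification, loss-of-heterozygosity (LOH) calling in the five Lynch
genes, MS-MLPA methylation interpretation, and a two-hit scenario
classifier, together with a seeded simulator and the validation arithmetic.
This vignette documents the models, their assumptions, the tunable
parameters, and the design decisions taken where the assay description
leaves the algorithm open.

## The panel

The bundled default panel reproduces the assay's geometry: 39 genes with a
merged exonic footprint of 477,945 bp, a 45,810 bp germline-reportable
region across the five Lynch genes (*MLH1*, *MSH2*, *MSH6*, *PMS2*,
*EPCAM*), 40 homopolymer markers of 12–20 nt, and the five Promega
mononucleotide markers (21–27 nt). The published assay does not include
probe coordinates or the custom marker loci, so the bundled panel is
**synthetic**: gene-sized exon blocks on a toy contig, sized so that the
printed footprints — and therefore the base-pair specificity denominators
477,945 × 58 = 27,720,810 and 45,810 × 5 = 229,050 — are exact. Real BED
files may be substituted via `load_panel()`. Intervals use 0-based
half-open BED semantics on disk and 1-based inclusive positions in memory
and reports, matching the conventions of the two representations.

## Paired variant calling

Calling operates on per-site paired allele counts and is a pure threshold
cascade (the upstream heuristic caller used by the original pipeline is out
of scope; its published thresholds are the contract):

1. *Caller floor*: no call below 1% tumor VAF or below 6x tumor / 4x normal
   coverage.
2. *Origin*: germline when the normal VAF ("het ratio") is ≥ 10%; somatic
   when the normal VAF is below 2%; in between, the call is surfaced as
   `ambiguous` rather than silently assigned, because no published rule
   resolves intermediate het ratios. The 2% somatic ceiling is this
   package's choice: it excludes germline heterozygotes while tolerating
   tumor-in-normal contamination at panel depths.
3. *Somatic guard*: candidates below the 5% reporting VAF additionally face
   a one-sided Fisher exact test of tumor vs normal counts (α = 0.05). The
   guard applies only in the sub-reporting band; at higher VAFs a paired
   test adds nothing and, at marginal coverage, would veto calls the
   threshold contract requires.
4. *Report level*: tumor < 100x, normal < 10x, or VAF < 5% set flags
   (`low_tumor_coverage`, `low_normal_coverage`, `below_reporting_vaf`);
   flagged calls are retained but not reportable.
5. *Germline reporting*: Q ≥ 30, normal coverage ≥ 10x, het ratio ≥ 10%.

Indels are normalized to a minimal left-aligned representation so
duplicates are detected deterministically; multi-allelic VCF records are
decomposed per alternate allele. The assay cites both a ~3% heuristic
detection capability and a ~5% practical limit; this package keeps the 1%
caller floor and the 5% reporting floor and leaves the tension visible as
flags rather than resolving it.

QC follows the assay's coverage metrics: fractions of targeted bases at
≥ 10x through ≥ 1000x (non-increasing by construction), and "noloco"
counting — maximal runs of bases under 20x — with samples failing above 10
nolocos.

## MSI classification

Each marker is compared between tumor and normal as two read-length
histograms. The assay delegates the per-site statistic to an external MSI
caller without stating it; this package uses the Pearson chi-square
homogeneity test that that class of tools popularized, with two numerical
guards: a 0.5 pseudocount per category, and merging of categories whose
pooled count is below 5 into their nearest neighbor, so the chi-square
approximation holds at panel depths. A marker is *covered* at ≥ 20
spanning reads per histogram (the assay is silent; 20 reads stabilizes the
test) and *unstable* when covered and rejected at α = 0.05. No per-site
multiple-testing correction is applied: the panel-level rule — *Failed*
below 35 covered markers, *High* at ≥ 20% unstable (inclusive, exactly as
printed), otherwise *Stable* — is the assay's aggregation mechanism, and a
per-site correction would silently shift the panel operating point.

MSI-Low exists only in the five-marker Bethesda classifier
(`classify_promega()`: ≥ 2 unstable = MSI-H, 1 = MSI-L, 0 = MSS), mirroring
the reference method; the NGS classifier is binary High/Stable because the
published criteria are, and because event counts in MSI-L tumors are not
separable from stable ones.

## LOH calling

Informative SNPs are germline heterozygotes — normal B-allele frequency in
[0.30, 0.70] — with ≥ 50x depth in both samples, drawn from the (primarily
intronic) panel content of the Lynch genes. A gene is called in LOH when
three conditions hold:

- at least 5 informative SNPs;
- the median mirrored deviation, median |tumor BAF − 0.5|, reaches
  τ = 0.125;
- a Stouffer combination of per-SNP exact binomial tests (tumor counts
  against 0.5, folded to the mirrored statistic so the test is symmetric in
  the two alleles) rejects at α = 0.05.

The median is robust to a minority of mis-genotyped SNPs. τ = 0.125 sits
halfway between the expected deviation of copy-neutral LOH at 20% tumor
fraction (0.10) and at 30% (0.15): the mixture algebra gives an expected
tumor BAF of (1 + f)/2 at affected fraction f, so the threshold places the
detection boundary between 20% and 30%, which is where the assay's
validation located it. Under copy-neutral LOH the affected fraction is
estimated as twice the median deviation (clipped to [0, 1]); a deletion
LOH produces a larger deviation at equal purity, so the estimate is a
lower bound — documented, not corrected. *PMS2* calls carry a pseudogene
caution annotation with no algorithmic special-casing. The folded per-SNP
p-values are conservative under the null, so the per-gene false-positive
rate stays at or below α.

The depth-ratio copy-number estimate (`estimate_gene_copy_number()`)
reproduces only the coarse granularity of array-derived per-gene copy
numbers: per-interval tumor/normal depth ratios, each normalized by its
sample's panel-wide median, summarized per gene and doubled. It is
deliberately purity-unadjusted (at 50% purity a true 4-copy gene reads as
3); allele-specific copy-number modeling is out of scope.

## MS-MLPA methylation

Per probe, the raw ratio is digested/undigested signal; ratios are
normalized by the mean raw ratio of HhaI-site-free reference probes and
averaged per CpG island. Because HhaI cannot cut methylated DNA, the
normalized ratio approximates the methylated fraction (0 = fully digested
= unmethylated). The decision rule is the kit's: methylated at ≥ 0.30 on a
single island or ≥ 0.15 on multiple islands, where "multiple" is read
minimally as at least 2 (the source does not define it). The assay
description also contains the sentence that a ratio of 1 indicates *no*
methylation, which contradicts the 0.3/0.15 thresholds in the same
paragraph; standard MS-MLPA semantics (ratio ≈ methylated fraction) are
adopted and the conflict is documented here rather than resolved.

## Two-hit scenario interpretation

Each gene with findings is classified independently against the archetype
scenarios: (A) germline pathogenic + one somatic hit; (B) germline
pathogenic + LOH, with or without an extra somatic hit; (H) germline
pathogenic + ≥ 2 somatic hits; (E) germline VUS + somatic pathogenic hit;
(F) ≥ 2 somatic + LOH; (C) one somatic + LOH; (D) ≥ 2 somatic; (G) *MLH1*
methylation + LOH with no mutations. The case-level scenario is the
highest-precedence gene, germline-bearing scenarios first (they dominate
clinical meaning), methylation last; all genes appear in the evidence
list. Diagnoses follow directly: A/B/H confirm Lynch syndrome (never
without a germline pathogenic/likely-pathogenic variant), C/D/F rule it
out as double-somatic, G is sporadic methylation, E emits VUS-upgrade
evidence only — final reclassification requires family history and
functional lines of evidence and is out of scope. Choices worth noting:

- Phase cannot be assessed from panel data; co-occurring hits in one gene
  are interpreted as biallelic, mirroring clinical practice.
- A germline pathogenic variant with no detectable second hit classifies as
  scenario `none`/`inconclusive` (every archetype carries a second hit);
  the evidence list still reports the germline finding.
- MSI-High is recorded as supporting evidence, not required for the
  double-somatic rule-out, since no published rule demands it.
- IHC concordance compares the observed absent-protein set with the
  heterodimer-driven expectation (MLH1→{MLH1, PMS2}, MSH2→{MSH2, MSH6},
  MSH6→{MSH6}, PMS2→{PMS2}, EPCAM→{MSH2, MSH6}); mismatches produce notes,
  never errors.

## Validation arithmetic and fixtures

`confusion_counts()`, `sensitivity()`, `specificity()`,
`discordance_rate()` and `proportion_ci()` (Clopper–Pearson default,
Wilson optional) reproduce the assay's validation numbers from its
confusion counts. Two fixture subtleties:

- **Display convention.** The published percentages mix rounding
  conventions: most cells round half-up, but the somatic specificity
  (99.999996% shown as 99.99%) and MSI sensitivity (96.226% shown as
  96.22%) are truncated toward zero. `printed_percent()` applies the
  convention recorded per metric in the `validation_counts()` fixture, so
  reproduced tables match their source digit for digit while the analysis
  functions always return full precision.
- **Internal inconsistencies.** The MSI cohort's footer counts (TP = 51,
  TN = 53) are inconsistent with its own rows (51 reference-positive
  samples, of which 2 are missed: TP = 49); the LOH table contains 31
  array-positive regions out of 155, while the printed sensitivity uses
  32/35 and the printed totals imply 159 regions, and three table cells
  contradict the accompanying narrative (the heterogeneous ~20%-LOH sample
  recorded with a positive NGS cell despite the note that it was not
  detected, and two cells conflicting with the single reported false
  positive). The fixtures store the rows verbatim, flag the contradictory
  cells in an `annotation` column, and the replay functions score either
  reading; with annotations applied, the replay reproduces the
  123-of-124-negative specificity split and the 1-false-positive /
  3-false-negative narrative exactly, while the printed sensitivity
  (32/35) is reproduced from the printed counts, which are shipped as
  inputs. The published 95% confidence intervals match neither
  Clopper–Pearson nor Wilson at spot-checked cells; intervals are computed
  and reported for reference but never asserted against the published
  ranges.

## The simulator

The simulator emulates paired panel sequencing at the study's conditions
and provides the truth labels for every property test.

- **Allele counts.** Per-site depths are Poisson (default mean 500x,
  matching the tumor-sample coverage tier the assay tracks); alternate
  counts are binomial at the tumor-mixture expectation
  `expected_baf(alt_copies, ref_copies, purity)` folded with a 0.1%
  background error. The normal sample is always diploid germline. Somatic
  VAFs derive from purity and copy state unless given explicitly, keeping
  variant and LOH signals mutually consistent.
- **Stutter.** Read lengths scatter around the reference tract length with
  a symmetric double-geometric distribution whose decay is
  `stutter_rate × reference_length` (default rate 0.01/nt): longer tracts
  produce wider histograms, the qualitative signature of polymerase
  slippage. At an unstable marker, a purity-weighted fraction of tumor
  reads — `purity × min(1, slip_per_nt × reference_length)`, default
  0.03/nt — carries an additional somatic deletion of 3 nt. Making the
  somatic slip probability proportional to tract length is the simplest
  mechanism that reproduces the observed property that longer markers are
  more sensitive MSI detectors; a fixed shift with length-proportional
  stutter alone would not.
- **Defaults.** Purity 0.5 (a typical FFPE tumor fraction, comfortably
  above the assay's 20% cellularity floor); 20 informative SNPs per gene;
  60% of markers unstable in MSI-High tumors (the typical majority of
  mononucleotide tracts affected under MMR deficiency); MLPA methylation
  level 0.02 for unmethylated and 0.5 for hypermethylated promoters.

The simulator reproduces read-count statistics, not reads: alignment
artifacts, FFPE deamination damage, sequence-context errors, capture
non-uniformity and pseudogene cross-mapping (the real complication for
*PMS2*) are all absent. Passing simulation-based tests therefore
demonstrates that the *decision rules* behave as specified under the
stated noise model — not that the assay achieves these operating
characteristics on real specimens; that evidence comes from the replayed
validation cohorts.

## Problem sizes and determinism

The test suite and acceptance script run at desk scale by choice: the LOH
limit-of-detection sweep uses purities 0.10–0.50 in 0.05 steps with 200
replicates, 20 SNPs and 500x depth; somatic-recovery checks use 2,000
simulated sites; cohort-level MSI checks use tens of cases. Every
stochastic path is seeded — cases derive independent per-case seeds from
the cohort seed — and `simulate_case()` is byte-identical for identical
configuration and seed. Boundary comparisons are inclusive exactly as
printed (≥ 20% unstable, ≥ 0.30 / ≥ 0.15 ratios, ≥ 10% het ratio).

## Known limitations

Alignment, realignment and base-quality recalibration are upstream and out
of scope, as are population-database polymorphism filtering, clinical
variant classification (labels are inputs), allele-specific copy-number
modeling, exon-level CNV calling, and reading histograms directly from
BAM. The affected-fraction estimate assumes copy-neutral LOH; the
copy-number estimate is purity-unadjusted; the scenario classifier cannot
phase hits. The ambiguous-origin band (normal VAF between 2% and 10%) is
reported, not resolved.
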