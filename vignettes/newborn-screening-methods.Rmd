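---
title: "Methods: variant triage, QC monitoring and benchmarking for gene-panel newborn screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant triage, QC monitoring and benchmarking for gene-panel newborn screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoscreen)
```

# The screening problem

Genomic newborn screening interprets sequencing data from *asymptomatic*
neonates. There is no phenotype to anchor interpretation, so the pipeline
cannot use phenotype ontologies or symptom-driven gene prioritisation: the
only defensible reporting policy is to restrict findings to variants with
established pathogenicity (ACMG classes 4 and 5, i.e. likely pathogenic and
pathogenic) in genes selected for early-onset, treatable disease. That
policy shapes every component in this package: the decision tree is
conservative by construction, variants of uncertain significance are stored
but never reviewed or reported, and quality control is strict enough that a
negative result can be trusted without human eyes on the sample.

The package operates downstream of alignment and variant calling: its input
is a per-sample VCF (plus QC metric tables), never reads. CNVs and
structural variants are out of scope — the panel's calling envelope is SNVs
and 1–15 bp indels within exons ± ~50 bp — and genes whose pathology is
predominantly CNV-driven are carried only as a `cnv_flagged` annotation.

# The decision tree

`run_decision_tree()` applies six conjunctive stages in a fixed order, and
records, for every input variant, the *first* stage that decided its fate:

1. **Scope.** Indels with more than 15 inserted/deleted bases are outside
   the caller's validated envelope; they are retained in I/O but never
   triaged.
2. **Panel.** A variant survives if its reference-affected span lies fully
   inside some panel gene's regions; survivors are annotated with the gene.
   A variant contained in two genes' regions is assigned to both and
   flagged ambiguous for the reviewer.
3. **Quality.** `depth ≥ dp_min` and `QD ≥ qd_min`. Missing DP or QD fails
   closed: a screening lab must not pass unverifiable calls. Defaults:
   `dp_min = 30` reads (matching the benchmark's depth floor) and
   `qd_min = 2` (common practice for GATK-style quality-by-depth); both are
   configurable in `triage_config()`.
4. **Frequency.** Survivors have population allele frequency strictly below
   `af_max = 0.01`, with two exceptions: variants in *frequent genes*
   (a per-gene flag for genes whose pathogenic alleles are common enough to
   trip a frequency filter) always pass, and variants with no frequency
   record are treated as rare — a novel pathogenic variant must not be lost
   to a missing annotation.
5. **Classification.** The knowledge base holds one resolved classification
   per variant per source: the laboratory's managed variant list (MVL), a
   ClinVar-like resolved table, and two auxiliary classifier tables that
   stand in for the external platforms a reviewer would consult. A variant
   is reportable when the MVL *or* the ClinVar-like source asserts P/LP and
   no consensus source (ClinVar-like or either auxiliary) dissents with
   B/LB; any dissent, or a source-level "conflicting" record, vetoes
   reporting. Absence from both primary sources means the variant cannot be
   reported at all, whatever the auxiliary sources say. A missing auxiliary
   assertion counts as non-dissent — requiring affirmative presence in all
   three sources would silence most genuinely reportable alleles.
6. **Zygosity.** Per gene: AR genes report homozygotes and possible
   compound heterozygotes (two or more distinct het P/LP variants; phase is
   unknowable from short reads, so the event is "possible" and goes to
   review); single AR hets are carrier findings and are suppressed. AD
   genes report every P/LP variant. XL genes report males hemizygous
   outside the pseudoautosomal regions — diploid callers emit `0/1` on X
   for males, so het-called genotypes count — and apply the AR rule to
   females and to PAR variants. Unknown sex on an XL gene fails *open*:
   the event is created with its mechanism unset and flagged for review,
   because silently dropping a possible hemizygous pathogenic variant is
   the one error a screening service cannot make.

A sample whose event list is empty is closed automatically; any event
triggers manual review and a confirmation rerun (represented as a report
flag — software cannot re-punch a blood spot card).

## Variant representation

Matching throughout the package is on exact normalized keys
`(chrom, pos, ref, alt)`. Normalization trims the shared right suffix, then
the shared left prefix, leaving one anchor base for indels — plain string
trimming, idempotent, with no reference genome involved. Multiallelic sites
are decomposed into one record per called alternate at read time.
Coordinates follow both standards: VCF positions are 1-based, BED and all
internal interval arithmetic 0-based half-open. Chromosome labels are
harmonized (default: strip a leading `"chr"`).

# QC thresholds and monitoring

Two threshold modes coexist in `build_threshold_set()`:

* **Fixed** routine thresholds, inclusive at the boundary (a printed
  minimum is read as attainable): Q30_pct ≥ 85 % (panel v1) / 90 % (v2);
  TARGET_BASES_30X_pct ≥ 93 %; MEAN_TARGET_COVERAGE ≥ 100×;
  SELECTED_BASES_pct ≥ 40 % (v1) / 78 % (v2, after the capture redesign);
  SNP_REFERENCE_BIAS ≤ 0.56 (elevated reference bias at het sites suggests
  contamination).
* **IQR-derived** fences for metrics without a prescribed value (PF_BASES
  by default): `median ± 1.5 × IQR` over the run history, with quartiles by
  linear interpolation between order statistics (`stats::quantile` type 7).
  The convention matters — a fence like 0.56 depends on it — so it is fixed
  and documented; the classical Tukey fence (`Q1/Q3 ± 1.5 × IQR`) is
  available behind `fence = "tukey"` as a deliberate deviation point.
  Deriving a fence needs at least 8 history values (configurable); fewer is
  an error, not a guess.

Three metrics are *very important* (VIPs): Q30_pct, TARGET_BASES_30X_pct
and SNP_REFERENCE_BIAS. The verdict logic is a strict partition: any VIP
failure ⇒ `repeat` (the whole wet-lab workflow restarts for that sample);
otherwise any failure ⇒ `review`; otherwise `pass`. The metric registry is
open — any metric with a rule row participates, so a laboratory monitoring
ten Picard metrics configures four more rows rather than new code.

Each 96-well plate carries an internal control in position H12 with two
known pathogenic variants; `check_internal_control()` passes the batch only
when both are found with the expected genotype and sufficient depth.
`levey_jennings()` tracks any monitored value across batches with
mean ± 1/2/3 SD bands; bands default to the full history (a rolling window
is available, since a long-running service may prefer local bands) and
points beyond 3 SD are flagged.

# Benchmarking

`compare_calls()` restricts both call sets to TOI ∩ HCR, applies the
`DP ≥ 30` floor, and matches on normalized key *plus genotype*: a genotype
mismatch at a shared site is one FP plus one FN, no half credit. Truth
records without DP are retained — the depth filter is a property of the
test sample's coverage, and reference truth sets often lack per-site depth.
Counts are stratified SNP vs indel and reported with sensitivity
`TP/(TP+FN)`, precision `TP/(TP+FP)` and concordance `C/(A+B+C)`; undefined
ratios (0/0) are `NA`, never 0 or 1. Matching is exact-key, not
haplotype-aware replay: representation differences at complex loci
(e.g. MNV decomposition) would count as FP+FN. That is a deliberate
desk-scale simplification — the fixture generator only emits normalized
representations, so tests are exact — and the main caveat when pointing the
module at external call sets.

# What the generators emulate — and what they do not

The synthetic fixtures are designed so that every module can be tested
against constructed ground truth:

* `make_panel()` builds genes with 2–6 exons (120–300 bp) carrying ± 50 bp
  flanks on disjoint blocks across autosomes and X (X blocks start beyond
  PAR1 so hemizygous scenarios are genuine); panels of any size, with
  inheritance mix, frequent-gene and CNV flags.
* `make_kb()` plants, per gene, one variant for every classification
  outcome (agreed P, ClinVar-only LP, MVL-only P, VUS, rare/common benign,
  conflicting, novel) and records the expected outcome per key.
* `make_sample()` plants one of eleven scenarios (negative, carrier,
  homozygous AR, compound-het AR, dominant AD, hemizygous XL male, XL
  female compound het, VUS-only, conflicting, off-panel, low-depth) plus
  background noise, with the expected triage result attached. Depths are
  drawn lognormal around 150× so QC-adjacent fields look realistic.
* `make_truth_pair()` plants exact (shared, test-only, truth-only) counts
  with a ~30 % indel fraction, all inside TOI at DP ≥ 30.
* `make_qc_history()` draws passing values from bands with structural
  margin to the thresholds and planted failures far outside the fence, so
  expected verdicts are certain by construction, not probabilistically.

Everything is seeded from one integer (per-file sub-seeds are derived
deterministically) and byte-identical across runs. What the generators do
**not** emulate: read-level error, realistic mutation spectra,
representation ambiguity across callers, population-scale allele-frequency
structure, or the genome-scale extent of real high-confidence regions.
Passing tests therefore demonstrate the *logic* of the workflow — filters,
consensus, zygosity, fences, matching — not the behaviour of a wet
laboratory or of a specific caller on real reads.

# Problem sizes and numerical choices

The test suite and acceptance script run at desk scale by design: panels of
8–16 genes for unit and property tests (a 359→405-gene revision exercises
the panel arithmetic), matcher properties on random sets of up to 50
variants across 100 seeds against an exhaustive all-pairs oracle, fence
derivation checked against an independently-coded quantile interpolation on
vectors up to length 200, and a cohort replay of 2600 QC records with a
planted 103/10/1 failure plan. Ties and degenerate inputs are handled
explicitly: boundary metric values pass; an empty VCF auto-closes; an empty
interval set contains nothing; `ref == alt` after trimming is an error;
duplicate keys in a benchmark set are deduplicated with a warning; a series
of one point yields a Levey–Jennings chart with no bands rather than an
error.

# Known limitations

* String-trim normalization cannot reconcile representation differences
  that require reference context (left-alignment across repeats).
* One inheritance mode per gene; dual-inheritance genes are not modelled.
* The ClinVar-like table carries one resolved classification per variant;
  review-status weighting (e.g. expert panel vs single submitter) is
  upstream curation, not package logic.
* Phasing is never attempted; compound heterozygotes are always
  "possible" and require human review.
* The confirmation rerun and all wet-lab loopbacks are report flags, not
  orchestration.
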