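# neoscreen

Computational core of a gene-panel genomic newborn-screening (NBS) workflow,
for laboratories that sequence dried-blood-spot DNA on a targeted panel and
must triage variants for *asymptomatic* neonates — no phenotype, no HPO
terms, only known pathogenic evidence. The package covers the three
computational jobs such a service runs every week:

1. **Variant triage** — a decision tree that reduces a sample's VCF to
   reportable events: panel containment → read-depth/quality-by-depth
   filters → population-frequency filter (strict `AF < 1%`, with a
   frequent-gene exception) → knowledge-base classification (ACMG class 4/5
   = {LP, P} from a managed variant list and a ClinVar-like table, with a
   three-source conflict veto) → inheritance-aware zygosity resolution.
   For autosomal-recessive genes only homozygotes and possible compound
   heterozygotes (≥ 2 distinct unphased hets) are reported — carriers are
   not; autosomal-dominant genes report any single P/LP variant; X-linked
   genes report hemizygous males (outside the PARs) and homozygous /
   compound-het females. Samples with nothing to review auto-close;
   everything else is flagged for manual review and a confirmation rerun.
2. **Sequencing QC** — per-sample metric evaluation against fixed routine
   thresholds (Q30_pct ≥ 85/90, TARGET_BASES_30X_pct ≥ 93,
   MEAN_TARGET_COVERAGE ≥ 100×, SELECTED_BASES_pct ≥ 40/78,
   SNP_REFERENCE_BIAS ≤ 0.56) and IQR fences derived from run history
   (`median ± 1.5 × IQR`); failure of a *very important* metric (VIP)
   forces a full workflow repeat. Includes the H12 internal-control sample
   check and Levey–Jennings longitudinal charts.
3. **Benchmarking** — truth-set comparison restricted to TOI ∩ HCR at
   DP ≥ 30, with genotype-aware exact matching after allele normalization:
   sensitivity `TP/(TP+FN)`, precision `TP/(TP+FP)` and pairwise
   concordance `C/(A+B+C)`, stratified by SNP vs indel (1–15 bp).

A deterministic synthetic fixture generator (`make_panel()`, `make_kb()`,
`make_sample()`, `make_truth_pair()`, `make_qc_history()`, `make_bundle()`)
produces every input with full ground truth, so the whole toolkit is
testable end to end at desk scale.

All user-facing functions take and return tibbles and compose with the
pipe; fitted/derived objects have `tidy()`, `glance()` and `autoplot()`
methods.

## Worked example

```r
library(neoscreen)

pan <- make_panel(12, seed = 42)$panel
kbb <- make_kb(pan, seed = 42)

# a newborn carrying two distinct het P/LP variants in an AR gene
s   <- make_sample(pan, kbb, "compound_het_AR", sample_id = "NB001", seed = 42)
res <- run_decision_tree(s$variants, pan, kbb$kb, s$meta)
res
#> <triage_result NB001: review_required, 1 event(s), 0 VUS stored, 7 audited>
#> # A tibble: 1 × 3
#>   gene   mechanism             n_variants
#> 1 GV1001 possible_compound_het          2
tidy(res)
#> # A tibble: 2 × 4
#>   sample_id gene   mechanism             key
#> 1 NB001     GV1001 possible_compound_het 1:1004670:C:G
#> 2 NB001     GV1001 possible_compound_het 1:1004690:G:T
```

The two heterozygous pathogenic variants in gene `GV1001` form one
*possible* compound-het event (short reads cannot phase them), so the
sample needs manual review; the audit trail records the terminal stage of
every input variant:

```r
res$audit[, c("key", "stage", "kept", "reason")]
#>   1:1004670:C:G  zygosity  TRUE  possible_compound_het
#>   1:1004690:G:T  zygosity  TRUE  possible_compound_het
#>   11:1004384:C:A frequency FALSE common-variant
#>   ...
```

Benchmarking a call set against a truth set with planted discordance
(3 test-only, 2 truth-only, 95 shared calls):

```r
tp  <- make_truth_pair(pan, seed = 42, a_fp = 3, b_fn = 2, c_shared = 95)
rep <- compare_calls(tp$test, tp$truth, tp$toi, tp$hcr, dp_min = 30)
tidy(rep)
#>   stratum    tp    fp    fn sensitivity precision concordance
#> 1 SNP        57     2     1       0.983     0.966        0.95
#> 2 INDEL      38     1     1       0.974     0.974        0.95
#> 3 ALL        95     3     2       0.979     0.969        0.95
```

QC verdicts for a 96-sample batch with two planted single-metric failures:

```r
qc  <- make_qc_history(96, failure_plan = c("1" = 2), seed = 42)
ths <- build_threshold_set(qc$metrics, qc$rules, "v1")
qc_verdicts(qc$metrics, ths) |> dplyr::count(status)
#>   status     n
#> 1 pass      94
#> 2 review     2
```

`run_batch()` wires the three stages together (QC gate → triage for
non-repeat samples → internal-control check) and `write_batch_report()`
serializes the result. A thin CLI over the same functions is installed at
`system.file("scripts", "nbs.R", package = "neoscreen")` with `triage`,
`bench`, `qc` and `synth` subcommands.

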