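# Truth-set benchmarking: restrict test and truth call sets to TOI ∩ HCR at
# DP >= 30, match on normalized (chrom, pos, ref, alt) plus genotype, and
# report TP/FP/FN with sensitivity, precision and pairwise concordance,
# stratified by variant type (SNP vs indel).

#' Restrict calls to benchmark regions and depth
#'
#' A call survives iff its span is contained in `toi` ∩ `hcr` and its depth
#' is at least `dp_min`. Truth sets often lack per-site depth: with
#' `truth = TRUE`, records without DP are retained (the depth filter is a
#' property of the test sample's coverage). Out-of-scope indels (> 15 bp) are
#' always excluded.
#'
#' @param calls Normalized, annotated variant tibble.
#' @param toi,hcr Interval sets (target-of-interest, high-confidence regions).
#' @param dp_min Minimum depth, default 30.
#' @param truth Logical: apply truth-set DP leniency.
#' @return Surviving rows.
#' @export
restrict_calls <- function(calls, toi, hcr, dp_min = 30, truth = FALSE) {
  region <- interval_intersect(toi, hcr)
  keep_dp <- if (truth) {
    is.na(calls$depth) | calls$depth >= dp_min
  } else {
    !is.na(calls$depth) & calls$depth >= dp_min
  }
  calls[variants_in_set(calls, region) & keep_dp & !calls$out_of_scope, ,
        drop = FALSE]
}

#' Match a test call set against a truth call set
#'
#' A pair matches iff the normalized keys (chrom, pos, ref, alt) are equal
#' and the genotypes are equal. A genotype mismatch at a shared site counts
#' as one FP plus one FN (no half credit). Duplicate identical keys within
#' one set are deduplicated with a warning. Counts are stratified by variant
#' type: SNP (`|ref| = |alt| = 1`) and INDEL (<= 15 bp), plus the ALL margin.
#'
#' @param test_calls,truth_calls Normalized, annotated (and typically
#'   restricted) variant tibbles.
#' @return A `comparison_counts` tibble: `stratum` (`SNP`, `INDEL`, `ALL`),
#'   `tp`, `fp`, `fn`.
#' @export
match_calls <- function(test_calls, truth_calls) {
  dedup <- function(x, label) {
    if (anyDuplicated(x$key)) {
      warn(sprintf("duplicate variant keys in %s set deduplicated", label))
      x <- distinct(x, .data$key, .keep_all = TRUE)
    }
    x
  }
  test_calls <- dedup(test_calls, "test")
  truth_calls <- dedup(truth_calls, "truth")
  test_calls <- filter(test_calls, !.data$out_of_scope)
  truth_calls <- filter(truth_calls, !.data$out_of_scope)
  tkey <- paste(test_calls$key, test_calls$genotype)
  gkey <- paste(truth_calls$key, truth_calls$genotype)
  test_calls$matched <- tkey %in% gkey
  truth_calls$matched <- gkey %in% tkey
  per_stratum <- function(str) {
    te <- if (str == "ALL") test_calls else filter(test_calls, .data$type == str)
    tr <- if (str == "ALL") truth_calls else filter(truth_calls, .data$type == str)
    tibble(stratum = str, tp = sum(tr$matched), fp = sum(!te$matched),
           fn = sum(!tr$matched))
  }
  out <- bind_rows(per_stratum("SNP"), per_stratum("INDEL"), per_stratum("ALL"))
  class(out) <- c("comparison_counts", class(out))
  out
}

#' Sensitivity from comparison counts
#'
#' @param counts A `comparison_counts` tibble (or any tibble with `tp`, `fn`).
#' @return `TP / (TP + FN)` per row; `NA` when the denominator is zero.
#' @export
bench_sensitivity <- function(counts) {
  denom <- counts$tp + counts$fn
  if_else(denom == 0, NA_real_, counts$tp / denom)
}

#' Precision from comparison counts
#'
#' @param counts A `comparison_counts` tibble (or any tibble with `tp`, `fp`).
#' @return `TP / (TP + FP)` per row; `NA` when the denominator is zero.
#' @export
bench_precision <- function(counts) {
  denom <- counts$tp + counts$fp
  if_else(denom == 0, NA_real_, counts$tp / denom)
}

#' Pairwise concordance from comparison counts
#'
#' `C / (A + B + C)` where C are variants found in both call sets, A only in
#' the first and B only in the second; symmetric under swapping the two
#' samples, and 1 for identical replicates.
#'
#' @param counts A `comparison_counts` tibble.
#' @return Concordance per row; `NA` when `A + B + C = 0`.
#' @export
bench_concordance <- function(counts) {
  denom <- counts$tp + counts$fp + counts$fn
  if_else(denom == 0, NA_real_, counts$tp / denom)
}

#' Compare two call sets restricted to benchmark regions
#'
#' End-to-end comparison: restrict both sets to TOI ∩ HCR at `dp_min`, match,
#' and compute per-stratum sensitivity, precision and concordance.
#'
#' @param test_calls,truth_calls Normalized annotated variant tibbles (or VCF
#'   paths together with `test_sample`/`truth_sample`).
#' @param toi,hcr Interval sets.
#' @param dp_min Minimum depth, default 30.
#' @param test_sample,truth_sample Sample ids used when paths are given.
#' @return A `comparison_report`: list with `counts` (per-stratum tibble with
#'   metrics) and `provenance` (region lengths, dp_min, input sizes).
#' @export
compare_calls <- function(test_calls, truth_calls, toi, hcr, dp_min = 30,
                          test_sample = NULL, truth_sample = NULL) {
  if (is.character(test_calls)) test_calls <- read_vcf(test_calls, test_sample)
  if (is.character(truth_calls)) truth_calls <- read_vcf(truth_calls, truth_sample)
  te <- restrict_calls(test_calls, toi, hcr, dp_min, truth = FALSE)
  tr <- restrict_calls(truth_calls, toi, hcr, dp_min, truth = TRUE)
  counts <- match_calls(te, tr)
  counts$sensitivity <- bench_sensitivity(counts)
  counts$precision <- bench_precision(counts)
  counts$concordance <- bench_concordance(counts)
  structure(
    list(counts = counts,
         provenance = tibble(
           toi_length = interval_total_length(toi),
           hcr_length = interval_total_length(hcr),
           restricted_length = interval_total_length(interval_intersect(toi, hcr)),
           dp_min = dp_min,
           n_test = nrow(te), n_truth = nrow(tr))),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report: dp_min %d, %d test / %d truth calls in regions>\n",
              x$provenance$dp_min, x$provenance$n_test, x$provenance$n_truth))
  print(x$counts)
  invisible(x)
}

#' @rdname compare_calls
#' @param x A `comparison_report`.
#' @param ... Unused.
#' @method tidy comparison_report
#' @export
tidy.comparison_report <- function(x, ...) {
  as_tibble(x$counts)
}

#' @rdname compare_calls
#' @method glance comparison_report
#' @export
glance.comparison_report <- function(x, ...) {
  all_row <- filter(x$counts, .data$stratum == "ALL")
  tibble(tp = all_row$tp, fp = all_row$fp, fn = all_row$fn,
         sensitivity = all_row$sensitivity, precision = all_row$precision,
         concordance = all_row$concordance, dp_min = x$provenance$dp_min)
}

#' Plot per-stratum benchmark metrics
#'
#' @param object A `comparison_report`.
#' @param ... Unused.
#' @return A ggplot bar chart of sensitivity/precision/concordance by stratum.
#' @method autoplot comparison_report
#' @export
autoplot.comparison_report <- function(object, ...) {
  df <- as_tibble(object$counts) |>
    tidyr::pivot_longer(c("sensitivity", "precision", "concordance"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stratum, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, title = "Benchmark metrics by stratum")
}
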