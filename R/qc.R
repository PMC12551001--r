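# Sequencing QC: IQR-fence threshold derivation from historical runs, fixed
# routine thresholds, per-sample pass/review/repeat verdicts with
# VIP-metric semantics, the plate-position H12 internal-control check, and
# Levey-Jennings longitudinal series.

.qc_metrics_v <- c("PF_BASES", "Q30_pct", "TARGET_BASES_30X_pct",
                   "MEAN_TARGET_COVERAGE", "SELECTED_BASES_pct",
                   "SNP_REFERENCE_BIAS")

#' Default QC metric rules
#'
#' The routine rule set: fixed thresholds where the workflow prescribes one
#' (Q30_pct >= 85 for panel v1 / 90 for v2; TARGET_BASES_30X_pct >= 93;
#' MEAN_TARGET_COVERAGE >= 100x; SELECTED_BASES_pct >= 40 v1 / 78 v2;
#' SNP_REFERENCE_BIAS <= 0.56), and a history-derived IQR fence for
#' PF_BASES. The very important metrics (VIPs) are Q30_pct,
#' TARGET_BASES_30X_pct and SNP_REFERENCE_BIAS: failure of any one forces a
#' full workflow repeat for that sample. The registry is open: any metric
#' with a rule row participates.
#'
#' @param panel_version `"v1"` or `"v2"`.
#' @return Tibble of `metric_rule` rows: `metric`, `direction`
#'   (`lower_bound`/`upper_bound`), `mode` (`fixed`/`iqr_derived`),
#'   `fixed_value`, `vip`.
#' @export
default_metric_rules <- function(panel_version = c("v1", "v2")) {
  panel_version <- match.arg(panel_version)
  v2 <- panel_version == "v2"
  tibble(
    metric = .qc_metrics_v,
    direction = c("lower_bound", "lower_bound", "lower_bound",
                  "lower_bound", "lower_bound", "upper_bound"),
    mode = c("iqr_derived", rep("fixed", 5)),
    fixed_value = c(NA, if (v2) 90 else 85, 93, 100, if (v2) 78 else 40, 0.56),
    vip = c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE)
  )
}

#' Derive an IQR-fence threshold from historical metric values
#'
#' Thresholds are set at `median - 1.5 * IQR` (lower bounds) or
#' `median + 1.5 * IQR` (upper bounds), with `IQR = Q3 - Q1` computed by
#' linear interpolation between order statistics (`stats::quantile` type 7).
#' An alternative Tukey-fence convention (`Q1 - k*IQR` / `Q3 + k*IQR`) is
#' available via `fence = "tukey"`.
#'
#' @param values Numeric vector of historical per-sample values (duplicates
#'   by sample excluded upstream to avoid bias).
#' @param direction `"lower_bound"` or `"upper_bound"`.
#' @param k Fence multiplier, default 1.5.
#' @param min_n Minimum history size; fewer values is an error. Default 8.
#' @param fence `"median"` (default) or `"tukey"`.
#' @return The threshold value.
#' @export
derive_threshold <- function(values, direction = c("lower_bound", "upper_bound"),
                             k = 1.5, min_n = 8, fence = c("median", "tukey")) {
  direction <- match.arg(direction)
  fence <- match.arg(fence)
  values <- values[!is.na(values)]
  if (length(values) < min_n) {
    abort(sprintf("insufficient history: %d value(s), need at least %d",
                  length(values), min_n))
  }
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  center <- switch(fence,
    median = q[2],
    tukey = if (direction == "lower_bound") q[1] else q[3]
  )
  if (direction == "lower_bound") center - k * iqr else center + k * iqr
}

#' Resolve a full threshold set from rules and history
#'
#' Fixed rules resolve to their fixed value; `iqr_derived` rules resolve via
#' [derive_threshold()] on the history of that metric.
#'
#' @param history Tibble of historical QC records: `sample_id`, one column
#'   per metric (long format `metric`/`value` also accepted).
#' @param rules Metric rules, e.g. [default_metric_rules()].
#' @param panel_version Label recorded in the output.
#' @param ... Passed to [derive_threshold()].
#' @return A `threshold_set`: tibble `metric`, `direction`, `threshold`,
#'   `vip`, `provenance`, with attribute `panel_version`.
#' @export
build_threshold_set <- function(history = NULL, rules = default_metric_rules(),
                                panel_version = "v1", ...) {
  long <- .metrics_long(history)
  out <- rules |>
    mutate(
      threshold = purrr::pmap_dbl(
        list(.data$metric, .data$direction, .data$mode, .data$fixed_value),
        function(metric, direction, mode, fixed_value) {
          if (mode == "fixed") return(fixed_value)
          vals <- long$value[long$metric == metric]
          derive_threshold(vals, direction, ...)
        }),
      provenance = if_else(
        .data$mode == "fixed", "fixed",
        sprintf("derived from %d samples",
                purrr::map_int(.data$metric,
                               ~ sum(long$metric == .x & !is.na(long$value)))))
    ) |>
    select("metric", "direction", "threshold", "vip", "provenance")
  if (any(!is.finite(out$threshold))) abort("non-finite resolved threshold")
  attr(out, "panel_version") <- panel_version
  class(out) <- c("threshold_set", class(out))
  out
}

# Accept wide (one column per metric) or long (metric,value) QC tables.
.metrics_long <- function(x) {
  if (is.null(x)) {
    return(tibble(sample_id = character(), metric = character(),
                  value = double()))
  }
  x <- as_tibble(x)
  if (all(c("metric", "value") %in% names(x))) return(x)
  id_cols <- intersect(c("sample_id", "batch_id", "run_date"), names(x))
  tidyr::pivot_longer(x, cols = -dplyr::all_of(id_cols),
                      names_to = "metric", values_to = "value")
}

#' Evaluate samples against a threshold set, metric by metric
#'
#' @param records Per-sample QC table: `sample_id` plus one column per metric
#'   (wide) or `sample_id`, `metric`, `value` (long). A metric configured in
#'   `thresholds` but missing from a record fails automatically.
#' @param thresholds A `threshold_set`.
#' @return Long tibble, one row per (sample, configured metric):
#'   `sample_id`, `metric`, `value`, `threshold`, `direction`, `vip`, `pass`.
#'   Boundary values pass (thresholds are attainable minima/maxima).
#' @export
evaluate_sample_metrics <- function(records, thresholds) {
  long <- .metrics_long(records) |> semi_join(thresholds, by = "metric")
  grid <- tidyr::expand_grid(sample_id = unique(.metrics_long(records)$sample_id),
                             metric = thresholds$metric)
  grid |>
    left_join(long[, c("sample_id", "metric", "value")],
              by = c("sample_id", "metric")) |>
    left_join(as_tibble(thresholds)[, c("metric", "direction", "threshold", "vip")],
              by = "metric") |>
    mutate(pass = !is.na(.data$value) & if_else(
      .data$direction == "lower_bound",
      .data$value >= .data$threshold,
      .data$value <= .data$threshold))
}

#' Per-sample QC verdicts
#'
#' Collapses per-metric evaluations into one status per sample:
#' `repeat` when at least one VIP metric fails (the whole workflow is
#' repeated), `review` when only non-VIP metrics fail, `pass` when all pass.
#'
#' @param detail Output of [evaluate_sample_metrics()], or a records table
#'   together with `thresholds`.
#' @param thresholds Optional `threshold_set`, when `detail` is a raw records
#'   table.
#' @return Tibble `sample_id`, `status`, `n_fail`, `vip_fail`,
#'   `failed_metrics`.
#' @export
qc_verdicts <- function(detail, thresholds = NULL) {
  if (!is.null(thresholds)) detail <- evaluate_sample_metrics(detail, thresholds)
  detail |>
    group_by(.data$sample_id) |>
    summarise(
      n_fail = sum(!.data$pass),
      vip_fail = any(!.data$pass & .data$vip),
      failed_metrics = paste(.data$metric[!.data$pass], collapse = ","),
      .groups = "drop"
    ) |>
    mutate(status = case_when(
      .data$vip_fail ~ "repeat",
      .data$n_fail > 0 ~ "review",
      TRUE ~ "pass"
    )) |>
    select("sample_id", "status", "n_fail", "vip_fail", "failed_metrics")
}

#' Check the internal control sample of a batch
#'
#' Every 96-well plate carries, in position H12, a control sample with two
#' known pathogenic variants. The batch passes when both variants are found
#' with the expected genotype and sufficient depth.
#'
#' @param variants The control sample's variant table (from [read_vcf()]).
#' @param expected Tibble `chrom, pos, ref, alt, genotype` of the expected
#'   control variants (genomic VCF coordinates).
#' @param min_depth Minimum acceptable read depth at each control variant.
#' @param batch_id Optional batch label carried into the result.
#' @return A `control_check`: tibble, one row per expected variant
#'   (`found`, `genotype_match`, `depth`, `allele_depth_fraction`, `ok`),
#'   with attributes `pass` (overall) and `batch_id`.
#' @export
check_internal_control <- function(variants, expected, min_depth = 30,
                                   batch_id = NA_character_) {
  expected <- as_tibble(expected) |>
    mutate(key = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt))
  obs <- variants |> distinct(.data$key, .keep_all = TRUE)
  res <- expected |>
    left_join(select(obs, "key", obs_genotype = "genotype", "depth",
                     "ad_ref", "ad_alt"),
              by = "key") |>
    mutate(
      found = !is.na(.data$obs_genotype),
      genotype_match = .data$found & .data$obs_genotype == .data$genotype,
      allele_depth_fraction = if_else(
        .data$found & !is.na(.data$ad_ref) & !is.na(.data$ad_alt) &
          (.data$ad_ref + .data$ad_alt) > 0,
        .data$ad_alt / (.data$ad_ref + .data$ad_alt), NA_real_),
      ok = .data$found & .data$genotype_match &
        !is.na(.data$depth) & .data$depth >= min_depth
    ) |>
    select("key", "genotype", "obs_genotype", "found", "genotype_match",
           "depth", "allele_depth_fraction", "ok")
  attr(res, "pass") <- all(res$ok)
  attr(res, "batch_id") <- batch_id
  class(res) <- c("control_check", class(res))
  res
}

#' @export
print.control_check <- function(x, ...) {
  cat(sprintf("<control_check %s: %s>\n", attr(x, "batch_id") %||% "",
              if (attr(x, "pass")) "PASS" else "FAIL"))
  NextMethod()
}

#' Levey-Jennings longitudinal series
#'
#' Computes, for one monitored metric across batches, the mean and +/-1/2/3
#' standard-deviation bands and flags points outside the 3-SD band. Bands use
#' all points in the window (default: the whole history).
#'
#' @param history Tibble with `batch_id`, `run_date` and a value column.
#' @param metric Name of the value column (default `"value"`).
#' @param window Either `"all"` (bands from the full series) or an integer
#'   rolling-window size.
#' @return An `lj_series` tibble ordered by `run_date`: `batch_id`,
#'   `run_date`, `value`, `mean`, `sd`, `flag`. With fewer than two points
#'   the bands are absent (`NA`), not an error.
#' @export
levey_jennings <- function(history, metric = "value", window = "all") {
  h <- as_tibble(history) |>
    arrange(.data$run_date) |>
    mutate(value = .data[[metric]])
  n <- nrow(h)
  if (identical(window, "all")) {
    m <- if (n >= 1) mean(h$value) else NA_real_
    s <- if (n >= 2) sd(h$value) else NA_real_
    h <- mutate(h, mean = m, sd = s)
  } else {
    w <- as.integer(window)
    h <- h |> mutate(
      mean = purrr::map_dbl(row_number(), function(i) {
        mean(h$value[max(1, i - w + 1):i])
      }),
      sd = purrr::map_dbl(row_number(), function(i) {
        v <- h$value[max(1, i - w + 1):i]
        if (length(v) >= 2) sd(v) else NA_real_
      }))
  }
  out <- h |>
    mutate(flag = !is.na(.data$sd) & .data$sd > 0 &
             abs(.data$value - .data$mean) > 3 * .data$sd) |>
    select(dplyr::any_of(c("batch_id", "run_date")), "value", "mean", "sd",
           "flag")
  class(out) <- c("lj_series", class(out))
  attr(out, "metric") <- metric
  out
}

#' Plot a Levey-Jennings series
#'
#' @param object An `lj_series`.
#' @param ... Unused.
#' @return A ggplot: per-batch values with mean and 1/2/3-SD bands; points
#'   beyond 3 SD highlighted.
#' @method autoplot lj_series
#' @export
autoplot.lj_series <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$run_date, y = .data$value)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$flag)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "steelblue",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "run date", y = attr(object, "metric") %||% "value",
                  title = "Levey-Jennings control chart")
  if (any(!is.na(df$sd))) {
    for (kk in 1:3) {
      p <- p +
        ggplot2::geom_hline(yintercept = df$mean[1] + kk * df$sd[1],
                            linetype = "dashed", colour = "grey40") +
        ggplot2::geom_hline(yintercept = df$mean[1] - kk * df$sd[1],
                            linetype = "dashed", colour = "grey40")
    }
    p <- p + ggplot2::geom_hline(yintercept = df$mean[1], colour = "grey20")
  }
  p
}
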