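# Batch orchestration: QC gate -> triage -> internal-control check. Samples
# whose QC status is "repeat" never reach triage (their whole workflow is
# repeated from the start); samples requiring review after triage are flagged
# for a confirmation rerun. The physical rerun itself is a report flag only.

#' Run a full screening batch
#'
#' Order of operations: evaluate QC verdicts, skip triage for repeat-status
#' samples, run the decision tree on the remaining samples, check the plate's
#' internal control (position H12) and assemble the batch report.
#'
#' @param metrics Per-sample QC table (see [evaluate_sample_metrics()]).
#' @param thresholds A `threshold_set`.
#' @param variant_sources Named list mapping `sample_id` to either a variant
#'   tibble or a VCF path.
#' @param p A `panel`.
#' @param kb A `knowledge_base`.
#' @param meta Sample metadata tibble: `sample_id`, `sex`, `plate_position`,
#'   `batch_id`.
#' @param config A [triage_config()].
#' @param control_expected Expected internal-control variants (tibble
#'   `chrom, pos, ref, alt, genotype`), or `NULL` to skip the control check.
#' @param control_position Plate position of the internal control sample
#'   (default `"H12"`).
#' @param control_min_depth Minimum depth for the control variants.
#' @return A `batch_report`: list with `verdicts`, `triage` (per-sample
#'   glance rows), `results` (named list of `triage_result`s), `control`
#'   (a `control_check` or `NULL`), `repeat_samples`,
#'   `confirmation_samples` (every review_required sample), `errors`,
#'   `pass` (FALSE iff the control check fails).
#' @export
run_batch <- function(metrics, thresholds, variant_sources, p, kb, meta,
                      config = triage_config(), control_expected = NULL,
                      control_position = "H12", control_min_depth = 30) {
  verdicts <- qc_verdicts(metrics, thresholds)
  errors <- tibble(sample_id = character(), error = character())

  control_id <- NULL
  if (!is.null(control_expected)) {
    control_id <- meta$sample_id[meta$plate_position %in% control_position]
    if (length(control_id) == 0) {
      abort(sprintf("internal control sample (position %s) missing from batch",
                    control_position))
    }
    control_id <- control_id[1]
  }

  triage_ids <- verdicts$sample_id[verdicts$status != "repeat"]
  triage_ids <- setdiff(intersect(triage_ids, meta$sample_id), control_id)
  results <- list()
  for (sid in triage_ids) {
    src <- variant_sources[[sid]]
    if (is.null(src)) {
      errors <- bind_rows(errors, tibble(sample_id = sid,
                                         error = "missing variant calls"))
      next
    }
    m <- meta[meta$sample_id == sid, , drop = FALSE]
    res <- tryCatch(
      run_decision_tree(src, p, kb, m, config),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      errors <- bind_rows(errors, tibble(sample_id = sid,
                                         error = conditionMessage(res)))
    } else {
      results[[sid]] <- res
    }
  }
  triage_tbl <- if (length(results) == 0) {
    tibble(sample_id = character(), status = character(),
           n_events = integer(), n_vus = integer(), n_audited = integer())
  } else {
    bind_rows(purrr::map(results, glance))
  }

  control <- NULL
  if (!is.null(control_expected)) {
    src <- variant_sources[[control_id]]
    if (is.null(src)) {
      abort(sprintf("internal control sample '%s' has no variant calls",
                    control_id))
    }
    cv <- if (is.character(src)) read_vcf(src, control_id) else src
    control <- check_internal_control(cv, control_expected,
                                      min_depth = control_min_depth,
                                      batch_id = meta$batch_id[1])
  }

  structure(
    list(
      verdicts = verdicts,
      triage = triage_tbl,
      results = results,
      control = control,
      repeat_samples = verdicts$sample_id[verdicts$status == "repeat"],
      confirmation_samples =
        triage_tbl$sample_id[triage_tbl$status == "review_required"],
      errors = errors,
      pass = is.null(control) || isTRUE(attr(control, "pass"))
    ),
    class = "batch_report"
  )
}

#' @export
print.batch_report <- function(x, ...) {
  cat(sprintf(paste0("<batch_report: %d samples QC'd (%d repeat), %d triaged, ",
                     "%d for confirmation, control %s>\n"),
              nrow(x$verdicts), length(x$repeat_samples), nrow(x$triage),
              length(x$confirmation_samples),
              if (is.null(x$control)) "not checked"
              else if (attr(x$control, "pass")) "PASS" else "FAIL"))
  invisible(x)
}

#' @rdname run_batch
#' @param x A `batch_report`.
#' @param ... Unused.
#' @method glance batch_report
#' @export
glance.batch_report <- function(x, ...) {
  tibble(
    n_samples = nrow(x$verdicts),
    n_repeat = length(x$repeat_samples),
    n_triaged = nrow(x$triage),
    n_confirmation = length(x$confirmation_samples),
    n_errors = nrow(x$errors),
    control_pass = is.null(x$control) || isTRUE(attr(x$control, "pass"))
  )
}

#' Write a batch report to a directory
#'
#' Emits `batch_report.json`, `verdicts.tsv` and, per triaged sample, a
#' triage JSON and a tab-delimited audit log.
#'
#' @param report A `batch_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_batch_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$verdicts, file.path(out_dir, "verdicts.tsv"),
                   progress = FALSE)
  for (sid in names(report$results)) {
    res <- report$results[[sid]]
    readr::write_tsv(res$audit, file.path(out_dir, paste0(sid, "_audit.tsv")),
                     progress = FALSE)
    jsonlite::write_json(
      list(sample_id = res$sample_id, status = res$status,
           events = dplyr::select(res$events, -"variants")),
      file.path(out_dir, paste0(sid, "_triage.json")),
      auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(
    c(as.list(glance(report)),
      list(repeat_samples = report$repeat_samples,
           confirmation_samples = report$confirmation_samples)),
    file.path(out_dir, "batch_report.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
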