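# Knowledge base: local assertion tables standing for the laboratory's managed
# variant list (MVL), a ClinVar-like resolved classification table, and two
# auxiliary classifier tables used for the three-source reporting consensus,
# plus a population allele-frequency table.

.kb_sources <- c("MVL", "CLINVAR", "AUX1", "AUX2")
.kb_classes <- c("P", "LP", "VUS", "LB", "B", "CONFLICTING")

#' Construct a knowledge base
#'
#' @param assertions Tibble `chrom, pos, ref, alt, source, classification`;
#'   `source` one of MVL, CLINVAR, AUX1, AUX2; `classification` one of
#'   P, LP, VUS, LB, B, CONFLICTING; at most one row per (variant, source).
#' @param frequencies Tibble `chrom, pos, ref, alt, af` with `af` in `[0, 1]`.
#' @return A `knowledge_base` object.
#' @export
knowledge_base <- function(assertions, frequencies = NULL) {
  assertions <- as_tibble(assertions)
  bad_src <- setdiff(unique(assertions$source), .kb_sources)
  if (length(bad_src) > 0) {
    abort(sprintf("unknown assertion source(s): %s", paste(bad_src, collapse = ", ")))
  }
  bad_cls <- setdiff(unique(assertions$classification), .kb_classes)
  if (length(bad_cls) > 0) {
    abort(sprintf("unknown classification(s): %s", paste(bad_cls, collapse = ", ")))
  }
  assertions <- assertions |>
    mutate(key = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt))
  if (anyDuplicated(assertions[, c("key", "source")])) {
    abort("multiple classifications for the same (variant, source)")
  }
  if (is.null(frequencies)) {
    frequencies <- tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(), af = double())
  }
  frequencies <- as_tibble(frequencies)
  if (any(frequencies$af < 0 | frequencies$af > 1)) {
    abort("allele frequencies must lie in [0, 1]")
  }
  frequencies <- frequencies |>
    mutate(key = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt))
  wide <- assertions |>
    select("key", "source", "classification") |>
    tidyr::pivot_wider(names_from = "source", values_from = "classification")
  for (s in setdiff(.kb_sources, names(wide))) wide[[s]] <- NA_character_
  structure(
    list(assertions = assertions, assertions_wide = wide,
         frequencies = frequencies),
    class = "knowledge_base"
  )
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat(sprintf("<knowledge_base: %d assertions on %d variants, %d frequency records>\n",
              nrow(x$assertions), dplyr::n_distinct(x$assertions$key),
              nrow(x$frequencies)))
  invisible(x)
}

#' Load assertion and frequency tables into a knowledge base
#'
#' @param assertions_path Tab-delimited `chrom pos ref alt source
#'   classification`.
#' @param frequencies_path Optional tab-delimited `chrom pos ref alt af`.
#' @param chrom_style See [harmonize_chrom()].
#' @return A `knowledge_base`.
#' @export
load_knowledge_base <- function(assertions_path, frequencies_path = NULL,
                                chrom_style = "strip") {
  a <- readr::read_tsv(assertions_path, col_types = "cicccc", progress = FALSE) |>
    mutate(chrom = harmonize_chrom(.data$chrom, chrom_style))
  f <- NULL
  if (!is.null(frequencies_path)) {
    f <- readr::read_tsv(frequencies_path, col_types = "ciccd", progress = FALSE) |>
      mutate(chrom = harmonize_chrom(.data$chrom, chrom_style))
  }
  knowledge_base(a, f)
}

#' Classify variants against the knowledge base
#'
#' Implements the reporting consensus for ACMG class-4/5 screening. Per
#' variant key:
#' \itemize{
#'   \item absent from both the MVL and the ClinVar-like source:
#'     \code{NOT_IN_DB} (never reported);
#'   \item a source-level \code{CONFLICTING} record in MVL or the
#'     ClinVar-like source: \code{CONFLICTING};
#'   \item P/LP in the MVL or the ClinVar-like source, with any B/LB dissent
#'     among the three consensus sources (ClinVar-like, AUX1, AUX2):
#'     \code{CONFLICTING}; without dissent: \code{REPORTABLE_P_LP}
#'     (a missing AUX assertion counts as non-dissent);
#'   \item otherwise \code{VUS} if the best primary assertion is VUS, else
#'     \code{BENIGN}.
#' }
#'
#' @param variants A normalized, key-annotated variant tibble.
#' @param kb A `knowledge_base`.
#' @return `variants` with per-source columns (`MVL`, `CLINVAR`, `AUX1`,
#'   `AUX2`) and a `classification` column added.
#' @export
classify_variants <- function(variants, kb) {
  out <- variants |>
    left_join(kb$assertions_wide, by = "key")
  for (s in .kb_sources) if (!s %in% names(out)) out[[s]] <- NA_character_
  plp <- c("P", "LP")
  blb <- c("B", "LB")
  out |>
    mutate(
      classification = case_when(
        is.na(.data$MVL) & is.na(.data$CLINVAR) ~ "NOT_IN_DB",
        .data$MVL %in% "CONFLICTING" | .data$CLINVAR %in% "CONFLICTING" ~ "CONFLICTING",
        (.data$MVL %in% plp | .data$CLINVAR %in% plp) &
          (.data$CLINVAR %in% blb | .data$AUX1 %in% blb | .data$AUX2 %in% blb) ~
          "CONFLICTING",
        .data$MVL %in% plp | .data$CLINVAR %in% plp ~ "REPORTABLE_P_LP",
        .data$MVL %in% "VUS" | .data$CLINVAR %in% "VUS" ~ "VUS",
        TRUE ~ "BENIGN"
      )
    )
}

#' Look up population allele frequencies
#'
#' @param variants A key-annotated variant tibble.
#' @param kb A `knowledge_base`.
#' @return `variants` with an `af` column (`NA` when no record exists; absent
#'   records are treated as rare downstream).
#' @export
annotate_frequency <- function(variants, kb) {
  variants |>
    left_join(select(kb$frequencies, "key", "af"), by = "key")
}
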