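# The variant interpretation decision tree for asymptomatic newborns.
# Stages, in order: caller scope -> gene panel -> depth/quality ->
# population frequency -> knowledge-base classification -> inheritance-aware
# zygosity resolution. Every input variant ends up exactly once in the audit
# trail at the first stage that decided its fate; samples with no reportable
# event are closed automatically, everything else goes to manual review.

#' Pseudoautosomal regions (hg19)
#'
#' PAR1 and PAR2 on the X chromosome in 0-based half-open coordinates.
#' Hemizygous calling in males applies only outside these regions.
#'
#' @return An `interval_set`.
#' @export
par_regions_hg19 <- function() {
  interval_set(tibble(
    chrom = c("X", "X"),
    start = c(60000L, 154931043L),
    end = c(2699520L, 155260560L)
  ))
}

#' Triage configuration
#'
#' @param dp_min Minimum read depth (DP); calls below are dropped. Default 30.
#' @param qd_min Minimum quality-by-depth (QD); missing QD fails closed.
#'   Default 2.
#' @param af_max Population-frequency cutoff; variants with AF strictly below
#'   it (or with no frequency record, or in frequent genes) are retained.
#'   Default 0.01 (1 percent).
#' @param par Pseudoautosomal `interval_set`; default hg19 PAR1/PAR2.
#' @param max_indel Indel scope limit in bases. Default 15.
#' @return A `triage_config` list.
#' @export
triage_config <- function(dp_min = 30, qd_min = 2, af_max = 0.01,
                          par = par_regions_hg19(), max_indel = 15L) {
  stopifnot(dp_min >= 0, qd_min >= 0, af_max > 0, af_max <= 1)
  structure(list(dp_min = dp_min, qd_min = qd_min, af_max = af_max,
                 par = par, max_indel = max_indel),
            class = "triage_config")
}

#' Filter variants to the gene panel
#'
#' A variant survives iff its reference span falls entirely within some panel
#' gene's regions; survivors are annotated with that gene's symbol,
#' inheritance mode and frequent-gene flag. A variant contained in two genes'
#' regions is assigned to both and flagged ambiguous.
#'
#' @param variants Normalized, annotated variant tibble.
#' @param p A `panel`.
#' @return Surviving variants (possibly one row per matching gene) with
#'   `symbol`, `inheritance`, `frequent_gene`, `ambiguous` columns.
#' @export
filter_panel <- function(variants, p) {
  if (nrow(variants) == 0) {
    return(mutate(variants, symbol = character(0), inheritance = character(0),
                  frequent_gene = logical(0), ambiguous = logical(0)))
  }
  sp <- variant_span(variants)
  v <- variants |>
    mutate(.start = sp$start, .end = sp$end, .row = row_number())
  hits <- v |>
    inner_join(p$regions, by = "chrom", suffix = c("", ".r"),
               relationship = "many-to-many") |>
    filter(.data$.start >= .data$start, .data$.end <= .data$end) |>
    distinct(.data$.row, .data$symbol, .keep_all = TRUE) |>
    left_join(select(p$genes, "symbol", "inheritance", "frequent_gene"),
              by = "symbol") |>
    group_by(.data$.row) |>
    mutate(ambiguous = dplyr::n() > 1) |>
    ungroup()
  hits |>
    select(-"start", -"end", -".start", -".end", -".row") |>
    as_tibble()
}

#' Filter variants on depth and quality-by-depth
#'
#' A variant survives iff `depth >= dp_min` and QD is present and
#' `>= qd_min`. Missing DP or QD fails closed: a screening pipeline must not
#' pass unverifiable calls.
#'
#' @param variants Variant tibble.
#' @param dp_min,qd_min Thresholds (boundary passes).
#' @return Surviving rows.
#' @export
filter_quality <- function(variants, dp_min = 30, qd_min = 2) {
  filter(variants,
         !is.na(.data$depth), .data$depth >= dp_min,
         !is.na(.data$qd), .data$qd >= qd_min)
}

#' Filter variants on population frequency
#'
#' A variant survives iff its population allele frequency is strictly below
#' `af_max`, or its gene carries the frequent-gene flag (the frequent-gene
#' exception bypasses the frequency filter), or it has no frequency record
#' (rare by default: novel pathogenic variants must not be lost).
#'
#' @param variants Gene-annotated variant tibble.
#' @param kb A `knowledge_base` supplying the frequency table.
#' @param af_max Cutoff as a fraction; comparison is strict `<`.
#' @return Surviving rows, with an `af` column added.
#' @export
filter_frequency <- function(variants, kb, af_max = 0.01) {
  variants |>
    annotate_frequency(kb) |>
    filter(is.na(.data$af) | .data$af < af_max | .data$frequent_gene)
}

#' Resolve zygosity and inheritance into reportable events
#'
#' Applies the per-inheritance reporting rules to P/LP variants in one gene:
#' \itemize{
#'   \item AR: a homozygous variant is reported (`homozygous`); two or more
#'     distinct heterozygous variants form one `possible_compound_het` event
#'     (unphased); a single heterozygous variant is a carrier finding and is
#'     not reported;
#'   \item AD: every variant is reported (`dominant_het`), regardless of
#'     zygosity;
#'   \item XL, male: any variant outside the PAR is reported as `hemizygous`
#'     (diploid callers emit 0/1 on X for males, so het-called genotypes
#'     count); PAR variants follow the AR rule;
#'   \item XL, female: the AR rule;
#'   \item XL, sex unknown: fail open — one event with mechanism unset,
#'     flagged for review.
#' }
#'
#' @param variants Classified `REPORTABLE_P_LP` variants of a single gene
#'   (columns as produced by the upstream filters).
#' @param inheritance `"AR"`, `"AD"` or `"XL"`.
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @param par Pseudoautosomal `interval_set`.
#' @return Tibble of events: `gene`, `mechanism`, `n_variants`, `keys`
#'   (list-column), `variants` (list-column of the contributing rows),
#'   `note`.
#' @export
resolve_zygosity <- function(variants, inheritance, sex = "unknown",
                             par = par_regions_hg19()) {
  if (nrow(variants) == 0) return(.empty_events())
  gene <- variants$symbol[1]
  if (inheritance == "AD") {
    return(.events_per_variant(variants, gene, "dominant_het"))
  }
  if (inheritance == "AR") {
    return(.ar_rule(variants, gene))
  }
  # XL
  if (sex == "male") {
    in_par <- variants_in_set(variants, par)
    ev <- bind_rows(
      .events_per_variant(variants[!in_par, , drop = FALSE], gene, "hemizygous"),
      .ar_rule(variants[in_par, , drop = FALSE], gene)
    )
    return(ev)
  }
  if (sex == "female") {
    return(.ar_rule(variants, gene))
  }
  # unknown sex on an X-linked gene: never silently drop
  .one_event(variants, gene, NA_character_, note = "sex-unknown-review")
}

.empty_events <- function() {
  tibble(gene = character(), mechanism = character(), n_variants = integer(),
         keys = list(), variants = list(), note = character())
}

.one_event <- function(v, gene, mechanism, note = NA_character_) {
  if (nrow(v) == 0) return(.empty_events())
  tibble(gene = gene, mechanism = mechanism, n_variants = nrow(v),
         keys = list(unique(v$key)), variants = list(v), note = note)
}

.events_per_variant <- function(v, gene, mechanism) {
  if (nrow(v) == 0) return(.empty_events())
  v <- distinct(v, .data$key, .keep_all = TRUE)
  bind_rows(purrr::map(seq_len(nrow(v)), function(i) {
    .one_event(v[i, , drop = FALSE], gene, mechanism)
  }))
}

.ar_rule <- function(v, gene) {
  if (nrow(v) == 0) return(.empty_events())
  v <- distinct(v, .data$key, .keep_all = TRUE)
  homs <- filter(v, .data$genotype %in% c("hom_alt", "hemi"))
  hets <- filter(v, .data$genotype == "het")
  ev <- .events_per_variant(homs, gene, "homozygous")
  if (nrow(hets) >= 2) {
    ev <- bind_rows(ev, .one_event(hets, gene, "possible_compound_het"))
  }
  ev
}

#' Run the full variant interpretation decision tree on one sample
#'
#' @param variants The sample's variant table (from [read_vcf()]), or a path
#'   to a VCF file.
#' @param p A `panel`.
#' @param kb A `knowledge_base`.
#' @param meta One-row sample metadata: `sample_id`, `sex`
#'   (`male`/`female`/`unknown`), optionally `plate_position`, `batch_id`.
#' @param config A [triage_config()].
#' @return A `triage_result`: list with `sample_id`, `status`
#'   (`auto_closed` when no events, else `review_required`), `events` (tibble
#'   of reportable events), `audit` (one row per input variant at its terminal
#'   stage), `vus` (variants of uncertain significance, stored but neither
#'   reviewed nor reported).
#' @export
run_decision_tree <- function(variants, p, kb, meta, config = triage_config()) {
  if (is.character(variants)) {
    variants <- read_vcf(variants, meta$sample_id, max_indel = config$max_indel)
  }
  sample_id <- meta$sample_id
  sex <- meta$sex %||% "unknown"
  audit <- list()
  drop <- function(keys, stage, reason, ambiguous = FALSE) {
    if (length(keys) == 0) return(NULL)
    tibble(key = unique(keys), stage = stage, kept = FALSE, reason = reason,
           ambiguous = ambiguous)
  }

  v0 <- distinct(variants, .data$key, .keep_all = TRUE)

  # stage 1: caller scope (1-15 bp indels, SNVs)
  audit$scope <- drop(v0$key[v0$out_of_scope], "scope", "indel-over-15bp")
  v1 <- filter(v0, !.data$out_of_scope)

  # stage 2: gene panel
  v2 <- filter_panel(v1, p)
  audit$panel <- drop(setdiff(v1$key, v2$key), "panel", "off-panel")

  # stage 3: depth / quality-by-depth
  v3 <- filter_quality(v2, config$dp_min, config$qd_min)
  dropped_q <- v2 |>
    filter(!.data$key %in% v3$key) |>
    distinct(.data$key, .keep_all = TRUE) |>
    mutate(reason = case_when(
      is.na(.data$depth) | .data$depth < config$dp_min ~ "low-depth",
      is.na(.data$qd) ~ "no-QD",
      TRUE ~ "low-QD"
    ))
  audit$quality <- if (nrow(dropped_q) == 0) NULL else
    tibble(key = dropped_q$key, stage = "quality", kept = FALSE,
           reason = dropped_q$reason, ambiguous = FALSE)

  # stage 4: population frequency (frequent-gene exception applies)
  v4 <- filter_frequency(v3, kb, config$af_max)
  audit$frequency <- drop(setdiff(v3$key, v4$key), "frequency", "common-variant")

  # stage 5: knowledge-base classification
  v5 <- classify_variants(v4, kb)
  vus <- filter(v5, .data$classification == "VUS") |>
    distinct(.data$key, .keep_all = TRUE)
  cls_drop <- v5 |>
    filter(.data$classification != "REPORTABLE_P_LP") |>
    distinct(.data$key, .keep_all = TRUE) |>
    mutate(reason = c(VUS = "vus-stored", BENIGN = "benign",
                      NOT_IN_DB = "not-in-database",
                      CONFLICTING = "conflicting-assertions")[.data$classification])
  audit$classification <- if (nrow(cls_drop) == 0) NULL else
    tibble(key = cls_drop$key, stage = "classification", kept = FALSE,
           reason = cls_drop$reason, ambiguous = FALSE)
  v6 <- filter(v5, .data$classification == "REPORTABLE_P_LP")

  # stage 6: zygosity / inheritance resolution, per annotated gene
  events <- .empty_events()
  if (nrow(v6) > 0) {
    events <- v6 |>
      group_by(.data$symbol) |>
      dplyr::group_split() |>
      purrr::map(function(g) {
        resolve_zygosity(g, inheritance = g$inheritance[1], sex = sex,
                         par = config$par)
      }) |>
      bind_rows()
  }
  event_keys <- unique(unlist(events$keys))
  kept_keys <- intersect(unique(v6$key), event_keys)
  amb <- v6 |> group_by(.data$key) |> summarise(amb = any(.data$ambiguous))
  audit$zygosity_kept <- if (length(kept_keys) == 0) NULL else {
    mech <- purrr::map_chr(kept_keys, function(k) {
      i <- which(purrr::map_lgl(events$keys, ~ k %in% .x))[1]
      events$mechanism[i] %||% NA_character_
    })
    tibble(key = kept_keys, stage = "zygosity", kept = TRUE,
           reason = if_else(is.na(mech), "sex-unknown-review", mech),
           ambiguous = amb$amb[match(kept_keys, amb$key)])
  }
  audit$zygosity_dropped <- drop(setdiff(unique(v6$key), event_keys),
                                 "zygosity", "carrier-not-reported")

  audit_tbl <- bind_rows(audit)
  if (nrow(audit_tbl) == 0) {
    audit_tbl <- tibble(key = character(), stage = character(),
                        kept = logical(), reason = character(),
                        ambiguous = logical())
  }
  audit_tbl <- audit_tbl |>
    arrange(match(.data$key, v0$key)) |>
    mutate(sample_id = sample_id, .before = 1)

  structure(
    list(sample_id = sample_id,
         status = if (nrow(events) == 0) "auto_closed" else "review_required",
         events = events,
         audit = audit_tbl,
         vus = vus),
    class = "triage_result"
  )
}

#' @export
print.triage_result <- function(x, ...) {
  cat(sprintf("<triage_result %s: %s, %d event(s), %d VUS stored, %d audited>\n",
              x$sample_id, x$status, nrow(x$events), nrow(x$vus),
              nrow(x$audit)))
  if (nrow(x$events) > 0) {
    print(select(x$events, "gene", "mechanism", "n_variants"))
  }
  invisible(x)
}

#' @rdname run_decision_tree
#' @param x A `triage_result`.
#' @param ... Unused.
#' @method tidy triage_result
#' @export
tidy.triage_result <- function(x, ...) {
  if (nrow(x$events) == 0) {
    return(tibble(sample_id = character(), gene = character(),
                  mechanism = character(), key = character()))
  }
  x$events |>
    mutate(sample_id = x$sample_id) |>
    select("sample_id", "gene", "mechanism", "keys") |>
    tidyr::unnest_longer("keys", values_to = "key")
}

#' @rdname run_decision_tree
#' @method glance triage_result
#' @export
glance.triage_result <- function(x, ...) {
  tibble(sample_id = x$sample_id, status = x$status,
         n_events = nrow(x$events), n_vus = nrow(x$vus),
         n_audited = nrow(x$audit))
}
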