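# Gene panel: per-gene inheritance mode, frequent-gene and CNV flags, targeted
# regions (exons +/- flank) and the union target-of-interest (TOI).

#' Construct a panel object
#'
#' @param genes Tibble with columns `symbol`, `inheritance` (`AR`/`AD`/`XL`),
#'   `frequent_gene` (logical), optionally `cnv_flagged` (logical: gene harbors
#'   reported CNV/SV mechanisms, outside small-variant calling scope).
#' @param regions Tibble `chrom, start, end, symbol` (0-based half-open).
#' @param version Panel version label (e.g. `"v1"`).
#' @return A `panel` object: list with `genes`, `regions` (merged per gene),
#'   `toi` (the merged union `interval_set`), `version`.
#' @export
panel <- function(genes, regions, version = "v1") {
  genes <- as_tibble(genes)
  regions <- as_tibble(regions)
  if (anyDuplicated(genes$symbol)) {
    abort(sprintf("duplicate gene symbol(s) in panel: %s",
                  paste(unique(genes$symbol[duplicated(genes$symbol)]), collapse = ", ")))
  }
  bad_mode <- setdiff(unique(genes$inheritance), c("AR", "AD", "XL"))
  if (length(bad_mode) > 0) {
    abort(sprintf("unknown inheritance mode(s): %s", paste(bad_mode, collapse = ", ")))
  }
  orphan <- setdiff(regions$symbol, genes$symbol)
  if (length(orphan) > 0) {
    abort(sprintf("BED region gene(s) absent from panel table: %s",
                  paste(orphan, collapse = ", ")))
  }
  missing_reg <- setdiff(genes$symbol, regions$symbol)
  if (length(missing_reg) > 0) {
    abort(sprintf("panel gene(s) without regions: %s",
                  paste(missing_reg, collapse = ", ")))
  }
  if (!"cnv_flagged" %in% names(genes)) genes$cnv_flagged <- FALSE
  # merge regions within each gene (flanked exons may overlap)
  regions <- regions |>
    group_by(.data$symbol) |>
    dplyr::group_modify(function(df, key) {
      as_tibble(interval_set(df))
    }) |>
    ungroup() |>
    select("chrom", "start", "end", "symbol") |>
    arrange(.chrom_rank(.data$chrom), .data$start)
  structure(
    list(genes = genes, regions = regions,
         toi = interval_set(regions[, c("chrom", "start", "end")]),
         version = version),
    class = "panel"
  )
}

#' @export
print.panel <- function(x, ...) {
  cat(sprintf("<panel %s: %d genes, %d regions, TOI %d bp>\n",
              x$version, nrow(x$genes), nrow(x$regions),
              interval_total_length(x$toi)))
  print(count(x$genes, .data$inheritance))
  invisible(x)
}

#' Load a panel from its definition table and BED4 region file
#'
#' @param path Tab-delimited table with columns `symbol`, `inheritance`
#'   (`AR`/`AD`/`XL`), `frequent_gene` (0/1), optionally `cnv_flagged` (0/1).
#' @param bed_path BED4 file whose 4th column carries the gene symbol.
#' @param version Panel version label.
#' @param chrom_style See [harmonize_chrom()].
#' @return A `panel` object.
#' @export
load_panel <- function(path, bed_path, version = "v1", chrom_style = "strip") {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    symbol = "c", inheritance = "c", frequent_gene = "i",
    .default = readr::col_guess()
  ), progress = FALSE)
  req <- c("symbol", "inheritance", "frequent_gene")
  if (!all(req %in% names(tab))) {
    abort(sprintf("panel table '%s' must have columns %s", path,
                  paste(req, collapse = ", ")))
  }
  genes <- tab |>
    mutate(frequent_gene = as.logical(.data$frequent_gene),
           cnv_flagged = if ("cnv_flagged" %in% names(tab)) {
             as.logical(.data$cnv_flagged)
           } else FALSE)
  regions <- read_bed4(bed_path, chrom_style = chrom_style)
  panel(genes, regions, version = version)
}

#' Write a panel's definition table and BED4 regions
#'
#' @param p A `panel`.
#' @param path,bed_path Output paths for the gene table (TSV) and regions
#'   (BED4).
#' @return A named list of the two paths, invisibly.
#' @export
write_panel <- function(p, path, bed_path) {
  genes <- p$genes |>
    mutate(frequent_gene = as.integer(.data$frequent_gene),
           cnv_flagged = as.integer(.data$cnv_flagged))
  readr::write_tsv(genes, path, progress = FALSE)
  write_bed(p$regions, bed_path)
  invisible(list(table = path, bed = bed_path))
}

#' Revise a panel: remove and add genes
#'
#' Builds the next panel version from an existing one, e.g. a 359-gene panel
#' minus 15 removals plus 61 additions yields 405 genes.
#'
#' @param p A `panel`.
#' @param remove Character vector of symbols to drop.
#' @param add_genes,add_regions Gene rows and their regions to append, in the
#'   formats accepted by [panel()].
#' @param version Version label for the revised panel.
#' @return A new `panel`.
#' @export
revise_panel <- function(p, remove = character(0), add_genes = NULL,
                         add_regions = NULL, version = "v2") {
  unknown <- setdiff(remove, p$genes$symbol)
  if (length(unknown) > 0) {
    abort(sprintf("cannot remove gene(s) not in panel: %s",
                  paste(unknown, collapse = ", ")))
  }
  genes <- filter(p$genes, !.data$symbol %in% remove)
  regions <- filter(p$regions, !.data$symbol %in% remove)
  if (!is.null(add_genes)) {
    genes <- bind_rows(genes, as_tibble(add_genes))
    regions <- bind_rows(regions, as_tibble(add_regions))
  }
  panel(genes, regions, version = version)
}

#' Gene-level summary of a panel
#'
#' @param p A `panel`.
#' @return One-row tibble: gene counts overall, per inheritance mode, number
#'   and percentage of CNV-flagged genes, and TOI length.
#' @export
panel_summary <- function(p) {
  tibble(
    version = p$version,
    n_genes = nrow(p$genes),
    n_ar = sum(p$genes$inheritance == "AR"),
    n_ad = sum(p$genes$inheritance == "AD"),
    n_xl = sum(p$genes$inheritance == "XL"),
    n_frequent = sum(p$genes$frequent_gene),
    n_cnv_flagged = sum(p$genes$cnv_flagged),
    pct_cnv_flagged = 100 * sum(p$genes$cnv_flagged) / nrow(p$genes),
    toi_length = interval_total_length(p$toi)
  )
}
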