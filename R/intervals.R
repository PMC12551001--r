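# Interval sets: strand-agnostic genomic region collections (TOI, HCR, PAR)
# stored merged per chromosome, 0-based half-open throughout. IRanges does the
# set algebra; the user-facing container is a tibble.

#' Build an interval set
#'
#' An interval set is a tibble with columns `chrom`, `start`, `end`
#' (0-based half-open) in which no two rows on the same chromosome overlap or
#' abut. Input rows are merged to restore that invariant.
#'
#' @param x A data frame with columns `chrom`, `start`, `end`.
#' @return A merged interval set (class `interval_set`, a tibble).
#' @examples
#' interval_set(data.frame(chrom = "1", start = c(10, 15), end = c(20, 30)))
#' @export
interval_set <- function(x = NULL) {
  if (is.null(x) || nrow(x) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer())
    class(out) <- c("interval_set", class(out))
    return(out)
  }
  x <- as_tibble(x)[, c("chrom", "start", "end")]
  if (any(!nzchar(x$chrom)) || any(is.na(x$chrom))) {
    abort("interval chromosomes must be non-empty")
  }
  if (any(x$start >= x$end)) {
    abort("interval start must be < end (0-based half-open)")
  }
  merged <- x |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end)) |>
    group_by(.data$chrom) |>
    group_modify_reduce() |>
    ungroup() |>
    arrange(.chrom_rank(.data$chrom), .data$start)
  class(merged) <- c("interval_set", class(merged))
  merged
}

# Merge overlapping/abutting intervals within one chromosome via IRanges.
group_modify_reduce <- function(grouped) {
  dplyr::group_modify(grouped, function(df, key) {
    ir <- IRanges::reduce(IRanges::IRanges(start = df$start + 1L, end = df$end))
    tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  })
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("<interval_set: %d interval(s), total length %d>\n",
              nrow(x), interval_total_length(x)))
  NextMethod()
}

#' Total length of an interval set
#'
#' @param s An `interval_set`.
#' @return Sum of `end - start` over all stored intervals.
#' @export
interval_total_length <- function(s) {
  if (nrow(s) == 0) return(0L)
  sum(s$end - s$start)
}

#' Intersect two interval sets
#'
#' @param a,b Interval sets.
#' @return The `interval_set` of regions present in both `a` and `b`.
#' @export
interval_intersect <- function(a, b) {
  chroms <- intersect(unique(a$chrom), unique(b$chrom))
  if (length(chroms) == 0) return(interval_set())
  pieces <- purrr::map(chroms, function(ch) {
    ia <- dplyr::filter(a, .data$chrom == ch)
    ib <- dplyr::filter(b, .data$chrom == ch)
    ir <- IRanges::intersect(
      IRanges::IRanges(start = ia$start + 1L, end = ia$end),
      IRanges::IRanges(start = ib$start + 1L, end = ib$end)
    )
    tibble(chrom = ch, start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  })
  interval_set(bind_rows(pieces))
}

#' Union of two interval sets
#'
#' @param a,b Interval sets.
#' @return The merged `interval_set` covering `a` and `b`.
#' @export
interval_union <- function(a, b) {
  interval_set(bind_rows(as_tibble(a), as_tibble(b)))
}

#' Test whether spans are fully contained in an interval set
#'
#' @param s An `interval_set`.
#' @param chrom,start,end Vectors describing query spans (0-based half-open).
#' @return Logical vector: `TRUE` where the whole span lies inside one stored
#'   interval of `s` (stored intervals are merged, so containment in the set
#'   equals containment in a single row).
#' @export
interval_contains <- function(s, chrom, start, end) {
  if (length(chrom) == 0) return(logical(0))
  q <- tibble(.qid = seq_along(chrom), chrom = chrom, start = start, end = end)
  if (nrow(s) == 0) return(rep(FALSE, nrow(q)))
  hits <- q |>
    inner_join(as_tibble(s), by = "chrom", suffix = c("", ".s"),
               relationship = "many-to-many") |>
    filter(.data$start >= .data$start.s, .data$end <= .data$end.s) |>
    pull(".qid")
  q$.qid %in% hits
}

#' Read a BED file as an interval set
#'
#' Accepts 3+ column BED (0-based half-open); extra columns are ignored here
#' (see [read_bed4()] for gene-annotated regions). Gzip input is accepted.
#'
#' @param path Path to a BED file.
#' @param chrom_style Chromosome-label convention passed to
#'   [harmonize_chrom()].
#' @return An `interval_set`.
#' @export
read_bed <- function(path, chrom_style = "strip") {
  df <- .read_bed_table(path)
  if (nrow(df) == 0) return(interval_set())
  if (any(df$start >= df$end)) {
    abort(sprintf("malformed BED '%s': start >= end", path))
  }
  interval_set(tibble(
    chrom = harmonize_chrom(df$chrom, chrom_style),
    start = df$start, end = df$end
  ))
}

#' Read a BED4 file (regions annotated with a gene symbol)
#'
#' @inheritParams read_bed
#' @return A tibble with columns `chrom`, `start`, `end`, `symbol`
#'   (not merged: rows keep their gene annotation).
#' @export
read_bed4 <- function(path, chrom_style = "strip") {
  df <- .read_bed_table(path, n_min = 4)
  if (any(df$start >= df$end)) {
    abort(sprintf("malformed BED '%s': start >= end", path))
  }
  tibble(
    chrom = harmonize_chrom(df$chrom, chrom_style),
    start = df$start, end = df$end, symbol = df$name
  )
}

.read_bed_table <- function(path, n_min = 3) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  df <- tryCatch(
    readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                    comment = "#", progress = FALSE),
    error = function(e) abort(sprintf("cannot read BED file '%s': %s", path, conditionMessage(e)))
  )
  if (nrow(df) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character()))
  }
  if (ncol(df) < n_min) {
    abort(sprintf("BED file '%s' has %d column(s); at least %d required",
                  path, ncol(df), n_min))
  }
  names(df)[seq_len(min(ncol(df), length(cols)))] <-
    cols[seq_len(min(ncol(df), length(cols)))]
  start <- suppressWarnings(as.integer(df$start))
  end <- suppressWarnings(as.integer(df$end))
  if (anyNA(start) || anyNA(end)) {
    abort(sprintf("malformed BED '%s': non-numeric coordinates", path))
  }
  tibble(chrom = df$chrom, start = start, end = end,
         name = if ("name" %in% names(df)) df$name else NA_character_)
}

#' Write an interval set to a BED file
#'
#' @param s An `interval_set` (or a BED4-style tibble with a `symbol` column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(s, path) {
  df <- as_tibble(s)
  cols <- intersect(c("chrom", "start", "end", "symbol"), names(df))
  readr::write_tsv(df[, cols], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
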