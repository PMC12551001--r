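# Shared helpers: chromosome naming, variant keys, seeded RNG scopes.

# Canonical chromosome order used when sorting records for output.
.chrom_levels <- c(as.character(1:22), "X", "Y", "MT")

#' Harmonize chromosome labels
#'
#' Chromosome naming differs between files ("chr1" vs "1"). All internal
#' tables use a single convention; the default strips any leading "chr".
#'
#' @param chrom Character vector of chromosome labels.
#' @param style Either `"strip"` (drop a leading `"chr"`, the default) or
#'   `"keep"` (leave labels untouched).
#' @return Character vector of harmonized labels.
#' @export
harmonize_chrom <- function(chrom, style = c("strip", "keep")) {
  style <- match.arg(style)
  if (style == "strip") sub("^chr", "", chrom) else chrom
}

.chrom_rank <- function(chrom) {
  r <- match(chrom, .chrom_levels)
  ifelse(is.na(r), length(.chrom_levels) + as.integer(factor(chrom)), r)
}

.is_sex_chrom <- function(chrom) chrom %in% c("X", "Y")

#' Variant key
#'
#' A canonical `chrom:pos:ref:alt` string identifying a normalized allele.
#'
#' @param chrom,pos,ref,alt Vectors of the four key components.
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# Run code under a locally-set RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation: one user-facing integer seeds every
# generator; offsets keep streams independent and below 2^31.
sub_seed <- function(seed, offset) {
  (as.integer(seed) + 7919L * as.integer(offset)) %% 2147483629L
}
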