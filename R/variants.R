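# Variant I/O and normalization. A variant table is a tibble with one row per
# (sample, site, alternate allele): multiallelic records are decomposed at read
# time and alleles are trimmed to a canonical minimal representation so that
# triage and benchmarking match on plain (chrom, pos, ref, alt) keys.

.variant_cols <- c("chrom", "pos", "ref", "alt", "genotype", "depth",
                   "ad_ref", "ad_alt", "qd", "sample_id")

#' Empty variant table
#'
#' @return A zero-row tibble with the canonical variant columns.
#' @export
variant_table <- function() {
  tibble(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    genotype = character(), depth = integer(), ad_ref = integer(),
    ad_alt = integer(), qd = double(), sample_id = character()
  )
}

#' Read one sample's small-variant calls from a VCF
#'
#' Reads a VCF (v4.x, optionally gzipped) through `vcfR`, extracts the GT, DP
#' and AD genotype fields plus the quality-by-depth score (QD, taken from
#' FORMAT when present, else INFO), decomposes multiallelic sites into one row
#' per called alternate allele, and normalizes allele representations
#' (see [normalize_variants()]). Sites where the sample carries no alternate
#' allele are dropped. Missing DP/AD/QD become `NA` (never zero) so that
#' depth- and quality-based filters fail closed.
#'
#' @param path Path to a VCF file.
#' @param sample_id Sample column to extract; must be present in the header.
#' @param chrom_style Chromosome-label convention (see [harmonize_chrom()]).
#' @param max_indel Indels with more than this many inserted/deleted bases are
#'   flagged `out_of_scope` (retained in the table, excluded from triage and
#'   benchmarking); the default mirrors the 1-15 bp caller scope.
#' @return A tibble of normalized variant calls with columns
#'   `chrom, pos, ref, alt, genotype, depth, ad_ref, ad_alt, qd, sample_id,
#'   key, type, out_of_scope`.
#' @export
read_vcf <- function(path, sample_id, chrom_style = "strip", max_indel = 15L) {
  if (!file.exists(path)) abort(sprintf("VCF file not found: '%s'", path))
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort(sprintf("malformed VCF '%s': %s", path, conditionMessage(e)))
  )
  samples <- colnames(v@gt)[-1]
  if (!sample_id %in% samples) {
    abort(sprintf("sample '%s' absent from VCF header of '%s' (samples: %s)",
                  sample_id, path, paste(samples, collapse = ", ")))
  }
  if (nrow(v@fix) == 0) return(annotate_variants(variant_table(), max_indel))

  fix <- as_tibble(as.data.frame(v@fix, stringsAsFactors = FALSE))
  gt_gt <- vcfR::extract.gt(v, element = "GT")[, sample_id]
  gt_dp <- suppressWarnings(
    as.integer(vcfR::extract.gt(v, element = "DP")[, sample_id]))
  gt_ad <- vcfR::extract.gt(v, element = "AD")[, sample_id]
  qd_fmt <- tryCatch(vcfR::extract.gt(v, element = "QD")[, sample_id],
                     error = function(e) rep(NA_character_, nrow(fix)))
  qd_info <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = "QD")))
  qd <- suppressWarnings(as.numeric(qd_fmt))
  qd <- ifelse(is.na(qd), qd_info, qd)

  rows <- purrr::map(seq_len(nrow(fix)), function(i) {
    .decompose_site(
      chrom = harmonize_chrom(fix$CHROM[i], chrom_style),
      pos = as.integer(fix$POS[i]), ref = fix$REF[i], alt = fix$ALT[i],
      gt = gt_gt[i], dp = gt_dp[i], ad = gt_ad[i], qd = qd[i],
      sample_id = sample_id
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) return(annotate_variants(variant_table(), max_indel))
  out <- normalize_variants(out)
  annotate_variants(out, max_indel)
}

# One VCF data line -> zero or more decomposed variant rows for one sample.
.decompose_site <- function(chrom, pos, ref, alt, gt, dp, ad, qd, sample_id) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NULL)
  alts <- strsplit(alt, ",", fixed = TRUE)[[1]]
  alleles <- strsplit(gt, "[/|]")[[1]]
  alleles <- suppressWarnings(as.integer(alleles[alleles != "."]))
  if (length(alleles) == 0) return(NULL)
  ploidy <- length(alleles)
  ads <- if (is.na(ad)) NULL else suppressWarnings(
    as.integer(strsplit(ad, ",", fixed = TRUE)[[1]]))
  called <- sort(unique(alleles[alleles > 0]))
  if (length(called) == 0) return(NULL)
  purrr::map(called, function(ai) {
    n_alt <- sum(alleles == ai)
    geno <- if (ploidy == 1) {
      if (.is_sex_chrom(chrom)) "hemi" else "hom_alt"
    } else if (n_alt >= 2) "hom_alt" else "het"
    tibble(
      chrom = chrom, pos = pos, ref = ref, alt = alts[ai],
      genotype = geno, depth = dp,
      ad_ref = if (is.null(ads)) NA_integer_ else ads[1],
      ad_alt = if (is.null(ads) || length(ads) < ai + 1) NA_integer_ else ads[ai + 1],
      qd = qd, sample_id = sample_id
    )
  }) |> bind_rows()
}

#' Normalize variant representations
#'
#' Trims the shared right suffix, then the shared left prefix of `ref`/`alt`,
#' leaving one anchor base for indels, and adjusts `pos` for trimmed prefix
#' bases. Idempotent: normalizing an already-minimal record is a no-op. This is
#' string trimming only (no reference-genome-aware left alignment).
#'
#' @param variants A variant tibble (one alternate allele per row).
#' @return The tibble with `pos`, `ref`, `alt` minimized.
#' @export
normalize_variants <- function(variants) {
  if (nrow(variants) == 0) return(variants)
  ref <- variants$ref
  alt <- variants$alt
  pos <- as.integer(variants$pos)
  if (any(ref == alt)) abort("degenerate variant: ref equals alt")
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    tr <- nr > 1L & na > 1L &
      substr(ref, nr, nr) == substr(alt, na, na)
    if (!any(tr)) break
    ref[tr] <- substr(ref[tr], 1L, nchar(ref[tr]) - 1L)
    alt[tr] <- substr(alt[tr], 1L, nchar(alt[tr]) - 1L)
  }
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    tl <- nr > 1L & na > 1L & substr(ref, 1, 1) == substr(alt, 1, 1)
    if (!any(tl)) break
    ref[tl] <- substr(ref[tl], 2L, nchar(ref[tl]))
    alt[tl] <- substr(alt[tl], 2L, nchar(alt[tl]))
    pos[tl] <- pos[tl] + 1L
  }
  if (any(ref == alt)) abort("degenerate variant after trimming: ref equals alt")
  variants$ref <- ref
  variants$alt <- alt
  variants$pos <- pos
  variants
}

#' Annotate a variant table with key, type and scope flags
#'
#' @param variants A normalized variant tibble.
#' @param max_indel Scope limit on inserted/deleted bases.
#' @return The tibble with `key`, `type` (`"SNP"`/`"INDEL"`) and
#'   `out_of_scope` columns added.
#' @export
annotate_variants <- function(variants, max_indel = 15L) {
  variants |>
    mutate(
      key = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt),
      type = if_else(nchar(.data$ref) == 1L & nchar(.data$alt) == 1L,
                     "SNP", "INDEL"),
      indel_len = abs(nchar(.data$ref) - nchar(.data$alt)),
      out_of_scope = .data$type == "INDEL" & .data$indel_len > max_indel
    ) |>
    select(-"indel_len")
}

# 0-based half-open span affected by a variant on the reference.
variant_span <- function(variants) {
  tibble(
    chrom = variants$chrom,
    start = as.integer(variants$pos) - 1L,
    end = as.integer(variants$pos) - 1L + nchar(variants$ref)
  )
}

#' Are variants contained in an interval set?
#'
#' A variant is contained when its reference-affected span (VCF `pos`
#' converted to 0-based, length of `ref`) lies fully within the set.
#'
#' @param variants A normalized variant tibble.
#' @param s An `interval_set`.
#' @return Logical vector, one element per row of `variants`.
#' @export
variants_in_set <- function(variants, s) {
  sp <- variant_span(variants)
  interval_contains(s, sp$chrom, sp$start, sp$end)
}

#' Write a variant table to a VCF file
#'
#' Emits a minimal well-formed single-sample VCF v4.2 (uncompressed) with
#' GT:DP:AD genotype fields and QD in INFO, sorted by chromosome and position.
#' Used by the fixture generators; round-trips through [read_vcf()].
#'
#' @param variants A variant tibble for one sample.
#' @param path Output path.
#' @param sample_id Sample column name; defaults to the table's `sample_id`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, sample_id = NULL) {
  sample_id <- sample_id %||%
    (if (nrow(variants) > 0) variants$sample_id[1] else "SAMPLE")
  v <- variants |> arrange(.chrom_rank(.data$chrom), .data$pos)
  contigs <- unique(v$chrom)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=neoscreen-synth",
    sprintf("##contig=<ID=%s>", contigs),
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Variant Confidence by Depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic Depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_id), collapse = "\t")
  )
  body <- if (nrow(v) == 0) character(0) else {
    gt <- c(het = "0/1", hom_alt = "1/1", hemi = "1")[v$genotype]
    ad <- ifelse(is.na(v$ad_ref) | is.na(v$ad_alt), ".",
                 paste(v$ad_ref, v$ad_alt, sep = ","))
    dp <- ifelse(is.na(v$depth), ".", as.character(v$depth))
    info <- ifelse(is.na(v$qd), ".", sprintf("QD=%.2f", v$qd))
    paste(v$chrom, v$pos, ".", v$ref, v$alt, "50", "PASS", info,
          "GT:DP:AD", paste(gt, dp, ad, sep = ":"), sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}
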