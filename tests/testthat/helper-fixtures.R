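# Test helpers: hand-built fixtures and independent oracles. The oracles are
# deliberately naive (nested loops, manual interpolation) and share no code
# with the implementation they check.

# Write a VCF from raw data lines (header supplied here).
vcf_text <- function(lines, sample = "S1", path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"qd\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample)
  )
  writeLines(c(header, lines), path)
  path
}

# A small hand-built panel: two AR genes, one AD gene, one XL gene on X
# (outside the PARs), all with a single wide region.
tiny_panel <- function() {
  genes <- tibble::tibble(
    symbol = c("AR1", "AR2", "AD1", "XL1"),
    inheritance = c("AR", "AR", "AD", "XL"),
    frequent_gene = c(FALSE, TRUE, FALSE, FALSE)
  )
  regions <- tibble::tibble(
    chrom = c("1", "2", "3", "X"),
    start = c(1000L, 5000L, 9000L, 5000000L),
    end = c(2000L, 6000L, 10000L, 5001000L),
    symbol = genes$symbol
  )
  panel(genes, regions)
}

# Hand-built call rows with sensible defaults.
call_row <- function(chrom, pos, ref = "A", alt = "G", genotype = "het",
                     depth = 100L, qd = 15, sample_id = "S1",
                     ad_alt = NULL) {
  ad_alt <- ad_alt %||% as.integer(round(depth * if (genotype == "het") 0.5 else 1))
  annotate_variants(tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    genotype = genotype, depth = as.integer(depth),
    ad_ref = as.integer(depth) - ad_alt, ad_alt = ad_alt, qd = qd,
    sample_id = sample_id
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force matcher: exhaustive all-pairs comparison on
# (chrom, pos, ref, alt, genotype), per stratum.
brute_match <- function(test, truth) {
  t_matched <- rep(FALSE, nrow(test))
  g_matched <- rep(FALSE, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    for (j in seq_len(nrow(test))) {
      if (truth$chrom[i] == test$chrom[j] && truth$pos[i] == test$pos[j] &&
          truth$ref[i] == test$ref[j] && truth$alt[i] == test$alt[j] &&
          truth$genotype[i] == test$genotype[j]) {
        g_matched[i] <- TRUE
        t_matched[j] <- TRUE
      }
    }
  }
  one <- function(str) {
    ti <- if (str == "ALL") rep(TRUE, nrow(test)) else test$type == str
    gi <- if (str == "ALL") rep(TRUE, nrow(truth)) else truth$type == str
    tibble::tibble(stratum = str, tp = sum(g_matched[gi]),
                   fp = sum(!t_matched[ti]), fn = sum(!g_matched[gi]))
  }
  dplyr::bind_rows(one("SNP"), one("INDEL"), one("ALL"))
}

# Independent type-7 quantile: manual linear interpolation between order
# statistics.
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

oracle_fence <- function(x, direction) {
  med <- oracle_quantile(x, 0.5)
  iqr <- oracle_quantile(x, 0.75) - oracle_quantile(x, 0.25)
  if (direction == "lower_bound") med - 1.5 * iqr else med + 1.5 * iqr
}

# Random normalized variant set for property tests (distinct positions so
# keys never collide).
random_calls <- function(n, sample_id = "S", chrom = "1") {
  pos <- sort(sample.int(100000, n)) * 30L
  is_indel <- stats::runif(n) < 0.4
  ref <- vapply(seq_len(n), function(i) {
    if (!is_indel[i]) return(sample(c("A", "C", "G", "T"), 1))
    paste(sample(c("A", "C", "G", "T"), sample(2:10, 1), replace = TRUE),
          collapse = "")
  }, character(1))
  alt <- vapply(seq_len(n), function(i) {
    if (!is_indel[i]) return(sample(setdiff(c("A", "C", "G", "T"), ref[i]), 1))
    substr(ref[i], 1, 1)
  }, character(1))
  annotate_variants(normalize_variants(tibble::tibble(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    genotype = sample(c("het", "hom_alt"), n, replace = TRUE),
    depth = sample(31:200, n, replace = TRUE),
    ad_ref = 50L, ad_alt = 50L, qd = 20, sample_id = sample_id
  )))
}
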