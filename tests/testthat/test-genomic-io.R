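# VCF reading/decomposition, allele normalization, BED interval sets.

test_that("read_vcf maps fields, decomposes multiallelics and drops ref calls", {
  path <- vcf_text(c(
    "chr1\t100\t.\tA\tG\t50\tPASS\tQD=12.5\tGT:DP:AD\t0/1:40:20,20",
    "chr1\t200\t.\tC\tG,T\t50\tPASS\t.\tGT:DP:AD\t1/2:60:0,30,30",
    "chr1\t300\t.\tT\tA\t50\tPASS\t.\tGT:DP:AD\t0/0:50:50,0"
  ))
  v <- read_vcf(path, "S1")
  expect_equal(nrow(v), 3L)

  snv <- dplyr::filter(v, pos == 100)
  expect_equal(snv$chrom, "1") # "chr" prefix harmonized away
  expect_equal(snv$genotype, "het")
  expect_equal(snv$depth, 40L)
  expect_equal(snv$ad_ref, 20L)
  expect_equal(snv$qd, 12.5)

  # 1/2 site: one record per alternate, each heterozygous
  multi <- dplyr::filter(v, pos == 200)
  expect_setequal(multi$alt, c("G", "T"))
  expect_equal(multi$genotype, c("het", "het"))
  expect_equal(multi$ad_alt, c(30L, 30L))

  # 0/0 never yields a record
  expect_equal(nrow(dplyr::filter(v, pos == 300)), 0L)
})

test_that("read_vcf fails on absent samples and missing files", {
  path <- vcf_text("chr1\t100\t.\tA\tG\t50\tPASS\t.\tGT:DP:AD\t0/1:40:20,20")
  expect_error(read_vcf(path, "NOBODY"), "absent from VCF header")
  expect_error(read_vcf(tempfile(), "S1"), "not found")
})

test_that("missing QD is an absent value, not zero", {
  path <- vcf_text("chr1\t100\t.\tA\tG\t50\tPASS\t.\tGT:DP:AD\t0/1:40:20,20")
  v <- read_vcf(path, "S1")
  expect_true(is.na(v$qd))
})

test_that("normalization trims suffix then prefix with indel anchors", {
  norm1 <- function(pos, ref, alt) {
    normalize_variants(call_row("1", pos, ref, alt))[, c("pos", "ref", "alt")]
  }
  expect_equal(norm1(100, "CAG", "CTG"),
               tibble::tibble(pos = 101L, ref = "A", alt = "T"))
  expect_equal(norm1(100, "A", "G"),
               tibble::tibble(pos = 100L, ref = "A", alt = "G"))
  expect_equal(norm1(100, "ATT", "AT"),
               tibble::tibble(pos = 100L, ref = "AT", alt = "A"))
  expect_error(normalize_variants(tibble::tibble(
    chrom = "1", pos = 1L, ref = "A", alt = "A", genotype = "het",
    depth = 1L, ad_ref = 0L, ad_alt = 1L, qd = 1, sample_id = "S")),
    "degenerate")
})

test_that("normalization is idempotent on random allele pairs", {
  set.seed(42)
  bases <- c("A", "C", "G", "T")
  for (i in 1:200) {
    ref <- paste(sample(bases, sample(1:8, 1), replace = TRUE), collapse = "")
    alt <- paste(sample(bases, sample(1:8, 1), replace = TRUE), collapse = "")
    if (ref == alt) next
    v <- call_row("1", 500L, ref, alt)
    n1 <- normalize_variants(v)
    n2 <- normalize_variants(n1)
    expect_identical(n1[, c("pos", "ref", "alt")], n2[, c("pos", "ref", "alt")])
  }
})

test_that("read_bed merges overlapping and abutting lines", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chr1\t15\t30", "chr2\t5\t8"), path)
  s <- read_bed(path)
  expect_equal(nrow(s), 2L)
  expect_equal(interval_total_length(s), 23L)
  expect_equal(dplyr::filter(s, chrom == "1")$end, 30L)

  writeLines(character(0), path)
  expect_equal(interval_total_length(read_bed(path)), 0L)

  writeLines("chr1\t30\t20", path)
  expect_error(read_bed(path), "start >= end")
})

test_that("interval intersection follows set semantics", {
  a <- interval_set(tibble::tibble(chrom = "1", start = 10L, end = 30L))
  b <- interval_set(tibble::tibble(chrom = "1", start = 20L, end = 40L))
  ab <- interval_intersect(a, b)
  expect_equal(as.data.frame(ab),
               data.frame(chrom = "1", start = 20L, end = 30L))
  disjoint <- interval_set(tibble::tibble(chrom = "2", start = 1L, end = 5L))
  expect_equal(nrow(interval_intersect(a, disjoint)), 0L)
  expect_equal(as.data.frame(interval_intersect(a, a)), as.data.frame(a))
})

test_that("intersection is commutative/associative; lengths bounded; BED round-trips", {
  set.seed(7)
  rand_set <- function() {
    n <- sample(1:8, 1)
    start <- sample.int(500, n)
    interval_set(tibble::tibble(
      chrom = sample(c("1", "2", "X"), n, replace = TRUE),
      start = start, end = start + sample.int(60, n)))
  }
  for (i in 1:25) {
    a <- rand_set(); b <- rand_set(); c <- rand_set()
    ab <- interval_intersect(a, b)
    expect_equal(as.data.frame(ab), as.data.frame(interval_intersect(b, a)))
    expect_equal(
      as.data.frame(interval_intersect(ab, c)),
      as.data.frame(interval_intersect(a, interval_intersect(b, c))))
    expect_lte(interval_total_length(ab),
               min(interval_total_length(a), interval_total_length(b)))
    path <- tempfile(fileext = ".bed")
    write_bed(a, path)
    expect_equal(as.data.frame(read_bed(path)), as.data.frame(a))
  }
})

test_that("variant span containment accounts for deletion footprints", {
  s <- interval_set(tibble::tibble(chrom = "1", start = 10L, end = 30L))
  expect_true(variants_in_set(call_row("1", 15), s))
  # 5 bp deletion starting at pos 28: span runs past the region end
  del <- call_row("1", 28, ref = "AAAAAA", alt = "A")
  expect_false(variants_in_set(del, s))
  expect_false(variants_in_set(call_row("1", 15), interval_set()))
})
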