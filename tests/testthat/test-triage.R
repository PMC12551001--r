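# Decision-tree filters, zygosity resolution and end-to-end triage semantics.

meta_f <- tibble::tibble(sample_id = "S1", sex = "female")
meta_m <- tibble::tibble(sample_id = "S1", sex = "male")

# a kb asserting P for any key given, and optional frequencies
kb_for <- function(variants, af = NULL) {
  a <- dplyr::transmute(variants, chrom, pos, ref, alt,
                        source = "CLINVAR", classification = "P")
  f <- if (is.null(af)) NULL else dplyr::transmute(variants, chrom, pos, ref,
                                                   alt, af = af)
  knowledge_base(a, f)
}

test_that("panel filter keeps contained variants and annotates their gene", {
  p <- tiny_panel()
  inside <- call_row("1", 1500)
  outside <- call_row("1", 50000)
  kept <- filter_panel(dplyr::bind_rows(inside, outside), p)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$symbol, "AR1")
  expect_equal(kept$inheritance, "AR")
})

test_that("quality filter enforces depth and fails closed on missing QD", {
  v <- dplyr::bind_rows(
    call_row("1", 1100, depth = 40, qd = 12),
    call_row("1", 1200, depth = 29, qd = 12),
    call_row("1", 1300, depth = 40, qd = NA_real_),
    call_row("1", 1400, depth = 30, qd = 2) # boundary passes
  )
  kept <- filter_quality(v, dp_min = 30, qd_min = 2)
  expect_setequal(kept$pos, c(1100L, 1400L))
})

test_that("frequency filter is strict-< with frequent-gene and rare-default exceptions", {
  p <- tiny_panel()
  common_ar1 <- call_row("1", 1100)   # AR1: not a frequent gene
  common_ar2 <- call_row("2", 5100)   # AR2: frequent gene
  norec <- call_row("1", 1200)
  v <- filter_panel(dplyr::bind_rows(common_ar1, common_ar2, norec), p)
  kb <- kb_for(dplyr::bind_rows(common_ar1, common_ar2), af = 0.02)
  kept <- filter_frequency(v, kb, af_max = 0.01)
  expect_setequal(kept$pos, c(5100L, 1200L))
})

test_that("zygosity resolution implements the inheritance reporting rules", {
  p <- tiny_panel()
  ar_het1 <- filter_panel(call_row("1", 1100), p)
  ar_het2 <- filter_panel(call_row("1", 1200), p)
  ar_hom <- filter_panel(call_row("1", 1300, genotype = "hom_alt"), p)

  # AR: single het = carrier, not reported
  expect_equal(nrow(resolve_zygosity(ar_het1, "AR", "female")), 0L)
  # AR: homozygous reported
  hom_ev <- resolve_zygosity(ar_hom, "AR", "female")
  expect_equal(hom_ev$mechanism, "homozygous")
  # AR: two distinct hets form one possible compound het with both variants
  ch_ev <- resolve_zygosity(dplyr::bind_rows(ar_het1, ar_het2), "AR", "female")
  expect_equal(ch_ev$mechanism, "possible_compound_het")
  expect_equal(ch_ev$n_variants, 2L)
  # AD: one het suffices
  ad_ev <- resolve_zygosity(filter_panel(call_row("3", 9100), p), "AD", "male")
  expect_equal(ad_ev$mechanism, "dominant_het")

  xl_het <- filter_panel(call_row("X", 5000100), p)
  # XL male outside PAR: het-called genotype is hemizygous
  expect_equal(resolve_zygosity(xl_het, "XL", "male")$mechanism, "hemizygous")
  # XL female: AR rule, so a single het is suppressed
  expect_equal(nrow(resolve_zygosity(xl_het, "XL", "female")), 0L)
  # XL unknown sex: fail open to review, mechanism unset
  unk <- resolve_zygosity(xl_het, "XL", "unknown")
  expect_equal(nrow(unk), 1L)
  expect_true(is.na(unk$mechanism))
  expect_equal(unk$note, "sex-unknown-review")

  # inside the PAR a male X variant is not hemizygous
  par1_region <- panel(
    tibble::tibble(symbol = "PARG", inheritance = "XL", frequent_gene = FALSE),
    tibble::tibble(chrom = "X", start = 100000L, end = 101000L, symbol = "PARG"))
  par_het <- filter_panel(call_row("X", 100500), par1_region)
  expect_equal(nrow(resolve_zygosity(par_het, "XL", "male")), 0L)
})

test_that("decision tree closes negative samples and reports positives", {
  pan <- make_panel(10, seed = 31)$panel
  kbb <- make_kb(pan, seed = 31)

  neg <- make_sample(pan, kbb, "negative", seed = 1)
  r_neg <- run_decision_tree(neg$variants, pan, kbb$kb, neg$meta)
  expect_equal(r_neg$status, "auto_closed")
  expect_equal(nrow(r_neg$events), 0L)

  hom <- make_sample(pan, kbb, "hom_AR", seed = 2)
  r_hom <- run_decision_tree(hom$variants, pan, kbb$kb, hom$meta)
  expect_equal(r_hom$status, "review_required")
  expect_equal(r_hom$events$mechanism, "homozygous")

  # empty input is a valid, automatically closed sample
  r_empty <- run_decision_tree(annotate_variants(variant_table()), pan,
                               kbb$kb, meta_f)
  expect_equal(r_empty$status, "auto_closed")
  expect_equal(nrow(r_empty$audit), 0L)
})

test_that("VUS are stored unreported and the audit covers every variant once", {
  pan <- make_panel(10, seed = 32)$panel
  kbb <- make_kb(pan, seed = 32)
  s <- make_sample(pan, kbb, "vus_only", seed = 3)
  r <- run_decision_tree(s$variants, pan, kbb$kb, s$meta)
  expect_equal(r$status, "auto_closed")
  expect_equal(nrow(r$vus), 1L)
  expect_true("vus-stored" %in% r$audit$reason)
  # audit partition: every input key exactly once, at a terminal stage
  expect_setequal(r$audit$key, unique(s$variants$key))
  expect_equal(anyDuplicated(r$audit$key), 0L)
})

test_that("carrier suppression: removing one compound-het variant removes the event", {
  pan <- make_panel(10, seed = 33)$panel
  kbb <- make_kb(pan, seed = 33)
  s <- make_sample(pan, kbb, "compound_het_AR", seed = 4)
  full <- run_decision_tree(s$variants, pan, kbb$kb, s$meta)
  expect_equal(full$events$mechanism, "possible_compound_het")
  one_key <- full$events$keys[[1]][1]
  reduced <- dplyr::filter(s$variants, key != one_key)
  r2 <- run_decision_tree(reduced, pan, kbb$kb, s$meta)
  expect_equal(nrow(r2$events), 0L)
  expect_equal(r2$status, "auto_closed")
  expect_true("carrier-not-reported" %in% r2$audit$reason)
})

test_that("conjunctive filters give the same events in either order", {
  pan <- make_panel(10, seed = 34)$panel
  kbb <- make_kb(pan, seed = 34)
  s <- make_sample(pan, kbb, "dominant_AD", seed = 5)
  cfg <- triage_config()
  v <- filter_panel(dplyr::filter(s$variants, !out_of_scope), pan)
  a <- filter_frequency(filter_quality(v, cfg$dp_min, cfg$qd_min), kbb$kb,
                        cfg$af_max)
  b <- filter_quality(filter_frequency(v, kbb$kb, cfg$af_max), cfg$dp_min,
                      cfg$qd_min)
  expect_setequal(a$key, b$key)
})

test_that("identical inputs give byte-identical audit trails", {
  pan <- make_panel(10, seed = 35)$panel
  kbb <- make_kb(pan, seed = 35)
  s <- make_sample(pan, kbb, "hemi_XL_male", seed = 6)
  r1 <- run_decision_tree(s$variants, pan, kbb$kb, s$meta)
  r2 <- run_decision_tree(s$variants, pan, kbb$kb, s$meta)
  expect_identical(r1$audit, r2$audit)
  expect_identical(
    readr::format_tsv(r1$audit), readr::format_tsv(r2$audit))
})

test_that("events never contain variants below the reporting classes", {
  pan <- make_panel(10, seed = 36)$panel
  kbb <- make_kb(pan, seed = 36)
  bad_roles <- c("vus", "benign_rare", "benign_common", "conflicting", "novel")
  bad_keys <- kbb$ledger$key[kbb$ledger$role %in% bad_roles]
  for (scen in c("negative", "carrier_AR", "hom_AR", "compound_het_AR",
                 "dominant_AD", "hemi_XL_male", "xl_female_comp_het",
                 "vus_only", "conflicting", "low_depth")) {
    s <- make_sample(pan, kbb, scen, seed = 7)
    r <- run_decision_tree(s$variants, pan, kbb$kb, s$meta)
    ev_keys <- unlist(r$events$keys)
    expect_length(intersect(ev_keys, bad_keys), 0)
  }
})

test_that("tidy and glance summarise triage results", {
  pan <- make_panel(10, seed = 37)$panel
  kbb <- make_kb(pan, seed = 37)
  s <- make_sample(pan, kbb, "compound_het_AR", sample_id = "S77", seed = 8)
  r <- run_decision_tree(s$variants, pan, kbb$kb, s$meta)
  td <- tidy(r)
  expect_equal(nrow(td), 2L)
  expect_equal(unique(td$sample_id), "S77")
  gl <- glance(r)
  expect_equal(gl$status, "review_required")
  expect_equal(gl$n_events, 1L)
})
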