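# IQR-fence thresholds, verdict semantics, control checks, Levey-Jennings.

test_that("IQR fences match hand-computed values", {
  expect_equal(derive_threshold(c(10, 10, 10, 10), "lower_bound", min_n = 4), 10)
  # median 50.5, Q1 25.75, Q3 75.25 by linear interpolation
  expect_equal(derive_threshold(1:100, "upper_bound"), 50.5 + 1.5 * 49.5)
  expect_error(derive_threshold(1:5, "lower_bound"), "insufficient history")
})

test_that("fence derivation equals an independent quantile oracle and is affine-equivariant", {
  set.seed(11)
  for (i in 1:40) {
    x <- stats::rnorm(sample(8:200, 1), mean = 50, sd = sample(1:20, 1))
    for (dir in c("lower_bound", "upper_bound")) {
      expect_equal(derive_threshold(x, dir), oracle_fence(x, dir))
    }
    k <- stats::runif(1, 0.1, 5)
    c0 <- stats::runif(1, -10, 10)
    expect_equal(derive_threshold(k * x + c0, "lower_bound"),
                 k * derive_threshold(x, "lower_bound") + c0)
  }
})

test_that("threshold sets resolve fixed and derived rules", {
  ths_v1 <- build_threshold_set(rules = default_metric_rules("v1")[
    default_metric_rules("v1")$mode == "fixed", ])
  get <- function(ths, m) ths$threshold[ths$metric == m]
  expect_equal(get(ths_v1, "Q30_pct"), 85)
  expect_equal(get(ths_v1, "SELECTED_BASES_pct"), 40)
  ths_v2 <- build_threshold_set(rules = default_metric_rules("v2")[
    default_metric_rules("v2")$mode == "fixed", ], panel_version = "v2")
  expect_equal(get(ths_v2, "Q30_pct"), 90)
  expect_equal(get(ths_v2, "SNP_REFERENCE_BIAS"), 0.56)
  expect_equal(get(ths_v2, "TARGET_BASES_30X_pct"), 93)
  expect_equal(get(ths_v2, "MEAN_TARGET_COVERAGE"), 100)
  expect_equal(get(ths_v2, "SELECTED_BASES_pct"), 78)

  set.seed(3)
  hist <- tibble::tibble(sample_id = sprintf("S%02d", 1:30),
                         PF_BASES = stats::rlnorm(30, log(1.2e9), 0.1))
  ths <- build_threshold_set(hist, default_metric_rules("v1"))
  expect_equal(get(ths, "PF_BASES"), oracle_fence(hist$PF_BASES, "lower_bound"))
  expect_match(ths$provenance[ths$metric == "PF_BASES"], "derived from 30")
})

test_that("verdicts implement the VIP repeat rule with boundary-inclusive passes", {
  ths <- build_threshold_set(rules = default_metric_rules("v2")[
    default_metric_rules("v2")$mode == "fixed", ], panel_version = "v2")
  rec <- function(...) tibble::tibble(sample_id = "S1", ...)
  ok <- rec(Q30_pct = 95, TARGET_BASES_30X_pct = 98, MEAN_TARGET_COVERAGE = 180,
            SELECTED_BASES_pct = 85, SNP_REFERENCE_BIAS = 0.5)
  expect_equal(qc_verdicts(ok, ths)$status, "pass")
  # boundary equals threshold: pass
  expect_equal(qc_verdicts(dplyr::mutate(ok, Q30_pct = 90,
                                         SNP_REFERENCE_BIAS = 0.56), ths)$status,
               "pass")
  # failing a VIP forces a workflow repeat
  expect_equal(qc_verdicts(dplyr::mutate(ok, Q30_pct = 88), ths)$status,
               "repeat")
  # failing only a non-VIP metric asks for review
  expect_equal(qc_verdicts(dplyr::mutate(ok, SELECTED_BASES_pct = 70), ths)$status,
               "review")
  # a configured metric missing from the record fails that metric
  v <- qc_verdicts(dplyr::select(ok, -"MEAN_TARGET_COVERAGE"), ths)
  expect_equal(v$status, "review")
  expect_equal(v$failed_metrics, "MEAN_TARGET_COVERAGE")
})

test_that("verdict statuses partition samples and respect the VIP rule on random tables", {
  ths <- build_threshold_set(rules = default_metric_rules("v1")[
    default_metric_rules("v1")$mode == "fixed", ])
  set.seed(19)
  for (i in 1:10) {
    n <- 40
    rec <- tibble::tibble(
      sample_id = sprintf("S%03d", 1:n),
      Q30_pct = stats::runif(n, 70, 100),
      TARGET_BASES_30X_pct = stats::runif(n, 85, 100),
      MEAN_TARGET_COVERAGE = stats::runif(n, 50, 300),
      SELECTED_BASES_pct = stats::runif(n, 20, 90),
      SNP_REFERENCE_BIAS = stats::runif(n, 0.4, 0.7))
    det <- evaluate_sample_metrics(rec, ths)
    verd <- qc_verdicts(det)
    expect_true(all(verd$status %in% c("pass", "review", "repeat")))
    vip_fail <- det |> dplyr::group_by(sample_id) |>
      dplyr::summarise(v = any(!pass & vip), f = any(!pass))
    merged <- dplyr::left_join(verd, vip_fail, by = "sample_id")
    expect_equal(merged$status == "repeat", merged$v)
    expect_equal(merged$status == "pass", !merged$f)
  }
})

test_that("raising a lower-bound threshold never turns a failure into a pass", {
  set.seed(23)
  rec <- tibble::tibble(sample_id = sprintf("S%02d", 1:50),
                        Q30_pct = stats::runif(50, 80, 100))
  mk <- function(th) {
    rules <- tibble::tibble(metric = "Q30_pct", direction = "lower_bound",
                            mode = "fixed", fixed_value = th, vip = TRUE)
    evaluate_sample_metrics(rec, build_threshold_set(rules = rules))$pass
  }
  lo <- mk(85); hi <- mk(92)
  expect_true(all(hi <= lo)) # pass set only shrinks
})

test_that("the internal control check verifies presence, genotype and depth", {
  expected <- tibble::tibble(chrom = c("1", "2"), pos = c(100L, 200L),
                             ref = "A", alt = "G", genotype = "het")
  good <- dplyr::bind_rows(call_row("1", 100), call_row("2", 200))
  cc <- check_internal_control(good, expected, min_depth = 30)
  expect_true(attr(cc, "pass"))
  expect_equal(cc$allele_depth_fraction, c(0.5, 0.5))

  # one expected variant absent
  cc2 <- check_internal_control(call_row("1", 100), expected)
  expect_false(attr(cc2, "pass"))
  expect_equal(cc2$found, c(TRUE, FALSE))

  # genotype mismatch: called homozygous where het expected
  bad_gt <- dplyr::bind_rows(call_row("1", 100, genotype = "hom_alt"),
                             call_row("2", 200))
  cc3 <- check_internal_control(bad_gt, expected)
  expect_false(attr(cc3, "pass"))
  expect_false(cc3$genotype_match[1])

  # insufficient depth
  low <- dplyr::bind_rows(call_row("1", 100, depth = 10), call_row("2", 200))
  expect_false(attr(check_internal_control(low, expected, min_depth = 30), "pass"))
})

test_that("Levey-Jennings series flags only genuine outliers", {
  base <- tibble::tibble(batch_id = sprintf("B%02d", 1:20),
                         run_date = as.Date("2023-01-01") + 1:20,
                         value = 100)
  lj <- levey_jennings(base)
  expect_equal(lj$sd[1], 0)
  expect_false(any(lj$flag))

  set.seed(5)
  jitter <- dplyr::mutate(base, value = stats::rnorm(20, 100, 2))
  spiked <- jitter
  spiked$value[12] <- 100 + 5 * stats::sd(jitter$value) * 3
  lj2 <- levey_jennings(spiked)
  expect_true(lj2$flag[12])
  expect_equal(sum(lj2$flag), 1L)

  one <- levey_jennings(base[1, ])
  expect_true(is.na(one$sd))
  expect_false(one$flag)

  expect_s3_class(autoplot(lj2), "ggplot")
})
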