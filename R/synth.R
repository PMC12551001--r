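# Deterministic synthetic fixture generators: gene panels, knowledge bases,
# per-sample VCFs with planted scenarios, truth/test VCF pairs with controlled
# discordance, and QC metric histories with planted failures. Every generator
# is seeded from one integer and records its ground truth, so the toolkit can
# be exercised end-to-end with known expected output. Coordinates live on real
# chromosome labels with arbitrary positions; no reference FASTA is involved
# (normalization is string-based). X-chromosome gene blocks start beyond PAR1
# so hemizygous scenarios fall outside the pseudoautosomal regions.

.BASES <- c("A", "C", "G", "T")

#' Generate a synthetic gene panel
#'
#' Genes are spread over autosomes and (from 5 genes up) the X chromosome,
#' each with 2-6 exons of 80-300 bp carrying +/- `flank` bp intronic flanks
#' (flanked exons that touch are merged); gene blocks never overlap. The
#' inheritance mix always contains AR and AD genes, and at least one
#' XL gene once an X gene exists; at least one gene carries the
#' frequent-gene flag.
#'
#' @param n_genes Number of genes (>= 3).
#' @param seed Integer seed; fixed seed gives byte-identical output files.
#' @param version Panel version label.
#' @param flank Flank size in bp around each exon (default 50).
#' @param n_cnv_flagged Number of genes flagged as harboring reported CNV/SV
#'   mechanisms (outside small-variant scope). Default 0.
#' @param out_dir If given, the panel TSV and BED4 files are written there.
#' @return A list: `panel` (a [panel()] object), `paths` (when written) and
#'   `ledger` (per-gene region bookkeeping: merged region length).
#' @export
make_panel <- function(n_genes, seed = 1, version = "v1", flank = 50L,
                       n_cnv_flagged = 0L, out_dir = NULL) {
  stopifnot(n_genes >= 3, n_cnv_flagged <= n_genes)
  with_seed(sub_seed(seed, 11), {
    symbols <- sprintf("G%s%03d", toupper(version), seq_len(n_genes))
    inheritance <- sample(c("AR", "AD", "XL"), n_genes, replace = TRUE,
                          prob = c(0.6, 0.3, 0.1))
    inheritance[1] <- "AR"
    inheritance[2] <- "AD"
    if (n_genes >= 5) {
      inheritance[5] <- "XL"
    } else {
      inheritance[inheritance == "XL"] <- "AR"
    }
    chrom <- ifelse(inheritance == "XL", "X",
                    as.character(rep_len(1:22, n_genes)))
    frequent <- stats::runif(n_genes) < 0.05
    frequent[1] <- TRUE
    cnv <- rep(FALSE, n_genes)
    if (n_cnv_flagged > 0) cnv[sample.int(n_genes, n_cnv_flagged)] <- TRUE

    # one disjoint 100 kb block per gene, indexed within its chromosome;
    # X blocks start at 3 Mb, safely outside PAR1
    regions <- purrr::map(seq_len(n_genes), function(g) {
      idx <- sum(chrom[seq_len(g)] == chrom[g])
      base <- if (chrom[g] == "X") 3000000L else 1000000L
      origin <- base + (idx - 1L) * 100000L
      n_ex <- sample(2:6, 1)
      lens <- sample(120:300, n_ex, replace = TRUE)
      gaps <- sample(500:3000, n_ex, replace = TRUE)
      starts <- origin + cumsum(gaps) + c(0L, cumsum(lens[-n_ex]))
      tibble(chrom = chrom[g],
             start = as.integer(starts - flank),
             end = as.integer(starts + lens + flank),
             symbol = symbols[g])
    }) |> bind_rows()

    genes <- tibble(symbol = symbols, inheritance = inheritance,
                    frequent_gene = frequent, cnv_flagged = cnv)
    p <- panel(genes, regions, version = version)
    ledger <- p$regions |>
      group_by(.data$symbol) |>
      summarise(region_length = sum(.data$end - .data$start), .groups = "drop")
    paths <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      paths <- write_panel(
        p,
        file.path(out_dir, sprintf("panel_%s.tsv", version)),
        file.path(out_dir, sprintf("panel_%s.bed", version))
      )
    }
    list(panel = p, paths = paths, ledger = ledger)
  })
}

# Deterministic planted-variant positions: evenly spaced SNV sites inside a
# gene's first (widest) region, clear of its edges.
.plant_sites <- function(p, symbol, n) {
  reg <- p$regions |> filter(.data$symbol == !!symbol) |>
    mutate(len = .data$end - .data$start) |> arrange(dplyr::desc(.data$len))
  r <- reg[1, ]
  stopifnot(r$len >= 20 * n + 40)
  tibble(chrom = r$chrom, pos = as.integer(r$start + 20 + 20 * (seq_len(n) - 1) + 1))
}

#' Generate a knowledge base matched to a panel
#'
#' Plants, inside every gene's regions, variants covering all classification
#' outcomes: fully-agreed P, ClinVar-only LP, MVL-only P, VUS, rare and
#' common benign, a conflicting assertion (LP with B dissent), and a novel
#' variant absent from every source. Two genes additionally receive the
#' internal-control P variants (the synthetic stand-ins for the routine
#' SERPINA1/ALDOB control alleles, supplied as genomic keys).
#'
#' @param p A `panel`.
#' @param seed Integer seed.
#' @param out_dir If given, writes `assertions.tsv` and `frequencies.tsv`.
#' @return A list: `kb` (a [knowledge_base()]), `ledger` (tibble mapping every
#'   planted key to gene, role and expected [classify_variants()] outcome),
#'   `control` (expected internal-control variants with genotypes), `paths`.
#' @export
make_kb <- function(p, seed = 1, out_dir = NULL) {
  roles <- tibble(
    role = c("p_agreed", "clinvar_lp", "mvl_p", "vus", "benign_rare",
             "benign_common", "conflicting", "novel"),
    expected = c("REPORTABLE_P_LP", "REPORTABLE_P_LP", "REPORTABLE_P_LP",
                 "VUS", "BENIGN", "BENIGN", "CONFLICTING", "NOT_IN_DB")
  )
  with_seed(sub_seed(seed, 23), {
    per_gene <- purrr::map(p$genes$symbol, function(sym) {
      sites <- .plant_sites(p, sym, nrow(roles))
      ref <- sample(.BASES, nrow(roles), replace = TRUE)
      alt <- purrr::map_chr(ref, ~ sample(setdiff(.BASES, .x), 1))
      tibble(gene = sym, role = roles$role, expected = roles$expected,
             chrom = sites$chrom, pos = sites$pos, ref = ref, alt = alt)
    }) |> bind_rows()

    assert_rows <- per_gene |>
      mutate(spec = purrr::map(.data$role, function(r) {
        switch(r,
          p_agreed = tibble(source = c("MVL", "CLINVAR", "AUX1", "AUX2"),
                            classification = "P"),
          clinvar_lp = tibble(source = "CLINVAR", classification = "LP"),
          mvl_p = tibble(source = "MVL", classification = "P"),
          vus = tibble(source = "CLINVAR", classification = "VUS"),
          benign_rare = tibble(source = "CLINVAR", classification = "B"),
          benign_common = tibble(source = "CLINVAR", classification = "B"),
          conflicting = tibble(source = c("CLINVAR", "AUX1"),
                               classification = c("LP", "B")),
          novel = tibble(source = character(), classification = character())
        )
      })) |>
      tidyr::unnest("spec") |>
      select("chrom", "pos", "ref", "alt", "source", "classification")

    freqs <- per_gene |>
      mutate(af = case_when(
        .data$role == "benign_common" ~ 0.05,
        .data$role %in% c("p_agreed", "clinvar_lp") ~ 0.0005,
        TRUE ~ NA_real_
      )) |>
      filter(!is.na(.data$af)) |>
      select("chrom", "pos", "ref", "alt", "af")

    kb <- knowledge_base(assert_rows, freqs)
    ledger <- per_gene |>
      mutate(key = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt)) |>
      select("key", "gene", "role", "expected")

    control_genes <- head(p$genes$symbol[p$genes$inheritance != "XL"], 2)
    control <- per_gene |>
      filter(.data$gene %in% control_genes, .data$role == "p_agreed") |>
      mutate(genotype = "het") |>
      select("chrom", "pos", "ref", "alt", "genotype", "gene")

    paths <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      paths <- list(assertions = file.path(out_dir, "assertions.tsv"),
                    frequencies = file.path(out_dir, "frequencies.tsv"))
      readr::write_tsv(assert_rows, paths$assertions, progress = FALSE)
      readr::write_tsv(freqs, paths$frequencies, progress = FALSE)
    }
    list(kb = kb, ledger = ledger, control = control, paths = paths)
  })
}

.scenarios <- c("negative", "carrier_AR", "hom_AR", "compound_het_AR",
                "dominant_AD", "hemi_XL_male", "xl_female_comp_het",
                "vus_only", "conflicting", "off_panel", "low_depth")

# inheritance mode each scenario's planted gene must have (NA = any non-XL)
.scenario_mode <- c(
  negative = NA, carrier_AR = "AR", hom_AR = "AR", compound_het_AR = "AR",
  dominant_AD = "AD", hemi_XL_male = "XL", xl_female_comp_het = "XL",
  vus_only = NA, conflicting = NA, off_panel = NA, low_depth = NA
)

# Draw call-level annotations for one planted variant.
.call_row <- function(site, genotype, sample_id, depth = NULL) {
  depth <- depth %||% max(30L, as.integer(round(stats::rlnorm(1, log(150), 0.25))))
  ad_alt <- switch(genotype,
    het = stats::rbinom(1, depth, 0.5),
    hom_alt = depth - stats::rbinom(1, 3, 0.5),
    hemi = depth - stats::rbinom(1, 3, 0.5)
  )
  tibble(chrom = site$chrom, pos = site$pos, ref = site$ref, alt = site$alt,
         genotype = genotype, depth = depth,
         ad_ref = depth - ad_alt, ad_alt = ad_alt,
         qd = round(stats::runif(1, 8, 25), 2), sample_id = sample_id)
}

.kb_site <- function(kb_bundle, gene, role) {
  row <- kb_bundle$ledger |>
    filter(.data$gene == !!gene, .data$role == !!role)
  parts <- strsplit(row$key[1], ":", fixed = TRUE)[[1]]
  tibble(chrom = parts[1], pos = as.integer(parts[2]), ref = parts[3],
         alt = parts[4])
}

#' Generate one sample VCF for a planted scenario
#'
#' Plants the variant configuration of `scenario` in a compatible panel gene,
#' adds background noise (a common benign variant, a rare benign variant, a
#' novel in-panel variant and two off-panel calls), and records the expected
#' triage outcome.
#'
#' @param p A `panel`.
#' @param kb_bundle Output of [make_kb()] for the same panel.
#' @param scenario One of `negative`, `carrier_AR`, `hom_AR`,
#'   `compound_het_AR`, `dominant_AD`, `hemi_XL_male`, `xl_female_comp_het`,
#'   `vus_only`, `conflicting`, `off_panel`, `low_depth`.
#' @param sample_id Sample identifier.
#' @param seed Integer seed.
#' @param gene Target gene symbol; defaults to the first panel gene whose
#'   inheritance mode is compatible with the scenario. Incompatible choices
#'   are an error.
#' @param out_dir If given, the VCF is written as `<sample_id>.vcf`.
#' @return A list: `variants` (the call table), `meta` (`sample_id`, `sex`),
#'   `expected` (list: `status`, `events` tibble of gene/mechanism/
#'   n_variants), `path` (when written).
#' @export
make_sample <- function(p, kb_bundle, scenario, sample_id = "S1", seed = 1,
                        gene = NULL, out_dir = NULL) {
  scenario <- match.arg(scenario, .scenarios)
  need <- .scenario_mode[[scenario]]
  candidates <- if (is.na(need)) {
    p$genes$symbol[p$genes$inheritance != "XL"]
  } else {
    p$genes$symbol[p$genes$inheritance == need]
  }
  if (is.null(gene)) gene <- candidates[1]
  if (length(gene) == 0 || is.na(gene) || !gene %in% candidates) {
    abort(sprintf("scenario '%s' needs a gene with inheritance %s", scenario,
                  if (is.na(need)) "AR or AD" else need))
  }
  sex <- switch(scenario, hemi_XL_male = "male", xl_female_comp_het = "female",
                "female")
  with_seed(sub_seed(seed, 37), {
    site <- function(role, g = gene) .kb_site(kb_bundle, g, role)
    planted <- switch(scenario,
      negative = NULL,
      carrier_AR = .call_row(site("p_agreed"), "het", sample_id),
      hom_AR = .call_row(site("p_agreed"), "hom_alt", sample_id),
      compound_het_AR = bind_rows(
        .call_row(site("p_agreed"), "het", sample_id),
        .call_row(site("clinvar_lp"), "het", sample_id)),
      dominant_AD = .call_row(site("p_agreed"), "het", sample_id),
      # diploid callers emit 0/1 on X for males
      hemi_XL_male = .call_row(site("p_agreed"), "het", sample_id),
      xl_female_comp_het = bind_rows(
        .call_row(site("p_agreed"), "het", sample_id),
        .call_row(site("clinvar_lp"), "het", sample_id)),
      vus_only = .call_row(site("vus"), "het", sample_id),
      conflicting = .call_row(site("conflicting"), "het", sample_id),
      off_panel = NULL,
      low_depth = .call_row(site("p_agreed"), "het", sample_id, depth = 15L)
    )
    noise_gene <- utils::tail(candidates, 1)
    noise <- bind_rows(
      .call_row(site("benign_common", noise_gene), "het", sample_id),
      .call_row(site("benign_rare", noise_gene), "het", sample_id),
      .call_row(site("novel", noise_gene), "het", sample_id),
      .call_row(tibble(chrom = "20", pos = 60000000L + sample.int(1000, 1) * 50L,
                       ref = "A", alt = "G"), "het", sample_id),
      .call_row(tibble(chrom = "21", pos = 70000000L + sample.int(1000, 1) * 50L,
                       ref = "C", alt = "T"), "het", sample_id)
    )
    variants <- bind_rows(planted, noise) |>
      annotate_variants()

    expected_events <- switch(scenario,
      hom_AR = tibble(gene = gene, mechanism = "homozygous", n_variants = 1L),
      compound_het_AR = tibble(gene = gene, mechanism = "possible_compound_het",
                               n_variants = 2L),
      dominant_AD = tibble(gene = gene, mechanism = "dominant_het",
                           n_variants = 1L),
      hemi_XL_male = tibble(gene = gene, mechanism = "hemizygous",
                            n_variants = 1L),
      xl_female_comp_het = tibble(gene = gene,
                                  mechanism = "possible_compound_het",
                                  n_variants = 2L),
      tibble(gene = character(), mechanism = character(),
             n_variants = integer())
    )
    expected <- list(
      status = if (nrow(expected_events) == 0) "auto_closed" else "review_required",
      events = expected_events
    )
    path <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      path <- file.path(out_dir, paste0(sample_id, ".vcf"))
      write_vcf(variants, path, sample_id)
    }
    list(variants = variants,
         meta = tibble(sample_id = sample_id, sex = sex, scenario = scenario,
                       gene = gene),
         expected = expected, path = path)
  })
}

#' Generate a truth/test VCF pair with controlled discordance
#'
#' Plants `c_shared` variants present in both call sets, `a_fp` test-only and
#' `b_fn` truth-only variants, all inside TOI ∩ HCR with DP >= 30, mixing
#' SNVs and 1-15 bp indels. [match_calls()] on the restricted pair returns
#' exactly `(tp = c_shared, fp = a_fp, fn = b_fn)`.
#'
#' @param p A `panel` (its TOI hosts the variants; the HCR is the TOI).
#' @param seed Integer seed.
#' @param a_fp,b_fn,c_shared Planted discordance counts (>= 0).
#' @param out_dir If given, writes `truth.vcf`, `test.vcf`, `toi.bed`,
#'   `hcr.bed`.
#' @return A list: `test`, `truth` (call tables), `toi`, `hcr`
#'   (interval sets), `expected` (tibble `tp, fp, fn`), `paths`.
#' @export
make_truth_pair <- function(p, seed = 1, a_fp = 0, b_fn = 0, c_shared = 50,
                            out_dir = NULL) {
  stopifnot(a_fp >= 0, b_fn >= 0, c_shared >= 0)
  n <- a_fp + b_fn + c_shared
  with_seed(sub_seed(seed, 53), {
    regions <- p$regions |> mutate(len = .data$end - .data$start)
    # spread sites over region rows, 25 bp apart, clear of edges
    slots <- regions |>
      mutate(n_slots = pmax(0L, as.integer((.data$len - 40) %/% 25L))) |>
      tidyr::uncount(.data$n_slots, .id = "slot") |>
      mutate(pos = as.integer(.data$start + 20L + (.data$slot - 1L) * 25L + 1L))
    if (nrow(slots) < n) abort("panel TOI too small for requested pair size")
    sites <- slots[sort(sample.int(nrow(slots), n)), c("chrom", "pos")]
    is_indel <- stats::runif(n) < 0.3
    ref <- purrr::map_chr(seq_len(n), function(i) {
      if (!is_indel[i]) return(sample(.BASES, 1))
      len <- sample(1:15, 1)
      paste(sample(.BASES, len + 1, replace = TRUE), collapse = "")
    })
    alt <- purrr::map_chr(seq_len(n), function(i) {
      if (!is_indel[i]) return(sample(setdiff(.BASES, ref[i]), 1))
      substr(ref[i], 1, 1)
    })
    # deletions may not run past their region; shift such sites is avoided by
    # the 20 bp edge margin (max ref length 16 < 20)
    calls <- tibble(
      chrom = sites$chrom, pos = sites$pos, ref = ref, alt = alt,
      genotype = sample(c("het", "hom_alt"), n, replace = TRUE,
                        prob = c(0.7, 0.3)),
      depth = as.integer(round(stats::runif(n, 35, 220)))
    ) |>
      mutate(ad_alt = as.integer(round(.data$depth * if_else(
               .data$genotype == "het", 0.5, 0.98))),
             ad_ref = .data$depth - .data$ad_alt,
             qd = round(stats::runif(n, 5, 30), 2))
    grp <- rep(c("shared", "fp", "fn"), c(c_shared, a_fp, b_fn))
    test <- calls[grp != "fn", ] |> mutate(sample_id = "TEST") |>
      normalize_variants() |> annotate_variants()
    truth <- calls[grp != "fp", ] |> mutate(sample_id = "TRUTH") |>
      normalize_variants() |> annotate_variants()
    paths <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      paths <- list(test = file.path(out_dir, "test.vcf"),
                    truth = file.path(out_dir, "truth.vcf"),
                    toi = file.path(out_dir, "toi.bed"),
                    hcr = file.path(out_dir, "hcr.bed"))
      write_vcf(test, paths$test, "TEST")
      write_vcf(truth, paths$truth, "TRUTH")
      write_bed(p$toi, paths$toi)
      write_bed(p$toi, paths$hcr)
    }
    list(test = test, truth = truth, toi = p$toi, hcr = p$toi,
         expected = tibble(tp = c_shared, fp = a_fp, fn = b_fn),
         paths = paths)
  })
}

#' Generate a QC metric history with planted failures
#'
#' All samples receive metric values comfortably inside the routine
#' thresholds except those selected by `failure_plan`, which violate exactly
#' the planned number of metrics (failing values sit far outside the fence so
#' the outcome is structural, not borderline). The per-metric choice favours
#' SELECTED_BASES_pct, the most frequent failure in routine practice.
#'
#' @param n_samples Number of samples.
#' @param failure_plan Named integer vector: `c("1" = 103, "2" = 10, "3" = 1)`
#'   means 103 samples fail one metric, 10 fail two, 1 fails three. Default:
#'   no failures.
#' @param seed Integer seed.
#' @param panel_version `"v1"` or `"v2"` (selects the fixed thresholds).
#' @param batch_size Samples per batch (default 96).
#' @param out_dir If given, writes `qc_history.tsv`.
#' @return A list: `metrics` (wide per-sample table), `expected` (tibble
#'   `sample_id`, `status`, `failed_metrics`), `rules`, `paths`.
#' @export
make_qc_history <- function(n_samples, failure_plan = NULL, seed = 1,
                            panel_version = "v1", batch_size = 96L,
                            out_dir = NULL) {
  rules <- default_metric_rules(panel_version)
  plan_n <- if (is.null(failure_plan)) integer(0) else failure_plan
  if (sum(plan_n) > n_samples) abort("failure plan exceeds n_samples")
  v2 <- panel_version == "v2"
  pass_gen <- list(
    PF_BASES = function(n) stats::runif(n, 1.10e9, 1.35e9),
    Q30_pct = function(n) stats::runif(n, 92, 97),
    TARGET_BASES_30X_pct = function(n) stats::runif(n, 95, 99.5),
    MEAN_TARGET_COVERAGE = function(n) stats::runif(n, 130, 260),
    SELECTED_BASES_pct = if (v2) function(n) stats::runif(n, 82, 95) else
      function(n) stats::runif(n, 50, 75),
    SNP_REFERENCE_BIAS = function(n) stats::runif(n, 0.46, 0.54)
  )
  fail_gen <- list(
    PF_BASES = function(n) stats::runif(n, 0.2e9, 0.4e9),
    Q30_pct = function(n) stats::runif(n, 70, 82),
    TARGET_BASES_30X_pct = function(n) stats::runif(n, 80, 90),
    MEAN_TARGET_COVERAGE = function(n) stats::runif(n, 40, 90),
    SELECTED_BASES_pct = if (v2) function(n) stats::runif(n, 50, 72) else
      function(n) stats::runif(n, 20, 38),
    SNP_REFERENCE_BIAS = function(n) stats::runif(n, 0.58, 0.70)
  )
  with_seed(sub_seed(seed, 71), {
    sample_id <- sprintf("S%05d", seq_len(n_samples))
    batch <- sprintf("B%03d", (seq_len(n_samples) - 1L) %/% batch_size + 1L)
    run_date <- as.Date("2023-01-02") +
      7L * ((seq_len(n_samples) - 1L) %/% batch_size)
    metrics <- tibble(sample_id = sample_id, batch_id = batch,
                      run_date = run_date)
    for (m in rules$metric) metrics[[m]] <- pass_gen[[m]](n_samples)

    fail_counts <- rep(as.integer(names(plan_n)), plan_n)
    fail_idx <- if (length(fail_counts) > 0) {
      sample.int(n_samples, length(fail_counts))
    } else integer(0)
    # SELECTED_BASES_pct is the dominant failure mode
    weights <- setNames(c(0.04, 0.05, 0.08, 0.10, 0.68, 0.05), rules$metric)
    planted <- purrr::map2(fail_idx, fail_counts, function(i, k) {
      ms <- sample(rules$metric, k, prob = weights[rules$metric])
      for (m in ms) metrics[[m]][i] <<- fail_gen[[m]](1)
      ms <- ms[order(match(ms, rules$metric))]
      tibble(sample_id = sample_id[i], failed_metrics = paste(ms, collapse = ","),
             vip_fail = any(ms %in% rules$metric[rules$vip]))
    }) |> bind_rows()
    if (nrow(planted) == 0) {
      planted <- tibble(sample_id = character(), failed_metrics = character(),
                        vip_fail = logical())
    }

    expected <- tibble(sample_id = sample_id) |>
      left_join(planted, by = "sample_id") |>
      mutate(
        failed_metrics = dplyr::coalesce(.data$failed_metrics, ""),
        status = case_when(
          dplyr::coalesce(.data$vip_fail, FALSE) ~ "repeat",
          .data$failed_metrics != "" ~ "review",
          TRUE ~ "pass"
        )
      ) |>
      select("sample_id", "status", "failed_metrics")

    paths <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      paths <- list(metrics = file.path(out_dir, "qc_history.tsv"))
      readr::write_tsv(metrics, paths$metrics, progress = FALSE)
    }
    list(metrics = metrics, expected = expected, rules = rules, paths = paths)
  })
}

#' Generate a full self-consistent fixture bundle
#'
#' One call produces everything a batch run consumes: a panel, its knowledge
#' base, per-sample VCFs following a scenario plan, sample metadata with plate
#' positions, a QC metric table (optionally with planted failures), the H12
#' internal-control sample, and the ground truth for all of it.
#'
#' @param seed Integer seed.
#' @param n_genes Panel size (default 12).
#' @param scenario_plan Named integer vector of scenario counts, e.g.
#'   `c(negative = 3, hom_AR = 1)`. Defaults to one of each scenario.
#' @param qc_fail_plan Passed to [make_qc_history()] as `failure_plan`; the
#'   history covers the batch samples.
#' @param out_dir If given, all files are written beneath it.
#' @return A list: `panel`, `kb_bundle`, `samples` (list of [make_sample()]
#'   outputs, plus the H12 control), `meta` (sample metadata incl. plate
#'   positions), `qc` ([make_qc_history()] output), `control_expected`,
#'   `ground_truth` (per-sample expected status/events).
#' @export
make_bundle <- function(seed = 1, n_genes = 12,
                        scenario_plan = setNames(rep(1L, length(.scenarios)),
                                                 .scenarios),
                        qc_fail_plan = NULL, out_dir = NULL) {
  pan <- make_panel(n_genes, seed = seed, out_dir = out_dir)
  kbb <- make_kb(pan$panel, seed = seed, out_dir = out_dir)
  scen <- rep(names(scenario_plan), scenario_plan)
  samples <- purrr::imap(scen, function(s, i) {
    make_sample(pan$panel, kbb, s, sample_id = sprintf("S%03d", i),
                seed = sub_seed(seed, 100 + i), out_dir = out_dir)
  })
  # H12 internal-control sample: both control variants, het, good depth
  control_variants <- with_seed(sub_seed(seed, 997), {
    purrr::map(seq_len(nrow(kbb$control)), function(i) {
      .call_row(kbb$control[i, c("chrom", "pos", "ref", "alt")], "het", "CTRL-H12")
    }) |> bind_rows() |> annotate_variants()
  })
  if (!is.null(out_dir)) write_vcf(control_variants,
                                   file.path(out_dir, "CTRL-H12.vcf"))
  n <- length(samples)
  wells <- paste0(rep(LETTERS[1:8], times = 12),
                  rep(1:12, each = 8))
  meta <- bind_rows(purrr::map(samples, "meta")) |>
    mutate(plate_position = wells[seq_len(n)], batch_id = "B001") |>
    bind_rows(tibble(sample_id = "CTRL-H12", sex = "female",
                     scenario = "control", gene = NA_character_,
                     plate_position = "H12", batch_id = "B001"))
  qc <- make_qc_history(n + 1L, failure_plan = qc_fail_plan, seed = seed)
  qc$metrics$sample_id <- meta$sample_id
  qc$expected$sample_id <- meta$sample_id
  if (!is.null(out_dir)) {
    qc$paths <- list(metrics = file.path(out_dir, "qc_history.tsv"))
    readr::write_tsv(qc$metrics, qc$paths$metrics, progress = FALSE)
  }
  ground_truth <- purrr::map(samples, function(s) {
    list(sample_id = s$meta$sample_id, expected = s$expected)
  })
  if (!is.null(out_dir)) {
    readr::write_tsv(meta, file.path(out_dir, "samples.tsv"), progress = FALSE)
    jsonlite::write_json(
      purrr::map(ground_truth, function(g) {
        list(sample_id = g$sample_id, status = g$expected$status,
             events = g$expected$events)
      }),
      file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  list(panel = pan$panel, kb_bundle = kbb, samples = samples,
       control_variants = control_variants, meta = meta, qc = qc,
       control_expected = kbb$control, ground_truth = ground_truth,
       out_dir = out_dir)
}

#' Composition of the analytical validation sample set
#'
#' The validation design: eight positive newborn samples run in triplicate on
#' two NovaSeq runs and in duplicate on one NextSeq run, the negative
#' newborn/adult samples interpreted on the same runs, and the eight
#' revalidation positives sequenced twice on the redesigned panel.
#'
#' @return A tibble with columns `phase`, `platform`, `group`, `n_samples`.
#' @export
validation_design <- function() {
  tibble(
    phase = c("initial", "initial", "initial", "initial", "revalidation"),
    platform = c("NovaSeq", "NextSeq", "NovaSeq", "NextSeq", "NovaSeq"),
    group = c("positive", "positive", "negative", "negative", "positive"),
    n_samples = c(48L, 16L, 112L, 24L, 16L)
  )
}

#' Flag genes as harboring reported CNV/SV mechanisms
#'
#' @param p A `panel`.
#' @param n Number of genes to flag.
#' @param seed Integer seed for the gene draw.
#' @return The panel with `n` genes carrying `cnv_flagged = TRUE`.
#' @export
assign_cnv_flags <- function(p, n, seed = 1) {
  stopifnot(n <= nrow(p$genes))
  with_seed(sub_seed(seed, 83), {
    genes <- p$genes
    genes$cnv_flagged <- FALSE
    genes$cnv_flagged[sample.int(nrow(genes), n)] <- TRUE
    panel(genes, p$regions, version = p$version)
  })
}
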