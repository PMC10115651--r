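test_that("paired favouring truth table is total and matches the quoted rules", {
  expect_equal(classify_paired_mutation("absent", "clonal"), "metastasis_favoured")
  expect_equal(classify_paired_mutation("absent", "subclonal"), "metastasis_favoured")
  expect_equal(classify_paired_mutation("subclonal", "clonal"), "metastasis_favoured")
  expect_equal(classify_paired_mutation("clonal", "subclonal"), "primary_favoured")
  expect_equal(classify_paired_mutation("clonal", "absent"), "primary_favoured")
  expect_equal(classify_paired_mutation("subclonal", "absent"), "primary_favoured")
  expect_equal(classify_paired_mutation("clonal", "clonal"), "maintained")

  # all 9 combinations map to exactly one label
  combos <- expand.grid(p = c("absent", "subclonal", "clonal"),
                        m = c("absent", "subclonal", "clonal"),
                        stringsAsFactors = FALSE)
  labels <- classify_paired_mutation(combos$p, combos$m)
  expect_equal(length(labels), 9)
  expect_true(all(labels %in% c("metastasis_favoured", "primary_favoured", "maintained")))
  expect_error(classify_paired_mutation("clonal", "weird"), "unknown")

  expect_equal(as.character(max_clonality(c("absent", "subclonal"))), "subclonal")
  expect_equal(as.character(max_clonality(c("clonal", "absent"))), "clonal")
})

test_that("exact multinomial p-values agree with brute-force enumeration", {
  bg <- c(1 / 3, 1 / 3, 1 / 3)
  # all ten events in one class
  res <- multinomial_test(c(0, 0, 10), bg)
  expect_equal(res$method, "exact")
  expect_equal(res$p_value, oracle_multinomial_p(c(0, 0, 10), bg), tolerance = 1e-12)

  cases <- list(c(2, 3, 5), c(0, 1, 9), c(4, 4, 4), c(7, 0, 1))
  bgs <- list(c(0.15, 0.1, 0.75), c(0.5, 0.25, 0.25), bg, c(0.6, 0.3, 0.1))
  for (i in seq_along(cases)) {
    expect_equal(multinomial_test(cases[[i]], bgs[[i]])$p_value,
                 oracle_multinomial_p(cases[[i]], bgs[[i]]), tolerance = 1e-10)
  }
  # counts matching expectation give p near 1
  expect_gt(multinomial_test(c(4, 4, 4), bg)$p_value, 0.9)
  expect_equal(multinomial_test(c(0, 0, 0), bg)$p_value, 1)
})

test_that("Monte-Carlo branch approximates the exact p-value above the cutoff", {
  bg <- c(0.15, 0.1, 0.75)
  x <- c(6, 2, 12)  # 20 events: exact with a raised cutoff vs seeded MC
  exact <- multinomial_test(x, bg, exact_max = 25)
  set.seed(1)
  mc <- multinomial_test(x, bg, exact_max = 12, nsim = 2e4)
  expect_equal(mc$method, "monte_carlo")
  expect_equal(mc$p_value, exact$p_value, tolerance = 0.02)
})

test_that("paired mutation test finds enriched genes and respects min_events", {
  set.seed(202)
  tabs <- generate_selection_tables(n_genes = 30, n_enriched = 4,
                                    events_per_gene = 12)
  fit <- paired_mutation_test(tabs$events)
  td <- tidy(fit)
  enr <- tabs$truth$gene[tabs$truth$enriched]
  # enriched genes rank above null genes by q (an occasional low-count
  # enriched gene may straggle, so the comparison is on the bulk)
  expect_lt(stats::median(td$q_value[td$gene %in% enr]),
            min(td$q_value[!td$gene %in% enr]))
  expect_gte(sum(td$q_value[td$gene %in% enr] < 0.1), 3)
  g <- glance(fit)
  expect_gte(g$n_significant, 3)

  # a gene with too few driver mutations is skipped, not tested
  ev <- dplyr::bind_rows(
    tibble::tibble(gene = "TINY", label = c("maintained", "maintained"),
                   is_driver = TRUE),
    tabs$events
  )
  fit2 <- paired_mutation_test(ev)
  expect_false("TINY" %in% tidy(fit2)$gene)
  expect_true("TINY" %in% fit2$skipped$gene)
})

test_that("SCNA event calls are ploidy-relative with exposed thresholds", {
  expect_equal(call_scna_event(2, 2), "neutral")
  expect_equal(call_scna_event(0, 2), "lost")
  expect_equal(call_scna_event(6, 2), "amplified")     # 3x ploidy
  expect_equal(call_scna_event(c(4, 1, 8), c(4, 4, 4)),
               c("neutral", "lost", "amplified"))
  expect_equal(call_scna_event(NA, 2), NA_character_)
})

test_that("paired SCNA favouring counts tumour-level presence in each group", {
  expect_equal(classify_paired_scna(c(TRUE, FALSE), c(TRUE, TRUE)), "maintained")
  expect_equal(classify_paired_scna(c(TRUE, TRUE), c(FALSE, FALSE)), "primary_favoured")
  expect_equal(classify_paired_scna(c(FALSE, FALSE), c(TRUE, FALSE)), "metastasis_favoured")
  expect_true(is.na(classify_paired_scna(c(FALSE, FALSE), FALSE)))

  calls <- tibble::tibble(
    tumour_id = rep(sprintf("P%02d", 1:12), 2),
    gene = rep(c("G1", "G2"), each = 12),
    is_driver = rep(c(TRUE, FALSE), each = 12),
    label = c(rep("metastasis_favoured", 10), rep("maintained", 2),
              rep(c("maintained", "primary_favoured"), 6))
  )
  fit <- paired_scna_test(calls)
  expect_equal(tidy(fit)$gene, "G1")
  expect_lt(tidy(fit)$p_value, 0.05)
})

test_that("gene G-scores use overlap, neighbour-mean gaps, and subtract cleanly", {
  scores <- tibble::tibble(chrom = "1",
                           start = c(1, 2001, 5001), end = c(1000, 3000, 6000),
                           g_score = c(1.0, 2.0, 0.5), q_value = c(0.01, 0.2, 0.01))
  genes <- tibble::tibble(gene = c("IN", "GAP", "OFF"),
                          chrom = c("1", "1", "7"),
                          start = c(100, 1200, 5), end = c(300, 1500, 50))
  # a gene on a chromosome without segments is dropped with a warning
  # (once per cohort table)
  expect_warning(expect_warning(
    gsd0 <- gscore_difference(scores, scores, genes, q_threshold = Inf),
    "OFF"), "OFF")
  # identical tables: gsd is 0 for every scored gene
  expect_equal(gsd0$gsd, rep(0, 2))
  expect_equal(gsd0$g_score_met[gsd0$gene == "IN"], 1.0)
  # gene in a gap between scores 1.0 and 2.0 -> neighbour mean 1.5
  expect_equal(gsd0$g_score_met[gsd0$gene == "GAP"], 1.5)

  shifted <- dplyr::mutate(scores, g_score = g_score - 0.25)
  gsd1 <- suppressWarnings(gscore_difference(scores, shifted, genes, q_threshold = Inf))
  expect_equal(gsd1$gsd, rep(0.25, 2))
  # antisymmetry under swapping cohorts
  gsd2 <- suppressWarnings(gscore_difference(shifted, scores, genes, q_threshold = Inf))
  expect_equal(gsd2$gsd, -gsd1$gsd)
  # significance filter keeps genes significant in the metastasis cohort
  # (the gap gene inherits the smaller neighbour q and stays)
  gsdq <- suppressWarnings(gscore_difference(scores, shifted, genes, q_threshold = 0.05))
  expect_equal(sort(gsdq$gene), c("GAP", "IN"))
})

test_that("dN/dS odds ratios are labelled by the 2 / 0.5 thresholds", {
  seeding <- tibble::tibble(gene = c("A", "B", "C", "D"),
                            dnds = c(6, 1, 0.8, 2), q_value = 0.01)
  nonseeding <- tibble::tibble(gene = c("A", "B", "C", "D"),
                               dnds = c(2, 1, 2, 0), q_value = 0.01)
  or <- dnds_odds_ratio(seeding, nonseeding)
  lab <- stats::setNames(or$label, or$gene)
  expect_equal(unname(lab["A"]), "seeding_favoured")  # OR 3
  expect_equal(unname(lab["B"]), "both")              # OR 1
  expect_equal(unname(lab["C"]), "primary_favoured")  # OR 0.4
  expect_equal(unname(lab["D"]), "undetermined")      # zero denominator
  # the q filter drops genes not significant in either input
  seeding$q_value <- c(0.01, 0.5, 0.5, 0.5)
  nonseeding$q_value <- 0.5
  expect_equal(dnds_odds_ratio(seeding, nonseeding)$gene, "A")
})
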