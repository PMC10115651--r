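test_that("primary-clonal clusters and mutation totals follow the group rule", {
  # chain where the deeper cluster is subclonal in one region only
  tree <- make_tree(
    tibble::tribble(
      ~cluster_id, ~R1, ~R2, ~M1,
      "1", 1.0, 1.0, 1.0,
      "2", 1.0, 0.5, 0.0
    ),
    parents = c("ROOT", "1"), n_mutations = c(50L, 30L)
  )
  pc <- primary_clonal_clusters(tree)
  expect_equal(pc$cluster_ids, "1")
  expect_equal(pc$n_mutations, 50L)

  # all clusters clonal everywhere -> all are primary-clonal
  allc <- make_tree(
    tibble::tibble(cluster_id = c("1", "2"), R1 = c(1, 1), R2 = c(1, 0.95), M1 = c(1, 1)),
    parents = c("ROOT", "1"), n_mutations = c(5L, 7L)
  )
  expect_equal(primary_clonal_clusters(allc)$n_mutations, 12L)

  # star tree with region-private children: only the root is primary-clonal
  star <- make_tree(
    tibble::tibble(cluster_id = c("1", "2", "3"),
                   R1 = c(1, 0.5, 0), R2 = c(1, 0, 0.5), M1 = c(1, 0, 0)),
    parents = c("ROOT", "1", "1"), n_mutations = c(40L, 10L, 10L)
  )
  expect_equal(primary_clonal_clusters(star)$cluster_ids, "1")
})

test_that("phylogenetic timing: shared clonal fraction and early/late labels", {
  # two primary-clonal clusters of 60 and 40 mutations; the second is
  # subclonal in the metastasis -> fraction 0.6, early
  tree <- make_tree(
    tibble::tribble(
      ~cluster_id, ~R1, ~R2, ~M1,
      "1", 1.0, 1.0, 1.0,
      "2", 1.0, 1.0, 0.5
    ),
    parents = c("ROOT", "1"), n_mutations = c(60L, 40L)
  )
  td <- time_divergence(tree)
  expect_equal(td$shared_clonal_fraction[td$level == "sample"], 0.6)
  expect_equal(td$label[td$level == "sample"], "early")

  # a primary-clonal cluster entirely absent from the metastasis -> early
  absent <- make_tree(
    tibble::tribble(
      ~cluster_id, ~R1, ~R2, ~M1,
      "1", 1.0, 1.0, 1.0,
      "2", 1.0, 1.0, 0.0
    ),
    parents = c("ROOT", "1")
  )
  expect_equal(time_divergence(absent)$label[1], "early")

  # everything clonal in the metastasis -> late with fraction exactly 1
  late <- make_tree(
    tibble::tibble(cluster_id = c("1", "2"), R1 = c(1, 1), R2 = c(1, 1), M1 = c(1, 1)),
    parents = c("ROOT", "1")
  )
  tl <- time_divergence(late)
  expect_equal(tl$shared_clonal_fraction, c(1, 1))
  expect_equal(tl$label, c("late", "late"))
})

test_that("case-level timing is early if any metastasis is early", {
  mixed <- make_tree(
    tibble::tribble(
      ~cluster_id, ~R1, ~M1, ~M2,
      "1", 1.0, 1.0, 1.0,
      "2", 1.0, 1.0, 0.0
    ),
    parents = c("ROOT", "1")
  )
  td <- time_divergence(mixed)
  expect_equal(td$label[td$target_id == "M1"], "late")
  expect_equal(td$label[td$target_id == "M2"], "early")
  expect_equal(td$label[td$level == "case"], "early")

  both_late <- make_tree(
    tibble::tibble(cluster_id = "1", R1 = 1, M1 = 1, M2 = 1), "ROOT"
  )
  expect_equal(time_divergence(both_late)$label[3], "late")
})

test_that("downsampling at k = n reproduces the full-sampling label", {
  tree <- make_tree(
    tibble::tribble(
      ~cluster_id, ~R1, ~R2, ~R3, ~M1,
      "1", 1.0, 1.0, 1.0, 1.0,
      "2", 1.0, 0.4, 0.0, 0.0
    ),
    parents = c("ROOT", "1")
  )
  full <- downsample_timing(tree, k = 3)
  expect_equal(full$label_at_k, "late")
  expect_equal(full$mean_shared_fraction, 1)
  expect_equal(full$n_combinations, 1L)
})

test_that("a region-private clonal-illusion cluster flips k = 1 to early", {
  tree <- make_tree(
    tibble::tribble(
      ~cluster_id, ~R1, ~R2, ~R3, ~M1,
      "1", 1.0, 1.0, 1.0, 1.0,
      "IL", 1.0, 0.0, 0.0, 0.0
    ),
    parents = c("ROOT", "1"), n_mutations = c(50L, 25L)
  )
  ds <- downsample_timing(tree, k = c(1, 2))
  expect_equal(ds$label_at_k[ds$k_regions == 1], "early")
  # only the subset {R1} sees the illusion cluster as clonal:
  # mean fraction at k=1 = (50/75 + 1 + 1) / 3
  expect_equal(ds$mean_shared_fraction[ds$k_regions == 1], (50 / 75 + 2) / 3)
  expect_equal(ds$label_at_k[ds$k_regions == 2], "late")
  expect_equal(ds$n_combinations, c(3L, 3L))
  expect_error(downsample_timing(tree, k = 5), "within")
})

test_that("mean shared fraction is non-decreasing in k on synthetic late cases", {
  co <- generate_cohort(synth_config(n_cases = 12, fraction_early = 0,
                                     fraction_polyclonal = 0, fraction_polyphyletic = 0,
                                     n_illusion = 1, primary_regions_range = c(3, 5),
                                     seed = 31))
  for (tr in co$trees) {
    ds <- downsample_timing(tr)
    expect_true(all(diff(ds$mean_shared_fraction) >= -1e-12))
  }
})

test_that("region-based shared fraction filters LOH loci and handles empty sets", {
  samples <- tibble::tibble(case_id = "C", sample_id = c("R1", "R2", "M1"),
                            kind = c("primary_region", "primary_region",
                                     "recurrence_progression"))
  # 10 primary-ubiquitous mutations; 2 fall under LOH; 6 of the remaining 8
  # are present in the metastasis -> 0.75
  muts <- tidyr::crossing(pos = 1:10 * 100L, sample_id = c("R1", "R2", "M1")) |>
    dplyr::mutate(chrom = "1", case_id = "C",
                  present = !(sample_id == "M1" & pos %in% c(300L, 400L)))
  loh <- tibble::tibble(chrom = "1", start = c(50, 950), end = c(150, 1050),
                        sample_id = "R2")  # covers pos 100 and 1000
  rs <- region_shared_fraction(muts, loh, samples)
  expect_equal(rs$n_primary_ubiquitous, 8L)
  expect_equal(rs$shared_fraction, 0.75)

  # no LOH and everything shared -> 1
  rs2 <- region_shared_fraction(muts |> dplyr::mutate(present = TRUE), NULL, samples)
  expect_equal(rs2$shared_fraction, 1)

  # every locus under LOH -> undefined marker, not an error
  loh_all <- tibble::tibble(chrom = "1", start = 0, end = 2000, sample_id = "R1")
  rs3 <- region_shared_fraction(muts, loh_all, samples)
  expect_true(is.na(rs3$shared_fraction))
})

test_that("LOH timing uses allele identity and the 75% arm threshold", {
  samples <- tibble::tibble(case_id = "C", sample_id = c("R1", "R2", "M1"),
                            kind = c("primary_region", "primary_region",
                                     "recurrence_progression"))
  # 4 ubiquitous arm losses; metastasis shares 3 -> early with fraction 0.75
  arms <- c("1p", "3p", "9p", "17p")
  loh <- dplyr::bind_rows(
    tidyr::crossing(sample_id = c("R1", "R2"), chrom_arm = arms) |>
      dplyr::mutate(lost_allele = "A", fraction_arm_lost = 0.9),
    tibble::tibble(sample_id = "M1", chrom_arm = c("1p", "3p", "9p"),
                   lost_allele = "A", fraction_arm_lost = 0.9)
  )
  lt <- loh_timing(loh, samples)
  expect_equal(lt$label, "early")
  expect_equal(lt$shared_clonal_fraction, 0.75)

  # same arm but the OTHER allele lost in the metastasis -> early
  loh2 <- dplyr::bind_rows(
    tibble::tibble(sample_id = c("R1", "R2"), chrom_arm = "17p",
                   lost_allele = "A", fraction_arm_lost = 0.8),
    tibble::tibble(sample_id = "M1", chrom_arm = "17p",
                   lost_allele = "B", fraction_arm_lost = 0.8)
  )
  expect_equal(loh_timing(loh2, samples)$label, "early")

  # all shared -> late; sub-threshold arm fractions are ignored entirely
  loh3 <- tidyr::crossing(sample_id = c("R1", "R2", "M1"), chrom_arm = c("1p", "17p")) |>
    dplyr::mutate(lost_allele = "B", fraction_arm_lost = 0.76)
  expect_equal(loh_timing(loh3, samples)$label, "late")
  loh4 <- dplyr::mutate(loh3, fraction_arm_lost = 0.5)
  expect_true(is.na(loh_timing(loh4, samples)$label))
})

test_that("WGD timing distinguishes shared, absent and parallel doubling events", {
  samples <- tibble::tibble(case_id = "C", sample_id = c("R1", "R2", "M1"),
                            kind = c("primary_region", "primary_region",
                                     "recurrence_progression"))
  base <- tibble::tibble(sample_id = c("R1", "R2"), has_wgd = TRUE, wgd_event_id = "w1")
  same <- dplyr::bind_rows(base, tibble::tibble(sample_id = "M1", has_wgd = TRUE,
                                                wgd_event_id = "w1"))
  expect_equal(wgd_timing(same, samples)$label, "late")
  none <- dplyr::bind_rows(base, tibble::tibble(sample_id = "M1", has_wgd = FALSE,
                                                wgd_event_id = NA))
  expect_equal(wgd_timing(none, samples)$label, "early")
  parallel <- dplyr::bind_rows(base, tibble::tibble(sample_id = "M1", has_wgd = TRUE,
                                                    wgd_event_id = "w2"))
  expect_equal(wgd_timing(parallel, samples)$label, "early")
  # primary WGD absent or subclonal -> not applicable
  sub <- tibble::tibble(sample_id = c("R1", "R2", "M1"),
                        has_wgd = c(TRUE, FALSE, TRUE),
                        wgd_event_id = c("w1", NA, "w1"))
  expect_true(is.na(wgd_timing(sub, samples)$label))
})
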