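test_that("fitness-effect draws match the stated distribution of fitness effects", {
  set.seed(1)
  expect_true(all(draw_fitness_effect(1000, 0, "mutation") == 0))
  expect_true(all(draw_fitness_effect(1000, 0, "event") == 0))

  mut <- draw_fitness_effect(1e6, 0.01, "mutation")
  # conditional branch means: negative Exp(mean s), positive Exp(mean s/2)
  expect_equal(mean(-mut[mut < 0]), 0.01, tolerance = 0.02)
  expect_equal(mean(mut[mut > 0]), 0.005, tolerance = 0.02)

  ev <- draw_fitness_effect(1e6, 0.01, "event")
  # events: positive mean twice the mutations' positive mean, negative mean
  # three times the mutations' negative mean
  expect_equal(mean(-ev[ev < 0]), 0.03, tolerance = 0.02)
  expect_equal(mean(ev[ev > 0]), 0.01, tolerance = 0.02)

  # drivers are a deterministic +10 s
  drv <- draw_fitness_effect(50, 0.01, "mutation", driver_prob = 1)
  expect_true(all(drv == 0.1))
})

test_that("growth is reproducible under a seed and conserves genotype bookkeeping", {
  set.seed(123); a <- grow_tumor(small_sim_config())
  set.seed(123); b <- grow_tumor(small_sim_config())
  expect_identical(a$regions, b$regions)
  expect_identical(a$n_mutations, b$n_mutations)
  expect_identical(a$size_history, b$size_history)
  expect_gte(a$n_cells, small_sim_config()$final_size)
  # regions are disjoint groups of ~region_cells cells
  totals <- tapply(a$regions$n_cells, a$regions$region_id, unique)
  expect_equal(length(totals), 4)
  expect_true(all(abs(unlist(totals) - 2e3) < 1e-6))
})

test_that("mutation burden scales with the mutation rate", {
  burden <- function(mu, seed) {
    set.seed(seed)
    grow_tumor(sim_config(final_size = 5e4, region_cells = 5e3, n_regions = 2,
                          mutation_rate = mu, founder_mutations = 0))$n_mutations
  }
  b4 <- mean(sapply(1:3, function(s) burden(0.4, s)))
  b6 <- mean(sapply(1:3, function(s) burden(0.6, s + 50)))
  expect_equal(b6 / b4, 1.5, tolerance = 0.1)
})

test_that("neutral growth carries no fitness variation", {
  set.seed(4)
  t0 <- grow_tumor(sim_config(final_size = 2e4, region_cells = 2e3, n_regions = 2,
                              s = 0))
  # with s = 0 every fitness effect is 0, so a clonal founder mutation keeps
  # VAF ~0.5 and the division rule reduces to density-dependent neutral growth
  w <- simulate_wes(t0$regions)
  founder <- w[w$mutation_id < 100, ]
  expect_equal(mean(founder$vaf), 0.5, tolerance = 0.05)
})

test_that("metastasis seeding contracts: founder counts, sources, primary selection", {
  set.seed(31)
  pair <- simulate_met_pair(small_sim_config(), divergence_size = 5e3,
                            n_cells = 1, met_final_size = 1e4,
                            met_n_regions = 2, met_region_cells = 1e3)
  # one founder cell -> a single founder genotype, monoclonal by construction
  expect_equal(length(pair$met_founders), 1)

  set.seed(32)
  pair100 <- simulate_met_pair(small_sim_config(), divergence_size = 1e4,
                               n_cells = 100, n_source_regions = 3,
                               met_final_size = 1e4,
                               met_n_regions = 2, met_region_cells = 1e3)
  expect_equal(length(pair100$met_founders), 100)
  expect_error(simulate_met_pair(small_sim_config(), divergence_size = 50,
                                 n_cells = 100), "divergence_size >= n_cells")
})

test_that("emulated WES has the right depth, VAF and detection behaviour", {
  regions <- tibble::tibble(region_id = "R1", mutation_id = seq_len(1e4),
                            carriers = 1e4, n_cells = 1e4)
  set.seed(6)
  w <- simulate_wes(regions, depth_mean = 400, error_rate = 1e-3)
  expect_equal(mean(w$depth), 400, tolerance = 0.02)
  expect_equal(mean(w$vaf), 0.5, tolerance = 0.01)   # clonal het
  expect_true(all(w$detected))

  absent <- tibble::tibble(region_id = "R1", mutation_id = 1:2000,
                           carriers = 0, n_cells = 1e4)
  w0 <- simulate_wes(absent, error_rate = 0)
  expect_true(all(w0$alt_reads == 0))
  expect_false(any(w0$detected))
})

test_that("simulated timing rule matches its definition on constructed tables", {
  prim <- tibble::tibble(
    region_id = rep(c("R1", "R2"), each = 2),
    mutation_id = rep(1:2, 2),
    depth = 400L, alt_reads = c(200L, 180L, 190L, 170L)
  ) |> dplyr::mutate(vaf = alt_reads / depth, detected = TRUE)
  met_all <- tibble::tibble(region_id = "M1", mutation_id = 1:2, depth = 400L,
                            alt_reads = 200L, vaf = 0.5, detected = TRUE)
  expect_equal(classify_sim_timing(prim, met_all)$label, "late")
  met_miss <- met_all[1, ]
  res <- classify_sim_timing(prim, met_miss)
  expect_equal(res$label, "early")
  expect_equal(res$shared_fraction, 0.5)
})

test_that("cell counts convert to cube-equivalent diameters", {
  expect_equal(cells_to_diameter(1, 1), 0.015)
  # the printed worked value: 2.5e8 cancer cells at 37% purity ~ 12-13 mm
  d <- cells_to_diameter(2.5e8, 0.37)
  expect_gt(d, 12); expect_lt(d, 13.5)
  # doubling the cells scales the diameter by 2^(1/3)
  expect_equal(cells_to_diameter(2e6, 0.5) / cells_to_diameter(1e6, 0.5),
               2^(1 / 3))
  expect_error(cells_to_diameter(0, 1), "purity")
})

test_that("the simulator output bridges into the observational pipeline", {
  set.seed(71)
  pair <- simulate_met_pair(small_sim_config(), divergence_size = 2e3,
                            n_cells = 1, met_final_size = 1e4,
                            met_n_regions = 2, met_region_cells = 1e3)
  wp <- simulate_wes(pair$regions)
  wm <- simulate_wes(pair$met_regions)
  tree <- abm_bridge(pair, wp, wm)
  # founder mutations form a cluster with CCF ~1 across all samples
  cl <- classify_clonality(tree)
  root_cluster <- as.character(pair$mutations$origin_genotype[
    pair$mutations$mutation_id == 0])
  expect_true(all(cl$status[cl$cluster_id == root_cluster] == "clonal"))
  # a single-founder metastasis is monoclonal through the full pipeline
  dd <- classify_dissemination(tree)
  expect_equal(dd$clonality[dd$level == "case"], "monoclonal")
  expect_error(abm_bridge(pair, wp, wm[0, ]), "empty")
})
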