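test_that("sample-level dissemination clonality follows the shared-cluster rule", {
  # all shared clusters clonal in the met -> monoclonal
  mono <- make_tree(
    tibble::tribble(
      ~cluster_id, ~R1, ~M1,
      "1", 1.0, 1.0,
      "2", 0.6, 1.0
    ),
    parents = c("ROOT", "1")
  )
  dd <- classify_dissemination(mono)
  expect_equal(dd$clonality[dd$level == "sample"], "monoclonal")

  # one shared cluster subclonal in the met -> polyclonal
  poly <- make_tree(
    tibble::tribble(
      ~cluster_id, ~R1, ~M1,
      "1", 1.0, 1.0,
      "2", 0.6, 0.4
    ),
    parents = c("ROOT", "1")
  )
  expect_equal(classify_dissemination(poly)$clonality[1], "polyclonal")

  # met-unique subclonal clusters do not make a met polyclonal
  root_only <- make_tree(
    tibble::tribble(
      ~cluster_id, ~R1, ~M1,
      "1", 1.0, 1.0,
      "2", 0.0, 0.5
    ),
    parents = c("ROOT", "1")
  )
  expect_equal(classify_dissemination(root_only)$clonality[1], "monoclonal")
})

test_that("case-level dissemination detects divergent shared sets across mets", {
  # two monoclonal mets with identical shared sets -> monoclonal case
  same <- make_tree(
    tibble::tibble(cluster_id = c("1", "2"), R1 = c(1, 0.5),
                   M1 = c(1, 1), M2 = c(1, 1)),
    parents = c("ROOT", "1")
  )
  expect_equal(classify_dissemination(same)$clonality[3], "monoclonal")

  # each met monoclonal but shared sets differ -> polyclonal at case level,
  # invisible when only one met is considered (undersampling property)
  diff_sets <- make_tree(
    tibble::tibble(cluster_id = c("1", "2"), R1 = c(1, 0.5),
                   M1 = c(1, 1), M2 = c(1, 0)),
    parents = c("ROOT", "1")
  )
  dd <- classify_dissemination(diff_sets)
  expect_equal(dd$clonality[dd$level == "sample"], c("monoclonal", "monoclonal"))
  expect_equal(dd$clonality[dd$level == "case"], "polyclonal")
  one_met <- make_tree(
    tibble::tibble(cluster_id = c("1", "2"), R1 = c(1, 0.5), M1 = c(1, 1)),
    parents = c("ROOT", "1")
  )
  expect_equal(classify_dissemination(one_met)$clonality[2], "monoclonal")

  # a polyclonal met makes the whole case polyclonal
  onepoly <- make_tree(
    tibble::tibble(cluster_id = c("1", "2"), R1 = c(1, 0.5),
                   M1 = c(1, 1), M2 = c(1, 0.3)),
    parents = c("ROOT", "1")
  )
  expect_equal(classify_dissemination(onepoly)$clonality[3], "polyclonal")
})

test_that("phyletic origin distinguishes single-branch from multi-branch seeding", {
  chain <- make_tree(
    tibble::tibble(cluster_id = c("1", "2", "3"),
                   R1 = c(1, 0.6, 0.3), M1 = c(1, 1, 0.5)),
    parents = c("ROOT", "1", "2")
  )
  expect_equal(phyletic_origin(chain), "monophyletic")

  siblings <- make_tree(
    tibble::tibble(cluster_id = c("1", "2", "3"),
                   R1 = c(1, 0.4, 0.4), M1 = c(1, 0.5, 0.4)),
    parents = c("ROOT", "1", "1")
  )
  expect_equal(phyletic_origin(siblings), "polyphyletic")

  # monoclonal met: origin necessarily monophyletic
  mono <- make_tree(
    tibble::tibble(cluster_id = c("1", "2"), R1 = c(1, 0.6), M1 = c(1, 1)),
    parents = c("ROOT", "1")
  )
  expect_equal(classify_dissemination(mono)$clonality[1], "monoclonal")
  expect_equal(phyletic_origin(mono), "monophyletic")
})

test_that("consensus origin over topologies flags disagreement as uncertain", {
  base <- tibble::tibble(cluster_id = c("1", "2", "3"),
                         R1 = c(1, 0.5, 0.3), M1 = c(1, 0.5, 0.4))
  # default topology: chain 1 -> 2 -> 3 (single branch); alternative: 2 and 3
  # as siblings (two branches)
  topo <- tibble::tibble(case_id = "T1", topology_id = "alt",
                         cluster_id = c("1", "2", "3"),
                         parent_id = c("ROOT", "1", "1"))
  clusters <- base |>
    tidyr::pivot_longer(-cluster_id, names_to = "sample_id", values_to = "ccf") |>
    dplyr::mutate(case_id = "T1",
                  parent_id = c("ROOT", "ROOT", "1", "1", "2", "2")[match(
                    paste(cluster_id), paste(cluster_id))]) |>
    dplyr::mutate(parent_id = dplyr::recode(cluster_id, "1" = "ROOT", "2" = "1", "3" = "2"),
                  n_mutations = 10L)
  samples <- tibble::tibble(case_id = "T1", sample_id = c("R1", "M1"),
                            kind = c("primary_region", "recurrence_progression"))
  tree <- cluster_tree(clusters, samples, topologies = topo)
  expect_equal(phyletic_origin(tree, topology = "default"), "monophyletic")
  expect_equal(phyletic_origin(tree, topology = "alt"), "polyphyletic")
  expect_equal(consensus_origin(tree), "uncertain")

  # identical labels across topologies -> that label
  tree1 <- cluster_tree(clusters, samples)
  expect_equal(consensus_origin(tree1), "monophyletic")
})

test_that("leaf-up seeding: clonal tip is sole seeder; subclonal tips ascend", {
  # chain root -> A -> B with B clonal in the met: B is the only seeder
  chain <- make_tree(
    tibble::tibble(cluster_id = c("R", "A", "B"),
                   R1 = c(1, 0.8, 0.4), M1 = c(1, 1, 1)),
    parents = c("ROOT", "R", "A")
  )
  s <- find_seeding_clusters(chain, met_sample = "M1")
  expect_equal(s$cluster_id, "B")

  # B subclonal (0.4) under A clonal (1.0): both seed (1.0 > 0.4, deepest
  # always included)
  chain2 <- make_tree(
    tibble::tibble(cluster_id = c("R", "A", "B"),
                   R1 = c(1, 0.8, 0.4), M1 = c(1, 1, 0.4)),
    parents = c("ROOT", "R", "A")
  )
  s2 <- find_seeding_clusters(chain2, met_sample = "M1")
  expect_equal(s2$cluster_id, c("A", "B"))

  # an ancestor whose met CCF does not exceed its path-child's is skipped
  chain3 <- make_tree(
    tibble::tibble(cluster_id = c("R", "A", "B"),
                   R1 = c(1, 0.8, 0.4), M1 = c(1, 0.4, 0.4)),
    parents = c("ROOT", "R", "A")
  )
  s3 <- find_seeding_clusters(chain3, met_sample = "M1")
  expect_true("B" %in% s3$cluster_id)
  expect_false("A" %in% s3$cluster_id)   # 0.4 is not > 0.4 (strict rule)
  expect_true("R" %in% s3$cluster_id)    # clonal stop, 1.0 > 0.4
})

test_that("converging branches sum their CCFs on the shared parent", {
  # two sibling branches at 0.5 + 0.5 under a met-clonal parent: both tips
  # seed and the parent (summed CCF 1.0 > 0.5) seeds too
  sib <- make_tree(
    tibble::tibble(cluster_id = c("P", "A", "B"),
                   R1 = c(1, 0.4, 0.4), M1 = c(1, 0.5, 0.5)),
    parents = c("ROOT", "P", "P")
  )
  s <- find_seeding_clusters(sib, met_sample = "M1")
  expect_equal(s$cluster_id, c("A", "B", "P"))
  expect_equal(s$truncal, c(FALSE, FALSE, TRUE))

  # every seeding cluster is shared with the primary
  cl <- classify_clonality(sib)
  shared <- intersect(
    cl$cluster_id[cl$sample_id == "R1" & cl$status != "absent"],
    cl$cluster_id[cl$sample_id == "M1" & cl$status != "absent"]
  )
  expect_true(all(s$cluster_id %in% shared))
})

test_that("sample-level labels are recovered exactly on noiseless synthetic cases", {
  co <- generate_cohort(synth_config(n_cases = 40, seed = 77))
  for (id in names(co$trees)) {
    tr <- co$trees[[id]]
    cl <- classify_clonality(tr)
    truth <- co$truth[co$truth$case_id == id, ]
    dd <- classify_dissemination(tr, cl)
    met_rows <- dd[dd$level == "sample", ]
    expect_equal(stats::setNames(met_rows$clonality, met_rows$target_id),
                 truth$met_clonality[[1]])
    expect_equal(phyletic_origin(tr, cl), truth$origin)
    for (m in names(truth$seeding[[1]])) {
      s <- find_seeding_clusters(tr, cl, met_sample = m)
      expect_equal(s$cluster_id, sort(truth$seeding[[1]][[m]]))
    }
  }
})
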