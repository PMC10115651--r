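#' Tidy a paired selection test
#'
#' @param x A `met_paired_test` from [paired_mutation_test()] or
#'   [paired_scna_test()].
#' @param ... Ignored.
#' @return The per-gene result tibble (counts, background proportions,
#'   `p_value`, `q_value`).
#' @export
tidy.met_paired_test <- function(x, ...) {
  x$table
}

#' One-row summary of a paired selection test
#'
#' @inheritParams tidy.met_paired_test
#' @param alpha Significance level for the reported counts (default 0.05 on
#'   q).
#' @return Tibble with `n_genes`, `n_skipped`, `n_significant`,
#'   `min_q_value`.
#' @export
glance.met_paired_test <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    n_genes = nrow(x$table),
    n_skipped = nrow(x$skipped),
    n_significant = sum(x$table$q_value < alpha, na.rm = TRUE),
    min_q_value = if (nrow(x$table) > 0) min(x$table$q_value) else NA_real_
  )
}

#' Tidy a cluster tree into the long cluster table
#'
#' @param x A [cluster_tree()].
#' @param ... Ignored.
#' @return Long tibble (case_id, cluster_id, parent_id, n_mutations,
#'   sample_id, ccf), the same dialect [read_cluster_table()] reads.
#' @export
tidy.cluster_tree <- function(x, ...) {
  dplyr::inner_join(x$ccf, x$clusters, by = "cluster_id") |>
    dplyr::mutate(case_id = x$case_id, .before = 1) |>
    dplyr::select("case_id", "cluster_id", "parent_id", "n_mutations",
                  "sample_id", "ccf")
}

#' One-row summary of a cluster tree
#'
#' @inheritParams tidy.cluster_tree
#' @return Tibble with case id, cluster/sample counts and the number of
#'   topologies.
#' @export
glance.cluster_tree <- function(x, ...) {
  tibble::tibble(
    case_id = x$case_id,
    n_clusters = nrow(x$clusters),
    n_primary_regions = sum(x$samples$kind == "primary_region"),
    n_met_samples = sum(x$samples$kind != "primary_region"),
    n_topologies = length(x$topologies),
    total_mutations = sum(x$clusters$n_mutations)
  )
}

#' Tidy a simulated tumour
#'
#' @param x A `sim_tumor` from [grow_tumor()].
#' @param ... Ignored.
#' @return The per-region mutation carrier table.
#' @export
tidy.sim_tumor <- function(x, ...) {
  x$regions
}

#' One-row summary of a simulated tumour
#'
#' @inheritParams tidy.sim_tumor
#' @return Tibble with cell, genotype, mutation, sweep and attempt counts.
#' @export
glance.sim_tumor <- function(x, ...) {
  tibble::tibble(
    n_cells = x$n_cells,
    n_genotypes = x$n_genotypes,
    n_mutations = x$n_mutations,
    n_sweeps = x$n_sweeps,
    attempts = x$attempts
  )
}
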