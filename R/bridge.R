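#' Convert simulated WES read-outs into pipeline-ready cluster tables
#'
#' Groups detected mutations into pseudo-clusters by the simulator genotype
#' that introduced them (the ground-truth analogue of mutation clustering,
#' which is outside this package's scope) and assigns each cluster a
#' per-sample CCF of twice its mean VAF (heterozygous-diploid convention).
#' The cluster tree is the genotype ancestry restricted to
#' mutation-introducing genotypes. The result feeds straight into
#' [cluster_tree()], so simulator output can be classified with the same
#' timing and dissemination machinery as observational data.
#'
#' @param pair A [simulate_met_pair()] result.
#' @param wes_primary,wes_met [simulate_wes()] tables for the pair (computed
#'   with defaults when omitted).
#' @param case_id Case id for the emitted tables.
#' @param min_cluster_mutations Drop pseudo-clusters with fewer detected
#'   mutations (default 1 keeps all).
#' @return A [cluster_tree()].
#' @export
abm_bridge <- function(pair,
                       wes_primary = simulate_wes(pair$regions),
                       wes_met = simulate_wes(pair$met_regions),
                       case_id = "SIM1",
                       min_cluster_mutations = 1) {
  if (nrow(wes_met) == 0) abort("metastasis WES table is empty")
  wes <- dplyr::bind_rows(
    dplyr::mutate(wes_primary, sample_id = paste0("P", .data$region_id)),
    dplyr::mutate(wes_met, sample_id = paste0("M", .data$region_id))
  )
  detected_ids <- unique(wes$mutation_id[wes$detected])
  muts <- pair$mutations |>
    dplyr::filter(.data$mutation_id %in% detected_ids)
  if (nrow(muts) == 0) abort("no detected mutations to bridge")

  cluster_sizes <- muts |> dplyr::count(.data$origin_genotype, name = "n_mutations")
  keep <- cluster_sizes |> dplyr::filter(.data$n_mutations >= min_cluster_mutations)
  muts <- dplyr::filter(muts, .data$origin_genotype %in% keep$origin_genotype)

  # cluster parent: nearest ancestor genotype that also owns kept mutations
  edges <- pair$genotype_edges
  parent_of <- stats::setNames(edges$parent_genotype, edges$genotype_id)
  kept_set <- as.character(keep$origin_genotype)
  resolve_parent <- function(g) {
    p <- parent_of[[as.character(g)]]
    while (!is.null(p) && p >= 0 && !(as.character(p) %in% kept_set)) {
      p <- parent_of[[as.character(p)]]
    }
    if (is.null(p) || p < 0) ROOT_MARKER else as.character(p)
  }

  sample_ids <- sort(unique(wes$sample_id))
  # mutations missing from a region's table were below the reporting floor
  # there: their VAF is 0, and must enter the cluster mean as 0
  ccf <- tidyr::crossing(muts, sample_id = sample_ids) |>
    dplyr::left_join(dplyr::select(wes, "mutation_id", "sample_id", "vaf"),
                     by = c("mutation_id", "sample_id")) |>
    dplyr::mutate(vaf = dplyr::coalesce(.data$vaf, 0)) |>
    dplyr::summarise(ccf = pmin(2 * mean(.data$vaf), 1.2),
                     .by = c("origin_genotype", "sample_id"))

  clusters <- ccf |>
    dplyr::mutate(cluster_id = as.character(.data$origin_genotype)) |>
    dplyr::inner_join(
      keep |> dplyr::mutate(cluster_id = as.character(.data$origin_genotype)) |>
        dplyr::select("cluster_id", "n_mutations"),
      by = "cluster_id"
    ) |>
    dplyr::mutate(parent_id = purrr::map_chr(.data$origin_genotype, resolve_parent),
                  case_id = case_id) |>
    dplyr::select("case_id", "cluster_id", "parent_id", "n_mutations",
                  "sample_id", "ccf")
  samples <- tibble::tibble(
    case_id = case_id,
    sample_id = sample_ids,
    kind = dplyr::if_else(startsWith(sample_ids, "M"),
                          "recurrence_progression", "primary_region")
  )
  cluster_tree(clusters, samples)
}
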