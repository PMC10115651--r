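# build a cluster_tree from a wide CCF table: one row per cluster, one
# column per sample; parents and mutation counts given alongside
make_tree <- function(ccf_wide, parents, n_mutations = NULL,
                      met_samples = NULL, case_id = "T1") {
  sample_ids <- setdiff(names(ccf_wide), "cluster_id")
  if (is.null(n_mutations)) n_mutations <- rep(10L, nrow(ccf_wide))
  if (is.null(met_samples)) met_samples <- grep("^M", sample_ids, value = TRUE)
  clusters <- ccf_wide |>
    tidyr::pivot_longer(-cluster_id, names_to = "sample_id", values_to = "ccf") |>
    dplyr::mutate(case_id = case_id,
                  parent_id = parents[match(cluster_id, ccf_wide$cluster_id)],
                  n_mutations = n_mutations[match(cluster_id, ccf_wide$cluster_id)])
  samples <- tibble::tibble(
    case_id = case_id,
    sample_id = sample_ids,
    kind = ifelse(sample_ids %in% met_samples, "recurrence_progression", "primary_region")
  )
  cluster_tree(clusters, samples)
}

# independent brute-force multinomial two-sided p-value over all outcomes
oracle_multinomial_p <- function(x, p) {
  n <- sum(x)
  m <- length(p)
  grid <- expand.grid(rep(list(0:n), m - 1))
  grid$last <- n - rowSums(grid)
  grid <- grid[grid$last >= 0, , drop = FALSE]
  probs <- apply(as.matrix(grid), 1, function(v) stats::dmultinom(v, prob = p))
  p_obs <- stats::dmultinom(x, prob = p)
  sum(probs[probs <= p_obs * (1 + 1e-12)])
}

small_sim_config <- function(...) {
  sim_config(final_size = 2e4, region_cells = 2e3, n_regions = 4, ...)
}
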