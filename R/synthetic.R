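#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a plausible multi-region NSCLC cohort: 2-8 primary
#' regions and 1-3 metastasis samples per case, 6-12 mutation clusters,
#' a quarter of cases diverging early and roughly a third disseminating
#' polyclonally (half of those polyphyletically). They are a realistic mix
#' for exercising the classifiers, not a fit to any particular cohort.
#'
#' @param n_cases Number of cases.
#' @param clusters_range Range (min, max) of mutation clusters per case,
#'   including trunk and special clusters; fillers pad up to the drawn size.
#' @param primary_regions_range Range of primary regions per case.
#' @param mets_range Range of metastasis samples per case.
#' @param fraction_early Fraction of cases whose designated metastasis
#'   diverges early.
#' @param fraction_polyclonal Total fraction of polyclonal cases (includes
#'   the polyphyletic ones).
#' @param fraction_polyphyletic Fraction of cases that are polyphyletic
#'   (must not exceed `fraction_polyclonal`; polyphyletic implies
#'   polyclonal). Early cases are always monophyletic in this generator (a
#'   post-divergence clonal sweep wipes off-trunk clones from the primary,
#'   so shared clusters are confined to the trunk).
#' @param ccf_noise_sd Gaussian noise added to every CCF, then truncated to
#'   `[0, 1]` (0 = noiseless).
#' @param n_illusion Number of region-private clonal-illusion clusters per
#'   (late) case: clusters with CCF 1 in exactly one region and absent
#'   everywhere else, which single-region sampling mistakes for clonal.
#' @param trunk_range Range of trunk (clonal-sweep) clusters.
#' @param seed Optional seed applied by [generate_cohort()].
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_cases = 100,
                         clusters_range = c(6, 12),
                         primary_regions_range = c(2, 8),
                         mets_range = c(1, 3),
                         fraction_early = 0.25,
                         fraction_polyclonal = 0.32,
                         fraction_polyphyletic = 0.15,
                         ccf_noise_sd = 0,
                         n_illusion = 0,
                         trunk_range = c(2, 3),
                         seed = NULL) {
  stopifnot(fraction_polyphyletic <= fraction_polyclonal,
            all(c(fraction_early, fraction_polyclonal, fraction_polyphyletic) >= 0),
            all(c(fraction_early, fraction_polyclonal, fraction_polyphyletic) <= 1),
            primary_regions_range[1] >= 2)
  structure(as.list(environment()), class = "synth_config")
}

rint <- function(range) if (range[1] == range[2]) range[1] else sample(range[1]:range[2], 1)

cluster_mutation_count <- function(n) stats::rnbinom(n, size = 3, mu = 25) + 1L

#' Generate one synthetic case with known ground truth
#'
#' Builds a clone tree and tree-consistent per-sample CCFs realising the
#' requested (or randomly drawn) labels, by construction:
#' \itemize{
#'   \item a clonal trunk (CCF 1 in every sample it swept);
#'   \item \emph{early} cases extend the trunk with a cluster clonal in all
#'     primary regions but absent from the metastases (a post-divergence
#'     sweep);
#'   \item \emph{late} cases attach a seeding branch, subclonal in a proper
#'     subset of regions and clonal in the metastases;
#'   \item \emph{polyclonal} cases leave one shared cluster subclonal in
#'     the metastasis; \emph{polyphyletic} cases place two seeding branches
#'     as siblings;
#'   \item filler clusters attach uniformly at random, confined to a proper
#'     subset of regions and absent from metastases, within the per-sample
#'     CCF budget of their parent (sum rule).
#' }
#' Ground-truth labels are recorded from the construction, never by running
#' the classifiers.
#'
#' @param config A [synth_config()].
#' @param case_id Case identifier.
#' @param timing,clonality,origin Optional forced labels (`"early"`/`"late"`,
#'   `"monoclonal"`/`"polyclonal"`, `"monophyletic"`/`"polyphyletic"`).
#' @param distinct_sets Force >= 2 metastases that are each monoclonal but
#'   share different cluster sets with the primary (a case-level polyclonal
#'   pattern invisible in any single metastasis).
#' @return List with `tree` (a [cluster_tree()]) and `truth` (a one-row
#'   tibble with label columns and list-columns `met_timing`,
#'   `met_clonality`, `seeding` - the per-metastasis seeding cluster ids -
#'   and `illusion_clusters`).
#' @export
generate_case <- function(config, case_id = "SYN001",
                          timing = NULL, clonality = NULL, origin = NULL,
                          distinct_sets = FALSE) {
  n_regions <- rint(config$primary_regions_range)
  n_mets <- rint(config$mets_range)
  if (distinct_sets) n_mets <- max(2L, n_mets)

  if (is.null(timing)) {
    forced_poly <- !is.null(origin) && origin == "polyphyletic"
    timing <- if (stats::runif(1) < config$fraction_early && !distinct_sets && !forced_poly) {
      "early"
    } else {
      "late"
    }
  }
  if (distinct_sets && timing == "early") {
    abort("distinct_sets cases must be late diverging")
  }
  if (is.null(origin) && is.null(clonality)) {
    u <- stats::runif(1)
    if (u < config$fraction_polyphyletic && timing == "late" && !distinct_sets) {
      origin <- "polyphyletic"; clonality <- "polyclonal"
    } else if (u < config$fraction_polyclonal) {
      origin <- "monophyletic"; clonality <- "polyclonal"
    } else {
      origin <- "monophyletic"; clonality <- "monoclonal"
    }
  }
  if (is.null(clonality)) clonality <- "monoclonal"
  if (is.null(origin)) origin <- "monophyletic"
  if (origin == "polyphyletic" && (timing == "early" || distinct_sets)) {
    abort("polyphyletic cases must be late and cannot use distinct_sets")
  }
  if (origin == "polyphyletic") clonality <- "polyclonal"
  if (distinct_sets) clonality <- "polyclonal"

  regions <- sprintf("R%d", seq_len(n_regions))
  mets <- sprintf("M%d", seq_len(n_mets))
  all_samples <- c(regions, mets)

  k <- rint(config$trunk_range)
  trunk <- sprintf("T%d", seq_len(k))
  nodes <- tibble::tibble(cluster_id = trunk,
                          parent_id = c(ROOT_MARKER, trunk[-k]))
  ccf <- matrix(0, nrow = 0, ncol = length(all_samples),
                dimnames = list(NULL, all_samples))
  add_node <- function(id, parent, ccf_row) {
    nodes <<- dplyr::bind_rows(nodes, tibble::tibble(cluster_id = id, parent_id = parent))
    ccf <<- rbind(ccf, matrix(ccf_row, nrow = 1, dimnames = list(id, all_samples)))
  }
  for (t in trunk) ccf <- rbind(ccf, matrix(1, 1, length(all_samples),
                                            dimnames = list(t, all_samples)))
  rownames(ccf)[seq_len(k)] <- trunk

  row_for <- function(region_vals, met_vals) c(region_vals, met_vals)
  zero_regions <- rep(0, n_regions)
  zero_mets <- rep(0, n_mets)

  # illusion clusters: clonal in exactly one region, absent elsewhere (late
  # cases only; an early case's post-divergence sweep leaves them no budget)
  illusion_ids <- character(0)
  illusion_regions <- character(0)
  if (config$n_illusion > 0 && timing == "late") {
    n_il <- min(config$n_illusion, n_regions - 1)
    illusion_regions <- sample(regions, n_il)
    for (i in seq_len(n_il)) {
      id <- sprintf("IL%d", i)
      vals <- zero_regions
      vals[match(illusion_regions[i], regions)] <- 1
      add_node(id, trunk[k], row_for(vals, zero_mets))
      illusion_ids <- c(illusion_ids, id)
    }
  }
  free_regions <- setdiff(regions, illusion_regions)

  # a proper subset of the non-illusion regions, non-empty
  pick_regions <- function(max_size = length(free_regions)) {
    upper <- min(max_size, length(free_regions), n_regions - 1)
    size <- sample(seq_len(max(upper, 1)), 1)
    sample(free_regions, size)
  }

  seeding_truth <- list()
  met_clonality_truth <- stats::setNames(rep("monoclonal", n_mets), mets)
  met_timing_truth <- stats::setNames(rep(timing, n_mets), mets)

  if (timing == "early") {
    # post-divergence sweep: clonal in every region, absent from every met
    add_node("E1", trunk[k], row_for(rep(1, n_regions), zero_mets))
    if (clonality == "polyclonal") {
      # divergence carried two clones: one with the full trunk (now subclonal
      # in the met), one with trunk[1..k-1] only
      v <- stats::runif(1, 0.15, 0.85)
      ccf[trunk[k], mets] <- v
      seeding_truth <- purrr::map(mets, ~ sort(c(trunk[k - 1], trunk[k])))
      met_clonality_truth[] <- "polyclonal"
    } else {
      seeding_truth <- purrr::map(mets, ~ trunk[k])
    }
  } else if (origin == "polyphyletic") {
    a_regions <- pick_regions(); b_regions <- pick_regions()
    va <- stats::runif(1, 0.15, 0.45); vb <- stats::runif(1, 0.15, 0.45)
    ar <- zero_regions; ar[match(a_regions, regions)] <- stats::runif(length(a_regions), 0.1, 0.45)
    br <- zero_regions; br[match(b_regions, regions)] <- stats::runif(length(b_regions), 0.1, 0.45)
    add_node("S1", trunk[k], row_for(ar, rep(va, n_mets)))
    add_node("S2", trunk[k], row_for(br, rep(vb, n_mets)))
    # converging leaf-up walk: both tips seed; the trunk parent collects the
    # summed CCF, exceeds either branch, and is clonal - also seeding
    seeding_truth <- purrr::map(mets, ~ sort(c("S1", "S2", trunk[k])))
    met_clonality_truth[] <- "polyclonal"
  } else if (distinct_sets) {
    # each met monoclonal; met 1 additionally shares S1 (clonal there only)
    s_regions <- pick_regions()
    sr <- zero_regions; sr[match(s_regions, regions)] <- stats::runif(length(s_regions), 0.15, 0.7)
    met_vals <- zero_mets; met_vals[1] <- 1
    add_node("S1", trunk[k], row_for(sr, met_vals))
    seeding_truth <- purrr::map(seq_len(n_mets),
                                ~ if (.x == 1) "S1" else trunk[k])
  } else {
    s_regions <- pick_regions()
    sr <- zero_regions
    sr[match(s_regions, regions)] <- stats::runif(length(s_regions), 0.15, 0.7)
    add_node("S1", trunk[k], row_for(sr, rep(1, n_mets)))
    if (clonality == "polyclonal") {
      s2_regions <- s_regions
      s2r <- zero_regions
      s2r[match(s2_regions, regions)] <- sr[match(s2_regions, regions)] *
        stats::runif(length(s2_regions), 0.3, 0.8)
      v <- stats::runif(1, 0.15, 0.85)
      add_node("S2", "S1", row_for(s2r, rep(v, n_mets)))
      seeding_truth <- purrr::map(mets, ~ c("S1", "S2"))
      met_clonality_truth[] <- "polyclonal"
    } else {
      seeding_truth <- purrr::map(mets, ~ "S1")
    }
  }

  # a metastasis-unique subclone per met keeps metastases from looking like
  # pure clones of the primary; attached to the deepest node with CCF budget
  # in that met so the sum rule holds
  node_depth <- function(id) {
    d <- 0L
    while (id != ROOT_MARKER) {
      id <- nodes$parent_id[nodes$cluster_id == id]
      d <- d + 1L
    }
    d
  }
  for (j in seq_len(n_mets)) {
    met_col <- n_regions + j
    met_budget <- function(node) {
      kids <- nodes$cluster_id[nodes$parent_id == node]
      ccf[node, met_col] - sum(ccf[kids, met_col])
    }
    cand <- rownames(ccf)[ccf[, met_col] > 0]
    cand <- cand[order(-purrr::map_int(cand, node_depth), cand)]
    cand <- cand[purrr::map_dbl(cand, met_budget) >= 0.2]
    if (length(cand) == 0) next
    parent <- cand[1]
    vals <- zero_mets
    vals[j] <- stats::runif(1, 0.1, min(0.6, met_budget(parent) - 0.05))
    add_node(sprintf("MU%d", j), parent, row_for(zero_regions, vals))
  }

  # filler clusters up to the drawn size, uniform attachment within budget
  n_target <- rint(config$clusters_range)
  budget <- function(node, region_idx) {
    kids <- nodes$cluster_id[nodes$parent_id == node]
    ccf[node, region_idx] - sum(ccf[kids, region_idx])
  }
  f <- 0
  while (nrow(nodes) < n_target && f < 4 * n_target) {
    f <- f + 1
    parent <- sample(nodes$cluster_id, 1)
    elig <- free_regions[purrr::map_dbl(free_regions,
                                        ~ budget(parent, match(.x, regions))) >= 0.15]
    elig <- setdiff(elig, character(0))
    if (length(elig) == 0) next
    upper <- min(length(elig), n_regions - 1)
    pres <- sample(elig, sample(seq_len(upper), 1))
    vals <- zero_regions
    for (r in pres) {
      b <- budget(parent, match(r, regions))
      vals[match(r, regions)] <- stats::runif(1, 0.1, min(0.85, b - 0.05))
    }
    add_node(sprintf("F%d", sum(startsWith(nodes$cluster_id, "F")) + 1),
             parent, row_for(vals, zero_mets))
  }

  if (config$ccf_noise_sd > 0) {
    noise <- matrix(stats::rnorm(length(ccf), 0, config$ccf_noise_sd),
                    nrow = nrow(ccf))
    ccf <- pmin(pmax(ccf + noise, 0), 1)
  }

  nodes$n_mutations <- cluster_mutation_count(nrow(nodes))
  clusters_long <- tibble::as_tibble(ccf, rownames = "cluster_id") |>
    tidyr::pivot_longer(-"cluster_id", names_to = "sample_id", values_to = "ccf") |>
    dplyr::inner_join(nodes, by = "cluster_id") |>
    dplyr::mutate(case_id = case_id)
  samples <- tibble::tibble(
    case_id = case_id,
    sample_id = all_samples,
    kind = c(rep("primary_region", n_regions), rep("recurrence_progression", n_mets))
  )
  tree <- cluster_tree(clusters_long, samples)

  case_clonality <- if (clonality == "polyclonal" || distinct_sets) "polyclonal" else "monoclonal"
  truth <- tibble::tibble(
    case_id = case_id,
    timing = timing,
    clonality = case_clonality,
    origin = origin,
    n_regions = n_regions,
    n_mets = n_mets,
    distinct_sets = distinct_sets,
    met_timing = list(met_timing_truth),
    met_clonality = list(met_clonality_truth),
    seeding = list(stats::setNames(seeding_truth, mets)),
    illusion_clusters = list(illusion_ids),
    noise_sd = config$ccf_noise_sd
  )
  list(tree = tree, truth = truth)
}

#' Generate a synthetic cohort
#'
#' @param config A [synth_config()].
#' @return List with `trees` (named list of [cluster_tree()]s), `clusters`
#'   and `samples` (cohort-level long tables in the package's TSV dialect)
#'   and `truth` (one row per case).
#' @examples
#' cohort <- generate_cohort(synth_config(n_cases = 3, seed = 1))
#' cohort$truth
#' @export
generate_cohort <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  ids <- sprintf("SYN%03d", seq_len(config$n_cases))
  cases <- purrr::map(ids, ~ generate_case(config, .x))
  trees <- stats::setNames(purrr::map(cases, "tree"), ids)
  list(
    trees = trees,
    clusters = purrr::map(trees, function(t) {
      dplyr::inner_join(t$ccf, t$clusters, by = "cluster_id") |>
        dplyr::mutate(case_id = t$case_id, .before = 1)
    }) |> dplyr::bind_rows(),
    samples = purrr::map(trees, "samples") |> dplyr::bind_rows(),
    truth = purrr::map(cases, "truth") |> dplyr::bind_rows()
  )
}

#' Synthetic per-gene selection event tables with known enrichment
#'
#' Draws driver-mutation favouring classes per gene from a multinomial:
#' null genes follow the background proportions, enriched genes a shifted
#' distribution favouring the metastasis class. Non-driver background
#' mutations follow the background proportions exactly in expectation.
#'
#' @param n_genes Number of driver genes.
#' @param n_enriched Number of metastasis-enriched genes among them.
#' @param events_per_gene Mean driver mutations per gene (Poisson, shifted
#'   so every gene has at least `min_events`).
#' @param min_events Lower bound on events per gene (default 5).
#' @param background Null proportions (metastasis-favoured,
#'   primary-favoured, maintained).
#' @param enriched Proportions for enriched genes.
#' @param n_background Number of non-driver background mutations.
#' @return List with `events` (tibble: gene, label, is_driver) and `truth`
#'   (tibble: gene, enriched).
#' @export
generate_selection_tables <- function(n_genes = 50, n_enriched = 5,
                                      events_per_gene = 10, min_events = 5,
                                      background = c(0.15, 0.10, 0.75),
                                      enriched = c(0.60, 0.05, 0.35),
                                      n_background = 5000) {
  stopifnot(abs(sum(background) - 1) < 1e-8, abs(sum(enriched) - 1) < 1e-8)
  genes <- sprintf("G%03d", seq_len(n_genes))
  is_enriched <- seq_len(n_genes) <= n_enriched
  events <- purrr::map2(genes, is_enriched, function(g, e) {
    n <- min_events + stats::rpois(1, max(events_per_gene - min_events, 0))
    p <- if (e) enriched else background
    tibble::tibble(gene = g,
                   label = sample(FAVOUR_LEVELS, n, replace = TRUE, prob = p),
                   is_driver = TRUE)
  }) |> dplyr::bind_rows()
  bg <- tibble::tibble(
    gene = "nondriver",
    label = sample(FAVOUR_LEVELS, n_background, replace = TRUE, prob = background),
    is_driver = FALSE
  )
  list(events = dplyr::bind_rows(events, bg),
       truth = tibble::tibble(gene = genes, enriched = is_enriched))
}
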