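# shared clusters of one metastasis: present (clonal or subclonal) in the
# primary sample group AND in the metastasis sample
shared_clusters_met <- function(tree, clonality, met_sample) {
  prim <- present_in_group(clonality, primary_sample_ids(tree))
  met <- clonality |>
    dplyr::filter(.data$sample_id == met_sample, .data$status != "absent")
  sort(intersect(prim, met$cluster_id))
}

#' Classify the clonality of metastatic dissemination
#'
#' Per metastasis sample: if every mutation cluster shared between the
#' primary tumour and the metastasis is clonal *within the metastasis*, a
#' single primary clone founded it - monoclonal dissemination. If any shared
#' cluster is subclonal in the metastasis, several genetically distinct
#' primary clones contributed - polyclonal. At the case level a case is
#' polyclonal if any metastasis is polyclonal, or - even with all-monoclonal
#' metastases - if the metastases were founded by different clones (their
#' shared-cluster sets differ).
#'
#' @inheritParams time_divergence
#' @return Tibble of class `met_dissemination` with one row per metastasis
#'   plus one case row: columns `case_id`, `level`, `target_id`, `clonality`
#'   (`"monoclonal"`/`"polyclonal"`) and a `shared_clusters` list-column
#'   (case level: union over metastases).
#' @examples
#' tree <- metevol_example_tree()
#' classify_dissemination(tree)
#' @export
classify_dissemination <- function(tree, clonality = classify_clonality(tree)) {
  mets <- metastasis_sample_ids(tree)
  if (length(mets) == 0) abort(paste0("case ", tree$case_id, " has no metastasis samples"))
  per_met <- purrr::map(mets, function(m) {
    shared <- shared_clusters_met(tree, clonality, m)
    if (length(shared) == 0) {
      abort(paste0("case ", tree$case_id, ", metastasis ", m,
                   ": no cluster is shared with the primary tumour; ",
                   "the root must be shared - malformed input"))
    }
    met_sub <- clonality |>
      dplyr::filter(.data$sample_id == m, .data$cluster_id %in% shared,
                    .data$status == "subclonal")
    tibble::tibble(level = "sample", target_id = m,
                   clonality = if (nrow(met_sub) > 0) "polyclonal" else "monoclonal",
                   shared_clusters = list(shared))
  }) |> dplyr::bind_rows()
  sets <- per_met$shared_clusters
  same_sets <- all(purrr::map_lgl(sets, ~ identical(.x, sets[[1]])))
  case_clonality <- if (any(per_met$clonality == "polyclonal") || !same_sets) {
    "polyclonal"
  } else {
    "monoclonal"
  }
  case_row <- tibble::tibble(level = "case", target_id = tree$case_id,
                             clonality = case_clonality,
                             shared_clusters = list(sort(unique(unlist(sets)))))
  out <- dplyr::bind_rows(per_met, case_row) |>
    dplyr::mutate(case_id = tree$case_id, .before = 1)
  new_met_tbl(out, c("met_dissemination", "tbl_df", "tbl", "data.frame"))
}

# do the given clusters lie on a single root-to-leaf path of the topology?
clusters_on_single_branch <- function(pm, cluster_ids) {
  if (length(cluster_ids) <= 1) return(TRUE)
  # a set lies on one path iff it is totally ordered by the ancestor relation,
  # which holds iff the deepest member's root path contains all members
  depths <- purrr::map_int(cluster_ids, ~ length(tree_path_to_root(pm, .x)))
  deepest <- cluster_ids[which.max(depths)]
  all(cluster_ids %in% tree_path_to_root(pm, deepest))
}

#' Phyletic origin of the seeding clusters
#'
#' Maps the clusters shared between primary and metastases onto the tree:
#' `monophyletic` when a single root-to-leaf path (branch) covers them all,
#' `polyphyletic` when they are spread over several branches. A monoclonal
#' metastasis is necessarily monophyletic. At the case level the union of
#' shared clusters over all metastases is used; if any metastasis is
#' polyphyletic, so is the case.
#'
#' @inheritParams time_divergence
#' @param met_sample A metastasis sample id for a sample-level call, or
#'   `NULL` (default) for the case-level call.
#' @param topology Which topology of the tree to use (default `"default"`).
#' @return `"monophyletic"` or `"polyphyletic"`.
#' @export
phyletic_origin <- function(tree, clonality = classify_clonality(tree),
                            met_sample = NULL, topology = "default") {
  pm <- tree_parent_map(tree, topology)
  mets <- if (is.null(met_sample)) metastasis_sample_ids(tree) else met_sample
  per_met <- purrr::map_chr(mets, function(m) {
    shared <- shared_clusters_met(tree, clonality, m)
    if (clusters_on_single_branch(pm, shared)) "monophyletic" else "polyphyletic"
  })
  if (!is.null(met_sample)) return(per_met)
  if (any(per_met == "polyphyletic")) return("polyphyletic")
  all_shared <- sort(unique(unlist(purrr::map(mets, ~ shared_clusters_met(tree, clonality, .x)))))
  if (clusters_on_single_branch(pm, all_shared)) "monophyletic" else "polyphyletic"
}

#' Consensus phyletic origin over alternative tree topologies
#'
#' Mutation clustering can admit several tree topologies; the phyletic origin
#' can depend on which one is used. The case-level origin is classified under
#' every topology attached to the tree; when all topologies agree the common
#' label is returned, otherwise `"uncertain"`.
#'
#' @inheritParams phyletic_origin
#' @return `"monophyletic"`, `"polyphyletic"` or `"uncertain"`.
#' @export
consensus_origin <- function(tree, clonality = classify_clonality(tree)) {
  labels <- purrr::map_chr(names(tree$topologies),
                           ~ phyletic_origin(tree, clonality, topology = .x))
  if (length(unique(labels)) == 1) unique(labels) else "uncertain"
}

#' Identify metastasis-seeding clusters (leaf-up algorithm)
#'
#' The seeding clone of a metastasis is the most recent clone shared with the
#' primary tumour. Shared clusters are mapped to the tree and each branch is
#' walked leaf-up: if the deepest shared cluster of a branch is clonal in the
#' metastasis it is the sole seeding cluster of that branch; otherwise its
#' ancestors are ascended until the first cluster clonal in the metastasis,
#' and a cluster on the path is marked seeding when its metastasis phyloCCF
#' strictly exceeds that of its child on the path (the deepest cluster is
#' always seeding - its clone demonstrably reached the metastasis). Where
#' several branches converge on a shared ancestor, the ancestor's effective
#' metastasis CCF is the sum over its converging branches, and the ascent
#' stops at the first cluster clonal in the metastasis.
#'
#' @inheritParams time_divergence
#' @param met_sample Metastasis sample id.
#' @return Tibble of class `met_seeding` with columns `case_id`,
#'   `met_sample_id`, `cluster_id`, `truncal` (is the cluster on the clonal
#'   trunk of the primary, i.e. clonal in every primary region), sorted by
#'   cluster id.
#' @export
find_seeding_clusters <- function(tree, clonality = classify_clonality(tree),
                                  met_sample, clonal_min = 0.9) {
  pm <- tree_parent_map(tree)
  shared <- shared_clusters_met(tree, clonality, met_sample)
  met_ccf <- tree$ccf |> dplyr::filter(.data$sample_id == met_sample)
  ccf <- stats::setNames(met_ccf$ccf, met_ccf$cluster_id)
  met_status <- clonality |> dplyr::filter(.data$sample_id == met_sample)
  is_clonal <- stats::setNames(met_status$status == "clonal", met_status$cluster_id)

  # collapse non-shared clusters: link each shared cluster to its nearest
  # shared ancestor (NA for the top of a shared component)
  nearest_shared_parent <- function(id) {
    cur <- unname(pm[[id]])
    while (cur != ROOT_MARKER && !(cur %in% shared)) cur <- unname(pm[[cur]])
    if (cur == ROOT_MARKER) NA_character_ else cur
  }
  sp <- purrr::map_chr(shared, nearest_shared_parent)
  names(sp) <- shared
  kids_of <- split(shared[!is.na(sp)], sp[!is.na(sp)])

  seeding <- character(0)
  # post-order walk; returns whether the leaf-up ascent is still "open" above
  # this cluster and the effective met CCF it carries upward
  visit <- function(v) {
    kids <- sort(kids_of[[v]] %||% character(0))
    res <- purrr::map(kids, visit)
    open_effs <- purrr::map_dbl(purrr::keep(res, "open"), "eff")
    if (length(kids) == 0) {
      # deepest shared cluster of its branch: always a seeding cluster
      seeding <<- c(seeding, v)
      eff <- ccf[[v]]
      return(list(open = !(isTRUE(is_clonal[[v]]) || eff >= clonal_min), eff = eff))
    }
    if (length(open_effs) == 0) {
      return(list(open = FALSE, eff = 0))  # all branches below terminated
    }
    # branches converging on v add their carried CCFs; a single-branch chain
    # uses v's own phyloCCF
    eff <- if (length(open_effs) >= 2) sum(open_effs) else ccf[[v]]
    if (eff > max(open_effs)) seeding <<- c(seeding, v)
    list(open = !(isTRUE(is_clonal[[v]]) || eff >= clonal_min), eff = eff)
  }
  for (r in sort(shared[is.na(sp)])) {
    if (visit(r)$open) {
      abort(paste0("case ", tree$case_id, ", metastasis ", met_sample,
                   ": leaf-up ascent reached the root without finding a cluster ",
                   "clonal in the metastasis - malformed input"))
    }
  }
  prim_status <- group_status_vec(clonality, primary_sample_ids(tree))
  out <- tibble::tibble(
    case_id = tree$case_id,
    met_sample_id = met_sample,
    cluster_id = sort(unique(seeding))
  ) |>
    dplyr::mutate(truncal = unname(prim_status[.data$cluster_id] == "clonal"))
  new_met_tbl(out, c("met_seeding", "tbl_df", "tbl", "data.frame"))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
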