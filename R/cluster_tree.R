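#' Assemble a mutation-cluster tree for one case
#'
#' A `cluster_tree` is the substrate of every analysis in metevol: a rooted
#' tree of mutation clusters (one node per cluster, parent links given by
#' `parent_id`, the root marked `"ROOT"`) together with the per-sample
#' phylogenetic cancer cell fraction (phyloCCF) of every cluster and the
#' sample metadata of the case.
#'
#' @param clusters Data frame in long format with columns `case_id`,
#'   `cluster_id`, `parent_id`, `n_mutations`, `sample_id`, `ccf` — one row
#'   per cluster x sample. phyloCCF values are point estimates and may
#'   overshoot 1 (they are accepted up to 1.5 and treated as clonal;
#'   correction to exactly 1 happens only inside [clone_proportions()]).
#' @param samples Data frame with columns `case_id`, `sample_id`, `kind`;
#'   `kind` is one of `"primary_region"`, `"primary_LN_satellite"`,
#'   `"recurrence_progression"`. Samples of the latter two kinds form the
#'   metastasis group.
#' @param topologies Optional data frame of alternate tree topologies with
#'   columns `topology_id`, `cluster_id`, `parent_id`. The default topology
#'   (the `parent_id` column of `clusters`) is always used unless an
#'   operation explicitly iterates topologies.
#'
#' @return An object of class `cluster_tree`: a list with tibbles `clusters`
#'   (cluster_id, parent_id, n_mutations), `ccf` (cluster_id, sample_id,
#'   ccf), `samples`, `topologies`, and `case_id`.
#' @examples
#' tree <- cluster_tree(
#'   clusters = tidyr::crossing(
#'     tibble::tibble(case_id = "C1",
#'                    cluster_id = c("1", "2"),
#'                    parent_id  = c("ROOT", "1"),
#'                    n_mutations = c(50L, 20L)),
#'     tibble::tibble(sample_id = c("M1", "R1"))
#'   ) |> dplyr::mutate(ccf = c(1, 1, 0, 0.4)),  # rows: (cluster, sample) sorted
#'   samples = tibble::tibble(case_id = "C1", sample_id = c("R1", "M1"),
#'                            kind = c("primary_region", "recurrence_progression"))
#' )
#' tree
#' @export
cluster_tree <- function(clusters, samples, topologies = NULL) {
  required <- c("case_id", "cluster_id", "parent_id", "n_mutations", "sample_id", "ccf")
  missing_cols <- setdiff(required, names(clusters))
  if (length(missing_cols) > 0) {
    abort(paste0("`clusters` is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (!all(c("case_id", "sample_id", "kind") %in% names(samples))) {
    abort("`samples` needs columns case_id, sample_id, kind")
  }
  case_id <- unique(as.character(clusters$case_id))
  if (length(case_id) != 1) {
    abort("`clusters` must describe exactly one case; see cluster_trees() for cohorts")
  }
  samples <- samples |>
    dplyr::filter(.data$case_id == .env$case_id) |>
    dplyr::mutate(dplyr::across(c("case_id", "sample_id", "kind"), as.character)) |>
    dplyr::arrange(.data$sample_id)
  bad_kind <- setdiff(samples$kind,
                      c("primary_region", "primary_LN_satellite", "recurrence_progression"))
  if (length(bad_kind) > 0) {
    abort(paste0("unknown sample kind: ", paste(bad_kind, collapse = ", ")))
  }
  clusters <- tibble::as_tibble(clusters) |>
    dplyr::mutate(dplyr::across(c("cluster_id", "parent_id", "sample_id"), as.character))

  node_tbl <- clusters |>
    dplyr::distinct(.data$cluster_id, .data$parent_id, .data$n_mutations) |>
    dplyr::arrange(.data$cluster_id)
  if (anyDuplicated(node_tbl$cluster_id)) {
    dup <- node_tbl$cluster_id[duplicated(node_tbl$cluster_id)]
    abort(paste0("inconsistent parent/n_mutations for cluster(s): ",
                 paste(unique(dup), collapse = ", ")))
  }

  ccf_tbl <- clusters |>
    dplyr::select("cluster_id", "sample_id", "ccf") |>
    dplyr::arrange(.data$cluster_id, .data$sample_id)
  if (anyDuplicated(ccf_tbl[c("cluster_id", "sample_id")])) {
    abort("duplicate (cluster_id, sample_id) CCF rows")
  }

  # every cluster must carry a CCF for every sample of the case
  missing_ccf <- tidyr::crossing(cluster_id = node_tbl$cluster_id,
                                 sample_id = samples$sample_id) |>
    dplyr::anti_join(ccf_tbl, by = c("cluster_id", "sample_id"))
  if (nrow(missing_ccf) > 0) {
    abort(paste0("missing CCF for cluster ", missing_ccf$cluster_id[1],
                 " in sample ", missing_ccf$sample_id[1],
                 " (", nrow(missing_ccf), " missing entries in total)"))
  }

  topo <- list(default = stats::setNames(node_tbl$parent_id, node_tbl$cluster_id))
  if (!is.null(topologies)) {
    topologies <- tibble::as_tibble(topologies) |>
      dplyr::mutate(dplyr::across(dplyr::any_of(c("topology_id", "cluster_id", "parent_id")),
                                  as.character))
    if ("case_id" %in% names(topologies)) {
      topologies <- dplyr::filter(topologies, .data$case_id == .env$case_id)
    }
    for (tid in sort(unique(topologies$topology_id))) {
      tt <- dplyr::filter(topologies, .data$topology_id == tid) |>
        dplyr::arrange(.data$cluster_id)
      if (!setequal(tt$cluster_id, node_tbl$cluster_id)) {
        abort(paste0("topology ", tid, " does not cover the same clusters as the default tree"))
      }
      topo[[tid]] <- stats::setNames(tt$parent_id, tt$cluster_id)
    }
  }

  structure(
    list(case_id = case_id,
         clusters = node_tbl,
         ccf = ccf_tbl,
         samples = samples,
         topologies = topo),
    class = "cluster_tree"
  )
}

#' Build one cluster tree per case from cohort tables
#'
#' @inheritParams cluster_tree
#' @return Named list of [cluster_tree()] objects, one per case, ordered by
#'   case id.
#' @export
cluster_trees <- function(clusters, samples, topologies = NULL) {
  ids <- sort(unique(as.character(clusters$case_id)))
  out <- lapply(ids, function(cid) {
    topo <- topologies
    if (!is.null(topo) && "case_id" %in% names(topo)) {
      topo <- dplyr::filter(topo, .data$case_id == cid)
      if (nrow(topo) == 0) topo <- NULL
    }
    cluster_tree(dplyr::filter(clusters, .data$case_id == cid), samples, topo)
  })
  stats::setNames(out, ids)
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat("<cluster_tree> case", x$case_id, "\n")
  cat(" ", nrow(x$clusters), "clusters,",
      sum(x$samples$kind == "primary_region"), "primary regions,",
      sum(x$samples$kind != "primary_region"), "metastasis samples,",
      length(x$topologies), "topology(ies)\n")
  invisible(x)
}

# ---- internal tree helpers -------------------------------------------------

tree_parent_map <- function(tree, topology = "default") {
  pm <- tree$topologies[[topology]]
  if (is.null(pm)) abort(paste0("unknown topology: ", topology))
  pm
}

tree_root <- function(tree, topology = "default") {
  pm <- tree_parent_map(tree, topology)
  roots <- names(pm)[pm == ROOT_MARKER]
  if (length(roots) != 1) abort("tree does not have exactly one root")
  roots
}

tree_children_map <- function(pm) {
  split(names(pm), factor(pm, levels = unique(c(ROOT_MARKER, pm))))
}

# root-to-node path (inclusive), as character vector of cluster ids
tree_path_to_root <- function(pm, id) {
  path <- character(0)
  cur <- id
  n <- length(pm)
  for (i in seq_len(n + 1)) {
    path <- c(cur, path)
    cur <- unname(pm[[cur]])
    if (identical(cur, ROOT_MARKER)) return(path)
    if (is.null(cur) || is.na(cur)) abort(paste0("parent of cluster ", path[1], " not found"))
  }
  abort(paste0("cycle detected while walking ancestors of cluster ", id))
}

primary_sample_ids <- function(tree) {
  sort(tree$samples$sample_id[tree$samples$kind == "primary_region"])
}

metastasis_sample_ids <- function(tree) {
  sort(tree$samples$sample_id[tree$samples$kind != "primary_region"])
}

ccf_lookup <- function(tree) {
  m <- tidyr::pivot_wider(tree$ccf, names_from = "sample_id", values_from = "ccf")
  mat <- as.matrix(m[, -1, drop = FALSE])
  rownames(mat) <- m$cluster_id
  mat
}

#' Validate the structure of a cluster tree
#'
#' Checks that the tree has exactly one root, that parent links are acyclic
#' and complete, and that CCFs are finite and within `[0, 1.5]`. Violations
#' of the phylogenetic sum rule (children CCFs summing above the parent CCF
#' plus `sum_tol` in some sample) are reported as warnings, not errors, since
#' phyloCCF point estimates are noisy.
#'
#' @param tree A [cluster_tree()].
#' @param sum_tol Tolerance for the sum-rule check (default 0.1).
#' @return A tibble of violations with columns `severity` (`"error"` or
#'   `"warning"`), `check` and `detail`; zero rows when the tree is valid.
#' @export
validate_tree <- function(tree, sum_tol = 0.1) {
  out <- list()
  add <- function(severity, check, detail) {
    out[[length(out) + 1]] <<- tibble::tibble(severity = severity, check = check, detail = detail)
  }
  pm <- tree$topologies$default
  roots <- names(pm)[pm == ROOT_MARKER]
  if (length(roots) != 1) {
    add("error", "single_root", paste0(length(roots), " root clusters found"))
  }
  unknown_parent <- setdiff(setdiff(unname(pm), ROOT_MARKER), names(pm))
  if (length(unknown_parent) > 0) {
    add("error", "parent_exists",
        paste0("parent id(s) not present as clusters: ", paste(unknown_parent, collapse = ", ")))
  }
  # cycle detection by iterative parent-walking with a visit bound
  if (length(unknown_parent) == 0) {
    for (id in names(pm)) {
      cur <- id
      ok <- FALSE
      for (i in seq_len(length(pm) + 1)) {
        cur <- unname(pm[[cur]])
        if (identical(cur, ROOT_MARKER)) { ok <- TRUE; break }
      }
      if (!ok) {
        add("error", "acyclic", paste0("cycle reachable from cluster ", id))
        break
      }
    }
  }
  bad_ccf <- tree$ccf |>
    dplyr::filter(!is.finite(.data$ccf) | .data$ccf < 0 | .data$ccf > 1.5)
  if (nrow(bad_ccf) > 0) {
    add("error", "ccf_range",
        paste0("CCF outside [0, 1.5] for cluster ", bad_ccf$cluster_id[1],
               " sample ", bad_ccf$sample_id[1]))
  }
  if (sum(unname(pm) == ROOT_MARKER) == 1 && length(unknown_parent) == 0) {
    parent_ccf <- tree$ccf |>
      dplyr::rename(parent_ccf = "ccf") |>
      dplyr::rename(parent_id = "cluster_id")
    sums <- tree$clusters |>
      dplyr::filter(.data$parent_id != ROOT_MARKER) |>
      dplyr::select("cluster_id", "parent_id") |>
      dplyr::inner_join(tree$ccf, by = "cluster_id") |>
      dplyr::summarise(child_sum = sum(.data$ccf), .by = c("parent_id", "sample_id")) |>
      dplyr::inner_join(parent_ccf, by = c("parent_id", "sample_id")) |>
      dplyr::filter(.data$child_sum > .data$parent_ccf + sum_tol)
    if (nrow(sums) > 0) {
      for (i in seq_len(nrow(sums))) {
        add("warning", "sum_rule",
            sprintf("children of %s sum to %.3f > parent CCF %.3f in sample %s",
                    sums$parent_id[i], sums$child_sum[i], sums$parent_ccf[i], sums$sample_id[i]))
      }
    }
  }
  if (length(out) == 0) {
    tibble::tibble(severity = character(), check = character(), detail = character())
  } else {
    dplyr::bind_rows(out)
  }
}
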