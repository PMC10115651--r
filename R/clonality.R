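#' Classify per-sample cluster clonality from phyloCCF
#'
#' Every (cluster, sample) pair is labelled `clonal`, `subclonal` or `absent`
#' from its phyloCCF point estimate: clonal when `ccf >= clonal_min`, absent
#' when `ccf < absent_max`, subclonal otherwise. Point estimates above 1
#' (overshoot) count as clonal. The thresholds are deliberately exposed:
#' upstream pipelines differ in how they call clonality (some use CCF
#' confidence intervals); the defaults here are a point-estimate stand-in.
#'
#' @param tree A [cluster_tree()].
#' @param clonal_min Minimum CCF to call a cluster clonal in a sample
#'   (default 0.9).
#' @param absent_max CCF below which a cluster is absent (default 0.05).
#' @return A tibble of class `met_clonality` with columns `cluster_id`,
#'   `sample_id`, `ccf` and `status` (ordered factor absent < subclonal <
#'   clonal), complete over clusters x samples.
#' @examples
#' tree <- metevol_example_tree()
#' classify_clonality(tree)
#' @export
classify_clonality <- function(tree, clonal_min = 0.9, absent_max = 0.05) {
  stopifnot(inherits(tree, "cluster_tree"))
  if (!(absent_max >= 0 && absent_max < clonal_min && clonal_min <= 1)) {
    abort("thresholds must satisfy 0 <= absent_max < clonal_min <= 1")
  }
  if (any(!is.finite(tree$ccf$ccf))) {
    bad <- tree$ccf[!is.finite(tree$ccf$ccf), ]
    abort(paste0("non-finite CCF for cluster ", bad$cluster_id[1],
                 " in sample ", bad$sample_id[1]))
  }
  out <- tree$ccf |>
    dplyr::mutate(
      status = dplyr::case_when(
        .data$ccf >= .env$clonal_min ~ "clonal",
        .data$ccf < .env$absent_max ~ "absent",
        TRUE ~ "subclonal"
      ),
      status = factor(.data$status, levels = STATUS_LEVELS, ordered = TRUE)
    ) |>
    dplyr::arrange(.data$cluster_id, .data$sample_id)
  new_met_tbl(out, c("met_clonality", "tbl_df", "tbl", "data.frame"))
}

#' Aggregate cluster clonality over a sample group
#'
#' A cluster is `clonal` at the group level only if it is clonal in every
#' sample of the group, `absent` only if absent in every sample, and
#' `subclonal` otherwise (i.e. subclonal or absent in at least one sample
#' while present in at least one).
#'
#' @param clonality A [classify_clonality()] table.
#' @param sample_ids Character vector of sample ids forming the group
#'   (non-empty).
#' @param group Label stored in the output (`"primary"`, `"metastases"` or
#'   any custom tag).
#' @return Tibble with columns `cluster_id`, `group`, `status`.
#' @export
group_status <- function(clonality, sample_ids, group = "custom") {
  if (length(sample_ids) == 0) abort("`sample_ids` must be non-empty")
  unknown <- setdiff(sample_ids, unique(clonality$sample_id))
  if (length(unknown) > 0) {
    abort(paste0("unknown sample id(s): ", paste(unknown, collapse = ", ")))
  }
  clonality |>
    dplyr::filter(.data$sample_id %in% .env$sample_ids) |>
    dplyr::summarise(
      status = dplyr::case_when(
        all(.data$status == "clonal") ~ "clonal",
        all(.data$status == "absent") ~ "absent",
        TRUE ~ "subclonal"
      ),
      .by = "cluster_id"
    ) |>
    dplyr::mutate(group = .env$group, .after = "cluster_id") |>
    dplyr::mutate(status = factor(.data$status, levels = STATUS_LEVELS, ordered = TRUE)) |>
    dplyr::arrange(.data$cluster_id)
}

# group status for a single cluster set, returned as a named factor
group_status_vec <- function(clonality, sample_ids) {
  gs <- group_status(clonality, sample_ids)
  stats::setNames(gs$status, gs$cluster_id)
}

# clusters "present" in a sample group: clonal or subclonal in >=1 sample
present_in_group <- function(clonality, sample_ids) {
  gs <- group_status_vec(clonality, sample_ids)
  sort(names(gs)[gs != "absent"])
}

#' Small worked-example tree
#'
#' A four-cluster, two-region, one-metastasis case used throughout the
#' documentation: a clonal trunk (clusters 1-2), a region-restricted
#' primary subclone (3) and a metastasis-shared subclone (4).
#'
#' @return A [cluster_tree()].
#' @export
metevol_example_tree <- function() {
  nodes <- tibble::tibble(
    cluster_id = c("1", "2", "3", "4"),
    parent_id = c(ROOT_MARKER, "1", "2", "2"),
    n_mutations = c(120L, 40L, 25L, 15L)
  )
  ccf <- tibble::tribble(
    ~cluster_id, ~R1, ~R2, ~M1,
    "1", 1.00, 1.00, 1.00,
    "2", 1.00, 0.98, 1.00,
    "3", 0.60, 0.00, 0.00,
    "4", 0.30, 0.45, 1.00
  ) |>
    tidyr::pivot_longer(-"cluster_id", names_to = "sample_id", values_to = "ccf")
  clusters <- dplyr::inner_join(nodes, ccf, by = "cluster_id") |>
    dplyr::mutate(case_id = "EX1", .before = 1)
  samples <- tibble::tibble(
    case_id = "EX1",
    sample_id = c("R1", "R2", "M1"),
    kind = c("primary_region", "primary_region", "recurrence_progression")
  )
  cluster_tree(clusters, samples)
}
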