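#' Estimate per-region clone proportions from phyloCCF
#'
#' Converts the cumulative phyloCCF of each mutation cluster into the
#' proportion of cancer cells belonging to exactly that clone, bottom-up:
#' a leaf cluster's clone proportion equals its phyloCCF (its mutations exist
#' only in cells of its own clone), and an internal cluster's proportion is
#' its phyloCCF minus the summed phyloCCF of its direct children (subtracting
#' all descendants would double-count). Because phyloCCF is a point estimate,
#' clonal clusters are first corrected to a CCF of exactly 1, negative
#' differences are clamped to 0, and the vector is renormalised to sum to 1
#' per sample. The output is the clone-labelling input expected by migration
#' -history tools such as MACHINA.
#'
#' @inheritParams time_divergence
#' @param sample_ids Samples to compute proportions for (default: all samples
#'   of the case).
#' @param clonality Used only for the clonal-CCF correction; pass `NULL` to
#'   skip the correction.
#' @return Tibble of class `met_proportions` with columns `case_id`,
#'   `sample_id`, `cluster_id`, `proportion`; proportions sum to 1 per
#'   sample.
#' @examples
#' tree <- metevol_example_tree()
#' clone_proportions(tree)
#' @export
clone_proportions <- function(tree, clonality = classify_clonality(tree),
                              sample_ids = sort(tree$samples$sample_id)) {
  pm <- tree_parent_map(tree)
  ids <- sort(names(pm))
  kids <- split(names(pm)[pm != ROOT_MARKER], pm[pm != ROOT_MARKER])
  out <- purrr::map(sample_ids, function(s) {
    cc <- tree$ccf |> dplyr::filter(.data$sample_id == s)
    ccf <- stats::setNames(cc$ccf, cc$cluster_id)
    if (!is.null(clonality)) {
      st <- clonality |> dplyr::filter(.data$sample_id == s)
      clonal_ids <- st$cluster_id[st$status == "clonal"]
      ccf[clonal_ids] <- 1
    }
    ccf <- pmin(ccf, 1)
    prop <- purrr::map_dbl(ids, function(v) {
      ch <- kids[[v]]
      if (is.null(ch)) ccf[[v]] else ccf[[v]] - sum(ccf[ch])
    })
    prop <- pmax(prop, 0)
    total <- sum(prop)
    if (total <= 0) {
      abort(paste0("case ", tree$case_id, ", sample ", s,
                   ": all clone proportions are zero"))
    }
    tibble::tibble(case_id = tree$case_id, sample_id = s,
                   cluster_id = ids, proportion = prop / total)
  }) |> dplyr::bind_rows()
  new_met_tbl(out, c("met_proportions", "tbl_df", "tbl", "data.frame"))
}

#' Clonal dispersion index of a regional CCF vector
#'
#' `D = 1 - (max(p) - 1/n) / (1 - 1/n)` where `p` is the CCF vector
#' normalised to proportions over the `n` primary regions. `D = 0` for a
#' clone entirely private to a single region, `D = 1` for a clone evenly
#' spread across all regions; invariant to uniform scaling of the CCFs.
#'
#' @param x Numeric vector of per-region CCFs (length >= 2, non-negative,
#'   not all zero).
#' @return The dispersion index in `[0, 1]`, or `NA` when `length(x) < 2`
#'   (the formula is degenerate for a single region).
#' @examples
#' dispersion_index(c(0.5, 0.5, 0.5)) # 1: evenly spread
#' dispersion_index(c(0.8, 0, 0))     # 0: region-private
#' dispersion_index(c(0.6, 0.2, 0.2)) # 0.6
#' @export
dispersion_index <- function(x) {
  if (length(x) < 2) return(NA_real_)
  if (any(x < 0) || !all(is.finite(x))) abort("CCFs must be finite and non-negative")
  total <- sum(x)
  if (total <= 0) abort("CCF vector sums to zero")
  p <- x / total
  n <- length(x)
  1 - (max(p) - 1 / n) / (1 - 1 / n)
}

#' Dispersion and maximum CCF of every cluster across primary regions
#'
#' Subclonal expansion of a clone within the primary tumour shows up as high
#' regional dominance (max CCF) and broad spread (dispersion). Seeding
#' clusters tend to score higher on both than non-seeding clusters.
#'
#' @inheritParams time_divergence
#' @return Tibble of class `met_dispersion` with one row per cluster:
#'   `case_id`, `cluster_id`, `n_regions`, `max_ccf`, `dispersion`.
#' @export
clonal_dispersion <- function(tree) {
  regions <- primary_sample_ids(tree)
  out <- tree$ccf |>
    dplyr::filter(.data$sample_id %in% regions) |>
    dplyr::summarise(
      n_regions = dplyr::n(),
      max_ccf = max(.data$ccf),
      dispersion = if (sum(.data$ccf) > 0) dispersion_index(.data$ccf) else NA_real_,
      .by = "cluster_id"
    ) |>
    dplyr::mutate(case_id = tree$case_id, .before = 1) |>
    dplyr::arrange(.data$cluster_id)
  new_met_tbl(out, c("met_dispersion", "tbl_df", "tbl", "data.frame"))
}
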