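#' Clusters clonal across all primary tumour regions
#'
#' Returns the clusters whose group-level status over all primary regions is
#' clonal, together with the total number of mutations they carry. These
#' mutations define the last clonal sweep of the primary tumour, the
#' reference point for early/late divergence.
#'
#' @inheritParams classify_clonality
#' @param clonality A [classify_clonality()] table; computed from `tree` with
#'   default thresholds when not supplied.
#' @param region_ids Primary regions to use; defaults to all
#'   `primary_region` samples of the case. Passing a subset implements
#'   downsampling.
#' @return List with `cluster_ids` (sorted character vector) and
#'   `n_mutations` (their summed mutation count).
#' @export
primary_clonal_clusters <- function(tree, clonality = classify_clonality(tree),
                                    region_ids = primary_sample_ids(tree)) {
  if (length(region_ids) == 0) abort("case has no primary regions")
  gs <- group_status_vec(clonality, region_ids)
  ids <- sort(names(gs)[gs == "clonal"])
  if (length(ids) == 0) {
    abort(paste0("case ", tree$case_id, ": no cluster is clonal in all primary regions; ",
                 "the root should be clonal everywhere - check the input CCFs"))
  }
  n <- sum(tree$clusters$n_mutations[tree$clusters$cluster_id %in% ids])
  list(cluster_ids = ids, n_mutations = n)
}

timing_call_sample <- function(tree, clonality, met_sample, epsilon = 1e-9,
                               region_ids = primary_sample_ids(tree)) {
  pc <- primary_clonal_clusters(tree, clonality, region_ids)
  met_status <- clonality |>
    dplyr::filter(.data$sample_id == met_sample, .data$cluster_id %in% pc$cluster_ids)
  shared_ids <- met_status$cluster_id[met_status$status == "clonal"]
  n_shared <- sum(tree$clusters$n_mutations[tree$clusters$cluster_id %in% shared_ids])
  frac <- n_shared / pc$n_mutations
  list(fraction = frac,
       label = if (frac < 1 - epsilon) "early" else "late")
}

#' Time metastatic divergence (phylogenetic method)
#'
#' For each metastasis sample, computes the fraction of primary-clonal
#' mutations (mutations in clusters clonal across all primary regions) that
#' are also clonal in the metastasis. A fraction below one means a clonal
#' sweep completed in the primary after the metastatic lineage branched off:
#' the metastasis diverged *early*. A fraction of one means no further sweep
#' occurred: *late* divergence. The case-level label is early if any
#' metastasis is early.
#'
#' @inheritParams primary_clonal_clusters
#' @param epsilon Numerical tolerance for "fraction < 1" (default 1e-9;
#'   fractions are ratios of integer mutation counts so the comparison is
#'   effectively exact).
#' @return A tibble of class `met_timing` with one row per metastasis sample
#'   plus one case-level row: columns `case_id`, `level` (`"sample"` /
#'   `"case"`), `target_id`, `label` (`"early"` / `"late"`),
#'   `shared_clonal_fraction` (case level: minimum over samples) and
#'   `method`.
#' @examples
#' tree <- metevol_example_tree()
#' time_divergence(tree)
#' @export
time_divergence <- function(tree, clonality = classify_clonality(tree), epsilon = 1e-9) {
  mets <- metastasis_sample_ids(tree)
  if (length(mets) == 0) abort(paste0("case ", tree$case_id, " has no metastasis samples"))
  per_met <- purrr::map(mets, function(m) {
    call <- timing_call_sample(tree, clonality, m, epsilon)
    tibble::tibble(level = "sample", target_id = m, label = call$label,
                   shared_clonal_fraction = call$fraction)
  }) |> dplyr::bind_rows()
  case_row <- tibble::tibble(
    level = "case", target_id = tree$case_id,
    label = if (any(per_met$label == "early")) "early" else "late",
    shared_clonal_fraction = min(per_met$shared_clonal_fraction)
  )
  out <- dplyr::bind_rows(per_met, case_row) |>
    dplyr::mutate(case_id = tree$case_id, .before = 1) |>
    dplyr::mutate(method = "phylogenetic")
  new_met_tbl(out, c("met_timing", "tbl_df", "tbl", "data.frame"))
}

#' Effect of downsampling primary regions on timing calls
#'
#' Re-times divergence using every k-subset of the primary regions, for each
#' requested k. Fewer regions inflate the apparent primary-clonal set
#' (subclonal clusters look clonal when the regions that reveal their
#' subclonality are dropped - the "illusion of clonality"), so cases that are
#' late at full sampling can be misclassified early. Per metastasis, the
#' shared clonal fraction is averaged over all C(n, k) subsets; the reported
#' per-k fraction additionally averages over metastases, and the per-k label
#' follows the any-early case convention applied to the per-metastasis mean
#' fractions.
#'
#' @inheritParams time_divergence
#' @param k Integer vector of subset sizes; default `1:(n-1)` where n is the
#'   number of primary regions (k = n is allowed and reproduces the full
#'   sampling call).
#' @return A tibble of class `met_downsample` with columns `case_id`,
#'   `k_regions`, `mean_shared_fraction`, `label_at_k`, `n_combinations`.
#' @export
downsample_timing <- function(tree, clonality = classify_clonality(tree),
                              k = NULL, epsilon = 1e-9) {
  regions <- primary_sample_ids(tree)
  n <- length(regions)
  if (is.null(k)) k <- seq_len(max(n - 1, 1))
  if (any(k < 1 | k > n)) abort(paste0("k must be within [1, ", n, "]"))
  mets <- metastasis_sample_ids(tree)
  rows <- purrr::map(sort(unique(k)), function(kk) {
    subsets <- utils::combn(regions, kk, simplify = FALSE)
    # per met: average fraction over subsets
    met_means <- purrr::map_dbl(mets, function(m) {
      mean(purrr::map_dbl(subsets, function(rs) {
        timing_call_sample(tree, clonality, m, epsilon, region_ids = rs)$fraction
      }))
    })
    tibble::tibble(
      case_id = tree$case_id,
      k_regions = kk,
      mean_shared_fraction = mean(met_means),
      label_at_k = if (any(met_means < 1 - epsilon)) "early" else "late",
      n_combinations = length(subsets)
    )
  }) |> dplyr::bind_rows()
  new_met_tbl(rows, c("met_downsample", "tbl_df", "tbl", "data.frame"))
}

#' Region-based shared mutation fraction
#'
#' Orthogonal, phylogeny-free timing evidence: among mutations detected in
#' every primary region (primary-ubiquitous) whose loci do not overlap a
#' segment of LOH in any sample (LOH can delete a mutation after divergence,
#' confounding presence calls), the fraction also detected in the metastasis.
#'
#' @param mutations Data frame with columns `chrom`, `pos` (1-based),
#'   `sample_id`, `present` (0/1 or logical), one row per mutation x sample.
#'   Mutations are identified by (chrom, pos).
#' @param loh_segments Data frame of LOH segments with columns `chrom`,
#'   `start`, `end` (0-based half-open) and `sample_id`; `NULL` for no
#'   filtering.
#' @param samples Sample metadata as in [cluster_tree()].
#' @return Tibble with one row per metastasis sample: `sample_id`,
#'   `n_primary_ubiquitous`, `shared_fraction` (`NA` when the
#'   primary-ubiquitous set is empty after LOH filtering).
#' @export
region_shared_fraction <- function(mutations, loh_segments, samples) {
  mutations <- tibble::as_tibble(mutations) |>
    dplyr::mutate(chrom = as.character(.data$chrom),
                  present = as.logical(.data$present),
                  mut_key = paste(.data$chrom, .data$pos, sep = ":"))
  primaries <- sort(samples$sample_id[samples$kind == "primary_region"])
  mets <- sort(samples$sample_id[samples$kind != "primary_region"])
  if (!is.null(loh_segments) && nrow(loh_segments) > 0) {
    loci <- dplyr::distinct(mutations, .data$chrom, .data$pos, .data$mut_key)
    seg_gr <- GenomicRanges::GRanges(
      seqnames = as.character(loh_segments$chrom),
      ranges = IRanges::IRanges(start = loh_segments$start + 1L, end = loh_segments$end)
    )
    mut_gr <- GenomicRanges::GRanges(
      seqnames = loci$chrom,
      ranges = IRanges::IRanges(start = loci$pos, width = 1L)
    )
    hits <- GenomicRanges::findOverlaps(mut_gr, seg_gr)
    drop_keys <- unique(loci$mut_key[S4Vectors_queryHits(hits)])
    mutations <- dplyr::filter(mutations, !(.data$mut_key %in% drop_keys))
  }
  ubiq <- mutations |>
    dplyr::filter(.data$sample_id %in% primaries) |>
    dplyr::summarise(in_all = sum(.data$present) == length(primaries) &&
                       dplyr::n() == length(primaries),
                     .by = "mut_key") |>
    dplyr::filter(.data$in_all)
  purrr::map(mets, function(m) {
    if (nrow(ubiq) == 0) {
      return(tibble::tibble(sample_id = m, n_primary_ubiquitous = 0L,
                            shared_fraction = NA_real_))
    }
    met_present <- mutations |>
      dplyr::filter(.data$sample_id == m, .data$mut_key %in% ubiq$mut_key, .data$present)
    tibble::tibble(sample_id = m,
                   n_primary_ubiquitous = nrow(ubiq),
                   shared_fraction = nrow(met_present) / nrow(ubiq))
  }) |> dplyr::bind_rows()
}

# thin wrapper so the IRanges generic is easy to stub in tests
S4Vectors_queryHits <- function(hits) S4Vectors::queryHits(hits)

#' LOH-based divergence timing
#'
#' Arm-level LOH is a ratchet: once an allele is lost in every cell it cannot
#' be regained. An arm-level LOH event (>= 75 percent of the arm lost) that is
#' ubiquitous in the primary (same arm, same lost allele in every region)
#' must predate divergence of any metastasis that carries it; a metastasis
#' missing such an event, or having lost the *other* allele, diverged before
#' the event swept - early.
#'
#' @param arm_loh Data frame with columns `sample_id`, `chrom_arm`,
#'   `lost_allele` (`"A"`/`"B"`), `fraction_arm_lost`; one row per observed
#'   arm-loss. Rows with `fraction_arm_lost < min_arm_fraction` are ignored.
#' @param samples Sample metadata as in [cluster_tree()].
#' @param min_arm_fraction Minimum fraction of the arm lost for an event to
#'   count (default 0.75).
#' @return Tibble of class `met_timing`: one row per metastasis with `label`
#'   (`NA` when no primary-ubiquitous arm LOH exists), the
#'   `shared_clonal_fraction` of ubiquitous events shared, and
#'   `method = "loh"`.
#' @export
loh_timing <- function(arm_loh, samples, min_arm_fraction = 0.75) {
  arm_loh <- tibble::as_tibble(arm_loh) |>
    dplyr::filter(.data$fraction_arm_lost >= min_arm_fraction)
  primaries <- sort(samples$sample_id[samples$kind == "primary_region"])
  mets <- sort(samples$sample_id[samples$kind != "primary_region"])
  ubiq <- arm_loh |>
    dplyr::filter(.data$sample_id %in% primaries) |>
    dplyr::distinct(.data$sample_id, .data$chrom_arm, .data$lost_allele) |>
    dplyr::summarise(n = dplyr::n(), .by = c("chrom_arm", "lost_allele")) |>
    dplyr::filter(.data$n == length(primaries))
  out <- purrr::map(mets, function(m) {
    if (nrow(ubiq) == 0) {
      return(tibble::tibble(level = "sample", target_id = m, label = NA_character_,
                            shared_clonal_fraction = NA_real_))
    }
    met_events <- arm_loh |>
      dplyr::filter(.data$sample_id == m) |>
      dplyr::distinct(.data$chrom_arm, .data$lost_allele)
    shared <- dplyr::inner_join(ubiq, met_events, by = c("chrom_arm", "lost_allele"))
    frac <- nrow(shared) / nrow(ubiq)
    tibble::tibble(level = "sample", target_id = m,
                   label = if (frac < 1) "early" else "late",
                   shared_clonal_fraction = frac)
  }) |> dplyr::bind_rows() |>
    dplyr::mutate(case_id = unique(samples$case_id)[1], .before = 1) |>
    dplyr::mutate(method = "loh")
  new_met_tbl(out, c("met_timing", "tbl_df", "tbl", "data.frame"))
}

#' WGD-based divergence timing
#'
#' When the primary tumour carries a clonal whole-genome doubling (the same
#' WGD event in all primary regions), a metastasis lacking WGD, or carrying a
#' *different* (parallel) WGD event, must have diverged before the primary's
#' doubling - early. A metastasis sharing the same event is late. Cases
#' without a clonal primary WGD are not informative (`NA`).
#'
#' @param wgd_calls Data frame with columns `sample_id`, `has_wgd` (logical),
#'   `wgd_event_id` (event identity; `NA` when `has_wgd` is `FALSE`).
#' @param samples Sample metadata as in [cluster_tree()].
#' @return Tibble of class `met_timing` with one row per metastasis,
#'   `method = "wgd"`; `label` is `NA` when not applicable.
#' @export
wgd_timing <- function(wgd_calls, samples) {
  wgd_calls <- tibble::as_tibble(wgd_calls)
  primaries <- sort(samples$sample_id[samples$kind == "primary_region"])
  mets <- sort(samples$sample_id[samples$kind != "primary_region"])
  prim <- dplyr::filter(wgd_calls, .data$sample_id %in% primaries)
  prim_event <- NA_character_
  if (nrow(prim) == length(primaries) && all(prim$has_wgd) &&
      length(unique(prim$wgd_event_id)) == 1) {
    prim_event <- unique(prim$wgd_event_id)
  }
  out <- purrr::map(mets, function(m) {
    row <- dplyr::filter(wgd_calls, .data$sample_id == m)
    label <- if (is.na(prim_event) || nrow(row) == 0) {
      NA_character_
    } else if (!row$has_wgd[1] || !identical(row$wgd_event_id[1], prim_event)) {
      "early"
    } else {
      "late"
    }
    tibble::tibble(level = "sample", target_id = m, label = label,
                   shared_clonal_fraction = NA_real_)
  }) |> dplyr::bind_rows() |>
    dplyr::mutate(case_id = unique(samples$case_id)[1], .before = 1) |>
    dplyr::mutate(method = "wgd")
  new_met_tbl(out, c("met_timing", "tbl_df", "tbl", "data.frame"))
}
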