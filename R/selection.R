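#' Maximum clonality over metastasis samples
#'
#' Collapses several per-sample statuses to the highest clonality observed
#' (clonal > subclonal > absent). Used for the metastasis side of the paired
#' favouring classification, which asks whether an event reached *higher*
#' clonality in any metastasis.
#'
#' @param status Character or factor vector of statuses.
#' @return Single status as an ordered factor level.
#' @export
max_clonality <- function(status) {
  status <- factor(as.character(status), levels = STATUS_LEVELS, ordered = TRUE)
  if (any(is.na(status))) abort("unknown clonality status")
  max(status)
}

#' Paired primary-metastasis favouring classification of mutation clusters
#'
#' A cluster is `metastasis_favoured` when its clonality is higher in the
#' metastasis than in the primary tumour (absent -> subclonal/clonal, or
#' subclonal -> clonal), `primary_favoured` when lower (clonal ->
#' subclonal/absent, or subclonal -> absent), and `maintained` otherwise.
#' Both inputs are tumour-level statuses (see [group_status()]); for the
#' metastasis side use the maximum clonality across metastasis samples
#' ([max_clonality()]). Vectorised; the cluster label propagates to every
#' mutation of the cluster.
#'
#' @param primary_status,met_status Vectors of statuses (`"absent"`,
#'   `"subclonal"`, `"clonal"`), recycled to a common length.
#' @return Character vector of labels.
#' @examples
#' classify_paired_mutation("absent", "clonal")     # metastasis_favoured
#' classify_paired_mutation("clonal", "clonal")     # maintained
#' classify_paired_mutation("subclonal", "absent")  # primary_favoured
#' @export
classify_paired_mutation <- function(primary_status, met_status) {
  p <- as.integer(factor(as.character(primary_status), levels = STATUS_LEVELS))
  m <- as.integer(factor(as.character(met_status), levels = STATUS_LEVELS))
  if (any(is.na(p)) || any(is.na(m))) abort("unknown clonality status")
  dplyr::case_when(
    m > p ~ "metastasis_favoured",
    m < p ~ "primary_favoured",
    TRUE ~ "maintained"
  )
}

#' Exact or Monte-Carlo multinomial goodness-of-fit test
#'
#' Two-sided test of observed category counts against given proportions.
#' The p-value is the total probability of outcomes no more probable than
#' the observed one. With at most `exact_max` total events all outcome
#' vectors are enumerated (exact); above that, `nsim` multinomial draws
#' estimate the p-value with the add-one correction `(1 + #{p <= p_obs}) /
#' (nsim + 1)`.
#'
#' @param x Integer vector of observed counts.
#' @param p Numeric vector of null proportions (same length, summing to 1).
#' @param exact_max Largest total count for which full enumeration is used
#'   (default 12).
#' @param nsim Number of Monte-Carlo draws otherwise (default 1e5).
#' @return List with `p_value`, `p_value_strict` (total probability of
#'   outcomes strictly less probable than the observed one; the pair brackets
#'   the discrete p-value and supports randomised-p calibration checks),
#'   `method` (`"exact"`/`"monte_carlo"`), `statistic` (probability of the
#'   observed table) and `n` (total events).
#' @export
multinomial_test <- function(x, p, exact_max = 12, nsim = 1e5) {
  if (length(x) != length(p)) abort("`x` and `p` must have the same length")
  if (any(x < 0) || any(x != round(x))) abort("`x` must be non-negative counts")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) abort("`p` must be proportions summing to 1")
  n <- sum(x)
  if (n == 0) {
    return(list(p_value = 1, p_value_strict = 0, method = "exact",
                statistic = 1, n = 0L))
  }
  p_obs <- stats::dmultinom(x, prob = p)
  tol <- 1e-12
  if (n <= exact_max) {
    outcomes <- compositions(n, length(p))
    probs <- apply(outcomes, 1, stats::dmultinom, prob = p)
    p_value <- sum(probs[probs <= p_obs * (1 + tol)])
    p_strict <- sum(probs[probs < p_obs * (1 - tol)])
    method <- "exact"
  } else {
    draws <- stats::rmultinom(nsim, size = n, prob = p)
    probs <- apply(draws, 2, stats::dmultinom, prob = p)
    p_value <- (1 + sum(probs <= p_obs * (1 + tol))) / (nsim + 1)
    p_strict <- sum(probs < p_obs * (1 - tol)) / (nsim + 1)
    method <- "monte_carlo"
  }
  list(p_value = min(p_value, 1), p_value_strict = min(p_strict, 1),
       method = method, statistic = p_obs, n = as.integer(n))
}

# all vectors of m non-negative integers summing to n, as a matrix
compositions <- function(n, m) {
  if (m == 1) return(matrix(n, ncol = 1))
  do.call(rbind, lapply(0:n, function(k) {
    cbind(k, compositions(n - k, m - 1))
  }))
}

FAVOUR_LEVELS <- c("metastasis_favoured", "primary_favoured", "maintained")

favour_counts <- function(label) {
  label <- factor(as.character(label), levels = FAVOUR_LEVELS)
  as.integer(table(label))
}

#' Per-gene paired mutation selection test
#'
#' Tests, gene by gene, whether the split of driver mutations into
#' metastasis-favoured / primary-favoured / maintained classes deviates from
#' the background split of non-driver mutations. The background is
#' mutation-weighted and computed within each stratum (e.g. histology) when a
#' `stratum` column is present. Genes with fewer than `min_events` driver
#' mutations are skipped. p-values come from [multinomial_test()] and are BH
#' -corrected across tested genes.
#'
#' @param events Data frame with one row per mutation: columns `gene`,
#'   `label` (a [classify_paired_mutation()] label), `is_driver` (logical),
#'   and optionally `stratum`.
#' @param min_events Minimum driver mutations per tested gene (default 5).
#' @param exact_max,nsim Passed to [multinomial_test()].
#' @return Object of class `met_paired_test`: list with `table` (per-gene
#'   tibble of counts, background proportions, `p_value`, `q_value`),
#'   `background` (per-stratum proportions) and `skipped` (genes below the
#'   event threshold). Use [tidy()] / [glance()] to extract results.
#' @export
paired_mutation_test <- function(events, min_events = 5, exact_max = 12, nsim = 1e5) {
  events <- tibble::as_tibble(events)
  if (!all(c("gene", "label", "is_driver") %in% names(events))) {
    abort("`events` needs columns gene, label, is_driver")
  }
  if (!"stratum" %in% names(events)) events$stratum <- "all"
  bad <- setdiff(unique(events$label), FAVOUR_LEVELS)
  if (length(bad) > 0) abort(paste0("unknown label(s): ", paste(bad, collapse = ", ")))

  background <- events |>
    dplyr::filter(!.data$is_driver) |>
    dplyr::count(.data$stratum, .data$label) |>
    tidyr::complete(stratum = unique(events$stratum),
                    label = FAVOUR_LEVELS, fill = list(n = 0L)) |>
    dplyr::mutate(prop = .data$n / sum(.data$n), .by = "stratum")
  if (any(is.na(background$prop))) {
    abort("a stratum has no non-driver mutations to form a background")
  }

  drivers <- events |>
    dplyr::filter(.data$is_driver) |>
    dplyr::count(.data$stratum, .data$gene, .data$label) |>
    tidyr::complete(tidyr::nesting(stratum, gene),
                    label = FAVOUR_LEVELS, fill = list(n = 0L))
  totals <- drivers |> dplyr::summarise(n_total = sum(.data$n), .by = c("stratum", "gene"))
  tested <- dplyr::filter(totals, .data$n_total >= min_events)
  skipped <- dplyr::filter(totals, .data$n_total < min_events)

  rows <- purrr::pmap(tested, function(stratum, gene, n_total) {
    cnt <- drivers |>
      dplyr::filter(.data$stratum == .env$stratum, .data$gene == .env$gene) |>
      dplyr::arrange(factor(.data$label, levels = FAVOUR_LEVELS))
    bg <- background |>
      dplyr::filter(.data$stratum == .env$stratum) |>
      dplyr::arrange(factor(.data$label, levels = FAVOUR_LEVELS))
    res <- multinomial_test(cnt$n, bg$prop, exact_max = exact_max, nsim = nsim)
    tibble::tibble(
      stratum = stratum, gene = gene,
      n_met_favoured = cnt$n[1], n_primary_favoured = cnt$n[2], n_maintained = cnt$n[3],
      n_total = n_total,
      bg_met_favoured = bg$prop[1], bg_primary_favoured = bg$prop[2],
      bg_maintained = bg$prop[3],
      p_value = res$p_value, method = res$method
    )
  })
  table <- dplyr::bind_rows(rows)
  if (nrow(table) > 0) {
    table <- table |>
      dplyr::mutate(q_value = stats::p.adjust(.data$p_value, method = "BH"),
                    .by = "stratum") |>
      dplyr::arrange(.data$stratum, .data$p_value, .data$gene)
  } else {
    table$q_value <- numeric(0)
  }
  structure(list(table = table, background = background, skipped = skipped,
                 min_events = min_events),
            class = "met_paired_test")
}

#' @export
print.met_paired_test <- function(x, ...) {
  cat("<met_paired_test>", nrow(x$table), "genes tested,",
      nrow(x$skipped), "skipped (<", x$min_events, "events )\n")
  print(x$table, n = 10)
  invisible(x)
}

#' Call gene-level copy-number events relative to sample ploidy
#'
#' `amplified` when `log2(cn / ploidy) > amp_log2`, `lost` when
#' `log2((cn + eps) / ploidy) < loss_log2`, otherwise `neutral`. The +-0.5
#' defaults follow the common ploidy-relative doubling/halving convention
#' and are exposed for pipelines that use different cut-offs.
#'
#' @param cn Numeric vector of ploidy-uncorrected total copy number per gene
#'   per sample.
#' @param ploidy Sample ploidy (recycled).
#' @param amp_log2,loss_log2 Log2-ratio thresholds (defaults +0.5 / -0.5).
#' @param eps Offset preventing `log2(0)` for homozygous deletions.
#' @return Character vector: `"amplified"`, `"lost"` or `"neutral"`; `NA`
#'   propagates.
#' @export
call_scna_event <- function(cn, ploidy, amp_log2 = 0.5, loss_log2 = -0.5, eps = 0.01) {
  lr <- log2((cn + eps) / ploidy)
  dplyr::case_when(
    is.na(cn) ~ NA_character_,
    log2(cn / ploidy) > amp_log2 ~ "amplified",
    lr < loss_log2 ~ "lost",
    TRUE ~ "neutral"
  )
}

#' Paired primary-metastasis favouring of copy-number events
#'
#' For one gene and one event type in one tumour: the event is `maintained`
#' when present (called in at least one sample) in both the metastasizing
#' primary regions and the matched metastases, `primary_favoured` when
#' present only in the primary, `metastasis_favoured` when present only in
#' the metastases. Tumours without the event in any sample return `NA` and
#' should not be counted.
#'
#' @param primary_events,met_events Logical vectors: was the event called in
#'   each primary / metastasis sample of the tumour?
#' @return A favouring label or `NA`.
#' @export
classify_paired_scna <- function(primary_events, met_events) {
  in_prim <- any(primary_events, na.rm = TRUE)
  in_met <- any(met_events, na.rm = TRUE)
  if (!in_prim && !in_met) return(NA_character_)
  if (in_prim && in_met) return("maintained")
  if (in_prim) "primary_favoured" else "metastasis_favoured"
}

#' Per-gene paired SCNA selection test
#'
#' Counts tumours whose event in a gene is metastasis-favoured, primary
#' -favoured or maintained and tests each driver gene with at least
#' `min_tumours` events against the background split over non-driver genes,
#' via [multinomial_test()] with BH correction.
#'
#' @param calls Data frame with one row per (tumour, gene): columns
#'   `tumour_id`, `gene`, `is_driver`, `label` (a [classify_paired_scna()]
#'   label; `NA` rows are dropped).
#' @param min_tumours Minimum tumours with an event per tested gene
#'   (default 5).
#' @inheritParams paired_mutation_test
#' @return A `met_paired_test` object (see [paired_mutation_test()]);
#'   counts are tumours rather than mutations.
#' @export
paired_scna_test <- function(calls, min_tumours = 5, exact_max = 12, nsim = 1e5) {
  calls <- tibble::as_tibble(calls) |>
    dplyr::filter(!is.na(.data$label))
  events <- calls |>
    dplyr::select(gene = "gene", label = "label", is_driver = "is_driver")
  paired_mutation_test(events, min_events = min_tumours,
                       exact_max = exact_max, nsim = nsim)
}

#' G-score difference between metastasis and non-metastatic cohorts
#'
#' Assigns each gene a G-score (a GISTIC-style amplitude x frequency
#' selection score) in both cohorts by overlap with the score segment
#' tables: the overlap-length-weighted mean score of overlapping segments,
#' or the mean of the two flanking segments when the gene falls in a gap.
#' Returns the per-gene difference (GSD = metastasis - non-metastatic),
#' keeping genes whose score is significant in the metastasis cohort.
#'
#' @param scores_met,scores_nonmet Segment score tables (one amplification
#'   or one deletion track at a time) with columns `chrom`, `start`, `end`
#'   (1-based closed), `g_score`, `q_value`.
#' @param genes Gene coordinate table with columns `gene`, `chrom`, `start`,
#'   `end`.
#' @param q_threshold Keep genes with metastasis-cohort q below this value;
#'   `Inf` keeps all (default 0.05).
#' @return Tibble of class `met_gsd` with `gene`, `g_score_met`,
#'   `g_score_nonmet`, `gsd`, `q_met`. Genes on chromosomes absent from a
#'   score table are dropped with a warning.
#' @export
gscore_difference <- function(scores_met, scores_nonmet, genes, q_threshold = 0.05) {
  genes <- tibble::as_tibble(genes) |> dplyr::mutate(chrom = as.character(.data$chrom))
  met <- gene_scores(scores_met, genes)
  nonmet <- gene_scores(scores_nonmet, genes)
  out <- dplyr::inner_join(
    dplyr::rename(met, g_score_met = "g_score", q_met = "q_value"),
    dplyr::select(dplyr::rename(nonmet, g_score_nonmet = "g_score"), -"q_value"),
    by = "gene"
  ) |>
    dplyr::mutate(gsd = .data$g_score_met - .data$g_score_nonmet) |>
    dplyr::filter(is.na(.data$q_met) | .data$q_met < .env$q_threshold,
                  !is.na(.data$g_score_met), !is.na(.data$g_score_nonmet)) |>
    dplyr::select("gene", "g_score_met", "g_score_nonmet", "gsd", "q_met") |>
    dplyr::arrange(dplyr::desc(abs(.data$gsd)), .data$gene)
  new_met_tbl(out, c("met_gsd", "tbl_df", "tbl", "data.frame"))
}

# per-gene score from a segment table: overlap-weighted mean, neighbour-mean
# fallback in gaps; NA (with warning) off covered chromosomes
gene_scores <- function(scores, genes) {
  scores <- tibble::as_tibble(scores) |>
    dplyr::mutate(chrom = as.character(.data$chrom)) |>
    dplyr::arrange(.data$chrom, .data$start)
  seg_gr <- GenomicRanges::GRanges(scores$chrom,
                                   IRanges::IRanges(scores$start, scores$end))
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(gene_gr, seg_gr)
  ov <- tibble::tibble(
    gi = S4Vectors::queryHits(hits),
    si = S4Vectors::subjectHits(hits)
  ) |>
    dplyr::mutate(
      w = pmin(genes$end[.data$gi], scores$end[.data$si]) -
        pmax(genes$start[.data$gi], scores$start[.data$si]) + 1,
      g = scores$g_score[.data$si],
      q = scores$q_value[.data$si]
    ) |>
    dplyr::summarise(g_score = sum(.data$g * .data$w) / sum(.data$w),
                     q_value = min(.data$q), .by = "gi")
  res <- genes |>
    dplyr::mutate(gi = dplyr::row_number()) |>
    dplyr::left_join(ov, by = "gi")
  gap <- which(is.na(res$g_score))
  skipped <- character(0)
  for (i in gap) {
    segs <- scores |> dplyr::filter(.data$chrom == res$chrom[i])
    if (nrow(segs) == 0) { skipped <- c(skipped, res$gene[i]); next }
    before <- segs |> dplyr::filter(.data$end < res$start[i]) |> dplyr::slice_tail(n = 1)
    after <- segs |> dplyr::filter(.data$start > res$end[i]) |> dplyr::slice_head(n = 1)
    nb <- dplyr::bind_rows(before, after)
    res$g_score[i] <- mean(nb$g_score)
    res$q_value[i] <- min(nb$q_value)
  }
  if (length(skipped) > 0) {
    warn(paste0("no score segments on the chromosome of gene(s): ",
                paste(skipped, collapse = ", "), "; dropped"))
  }
  dplyr::select(res, "gene", "g_score", "q_value")
}

#' Gene-level dN/dS odds ratio between seeding and non-seeding mutations
#'
#' Consumes externally computed per-gene dN/dS point estimates (missense and
#' truncating combined) for the seeding-cluster mutations and for the
#' combined primary-unique / non-metastatic mutations. The odds ratio is
#' `dnds_seeding / dnds_nonseeding`; a gene is `seeding_favoured` when
#' OR > 2, `primary_favoured` when OR < 0.5, and `both` in between. Genes
#' are reported when significant (`q < q_max`) in either input.
#'
#' @param seeding,nonseeding Data frames with columns `gene`, `dnds` and
#'   optionally `q_value`.
#' @param q_max Significance filter on either input's q (default 0.1; `Inf`
#'   disables).
#' @return Tibble of class `met_dnds` with `gene`, `dnds_seeding`,
#'   `dnds_nonseeding`, `odds_ratio`, `label` (`"undetermined"` when the
#'   denominator is zero or missing).
#' @export
dnds_odds_ratio <- function(seeding, nonseeding, q_max = 0.1) {
  seeding <- tibble::as_tibble(seeding)
  nonseeding <- tibble::as_tibble(nonseeding)
  if (!"q_value" %in% names(seeding)) seeding$q_value <- NA_real_
  if (!"q_value" %in% names(nonseeding)) nonseeding$q_value <- NA_real_
  out <- dplyr::full_join(
    dplyr::select(seeding, "gene", dnds_seeding = "dnds", q_seeding = "q_value"),
    dplyr::select(nonseeding, "gene", dnds_nonseeding = "dnds", q_nonseeding = "q_value"),
    by = "gene"
  ) |>
    dplyr::mutate(.q_min = suppressWarnings(
      pmin(.data$q_seeding, .data$q_nonseeding, na.rm = TRUE))) |>
    dplyr::filter(is.infinite(.env$q_max) | is.na(.data$.q_min) |
                    .data$.q_min < .env$q_max) |>
    dplyr::select(-".q_min") |>
    dplyr::mutate(
      odds_ratio = .data$dnds_seeding / .data$dnds_nonseeding,
      label = dplyr::case_when(
        is.na(.data$odds_ratio) | is.infinite(.data$odds_ratio) ~ "undetermined",
        .data$odds_ratio > 2 ~ "seeding_favoured",
        .data$odds_ratio < 0.5 ~ "primary_favoured",
        TRUE ~ "both"
      )
    ) |>
    dplyr::arrange(.data$gene)
  new_met_tbl(out, c("met_dnds", "tbl_df", "tbl", "data.frame"))
}
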