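#' Configuration of the deme-based tumour growth model
#'
#' The model grows a tumour in demes of `deme_capacity` cells on a 3D cubic
#' lattice. Per synchronous sweep a cell divides with probability
#' `(fitness / max fitness in deme) * (1 - deme total / deme_capacity)` and
#' dies with probability `death_rate`; full demes split into an empty
#' neighbouring lattice site. Each daughter acquires `Poisson(mutation_rate)`
#' mutations whose fitness effects come from an asymmetric Laplace
#' distribution centred at 0 and skewed negative (see
#' [draw_fitness_effect()]); rare driver mutations (probability
#' `driver_prob`) add a deterministic `driver_mult * s` benefit and enable
#' large genomic events, which then occur with probability `event_prob` per
#' division with a broader effect distribution. Defaults follow the study
#' conditions: demes of 5,000 cells, death rate 0.2, selection coefficient
#' 0.01, mutation rate 0.4 per division over the exome, drivers at 1e-5 with
#' a 10-fold effect, events at 0.3 per division, 8 sampled regions of
#' ~50,000 cells and 400x emulated coverage.
#'
#' @param deme_capacity Cells per deme (default 5000).
#' @param final_size Primary tumour size at which growth halts (cells).
#' @param death_rate Per-cell death probability per sweep (default 0.2).
#' @param mutation_rate Expected new mutations per division over the exome
#'   (0.4 or 0.6 in the study; default 0.4). The equivalent per-bp rate over
#'   `exome_size` is bookkeeping metadata only.
#' @param s Global selection coefficient (>= 0; 0 gives neutral evolution).
#' @param driver_prob Per-mutation probability of a driver (default 1e-5).
#' @param driver_mult Driver fitness effect as a multiple of `s`
#'   (default 10).
#' @param event_prob Genomic-event probability per division for
#'   rearrangement-enabled lineages (default 0.3).
#' @param exome_size Exome size in bp used to express per-bp mutation rates.
#' @param n_regions,region_cells Number and size of sampled bulk regions.
#' @param depth_mean Mean sequencing depth for WES emulation (default 400).
#' @param error_rate Per-base sequencing error rate (default 1e-3).
#' @param min_report_frac Carrier-fraction floor below which mutations are
#'   not carried into the read-out tables (default 0.005, well below the
#'   detection limit).
#' @param founder_mutations Truncal mutations carried by the founder cell
#'   (the pre-expansion mutation burden; clonal in every descendant cell).
#' @param max_attempts Extinction retries before giving up.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(deme_capacity = 5000,
                       final_size = 1e9,
                       death_rate = 0.2,
                       mutation_rate = 0.4,
                       s = 0.01,
                       driver_prob = 1e-5,
                       driver_mult = 10,
                       event_prob = 0.3,
                       exome_size = 6e7,
                       n_regions = 8,
                       region_cells = 5e4,
                       depth_mean = 400,
                       error_rate = 1e-3,
                       min_report_frac = 0.005,
                       founder_mutations = 100,
                       max_attempts = 100) {
  stopifnot(final_size >= 1, deme_capacity >= 2,
            death_rate >= 0, death_rate < 1,
            mutation_rate >= 0, s >= 0,
            event_prob >= 0, event_prob <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Draw fitness effects from the model's distribution of fitness effects
#'
#' Ordinary mutations: exponential tails with mean `s` (negative side,
#' probability 2/3) and `s / 2` (positive side); rare drivers (probability
#' `driver_prob`) get exactly `driver_mult * s`. Large genomic events use
#' tails with mean `3 s` (negative) and `s` (positive). At `s = 0` every
#' effect is 0 (neutral evolution). At `s = 0.01` ordinary effects
#' effectively span about -0.07 to +0.02 and drivers are +0.1.
#'
#' @param n Number of draws.
#' @param s Global selection coefficient.
#' @param kind `"mutation"` or `"event"`.
#' @param driver_prob Driver probability (only for `kind = "mutation"`;
#'   default 0 so the pure DFE is returned).
#' @param driver_mult Driver multiple of `s`.
#' @return Numeric vector of multiplicative fitness effects.
#' @export
draw_fitness_effect <- function(n, s, kind = c("mutation", "event"),
                                driver_prob = 0, driver_mult = 10) {
  kind <- match.arg(kind)
  cpp_dfe_draws(n, s, kind, driver_prob, driver_mult)
}

met_defaults <- function(config, divergence_size) {
  list(divergence_size = divergence_size,
       met_n_cells = 1L,
       met_n_source_regions = 1L,
       met_s = config$s,
       met_final_size = config$final_size,
       met_n_regions = config$n_regions,
       met_region_cells = config$region_cells)
}

#' Grow a primary tumour
#'
#' Runs the agent model from a single founder cell to `final_size` cells and
#' samples `n_regions` spatially contiguous bulk regions.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_tumor`: `regions` (per-region tibbles of
#'   mutation carrier counts), `mutations`, `genotype_edges`, and provenance
#'   scalars (`n_cells`, `n_genotypes`, `n_mutations`, `n_sweeps`,
#'   `attempts`).
#' @examples
#' set.seed(1)
#' tum <- grow_tumor(sim_config(final_size = 2e4, region_cells = 2e3, n_regions = 4))
#' tum$n_cells
#' @export
grow_tumor <- function(config) {
  res <- cpp_simulate(c(unclass(config), met_defaults(config, 0)))
  tidy_sim_result(res, config)
}

#' Simulate a primary-metastasis pair diverging at a given primary size
#'
#' Grows the primary to `final_size`; when it first reaches
#' `divergence_size` cells, `n_cells` founder cells are drawn from the
#' surface of `n_source_regions` distinct surface localities and seed a
#' metastasis, grown under its own selection coefficient `met_s` to
#' `met_final_size`. Both tumours are then sampled and returned as carrier
#' -count region tables ready for [simulate_wes()].
#'
#' @param config A [sim_config()] for the primary (the study always grows
#'   the primary at `s = 0.01`).
#' @param divergence_size Primary size (cells) at metastatic divergence.
#' @param n_cells Number of founder cells (1, 10, 30 or 100 in the study).
#' @param n_source_regions Number of distinct source localities (1 or 3).
#' @param met_s Selection coefficient of the metastasis (0, 0.001, 0.005 or
#'   0.01 in the study; defaults to the primary's).
#' @param met_final_size,met_n_regions,met_region_cells Metastasis size and
#'   sampling scheme (default: same as the primary).
#' @return A list of class `sim_pair`: `primary` and `met` (each a
#'   `sim_tumor`-like list with `regions`), `mutations`, `genotype_edges`,
#'   `met_founders` and provenance scalars.
#' @export
simulate_met_pair <- function(config, divergence_size,
                              n_cells = 1, n_source_regions = 1,
                              met_s = config$s,
                              met_final_size = config$final_size,
                              met_n_regions = config$n_regions,
                              met_region_cells = config$region_cells) {
  stopifnot(divergence_size >= n_cells)
  cfg <- c(unclass(config),
           list(divergence_size = divergence_size,
                met_n_cells = as.integer(n_cells),
                met_n_source_regions = as.integer(n_source_regions),
                met_s = met_s,
                met_final_size = met_final_size,
                met_n_regions = met_n_regions,
                met_region_cells = met_region_cells))
  res <- cpp_simulate(cfg)
  out <- tidy_sim_result(res, config)
  out$met_regions <- region_list_to_tbl(res$met_regions, prefix = "M")
  out$met_founders <- res$met_founders
  out$n_cells_met <- res$n_cells_met
  out$attempts_met <- res$attempts_met
  class(out) <- c("sim_pair", class(out))
  out
}

region_list_to_tbl <- function(lst, prefix = "R") {
  purrr::imap(lst, function(tab, i) {
    tibble::tibble(region_id = sprintf("%s%d", prefix, i),
                   mutation_id = tab$mutation_id,
                   carriers = tab$carriers,
                   n_cells = tab$n_cells)
  }) |> dplyr::bind_rows()
}

tidy_sim_result <- function(res, config) {
  structure(
    list(regions = region_list_to_tbl(res$primary_regions, prefix = "R"),
         mutations = tibble::as_tibble(res$mutations),
         genotype_edges = tibble::as_tibble(res$genotype_edges),
         n_cells = res$n_cells_primary,
         n_genotypes = res$n_genotypes,
         n_mutations = res$n_mutations,
         n_sweeps = res$n_sweeps,
         size_history = res$size_history,
         attempts = res$attempts_primary,
         config = config),
    class = "sim_tumor"
  )
}

#' @export
print.sim_tumor <- function(x, ...) {
  cat("<sim_tumor>", format(x$n_cells, big.mark = ","), "cells,",
      x$n_genotypes, "genotypes,", x$n_mutations, "mutations,",
      x$n_sweeps, "sweeps\n")
  invisible(x)
}

#' Emulate whole-exome sequencing of simulated bulk regions
#'
#' The true variant allele frequency of a mutation is its carrier fraction
#' divided by two (heterozygous-diploid convention). Per mutation and
#' region, depth is `Poisson(depth_mean)` and alt reads are
#' `Binomial(depth, vaf (1 - e) + (1 - vaf) e / 3)` with per-base error
#' `e`. A mutation is detected when it has at least `min_alt` alt reads and
#' an observed VAF of at least `min_vaf`.
#'
#' @param regions Region carrier table from [grow_tumor()] /
#'   [simulate_met_pair()] (columns `region_id`, `mutation_id`, `carriers`,
#'   `n_cells`).
#' @param depth_mean Mean coverage (default 400).
#' @param error_rate Per-base substitution error rate (default 1e-3).
#' @param min_alt,min_vaf Detection filter (defaults 2 reads and 0.02).
#' @return Tibble of class `sim_wes` with columns `region_id`,
#'   `mutation_id`, `depth`, `alt_reads`, `vaf`, `detected`.
#' @export
simulate_wes <- function(regions, depth_mean = 400, error_rate = 1e-3,
                         min_alt = 2, min_vaf = 0.02) {
  true_vaf <- regions$carriers / regions$n_cells / 2
  n <- nrow(regions)
  depth <- stats::rpois(n, depth_mean)
  p_alt <- true_vaf * (1 - error_rate) + (1 - true_vaf) * error_rate / 3
  alt <- stats::rbinom(n, depth, p_alt)
  out <- regions |>
    dplyr::mutate(depth = depth,
                  alt_reads = alt,
                  vaf = dplyr::if_else(depth > 0, alt / depth, 0),
                  detected = .data$alt_reads >= min_alt & .data$vaf >= min_vaf) |>
    dplyr::select("region_id", "mutation_id", "depth", "alt_reads", "vaf", "detected")
  new_met_tbl(out, c("sim_wes", "tbl_df", "tbl", "data.frame"))
}

#' Classify simulated divergence timing from emulated WES
#'
#' Mutations with VAF above `vaf_clonal` in at least `region_frac` of the
#' primary regions are primary-clonal. The pair is *late* when every
#' primary-clonal mutation is present (detected in any region) in the
#' metastasis, *early* otherwise.
#'
#' @param wes_primary,wes_met [simulate_wes()] tables for the primary and
#'   metastasis regions.
#' @param vaf_clonal VAF threshold for clonality (default 0.3).
#' @param region_frac Fraction of primary regions required (default 0.9).
#' @return List with `label` (`"early"`/`"late"`), `n_clonal`, `n_shared`
#'   and `shared_fraction`.
#' @export
classify_sim_timing <- function(wes_primary, wes_met,
                                vaf_clonal = 0.3, region_frac = 0.9) {
  n_regions <- dplyr::n_distinct(wes_primary$region_id)
  need <- ceiling(region_frac * n_regions)
  clonal <- wes_primary |>
    dplyr::filter(.data$detected, .data$vaf > vaf_clonal) |>
    dplyr::count(.data$mutation_id) |>
    dplyr::filter(.data$n >= need)
  met_present <- wes_met |>
    dplyr::filter(.data$detected) |>
    dplyr::distinct(.data$mutation_id)
  n_clonal <- nrow(clonal)
  n_shared <- sum(clonal$mutation_id %in% met_present$mutation_id)
  list(label = if (n_clonal > 0 && n_shared < n_clonal) "early" else "late",
       n_clonal = n_clonal, n_shared = n_shared,
       shared_fraction = if (n_clonal > 0) n_shared / n_clonal else NA_real_)
}

#' Convert a cancer-cell count to an equivalent tumour diameter
#'
#' Assumes cubic cells of side `cell_side_um` (15 um, a typical parenchymal
#' cell); non-cancer cells are added via `purity` (total cells =
#' `n_cancer_cells / purity`). The diameter is the side of the cube with the
#' total cell volume, reported in mm. With 2.5e8 cancer cells at 37% purity
#' this gives ~13 mm.
#'
#' @param n_cancer_cells Number of cancer cells (> 0).
#' @param purity Tumour purity in (0, 1].
#' @param cell_side_um Cell side length in micrometres (default 15).
#' @return Diameter in millimetres.
#' @examples
#' cells_to_diameter(2.5e8, purity = 0.37)
#' @export
cells_to_diameter <- function(n_cancer_cells, purity = 1, cell_side_um = 15) {
  if (any(n_cancer_cells <= 0) || any(purity <= 0) || any(purity > 1)) {
    abort("need n_cancer_cells > 0 and purity in (0, 1]")
  }
  total_cells <- n_cancer_cells / purity
  volume_um3 <- total_cells * cell_side_um^3
  volume_um3^(1 / 3) / 1000
}

#' Early-divergence fraction as a function of primary size at divergence
#'
#' For each divergence size, simulates `replicates` primary-metastasis
#' pairs, emulates WES on both tumours and classifies timing with
#' [classify_sim_timing()]. Early divergence becomes rarer as the primary
#' grows: later-arising mutations rarely sweep to clonality afterwards.
#'
#' @param divergence_sizes Numeric vector of primary sizes (cells) at
#'   divergence.
#' @param config A [sim_config()].
#' @param replicates Pairs per size (default 20).
#' @param purity Purity used for the reported diameter (default 0.37).
#' @param ... Passed to [simulate_met_pair()] (founder cells, metastasis
#'   selection, metastasis size and sampling).
#' @return Tibble of class `met_sim_experiment`: `divergence_size`,
#'   `diameter_mm`, `n_early`, `n_replicates`, `fraction_early`.
#' @export
run_timing_experiment <- function(divergence_sizes, config, replicates = 20,
                                  purity = 0.37, ...) {
  rows <- purrr::map(sort(divergence_sizes), function(sz) {
    labels <- purrr::map_chr(seq_len(replicates), function(i) {
      pair <- simulate_met_pair(config, divergence_size = sz, ...)
      wes_p <- simulate_wes(pair$regions, config$depth_mean, config$error_rate)
      wes_m <- simulate_wes(pair$met_regions, config$depth_mean, config$error_rate)
      classify_sim_timing(wes_p, wes_m)$label
    })
    tibble::tibble(divergence_size = sz,
                   diameter_mm = cells_to_diameter(sz, purity),
                   n_early = sum(labels == "early"),
                   n_replicates = replicates,
                   fraction_early = mean(labels == "early"))
  }) |> dplyr::bind_rows()
  new_met_tbl(rows, c("met_sim_experiment", "tbl_df", "tbl", "data.frame"))
}
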