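#' Read the long-format cluster table dialect
#'
#' TSV with columns `case_id`, `cluster_id`, `parent_id`, `n_mutations`,
#' `sample_id`, `ccf` (one row per cluster x sample; parent of the root is
#' the literal token `ROOT`).
#'
#' @param path File path.
#' @return Tibble; combine with a sample table via [cluster_trees()].
#' @export
read_cluster_table <- function(path) {
  tab <- read_tsv_checked(path, c("case_id", "cluster_id", "parent_id",
                                  "n_mutations", "sample_id", "ccf"))
  tab$ccf <- as.numeric(tab$ccf)
  tab$n_mutations <- as.integer(tab$n_mutations)
  bad <- which(!is.finite(tab$ccf) | tab$ccf < 0 | tab$ccf > 2)
  if (length(bad) > 0) {
    abort(paste0(path, ": CCF outside [0, 2] at data row ", bad[1]))
  }
  dup <- duplicated(tab[c("case_id", "cluster_id", "sample_id")])
  if (any(dup)) {
    abort(paste0(path, ": duplicate (case, cluster, sample) row at data row ",
                 which(dup)[1]))
  }
  tab
}

#' Read the sample metadata dialect
#'
#' TSV with columns `case_id`, `sample_id`, `kind` (`primary_region`,
#' `primary_LN_satellite` or `recurrence_progression`).
#'
#' @inheritParams read_cluster_table
#' @return Tibble.
#' @export
read_sample_table <- function(path) {
  read_tsv_checked(path, c("case_id", "sample_id", "kind"))
}

#' Read alternate tree topologies
#'
#' TSV with columns `case_id`, `topology_id`, `cluster_id`, `parent_id`.
#'
#' @inheritParams read_cluster_table
#' @return Tibble.
#' @export
read_topologies <- function(path) {
  read_tsv_checked(path, c("case_id", "topology_id", "cluster_id", "parent_id"))
}

#' Read BED-like genomic segments
#'
#' TSV with columns `chrom`, `start`, `end` (0-based half-open) plus any
#' extra columns (e.g. `sample_id`, `allele`). Chromosome names are
#' normalised by stripping a `chr` prefix when the file mixes styles.
#'
#' @inheritParams read_cluster_table
#' @return Tibble sorted by chrom, start.
#' @export
read_segments <- function(path) {
  tab <- read_tsv_checked(path, c("chrom", "start", "end"))
  tab$start <- as.numeric(tab$start)
  tab$end <- as.numeric(tab$end)
  if (any(tab$start >= tab$end)) {
    abort(paste0(path, ": segment with start >= end at data row ",
                 which(tab$start >= tab$end)[1]))
  }
  tab$chrom <- as.character(tab$chrom)
  has_prefix <- startsWith(tab$chrom, "chr")
  if (any(has_prefix) && !all(has_prefix)) {
    warn(paste0(path, ": mixed chromosome naming; stripping 'chr' prefixes"))
    tab$chrom <- sub("^chr", "", tab$chrom)
  }
  dplyr::arrange(tab, .data$chrom, .data$start)
}

#' Read the per-mutation presence table dialect
#'
#' TSV with columns `chrom`, `pos` (1-based), `case_id`, `sample_id`,
#' `present` (0/1).
#'
#' @inheritParams read_cluster_table
#' @return Tibble.
#' @export
read_mutation_table <- function(path) {
  tab <- read_tsv_checked(path, c("chrom", "pos", "case_id", "sample_id", "present"))
  tab$pos <- as.integer(tab$pos)
  tab$present <- as.integer(tab$present) > 0
  tab
}

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "#")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0(path, ": missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  tibble::as_tibble(tab)
}

#' Write a table as deterministic TSV
#'
#' Rows are sorted by all character/id columns so identical inputs give
#' byte-identical, diffable files. List columns are comma-joined.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_sorted <- function(x, path) {
  x <- tibble::as_tibble(x)
  x <- dplyr::mutate(x, dplyr::across(dplyr::where(is.list),
                                      ~ purrr::map_chr(.x, paste, collapse = ",")))
  key_cols <- names(x)[vapply(x, is.character, logical(1))]
  if (length(key_cols) > 0) x <- dplyr::arrange(x, dplyr::across(dplyr::all_of(key_cols)))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Record run provenance
#'
#' @param command Free-text description of the command/analysis.
#' @param inputs Named character vector of input file paths (digested with
#'   md5 when they exist).
#' @param seed Seed(s) used.
#' @param params Named list of parameters.
#' @return List of class `run_provenance`.
#' @export
run_provenance <- function(command, inputs = character(0), seed = NA_integer_,
                           params = list()) {
  digests <- purrr::map_chr(inputs, function(p) {
    if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_
  })
  structure(
    list(command = command,
         inputs = as.list(digests),
         seed = seed,
         params = params,
         package_version = as.character(utils::packageVersion("metevol")),
         timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)),
    class = "run_provenance"
  )
}

#' Write a provenance record as JSON
#'
#' @param prov A [run_provenance()] record.
#' @param path Output path (conventionally `provenance.json` in the output
#'   directory; one record per directory).
#' @return `path`, invisibly.
#' @export
write_provenance <- function(prov, path) {
  jsonlite::write_json(unclass(prov), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Export a cluster tree in Newick format
#'
#' For viewing cluster trees in standard phylogeny viewers. Internal nodes
#' are labelled (cluster trees are trees of clones, not of extant tips) and
#' branch lengths are the cluster mutation counts.
#'
#' @param tree A [cluster_tree()].
#' @return Newick string (terminated by `;`).
#' @export
as_newick <- function(tree) {
  pm <- tree$topologies$default
  kids <- tree_children_map(pm)
  nmut <- stats::setNames(tree$clusters$n_mutations, tree$clusters$cluster_id)
  fmt <- function(id) {
    ch <- sort(kids[[id]] %||% character(0))
    label <- paste0(id, ":", nmut[[id]])
    if (length(ch) == 0) return(label)
    paste0("(", paste(vapply(ch, fmt, character(1)), collapse = ","), ")", label)
  }
  paste0(fmt(tree_root(tree)), ";")
}
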