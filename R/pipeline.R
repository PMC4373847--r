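#' Segment-count table over a set of homology maps
#'
#' One row per map: probe panel, target species, number of signal records and
#' total homologous segments, with any transcription note surfaced in the
#' \code{note} column rather than hidden.
#'
#' @param maps List of [homology_map()] objects.
#' @return data.frame with columns \code{target}, \code{probe},
#'   \code{n_signals}, \code{n_segments}, \code{note}.
#' @export
segment_count_table <- function(maps) {
  if (!length(maps)) stop("no homology maps given")
  rows <- lapply(maps, function(m) {
    stopifnot(inherits(m, "homology_map"))
    data.frame(target = m$target_species, probe = m$probe_species,
               n_signals = nrow(m$signals),
               n_segments = count_segments(m),
               note = m$note %||% "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Code a character matrix from homology maps and annotations
#'
#' Runs the full coding stage: synteny partitions per map, segmental
#' association and syntenic-disruption characters over the reference
#' complement, merged with structural annotations into one
#' [character_matrix()].
#'
#' @param maps List of [homology_map()]s sharing one probe (reference)
#'   species.
#' @param annotations Optional structural annotation data.frame (see
#'   [merge_structural_characters()]).
#' @param reference Optional reference [karyotype()] for unit-label checks.
#' @return A [character_matrix()].
#' @export
code_characters <- function(maps, annotations = NULL, reference = NULL) {
  parts <- lapply(maps, synteny_partition)
  assoc <- derive_association_characters(parts, reference)
  disr <- derive_disruption_characters(parts, maps, reference)
  merge_structural_characters(annotations, assoc, disr)
}

#' Run the full chromosomal-phylogeny pipeline
#'
#' Character coding (when maps are given), exhaustive maximum-parsimony
#' search, nonparametric bootstrap, Bremer decay indices, outgroup rooting
#' and a-posteriori character classification, collected into one run object.
#' All randomness flows through \code{seed}; two runs with identical inputs
#' and seed produce identical results.
#'
#' @param matrix A [character_matrix()]; or \code{NULL} to code one from
#'   \code{maps} (+ \code{annotations}).
#' @param maps,annotations,reference Inputs for [code_characters()] when
#'   \code{matrix} is \code{NULL}.
#' @param outgroup Character vector of outgroup taxa (required).
#' @param n_bootstrap Bootstrap replicates (default 2000).
#' @param seed Integer seed for the bootstrap resampling.
#' @param optimization \code{"deltran"} (default) or \code{"acctran"}.
#' @param consensus_threshold Majority-rule threshold (default 0.5).
#' @return An object of class \code{chromoclad_run}.
#' @export
run_chromosome_phylogeny <- function(matrix = NULL, maps = NULL,
                                     annotations = NULL, reference = NULL,
                                     outgroup, n_bootstrap = 2000L,
                                     seed = 1L,
                                     optimization = c("deltran", "acctran"),
                                     consensus_threshold = 0.5) {
  optimization <- match.arg(optimization)
  if (is.null(matrix)) {
    if (is.null(maps)) stop("give either a character matrix or homology maps")
    matrix <- code_characters(maps, annotations, reference)
  }
  if (length(matrix$taxa) < 4L) stop("need at least 4 taxa")
  missing_og <- setdiff(outgroup, matrix$taxa)
  if (length(missing_og)) {
    stop("outgroup taxa absent from matrix: ",
         paste(missing_og, collapse = ", "))
  }
  search <- exhaustive_search(matrix)
  boot <- bootstrap_support(matrix, n_reps = n_bootstrap, seed = seed,
                            space = search$space)
  bremer <- bremer_support(matrix, search)
  mp_consensus <- if (length(search$mp_trees) > 1L) {
    majority_rule_consensus(search$mp_trees, threshold = 0.999)
  } else {
    NULL
  }
  rooted <- root_on_outgroup(search$mp_trees[[1L]], outgroup)
  mapping <- classify_characters(rooted, matrix, optimization)
  root_report <- root_state_report(rooted, matrix, optimization)
  structure(list(
    matrix = matrix,
    n_informative = count_informative(matrix),
    search = search,
    bootstrap = boot,
    bremer = bremer,
    mp_consensus = mp_consensus,
    rooted_tree = rooted,
    classification = mapping,
    root_report = root_report,
    outgroup = outgroup,
    seed = seed,
    n_bootstrap = n_bootstrap,
    optimization = optimization,
    consensus_threshold = consensus_threshold),
    class = "chromoclad_run")
}

#' @export
print.chromoclad_run <- function(x, ...) {
  cat("Chromosomal-phylogeny run\n")
  cat(sprintf("  matrix: %d taxa x %d characters (%d parsimony-informative)\n",
              length(x$matrix$taxa), length(x$matrix$defs), x$n_informative))
  cat(sprintf("  exhaustive search: %d topologies, score = %d, CI = %.4f, %d MP tree(s)\n",
              x$search$n_topologies_examined, x$search$length, x$search$ci,
              length(x$search$mp_trees)))
  cat(sprintf("  bootstrap: %d replicates (seed %d); Bremer by full enumeration\n",
              x$n_bootstrap, x$seed))
  counts <- attr(x$classification, "counts")
  cat(sprintf("  changes: %d autapomorphies, %d synapomorphies, %d plesiomorphies, %d homoplasies, %d constant\n",
              counts[["autapomorphy"]], counts[["synapomorphy"]],
              counts[["plesiomorphy"]], counts[["homoplasy"]],
              counts[["constant"]]))
  invisible(x)
}

#' Write a machine-readable run report
#'
#' Writes the rooted MP tree (newick), the support table (clade, bootstrap
#' percentage, Bremer), the character mapping table and a YAML summary into a
#' directory. Output is deterministic for a given run object.
#'
#' @param run A [run_chromosome_phylogeny()] result.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_run_report <- function(run, dir) {
  stopifnot(inherits(run, "chromoclad_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ape::write.tree(run$rooted_tree, file.path(dir, "mp_tree_rooted.nwk"))
  ape::write.tree(run$search$mp_trees, file.path(dir, "mp_trees.nwk"))
  support <- run$bootstrap[, c("clade", "bootstrap_pct")]
  support$bremer <- vapply(seq_len(nrow(support)), function(i)
    support_for(run$bremer, strsplit(support$clade[i], "+", fixed = TRUE)[[1L]]),
    0)
  utils::write.table(support, file.path(dir, "support.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(run$classification),
                     file.path(dir, "character_mapping.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  counts <- attr(run$classification, "counts")
  yaml::write_yaml(list(
    taxa = run$matrix$taxa,
    n_characters = length(run$matrix$defs),
    n_informative = run$n_informative,
    length = run$search$length,
    consistency_index = run$search$ci,
    n_mp_trees = length(run$search$mp_trees),
    n_topologies_examined = run$search$n_topologies_examined,
    outgroup = run$outgroup,
    seed = run$seed,
    n_bootstrap = run$n_bootstrap,
    optimization = run$optimization,
    category_counts = as.list(counts)),
    file.path(dir, "summary.yaml"))
  invisible(dir)
}
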