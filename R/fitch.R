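# Leaf state encoding for the Fitch pass: bit 1 = state 0, bit 2 = state 1,
# '?' = {0,1} = 3 (union semantics: missing data never adds steps).
encode_states <- function(matrix) {
  enc <- matrix(3L, nrow(matrix$states), ncol(matrix$states))
  enc[matrix$states == "0"] <- 1L
  enc[matrix$states == "1"] <- 2L
  enc
}

# Per-character Fitch steps for one merge schedule, vectorised over characters.
fitch_steps_schedule <- function(sched, leaf_enc) {
  n <- nrow(leaf_enc)
  C <- ncol(leaf_enc)
  node <- matrix(0L, 2L * n - 1L, C)  # n leaves + n-1 merge products
  node[seq_len(n), ] <- leaf_enc
  steps <- integer(C)
  for (r in seq_len(nrow(sched))) {
    a <- node[sched[r, 1L], ]
    b <- node[sched[r, 2L], ]
    inter <- bitwAnd(a, b)
    miss <- inter == 0L
    steps <- steps + miss
    inter[miss] <- bitwOr(a, b)[miss]
    node[sched[r, 3L], ] <- inter
  }
  steps
}

# Topologies x characters matrix of Fitch steps over a whole topology space.
steps_matrix <- function(space, matrix) {
  if (!identical(space$taxa, matrix$taxa)) {
    # allow any order as long as the sets agree
    if (!setequal(space$taxa, matrix$taxa)) stop("taxa mismatch")
    matrix$states <- matrix$states[space$taxa, , drop = FALSE]
    matrix$taxa <- space$taxa
  }
  enc <- encode_states(matrix)
  out <- matrix(0L, length(space$schedules), ncol(enc))
  for (t in seq_along(space$schedules)) {
    out[t, ] <- fitch_steps_schedule(space$schedules[[t]], enc)
  }
  out
}

#' Fitch parsimony length of a tree
#'
#' Sum over characters of the minimum number of unordered state changes
#' required on the tree (Fitch pass on the unrooted topology, rooted
#' arbitrarily; \code{?} treated as the full state set). The result is
#' invariant to the choice of root.
#'
#' @param tree A \code{phylo} tree whose tips are exactly the matrix taxa.
#'   Binary internal nodes are required (a trifurcating or bifurcating root is
#'   fine).
#' @param matrix A [character_matrix()].
#' @return Non-negative integer.
#' @export
fitch_length <- function(tree, matrix) {
  stopifnot(inherits(tree, "phylo"), inherits(matrix, "character_matrix"))
  if (!setequal(tree$tip.label, matrix$taxa)) {
    stop("tree leaves and matrix taxa differ")
  }
  enc <- encode_states(matrix)[match(tree$tip.label, matrix$taxa), ,
                               drop = FALSE]
  n <- length(tree$tip.label)
  C <- ncol(enc)
  tree <- stats::reorder(tree, "postorder")
  node <- matrix(0L, n + tree$Nnode, C)
  node[seq_len(n), ] <- enc
  seen <- logical(n + tree$Nnode)
  seen[seq_len(n)] <- TRUE
  steps <- integer(C)
  for (r in seq_len(nrow(tree$edge))) {
    p <- tree$edge[r, 1L]
    ch <- tree$edge[r, 2L]
    if (!seen[p]) {
      node[p, ] <- node[ch, ]
      seen[p] <- TRUE
    } else {
      a <- node[p, ]
      b <- node[ch, ]
      inter <- bitwAnd(a, b)
      miss <- inter == 0L
      steps <- steps + miss
      inter[miss] <- bitwOr(a, b)[miss]
      node[p, ] <- inter
    }
  }
  sum(steps)
}

#' Ensemble consistency index
#'
#' CI = (sum over characters of the minimum conceivable steps) / (tree
#' length), reported to 4 decimals. Equals 1 exactly when the matrix is free
#' of homoplasy on its most-parsimonious tree.
#'
#' @param matrix A [character_matrix()].
#' @param length Tree length (total Fitch steps), a non-negative integer.
#' @return Fraction in (0, 1], rounded to 4 decimals.
#' @export
consistency_index <- function(matrix, length) {
  msum <- sum(char_min_steps(matrix))
  if (length == 0L) {
    if (msum > 0L) stop("length 0 with nonzero minimum steps")
    return(1)
  }
  if (length < msum) stop("length below the per-character minimum total")
  round(msum / length, 4L)
}

#' Exhaustive maximum-parsimony search
#'
#' Scores every unrooted binary topology over the matrix taxa by Fitch
#' parsimony and returns all topologies attaining the minimum length, in
#' deterministic canonical-newick order, together with the tree length,
#' ensemble consistency index and the number of topologies examined.
#'
#' @param matrix A [character_matrix()] with 3 to 9 taxa (the exhaustive
#'   enumeration cap; larger problems would need branch-and-bound).
#' @param space Optional precomputed [topology_space()] over the same taxa.
#' @return An object of class \code{tree_search}: list with \code{mp_trees}
#'   (\code{multiPhylo}), \code{length}, \code{ci},
#'   \code{n_topologies_examined}, plus internals reused by
#'   [bremer_support()].
#' @export
exhaustive_search <- function(matrix, space = NULL) {
  stopifnot(inherits(matrix, "character_matrix"))
  if (is.null(space)) space <- topology_space(matrix$taxa)
  S <- steps_matrix(space, matrix)
  lengths <- as.integer(rowSums(S))
  L <- min(lengths)
  idx <- which(lengths == L)
  nwk <- space$newicks[idx]
  ord <- order(nwk)
  idx <- idx[ord]
  trees <- ape::read.tree(text = paste(space$newicks[idx], collapse = "\n"))
  if (inherits(trees, "phylo")) trees <- c(trees)
  structure(list(
    mp_trees = trees,
    length = L,
    ci = consistency_index(matrix, L),
    n_topologies_examined = length(lengths),
    mp_index = idx,
    lengths = lengths,
    space = space,
    taxa = space$taxa),
    class = "tree_search")
}

#' @export
print.tree_search <- function(x, ...) {
  cat(sprintf("Exhaustive maximum-parsimony search over %d topologies (%d taxa)\n",
              x$n_topologies_examined, length(x$taxa)))
  cat(sprintf("  best score (length) = %d, CI = %.4f, %d MP tree(s)\n",
              x$length, x$ci, length(x$mp_trees)))
  invisible(x)
}

#' Strict consensus bipartitions of the MP trees
#'
#' Bipartitions present in every most-parsimonious tree of a search result,
#' as taxon subsets (the side not containing the last taxon).
#'
#' @param result A [exhaustive_search()] result.
#' @return List of character vectors of taxon labels.
#' @export
strict_consensus_clades <- function(result) {
  stopifnot(inherits(result, "tree_search"))
  masksets <- result$space$masks[result$mp_index]
  common <- Reduce(intersect, masksets)
  lapply(common, mask_members, taxa = result$taxa)
}
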