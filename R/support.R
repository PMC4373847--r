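#' Nonparametric bootstrap clade support
#'
#' Resamples characters with replacement to the original count, runs an
#' exhaustive maximum-parsimony search per replicate (via a precomputed
#' topology-by-character steps matrix, so each replicate is a single weighted
#' re-scoring of the full tree space), and tallies the bipartitions of all MP
#' trees. When a replicate ties over several MP trees, each contributes
#' fractionally (1/count), avoiding bias toward arbitrary tie order.
#' Reproducible per seed.
#'
#' @param matrix A [character_matrix()] with at least 4 taxa.
#' @param n_reps Number of bootstrap replicates (default 2000).
#' @param seed Optional integer seed.
#' @param space Optional precomputed [topology_space()].
#' @return data.frame of class \code{clade_support} with columns \code{clade}
#'   (taxon labels, \code{+}-joined), \code{bootstrap_pct} and the internal
#'   \code{mask}; attributes \code{n_reps}, \code{seed}, \code{taxa}.
#' @export
bootstrap_support <- function(matrix, n_reps = 2000L, seed = NULL,
                              space = NULL) {
  stopifnot(inherits(matrix, "character_matrix"))
  if (n_reps < 1L) stop("n_reps must be >= 1")
  if (length(matrix$taxa) < 4L) stop("need at least 4 taxa")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(space)) space <- topology_space(matrix$taxa)
  S <- steps_matrix(space, matrix)
  storage.mode(S) <- "double"
  C <- ncol(S)
  tally <- new.env(parent = emptyenv())
  for (rep in seq_len(n_reps)) {
    w <- tabulate(sample.int(C, C, replace = TRUE), nbins = C)
    lens <- as.vector(S %*% w)
    idx <- which(lens == min(lens))
    frac <- 1 / length(idx)
    for (t in idx) {
      for (m in space$masks[[t]]) {
        key <- as.character(m)
        tally[[key]] <- (tally[[key]] %||% 0) + frac
      }
    }
  }
  keys <- ls(tally)
  masks <- as.integer(keys)
  pct <- vapply(keys, function(k) tally[[k]], 0) / n_reps * 100
  clades <- vapply(masks, function(m)
    paste(mask_members(m, space$taxa), collapse = "+"), "")
  out <- data.frame(clade = clades, bootstrap_pct = unname(pct),
                    mask = masks, stringsAsFactors = FALSE)
  out <- out[order(-out$bootstrap_pct, out$clade), ]
  rownames(out) <- NULL
  attr(out, "n_reps") <- n_reps
  attr(out, "seed") <- seed
  attr(out, "taxa") <- space$taxa
  class(out) <- c("clade_support", "data.frame")
  out
}

#' Majority-rule consensus tree
#'
#' Consensus of a set of trees over one leaf set: every bipartition whose
#' frequency strictly exceeds the threshold is retained (the retained set is
#' guaranteed compatible for thresholds >= 0.5) and annotated with its
#' frequency as a node label (percentage, one decimal).
#'
#' @param trees A \code{multiPhylo} or list of \code{phylo} trees sharing a
#'   leaf set.
#' @param threshold Retention threshold as a fraction (default 0.5).
#' @return A \code{phylo} tree with frequency node labels; attribute
#'   \code{frequencies} holds the full bipartition frequency table.
#' @export
majority_rule_consensus <- function(trees, threshold = 0.5) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("no trees")
  taxa <- sort(trees[[1L]]$tip.label)
  for (tr in trees) {
    if (!setequal(tr$tip.label, taxa)) stop("trees have mismatched leaf sets")
  }
  counts <- new.env(parent = emptyenv())
  for (tr in trees) {
    for (m in phylo_bipartitions(tr, taxa)) {
      key <- as.character(m)
      counts[[key]] <- (counts[[key]] %||% 0) + 1
    }
  }
  keys <- ls(counts)
  masks <- as.integer(keys)
  freq <- vapply(keys, function(k) counts[[k]], 0) / length(trees)
  keep <- freq > threshold
  freq_tab <- data.frame(
    clade = vapply(masks, function(m)
      paste(mask_members(m, taxa), collapse = "+"), ""),
    frequency = unname(freq), retained = unname(keep),
    stringsAsFactors = FALSE)
  masks <- masks[keep]
  freq <- freq[keep]
  ord <- order(vapply(masks, function(m)
    length(mask_members(m, taxa)), 0L), decreasing = TRUE)
  masks <- masks[ord]
  freq <- freq[ord]
  # nest retained clades (pairwise compatible for threshold >= 0.5):
  # only maximal clades at top level
  is_max <- vapply(seq_along(masks), function(j) {
    memj <- mask_members(masks[j], taxa)
    !any(vapply(seq_along(masks), function(k) {
      k != j && all(memj %in% mask_members(masks[k], taxa))
    }, TRUE))
  }, TRUE)
  placed <- character()
  children <- character()
  for (j in which(is_max)) {
    mem <- mask_members(masks[j], taxa)
    inner <- which(vapply(seq_along(masks), function(k)
      k != j && all(mask_members(masks[k], taxa) %in% mem), TRUE))
    children <- c(children,
                  paste0(build_clade(masks, freq, taxa, j, inner),
                         sprintf("%.1f", 100 * freq[j])))
    placed <- c(placed, mem)
  }
  singles <- setdiff(taxa, placed)
  nwk <- paste0("(", paste(c(children, singles), collapse = ","), ");")
  tree <- ape::read.tree(text = nwk)
  attr(tree, "frequencies") <- freq_tab[order(-freq_tab$frequency), ]
  tree
}

# recursive newick builder for one retained clade and the retained clades
# strictly inside it
build_clade <- function(masks, freq, taxa, j, inner_idx) {
  mem <- mask_members(masks[j], taxa)
  is_max <- vapply(inner_idx, function(k) {
    memk <- mask_members(masks[k], taxa)
    !any(vapply(inner_idx, function(l) {
      l != k && all(memk %in% mask_members(masks[l], taxa))
    }, TRUE))
  }, TRUE)
  placed <- character()
  children <- character()
  for (k in inner_idx[is_max]) {
    memk <- mask_members(masks[k], taxa)
    deeper <- inner_idx[vapply(inner_idx, function(l)
      l != k && all(mask_members(masks[l], taxa) %in% memk), TRUE)]
    children <- c(children,
                  paste0(build_clade(masks, freq, taxa, k, deeper),
                         sprintf("%.1f", 100 * freq[k])))
    placed <- c(placed, memk)
  }
  singles <- setdiff(mem, placed)
  paste0("(", paste(c(children, singles), collapse = ","), ")")
}

#' Bremer decay index per clade
#'
#' For each clade in the strict consensus of the MP trees: the extra steps
#' needed before the clade is lost, i.e. (minimum length among enumerated
#' topologies NOT containing the clade) minus the MP length. Computed by full
#' enumeration over the precomputed tree space, so the values are exact and
#' independent of any random seed.
#'
#' @param matrix The [character_matrix()] the search was run on.
#' @param result The [exhaustive_search()] result for that matrix.
#' @return data.frame of class \code{clade_support} with columns \code{clade},
#'   \code{bremer} and \code{mask}.
#' @export
bremer_support <- function(matrix, result) {
  stopifnot(inherits(result, "tree_search"))
  space <- result$space
  masksets <- space$masks[result$mp_index]
  common <- Reduce(intersect, masksets)
  if (!length(common)) {
    out <- data.frame(clade = character(), bremer = integer(),
                      mask = integer(), stringsAsFactors = FALSE)
    class(out) <- c("clade_support", "data.frame")
    return(out)
  }
  bremer <- vapply(common, function(m) {
    lacking <- !vapply(space$masks, function(ms) m %in% ms, TRUE)
    as.integer(min(result$lengths[lacking]) - result$length)
  }, 0L)
  clades <- vapply(common, function(m)
    paste(mask_members(m, result$taxa), collapse = "+"), "")
  out <- data.frame(clade = clades, bremer = bremer, mask = common,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$bremer, out$clade), ]
  rownames(out) <- NULL
  attr(out, "taxa") <- result$taxa
  class(out) <- c("clade_support", "data.frame")
  out
}

#' Look up a support value by clade membership
#'
#' Retrieves the bootstrap percentage or Bremer index for a clade from a
#' support table; either side of the bipartition may be given (tables store
#' the side not containing the last taxon).
#'
#' @param support A table from [bootstrap_support()] or [bremer_support()].
#' @param members Character vector of taxon labels on one side of the
#'   bipartition.
#' @return The support value, or \code{NA} when the clade is absent.
#' @export
support_for <- function(support, members) {
  taxa <- attr(support, "taxa")
  n <- length(taxa)
  idx <- match(intersect(members, taxa), taxa)
  if (!length(idx)) return(NA_real_)
  m <- mask_of(idx)
  ref_bit <- bitwShiftL(1L, n - 1L)
  full <- bitwShiftL(1L, n) - 1L
  if (bitwAnd(m, ref_bit) != 0L) m <- bitwAnd(full, bitwNot(m))
  hit <- which(support$mask == m)
  if (!length(hit)) return(NA_real_)
  col <- setdiff(names(support), c("clade", "mask"))[1L]
  support[[col]][hit[1L]]
}
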