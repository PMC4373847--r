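# Unrooted binary topologies over n taxa are enumerated through the classical
# bijection with rooted binary trees on the first n-1 taxa: taxon n is attached
# at the root position. Trees are built by stepwise addition (taxon k is
# inserted into each of the 2k-5 edges of every (k-1)-taxon tree), which yields
# every topology exactly once -- (2n-5)!! in total.
#
# Each topology is stored as a "merge schedule": a (n-1) x 3 integer matrix of
# postorder merges (left child id, right child id, new internal id), with
# leaves numbered 1..n and internals n+1..2n-2. The last merge joins the
# subtree root with leaf n. Schedules drive the vectorised Fitch pass; the
# clade bitmasks of the n-3 internal edges are precomputed alongside.

# enumerate nested-pair trees over leaves 1..m (m >= 2)
enumerate_nested <- function(m) {
  insert_edges <- function(tr, k) {
    out <- list(list(tr, k))
    if (is.list(tr)) {
      for (i in 1:2) {
        for (sub in insert_edges(tr[[i]], k)) {
          t2 <- tr
          t2[[i]] <- sub
          out[[length(out) + 1L]] <- t2
        }
      }
    }
    out
  }
  trees <- list(list(1L, 2L))
  if (m >= 3L) {
    for (k in 3:m) {
      trees <- unlist(lapply(trees, insert_edges, k = k), recursive = FALSE)
    }
  }
  trees
}

# nested tree + root leaf n -> schedule, internal-edge masks, canonical newick
nested_to_schedule <- function(tr, n, taxa) {
  m <- n - 1L
  sched <- matrix(0L, n - 1L, 3L)
  masks <- integer(0)
  row <- 0L
  next_id <- n
  walk <- function(node) {
    if (!is.list(node)) {
      return(list(id = node, mask = bitwShiftL(1L, node - 1L),
                  min = node, nwk = taxa[node]))
    }
    l <- walk(node[[1L]])
    r <- walk(node[[2L]])
    next_id <<- next_id + 1L
    row <<- row + 1L
    sched[row, ] <<- c(l$id, r$id, next_id)
    mask <- bitwOr(l$mask, r$mask)
    masks <<- c(masks, mask)
    if (l$min > r$min) { tmp <- l; l <- r; r <- tmp }
    list(id = next_id, mask = mask, min = l$min,
         nwk = paste0("(", l$nwk, ",", r$nwk, ")"))
  }
  res <- walk(tr)
  row <- row + 1L
  next_id <- next_id + 1L
  sched[row, ] <- c(res$id, n, next_id)
  # the subtree-root clade (all of 1..m) is the trivial pendant bipartition of
  # leaf n; drop it from the internal-edge masks
  masks <- masks[masks != (bitwShiftL(1L, m) - 1L)]
  list(schedule = sched, masks = masks,
       newick = paste0("(", res$nwk, ",", taxa[n], ");"))
}

#' Precompute the exhaustive topology space
#'
#' Enumerates every distinct unrooted binary topology over the given taxa
#' ((2n-5)!! of them) together with the postorder merge schedules and
#' internal-edge bipartition bitmasks used by the search, bootstrap and Bremer
#' routines. Practical up to 9 taxa (135,135 topologies); beyond that an
#' exhaustive enumeration is refused and a branch-and-bound strategy would be
#' required.
#'
#' @param taxa Character vector of 3 to 9 taxon labels.
#' @return An object of class \code{topology_space}.
#' @export
topology_space <- function(taxa) {
  n <- length(taxa)
  if (n < 3L) stop("need at least 3 taxa")
  if (n > 9L) {
    stop("exhaustive enumeration refused for ", n,
         " taxa ((2n-5)!! topologies); a branch-and-bound search would be ",
         "needed beyond 9 taxa")
  }
  nested <- enumerate_nested(n - 1L)
  items <- lapply(nested, nested_to_schedule, n = n, taxa = taxa)
  structure(list(
    taxa = taxa,
    n = n,
    schedules = lapply(items, `[[`, "schedule"),
    masks = lapply(items, `[[`, "masks"),
    newicks = vapply(items, `[[`, "", "newick")),
    class = "topology_space")
}

#' @export
print.topology_space <- function(x, ...) {
  cat(sprintf("Topology space: %d unrooted binary topologies over %d taxa\n",
              length(x$schedules), x$n))
  invisible(x)
}

#' Enumerate unrooted binary topologies
#'
#' Yields every distinct unrooted binary topology over the taxa exactly once,
#' as \code{ape} \code{phylo} objects in canonical newick form; the count is
#' (2n-5)!!.
#'
#' @inheritParams topology_space
#' @return A \code{multiPhylo} list of trees.
#' @export
enumerate_topologies <- function(taxa) {
  space <- topology_space(taxa)
  trees <- ape::read.tree(text = paste(space$newicks, collapse = "\n"))
  if (inherits(trees, "phylo")) trees <- c(trees)
  trees
}

# Bipartitions of an arbitrary phylo tree as bitmasks over `taxa`, canonical
# side = the side not containing the last taxon. Non-trivial edges only.
phylo_bipartitions <- function(tree, taxa) {
  n <- length(taxa)
  idx <- match(tree$tip.label, taxa)
  if (anyNA(idx)) stop("tree leaves do not match taxa")
  full <- if (n >= 31L) stop("too many taxa for bitmask bipartitions") else
    bitwShiftL(1L, n) - 1L
  pp <- ape::prop.part(tree)
  masks <- vapply(pp, function(tips) mask_of(idx[tips]), 0L)
  ref_bit <- bitwShiftL(1L, n - 1L)
  masks <- vapply(masks, function(m) {
    if (bitwAnd(m, ref_bit) != 0L) bitwAnd(full, bitwNot(m)) else m
  }, 0L)
  sizes <- vapply(masks, function(m) sum(bitwAnd(bitwShiftR(m, 0:(n - 1L)), 1L)), 0)
  unique(masks[sizes >= 2L & sizes <= n - 2L])
}
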