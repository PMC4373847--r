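#' Root a tree on an outgroup
#'
#' Places the root on the branch separating the outgroup taxa from the
#' ingroup (the classical outgroup method: polarity is established a
#' posteriori by rooting, not assumed when coding). The outgroup must be
#' separable from the ingroup by a single edge of the unrooted topology.
#'
#' @param tree An unrooted (or arbitrarily rooted) binary \code{phylo} tree.
#' @param outgroup Character vector of outgroup taxon labels.
#' @return A rooted \code{phylo} tree with attributes \code{outgroup} and
#'   \code{ingroup}.
#' @export
root_on_outgroup <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"))
  taxa <- tree$tip.label
  missing <- setdiff(outgroup, taxa)
  if (length(missing)) {
    stop("outgroup taxa absent from tree: ", paste(missing, collapse = ", "))
  }
  ingroup <- setdiff(taxa, outgroup)
  if (!length(ingroup)) stop("outgroup covers the whole tree")
  if (length(outgroup) > 1L && length(ingroup) > 1L) {
    sorted <- sort(taxa)
    ref_bit_side <- sort(outgroup)
    biparts <- phylo_bipartitions(tree, sorted)
    sets <- lapply(biparts, mask_members, taxa = sorted)
    separable <- any(vapply(sets, function(s)
      setequal(s, outgroup) || setequal(s, ingroup), TRUE))
    if (!separable) {
      stop("outgroup is interdigitated with the ingroup; no single edge ",
           "separates {", paste(outgroup, collapse = ", "), "}")
    }
  }
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  attr(rooted, "outgroup") <- outgroup
  attr(rooted, "ingroup") <- ingroup
  rooted
}

# Sankoff-style two-pass reconstruction for binary characters with Fitch
# (unit) costs, vectorised over characters. Returns per-node conditional
# costs and most-parsimonious-reconstruction (MPR) state sets.
mpr_tables <- function(rtree, matrix) {
  stopifnot(inherits(rtree, "phylo"))
  if (!setequal(rtree$tip.label, matrix$taxa)) {
    stop("tree leaves and matrix taxa differ")
  }
  BIG <- 1e9
  n <- length(rtree$tip.label)
  C <- length(matrix$defs)
  M <- n + rtree$Nnode
  st <- matrix$states[match(rtree$tip.label, matrix$taxa), , drop = FALSE]
  d0 <- matrix(0, M, C); d1 <- matrix(0, M, C)
  d0[seq_len(n), ][st == "1"] <- BIG
  d1[seq_len(n), ][st == "0"] <- BIG
  po <- stats::reorder(rtree, "postorder")
  for (r in seq_len(nrow(po$edge))) {
    p <- po$edge[r, 1L]; ch <- po$edge[r, 2L]
    d0[p, ] <- d0[p, ] + pmin(d0[ch, ], d1[ch, ] + 1)
    d1[p, ] <- d1[p, ] + pmin(d1[ch, ], d0[ch, ] + 1)
  }
  root <- n + 1L
  total <- pmin(d0[root, ], d1[root, ])
  # up-pass: cost of the rest of the tree given a node's state
  u0 <- matrix(0, M, C); u1 <- matrix(0, M, C)
  pre <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]
  children <- split(po$edge[, 2L], po$edge[, 1L])
  for (r in seq_len(nrow(pre))) {
    p <- pre[r, 1L]; ch <- pre[r, 2L]
    sibs <- setdiff(children[[as.character(p)]], ch)
    A0 <- u0[p, ]; A1 <- u1[p, ]
    for (b in sibs) {
      A0 <- A0 + pmin(d0[b, ], d1[b, ] + 1)
      A1 <- A1 + pmin(d1[b, ], d0[b, ] + 1)
    }
    u0[ch, ] <- pmin(A0, A1 + 1)
    u1[ch, ] <- pmin(A1, A0 + 1)
  }
  list(tree = po, n_tip = n, root = root, d0 = d0, d1 = d1, u0 = u0, u1 = u1,
       steps = as.integer(round(pmin(total, BIG))),
       mpr0 = (d0 + u0) <= (total[col(d0)] + 1e-6),
       mpr1 = (d1 + u1) <= (total[col(d1)] + 1e-6),
       children = children)
}

#' Ancestral state sets under maximum parsimony
#'
#' Most-parsimonious-reconstruction (MPR) state sets for every node of a
#' rooted binary tree: the states a node can take in at least one
#' minimum-length assignment. Ambiguous nodes carry \{0,1\}.
#'
#' @param rtree A rooted binary \code{phylo} tree (from
#'   [root_on_outgroup()]).
#' @param matrix A [character_matrix()].
#' @return An object of class \code{ancestral_states}: list with
#'   \code{steps} (per-character Fitch steps), \code{mpr0}/\code{mpr1}
#'   (nodes x characters logical matrices: state 0 / state 1 in the MPR set)
#'   and the reordered \code{tree}. Node rows follow \code{ape} numbering
#'   (tips first).
#' @export
ancestral_states <- function(rtree, matrix) {
  tab <- mpr_tables(rtree, matrix)
  structure(tab, class = "ancestral_states")
}

# Resolve one minimum-length assignment from the MPR tables.
# deltran delays changes (keeps the parental state on ties, root tie -> 0);
# acctran accelerates them (switches on ties, root tie -> 1).
resolve_states <- function(tab, mode = c("deltran", "acctran")) {
  mode <- match.arg(mode)
  M <- nrow(tab$d0)
  C <- ncol(tab$d0)
  state <- matrix(NA_integer_, M, C)
  root <- tab$root
  r0 <- tab$d0[root, ]; r1 <- tab$d1[root, ]
  state[root, ] <- ifelse(r0 < r1, 0L,
                          ifelse(r1 < r0, 1L,
                                 if (mode == "deltran") 0L else 1L))
  pre <- tab$tree$edge[rev(seq_len(nrow(tab$tree$edge))), , drop = FALSE]
  for (r in seq_len(nrow(pre))) {
    p <- pre[r, 1L]; ch <- pre[r, 2L]
    sp <- state[p, ]
    cost_keep <- ifelse(sp == 0L, tab$d0[ch, ], tab$d1[ch, ])
    cost_switch <- ifelse(sp == 0L, tab$d1[ch, ], tab$d0[ch, ]) + 1
    switch_ <- if (mode == "deltran") cost_switch < cost_keep
               else cost_switch <= cost_keep
    state[ch, ] <- ifelse(switch_, 1L - sp, sp)
  }
  state
}

# human-readable branch id: the descendant tip set of the edge's child node
branch_labels <- function(tree) {
  n <- length(tree$tip.label)
  lab <- character(n + tree$Nnode)
  lab[seq_len(n)] <- tree$tip.label
  po <- stats::reorder(tree, "postorder")
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- tree$tip.label[i]
  for (r in seq_len(nrow(po$edge))) {
    p <- po$edge[r, 1L]; ch <- po$edge[r, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  for (i in seq_len(n + tree$Nnode)) {
    lab[i] <- paste(sort_labels(desc[[i]]), collapse = "+")
  }
  lab
}

#' Classify chromosomal characters on the rooted tree
#'
#' Maps every character a posteriori onto the rooted most-parsimonious tree
#' and assigns exactly one category:
#' \describe{
#'   \item{constant}{minimum conceivable steps is 0 (no variation).}
#'   \item{homoplasy}{realised steps exceed the minimum (convergence or
#'     reversal).}
#'   \item{plesiomorphy}{the derived condition (state 1) is already present
#'     at the ingroup's most recent common ancestor \emph{and} at the root
#'     (i.e. it arose below the ingroup and is shared with the outgroup);
#'     a state fixed on the ingroup stem itself is a synapomorphy of the
#'     ingroup, not a plesiomorphy.}
#'   \item{autapomorphy}{the single change lies on a terminal branch.}
#'   \item{synapomorphy}{the single change lies on an internal branch.}
#' }
#' Precedence is homoplasy > plesiomorphy > autapomorphy > synapomorphy.
#' Ambiguous change placement is resolved under DELTRAN by default (changes
#' pushed toward the tips); the classification is recomputed under ACCTRAN
#' and characters whose category depends on the optimization are flagged.
#'
#' @param rtree A rooted tree from [root_on_outgroup()] (the \code{ingroup}
#'   attribute identifies the ingroup; alternatively pass \code{outgroup}).
#' @param matrix A [character_matrix()].
#' @param optimization \code{"deltran"} (default) or \code{"acctran"}.
#' @param outgroup Outgroup labels if \code{rtree} lacks the attribute.
#' @return data.frame of class \code{character_mapping}: one row per
#'   character with \code{character_id}, \code{steps}, \code{min_steps},
#'   \code{change_branches}, \code{category},
#'   \code{optimization_dependent}; attribute \code{counts} holds the
#'   per-category totals.
#' @export
classify_characters <- function(rtree, matrix,
                                optimization = c("deltran", "acctran"),
                                outgroup = NULL) {
  optimization <- match.arg(optimization)
  outgroup <- attr(rtree, "outgroup") %||% outgroup
  if (is.null(outgroup)) stop("outgroup unknown; root with root_on_outgroup()")
  ingroup <- setdiff(rtree$tip.label, outgroup)
  tab <- mpr_tables(rtree, matrix)
  tree <- tab$tree
  min_steps <- char_min_steps(matrix)
  steps <- tab$steps
  mrca_in <- if (length(ingroup) > 1L) {
    ape::getMRCA(tree, ingroup)
  } else {
    match(ingroup, tree$tip.label)
  }
  labels <- branch_labels(tree)
  n <- tab$n_tip
  categorise <- function(state) {
    chg <- lapply(seq_len(ncol(state)), function(ci) {
      e <- tree$edge
      which(state[e[, 1L], ci] != state[e[, 2L], ci])
    })
    cat <- character(ncol(state))
    for (ci in seq_len(ncol(state))) {
      if (min_steps[ci] == 0L) {
        cat[ci] <- "constant"
      } else if (steps[ci] > min_steps[ci]) {
        cat[ci] <- "homoplasy"
      } else if (state[mrca_in, ci] == 1L && state[tab$root, ci] == 1L) {
        cat[ci] <- "plesiomorphy"
      } else {
        child <- tree$edge[chg[[ci]], 2L]
        cat[ci] <- if (all(child <= n)) "autapomorphy" else "synapomorphy"
      }
    }
    list(category = cat, changes = chg)
  }
  res_main <- categorise(resolve_states(tab, optimization))
  res_alt <- categorise(resolve_states(
    tab, if (optimization == "deltran") "acctran" else "deltran"))
  branches <- vapply(res_main$changes, function(e)
    paste(labels[tree$edge[e, 2L]], collapse = "; "), "")
  out <- data.frame(
    character_id = vapply(matrix$defs, `[[`, "", "id"),
    steps = steps,
    min_steps = min_steps,
    change_branches = branches,
    category = res_main$category,
    optimization_dependent = res_main$category != res_alt$category,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  counts <- table(factor(out$category,
                         levels = c("autapomorphy", "synapomorphy",
                                    "plesiomorphy", "homoplasy", "constant")))
  attr(out, "counts") <- counts
  attr(out, "optimization") <- optimization
  attr(out, "ingroup") <- ingroup
  class(out) <- c("character_mapping", "data.frame")
  out
}

#' @export
print.character_mapping <- function(x, ...) {
  counts <- attr(x, "counts")
  cat(sprintf("Chromosomal changes mapped a posteriori (%d characters, %s):\n",
              nrow(x), attr(x, "optimization")))
  cat(sprintf("  %d autapomorphies, %d synapomorphies, %d plesiomorphies, %d homoplasies, %d constant\n",
              counts[["autapomorphy"]], counts[["synapomorphy"]],
              counts[["plesiomorphy"]], counts[["homoplasy"]],
              counts[["constant"]]))
  if (any(x$optimization_dependent)) {
    cat("  (", sum(x$optimization_dependent),
        "character(s) change category under the alternative optimization )\n")
  }
  NextMethod()
  invisible(x)
}

#' Characters ancestral for the ingroup
#'
#' Lists the characters whose derived condition (state 1) is inferred at the
#' ingroup's most recent common ancestor -- the character-set counterpart of
#' an ancestral-karyotype reconstruction -- together with the reference units
#' inferred conserved in toto at that node (units with no disruption
#' character scored 1 at the root).
#'
#' @inheritParams classify_characters
#' @return An object of class \code{root_state_report}: list with
#'   \code{root_characters} (character ids), \code{conserved_units}, and the
#'   \code{optimization} used.
#' @export
root_state_report <- function(rtree, matrix,
                              optimization = c("deltran", "acctran"),
                              outgroup = NULL) {
  optimization <- match.arg(optimization)
  outgroup <- attr(rtree, "outgroup") %||% outgroup
  if (is.null(outgroup)) stop("outgroup unknown; root with root_on_outgroup()")
  ingroup <- setdiff(rtree$tip.label, outgroup)
  tab <- mpr_tables(rtree, matrix)
  state <- resolve_states(tab, optimization)
  mrca_in <- if (length(ingroup) > 1L) {
    ape::getMRCA(tab$tree, ingroup)
  } else {
    match(ingroup, tab$tree$tip.label)
  }
  ids <- vapply(matrix$defs, `[[`, "", "id")
  at_root <- state[mrca_in, ] == 1L
  kinds <- vapply(matrix$defs, `[[`, "", "kind")
  units <- sort_labels(unique(unlist(lapply(matrix$defs, `[[`,
                                            "reference_units"))))
  disrupted_at_root <- unique(unlist(lapply(
    which(kinds == "disruption" & at_root),
    function(i) matrix$defs[[i]]$reference_units)))
  structure(list(root_characters = ids[at_root],
                 conserved_units = setdiff(units, disrupted_at_root),
                 optimization = optimization,
                 ingroup = ingroup),
            class = "root_state_report")
}

#' @export
print.root_state_report <- function(x, ...) {
  cat("Ingroup-root character report (", x$optimization, "):\n", sep = "")
  cat("  derived conditions at the ingroup root:",
      if (length(x$root_characters))
        paste(x$root_characters, collapse = ", ") else "(none)", "\n")
  cat("  reference units conserved in toto at the root:",
      if (length(x$conserved_units))
        paste(x$conserved_units, collapse = ", ") else "(none)", "\n")
  invisible(x)
}
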