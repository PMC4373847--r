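# A complement is a list of chromosomes; each chromosome is a list with
# `blocks` (integer vector of ancestral-unit ids, one element per contiguous
# block, in order along the chromosome) and `biarmed` (logical morphology
# flag). The ancestral complement has one single-block one-armed chromosome
# per conserved unit; rearrangements never gain or lose material.

ancestral_complement <- function(ancestral_units) {
  lapply(seq_len(ancestral_units), function(u)
    list(blocks = u, biarmed = FALSE))
}

#' Configure a karyotype-evolution simulation
#'
#' Defines the study conditions for [simulate_karyotypes()]: the known tree,
#' the size of the ancestral complement of conserved units, and per-event-type
#' rates (expected events per unit branch length). Event counts per branch are
#' Poisson with mean rate x branch length, unless fixed counts are supplied
#' through \code{per_branch_events} (one count applied to every branch).
#'
#' @param tree A rooted binary \code{phylo} tree with tip labels; missing
#'   branch lengths default to 1.
#' @param ancestral_units Number of conserved reference units (>= 2);
#'   default 16, a PHA-like complement (15 autosome pairs + X).
#' @param rates Named numeric vector of per-event-type rates with names
#'   \code{fusion}, \code{fission}, \code{translocation}, \code{inversion}.
#' @param seed Integer seed; all randomness in the simulation flows through
#'   it.
#' @param unit_internal_fission Allow fission breakpoints inside a unit's
#'   block (raising the block count of that unit on both products), off by
#'   default.
#' @param per_branch_events Optional fixed number of events per branch
#'   (overrides the Poisson draw; branch lengths then only order events).
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(tree, ancestral_units = 16L,
                       rates = c(fusion = 0.3, fission = 0.3,
                                 translocation = 0.2, inversion = 0.2),
                       seed = 1L, unit_internal_fission = FALSE,
                       per_branch_events = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("simulation tree must be rooted")
  if (ancestral_units < 2L) stop("ancestral_units must be >= 2")
  need <- c("fusion", "fission", "translocation", "inversion")
  if (!all(need %in% names(rates))) {
    stop("rates must name ", paste(need, collapse = ", "))
  }
  if (any(rates < 0)) stop("rates must be >= 0")
  if (is.null(tree$edge.length)) tree$edge.length <- rep(1, nrow(tree$edge))
  structure(list(tree = tree, ancestral_units = as.integer(ancestral_units),
                 rates = rates[need], seed = as.integer(seed),
                 unit_internal_fission = unit_internal_fission,
                 per_branch_events = per_branch_events),
            class = "sim_config")
}

# apply one recorded event to a complement; used by both simulate and replay
apply_event <- function(comp, ev) {
  type <- ev$type
  if (type == "fusion") {
    i <- ev$chr1; j <- ev$chr2
    fused <- list(blocks = c(comp[[i]]$blocks, comp[[j]]$blocks),
                  biarmed = TRUE)
    keep <- min(i, j); drop <- max(i, j)
    comp[[keep]] <- fused
    comp[[drop]] <- NULL
  } else if (type == "fission") {
    i <- ev$chr1; pos <- ev$pos1
    blocks <- comp[[i]]$blocks
    if (ev$internal) {
      # split inside block `pos`: both products keep a copy of that unit
      left <- list(blocks = blocks[seq_len(pos)], biarmed = FALSE)
      right <- list(blocks = blocks[seq(pos, length(blocks))], biarmed = FALSE)
    } else {
      left <- list(blocks = blocks[seq_len(pos)], biarmed = FALSE)
      right <- list(blocks = blocks[seq(pos + 1L, length(blocks))],
                    biarmed = FALSE)
    }
    comp <- append(comp[-i], list(left, right), after = i - 1L)
  } else if (type == "translocation") {
    i <- ev$chr1; j <- ev$chr2; pi_ <- ev$pos1; pj <- ev$pos2
    bi <- comp[[i]]$blocks; bj <- comp[[j]]$blocks
    comp[[i]]$blocks <- c(bi[seq_len(pi_)], bj[seq(pj + 1L, length(bj))])
    comp[[j]]$blocks <- c(bj[seq_len(pj)], bi[seq(pi_ + 1L, length(bi))])
  } else if (type == "inversion") {
    i <- ev$chr1
    comp[[i]]$biarmed <- !comp[[i]]$biarmed
  } else {
    stop("malformed event log: unknown event type ", type)
  }
  comp
}

# draw one valid event for the current complement (resampling invalid draws)
draw_event <- function(comp, rates, internal_ok) {
  for (attempt in seq_len(1000L)) {
    type <- sample(names(rates), 1L, prob = rates)
    if (type == "fusion" || type == "translocation") {
      if (length(comp) < 2L) next
      ij <- sample.int(length(comp), 2L)
      if (type == "fusion") {
        return(list(type = "fusion", chr1 = ij[1L], chr2 = ij[2L],
                    pos1 = NA_integer_, pos2 = NA_integer_, internal = FALSE))
      }
      li <- length(comp[[ij[1L]]]$blocks)
      lj <- length(comp[[ij[2L]]]$blocks)
      if (li < 2L || lj < 2L) next
      return(list(type = "translocation", chr1 = ij[1L], chr2 = ij[2L],
                  pos1 = sample.int(li - 1L, 1L),
                  pos2 = sample.int(lj - 1L, 1L), internal = FALSE))
    }
    if (type == "fission") {
      i <- sample.int(length(comp), 1L)
      L <- length(comp[[i]]$blocks)
      n_boundary <- L - 1L
      n_internal <- if (internal_ok) L else 0L
      if (n_boundary + n_internal == 0L) next  # single-unit, single-block
      cut <- sample.int(n_boundary + n_internal, 1L)
      if (cut <= n_boundary) {
        return(list(type = "fission", chr1 = i, chr2 = NA_integer_,
                    pos1 = cut, pos2 = NA_integer_, internal = FALSE))
      }
      return(list(type = "fission", chr1 = i, chr2 = NA_integer_,
                  pos1 = cut - n_boundary, pos2 = NA_integer_,
                  internal = TRUE))
    }
    # inversion: always valid
    return(list(type = "inversion", chr1 = sample.int(length(comp), 1L),
                chr2 = NA_integer_, pos1 = NA_integer_, pos2 = NA_integer_,
                internal = FALSE))
  }
  NULL
}

unit_labels <- function(ancestral_units) paste0("ANC-", seq_len(ancestral_units))

# painting-style homology map of one tip complement: probes are the ancestral
# units, block counts are maximal runs per (unit, chromosome)
complement_to_map <- function(comp, tip) {
  rows <- list()
  for (k in seq_along(comp)) {
    runs <- rle(comp[[k]]$blocks)
    tab <- table(runs$values)
    for (u in as.integer(names(tab))) {
      rows[[length(rows) + 1L]] <- data.frame(
        probe = paste0("ANC-", u),
        target = paste0(tip, "-", k),
        n_blocks = as.integer(tab[[as.character(u)]]),
        region = NA_character_, stringsAsFactors = FALSE)
    }
  }
  sig <- if (length(rows)) do.call(rbind, rows) else
    data.frame(probe = character(), target = character(),
               n_blocks = integer(), region = character())
  homology_map("ANC", tip, sig, check_species = FALSE)
}

# true binary matrix computed from the tip complements and the inversion
# events -- deliberately not by running the character coder, so that the
# generator and the coder cross-validate each other
truth_matrix <- function(complements, inversion_chars) {
  tips <- names(complements)
  unit_lab <- function(u) paste0("ANC-", u)
  assoc <- list(); disr <- character()
  per_tip_pairs <- list(); per_tip_disr <- list()
  for (tp in tips) {
    pairs <- character(); broken <- integer()
    counts <- integer()
    for (ch in complements[[tp]]) {
      units <- unique(ch$blocks)
      if (length(units) > 1L) {
        cmb <- utils::combn(sort(units), 2L)
        pairs <- c(pairs, apply(cmb, 2L, function(p)
          assoc_id(unit_lab(p[1L]), unit_lab(p[2L]))))
      }
      runs <- rle(ch$blocks)
      multi <- as.integer(names(which(table(runs$values) > 1L)))
      broken <- c(broken, multi)
      counts <- c(counts, unique(ch$blocks))
    }
    broken <- c(broken, as.integer(names(which(table(counts) > 1L))))
    per_tip_pairs[[tp]] <- unique(pairs)
    per_tip_disr[[tp]] <- unique(broken)
  }
  assoc_ids <- sort(unique(unlist(per_tip_pairs)))
  disr_units <- sort(unique(unlist(per_tip_disr)))
  disr_ids <- vapply(disr_units, function(u) disr_id(unit_lab(u)), "")
  ord <- order(disr_ids); disr_units <- disr_units[ord]; disr_ids <- disr_ids[ord]
  ids <- c(assoc_ids, disr_ids, sort(names(inversion_chars)))
  states <- matrix("0", length(tips), length(ids),
                   dimnames = list(tips, ids))
  for (tp in tips) {
    states[tp, per_tip_pairs[[tp]]] <- "1"
    states[tp, disr_ids[disr_units %in% per_tip_disr[[tp]]]] <- "1"
  }
  for (id in names(inversion_chars)) {
    states[inversion_chars[[id]], id] <- "1"
  }
  defs <- lapply(ids, function(id) {
    if (startsWith(id, "A.")) {
      units <- strsplit(sub("^A\\.", "", id), "+", fixed = TRUE)[[1L]]
      character_def(id, "association",
                    sprintf("%s/%s syntenic on one chromosome",
                            units[1L], units[2L]), units)
    } else if (startsWith(id, "D.")) {
      u <- sub("^D\\.", "", id)
      character_def(id, "disruption",
                    sprintf("%s split into >= 2 segments", u), u)
    } else {
      character_def(id, "structural", id)
    }
  })
  character_matrix(tips, defs, states)
}

#' Simulate karyotype evolution along a known tree
#'
#' Accumulates fusion, fission, reciprocal-translocation and pericentric
#' inversion events along the branches of a known tree, starting from an
#' ancestral complement of single-unit chromosomes, and emits everything the
#' analysis pipeline consumes: painting-style homology maps per tip (probes =
#' ancestral units), a structural annotation table (one character per
#' inversion event; inversions are invisible to painting), the true binary
#' character matrix, and a replayable event log. Deterministic per seed.
#'
#' Fusions join two chromosomes (creating segmental associations); fissions
#' split a chromosome at a unit boundary (creating a syntenic disruption), or
#' inside a unit when \code{unit_internal_fission} is enabled (raising that
#' unit's block count); reciprocal translocations exchange terminal blocks;
#' inversions toggle the morphology flag only. Material is never gained or
#' lost.
#'
#' @param config A [sim_config()].
#' @return An object of class \code{karyo_sim}: list with \code{maps} (named
#'   list of [homology_map()]s), \code{annotations} (structural annotation
#'   data.frame), \code{matrix} (the true [character_matrix()]),
#'   \code{event_log}, \code{complements} (per-tip), and \code{config}.
#' @export
simulate_karyotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- stats::reorder(config$tree, "cladewise")  # preorder edges
  n <- length(tree$tip.label)
  comp_at <- vector("list", n + tree$Nnode)
  comp_at[[n + 1L]] <- ancestral_complement(config$ancestral_units)
  log_rows <- list()
  inversion_chars <- list()
  total_rate <- sum(config$rates)
  tips_below <- branch_labels(tree)
  ev_id <- 0L
  for (r in seq_len(nrow(tree$edge))) {
    p <- tree$edge[r, 1L]; ch <- tree$edge[r, 2L]
    comp <- comp_at[[p]]
    n_ev <- if (!is.null(config$per_branch_events)) {
      config$per_branch_events
    } else {
      stats::rpois(1L, total_rate * tree$edge.length[r])
    }
    k <- 0L
    while (k < n_ev) {
      ev <- draw_event(comp, config$rates, config$unit_internal_fission)
      if (is.null(ev)) break
      k <- k + 1L
      ev_id <- ev_id + 1L
      comp <- apply_event(comp, ev)
      log_rows[[ev_id]] <- data.frame(
        branch = tips_below[ch], order = k, type = ev$type,
        chr1 = ev$chr1, pos1 = ev$pos1, chr2 = ev$chr2, pos2 = ev$pos2,
        internal = ev$internal, event_id = ev_id, stringsAsFactors = FALSE)
      if (ev$type == "inversion") {
        id <- sprintf("S.inv%03d", ev_id)
        desc <- strsplit(tips_below[ch], "+", fixed = TRUE)[[1L]]
        inversion_chars[[id]] <- desc
      }
    }
    comp_at[[ch]] <- comp
  }
  complements <- comp_at[seq_len(n)]
  names(complements) <- tree$tip.label
  maps <- lapply(tree$tip.label, function(tp)
    complement_to_map(complements[[tp]], tp))
  names(maps) <- tree$tip.label
  annotations <- if (length(inversion_chars)) {
    do.call(rbind, lapply(sort(names(inversion_chars)), function(id) {
      data.frame(taxon = tree$tip.label,
                 character_id = id,
                 state = ifelse(tree$tip.label %in% inversion_chars[[id]],
                                "1", "0"),
                 note = "pericentric inversion (simulated)",
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(taxon = character(), character_id = character(),
               state = character(), note = character(),
               stringsAsFactors = FALSE)
  }
  log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(branch = character(), order = integer(), type = character(),
               chr1 = integer(), pos1 = integer(), chr2 = integer(),
               pos2 = integer(), internal = logical(), event_id = integer(),
               stringsAsFactors = FALSE)
  attr(log, "tree") <- tree
  attr(log, "ancestral_units") <- config$ancestral_units
  class(log) <- c("event_log", "data.frame")
  structure(list(maps = maps,
                 annotations = annotations,
                 matrix = truth_matrix(complements, inversion_chars),
                 event_log = log,
                 complements = complements,
                 config = config),
            class = "karyo_sim")
}

#' Replay an event log
#'
#' Re-applies the recorded events, in recorded order, from the ancestral
#' complement down the tree, with no randomness: the round-trip oracle for
#' [simulate_karyotypes()] (tip complements must match bit-exactly).
#'
#' @param log An \code{event_log} from [simulate_karyotypes()].
#' @param ancestral_units Number of ancestral units; defaults to the value
#'   recorded in the log.
#' @return Named list of per-tip complements.
#' @export
replay_events <- function(log, ancestral_units = NULL) {
  if (!inherits(log, "event_log")) stop("malformed log: not an event_log")
  tree <- attr(log, "tree")
  ancestral_units <- ancestral_units %||% attr(log, "ancestral_units")
  need <- c("branch", "order", "type", "chr1", "pos1", "chr2", "pos2",
            "internal")
  if (!all(need %in% names(log))) stop("malformed log: missing columns")
  n <- length(tree$tip.label)
  comp_at <- vector("list", n + tree$Nnode)
  comp_at[[n + 1L]] <- ancestral_complement(ancestral_units)
  tips_below <- branch_labels(tree)
  for (r in seq_len(nrow(tree$edge))) {
    p <- tree$edge[r, 1L]; ch <- tree$edge[r, 2L]
    comp <- comp_at[[p]]
    evs <- log[log$branch == tips_below[ch], , drop = FALSE]
    evs <- evs[order(evs$order), , drop = FALSE]
    for (i in seq_len(nrow(evs))) {
      comp <- apply_event(comp, as.list(evs[i, ]))
    }
    comp_at[[ch]] <- comp
  }
  out <- comp_at[seq_len(n)]
  names(out) <- tree$tip.label
  out
}

#' @export
print.karyo_sim <- function(x, ...) {
  cat(sprintf("Karyotype simulation: %d tips, %d ancestral units, %d events (seed %d)\n",
              length(x$complements), x$config$ancestral_units,
              nrow(x$event_log), x$config$seed))
  cat(sprintf("  emitted matrix: %d characters (%d informative)\n",
              length(x$matrix$defs), count_informative(x$matrix)))
  invisible(x)
}
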