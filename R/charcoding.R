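#' Define a cladistic character
#'
#' @param id Character id, unique within a matrix. The derivation functions
#'   use \code{A.<u>+<v>} for segmental associations, \code{D.<u>} for
#'   syntenic disruptions and free-form \code{S.*} ids for structural
#'   characters.
#' @param kind One of \code{association}, \code{disruption},
#'   \code{structural}.
#' @param description Human-readable statement of the derived condition.
#' @param reference_units Reference chromosome labels involved (exactly 2 for
#'   associations, exactly 1 for disruptions).
#' @return An object of class \code{character_def} (a list).
#' @export
character_def <- function(id, kind, description = "",
                          reference_units = character()) {
  kind <- match.arg(kind, c("association", "disruption", "structural"))
  if (kind == "association" && length(reference_units) != 2L) {
    stop("association characters reference exactly 2 units")
  }
  if (kind == "disruption" && length(reference_units) != 1L) {
    stop("disruption characters reference exactly 1 unit")
  }
  structure(list(id = id, kind = kind, description = description,
                 reference_units = reference_units),
            class = "character_def")
}

defs_table <- function(defs) {
  data.frame(
    id = vapply(defs, `[[`, "", "id"),
    kind = vapply(defs, `[[`, "", "kind"),
    description = vapply(defs, `[[`, "", "description"),
    reference_units = vapply(defs, function(d)
      paste(d$reference_units, collapse = ","), ""),
    stringsAsFactors = FALSE)
}

#' Construct a binary character matrix
#'
#' Taxa x characters grid over \{0, 1, ?\} with per-character metadata. At
#' least one taxon must be scored non-\code{?} for every character.
#'
#' @param taxa Ordered character vector of species codes.
#' @param defs List of [character_def()] objects (one per column).
#' @param states Character matrix (values \code{"0"}, \code{"1"}, \code{"?"})
#'   with \code{length(taxa)} rows and \code{length(defs)} columns.
#' @return An object of class \code{character_matrix}.
#' @export
character_matrix <- function(taxa, defs, states) {
  states <- as.matrix(states)
  if (nrow(states) != length(taxa) || ncol(states) != length(defs)) {
    stop("states grid dimensions do not match taxa and characters lists")
  }
  if (anyDuplicated(taxa)) stop("duplicate taxa")
  ids <- vapply(defs, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate character ids")
  bad <- !states %in% c("0", "1", "?")
  if (any(bad)) stop("states must be '0', '1' or '?'")
  if (ncol(states) > 0) {
    allmiss <- colSums(states != "?") == 0L
    if (any(allmiss)) {
      stop("character(s) with no scored taxon: ",
           paste(ids[allmiss], collapse = ", "))
    }
  }
  dimnames(states) <- list(taxa, ids)
  structure(list(taxa = taxa, defs = defs, states = states),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  kinds <- table(factor(vapply(x$defs, `[[`, "", "kind"),
                        levels = c("association", "disruption", "structural")))
  cat(sprintf("Character matrix: %d taxa x %d characters (%d association, %d disruption, %d structural), %d parsimony-informative\n",
              length(x$taxa), length(x$defs), kinds[["association"]],
              kinds[["disruption"]], kinds[["structural"]],
              count_informative(x)))
  print(x$states, quote = FALSE)
  invisible(x)
}

assoc_id <- function(u, v) {
  uv <- sort_labels(c(u, v))
  paste0("A.", uv[1L], "+", uv[2L])
}

disr_id <- function(u) paste0("D.", u)

#' Derive segmental-association characters
#'
#' One binary character per unordered pair of reference units found joined on
#' a single chromosome in at least one taxon. A taxon scores 1 when the two
#' units share a partition group, 0 when both are detected but never share,
#' and ? when either unit is undetected in that taxon (absence of painting
#' evidence is not evidence of conservation).
#'
#' @param states List of [synteny_partition()] results, all over the same
#'   reference probe species.
#' @param reference The reference [karyotype()] (used to check unit labels),
#'   or \code{NULL} to skip the check.
#' @return List with elements \code{defs} (list of [character_def()]) and
#'   \code{states} (taxa x characters matrix), characters in lexicographic id
#'   order.
#' @export
derive_association_characters <- function(states, reference = NULL) {
  check_partitions(states, reference)
  taxa <- vapply(states, `[[`, "", "taxon")
  # pairs co-occurring in >= 1 taxon
  pair_ids <- character()
  pair_units <- list()
  for (st in states) {
    for (grp in st$partition) {
      if (length(grp) < 2L) next
      cmb <- utils::combn(grp, 2L)
      for (j in seq_len(ncol(cmb))) {
        id <- assoc_id(cmb[1L, j], cmb[2L, j])
        if (!id %in% pair_ids) {
          pair_ids <- c(pair_ids, id)
          pair_units[[id]] <- sort_labels(cmb[, j])
        }
      }
    }
  }
  pair_ids <- sort(pair_ids)
  mat <- matrix("?", length(taxa), length(pair_ids),
                dimnames = list(taxa, pair_ids))
  for (i in seq_along(states)) {
    st <- states[[i]]
    detected <- unique(unlist(st$partition, use.names = FALSE))
    joined <- character()
    for (grp in st$partition) {
      if (length(grp) < 2L) next
      cmb <- utils::combn(grp, 2L)
      joined <- c(joined, apply(cmb, 2L, function(p) assoc_id(p[1L], p[2L])))
    }
    for (id in pair_ids) {
      uv <- pair_units[[id]]
      if (!all(uv %in% detected)) next
      mat[i, id] <- if (id %in% joined) "1" else "0"
    }
  }
  defs <- lapply(pair_ids, function(id) {
    uv <- pair_units[[id]]
    character_def(id, "association",
                  sprintf("%s/%s syntenic on one chromosome", uv[1L], uv[2L]),
                  uv)
  })
  list(defs = defs, states = mat)
}

#' Derive syntenic-disruption characters
#'
#' One binary character per reference unit whose homologous material is, in at
#' least one taxon, split across several target chromosomes or found in more
#' than one discontiguous block on a single chromosome. A taxon scores 1 when
#' the unit is disrupted, 0 when conserved in toto, ? when undetected.
#'
#' @inheritParams derive_association_characters
#' @param maps The [homology_map()]s the partitions came from (needed for the
#'   within-chromosome block counts), in the same taxon order.
#' @return Same shape as [derive_association_characters()].
#' @export
derive_disruption_characters <- function(states, maps, reference = NULL) {
  check_partitions(states, reference)
  taxa <- vapply(states, `[[`, "", "taxon")
  map_taxa <- vapply(maps, function(m) m$target_species, "")
  if (!identical(unname(map_taxa), unname(taxa))) {
    stop("maps and partitions must cover the same taxa in the same order")
  }
  disrupted_in <- function(st, map, unit) {
    n_groups <- sum(vapply(st$partition, function(g) unit %in% g, TRUE))
    if (n_groups > 1L) return(TRUE)
    any(map$signals$n_blocks[map$signals$probe == unit] > 1L)
  }
  units <- sort_labels(unique(unlist(lapply(states, function(st)
    unlist(st$partition, use.names = FALSE)))))
  keep <- vapply(units, function(u) {
    any(mapply(function(st, m) disrupted_in(st, m, u), states, maps))
  }, TRUE)
  units <- units[keep]
  ids <- vapply(units, disr_id, "")
  ord <- order(ids)
  units <- units[ord]; ids <- ids[ord]
  mat <- matrix("?", length(taxa), length(ids), dimnames = list(taxa, ids))
  for (i in seq_along(states)) {
    st <- states[[i]]
    detected <- unique(unlist(st$partition, use.names = FALSE))
    for (j in seq_along(units)) {
      if (!units[j] %in% detected) next
      mat[i, j] <- if (disrupted_in(st, maps[[i]], units[j])) "1" else "0"
    }
  }
  defs <- mapply(function(id, u) {
    character_def(id, "disruption",
                  sprintf("%s split into >= 2 segments", u), u)
  }, ids, units, SIMPLIFY = FALSE)
  list(defs = unname(defs), states = mat)
}

check_partitions <- function(states, reference) {
  refs <- unique(vapply(states, `[[`, "", "reference"))
  if (length(refs) > 1L) {
    stop("mixed probe species among partitions: ", paste(refs, collapse = ", "))
  }
  if (!is.null(reference)) {
    ok <- karyotype_labels(reference)
    units <- unique(unlist(lapply(states, function(st)
      unlist(st$partition, use.names = FALSE))))
    bad <- setdiff(units, ok)
    if (length(bad)) {
      stop("reference units absent from ", reference$species_code,
           " complement: ", paste(bad, collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Assemble the full character matrix
#'
#' Concatenates derived synteny characters with per-taxon structural
#' annotations (inversions, NOR position, heterochromatin states) into one
#' [character_matrix()]. Column order is deterministic: associations, then
#' disruptions, then structural characters, each lexicographic by id.
#' Structural states default to \code{?} for taxa without an annotation row.
#'
#' @param annotations data.frame with columns \code{taxon},
#'   \code{character_id}, \code{state} (in \{0,1,?\}) and optionally
#'   \code{note}; may be \code{NULL} or empty.
#' @param associations,disruptions Results of the two derivation functions
#'   (either may be \code{NULL}).
#' @param taxa Optional taxa order; defaults to the derived characters' taxa,
#'   extended by any annotation-only taxa.
#' @return A [character_matrix()].
#' @export
merge_structural_characters <- function(annotations = NULL,
                                        associations = NULL,
                                        disruptions = NULL,
                                        taxa = NULL) {
  derived_taxa <- unique(c(
    if (!is.null(associations)) rownames(associations$states),
    if (!is.null(disruptions)) rownames(disruptions$states)))
  if (is.null(taxa)) {
    taxa <- derived_taxa
    if (!is.null(annotations) && nrow(annotations)) {
      taxa <- unique(c(taxa, annotations$taxon))
    }
  }
  if (!is.null(annotations) && nrow(annotations)) {
    bad <- setdiff(annotations$taxon, taxa)
    if (length(bad)) stop("annotation taxa not in taxa list: ",
                          paste(unique(bad), collapse = ", "))
    badst <- !annotations$state %in% c("0", "1", "?")
    if (any(badst)) stop("annotation state outside {0,1,?} at row(s): ",
                         paste(which(badst), collapse = ", "))
    key <- paste(annotations$taxon, annotations$character_id, sep = "\r")
    if (anyDuplicated(key)) {
      stop("duplicate (taxon, character) annotation row(s): ",
           paste(which(duplicated(key)), collapse = ", "))
    }
  }
  expand <- function(block) {
    if (is.null(block)) return(NULL)
    m <- matrix("?", length(taxa), ncol(block$states),
                dimnames = list(taxa, colnames(block$states)))
    m[rownames(block$states), ] <- block$states
    list(defs = block$defs, states = m)
  }
  blocks <- Filter(Negate(is.null), list(expand(associations),
                                         expand(disruptions)))
  defs <- do.call(c, c(lapply(blocks, `[[`, "defs"), list(list())))
  states <- if (length(blocks)) {
    do.call(cbind, lapply(blocks, `[[`, "states"))
  } else {
    matrix(character(), length(taxa), 0L, dimnames = list(taxa, NULL))
  }
  if (!is.null(annotations) && nrow(annotations)) {
    ids <- sort(unique(annotations$character_id))
    sm <- matrix("?", length(taxa), length(ids), dimnames = list(taxa, ids))
    for (r in seq_len(nrow(annotations))) {
      sm[annotations$taxon[r], annotations$character_id[r]] <-
        annotations$state[r]
    }
    sdefs <- lapply(ids, function(id) {
      notes <- annotations$note[annotations$character_id == id]
      notes <- notes[!is.na(notes) & nzchar(notes)]
      character_def(id, "structural",
                    if (length(notes)) notes[1L] else id)
    })
    defs <- c(defs, sdefs)
    states <- cbind(states, sm)
  }
  character_matrix(taxa, defs, states)
}

#' Count parsimony-informative characters
#'
#' A binary character is parsimony-informative when at least two taxa score 1
#' and at least two score 0 (\code{?} ignored).
#'
#' @param matrix A [character_matrix()].
#' @return Non-negative integer.
#' @export
count_informative <- function(matrix) {
  stopifnot(inherits(matrix, "character_matrix"))
  if (!ncol(matrix$states)) return(0L)
  sum(colSums(matrix$states == "1") >= 2L &
        colSums(matrix$states == "0") >= 2L)
}

#' Minimum conceivable steps per character
#'
#' Number of distinct observed non-\code{?} states minus one; the per-character
#' floor used by the consistency index.
#'
#' @param matrix A [character_matrix()].
#' @return Integer vector, one entry per character.
#' @export
char_min_steps <- function(matrix) {
  stopifnot(inherits(matrix, "character_matrix"))
  apply(matrix$states, 2L, function(col) {
    length(unique(col[col != "?"])) - 1L
  })
}
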