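#' Construct a painting homology map
#'
#' The set of hybridization signals of one whole-chromosome probe panel
#' (reference species) on the metaphases of one target species. Each signal
#' records a probe (reference chromosome), a target chromosome, the number of
#' discontiguous hybridization blocks of that probe on that chromosome, and an
#' optional free-text region qualifier (painting has no base-pair resolution,
#' so qualifiers are never parsed).
#'
#' @param probe_species,target_species Three-letter species codes.
#' @param signals data.frame with columns \code{probe}, \code{target},
#'   \code{n_blocks} and optionally \code{region}.
#' @param note Optional free-text note attached to the map (e.g. a transcription
#'   discrepancy flag); surfaced by [segment_count_table()].
#' @param karyotypes Optional named list of [karyotype()] objects; when the
#'   probe or target species is present, signal labels are checked against the
#'   species' complement.
#' @param check_species Validate species codes against [known_species()].
#' @return An object of class \code{homology_map}.
#' @export
homology_map <- function(probe_species, target_species, signals, note = NULL,
                         karyotypes = NULL, check_species = TRUE) {
  if (check_species) {
    for (sp in c(probe_species, target_species)) {
      if (!sp %in% known_species()) stop("unknown species code: ", sp)
    }
  }
  signals <- as.data.frame(signals, stringsAsFactors = FALSE)
  if (!nrow(signals)) {
    signals <- data.frame(probe = character(), target = character(),
                          n_blocks = integer(), region = character(),
                          stringsAsFactors = FALSE)
  }
  if (!all(c("probe", "target", "n_blocks") %in% names(signals))) {
    stop("signals need columns probe, target, n_blocks")
  }
  if (is.null(signals$region)) signals$region <- NA_character_
  signals$n_blocks <- as.integer(signals$n_blocks)
  bad <- which(is.na(signals$n_blocks) | signals$n_blocks < 1L)
  if (length(bad)) {
    stop("n_blocks must be >= 1; offending row(s): ",
         paste(bad, collapse = ", "))
  }
  key <- paste(signals$probe, signals$target, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (probe, target) pair(s) at row(s): ",
         paste(which(duplicated(key)), collapse = ", "))
  }
  check_prefix <- function(labels, species, what) {
    pre <- sub("-.*$", "", labels)
    bad <- which(pre != species)
    if (length(bad)) {
      stop(what, " label(s) not of species ", species, " at row(s): ",
           paste(bad, collapse = ", "))
    }
  }
  if (nrow(signals)) {
    check_prefix(signals$probe, probe_species, "probe")
    check_prefix(signals$target, target_species, "target")
  }
  if (!is.null(karyotypes)) {
    check_complement <- function(labels, sp, what) {
      if (!sp %in% names(karyotypes)) return()
      ok <- karyotype_labels(karyotypes[[sp]])
      bad <- which(!labels %in% ok)
      if (length(bad)) {
        stop(what, " label(s) absent from ", sp, " complement at row(s): ",
             paste(bad, collapse = ", "), " (",
             paste(unique(labels[bad]), collapse = ", "), ")")
      }
    }
    check_complement(signals$probe, probe_species, "probe")
    check_complement(signals$target, target_species, "target")
  }
  rownames(signals) <- NULL
  structure(list(probe_species = probe_species,
                 target_species = target_species,
                 signals = signals,
                 note = note),
            class = "homology_map")
}

#' Read a homology map from TSV
#'
#' The file is tab-separated with header \code{probe, target, n_blocks,
#' region}. Lines starting with \code{#} are comments; the special comments
#' \code{# probe_species:}, \code{# target_species:} and \code{# note:} carry
#' map metadata. Row order is preserved.
#'
#' @param path Path to the TSV file.
#' @inheritParams homology_map
#' @return A validated [homology_map()].
#' @export
read_homology_map <- function(path, karyotypes = NULL, check_species = TRUE) {
  lines <- readLines(path, warn = FALSE)
  meta <- function(field) {
    rx <- paste0("^#\\s*", field, ":\\s*")
    hit <- grep(rx, lines, value = TRUE)
    if (length(hit)) trimws(sub(rx, "", hit[1L])) else NULL
  }
  probe_species <- meta("probe_species")
  target_species <- meta("target_species")
  if (is.null(probe_species) || is.null(target_species)) {
    stop("missing '# probe_species:' or '# target_species:' header in ", path)
  }
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(body)) stop("no header line in ", path)
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("probe", "target", "n_blocks") %in% names(df))) {
    stop("expected columns probe, target, n_blocks in ", path)
  }
  if (nrow(df)) {
    nb <- suppressWarnings(as.integer(df$n_blocks))
    bad <- which(is.na(nb) | nb < 1L)
    if (length(bad)) {
      stop("invalid n_blocks in ", path, " at data row(s): ",
           paste(bad, collapse = ", "))
    }
    df$n_blocks <- nb
  } else {
    df$n_blocks <- integer(0)
  }
  if (!is.null(df$region)) df$region[df$region == ""] <- NA_character_
  homology_map(probe_species, target_species, df, note = meta("note"),
               karyotypes = karyotypes, check_species = check_species)
}

#' Write a homology map to TSV
#'
#' Inverse of [read_homology_map()]: metadata comments followed by the signal
#' table. Writing then reading reproduces an identical object.
#'
#' @param map A [homology_map()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_homology_map <- function(map, path) {
  stopifnot(inherits(map, "homology_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("# probe_species:", map$probe_species),
               paste("# target_species:", map$target_species)), con)
  if (!is.null(map$note)) writeLines(paste("# note:", map$note), con)
  sig <- map$signals
  sig$region[is.na(sig$region)] <- ""
  utils::write.table(sig, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count homologous segments
#'
#' Total number of hybridization blocks in a map: the sum of \code{n_blocks}
#' over all signals. Discontiguous blocks of one probe on one chromosome count
#' separately.
#'
#' @param map A [homology_map()].
#' @return Non-negative integer.
#' @export
count_segments <- function(map) {
  stopifnot(inherits(map, "homology_map"))
  sum(map$signals$n_blocks)
}

#' Synteny partition of a target karyotype
#'
#' Groups the detected reference units (probes) by target chromosome: one
#' group per target chromosome bearing at least one signal, each group being
#' the set of reference chromosomes painting it. This is the raw material for
#' segmental-association and syntenic-disruption characters.
#'
#' @param map A [homology_map()].
#' @return An object of class \code{synteny_state}: list with \code{taxon},
#'   \code{reference} (probe species) and \code{partition} (named list of
#'   probe-label sets, named by target chromosome, in natural label order).
#' @export
synteny_partition <- function(map) {
  stopifnot(inherits(map, "homology_map"))
  sig <- map$signals
  targets <- unique(sig$target)
  targets <- sort_labels(targets)
  partition <- lapply(targets, function(tg) {
    sort_labels(unique(sig$probe[sig$target == tg]))
  })
  names(partition) <- targets
  structure(list(taxon = map$target_species,
                 reference = map$probe_species,
                 partition = partition),
            class = "synteny_state")
}

#' @export
print.homology_map <- function(x, ...) {
  cat(sprintf("Homology map: %s probes on %s (%d signals, %d segments)\n",
              x$probe_species, x$target_species, nrow(x$signals),
              count_segments(x)))
  if (!is.null(x$note)) cat("Note:", x$note, "\n")
  invisible(x)
}

#' @export
print.synteny_state <- function(x, ...) {
  cat(sprintf("Synteny partition of %s over %s units:\n", x$taxon, x$reference))
  for (tg in names(x$partition)) {
    cat(" ", tg, "<-", paste(x$partition[[tg]], collapse = " + "), "\n")
  }
  invisible(x)
}
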