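#' Write a character matrix as NEXUS
#'
#' Emits a minimal \code{DATA} block (\code{FORMAT DATATYPE=STANDARD
#' SYMBOLS="01" MISSING=?}) in the dialect accepted by common parsimony
#' programs. Character ids are preserved in a bracketed comment so that
#' [read_nexus_matrix()] can restore them; output is deterministic, so
#' read -> write -> read round trips are byte-stable.
#'
#' @param matrix A [character_matrix()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_nexus_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "character_matrix"))
  ids <- colnames(matrix$states)
  pad <- max(nchar(matrix$taxa)) + 2L
  rows <- vapply(seq_along(matrix$taxa), function(i) {
    paste0("    ", formatC(matrix$taxa[i], width = -pad),
           paste(matrix$states[i, ], collapse = ""))
  }, "")
  lines <- c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(matrix$taxa),
            length(matrix$defs)),
    "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=? GAP=-;",
    sprintf("  [chromoclad-characters: %s]", paste(ids, collapse = " ")),
    "  MATRIX",
    rows,
    "  ;",
    "END;")
  writeLines(lines, path)
  invisible(path)
}

#' Read a character matrix from NEXUS
#'
#' Parses a standard-datatype \code{DATA} block via \code{ape::read.nexus.data}.
#' Character ids are restored from the \code{[chromoclad-characters: ...]}
#' comment when present (files written by [write_nexus_matrix()]); otherwise
#' columns are named \code{char001}, \code{char002}, ... Character kinds are
#' inferred from the id prefix (\code{A.}, \code{D.}, anything else
#' structural).
#'
#' @param path Path to a NEXUS file.
#' @return A [character_matrix()].
#' @export
read_nexus_matrix <- function(path) {
  dat <- ape::read.nexus.data(path)
  taxa <- names(dat)
  states <- do.call(rbind, lapply(dat, function(x) toupper(x)))
  states[states == "-"] <- "?"
  nchar_ <- ncol(states)
  lines <- readLines(path, warn = FALSE)
  hit <- grep("\\[chromoclad-characters:", lines, value = TRUE)
  ids <- if (length(hit)) {
    txt <- sub(".*\\[chromoclad-characters:\\s*", "", hit[1L])
    txt <- sub("\\].*$", "", txt)
    strsplit(trimws(txt), "\\s+")[[1L]]
  } else {
    sprintf("char%03d", seq_len(nchar_))
  }
  if (length(ids) != nchar_) {
    stop("character-id comment lists ", length(ids), " ids but matrix has ",
         nchar_, " characters")
  }
  defs <- lapply(ids, function(id) {
    if (startsWith(id, "A.")) {
      units <- strsplit(sub("^A\\.", "", id), "+", fixed = TRUE)[[1L]]
      if (length(units) == 2L) {
        return(character_def(id, "association",
                             sprintf("%s/%s syntenic on one chromosome",
                                     units[1L], units[2L]), units))
      }
    }
    if (startsWith(id, "D.")) {
      u <- sub("^D\\.", "", id)
      return(character_def(id, "disruption",
                           sprintf("%s split into >= 2 segments", u), u))
    }
    character_def(id, "structural", id)
  })
  character_matrix(taxa, defs, states)
}

#' Write a character matrix as TSV
#'
#' Two plain-text files: the states grid (taxa rows, character-id columns)
#' and a character-definition table (\code{id}, \code{kind},
#' \code{description}, \code{reference_units}).
#'
#' @param matrix A [character_matrix()].
#' @param path States output path.
#' @param defs_path Definitions output path; default \code{<path>.chars.tsv}.
#' @return \code{path}, invisibly.
#' @export
write_character_matrix <- function(matrix, path,
                                   defs_path = paste0(path, ".chars.tsv")) {
  stopifnot(inherits(matrix, "character_matrix"))
  df <- data.frame(taxon = matrix$taxa, matrix$states,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(defs_table(matrix$defs), defs_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a character matrix from TSV
#'
#' @param path States TSV (first column \code{taxon}).
#' @param defs_path Optional definitions TSV written by
#'   [write_character_matrix()]; when absent, kinds are inferred from id
#'   prefixes as in [read_nexus_matrix()].
#' @return A [character_matrix()].
#' @export
read_character_matrix <- function(path,
                                  defs_path = paste0(path, ".chars.tsv")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (names(df)[1L] != "taxon") stop("first column must be 'taxon'")
  taxa <- df$taxon
  states <- as.matrix(df[, -1L, drop = FALSE])
  ids <- colnames(states)
  defs <- NULL
  if (!is.null(defs_path) && file.exists(defs_path)) {
    dt <- utils::read.delim(defs_path, stringsAsFactors = FALSE,
                            colClasses = "character")
    dt <- dt[match(ids, dt$id), , drop = FALSE]
    if (anyNA(dt$id)) stop("definitions file does not cover all characters")
    defs <- lapply(seq_len(nrow(dt)), function(i) {
      units <- strsplit(dt$reference_units[i], ",", fixed = TRUE)[[1L]]
      units <- units[nzchar(units)]
      character_def(dt$id[i], dt$kind[i], dt$description[i], units)
    })
  } else {
    defs <- lapply(ids, function(id) {
      if (startsWith(id, "A.")) {
        units <- strsplit(sub("^A\\.", "", id), "+", fixed = TRUE)[[1L]]
        if (length(units) == 2L) {
          return(character_def(id, "association", id, units))
        }
      }
      if (startsWith(id, "D.")) {
        return(character_def(id, "disruption", id, sub("^D\\.", "", id)))
      }
      character_def(id, "structural", id)
    })
  }
  character_matrix(taxa, defs, states)
}
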