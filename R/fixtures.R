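#' Built-in phyllostomid karyotypes
#'
#' Karyotype configs for the painted taxa shipped with the package: TSA
#' (\emph{Tonatia saurophila}), LSI (\emph{Lophostoma silvicola}), PDI
#' (\emph{Phyllostomus discolor}), PHA (\emph{P. hastatus}, the reference
#' complement) and CBR (\emph{Carollia brevicauda}, second probe panel).
#'
#' @return Named list of [karyotype()] objects.
#' @export
phyllostomini_karyotypes <- function() {
  codes <- c("TSA", "LSI", "PDI", "PHA", "CBR")
  ks <- lapply(codes, function(sp) {
    read_karyotype(system.file("extdata",
                               paste0("karyotype_", sp, ".yaml"),
                               package = "chromoclad", mustWork = TRUE))
  })
  names(ks) <- codes
  ks
}

#' Built-in painting homology maps
#'
#' The cross-species painting maps shipped with the package, transcribed from
#' the published per-probe enumerations: PHA and CBR probe panels on TSA and
#' LSI, and the two-probe PHA panel on PDI. Signal labels are validated
#' against the built-in karyotypes. Maps carrying transcription caveats (the
#' LSI x CBR total, ambiguous doubled-block placements) have a \code{note}
#' set; see [segment_count_table()].
#'
#' @return Named list of [homology_map()] objects
#'   (\code{TSAxPHA}, \code{TSAxCBR}, \code{LSIxPHA}, \code{LSIxCBR},
#'   \code{PDIxPHA}).
#' @export
phyllostomini_maps <- function() {
  ks <- phyllostomini_karyotypes()
  files <- c(TSAxPHA = "homology_map_TSA_PHA.tsv",
             TSAxCBR = "homology_map_TSA_CBR.tsv",
             LSIxPHA = "homology_map_LSI_PHA.tsv",
             LSIxCBR = "homology_map_LSI_CBR.tsv",
             PDIxPHA = "homology_map_PDI_PHA.tsv")
  maps <- lapply(files, function(f) {
    read_homology_map(system.file("extdata", f, package = "chromoclad",
                                  mustWork = TRUE),
                      karyotypes = ks)
  })
  names(maps) <- names(files)
  maps
}

#' Built-in structural character annotations
#'
#' Per-taxon structural annotations (pericentric inversion of pair 15,
#' constitutive-heterochromatin blocks, NOR position) for the painted taxa,
#' coded as binary states with \code{?} for taxa where the trait cannot be
#' scored.
#'
#' @return data.frame with columns \code{taxon}, \code{character_id},
#'   \code{state}, \code{note}.
#' @export
phyllostomini_annotations <- function() {
  path <- system.file("extdata", "structural_annotations.tsv",
                      package = "chromoclad", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}

#' Path to a user-supplied published character matrix
#'
#' The original cladistic analysis distributed its 7 x 55 basic data matrix
#' only as a formatted document, not as machine-readable data. Users who
#' transcribe it can drop a NEXUS file at
#' \code{inst/extdata/published_character_matrix.nex} (or pass any path to the
#' readers directly); this helper returns that path, or \code{NA} when the
#' file is absent.
#'
#' @return Path or \code{NA_character_}.
#' @export
published_matrix_path <- function() {
  p <- system.file("extdata", "published_character_matrix.nex",
                   package = "chromoclad")
  if (nzchar(p)) p else NA_character_
}
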