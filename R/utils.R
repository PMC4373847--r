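#' @keywords internal
"_PACKAGE"

# Default species registry: the eight painted phyllostomid taxa handled by the
# shipped fixtures. Extra codes can be registered through
# options(chromoclad.species = c(...)).
.default_species <- c("TSA", "LSI", "PDI", "PHA", "CBR", "DEC", "DRO", "DYO")

#' Known species codes
#'
#' The closed set of three-letter species codes accepted by the validators:
#' the eight built-in phyllostomid codes plus any registered through
#' \code{options(chromoclad.species = ...)}.
#'
#' @return Character vector of species codes.
#' @export
known_species <- function() {
  unique(c(.default_species, getOption("chromoclad.species", character())))
}

# Natural ordering for chromosome labels such as "PHA-13": species prefix
# first, then numeric suffix numerically, non-numeric suffixes (X, Y2) last.
label_order <- function(labels) {
  parts <- strsplit(labels, "-", fixed = TRUE)
  prefix <- vapply(parts, `[`, "", 1L)
  suffix <- vapply(parts, function(p) paste(p[-1L], collapse = "-"), "")
  num <- suppressWarnings(as.numeric(suffix))
  order(prefix, is.na(num), num, suffix)
}

sort_labels <- function(labels) labels[label_order(labels)]

# Bitmask helpers for taxon subsets (n <= 30).
mask_of <- function(idx) sum(bitwShiftL(1L, idx - 1L))

mask_members <- function(mask, taxa) {
  taxa[bitwAnd(bitwShiftR(mask, seq_along(taxa) - 1L), 1L) == 1L]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
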