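.morphologies <- c("metacentric", "submetacentric", "acrocentric",
                   "one_armed", "bi_armed", "unknown")

# Arms contributed by one chromosome under the fundamental-number convention:
# 2 for any bi-armed form, 1 for one-armed, NA when unknown.
chromosome_arms <- function(morphology) {
  ifelse(morphology %in% c("metacentric", "submetacentric", "bi_armed"), 2L,
         ifelse(morphology %in% c("acrocentric", "one_armed"), 1L, NA_integer_))
}

#' Construct a karyotype
#'
#' A species' chromosomal complement: diploid number (2n), fundamental number
#' (FN, autosomal arms counted over both homologs), one row per autosome pair
#' and the sex chromosomes. Multiple sex-chromosome systems (e.g. XY1Y2, as in
#' \emph{Carollia}) are supported with three sex chromosomes, in which case 2n
#' refers to the complement carrying all listed sex chromosomes.
#'
#' Structural problems (bad morphology strings, duplicate labels) raise errors;
#' arithmetic inconsistencies between 2n/FN and the chromosome list do not --
#' they are reported by [validate_karyotype()].
#'
#' @param species_code Three-letter species code (see [known_species()]).
#' @param diploid_number 2n, a positive integer.
#' @param fundamental_number FN, a positive integer.
#' @param autosome_pairs data.frame with columns \code{label}, \code{morphology}
#'   (one row per autosome pair).
#' @param sex_system data.frame with the same columns, 2 or 3 rows.
#' @param check_species Validate the species code against [known_species()].
#' @return An object of class \code{karyotype}.
#' @export
karyotype <- function(species_code, diploid_number, fundamental_number,
                      autosome_pairs, sex_system, check_species = TRUE) {
  stopifnot(is.character(species_code), length(species_code) == 1L)
  if (check_species && !species_code %in% known_species()) {
    stop("unknown species code: ", species_code,
         " (register it via options(chromoclad.species = ...))")
  }
  autosome_pairs <- as.data.frame(autosome_pairs, stringsAsFactors = FALSE)
  sex_system <- as.data.frame(sex_system, stringsAsFactors = FALSE)
  for (df in list(autosome_pairs, sex_system)) {
    if (!all(c("label", "morphology") %in% names(df))) {
      stop("chromosome tables need 'label' and 'morphology' columns")
    }
    bad <- setdiff(df$morphology, .morphologies)
    if (length(bad)) stop("unknown morphology: ", paste(bad, collapse = ", "))
  }
  if (!nrow(sex_system) %in% c(2L, 3L)) {
    stop("sex_system must list 2 or 3 chromosomes")
  }
  labels <- c(autosome_pairs$label, sex_system$label)
  if (anyDuplicated(labels)) {
    stop("duplicate chromosome labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  structure(
    list(species_code = species_code,
         diploid_number = as.integer(diploid_number),
         fundamental_number = as.integer(fundamental_number),
         autosome_pairs = autosome_pairs,
         sex_system = sex_system),
    class = "karyotype")
}

#' Validate karyotype arithmetic
#'
#' Checks the two classical identities: 2n = 2 x (autosome pairs) + (number of
#' sex chromosomes), and FN = sum of autosomal arms over both homologs (2 arms
#' per bi-armed, 1 per one-armed pair member; sex chromosomes excluded).
#' Violations are returned as report rows, never raised as errors.
#'
#' @param k A [karyotype()].
#' @return data.frame with columns \code{rule} and \code{message}; zero rows
#'   when both identities hold.
#' @export
validate_karyotype <- function(k) {
  stopifnot(inherits(k, "karyotype"))
  report <- list()
  expected_2n <- 2L * nrow(k$autosome_pairs) + nrow(k$sex_system)
  if (k$diploid_number != expected_2n) {
    report[[length(report) + 1L]] <- data.frame(
      rule = "2n mismatch",
      message = sprintf(
        "declared 2n = %d but complement implies %d (%d autosome pairs + %d sex chromosomes)",
        k$diploid_number, expected_2n, nrow(k$autosome_pairs), nrow(k$sex_system)))
  }
  arms <- chromosome_arms(k$autosome_pairs$morphology)
  if (anyNA(arms)) {
    report[[length(report) + 1L]] <- data.frame(
      rule = "FN unverifiable",
      message = paste("autosomes with unknown morphology:",
                      paste(k$autosome_pairs$label[is.na(arms)], collapse = ", ")))
  } else {
    expected_fn <- 2L * sum(arms)
    if (k$fundamental_number != expected_fn) {
      report[[length(report) + 1L]] <- data.frame(
        rule = "FN mismatch",
        message = sprintf("declared FN = %d but autosomal arms sum to %d",
                          k$fundamental_number, expected_fn))
    }
  }
  if (length(report)) do.call(rbind, report) else
    data.frame(rule = character(), message = character())
}

#' All chromosome labels of a karyotype
#' @param k A [karyotype()].
#' @return Character vector (autosomes then sex chromosomes).
#' @export
karyotype_labels <- function(k) {
  c(k$autosome_pairs$label, k$sex_system$label)
}

#' Read a karyotype from a YAML config
#'
#' Expected keys: \code{species_code}, \code{diploid_number},
#' \code{fundamental_number}, \code{autosome_pairs} and \code{sex_system}
#' (lists of \code{label}/\code{morphology} maps).
#'
#' @param path Path to a YAML file.
#' @inheritParams karyotype
#' @return A [karyotype()].
#' @export
read_karyotype <- function(path, check_species = TRUE) {
  y <- yaml::read_yaml(path)
  need <- c("species_code", "diploid_number", "fundamental_number",
            "autosome_pairs", "sex_system")
  missing <- setdiff(need, names(y))
  if (length(missing)) {
    stop("karyotype config ", path, " lacks fields: ",
         paste(missing, collapse = ", "))
  }
  to_df <- function(lst) {
    data.frame(label = vapply(lst, `[[`, "", "label"),
               morphology = vapply(lst, `[[`, "", "morphology"),
               stringsAsFactors = FALSE)
  }
  karyotype(y$species_code, y$diploid_number, y$fundamental_number,
            to_df(y$autosome_pairs), to_df(y$sex_system),
            check_species = check_species)
}

#' @export
print.karyotype <- function(x, ...) {
  cat(sprintf("Karyotype %s: 2n = %d, FN = %d (%d autosome pairs, %d sex chromosomes)\n",
              x$species_code, x$diploid_number, x$fundamental_number,
              nrow(x$autosome_pairs), nrow(x$sex_system)))
  v <- validate_karyotype(x)
  if (nrow(v)) {
    cat("Violations:\n")
    for (i in seq_len(nrow(v))) cat("  -", v$rule[i], ":", v$message[i], "\n")
  } else {
    cat("2n and FN arithmetic consistent.\n")
  }
  invisible(x)
}
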