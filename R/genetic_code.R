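#' Genetic-code tables with synonymous-family structure
#'
#' Builds a genetic-code object from the packaged NCBI translation-table
#' definitions. Table 5 (invertebrate mitochondrial: ATA = Met, TGA = Trp,
#' AGA/AGG = Ser, stops TAA/TAG) is the default used throughout the package;
#' table 1 (standard nuclear code) is included for generality. The object
#' carries the codon-to-amino-acid map, the stop and start codon sets, and the
#' partition of sense codons into synonymous families with their degeneracies,
#' which is the structure every downstream metric (RSCU, GC3s, ENC) consumes.
#'
#' Codons are represented internally as uppercase DNA triplets (T, not U);
#' input in the RNA alphabet is normalized on entry everywhere in the package.
#'
#' @param table_id NCBI translation-table number; 5 (invertebrate
#'   mitochondrial, the default) and 1 (standard) are shipped. The registry is
#'   file-based, so additional tables can be added as data without code
#'   changes.
#' @return An object of class \code{"genetic_code"}: a list with elements
#'   \code{table_id}, \code{codon_to_aa} (named character of length 64),
#'   \code{stop_codons}, \code{start_codons}, \code{sense_codons},
#'   \code{families} (list amino acid -> codons) and \code{degeneracy}
#'   (named integer, family sizes).
#' @examples
#' code5 <- genetic_code(5)
#' code5$codon_to_aa[["ATA"]]   # "M" under the invertebrate mitochondrial code
#' code5$degeneracy[["S"]]      # Ser is 8-fold (TCN + AGN)
#' @export
genetic_code <- function(table_id = 5L) {
  table_id <- as.integer(table_id)
  if (length(table_id) != 1L || is.na(table_id)) {
    stop("'table_id' must be a single integer")
  }
  path <- system.file("extdata", "genetic_codes",
                      paste0("table", table_id, ".tsv"),
                      package = "mitocodon")
  if (!nzchar(path)) {
    stop("unsupported genetic code table: ", table_id,
         " (shipped tables: 1, 5)")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "integer"))
  if (nrow(tab) != 64L || anyDuplicated(tab$codon)) {
    stop("corrupt genetic-code definition for table ", table_id)
  }
  codon_to_aa <- stats::setNames(tab$aa, tab$codon)
  is_sense <- tab$aa != "*"
  families <- split(tab$codon[is_sense], tab$aa[is_sense])
  structure(list(
    table_id     = table_id,
    codon_to_aa  = codon_to_aa,
    stop_codons  = tab$codon[!is_sense],
    start_codons = tab$codon[tab$start == 1L],
    sense_codons = tab$codon[is_sense],
    families     = families,
    degeneracy   = vapply(families, length, integer(1))
  ), class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  census <- table(x$degeneracy)
  cat("Genetic code: NCBI translation table", x$table_id, "\n")
  cat(" sense codons:", length(x$sense_codons),
      " stop codons:", paste(x$stop_codons, collapse = ", "), "\n")
  cat(" degeneracy census:",
      paste(sprintf("%s-fold x%d", names(census), as.integer(census)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Synonymous family of a codon
#'
#' Looks up the synonymous family (amino acid, member codons, degeneracy) a
#' codon belongs to. Stop codons return a distinguished STOP marker rather
#' than a family.
#'
#' @param code a \code{\link{genetic_code}} object.
#' @param codon a single codon string (DNA or RNA alphabet, any case).
#' @return A list of class \code{"synonymous_family"} with elements
#'   \code{amino_acid}, \code{codons}, \code{degeneracy} and \code{stop}
#'   (logical). For stop codons \code{amino_acid} is \code{"*"},
#'   \code{codons} are the code's stop codons and \code{degeneracy} is
#'   \code{NA}.
#' @examples
#' codon_family(genetic_code(5), "TCA")  # Ser, degeneracy 8
#' @export
codon_family <- function(code, codon) {
  stopifnot(inherits(code, "genetic_code"))
  codon <- normalize_codon(codon)
  aa <- code$codon_to_aa[[codon]]
  if (aa == "*") {
    fam <- list(amino_acid = "*", codons = code$stop_codons,
                degeneracy = NA_integer_, stop = TRUE)
  } else {
    fam <- list(amino_acid = aa, codons = code$families[[aa]],
                degeneracy = code$degeneracy[[aa]], stop = FALSE)
  }
  structure(fam, class = "synonymous_family")
}

#' @export
print.synonymous_family <- function(x, ...) {
  if (x$stop) {
    cat("STOP (", paste(x$codons, collapse = ", "), ")\n", sep = "")
  } else {
    cat(x$amino_acid, " (", x$degeneracy, "-fold): ",
        paste(x$codons, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# Uppercase, U->T, and reject anything that is not an unambiguous triplet.
normalize_codon <- function(codon) {
  if (length(codon) != 1L || is.na(codon)) stop("invalid codon: not a string")
  codon <- chartr("u", "T", chartr("U", "T", toupper(codon)))
  if (!grepl("^[ACGT]{3}$", codon)) {
    stop("invalid codon: '", codon, "' is not an unambiguous DNA triplet")
  }
  codon
}
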