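#' Genetic code with synonymous-family structure
#'
#' Builds the codon-to-amino-acid map for an NCBI translation table together
#' with the derived structure the codon-usage machinery needs: the synonymous
#' family size of every amino acid and the degenerate-codon universe (sense
#' codons belonging to amino acids with two or more synonymous codons).
#'
#' Under the bacterial/archaeal/plastid code (table 11, the default) the
#' degenerate universe contains 59 codons: the 61 sense codons minus ATG (Met)
#' and TGG (Trp), which have no synonymous alternative.
#'
#' @param table_id NCBI translation table identifier, as a character string or
#'   integer accepted by [Biostrings::getGeneticCode()]. Default `"11"`.
#' @return An object of class `genetic_code`: a list with elements
#'   `table_id`, `codon_to_aa` (named character over the 64 codons, `"*"` for
#'   stops), `family_size` (named integer per amino acid), `degenerate_codons`
#'   (character vector, the universe D), `stop_codons`, and `codons` (all 64).
#' @examples
#' code <- genetic_code()
#' length(code$degenerate_codons)  # 59
#' @export
genetic_code <- function(table_id = "11") {
  map <- Biostrings::getGeneticCode(as.character(table_id))
  codons <- names(map)
  aa <- unname(map)
  fam <- table(aa[aa != "*"])
  family_size <- stats::setNames(as.integer(fam), names(fam))
  degenerate <- codons[aa != "*" & family_size[aa] >= 2]
  structure(list(
    table_id = as.character(table_id),
    codon_to_aa = map,
    family_size = family_size,
    degenerate_codons = degenerate,
    stop_codons = codons[aa == "*"],
    codons = codons
  ), class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code, translation table ", x$table_id, ": ",
      sum(x$codon_to_aa != "*"), " sense codons, ",
      length(x$degenerate_codons), " degenerate, ",
      length(x$stop_codons), " stops\n", sep = "")
  invisible(x)
}

#' Synonymous codons of one amino acid
#'
#' @param code A [genetic_code()] object.
#' @param aa Single-letter amino-acid symbol.
#' @return Character vector of codons translating to `aa`.
#' @export
synonymous_codons <- function(code, aa) {
  code$codons[code$codon_to_aa == aa]
}
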