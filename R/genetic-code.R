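#' Genetic code model
#'
#' Builds the genetic-code object all other operations consume: the
#' codon-to-amino-acid map, the stop-codon set, the ordered list of sense
#' codons, and the synonym families (the set of codons encoding each amino
#' acid). Under the standard code (NCBI translation table 1) there are 61
#' sense codons, 3 stop codons, and two single-codon families (Met: ATG,
#' Trp: TGG).
#'
#' Codons use the DNA alphabet (T, not U). Sense codons and the codons
#' within each family are kept in alphabetical order; this is the fixed
#' codon order used by all tabular output.
#'
#' @param table_id NCBI genetic-code table identifier (default `"1"`, the
#'   standard code). Passed to [Biostrings::getGeneticCode()], so any table
#'   Biostrings knows is accepted; all defaults in this package assume the
#'   standard code.
#' @return An object of class `genetic_code`: a list with elements
#'   `codon_to_aa` (named character, 64 codons), `stop_codons`,
#'   `sense_codons` (alphabetical), `families` (named list, amino acid ->
#'   codons), `amino_acids`, and `table_id`.
#' @examples
#' code <- genetic_code()
#' length(code$sense_codons)   # 61
#' code$families[["W"]]        # "TGG"
#' @export
genetic_code <- function(table_id = "1") {
  raw <- Biostrings::getGeneticCode(as.character(table_id))
  raw <- raw[order(names(raw))]
  stop_codons <- names(raw)[raw == "*"]
  sense <- names(raw)[raw != "*"]
  aa <- raw[sense]
  families <- split(sense, aa)
  families <- lapply(families, sort)
  structure(list(
    codon_to_aa = raw,
    stop_codons = stop_codons,
    sense_codons = sense,
    families = families,
    amino_acids = sort(names(families)),
    table_id = as.character(table_id)
  ), class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("<genetic_code> NCBI table ", x$table_id, ": ",
      length(x$sense_codons), " sense codons, ",
      length(x$stop_codons), " stop codons (",
      paste(x$stop_codons, collapse = ", "), "), ",
      length(x$families), " synonym families\n", sep = "")
  invisible(x)
}

# amino acid of a sense codon (vectorised); stops return "*"
codon_aa <- function(codons, code) {
  unname(code$codon_to_aa[codons])
}

# synonym family of a sense codon
codon_family <- function(codon, code) {
  code$families[[code$codon_to_aa[[codon]]]]
}

is_stop_codon <- function(codons, code) {
  codons %in% code$stop_codons
}
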