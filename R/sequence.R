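#' Create a coding-sequence record
#'
#' A light container for one DNA sequence. On construction the sequence is
#' normalized: lowercase is upcased and RNA-style `U` is transliterated to
#' `T` (with a message, so silent dialect conversion never goes unnoticed).
#' By default any symbol outside `A`, `C`, `G`, `T` is an error; pass
#' `strict = FALSE` to keep ambiguous symbols (e.g. `N`) so that
#' [validate_cds()] can report their positions instead.
#'
#' @param id record identifier (free text).
#' @param seq DNA sequence string.
#' @param strict error on symbols outside `ACGT` (default `TRUE`).
#' @return An object of class `sequence_record` with elements `id` and `seq`.
#' @examples
#' rec <- sequence_record("mini", "atgTGGtaa")
#' rec$seq  # "ATGTGGTAA"
#' @export
sequence_record <- function(id, seq, strict = TRUE) {
  if (!is.character(id) || length(id) != 1L) cs_stop("id must be a single string")
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    cs_stop("seq must be a non-empty string")
  seq <- toupper(seq)
  n_u <- lengths(regmatches(seq, gregexpr("U", seq, fixed = TRUE)))
  if (n_u > 0L) {
    seq <- gsub("U", "T", seq, fixed = TRUE)
    message("sequence_record('", id, "'): transliterated ", n_u, " U -> T")
  }
  if (strict && grepl("[^ACGT]", seq))
    cs_stop("record '", id, "' contains symbols outside {A,C,G,T}; ",
            "use strict = FALSE to keep them for validation")
  structure(list(id = id, seq = seq), class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  preview <- if (nchar(x$seq) > 60L) paste0(substr(x$seq, 1L, 57L), "...") else x$seq
  cat("<sequence_record> ", x$id, " (", nchar(x$seq), " nt)\n  ", preview, "\n", sep = "")
  invisible(x)
}

#' @export
as.character.sequence_record <- function(x, ...) x$seq

#' Read coding sequences from a FASTA file
#'
#' Multi-record FASTA reader. Sequences are normalized as in
#' [sequence_record()] (upcased, `U` transliterated to `T`).
#'
#' @param path FASTA file.
#' @param strict error on ambiguous symbols (default `TRUE`); with
#'   `strict = FALSE` offending records are kept and can be triaged with
#'   [validate_cds()] or dropped by [count_codons()]'s skip-invalid mode.
#' @return List of `sequence_record`.
#' @export
read_fasta <- function(path, strict = TRUE) {
  if (!file.exists(path)) cs_stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) cs_stop("FASTA file has no records: ", path)
  ids <- sub("\\s.*$", "", names(set))
  mapply(function(id, s) sequence_record(id, s, strict = strict),
         ids, as.character(set), SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write coding sequences to a FASTA file
#'
#' Writes records wrapped at 60 columns. Output is byte-deterministic for a
#' given list of records.
#'
#' @param records a `sequence_record` or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "sequence_record")) records <- list(records)
  set <- Biostrings::BStringSet(vapply(records, `[[`, "", "seq"))
  names(set) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Validate a coding sequence
#'
#' Checks the properties a CDS needs before codon counting, translation or
#' recoding: reading-frame length, start and terminal-stop presence,
#' internal stop codons, and ambiguous symbols. Problems are reported, not
#' raised. The frame always starts at position 0; no frame inference.
#'
#' A CDS is *strictly valid* iff its length is a multiple of three, it has
#' no internal stop codon, and no ambiguous symbol. A start codon and a
#' terminal stop are reported but not required.
#'
#' @param record a [sequence_record()].
#' @param code a [genetic_code()].
#' @return An object of class `cds_validation_report`: list with
#'   `length_multiple_of_three`, `has_start`, `has_terminal_stop`,
#'   `internal_stop_positions` (0-based codon indices),
#'   `ambiguous_positions` (0-based nucleotide offsets) and `strictly_valid`.
#' @examples
#' validate_cds(sequence_record("x", "ATGTGGTAA"))$strictly_valid  # TRUE
#' @export
validate_cds <- function(record, code = genetic_code()) {
  if (!inherits(record, "sequence_record")) cs_stop("record must be a sequence_record")
  seq <- record$seq
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  ambiguous <- which(!chars %in% c("A", "C", "G", "T")) - 1L
  mult3 <- nchar(seq) %% 3L == 0L
  codons <- split_codons(seq)
  n_cod <- length(codons)
  clean <- !grepl("[^ACGT]", codons)
  stops <- logical(n_cod)
  stops[clean] <- is_stop_codon(codons[clean], code)
  has_terminal_stop <- mult3 && n_cod > 0L && stops[n_cod]
  internal_idx <- which(stops)
  if (mult3 && n_cod > 0L) internal_idx <- setdiff(internal_idx, n_cod)
  report <- list(
    length_multiple_of_three = mult3,
    has_start = n_cod > 0L && clean[1L] && codons[1L] == "ATG",
    has_terminal_stop = has_terminal_stop,
    internal_stop_positions = internal_idx - 1L,
    ambiguous_positions = ambiguous
  )
  report$strictly_valid <- mult3 && length(report$internal_stop_positions) == 0L &&
    length(ambiguous) == 0L
  structure(report, class = "cds_validation_report")
}

#' @export
print.cds_validation_report <- function(x, ...) {
  cat("<cds_validation_report> strictly_valid=", x$strictly_valid,
      " mult3=", x$length_multiple_of_three,
      " start=", x$has_start,
      " terminal_stop=", x$has_terminal_stop,
      " internal_stops=", length(x$internal_stop_positions),
      " ambiguous=", length(x$ambiguous_positions), "\n", sep = "")
  invisible(x)
}

#' Translate a coding sequence
#'
#' Translates a strictly valid CDS to its amino-acid sequence; a terminal
#' stop, if present, is dropped from the protein. Translation is the
#' identity that synonymous recoding must preserve, so errors name the
#' offending codon index rather than guessing.
#'
#' @inheritParams validate_cds
#' @return Amino-acid string, one symbol per sense codon.
#' @examples
#' translate_cds(sequence_record("x", "ATGTGG"))  # "MW"
#' @export
translate_cds <- function(record, code = genetic_code()) {
  rep_ <- validate_cds(record, code)
  if (length(rep_$ambiguous_positions) > 0L)
    cs_stop("record '", record$id, "': ambiguous symbol at nucleotide offset ",
            rep_$ambiguous_positions[1L])
  if (!rep_$length_multiple_of_three)
    cs_stop("record '", record$id, "': length ", nchar(record$seq),
            " is not a multiple of three")
  if (length(rep_$internal_stop_positions) > 0L)
    cs_stop("record '", record$id, "': internal stop codon at codon index ",
            rep_$internal_stop_positions[1L])
  codons <- split_codons(record$seq)
  if (rep_$has_terminal_stop) codons <- codons[-length(codons)]
  paste(code$codon_to_aa[codons], collapse = "")
}
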