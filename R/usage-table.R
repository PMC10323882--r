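#' Construct a codon-usage table
#'
#' The central container: per-codon counts and/or the two frequency
#' normalizations used throughout the package.
#'
#' Two normalizations are carried side by side because "frequency of use"
#' is ambiguous in the literature:
#' \describe{
#'   \item{`rel_freq_aa`}{per-amino-acid relative frequency: a codon's count
#'     divided by its synonym family's total. Sums to 1 within each family.}
#'   \item{`global_freq`}{global codon frequency: a codon's count divided by
#'     all sense-codon counts (often reported per 1000 elsewhere; stored as
#'     fractions here). Sums to 1 over the 61 sense codons.}
#' }
#' Stop codons are counted separately and excluded from both
#' normalizations and from the 61-codon sense universe.
#'
#' Most users will build tables with [count_codons()] +
#' [normalize_table()]; the constructor is exported for synthetic tables
#' and for file readers.
#'
#' @param counts named non-negative integer vector over sense codons
#'   (missing codons are taken as 0), or `NULL`.
#' @param rel_freq_aa,global_freq named numeric vectors over sense codons
#'   (`NA` = undefined), or `NULL`.
#' @param stop_counts named counts over the stop codons, or `NULL`.
#' @param source_label free-text provenance label.
#' @param pseudocount pseudocount used when `rel_freq_aa` was computed.
#' @param code a [genetic_code()].
#' @return Object of class `codon_usage_table`: list with `counts`,
#'   `stop_counts`, `total_sense`, `rel_freq_aa`, `global_freq`,
#'   `source_label`, `pseudocount`, and flags `has_counts`, `has_rel`,
#'   `has_global`. Frequency vectors are aligned to `code$sense_codons`.
#' @export
codon_usage_table <- function(counts = NULL, rel_freq_aa = NULL, global_freq = NULL,
                              stop_counts = NULL, source_label = "",
                              pseudocount = 0, code = genetic_code()) {
  sense <- code$sense_codons
  align <- function(x, what, default) {
    out <- stats::setNames(rep(default, length(sense)), sense)
    if (!is.null(x)) {
      if (is.null(names(x)) || any(!names(x) %in% sense))
        cs_stop(what, " must be named by sense codons")
      out[names(x)] <- x
    }
    out
  }
  has_counts <- !is.null(counts)
  counts <- align(counts, "counts", 0)
  if (any(counts < 0) || any(counts != round(counts)))
    cs_stop("counts must be non-negative integers")
  counts <- stats::setNames(as.integer(round(counts)), names(counts))
  st <- stats::setNames(rep(0L, length(code$stop_codons)), code$stop_codons)
  if (!is.null(stop_counts)) st[names(stop_counts)] <- as.integer(stop_counts)
  has_rel <- !is.null(rel_freq_aa)
  has_global <- !is.null(global_freq)
  tab <- structure(list(
    counts = if (has_counts) counts else NULL,
    stop_counts = st,
    total_sense = if (has_counts) sum(counts) else NA_real_,
    rel_freq_aa = align(rel_freq_aa, "rel_freq_aa", NA_real_),
    global_freq = align(global_freq, "global_freq", NA_real_),
    source_label = source_label,
    pseudocount = pseudocount,
    has_counts = has_counts, has_rel = has_rel, has_global = has_global,
    code = code
  ), class = "codon_usage_table")
  if (has_rel) check_family_sums(tab)
  if (has_global) {
    g <- tab$global_freq
    if (!anyNA(g) && abs(sum(g) - 1) > 1e-9)
      cs_stop("global_freq must sum to 1 over the sense codons (got ",
              format(sum(g)), ")")
  }
  tab
}

# per-family sums of rel_freq_aa must be 1 (within tolerance) where defined
check_family_sums <- function(tab, tol = 1e-9) {
  for (aa in names(tab$code$families)) {
    fam <- tab$code$families[[aa]]
    v <- tab$rel_freq_aa[fam]
    if (anyNA(v)) next
    if (abs(sum(v) - 1) > tol)
      cs_stop("rel_freq_aa for family ", aa, " sums to ", format(sum(v)),
              ", expected 1")
  }
  invisible(tab)
}

#' @export
print.codon_usage_table <- function(x, ...) {
  cat("<codon_usage_table> '", x$source_label, "'", sep = "")
  if (x$has_counts) cat(" total_sense=", x$total_sense, sep = "")
  cat(" [", paste(c("counts", "rel_freq_aa", "global_freq")[
    c(x$has_counts, x$has_rel, x$has_global)], collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Count codons over a set of coding sequences
#'
#' Exact codon counts summed over all records; the substrate for every
#' frequency table in the package. Every record must be strictly valid
#' (see [validate_cds()]); alternatively `skip_invalid = TRUE` logs and
#' drops offenders — opt-in, because silently losing genes while building
#' a gene-set table would bias the frequencies.
#'
#' @param records a `sequence_record` or list of them.
#' @param code a [genetic_code()].
#' @param skip_invalid drop invalid records with a message instead of
#'   erroring (default `FALSE`).
#' @param source_label provenance label for the resulting table.
#' @return A [codon_usage_table()] with counts populated (frequencies not
#'   yet; see [normalize_table()]).
#' @examples
#' tab <- count_codons(sequence_record("g", "ATGCTGCTGTTA"))
#' tab$counts[c("ATG", "CTG", "TTA")]  # 1 2 1
#' @export
count_codons <- function(records, code = genetic_code(), skip_invalid = FALSE,
                         source_label = "") {
  if (inherits(records, "sequence_record")) records <- list(records)
  if (!is.list(records) || length(records) == 0L)
    cs_stop("records must be a non-empty list of sequence_record")
  counts <- stats::setNames(rep(0L, length(code$sense_codons)), code$sense_codons)
  stop_counts <- stats::setNames(rep(0L, length(code$stop_codons)), code$stop_codons)
  n_used <- 0L
  for (rec in records) {
    if (!inherits(rec, "sequence_record")) cs_stop("records must be sequence_record objects")
    rep_ <- validate_cds(rec, code)
    if (!rep_$strictly_valid) {
      if (skip_invalid) {
        message("count_codons: skipping invalid record '", rec$id, "'")
        next
      }
      cs_stop("record '", rec$id, "' is not a strictly valid CDS ",
              "(mult3=", rep_$length_multiple_of_three,
              ", internal_stops=", length(rep_$internal_stop_positions),
              ", ambiguous=", length(rep_$ambiguous_positions), ")")
    }
    codons <- split_codons(rec$seq)
    tb <- table(codons)
    is_stop <- names(tb) %in% code$stop_codons
    if (any(!is_stop)) counts[names(tb)[!is_stop]] <-
        counts[names(tb)[!is_stop]] + as.integer(tb[!is_stop])
    if (any(is_stop)) stop_counts[names(tb)[is_stop]] <-
        stop_counts[names(tb)[is_stop]] + as.integer(tb[is_stop])
    n_used <- n_used + 1L
  }
  if (n_used == 0L) cs_stop("no valid records to count")
  codon_usage_table(counts = counts, stop_counts = stop_counts,
                    source_label = source_label, code = code)
}

#' Normalize a codon-usage table
#'
#' Populates both frequency normalizations from counts:
#' `rel_freq_aa(c) = (count(c) + pseudocount) / sum over c's family of
#' (count + pseudocount)` and `global_freq(c) = count(c) / total_sense`.
#' A family with zero observations and zero pseudocount has its
#' `rel_freq_aa` left undefined (`NA`); with a positive pseudocount it
#' becomes uniform over the family.
#'
#' The pseudocount default is 0: gene-scale inputs (hundreds of codons)
#' rarely leave a family empty, and an unsmoothed table is exactly the
#' observed usage.
#'
#' @param table a [codon_usage_table()] with counts populated.
#' @param pseudocount non-negative real added to every sense-codon count
#'   for the per-family normalization only.
#' @return The table with `rel_freq_aa` and `global_freq` populated.
#' @examples
#' tab <- count_codons(sequence_record("g", "ATGCTGCTGTTA"))
#' tab <- normalize_table(tab)
#' tab$rel_freq_aa[c("CTG", "TTA")]  # 2/3, 1/3
#' @export
normalize_table <- function(table, pseudocount = 0) {
  if (!inherits(table, "codon_usage_table")) cs_stop("table must be a codon_usage_table")
  if (!table$has_counts) cs_stop("counts are not populated; nothing to normalize")
  pseudocount <- cs_assert_scalar_number(pseudocount, "pseudocount", min = 0)
  code <- table$code
  rel <- stats::setNames(rep(NA_real_, length(code$sense_codons)), code$sense_codons)
  for (aa in names(code$families)) {
    fam <- code$families[[aa]]
    cnt <- table$counts[fam] + pseudocount
    tot <- sum(cnt)
    if (tot > 0) rel[fam] <- cnt / tot
  }
  glob <- if (table$total_sense > 0) table$counts / table$total_sense else
    stats::setNames(rep(NA_real_, length(code$sense_codons)), code$sense_codons)
  table$rel_freq_aa <- rel
  table$global_freq <- glob
  table$pseudocount <- pseudocount
  table$has_rel <- TRUE
  table$has_global <- TRUE
  check_family_sums(table)
  table
}

# named frequency vector under a normalization label, aligned to sense order
usage_vector <- function(table, normalization) {
  normalization <- cs_match_arg(normalization, c("rel_freq_aa", "global_freq"),
                                "normalization")
  has <- if (normalization == "rel_freq_aa") table$has_rel else table$has_global
  if (!has) cs_stop("table '", table$source_label, "' has no ", normalization,
                    " normalization populated")
  table[[normalization]]
}

#' Write a codon-usage table to TSV
#'
#' The package's codon-table dialect: comment lines (`# key=value`), then a
#' header `codon  amino_acid  count  rel_freq_aa  global_freq` and 61
#' tab-separated data rows in fixed (alphabetical) codon order, with `.`
#' for undefined fields.
#'
#' @param table a [codon_usage_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_codon_table <- function(table, path) {
  if (!inherits(table, "codon_usage_table")) cs_stop("table must be a codon_usage_table")
  code <- table$code
  fmt <- function(x) ifelse(is.na(x), ".", format(x, digits = 15, scientific = FALSE,
                                                  trim = TRUE))
  counts <- if (table$has_counts) table$counts else
    stats::setNames(rep(NA_real_, length(code$sense_codons)), code$sense_codons)
  lines <- c(
    paste0("# source_label=", table$source_label),
    paste0("# pseudocount=", table$pseudocount),
    paste0("codon\tamino_acid\tcount\trel_freq_aa\tglobal_freq"),
    paste(code$sense_codons,
          codon_aa(code$sense_codons, code),
          fmt(counts),
          fmt(table$rel_freq_aa),
          fmt(table$global_freq),
          sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a codon-usage table from TSV
#'
#' Reads the dialect written by [write_codon_table()], and also accepts
#' external two-column `codon  frequency` files (published state-specific
#' gene-set tables) whose normalization is declared in a `# normalization=` comment
#' line (`rel_freq_aa` or `global_freq`). Two-column global frequencies on
#' a per-1000 scale are rescaled to fractions; stop-codon rows in external
#' files are ignored.
#'
#' @param path input TSV.
#' @param code a [genetic_code()].
#' @return A [codon_usage_table()].
#' @export
read_codon_table <- function(path, code = genetic_code()) {
  if (!file.exists(path)) cs_stop("codon table not found: ", path)
  raw <- readLines(path)
  comments <- raw[startsWith(raw, "#")]
  body <- raw[!startsWith(raw, "#") & nzchar(raw)]
  if (length(body) < 2L) cs_stop("codon table has no data rows: ", path)
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1]]
  get_comment <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "="), comments, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    sub(paste0("^#\\s*", key, "="), "", hit[1L])
  }
  df <- utils::read.table(text = paste(body[-1L], collapse = "\n"), sep = "\t",
                          col.names = header, na.strings = ".",
                          stringsAsFactors = FALSE)
  df$codon <- toupper(gsub("U", "T", df$codon, fixed = TRUE))
  if (identical(sort(header), sort(c("codon", "frequency")))) {
    norm <- get_comment("normalization")
    if (is.null(norm)) cs_stop("two-column codon table needs a '# normalization=' ",
                               "comment line: ", path)
    norm <- cs_match_arg(norm, c("rel_freq_aa", "global_freq"), "normalization")
    df <- df[df$codon %in% code$sense_codons, , drop = FALSE]
    if (nrow(df) != length(code$sense_codons))
      cs_stop("two-column table must cover all 61 sense codons; got ", nrow(df))
    freq <- stats::setNames(as.numeric(df$frequency), df$codon)
    if (norm == "global_freq") {
      freq <- freq / sum(freq)  # accepts per-1000 or percentage dialects
      return(codon_usage_table(global_freq = freq,
                               source_label = get_comment("source_label") %||% path,
                               code = code))
    }
    # per-family renormalization absorbs rounding in external tables
    for (fam in code$families) freq[fam] <- freq[fam] / sum(freq[fam])
    return(codon_usage_table(rel_freq_aa = freq,
                             source_label = get_comment("source_label") %||% path,
                             code = code))
  }
  need <- c("codon", "amino_acid", "count", "rel_freq_aa", "global_freq")
  if (!all(need %in% header)) cs_stop("unrecognized codon-table header in ", path)
  if (!setequal(df$codon, code$sense_codons))
    cs_stop("codon table must have one row per sense codon: ", path)
  rownames(df) <- df$codon
  df <- df[code$sense_codons, ]
  counts <- if (all(is.na(df$count))) NULL else
    stats::setNames(as.numeric(df$count), df$codon)
  rel <- if (all(is.na(df$rel_freq_aa))) NULL else
    stats::setNames(as.numeric(df$rel_freq_aa), df$codon)
  glob <- if (all(is.na(df$global_freq))) NULL else
    stats::setNames(as.numeric(df$global_freq), df$codon)
  codon_usage_table(counts = counts, rel_freq_aa = rel, global_freq = glob,
                    source_label = get_comment("source_label") %||% path,
                    pseudocount = as.numeric(get_comment("pseudocount") %||% 0),
                    code = code)
}
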