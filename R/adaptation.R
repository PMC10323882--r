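#' Squared Pearson correlation between two codon-usage vectors
#'
#' The adaptation statistic: each codon contributes one point whose
#' coordinates are its frequency in the two tables, and R-squared is the
#' squared Pearson correlation of that per-codon scatter (equivalently,
#' the coefficient of determination of the simple least-squares line with
#' intercept). It is symmetric in its arguments and invariant to positive
#' affine rescaling of either vector, so per-1000 and fractional dialects
#' agree.
#'
#' Codon-set handling: under `rel_freq_aa` the single-codon families (ATG,
#' TGG) are constant 1.0 in every table, so they are always dropped (and
#' reported among `dropped_codons`); under `global_freq` they carry
#' information and `codon_set = "all_61"` keeps them. Codons with an
#' undefined frequency in either table are dropped pairwise.
#'
#' @param vec_a,vec_b [codon_usage_table()]s with the requested
#'   normalization populated.
#' @param normalization `"global_freq"` (default) or `"rel_freq_aa"`.
#' @param codon_set `"all_61"` (default) or `"multi_codon_families_only"`.
#' @param code a [genetic_code()].
#' @param details return a list with `r2`, `n_points`, `dropped_codons`
#'   instead of the bare number.
#' @return R-squared in `[0, 1]` (or the detail list).
#' @examples
#' pair <- sample_state_pair(seed = 1, kappa = 0.9)
#' codon_usage_r2(pair$source, pair$source, normalization = "rel_freq_aa")  # 1
#' @export
codon_usage_r2 <- function(vec_a, vec_b, normalization = "global_freq",
                           codon_set = "all_61", code = genetic_code(),
                           details = FALSE) {
  normalization <- cs_match_arg(normalization, c("global_freq", "rel_freq_aa"),
                                "normalization")
  codon_set <- cs_match_arg(codon_set, c("all_61", "multi_codon_families_only"),
                            "codon_set")
  a <- usage_vector(vec_a, normalization)
  b <- usage_vector(vec_b, normalization)
  keep <- code$sense_codons
  if (codon_set == "multi_codon_families_only" || normalization == "rel_freq_aa") {
    singles <- unlist(code$families[lengths(code$families) == 1L], use.names = FALSE)
    keep <- setdiff(keep, singles)
  }
  defined <- keep[!is.na(a[keep]) & !is.na(b[keep])]
  dropped <- setdiff(code$sense_codons, defined)
  if (length(defined) < 3L)
    cs_stop("fewer than 3 codons with defined frequencies in both tables (",
            length(defined), ")")
  x <- a[defined]; y <- b[defined]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    cs_stop_degenerate("R-squared undefined: zero variance in a frequency vector")
  r2 <- stats::cor(x, y)^2
  if (!details) return(r2)
  list(r2 = r2, n_points = length(defined), dropped_codons = dropped)
}

#' Score a gene's codon-usage adaptation to two cell states
#'
#' Builds the gene's own codon-usage table and correlates it against a
#' source-state table (e.g. a differentiation-specific gene set) and a
#' target-state table (e.g. a proliferation-specific gene set). A gene
#' translated efficiently under a state's tRNA program is expected to show
#' the higher R-squared against that state's table.
#'
#' @param gene a strictly valid [sequence_record()].
#' @param source_table,target_table normalized [codon_usage_table()]s for
#'   the two states.
#' @param normalization,codon_set passed to [codon_usage_r2()].
#' @param pseudocount smoothing for the gene's own table (default 0).
#' @param code a [genetic_code()].
#' @return Object of class `adaptation_report`: list with `gene_id`,
#'   `r2_source`, `r2_target`, `normalization_used`, `codon_set`,
#'   `n_points`, `dropped_codons`.
#' @export
adaptation_report <- function(gene, source_table, target_table,
                              normalization = "global_freq",
                              codon_set = "all_61", pseudocount = 0,
                              code = genetic_code()) {
  gene_tab <- normalize_table(count_codons(gene, code = code,
                                           source_label = gene$id),
                              pseudocount = pseudocount)
  src <- codon_usage_r2(gene_tab, source_table, normalization, codon_set,
                        code, details = TRUE)
  tgt <- codon_usage_r2(gene_tab, target_table, normalization, codon_set,
                        code, details = TRUE)
  structure(list(
    gene_id = gene$id,
    r2_source = src$r2,
    r2_target = tgt$r2,
    normalization_used = normalization,
    codon_set = codon_set,
    n_points = min(src$n_points, tgt$n_points),
    dropped_codons = sort(union(src$dropped_codons, tgt$dropped_codons))
  ), class = "adaptation_report")
}

#' @export
print.adaptation_report <- function(x, ...) {
  cat("<adaptation_report> ", x$gene_id,
      ": R2(source)=", round(x$r2_source, 4),
      "  R2(target)=", round(x$r2_target, 4),
      "  [", x$normalization_used, ", ", x$codon_set,
      ", n=", x$n_points, "]\n", sep = "")
  invisible(x)
}

#' Write an adaptation report as JSON
#'
#' @param report an [adaptation_report()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_adaptation_json <- function(report, path) {
  if (!inherits(report, "adaptation_report")) cs_stop("report must be an adaptation_report")
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Export a per-codon scatter for external plotting
#'
#' One row per codon with its frequency in the gene and in the state
#' table, the raw material of the adaptation scatter plot.
#'
#' @param gene_table,state_table normalized [codon_usage_table()]s.
#' @param path output TSV.
#' @param normalization which frequency to export.
#' @param code a [genetic_code()].
#' @return `path`, invisibly.
#' @export
write_scatter_tsv <- function(gene_table, state_table, path,
                              normalization = "global_freq",
                              code = genetic_code()) {
  a <- usage_vector(gene_table, normalization)
  b <- usage_vector(state_table, normalization)
  df <- data.frame(codon = code$sense_codons,
                   amino_acid = codon_aa(code$sense_codons, code),
                   freq_in_gene = a,
                   freq_in_state = b)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
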