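#' Design configuration for state recoding
#'
#' Bundles the tunable parameters of the cross-state frequency-matching
#' design:
#' \describe{
#'   \item{`delta`}{the "similar frequency" tolerance: a codon whose
#'     cross-state frequency discrepancy is at most `delta` is maintained.
#'     Default 0 — the implied nonzero tolerance of a published design can
#'     be recovered with [calibrate_delta()] instead of guessed.}
#'   \item{`normalization`}{frequency space used for matching. Default
#'     `"rel_freq_aa"`: frequencies are only commensurable across states
#'     within a synonym family; global frequencies confound amino-acid
#'     composition. Configurable for sensitivity sweeps.}
#'   \item{`tie_break`}{`"lexicographic"` (deterministic codon order,
#'     default) or `"min_nucleotide_changes"` (biologically conservative:
#'     fewest substitutions, then lexicographic).}
#'   \item{`stop_policy`}{`"keep_original"` (default) or `"remap_never"`;
#'     both leave stop codons untouched — the design covers sense codons
#'     only — and are kept as distinct provenance labels.}
#' }
#'
#' @param delta non-negative real.
#' @param normalization `"rel_freq_aa"` or `"global_freq"`.
#' @param tie_break `"lexicographic"` or `"min_nucleotide_changes"`.
#' @param stop_policy `"keep_original"` or `"remap_never"`.
#' @return Object of class `design_config`.
#' @export
design_config <- function(delta = 0, normalization = "rel_freq_aa",
                          tie_break = "lexicographic",
                          stop_policy = "keep_original") {
  structure(list(
    delta = cs_assert_scalar_number(delta, "delta", min = 0),
    normalization = cs_match_arg(normalization, c("rel_freq_aa", "global_freq"),
                                 "normalization"),
    tie_break = cs_match_arg(tie_break, c("lexicographic", "min_nucleotide_changes"),
                             "tie_break"),
    stop_policy = cs_match_arg(stop_policy, c("keep_original", "remap_never"),
                               "stop_policy")
  ), class = "design_config")
}

#' Construct a codon mapping
#'
#' Low-level constructor for the 61-entry sense-codon design map; validates
#' synonymity (every codon maps within its own synonym family, so
#' translation is preserved by construction) and that single-codon families
#' map to themselves. Most mappings come from [build_codon_mapping()]; the
#' constructor is exported so that mappings can be crafted directly (e.g.
#' when reconstructing a published design from its substitution table).
#'
#' @param map named character vector: 61 sense codons -> sense codons.
#' @param match_error optional named numeric: per-codon matching error.
#' @param config a [design_config()] (provenance).
#' @param provenance free-text labels of the two tables used.
#' @param code a [genetic_code()].
#' @return Object of class `codon_mapping`: list with `map`, `maintained`
#'   (codons with `map(c) == c`), `match_error`, `config`, `provenance`.
#' @export
codon_mapping <- function(map, match_error = NULL, config = design_config(),
                          provenance = character(0), code = genetic_code()) {
  sense <- code$sense_codons
  if (is.null(names(map)) || !setequal(names(map), sense))
    cs_stop("map must be named by exactly the 61 sense codons")
  map <- map[sense]
  if (any(!map %in% sense)) cs_stop("map values must be sense codons")
  same_aa <- codon_aa(map, code) == codon_aa(sense, code)
  if (any(!same_aa))
    cs_stop("map is not synonymous at: ",
            paste(sense[!same_aa], collapse = ", "))
  singles <- unlist(code$families[lengths(code$families) == 1L], use.names = FALSE)
  if (any(map[singles] != singles))
    cs_stop("single-codon families must map to themselves")
  me <- stats::setNames(rep(NA_real_, length(sense)), sense)
  if (!is.null(match_error)) me[names(match_error)] <- match_error
  structure(list(
    map = map,
    maintained = sense[map == sense],
    match_error = me,
    config = config,
    provenance = provenance,
    code = code
  ), class = "codon_mapping")
}

#' @export
print.codon_mapping <- function(x, ...) {
  n_changed <- sum(x$map != names(x$map))
  cat("<codon_mapping> ", n_changed, " of ", length(x$map),
      " codon types remapped (", length(x$maintained), " maintained)\n", sep = "")
  if (length(x$provenance)) cat("  tables: ", paste(x$provenance, collapse = " -> "),
                                "\n", sep = "")
  invisible(x)
}

#' Build the cross-state frequency-matching codon map
#'
#' The core design algorithm. For each sense codon `c` with frequency
#' `f_source(c)` in the source-state table: if the same codon's frequency
#' in the target state is already similar
#' (`|f_target(c) - f_source(c)| <= delta`) the codon is maintained;
#' otherwise `c` is mapped to the synonym `c'` whose target-state frequency
#' best approximates the codon's source-state frequency, i.e. the argmin of
#' `|f_target(c') - f_source(c)|` over the synonym family (the codon itself
#' included as a candidate). Ties are broken per `config$tie_break`. The
#' mapping is per codon type, deterministic given its inputs, and not
#' required to be injective within a family.
#'
#' @param source_table,target_table [codon_usage_table()]s with the
#'   matching normalization populated and defined for all 61 sense codons.
#' @param config a [design_config()].
#' @param code a [genetic_code()].
#' @return A [codon_mapping()].
#' @examples
#' pair <- sample_state_pair(seed = 7, kappa = 1)
#' m <- build_codon_mapping(pair$source, pair$target)
#' mapping_summary(m)$codon_types_changed
#' @export
build_codon_mapping <- function(source_table, target_table,
                                config = design_config(),
                                code = genetic_code()) {
  if (!inherits(config, "design_config")) cs_stop("config must be a design_config")
  f_s <- usage_vector(source_table, config$normalization)
  f_t <- usage_vector(target_table, config$normalization)
  undef <- code$sense_codons[is.na(f_s) | is.na(f_t)]
  if (length(undef) > 0L)
    cs_stop("undefined ", config$normalization, " for codon(s): ",
            paste(undef, collapse = ", "))
  map <- stats::setNames(code$sense_codons, code$sense_codons)
  match_error <- stats::setNames(rep(NA_real_, length(map)), names(map))
  for (c0 in code$sense_codons) {
    disc <- abs(f_t[[c0]] - f_s[[c0]])
    if (disc <= config$delta) {
      match_error[[c0]] <- disc
      next
    }
    fam <- codon_family(c0, code)        # alphabetical candidate order
    errs <- abs(f_t[fam] - f_s[[c0]])
    best <- fam[errs == min(errs)]
    if (length(best) > 1L && config$tie_break == "min_nucleotide_changes") {
      d <- vapply(best, hamming, 0, b = c0)
      best <- best[d == min(d)]
    }
    map[[c0]] <- best[1L]                # lexicographic among remaining ties
    match_error[[c0]] <- min(errs)
  }
  codon_mapping(map, match_error = match_error, config = config,
                provenance = c(source_table$source_label,
                               target_table$source_label),
                code = code)
}

#' Recode a coding sequence through a codon mapping
#'
#' Replaces every sense codon by its image under the mapping; a terminal
#' stop codon is left untouched (see `stop_policy` in [design_config()]).
#' The recoded sequence encodes the identical protein — the synonymity of
#' the mapping guarantees it, and the function asserts it.
#'
#' @param cds a strictly valid [sequence_record()].
#' @param mapping a [codon_mapping()].
#' @param id_suffix appended to the record id of the recoded sequence.
#' @return Object of class `design_result`: list with `original`,
#'   `recoded`, `mapping`, `positions_changed`, `codon_types_changed`,
#'   `nt_substitutions`, `gc_original`, `gc_recoded`.
#' @examples
#' pair <- sample_state_pair(seed = 7, kappa = 1)
#' m <- build_codon_mapping(pair$source, pair$target)
#' gene <- sample_cds(protein_length = 50, table = pair$source, seed = 11)
#' res <- recode_sequence(gene, m)
#' translate_cds(res$recoded) == translate_cds(gene)  # TRUE
#' @export
recode_sequence <- function(cds, mapping, id_suffix = "_recoded") {
  if (!inherits(mapping, "codon_mapping")) cs_stop("mapping must be a codon_mapping")
  code <- mapping$code
  rep_ <- validate_cds(cds, code)
  if (!rep_$strictly_valid)
    cs_stop("record '", cds$id, "' is not a strictly valid CDS")
  codons <- split_codons(cds$seq)
  is_stop <- is_stop_codon(codons, code)
  new_codons <- codons
  missing <- setdiff(codons[!is_stop], names(mapping$map))
  if (length(missing) > 0L)
    cs_stop("codon(s) absent from mapping: ", paste(unique(missing), collapse = ", "))
  new_codons[!is_stop] <- mapping$map[codons[!is_stop]]
  recoded <- sequence_record(paste0(cds$id, id_suffix),
                             paste(new_codons, collapse = ""))
  if (translate_cds(recoded, code) != translate_cds(cds, code))
    cs_stop("internal error: recoding altered the protein")  # unreachable by construction
  changed <- new_codons != codons
  structure(list(
    original = cds,
    recoded = recoded,
    mapping = mapping,
    positions_changed = sum(changed),
    codon_types_changed = length(unique(codons[changed])),
    nt_substitutions = sum(vapply(which(changed), function(i)
      hamming(codons[i], new_codons[i]), 0)),
    gc_original = gc_fraction(cds$seq),
    gc_recoded = gc_fraction(recoded$seq)
  ), class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  n <- nchar(x$original$seq) %/% 3L
  cat("<design_result> ", x$original$id, " -> ", x$recoded$id, "\n",
      "  positions changed: ", x$positions_changed, " of ", n,
      " codons (", x$codon_types_changed, " codon types, ",
      x$nt_substitutions, " nt substitutions)\n",
      "  GC: ", round(x$gc_original, 4), " -> ", round(x$gc_recoded, 4),
      "\n", sep = "")
  invisible(x)
}

#' Summarize a codon mapping
#'
#' Counts how much of the 61-sense-codon universe the design rewrites:
#' maintained versus changed codon types, the percentage changed (nearest
#' integer, so a 50-of-61 design reports 82), and a per-family breakdown.
#'
#' @param mapping a [codon_mapping()].
#' @return List with `codon_types_changed`, `maintained_count`,
#'   `percent_changed`, and `per_family` (data frame: amino acid, family
#'   size, changed count).
#' @export
mapping_summary <- function(mapping) {
  if (!inherits(mapping, "codon_mapping")) cs_stop("mapping must be a codon_mapping")
  code <- mapping$code
  changed <- names(mapping$map)[mapping$map != names(mapping$map)]
  per_family <- data.frame(
    amino_acid = names(code$families),
    family_size = lengths(code$families),
    n_changed = vapply(code$families, function(f) sum(f %in% changed), 0L),
    row.names = NULL
  )
  list(
    codon_types_changed = length(changed),
    maintained_count = length(mapping$maintained),
    percent_changed = round(100 * length(changed) / length(mapping$map)),
    per_family = per_family
  )
}

#' Calibrate the maintenance tolerance delta
#'
#' Inverts the design: finds the smallest `delta` (drawn from the sorted
#' cross-state frequency discrepancies, 0 included) at which
#' [build_codon_mapping()] maintains at least `maintained_target` codon
#' types. Because a codon can also be maintained by being its own argmin,
#' the maintained count at a given delta can exceed the number of
#' discrepancies below it; the calibration therefore counts maintained
#' codons by actually building the mapping at each candidate. The result
#' is monotone: a larger `maintained_target` never yields a smaller delta.
#'
#' @param source_table,target_table as in [build_codon_mapping()].
#' @param maintained_target integer in `[2, 61]` (the two single-codon
#'   families are always maintained, so fewer than 2 is unreachable).
#' @param config a [design_config()]; its `delta` is ignored.
#' @param code a [genetic_code()].
#' @return The calibrated delta (non-negative real).
#' @export
calibrate_delta <- function(source_table, target_table, maintained_target,
                            config = design_config(), code = genetic_code()) {
  maintained_target <- cs_assert_scalar_number(maintained_target,
                                               "maintained_target", min = 2,
                                               max = length(code$sense_codons))
  if (maintained_target != round(maintained_target))
    cs_stop("maintained_target must be an integer")
  f_s <- usage_vector(source_table, config$normalization)
  f_t <- usage_vector(target_table, config$normalization)
  disc <- sort(unique(c(0, abs(f_t - f_s))))
  for (d in disc) {
    cfg <- config
    cfg$delta <- d
    m <- build_codon_mapping(source_table, target_table, cfg, code)
    if (length(m$maintained) >= maintained_target) return(d)
  }
  max(disc)  # delta = max discrepancy maintains all 61
}

#' Diff two synonymous coding sequences
#'
#' Reconstructs the substitution table from a wildtype/recoded sequence
#' pair: the per-position codon changes, the inferred codon-type mapping,
#' and whether that mapping is consistent (every occurrence of a codon
#' type in `a` maps to the same codon type in `b`).
#'
#' @param a,b strictly valid [sequence_record()]s of equal length encoding
#'   the identical protein.
#' @param code a [genetic_code()].
#' @return List with `positions` (data frame: 0-based `index`, `codon_a`,
#'   `codon_b` for differing positions), `inferred_mapping` (named vector
#'   over codon types present in `a`), `consistent`,
#'   `n_positions_changed`, `nt_substitutions`.
#' @export
diff_codons <- function(a, b, code = genetic_code()) {
  if (nchar(a$seq) != nchar(b$seq))
    cs_stop("sequences have different lengths (", nchar(a$seq), " vs ",
            nchar(b$seq), ")")
  if (translate_cds(a, code) != translate_cds(b, code))
    cs_stop("sequences are not synonymous variants: translations differ")
  ca <- split_codons(a$seq)
  cb <- split_codons(b$seq)
  changed <- which(ca != cb)
  inferred <- tapply(cb, ca, unique, simplify = FALSE)
  consistent <- all(lengths(inferred) == 1L)
  list(
    positions = data.frame(index = changed - 1L,
                           codon_a = ca[changed],
                           codon_b = cb[changed],
                           row.names = NULL),
    inferred_mapping = if (consistent)
      vapply(inferred, `[[`, "", 1L) else inferred,
    consistent = consistent,
    n_positions_changed = length(changed),
    nt_substitutions = sum(vapply(changed, function(i) hamming(ca[i], cb[i]), 0))
  )
}

#' Write a codon mapping to TSV
#'
#' 61 rows in fixed codon order with columns `source_codon`,
#' `target_codon`, `amino_acid`, `f_source`, `f_target`, `match_error`,
#' `maintained`.
#'
#' @param mapping a [codon_mapping()].
#' @param path output file.
#' @param source_table,target_table optional tables to populate `f_source`
#'   / `f_target` under the mapping's normalization.
#' @return `path`, invisibly.
#' @export
write_mapping_table <- function(mapping, path, source_table = NULL,
                                target_table = NULL) {
  code <- mapping$code
  sense <- code$sense_codons
  norm <- mapping$config$normalization
  f_s <- if (!is.null(source_table)) usage_vector(source_table, norm) else
    stats::setNames(rep(NA_real_, length(sense)), sense)
  f_t <- if (!is.null(target_table)) usage_vector(target_table, norm) else
    stats::setNames(rep(NA_real_, length(sense)), sense)
  fmt <- function(x) ifelse(is.na(x), ".",
                            format(x, digits = 15, scientific = FALSE, trim = TRUE))
  lines <- c(
    paste0("# provenance=", paste(mapping$provenance, collapse = " -> ")),
    paste0("# delta=", mapping$config$delta),
    paste0("# normalization=", norm),
    paste0("# tie_break=", mapping$config$tie_break),
    "source_codon\ttarget_codon\tamino_acid\tf_source\tf_target\tmatch_error\tmaintained",
    paste(sense, mapping$map[sense], codon_aa(sense, code),
          fmt(f_s[sense]), fmt(f_t[mapping$map[sense]]),
          fmt(mapping$match_error[sense]),
          ifelse(mapping$map[sense] == sense, "TRUE", "FALSE"),
          sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a codon mapping from TSV
#'
#' Reads the dialect written by [write_mapping_table()].
#'
#' @param path input file.
#' @param code a [genetic_code()].
#' @return A [codon_mapping()].
#' @export
read_mapping_table <- function(path, code = genetic_code()) {
  if (!file.exists(path)) cs_stop("mapping table not found: ", path)
  raw <- readLines(path)
  body <- raw[!startsWith(raw, "#") & nzchar(raw)]
  df <- utils::read.table(text = paste(body, collapse = "\n"), sep = "\t",
                          header = TRUE, na.strings = ".",
                          stringsAsFactors = FALSE)
  if (!all(c("source_codon", "target_codon") %in% names(df)))
    cs_stop("unrecognized mapping-table header in ", path)
  get_comment <- function(key, default) {
    hit <- grep(paste0("^#\\s*", key, "="), raw, value = TRUE)
    if (length(hit) == 0L) return(default)
    sub(paste0("^#\\s*", key, "="), "", hit[1L])
  }
  cfg <- design_config(delta = as.numeric(get_comment("delta", "0")),
                       normalization = get_comment("normalization", "rel_freq_aa"),
                       tie_break = get_comment("tie_break", "lexicographic"))
  me <- if ("match_error" %in% names(df))
    stats::setNames(df$match_error, df$source_codon) else NULL
  codon_mapping(stats::setNames(df$target_codon, df$source_codon),
                match_error = me, config = cfg,
                provenance = get_comment("provenance", ""), code = code)
}
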