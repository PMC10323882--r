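# Independent oracles used to cross-check the implementation. These
# deliberately re-derive results from first principles (plain loops,
# closed forms, full enumeration) and never call the code paths they check.

# synonym family of a codon, via the raw code tables
fam_of <- function(codon, code) code$families[[code$codon_to_aa[[codon]]]]

# triplet splitter (test-side copy so tests never reach into internals)
split_codons_chr <- function(seq) {
  n <- nchar(seq) %/% 3L
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# Exhaustive per-codon argmin mapping at delta 0: for every sense codon,
# enumerate all synonyms and take the minimum |f_target(c') - f_source(c)|,
# first-in-alphabetical-order on ties.
oracle_argmin_mapping <- function(f_source, f_target, code) {
  map <- character(0)
  for (c0 in code$sense_codons) {
    fam <- fam_of(c0, code)
    errs <- vapply(fam, function(c1) abs(f_target[[c1]] - f_source[[c0]]), 0)
    map[[c0]] <- fam[which.min(errs)]
  }
  map[code$sense_codons]
}

# Closed-form squared Pearson correlation from raw sums.
oracle_r2 <- function(x, y) {
  n <- length(x)
  num <- (n * sum(x * y) - sum(x) * sum(y))^2
  den <- (n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2)
  num / den
}

# Total frequency-matching objective of a candidate synonymous sequence:
# sum over positions of |f_target(new codon) - f_source(original codon)|.
matching_objective <- function(orig_codons, new_codons, f_source, f_target) {
  sum(abs(f_target[new_codons] - f_source[orig_codons]))
}

# Minimum of the matching objective over ALL synonymous sequences, by full
# enumeration (expand.grid over every per-position synonym choice).
oracle_enumerated_minimum <- function(orig_codons, f_source, f_target, code) {
  fams <- lapply(orig_codons, fam_of, code = code)
  grid <- do.call(expand.grid, c(lapply(fams, seq_along),
                                 list(KEEP.OUT.ATTRS = FALSE)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    cand <- vapply(seq_along(fams), function(i) fams[[i]][grid[r, i]], "")
    obj <- matching_objective(orig_codons, cand, f_source, f_target)
    if (obj < best) best <- obj
  }
  best
}

# A valid synonymous mapping with exactly `n_changed` codon types remapped:
# the first n multi-family sense codons are shifted to the next synonym in
# alphabetical family order, the rest stay put.
make_shifted_mapping <- function(n_changed, code = genetic_code()) {
  map <- stats::setNames(code$sense_codons, code$sense_codons)
  multi <- code$sense_codons[
    vapply(code$sense_codons, function(c0) length(fam_of(c0, code)) > 1L, TRUE)]
  stopifnot(n_changed <= length(multi))
  for (c0 in multi[seq_len(n_changed)]) {
    fam <- fam_of(c0, code)
    i <- match(c0, fam)
    map[[c0]] <- fam[(i %% length(fam)) + 1L]
  }
  codon_mapping(map, code = code)
}

# Random strictly valid CDS (uniform codon choice), for translation checks.
random_valid_cds <- function(n_codons, seed, code = genetic_code(),
                             terminal_stop = FALSE) {
  withr::with_seed(seed, {
    codons <- sample(code$sense_codons, n_codons, replace = TRUE)
    if (terminal_stop) codons <- c(codons, sample(code$stop_codons, 1L))
    sequence_record(sprintf("random_cds_%d", seed),
                    paste(codons, collapse = ""))
  })
}
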