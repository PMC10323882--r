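code <- genetic_code()

# identical state tables with generic (tie-free) frequencies
identical_pair <- function(seed = 21) sample_state_pair(seed = seed, kappa = 0)

# surgically set one family's frequencies in a table's rel_freq_aa
set_family <- function(table, codons, freqs) {
  table$rel_freq_aa[codons] <- freqs
  table
}

test_that("identical tables with tie-free frequencies give the identity mapping", {
  pair <- identical_pair()
  m <- build_codon_mapping(pair$source, pair$target, design_config(delta = 0), code)
  expect_identical(unname(m$map), names(m$map))
  expect_length(m$maintained, 61)
  expect_identical(mapping_summary(m)$codon_types_changed, 0L)
  expect_identical(mapping_summary(m)$percent_changed, 0)
})

test_that("a two-codon family with crossed frequencies swaps its codons", {
  pair <- identical_pair()
  src <- set_family(pair$source, c("AAA", "AAG"), c(0.8, 0.2))
  tgt <- set_family(pair$target, c("AAA", "AAG"), c(0.3, 0.7))
  m <- build_codon_mapping(src, tgt, design_config(delta = 0), code)
  expect_identical(unname(m$map["AAA"]), "AAG")   # |0.7-0.8| = 0.1 beats 0.5
  expect_identical(unname(m$map["AAG"]), "AAA")   # |0.3-0.2| = 0.1 beats 0.5
  expect_equal(unname(m$match_error[c("AAA", "AAG")]), c(0.1, 0.1))
})

test_that("the mapping is synonymous, deterministic and argmin-optimal", {
  for (seed in c(31, 32, 33)) {
    pair <- sample_state_pair(seed = seed, kappa = 1)
    m1 <- build_codon_mapping(pair$source, pair$target, design_config(), code)
    m2 <- build_codon_mapping(pair$source, pair$target, design_config(), code)
    expect_identical(m1$map, m2$map)
    f_s <- pair$source$rel_freq_aa
    f_t <- pair$target$rel_freq_aa
    for (c0 in code$sense_codons) {
      expect_identical(code$codon_to_aa[[m1$map[[c0]]]], code$codon_to_aa[[c0]])
      fam <- fam_of(c0, code)
      expect_lte(m1$match_error[[c0]],
                 min(abs(f_t[fam] - f_s[[c0]])) + 1e-15)
    }
  }
})

test_that("delta forces maintenance; undefined frequencies name the codon", {
  pair <- identical_pair()
  src <- set_family(pair$source, c("AAA", "AAG"), c(0.5625, 0.4375))
  tgt <- set_family(pair$target, c("AAA", "AAG"), c(0.4375, 0.5625))
  # at delta 0 the two codons cross-match (error 0 beats 0.125)...
  m0 <- build_codon_mapping(src, tgt, design_config(delta = 0), code)
  expect_identical(unname(m0$map["AAA"]), "AAG")
  # ...a delta of 0.125 keeps them in place
  m1 <- build_codon_mapping(src, tgt, design_config(delta = 0.125), code)
  expect_identical(unname(m1$map["AAA"]), "AAA")
  expect_true(all(c("AAA", "AAG") %in% m1$maintained))

  broken <- pair$source
  broken$rel_freq_aa["GCT"] <- NA_real_
  expect_error(build_codon_mapping(broken, pair$target, design_config(), code),
               "GCT")
})

test_that("tie-breaking is lexicographic by default, nucleotide-aware on request", {
  pair <- identical_pair()
  # six-codon Leu family: CTA and TTA sit at the exact same (binary-exact)
  # distance 0.25 from TTG's source frequency 0.5; CTA wins lexicographically,
  # TTA by fewest nucleotide changes (1 vs 2 substitutions from TTG)
  src <- set_family(pair$source, c("CTA", "CTC", "CTG", "CTT", "TTA", "TTG"),
                    c(0.125, 0.125, 0.125, 0.125, 0, 0.5))
  tgt <- set_family(pair$target, c("CTA", "CTC", "CTG", "CTT", "TTA", "TTG"),
                    c(0.25, 0, 0, 0, 0.75, 0))
  m_lex <- build_codon_mapping(src, tgt, design_config(tie_break = "lexicographic"),
                               code)
  expect_identical(unname(m_lex$map["TTG"]), "CTA")
  m_nt <- build_codon_mapping(src, tgt,
                              design_config(tie_break = "min_nucleotide_changes"),
                              code)
  expect_identical(unname(m_nt$map["TTG"]), "TTA")
})

test_that("recoding preserves the protein and reports exact change statistics", {
  m <- codon_mapping(local({
    map <- stats::setNames(code$sense_codons, code$sense_codons)
    map["CTG"] <- "TTG"
    map
  }), code = code)
  res <- recode_sequence(sequence_record("g", "ATGCTG"), m)
  expect_identical(res$recoded$seq, "ATGTTG")
  expect_identical(res$positions_changed, 1L)
  expect_identical(res$nt_substitutions, 1)
  expect_identical(translate_cds(res$recoded, code), "ML")

  idm <- codon_mapping(stats::setNames(code$sense_codons, code$sense_codons),
                       code = code)
  cds <- random_valid_cds(80, 44, code, terminal_stop = TRUE)
  res <- recode_sequence(cds, idm, id_suffix = "")
  expect_identical(res$recoded$seq, cds$seq)
  expect_identical(res$positions_changed, 0L)
})

test_that("terminal stop codons are never remapped", {
  pair <- sample_state_pair(seed = 51, kappa = 1)
  m <- build_codon_mapping(pair$source, pair$target, design_config(), code)
  cds <- random_valid_cds(60, 52, code, terminal_stop = TRUE)
  res <- recode_sequence(cds, m)
  n <- nchar(cds$seq)
  expect_identical(substr(res$recoded$seq, n - 2, n), substr(cds$seq, n - 2, n))
})

test_that("protein preservation holds over random mappings and sequences", {
  for (seed in 1:25) {
    pair <- sample_state_pair(seed = 100 + seed, kappa = 1)
    m <- build_codon_mapping(pair$source, pair$target, design_config(), code)
    cds <- random_valid_cds(60, 200 + seed, code,
                            terminal_stop = seed %% 2 == 0)
    res <- recode_sequence(cds, m)
    expect_identical(translate_cds(res$recoded, code), translate_cds(cds, code))
    expect_identical(nchar(res$recoded$seq), nchar(cds$seq))
  }
})

test_that("recoding an already-recoded sequence follows the mapping's image", {
  pair <- sample_state_pair(seed = 61, kappa = 1)
  m <- build_codon_mapping(pair$source, pair$target, design_config(), code)
  cds <- random_valid_cds(100, 62, code)
  once <- recode_sequence(cds, m)
  twice <- recode_sequence(once$recoded, m)
  # positions that moved again are exactly those whose image is itself remapped
  c1 <- split_codons_chr(once$recoded$seq)
  c2 <- split_codons_chr(twice$recoded$seq)
  remapped_images <- names(m$map)[m$map != names(m$map)]
  expect_identical(which(c1 != c2), which(c1 %in% remapped_images))

  # an idempotent mapping makes the second pass a no-op: keep only the
  # assignments whose image is a fixed point of the original mapping
  img <- unname(m$map)
  keep <- unname(m$map[img]) == img
  idem <- local({
    out <- stats::setNames(names(m$map), names(m$map))
    out[keep] <- img[keep]
    codon_mapping(out, code = code)
  })
  expect_identical(unname(idem$map[unname(idem$map)]), unname(idem$map))
  a <- recode_sequence(cds, idem)
  b <- recode_sequence(a$recoded, idem)
  expect_identical(b$recoded$seq, a$recoded$seq)
})

test_that("mapping summaries count changed codon types with rounded percent", {
  expect_identical(mapping_summary(make_shifted_mapping(0, code))$percent_changed, 0)
  s50 <- mapping_summary(make_shifted_mapping(50, code))
  expect_identical(s50$codon_types_changed, 50L)
  expect_identical(s50$percent_changed, 82)
  s59 <- mapping_summary(make_shifted_mapping(59, code))
  expect_identical(s59$codon_types_changed, 59L)
  expect_identical(s59$percent_changed, 97)
  expect_identical(sum(s50$per_family$n_changed), 50L)
  expect_identical(sum(s50$per_family$family_size), 61L)
})

test_that("delta calibration finds the smallest workable tolerance, monotonically", {
  pair <- sample_state_pair(seed = 71, kappa = 1)
  f_s <- pair$source$rel_freq_aa
  f_t <- pair$target$rel_freq_aa
  disc <- abs(f_t - f_s)
  expect_equal(calibrate_delta(pair$source, pair$target, 61,
                               design_config(), code), max(disc))
  deltas <- vapply(c(10, 20, 30, 40, 50, 61), function(k)
    calibrate_delta(pair$source, pair$target, k, design_config(), code), 0)
  expect_true(all(diff(deltas) >= 0))
  for (k in c(10, 40)) {
    d <- calibrate_delta(pair$source, pair$target, k, design_config(), code)
    m <- build_codon_mapping(pair$source, pair$target,
                             design_config(delta = d), code)
    expect_gte(length(m$maintained), k)
    smaller <- max(c(0, disc[disc < d]))
    if (smaller < d) {
      m2 <- build_codon_mapping(pair$source, pair$target,
                                design_config(delta = smaller), code)
      expect_lt(length(m2$maintained), k)
    }
  }
  expect_error(calibrate_delta(pair$source, pair$target, 1,
                               design_config(), code), "maintained_target")
})

test_that("sequence diffs reconstruct the substitution table", {
  a <- sequence_record("a", "ATGCTG")
  expect_identical(diff_codons(a, a, code)$n_positions_changed, 0L)
  d <- diff_codons(a, sequence_record("b", "ATGTTG"), code)
  expect_identical(d$positions$index, 1L)
  expect_identical(d$positions$codon_a, "CTG")
  expect_identical(d$positions$codon_b, "TTG")
  expect_true(d$consistent)
  expect_identical(d$nt_substitutions, 1)

  expect_error(diff_codons(a, sequence_record("c", "ATGCTGCTG"), code), "lengths")
  expect_error(diff_codons(a, sequence_record("d", "ATGATG"), code),
               "not synonymous")
})

test_that("diffing a recoded sequence against its input recovers the mapping", {
  for (seed in c(81, 82, 83)) {
    pair <- sample_state_pair(seed = seed, kappa = 1)
    m <- build_codon_mapping(pair$source, pair$target, design_config(), code)
    cds <- random_valid_cds(150, seed + 10, code)
    res <- recode_sequence(cds, m)
    d <- diff_codons(cds, res$recoded, code)
    expect_true(d$consistent)
    present <- intersect(names(d$inferred_mapping), names(m$map))
    expect_identical(d$inferred_mapping[present], m$map[present])
    expect_identical(d$n_positions_changed, res$positions_changed)
  }
})

test_that("mapping TSV round-trips the design and its provenance", {
  pair <- sample_state_pair(seed = 91, kappa = 0.9)
  m <- build_codon_mapping(pair$source, pair$target,
                           design_config(delta = 0.02), code)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mapping_table(m, path, pair$source, pair$target)
  back <- read_mapping_table(path, code)
  expect_identical(back$map, m$map)
  expect_identical(back$maintained, m$maintained)
  expect_equal(back$match_error, m$match_error, tolerance = 1e-12)
  expect_identical(back$config$delta, 0.02)
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  expect_identical(nrow(df), 61L)
})

test_that("crafted mappings reject non-synonymous or single-family remaps", {
  map <- stats::setNames(code$sense_codons, code$sense_codons)
  bad <- map; bad["AAA"] <- "TGG"
  expect_error(codon_mapping(bad, code = code), "synonymous|single-codon")
  bad2 <- map; bad2["ATG"] <- "ATG"; bad2["AAA"] <- "GGG"
  expect_error(codon_mapping(bad2, code = code), "not synonymous")
})
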