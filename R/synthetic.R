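#' Sample a synthetic pair of state codon-usage tables
#'
#' Generates two fully normalized codon-usage tables playing the role of
#' the state-specific gene-set tables (e.g. proliferation- and
#' differentiation-specific sets), with a single divergence dial. For each
#' synonym family of size `k`, the source frequencies are a symmetric
#' Dirichlet(`alpha`) draw `S`; an independent draw `Q` is mixed in to give
#' the target: `T = (1 - kappa) * S + kappa * Q`. Divergence is thus a
#' convex mixture, not a permutation, so `kappa` interpolates smoothly
#' from identical states (`kappa = 0`: `T == S` to machine precision) to
#' independent states (`kappa = 1`). Single-codon families have frequency
#' 1 in both states always.
#'
#' Global frequencies are derived assuming the generator's uniform
#' amino-acid composition: `global_freq = rel_freq_aa / n_amino_acids`.
#'
#' @param seed integer seed; the draw is deterministic given
#'   `(seed, kappa, alpha)` (Mersenne-Twister, no global RNG state leaks).
#' @param kappa divergence in `[0, 1]` (default 0.8, a strongly divergent
#'   pair as used for direction benchmarks).
#' @param alpha Dirichlet concentration (> 0, default 1 = uniform
#'   simplex); small values stress near-degenerate frequencies.
#' @param code a [genetic_code()].
#' @return Object of class `state_pair`: list with `source`, `target`
#'   ([codon_usage_table()]s), `kappa`, `alpha`, `seed`.
#' @examples
#' pair <- sample_state_pair(seed = 1, kappa = 0)
#' identical(pair$source$rel_freq_aa, pair$target$rel_freq_aa)  # TRUE
#' @export
sample_state_pair <- function(seed, kappa = 0.8, alpha = 1,
                              code = genetic_code()) {
  kappa <- cs_assert_scalar_number(kappa, "kappa", min = 0, max = 1)
  alpha <- cs_assert_scalar_number(alpha, "alpha", min = 1e-12)
  sense <- code$sense_codons
  rel_s <- stats::setNames(rep(NA_real_, length(sense)), sense)
  rel_t <- rel_s
  cs_with_seed(seed, {
    for (aa in names(code$families)) {   # alphabetical: fixed draw order
      fam <- code$families[[aa]]
      k <- length(fam)
      if (k == 1L) {
        rel_s[fam] <- 1
        rel_t[fam] <- 1
        next
      }
      s <- stats::rgamma(k, shape = alpha)
      s <- s / sum(s)
      q <- stats::rgamma(k, shape = alpha)
      q <- q / sum(q)
      rel_s[fam] <- s
      rel_t[fam] <- (1 - kappa) * s + kappa * q
    }
  })
  n_aa <- length(code$families)
  mk <- function(rel, label) codon_usage_table(
    rel_freq_aa = rel, global_freq = rel / n_aa,
    source_label = label, code = code)
  structure(list(
    source = mk(rel_s, sprintf("synthetic_source(seed=%d,kappa=%g,alpha=%g)",
                               as.integer(seed), kappa, alpha)),
    target = mk(rel_t, sprintf("synthetic_target(seed=%d,kappa=%g,alpha=%g)",
                               as.integer(seed), kappa, alpha)),
    kappa = kappa, alpha = alpha, seed = as.integer(seed)
  ), class = "state_pair")
}

#' @export
print.state_pair <- function(x, ...) {
  l1 <- mean_family_l1(x$source, x$target)
  cat("<state_pair> seed=", x$seed, " kappa=", x$kappa, " alpha=", x$alpha,
      "  mean per-family L1 divergence=", round(l1, 4), "\n", sep = "")
  invisible(x)
}

#' Mean per-family L1 distance between two tables
#'
#' The divergence/recovery metric: for each synonym family, the L1
#' distance between the two `rel_freq_aa` sub-vectors; averaged over all
#' families (single-codon families contribute 0).
#'
#' @param a,b [codon_usage_table()]s with `rel_freq_aa` populated.
#' @param code a [genetic_code()].
#' @return Non-negative real.
#' @export
mean_family_l1 <- function(a, b, code = genetic_code()) {
  fa <- usage_vector(a, "rel_freq_aa")
  fb <- usage_vector(b, "rel_freq_aa")
  mean(vapply(code$families, function(fam) sum(abs(fa[fam] - fb[fam])), 0))
}

#' Sample a coding sequence codon-by-codon from a usage table
#'
#' Generates a strictly valid CDS with the statistical structure the
#' adaptation analysis assumes: amino acids drawn uniformly (or taken from
#' a given protein), each codon drawn from its family's per-amino-acid
#' frequencies in `table`.
#'
#' @param protein amino-acid string to encode; if missing, a random
#'   protein of `protein_length` uniform draws over the 20 amino acids.
#' @param protein_length number of codons when `protein` is missing.
#' @param table a [codon_usage_table()] with `rel_freq_aa` defined for
#'   every amino acid used.
#' @param seed integer seed (deterministic draw).
#' @param append_stop append a uniformly drawn stop codon (default
#'   `FALSE`).
#' @param id record id (default derived from the seed).
#' @param code a [genetic_code()].
#' @return A [sequence_record()].
#' @examples
#' pair <- sample_state_pair(seed = 3, kappa = 0.5)
#' gene <- sample_cds(protein_length = 100, table = pair$source, seed = 4)
#' nchar(gene$seq)  # 300
#' @export
sample_cds <- function(protein_length = NULL, table, seed, append_stop = FALSE,
                       protein = NULL, id = NULL, code = genetic_code()) {
  if (!inherits(table, "codon_usage_table")) cs_stop("table must be a codon_usage_table")
  rel <- usage_vector(table, "rel_freq_aa")
  id <- id %||% sprintf("synthetic_cds_seed%d", as.integer(seed))
  codons <- cs_with_seed(seed, {
    if (is.null(protein)) {
      if (is.null(protein_length) || protein_length < 1)
        cs_stop("provide protein or a positive protein_length")
      aa_seq <- sample(code$amino_acids, protein_length, replace = TRUE)
    } else {
      aa_seq <- strsplit(toupper(protein), "", fixed = TRUE)[[1]]
      bad <- setdiff(unique(aa_seq), code$amino_acids)
      if (length(bad) > 0L)
        cs_stop("protein contains symbols outside the amino-acid alphabet: ",
                paste(bad, collapse = ", "))
    }
    out <- character(length(aa_seq))
    for (aa in sort(unique(aa_seq))) {   # fixed per-family draw order
      fam <- code$families[[aa]]
      p <- rel[fam]
      if (anyNA(p)) cs_stop("rel_freq_aa undefined for family ", aa)
      idx <- which(aa_seq == aa)
      out[idx] <- if (length(fam) == 1L) fam else
        sample(fam, length(idx), replace = TRUE, prob = p)
    }
    if (append_stop) out <- c(out, sample(code$stop_codons, 1L))
    out
  })
  sequence_record(id, paste(codons, collapse = ""))
}

#' Generate a benchmark bundle with known ground truth
#'
#' The full synthetic study: a divergent state pair, genes sampled
#' codon-by-codon from each state's table, and the exact truth — the
#' sampling tables themselves and the delta-0 frequency-matching mapping
#' between them. The manifest records every parameter and seed, so the
#' bundle regenerates bit-for-bit.
#'
#' Per-gene seeds are derived deterministically from the bundle seed
#' (`seed + 1000 + i` for source genes, `seed + 2000 + i` for target
#' genes), keeping every seed an explicit 32-bit integer.
#'
#' @param seed integer bundle seed.
#' @param kappa,alpha passed to [sample_state_pair()].
#' @param n_genes_per_state genes sampled from each state (default 10).
#' @param gene_length codons per gene (default 300).
#' @param code a [genetic_code()].
#' @return Object of class `benchmark_bundle`: list with `state_pair`,
#'   `genes` (list of `sequence_record`), `gene_states` (named
#'   `"source"`/`"target"` labels), `truth_mapping`, `manifest`.
#' @export
make_benchmark <- function(seed, kappa = 0.8, n_genes_per_state = 10,
                           gene_length = 300, alpha = 1,
                           code = genetic_code()) {
  n_genes_per_state <- as.integer(
    cs_assert_scalar_number(n_genes_per_state, "n_genes_per_state", min = 1))
  gene_length <- as.integer(
    cs_assert_scalar_number(gene_length, "gene_length", min = 1))
  pair <- sample_state_pair(seed, kappa = kappa, alpha = alpha, code = code)
  genes <- list()
  gene_states <- character(0)
  for (state in c("source", "target")) {
    offset <- if (state == "source") 1000L else 2000L
    tab <- pair[[state]]
    for (i in seq_len(n_genes_per_state)) {
      g <- sample_cds(protein_length = gene_length, table = tab,
                      seed = as.integer(seed) + offset + i,
                      id = sprintf("%s_gene_%03d", state, i), code = code)
      genes[[length(genes) + 1L]] <- g
      gene_states[g$id] <- state
    }
  }
  truth_mapping <- build_codon_mapping(pair$source, pair$target,
                                       design_config(delta = 0), code)
  manifest <- list(seed = as.integer(seed), kappa = kappa, alpha = alpha,
                   n_genes_per_state = n_genes_per_state,
                   gene_length = gene_length,
                   rng = "Mersenne-Twister/Inversion/Rejection",
                   generator = "sample_state_pair + sample_cds")
  structure(list(state_pair = pair, genes = genes, gene_states = gene_states,
                 truth_mapping = truth_mapping, manifest = manifest),
            class = "benchmark_bundle")
}

#' @export
print.benchmark_bundle <- function(x, ...) {
  cat("<benchmark_bundle> seed=", x$manifest$seed, " kappa=", x$manifest$kappa,
      ": ", length(x$genes), " genes (", x$manifest$gene_length,
      " codons each), truth mapping with ",
      sum(x$truth_mapping$map != names(x$truth_mapping$map)),
      " remapped codon types\n", sep = "")
  invisible(x)
}

#' Write a benchmark bundle to a directory
#'
#' Layout: `states/source.tsv`, `states/target.tsv` (codon-table TSV),
#' `genes.fasta`, `truth_mapping.tsv`, `manifest.json`. Replaying
#' [make_benchmark()] with the manifest parameters reproduces every file
#' byte-for-byte.
#'
#' @param bundle a [make_benchmark()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bundle, dir) {
  if (!inherits(bundle, "benchmark_bundle")) cs_stop("bundle must be a benchmark_bundle")
  dir.create(file.path(dir, "states"), recursive = TRUE, showWarnings = FALSE)
  write_codon_table(bundle$state_pair$source, file.path(dir, "states", "source.tsv"))
  write_codon_table(bundle$state_pair$target, file.path(dir, "states", "target.tsv"))
  write_fasta(bundle$genes, file.path(dir, "genes.fasta"))
  write_mapping_table(bundle$truth_mapping, file.path(dir, "truth_mapping.tsv"),
                      source_table = bundle$state_pair$source,
                      target_table = bundle$state_pair$target)
  manifest <- c(bundle$manifest, list(gene_states = as.list(bundle$gene_states)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
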