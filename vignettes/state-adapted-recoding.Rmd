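---
title: "State-adapted codon usage: scoring and synonymous recoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{State-adapted codon usage: scoring and synonymous recoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonstate)
```

## The problem

Synonymous codons are not used interchangeably. Cells in different
states — proliferating versus differentiated is the canonical contrast —
express different tRNA repertoires, and the genes specifically expressed
in each state show codon-usage frequencies matched to that repertoire. A
gene whose codon usage fits one state's translation program may be
translated with different speed and co-translational folding when the
cell switches state, even though its protein sequence is unchanged.

`codonstate` implements the two computational halves of studying this:

1. **Scoring adaptation.** How well does a gene's codon usage fit a
   state's usage table? We summarise it as the squared Pearson
   correlation of per-codon frequencies.
2. **Recoding.** Design a synonymous variant of the gene whose codon
   usage is adapted to a *different* state, by cross-state frequency
   matching, so the protein is untouched while the codon-level signal is
   moved from one translation program to the other.

A seeded synthetic-data generator supplies state table pairs and
codon-sampled genes with known ground truth, so every stage is testable
at desk scale without any external download.

## Codon-usage tables and their two normalizations

For a gene set (or a single CDS) we count codons over the 61 sense
codons of the standard genetic code; the 3 stop codons are counted
separately and excluded from all frequencies, so the design universe is
exactly the 61 sense codons. Two normalizations are carried side by
side, because "frequency of use" is genuinely ambiguous in the
literature:

* per-amino-acid relative frequency,
  $f^{\mathrm{aa}}(c) = n_c \big/ \sum_{c' \in \mathrm{fam}(c)} n_{c'}$,
  which sums to 1 within each synonym family; and
* global frequency, $f^{\mathrm{glob}}(c) = n_c / N$, with $N$ the total
  sense-codon count (fraction scale; per-1000 dialects are accepted on
  read and rescaled).

Neither is asserted as "the" frequency: every operation takes a
`normalization` argument. The per-family normalization gets a
`pseudocount` (default 0 — gene-scale inputs of hundreds of codons
rarely leave a family empty, and the unsmoothed table is exactly the
observed usage; a family with zero observations and zero pseudocount is
reported as undefined rather than silently invented).

## The adaptation statistic

Given a gene table $g$ and a state table $s$, each codon contributes a
point $(g(c), s(c))$ and

$$R^2 = \mathrm{cor}(g, s)^2$$

over the chosen codon set. $R^2$ rather than $r$ because the per-codon
scatter against a fitted line is the field's standard display; the
square is symmetric in its arguments and invariant to positive affine
rescaling, so table dialects (fractions, per-1000) cannot change the
answer.

Choices a user controls, and the defaults:

* **Normalization for $R^2$: `global_freq`.** Under `rel_freq_aa` the
  two single-codon families (ATG for Met, TGG for Trp) are constant 1.0
  in every table; they carry no information and would only distort the
  correlation, so under that normalization they are always dropped
  (with the drop reported in `n_points` / `dropped_codons`). Under
  `global_freq` they are ordinary points and the default
  `codon_set = "all_61"` keeps them; `"multi_codon_families_only"` is
  available for sensitivity checks.
* Codons undefined in either table are dropped pairwise and counted.
* Fewer than 3 usable points, or a zero-variance vector, is an error
  (a degenerate-statistics error, distinct from input errors — the CLI
  maps them to exit codes 3 and 2 respectively), never an `NA` that
  could flow silently into a comparison.

## The cross-state frequency-matching design

The design input is a *source* state table (where the gene's usage is at
home) and a *target* state table (where we want it to be at home), in a
common normalization. For each sense codon $c$:

* if $|f_T(c) - f_S(c)| \le \delta$, the codon is **maintained** — its
  frequency of use is already similar in the two states;
* otherwise $c$ is mapped to
  $\arg\min_{c' \in \mathrm{fam}(c)} |f_T(c') - f_S(c)|$ — the synonym
  whose target-state frequency best approximates the original codon's
  source-state frequency. The source codon itself is always a
  candidate, so a codon that is its own argmin stays put even with
  $\delta = 0$.

Design decisions, made once and documented here because the procedure
leaves them genuinely open:

* **Matching space defaults to `rel_freq_aa`.** Frequencies are only
  commensurable across states within a synonym family; global
  frequencies mix in amino-acid composition, which no synonymous design
  can alter. The `global_freq` option exists for sensitivity sweeps.
* **The map is per codon type, not per position.** A single 61-entry
  outcome is what a substitution table between a wildtype and a
  redesigned sequence expresses; nothing requires injectivity within a
  family, and none is imposed (two source codons may share a target).
* **$\delta$ defaults to 0.** "Similar frequency" has no canonical
  numeric value; instead of guessing, `calibrate_delta()` inverts the
  design — it scans the sorted cross-state discrepancies and returns
  the smallest $\delta$ at which the built mapping maintains at least a
  requested number of codon types. Because self-argmin codons are
  maintained regardless of $\delta$, the calibration counts maintained
  codons by actually building the mapping at each candidate, and the
  result is monotone in the target.
* **Ties break lexicographically** by default (deterministic and
  auditable); `min_nucleotide_changes` is offered as the biologically
  conservative alternative (fewest substitutions, then lexicographic).
  With continuous synthetic frequencies ties have probability zero;
  they matter for hand-built or heavily rounded tables.
* **Stop codons are never remapped.** The design covers sense codons;
  a terminal stop passes through recoding verbatim.
* The summary percentage uses nearest-integer rounding: a design
  rewriting 50 of 61 codon types reports 82% changed, one rewriting 59
  of 61 reports 97%.

Because the mapping is synonymous by construction,
`translate(recode(x)) == translate(x)` for every strictly valid CDS;
`recode_sequence()` asserts it anyway, and the objective
$\sum_i |f_T(c'_i) - f_S(c_i)|$ is separable over positions, so the
per-codon argmin is also the global sequence-level optimum — a fact the
test suite verifies by full enumeration on short peptides.

## The synthetic-data generator

`sample_state_pair(seed, kappa, alpha)` emulates a pair of
state-specific usage tables. For each synonym family of size $k$ it
draws $S \sim \mathrm{Dirichlet}(\alpha \mathbf{1}_k)$ and an
independent $Q$ likewise, and sets

$$T = (1 - \kappa)\, S + \kappa\, Q .$$

The convex mixture (rather than a swap or permutation) makes $\kappa$
interpolate smoothly: $\kappa = 0$ gives identical states to machine
precision, $\kappa = 1$ independent states. Defaults: $\kappa = 0.8$
(a strongly divergent pair, the regime where direction benchmarks are
meaningful) and $\alpha = 1$ (uniform on the simplex; small $\alpha$
stress-tests near-degenerate frequencies and tie handling).

`sample_cds()` draws amino acids uniformly over the 20 (or encodes a
given protein) and each codon from its family's `rel_freq_aa` — exactly
the generative structure the adaptation statistic assumes. Global
frequencies of synthetic tables are derived as `rel_freq_aa / 20`,
consistent with the uniform composition. `make_benchmark()` packages a
state pair, genes sampled from each state, and the exact truth (the
sampling tables and the $\delta = 0$ mapping between them); the
manifest regenerates the bundle byte-for-byte.

What the generator does **not** emulate: real amino-acid composition
(a composition argument is accepted but uniform is the default), codon
autocorrelation along genes, GC-content gradients, gene-length
distributions, or any mechanistic layer (tRNA pools, ribosome kinetics,
co-translational folding). Passing tests therefore certify the
*algorithms* — counting, normalization, correlation, argmin matching,
calibration, diffing — under a clean generative model, not the
biological claim that any particular real gene is state-adapted.

All randomness is seeded explicitly (Mersenne-Twister with fixed normal
and sample kinds), the ambient RNG state is saved and restored around
every draw, and per-gene seeds are small deterministic offsets of the
bundle seed, so identical seeds give identical bytes across runs and
platforms.

## Numerical choices and degenerate inputs

* Family and global frequency sums are asserted to 1 within $10^{-9}$.
* Frequencies in TSV output are written with 15 significant digits, so
  tables round-trip to within $10^{-12}$; external two-column tables
  are renormalized per family (relative) or to unit sum (global) to
  absorb published rounding.
* A CDS is *strictly valid* iff its length is a multiple of 3, it has
  no internal stop and no ambiguous symbol; a start codon and terminal
  stop are reported but not required. Invalid records fail loudly;
  the opt-in skip-invalid mode logs every dropped record, because
  silent loss while building a gene-set table would bias frequencies.
* Validation never throws; translation and recoding throw naming the
  offending codon index.

## Problem sizes used by the checks

The shipped verification uses sizes chosen to give comfortable
statistical margins at interactive cost: 100 seeded state pairs for
oracle agreement, 1000 mapping/sequence pairs for protein preservation,
10,000 sampled codons for table recovery (mean per-family L1 error,
averaged over all 20 families, typically 0.03–0.05 against a 0.05
bound), and 100 genes of 600 codons at $\kappa = 0.8$ for the
adaptation direction rate. The whole suite runs in well under a minute.

## Limitations

* Single-objective design: no GC clamps, restriction-site avoidance,
  mRNA-structure awareness, ramp/5'-end special-casing or per-position
  context rules. The output is a starting point for such constraints,
  not a replacement.
* No codon-adaptation indices (CAI, tAI, ENC, codon-pair bias) and no
  statistical test on $R^2$ differences; the package quantifies and
  rewrites frequency fit, nothing more.
* Standard genetic code by default; the code object is injectable, so
  other NCBI tables work, but all defaults and the 61-codon universe
  assume table 1.
* Which normalization a published usage table reports is often
  undocumented; when reproducing external analyses, sweep both
  (`rel_freq_aa`, `global_freq`) and both codon sets and report which
  configuration you used — the report objects carry that provenance for
  exactly this reason.
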