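# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom withr with_seed
cs_with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code,
                   .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion",
                   .rng_sample_kind = "Rejection")
}

# input errors (CLI exit 2)
cs_stop <- function(..., class = "cs_input_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# degenerate-statistics errors, e.g. zero-variance R^2 (CLI exit 3)
cs_stop_degenerate <- function(...) {
  cs_stop(..., class = "cs_degenerate_error")
}

cs_assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max)
    cs_stop(name, " must be a single finite number in [", min, ", ", max, "]")
  as.numeric(x)
}

cs_match_arg <- function(arg, choices, name) {
  if (!is.character(arg) || length(arg) != 1L || !(arg %in% choices))
    cs_stop(name, " must be one of: ", paste(choices, collapse = ", "))
  arg
}

# split a DNA string into consecutive triplets (incomplete tail dropped)
split_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

gc_fraction <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  mean(chars %in% c("G", "C"))
}

hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}
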