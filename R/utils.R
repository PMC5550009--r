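#' Reverse-complement character sequences
#'
#' Thin vectorised wrapper used throughout the package; sequences are plain
#' uppercase character strings over A/C/G/T/N.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp(c("ACGT", "AAAC"))
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(b) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[b])
}

#' Derive independent sub-seeds from one master seed
#'
#' One integer seed drives every stochastic stage; stages draw their own
#' sub-seed so inserting or removing a stage does not perturb the others.
#'
#' @param seed Master integer seed.
#' @param n Number of sub-seeds.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

# uniform integer draw from [lo, hi]; safe when lo == hi (unlike sample())
sample_range <- function(lo, hi) {
  if (lo >= hi) return(as.integer(lo))
  as.integer(lo + sample.int(hi - lo + 1L, 1L) - 1L)
}

assert_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1]", name))
  }
  invisible(x)
}

#' Count mismatching positions between two equal-length strings
#' @noRd
string_mismatches <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  which(ra != rb)
}

# fast per-position character access for a vector of equal-length strings
str_char_at <- function(x, at) {
  substring(x, at, at)
}
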