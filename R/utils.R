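#' Reverse complement of DNA strings
#'
#' Vectorised over a character vector. Complements the IUPAC alphabet (case
#' preserved for upper-case input; `N` maps to `N`) and reverses each string.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp_dna(c("ACGT", "AANT"))
revcomp_dna <- function(x) {
  stringi::stri_reverse(chartr("ACGTUMRWSYKVHDBNacgtumrwsykvhdbn",
                               "TGCAAKYWSRMBDHVNtgcaakywsrmbdhvn", x))
}

#' All k-mers of a sequence
#'
#' Returns the `nchar(seq) - k + 1` substrings of length `k` in order, or a
#' zero-length vector when the sequence is shorter than `k`.
#'
#' @param seq A single DNA string.
#' @param k K-mer length.
#' @return Character vector of k-mers.
#' @export
kmerize <- function(seq, k) {
  n <- nchar(seq) - k + 1L
  if (n < 1L) return(character(0))
  starts <- seq_len(n)
  substring(seq, starts, starts + k - 1L)
}

# Round half away from zero (symmetric for gaps vs overlaps).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# TRUE for strings containing only A/C/G/T.
is_acgt <- function(x) !grepl("[^ACGT]", x) & nzchar(x)

flip_orient <- function(o) unname(c(`+` = "-", `-` = "+")[o])

# Draw n uniform random DNA bases as one string each of length len (vectorised
# over len).
random_dna <- function(len) {
  vapply(len, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

with_opt_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}
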