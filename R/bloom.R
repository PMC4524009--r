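#' @useDynLib scafflink, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
NULL

bloom_sizing <- function(n_expected, p) {
  n <- max(n_expected, 1)
  m <- ceiling(-n * log(p) / log(2)^2)
  h <- max(1L, as.integer(round(m / n * log(2))))
  list(m = m, h = h)
}

new_bloom_filter <- function(bits, m, h, k, p, n_inserted, n_expected) {
  structure(list(bits = bits, m = m, num_hashes = h, k = k, target_fpr = p,
                 n_inserted = n_inserted, n_expected = n_expected),
            class = "bloom_filter")
}

#' Build a Bloom filter over the k-mers of an assembly
#'
#' Shreds every contig into k-mers on both strands and inserts them into a
#' Bloom filter sized from the exact expected element count
#' `2 * sum(max(0, length - k + 1))` and the requested false-positive rate
#' `p` by the standard optimal-sizing formulas. K-mers containing non-ACGT
#' symbols are skipped. Inserted keys always query `TRUE` (no false
#' negatives); absent keys query `TRUE` with probability about `p`.
#'
#' @param contigs Contig tibble (`id`, `seq`, `length`) from
#'   [read_assembly()].
#' @param k K-mer length (>= 4).
#' @param p Target false-positive rate, in (0, 0.5).
#' @return A `bloom_filter` object.
#' @export
#' @examples
#' ctg <- tibble::tibble(id = "c1", seq = "AAAACCCC", length = 8L)
#' bf <- build_bloom(ctg, k = 4, p = 0.01)
#' kmer_query(bf, "GGGG")  # reverse complement of CCCC: TRUE
build_bloom <- function(contigs, k, p = 0.001) {
  stopifnot(k >= 4, p > 0, p < 0.5)
  n_expected <- 2 * sum(pmax(0, contigs$length - k + 1))
  if (n_expected == 0) stop("no k-mers to index (no contig of length >= k)")
  sz <- bloom_sizing(n_expected, p)
  bits <- bloom_bits_alloc(sz$m)
  n_ins <- 0
  for (s in contigs$seq) {
    km <- kmerize(s, k)
    km <- km[is_acgt(km)]
    if (length(km) == 0) next
    both <- c(km, revcomp_dna(km))
    bloom_insert_cpp(bits, sz$m, sz$h, both)
    n_ins <- n_ins + length(both)
  }
  new_bloom_filter(bits, sz$m, sz$h, k, p, n_ins, n_expected)
}

#' Build an exact k-mer set index
#'
#' Same membership contract as [build_bloom()] but backed by an exact set
#' (zero false positives). Used to bypass the probabilistic backend and as
#' the oracle it is compared against.
#'
#' @inheritParams build_bloom
#' @return An `exact_kmer_index` object.
#' @export
build_exact_index <- function(contigs, k) {
  stopifnot(k >= 4)
  if (!any(contigs$length >= k)) stop("no k-mers to index (no contig of length >= k)")
  km <- unlist(lapply(contigs$seq, kmerize, k = k), use.names = FALSE)
  km <- km[is_acgt(km)]
  structure(list(kmers = unique(c(km, revcomp_dna(km))), k = k),
            class = "exact_kmer_index")
}

#' Query a k-mer membership index
#'
#' @param index A `bloom_filter` or `exact_kmer_index`.
#' @param kmers Character vector of A/C/G/T k-mers of the index's `k`.
#' @return Logical vector: `TRUE` where the k-mer is (probably) present.
#' @export
kmer_query <- function(index, kmers) UseMethod("kmer_query")

#' @export
kmer_query.bloom_filter <- function(index, kmers) {
  if (length(kmers) == 0) return(logical(0))
  if (any(nchar(kmers) != index$k)) {
    stop("query k-mer length differs from index k = ", index$k)
  }
  bloom_query_cpp(index$bits, index$m, index$num_hashes, kmers)
}

#' @export
kmer_query.exact_kmer_index <- function(index, kmers) {
  if (length(kmers) == 0) return(logical(0))
  if (any(nchar(kmers) != index$k)) {
    stop("query k-mer length differs from index k = ", index$k)
  }
  kmers %in% index$kmers
}

#' @export
print.bloom_filter <- function(x, ...) {
  cat("<bloom_filter> k =", x$k, "| m =", format(x$m, big.mark = ","),
      "bits | h =", x$num_hashes, "| target FPR =", x$target_fpr,
      "|", format(x$n_inserted, big.mark = ","), "insertions\n")
  invisible(x)
}

BLOOM_MAGIC <- "SCFLBLOOM1"

#' Save / load a Bloom filter
#'
#' The sidecar file stores a magic string, version header (`m`, `h`, `k`,
#' `p`, insertion and sizing counts) and the bit array; bytes are
#' deterministic for a fixed build order. A loaded filter answers every
#' query identically to the saved one. `load_bloom()` refuses a file whose
#' `k` differs from `expect_k` so a reused filter can never silently
#' disagree with the run's k-mer length.
#'
#' @param filter A `bloom_filter`.
#' @param path File path for the binary sidecar.
#' @param expect_k If non-NULL, required `k` of the loaded filter.
#' @return `save_bloom()` returns `path` invisibly; `load_bloom()` returns
#'   the restored `bloom_filter`.
#' @export
save_bloom <- function(filter, path) {
  stopifnot(inherits(filter, "bloom_filter"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(BLOOM_MAGIC), con)
  writeBin(as.double(c(filter$m, filter$num_hashes, filter$k,
                       filter$target_fpr, filter$n_inserted,
                       filter$n_expected)), con, endian = "little")
  writeBin(filter$bits, con)
  invisible(path)
}

#' @rdname save_bloom
#' @export
load_bloom <- function(path, expect_k = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", nchar(BLOOM_MAGIC)))
  if (!identical(magic, BLOOM_MAGIC)) {
    stop("not a Bloom filter file (bad magic): ", path)
  }
  hdr <- readBin(con, "double", 6, endian = "little")
  if (length(hdr) != 6 || any(!is.finite(hdr))) {
    stop("corrupted Bloom filter header in ", path)
  }
  bits <- readBin(con, "raw", ceiling(hdr[1] / 8))
  if (length(bits) != ceiling(hdr[1] / 8)) {
    stop("truncated Bloom filter bit array in ", path)
  }
  if (!is.null(expect_k) && hdr[3] != expect_k) {
    stop("Bloom filter was built with k = ", hdr[3],
         " but this run uses k = ", expect_k)
  }
  new_bloom_filter(bits, hdr[1], as.integer(hdr[2]), as.integer(hdr[3]),
                   hdr[4], hdr[5], hdr[6])
}
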