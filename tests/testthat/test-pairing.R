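# Brute-force oracle for the number of candidate windows: enumerate starts.
count_windows_oracle <- function(L, d, t) {
  w <- 0L; n <- 0L
  while (w + d <= L) { n <- n + 1L; w <- w + t }
  n
}

test_that("candidate window counts match brute-force enumeration", {
  contigs <- contig_tbl(rand_genome(3000, seed = 3))
  idx <- build_exact_index(contigs, 15)
  cases <- expand.grid(L = c(999, 1000, 1001, 1057, 2500),
                       d = c(1000, 1300), t = c(1, 2, 7))
  for (i in seq_len(nrow(cases))) {
    L <- cases$L[i]; d <- cases$d[i]; t <- cases$t[i]
    reads <- tibble::tibble(id = "r", seq = substr(contigs$seq, 1, L))
    st <- extract_pairs(reads, idx, 15, d, t)
    expect_equal(attr(st, "n_candidates"), count_windows_oracle(L, d, t),
                 info = sprintf("L=%d d=%d t=%d", L, d, t))
  }
})

test_that("calc_gap reproduces the worked distance arithmetic", {
  expect_equal(calc_gap(4000, 2000, 1000, 385, 15), 2600)
  expect_equal(calc_gap(4000, 2000, 0, 1985, 15), 0)   # abutting
  # footprint 4400 at d = 4000: a 400 bp overlap
  expect_equal(calc_gap(4000, 2000, 0, 2385, 15), -400)
})

test_that("k-mer placement records strand, position and multiplicity", {
  c1 <- "ACGTTTGACCTGATCGGCTA"
  ctg <- contig_tbl(c(c1, paste0("TTTTTTTT", substr(c1, 1, 8))))
  # fake store holding the k-mers of interest
  fake_store <- structure(
    tibble::tibble(kmer_a = c("ACGTTTGA", revcomp_dna("CCTGATCG")),
                   kmer_b = c("GACCTGAT", "TCGGCTAx"), n_obs = 1L),
    k = 8L)
  pl <- place_kmers(ctg, 8, fake_store)
  fwd <- dplyr::filter(pl, kmer == "ACGTTTGA")
  # occurs in c1 (+) and as prefix of c2 (+): multiplicity 2
  expect_equal(sort(fwd$contig), c("c1", "c2"))
  expect_equal(unique(fwd$multiplicity), 2L)
  expect_equal(fwd$start[fwd$contig == "c1"], 0L)
  rc <- dplyr::filter(pl, kmer == revcomp_dna("CCTGATCG"))
  expect_equal(rc$strand, "-")
  expect_equal(rc$multiplicity, 1L)
  expect_equal(rc$start, 8L)  # CCTGATCG starts at 0-based 8 on the + strand
})

test_that("links accumulate planted junction pairs with exact gaps", {
  fx <- two_contig_fixture(len1 = 3000, len2 = 3000, gap = 10, seed = 21)
  d <- 4000; t <- 2
  # one read spanning the junction giving exactly 7 candidate windows
  s0 <- fx$junction - 2000  # 1-based read start
  read <- tibble::tibble(id = "r1",
                         seq = substr(fx$genome, s0, s0 + d + 12 - 1))
  ls <- pair_pipeline(fx$contigs, read, k = 15, d = d, t = t,
                      backend = "exact")
  expect_equal(nrow(ls$links), 1L)
  expect_equal(ls$links$n_links, 7L)           # 7 windows, all accepted
  expect_equal(ls$links$contig1, "c1")
  expect_equal(ls$links$orient1, "+")
  expect_equal(ls$links$orient2, "+")
  expect_equal(ls$links$mean_gap, 10)          # D = 3990 for every pair
  expect_equal(unique(ls$links$gaps[[1]]), 10L)
})

test_that("pairs on one contig and out-of-tolerance footprints are rejected", {
  # same-contig rejection: read wholly inside one contig
  fx <- two_contig_fixture(len1 = 3000, len2 = 3000, gap = 100, seed = 22)
  inside <- tibble::tibble(id = "r", seq = substr(fx$genome, 1, 1500))
  ls <- pair_pipeline(fx$contigs, inside, k = 15, d = 1000, t = 1,
                      backend = "exact")
  expect_equal(nrow(ls$links), 0L)
  expect_gt(ls$issues$counts$n[ls$issues$counts$reason == "same_contig"], 0)

  # planted 400 bp overlap: D = 4400 at d = 4000, e = 0.1 -> rejected
  # (the +/- 400 band excludes its own boundary)
  ov <- two_contig_fixture(len1 = 3000, len2 = 3000, gap = -400, seed = 23)
  s0 <- ov$junction - 2200
  read <- tibble::tibble(id = "r", seq = substr(ov$genome, s0, s0 + 4400))
  ls2 <- pair_pipeline(ov$contigs, read, k = 15, d = 4000, t = 1,
                       backend = "exact")
  expect_equal(nrow(ls2$links), 0L)
  rej <- ls2$issues$records
  expect_true(all(rej$distance[rej$reason == "out_of_tolerance"] == 4400))
  # at e just above 0.1 the same evidence is accepted
  st <- extract_pairs(read, build_exact_index(ov$contigs, 15), 15, 4000, 1)
  pl <- place_kmers(ov$contigs, 15, st)
  ls3 <- build_links(st, pl, ov$contigs, d = 4000, e = 0.101)
  expect_equal(nrow(ls3$links), 1L)
  expect_equal(ls3$links$mean_gap, -400)
})

test_that("issue-log arithmetic closes over all rejection reasons", {
  tr <- make_truth(40000, 4, c(50, 200), seed = 31, flip_prob = 0.5)
  pp <- preset_nanopore_r7()
  reads <- simulate_read_set(tr$genome, 120, 5000, params = pp, seed = 32)
  ls <- pair_pipeline(tr$contigs, reads, k = 15, d = 3000, t = 2)
  expect_equal(sum(ls$links$n_links) + sum(ls$issues$counts$n),
               ls$n_placed_obs)
  expect_equal(nrow(ls$issues$records), sum(ls$issues$counts$n))
})

test_that("reverse-complementing every read leaves the link set invariant", {
  tr <- make_truth(30000, 3, c(80, 120), seed = 41, flip_prob = 0.5)
  reads <- simulate_read_set(tr$genome, 40, 4000, params = NULL, seed = 42)
  fwd <- pair_pipeline(tr$contigs, reads, k = 15, d = 2000, t = 1,
                       backend = "exact")
  rc_reads <- dplyr::mutate(reads, seq = revcomp_dna(seq))
  rev <- pair_pipeline(tr$contigs, rc_reads, k = 15, d = 2000, t = 1,
                       backend = "exact")
  cols <- c("contig1", "orient1", "contig2", "orient2", "n_links", "mean_gap")
  expect_gt(nrow(fwd$links), 0)
  expect_equal(as.data.frame(fwd$links[cols]), as.data.frame(rev$links[cols]))
})

test_that("k-mer support fraction separates verbatim, noisy and random reads", {
  tr <- make_truth(30000, 2, c(100, 100), seed = 51)
  bf <- build_bloom(tr$contigs, 15, p = 0.001)
  verb <- simulate_read_set(tr$genome, 10, 3000, params = NULL, seed = 52)
  # keep reads fully inside contigs so every k-mer is indexed
  verb <- dplyr::mutate(verb, seq = substr(tr$contigs$seq[1], 1, 3000))
  expect_equal(profile_kmer_support(verb, bf, 15)$fraction, 1.0)

  set.seed(53)
  rand <- tibble::tibble(id = paste0("rr", 1:10),
                         seq = vapply(1:10, function(i) rand_genome(3000),
                                      character(1)))
  expect_lte(profile_kmer_support(rand, bf, 15)$fraction, 0.002)

  noisy <- simulate_read_set(tr$contigs$seq[1], 10, 3000,
                             params = preset_nanopore_r7(), seed = 54)
  fr <- vapply(c(13L, 15L, 17L), function(k) {
    profile_kmer_support(noisy, build_bloom(tr$contigs, k, 0.001), k)$fraction
  }, double(1))
  expect_true(all(fr > 0.002 & fr < 1))
  expect_true(all(diff(fr) < 0))  # support decreases with k

  none <- tibble::tibble(id = "n", seq = "NNNNNNNNNNNNNNNNNNNN")
  expect_true(is.na(profile_kmer_support(none, bf, 15)$fraction))
})
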