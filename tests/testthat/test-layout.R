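mk_links <- function(...) {
  rows <- list(...)
  tibble::tibble(
    contig1 = vapply(rows, `[[`, character(1), 1),
    orient1 = vapply(rows, `[[`, character(1), 2),
    contig2 = vapply(rows, `[[`, character(1), 3),
    orient2 = vapply(rows, `[[`, character(1), 4),
    n_links = as.integer(vapply(rows, `[[`, numeric(1), 5)),
    mean_gap = vapply(rows, `[[`, numeric(1), 6),
    gaps = replicate(length(rows), integer(0), simplify = FALSE))
}

test_that("neighbour selection honours the minimum-link and ratio guards", {
  expect_equal(select_neighbor(c(B = 10, C = 2), l = 5, a = 0.3), "B")
  expect_true(is.na(select_neighbor(c(B = 10, C = 4), l = 5, a = 0.3)))
  expect_true(is.na(select_neighbor(c(B = 4), l = 5, a = 0.3)))
  expect_true(is.na(select_neighbor(c(B = 7, C = 7), l = 5, a = 0.3)))  # tie
  expect_true(is.na(select_neighbor(stats::setNames(numeric(0), character(0)))))
  expect_equal(select_neighbor(c(B = 10, C = 3), l = 5, a = 0.3), "B")
})

test_that("a linked chain lays out in order with composed orientations", {
  ctg <- contig_tbl(c(rand_genome(900, seed = 1), rand_genome(800, seed = 2),
                      rand_genome(700, seed = 3)))
  links <- mk_links(list("c1", "+", "c2", "+", 8, 50),
                    list("c2", "+", "c3", "-", 9, 20))
  lay <- build_scaffolds(links, ctg, l = 5, a = 0.3)
  expect_equal(unique(lay$scaffold), "scaffold1")
  expect_equal(lay$contig, c("c1", "c2", "c3"))
  expect_equal(lay$orient, c("+", "+", "-"))
  expect_equal(lay$gap_to_next, c(50, 20, NA))
})

test_that("without links every contig is its own scaffold, longest first", {
  ctg <- contig_tbl(c(rand_genome(500), rand_genome(900), rand_genome(700)))
  lay <- build_scaffolds(mk_links(), ctg)
  expect_equal(nrow(lay), 3L)
  expect_equal(length(unique(lay$scaffold)), 3L)
  expect_equal(lay$contig, c("c2", "c3", "c1"))  # descending length seeds
})

test_that("a two-contig cycle terminates with each contig used once", {
  ctg <- contig_tbl(c(rand_genome(600), rand_genome(600)))
  links <- mk_links(list("c1", "+", "c2", "+", 20, 10),
                    list("c1", "-", "c2", "-", 20, 10))  # c2 -> c1 again
  lay <- build_scaffolds(links, ctg, l = 5, a = 0.3)
  expect_equal(sort(lay$contig), c("c1", "c2"))
  expect_equal(anyDuplicated(lay$contig), 0L)
})

test_that("random link sets always yield a permutation of the contigs", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    ctg <- contig_tbl(vapply(seq_len(n), function(i)
      rand_genome(sample(500:2000, 1)), character(1)))
    n_l <- sample(0:15, 1)
    rows <- lapply(seq_len(n_l), function(i) {
      pair <- sample(ctg$id, 2)
      list(pair[1], sample(c("+", "-"), 1), pair[2], sample(c("+", "-"), 1),
           sample(1:20, 1), sample(-50:200, 1))
    })
    links <- do.call(mk_links, rows)
    links <- dplyr::distinct(links, contig1, orient1, contig2, orient2,
                             .keep_all = TRUE)
    lay <- build_scaffolds(links, ctg, l = 3, a = 0.5)
    expect_setequal(lay$contig, ctg$id)
    expect_equal(anyDuplicated(lay$contig), 0L)
  }
})

test_that("layout and emission are deterministic", {
  ctg <- contig_tbl(c(rand_genome(900, seed = 7), rand_genome(800, seed = 8),
                      rand_genome(850, seed = 9)))
  links <- mk_links(list("c1", "+", "c2", "-", 6, 30),
                    list("c3", "+", "c1", "+", 7, -5))
  a <- build_scaffolds(links, ctg, l = 5, a = 0.3)
  b <- build_scaffolds(links, ctg, l = 5, a = 0.3)
  expect_identical(a, b)
  expect_identical(emit_sequences(a, ctg), emit_sequences(b, ctg))
})

test_that("emitted sequences encode gaps, overlaps and orientation", {
  ctg <- contig_tbl(c("ACGTACGTAC", "GGGTTTGGGT"))
  lay2 <- function(gap) tibble::tibble(
    scaffold = "scaffold1", position = 1:2, contig = c("c1", "c2"),
    orient = c("+", "+"), gap_to_next = c(gap, NA))
  expect_equal(emit_sequences(lay2(3), ctg)$seq,
               paste0(ctg$seq[1], "NNN", ctg$seq[2]))
  expect_equal(emit_sequences(lay2(-400), ctg)$seq,
               paste0(ctg$seq[1], "n", ctg$seq[2]))
  single <- tibble::tibble(scaffold = "scaffold1", position = 1L,
                           contig = "c1", orient = "-", gap_to_next = NA)
  expect_equal(emit_sequences(single, ctg)$seq, revcomp_dna(ctg$seq[1]))
})
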