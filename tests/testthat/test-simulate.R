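pp <- preset_nanopore_r7()

test_that("degenerate mixtures reproduce their closed-form means", {
  n <- 1e5
  # pure geometric (a -> 0): mean (1-p)/p, zero-indexed
  gm <- error_model_params(mismatch = list(a = 1e-9, lambda = 2, p = 0.4),
                           insertion = pp$insertion, deletion = pp$deletion)
  x <- sample_run_lengths(gm, "mismatch", n, seed = 1)
  se <- stats::sd(x) / sqrt(n)
  expect_lt(abs(mean(x) - 0.6 / 0.4), 3 * se)

  # pure Poisson (a -> 1), lambda = 2
  po <- error_model_params(mismatch = list(a = 1 - 1e-9, lambda = 2, p = 0.4),
                           insertion = pp$insertion, deletion = pp$deletion)
  y <- sample_run_lengths(po, "mismatch", n, seed = 2)
  expect_lt(abs(mean(y) - 2), 3 * stats::sd(y) / sqrt(n))
})

test_that("the full mixture matches its closed-form mean", {
  n <- 1e5
  z <- sample_run_lengths(pp, "mismatch", n, seed = 3)
  m <- pp$mismatch
  mu <- m$a * m$lambda + (1 - m$a) * (1 - m$p) / m$p
  expect_lt(abs(mean(z) - mu), 3 * stats::sd(z) / sqrt(n))

  # indel draws are one-indexed and match the discretised mixture mean
  w <- sample_run_lengths(pp, "insertion", n, seed = 4)
  expect_gte(min(w), 1L)
  i <- pp$insertion
  supp <- 1:500
  mu_i <- sum(supp * scafflink:::mixture_pmf(supp, i, "insertion"))
  expect_lt(abs(mean(w) - mu_i), 3 * stats::sd(w) / sqrt(n))
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(error_model_params(
    mismatch = list(a = 1.2, lambda = 2, p = 0.4),
    insertion = pp$insertion, deletion = pp$deletion), "mismatch\\$a")
  expect_error(error_model_params(
    mismatch = pp$mismatch,
    insertion = list(a = 0.5, shape = -1, scale = 2, p = 0.5),
    deletion = pp$deletion), "shape")
})

test_that("simulated reads honour the error bookkeeping", {
  g <- rand_genome(50000, seed = 11)
  # zero errors: the identity case
  r0 <- simulate_read(g, 101, 2000)
  expect_identical(r0$seq, substr(g, 101, 2100))
  expect_equal(r0$identity, 1)

  # deletions only: emitted length = span - deleted bases
  del_only <- error_model_params(
    mismatch = pp$mismatch, insertion = pp$insertion, deletion = pp$deletion,
    type_weights = c(mismatch = 0, insertion = 0, deletion = 1))
  rd <- simulate_read(g, 1, 20000, del_only, seed = 12)
  expect_equal(nchar(rd$seq), 20000 - rd$n_del)
  expect_equal(rd$n_ins, 0L)
  expect_equal(rd$n_mismatch, 0L)

  # general case: consumed genome = matches + mismatches + deletions
  rr <- simulate_read(g, 1, 20000, pp, seed = 13)
  expect_equal(rr$n_match + rr$n_mismatch + rr$n_del, 20000)
  expect_equal(nchar(rr$seq), rr$n_match + rr$n_mismatch + rr$n_ins)
})

test_that("the nanopore preset lands in the published identity band", {
  g <- rand_genome(120000, seed = 21)
  ids <- vapply(1:3, function(s) simulate_read(g, 1, 1e5, pp, seed = s)$identity,
                double(1))
  expect_true(all(ids > 0.665 & ids < 0.877))   # 77.1 +/- 10.6 %
  expect_lt(max(ids) - min(ids), 0.04)          # stable +/- 2 % across seeds
})

test_that("synthetic truth fixtures are consistent and reproducible", {
  # zero gaps: contigs concatenate back to the genome
  tr0 <- make_truth(12000, 4, c(0, 0), seed = 31)
  expect_equal(paste(tr0$contigs$seq, collapse = ""), tr0$genome)
  expect_equal(sum(tr0$contigs$length), 12000)

  # single contig: no junctions
  tr1 <- make_truth(5000, 1, c(100, 200), seed = 32)
  expect_equal(nrow(tr1$truth), 1L)
  expect_true(is.na(tr1$truth$gap_to_next))

  # determinism: byte-identical fixture across runs
  a <- make_truth(200000, 20, c(100, 500), seed = 33)
  b <- make_truth(200000, 20, c(100, 500), seed = 33)
  expect_identical(a, b)

  # flipped contigs store the reverse complement and record '-'
  trf <- make_truth(30000, 6, c(50, 100), seed = 34, flip_prob = 0.99)
  expect_true(any(trf$truth$orient == "-"))
  i <- which(trf$truth$orient == "-")[1]
  expect_equal(trf$contigs$seq[i],
               revcomp_dna(substr(trf$genome, trf$truth$start[i],
                                  trf$truth$end[i])))

  expect_error(make_truth(5000, 10, c(100, 200), seed = 35), "infeasible")
})
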