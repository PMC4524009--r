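# Shared fixture builders. Everything is generated in code at test time.

rand_genome <- function(n, seed = NULL) {
  scafflink:::with_opt_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  })
}

contig_tbl <- function(seqs, ids = paste0("c", seq_along(seqs))) {
  tibble::tibble(id = ids, seq = toupper(seqs), length = nchar(seqs))
}

# Two contigs cut from one genome with a planted gap (or overlap when
# gap < 0: the contigs share -gap genome bases), plus the genome itself.
two_contig_fixture <- function(len1 = 2000, len2 = 2000, gap = 10,
                               seed = 42) {
  g <- rand_genome(len1 + max(gap, 0) + len2, seed = seed)
  c1 <- substr(g, 1, len1)
  c2_start <- len1 + gap + 1
  c2 <- substr(g, c2_start, c2_start + len2 - 1)
  list(genome = g, contigs = contig_tbl(c(c1, c2)), gap = gap,
       junction = len1)  # junction: last genome base of c1 (1-based)
}

# Write a contig tibble as a FASTA file and return the path.
write_contig_fa <- function(contigs, path = tempfile(fileext = ".fa")) {
  write_fasta(contigs$id, contigs$seq, path)
  path
}

# Write reads + a file-of-filenames; returns the fof path.
write_reads_fof <- function(reads, dir = tempfile("reads")) {
  dir.create(dir, showWarnings = FALSE)
  fa <- file.path(dir, "reads.fa")
  write_fasta(reads$id, reads$seq, fa)
  fof <- file.path(dir, "reads.fof")
  writeLines(fa, fof)
  fof
}

# Deterministic full pairing run on in-memory objects.
pair_pipeline <- function(contigs, reads, k, d, t = 2, e = 0.1,
                          p = 1e-6, backend = c("bloom", "exact")) {
  backend <- match.arg(backend)
  idx <- if (backend == "bloom") build_bloom(contigs, k, p)
         else build_exact_index(contigs, k)
  st <- extract_pairs(reads, idx, k, d, t)
  pl <- place_kmers(contigs, k, st)
  build_links(st, pl, contigs, d = d, e = e)
}
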