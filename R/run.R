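#' Run configuration
#'
#' Bundles and validates the run parameters of the scaffolder. `d` may be
#' an ascending vector for iterative multi-distance scaffolding; `t` is
#' recycled or given per iteration.
#'
#' @param f Path to the assembly FASTA to scaffold.
#' @param s Path to the file-of-filenames listing long-read FASTA/FASTQ
#'   files.
#' @param k K-mer length (default 15).
#' @param d Target 5'-to-5' k-mer pair distance(s), bases (default 4000).
#' @param t Sliding-window step(s), bases (default 2).
#' @param e Allowed fractional deviation of calculated distances
#'   (default 0.1).
#' @param l Minimum links to merge (default 5).
#' @param a Maximum alternate-to-primary link ratio (default 0.3).
#' @param p Bloom filter false-positive rate (default 0.001).
#' @param r Optional path to a saved Bloom filter reused for the first
#'   iteration.
#' @param x If `TRUE`, use the exact k-mer set backend instead of the
#'   Bloom filter.
#' @param b Output path prefix (default `"scafflink_out"`).
#' @param z Minimum input contig length, bases (default 500).
#' @param seed Optional integer seed for any stochastic utility.
#' @return A validated `run_config` list.
#' @export
links_config <- function(f, s, k = 15, d = 4000, t = 2, e = 0.1, l = 5,
                         a = 0.3, p = 0.001, r = NULL, x = FALSE,
                         b = "scafflink_out", z = 500, seed = NULL) {
  stopifnot(k >= 4, all(d > k), all(t >= 1), e > 0, l >= 1, a > 0, a <= 1,
            p > 0, p < 0.5, z >= 0)
  if (!length(t) %in% c(1L, length(d))) {
    stop("t must have length 1 or length(d)")
  }
  if (is.unsorted(d)) stop("d values must be ascending")
  structure(list(f = f, s = s, k = as.integer(k), d = as.integer(d),
                 t = as.integer(rep_len(t, length(d))), e = e,
                 l = l, a = a, p = p, r = r, x = isTRUE(x), b = b,
                 z = as.integer(z), seed = seed),
            class = "run_config")
}

#' Scaffold an assembly with paired k-mers from long reads
#'
#' The full run protocol: for each distance `d[i]` in ascending order,
#' build (or, for the first iteration, optionally reuse via `r`) the k-mer
#' membership index over the *current* assembly, extract spaced k-mer
#' pairs from the long reads at `d[i]` with step `t[i]`, convert them into
#' distance-validated oriented links, lay out scaffolds, and write the
#' output family suffixed `.iter<i>`; each iteration's scaffolds become
#' the next iteration's input assembly. The final outputs are also written
#' unsuffixed. The Bloom filter is rebuilt between iterations because
#' merge pads change the sequence content.
#'
#' @param config A `run_config` from [links_config()], or `NULL` to build
#'   one from `...`.
#' @param ... Passed to [links_config()] when `config` is `NULL`.
#' @return (Invisibly) a list: `scaffolds` (final `scaffold_layout`),
#'   `sequences` (final tibble `id`, `seq`, `length`), `stats` (one-row
#'   tibble per iteration: pair counts, acceptance tallies, merges,
#'   sequence counts).
#' @export
run_links <- function(config = NULL, ...) {
  cfg <- config %||% links_config(...)
  stopifnot(inherits(cfg, "run_config"))
  contigs <- read_assembly(cfg$f, min_len = cfg$z)
  if (nrow(contigs) == 0) stop("no contigs of length >= ", cfg$z, " in ", cfg$f)
  reads <- read_long_reads(cfg$s)

  stats_rows <- vector("list", length(cfg$d))
  layouts <- NULL; seqs <- NULL; link_set <- NULL
  for (i in seq_along(cfg$d)) {
    d_i <- cfg$d[i]; t_i <- cfg$t[i]
    index <- if (i == 1L && !is.null(cfg$r)) {
      load_bloom(cfg$r, expect_k = cfg$k)
    } else if (cfg$x) {
      build_exact_index(contigs, cfg$k)
    } else {
      build_bloom(contigs, cfg$k, cfg$p)
    }
    store <- extract_pairs(reads, index, cfg$k, d_i, t_i)
    placement <- place_kmers(contigs, cfg$k, store)
    link_set <- build_links(store, placement, contigs, d = d_i, e = cfg$e)
    layouts <- build_scaffolds(link_set, contigs, l = cfg$l, a = cfg$a)
    seqs <- emit_sequences(layouts, contigs)
    n_merges <- nrow(contigs) - nrow(seqs)
    log_lines <- c(
      sprintf("iteration %d: d=%d t=%d", i, d_i, t_i),
      sprintf("  candidate windows: %d; pairs kept: %d; distinct pairs: %d",
              attr(store, "n_candidates"), attr(store, "n_kept"),
              nrow(store)),
      sprintf("  placed observations: %d; accepted links: %d",
              link_set$n_placed_obs, sum(link_set$links$n_links)),
      paste0("  rejected: ",
             paste(link_set$issues$counts$reason,
                   link_set$issues$counts$n, sep = "=", collapse = ", ")),
      sprintf("  merges: %d; sequences: %d -> %d",
              n_merges, nrow(contigs), nrow(seqs)))
    write_outputs(layouts, contigs, paste0(cfg$b, ".iter", i),
                  issues = link_set$issues, distances = link_set$distances,
                  log_lines = log_lines)
    stats_rows[[i]] <- tibble::tibble(
      iteration = i, d = d_i, t = t_i,
      n_candidates = attr(store, "n_candidates"),
      n_pairs_kept = attr(store, "n_kept"),
      n_placed_obs = link_set$n_placed_obs,
      n_accepted = sum(link_set$links$n_links),
      n_merges = n_merges,
      n_sequences_in = nrow(contigs), n_sequences_out = nrow(seqs))
    if (i < length(cfg$d)) {
      contigs <- seqs  # scaffolds feed the next iteration
    }
  }
  # final outputs unsuffixed; layouts reference the last iteration's input
  write_outputs(layouts, contigs, cfg$b, issues = link_set$issues,
                distances = link_set$distances)
  invisible(list(scaffolds = layouts, sequences = seqs,
                 stats = dplyr::bind_rows(stats_rows)))
}
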