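#' Error-model parameters for nanopore-like reads
#'
#' Run lengths of the three base-calling error modes follow two-component
#' mixtures: mismatch runs mix a Poisson with a geometric; insertion and
#' deletion runs mix a Weibull (rounded to the nearest positive integer)
#' with a geometric. Mismatch run lengths are zero-indexed (a stored value
#' of 0 is a run of one mismatched base); indel run lengths are one-indexed,
#' modelling interarrival times of read failures. Along a read, correct
#' stretches of geometric length alternate with error events whose type is
#' drawn from `type_weights`.
#'
#' @param mismatch List `a`, `lambda`, `p`: mixture weight of the Poisson
#'   component, Poisson mean, and geometric Bernoulli probability.
#' @param insertion,deletion Lists `a`, `shape`, `scale`, `p`: mixture
#'   weight of the Weibull component, its shape and scale, and the
#'   geometric Bernoulli probability.
#' @param type_weights Probabilities that an error event is a mismatch,
#'   insertion or deletion (named, sums to 1).
#' @param stretch_mean Mean length in bases of the correct stretches
#'   between error events (default 14, matching the 13-15 bp bursts of
#'   accurate bases seen in R7-chemistry 2D nanopore data).
#' @param substitution 4x4 row-stochastic matrix (rows/cols A,C,G,T, zero
#'   diagonal): distribution of the base a mismatch replaces each original
#'   base with.
#' @return An `error_model_params` object (validated list).
#' @export
error_model_params <- function(mismatch, insertion, deletion,
                               type_weights = c(mismatch = 0.5,
                                                insertion = 0.25,
                                                deletion = 0.25),
                               stretch_mean = 14,
                               substitution = default_substitution()) {
  chk01 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || x <= 0 || x >= 1) {
      stop(nm, " must be a single number in (0, 1)")
    }
  }
  chkpos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || x <= 0) {
      stop(nm, " must be a single positive number")
    }
  }
  chk01(mismatch$a, "mismatch$a"); chkpos(mismatch$lambda, "mismatch$lambda")
  chk01(mismatch$p, "mismatch$p")
  for (nm in c("insertion", "deletion")) {
    cmp <- get(nm)
    chk01(cmp$a, paste0(nm, "$a")); chkpos(cmp$shape, paste0(nm, "$shape"))
    chkpos(cmp$scale, paste0(nm, "$scale")); chk01(cmp$p, paste0(nm, "$p"))
  }
  stopifnot(length(type_weights) == 3, all(type_weights >= 0),
            abs(sum(type_weights) - 1) < 1e-8, stretch_mean > 0)
  if (!all(dim(substitution) == c(4, 4)) ||
      any(abs(rowSums(substitution) - 1) > 1e-8) ||
      any(diag(substitution) != 0)) {
    stop("substitution must be 4x4, row sums 1, zero diagonal")
  }
  structure(list(mismatch = mismatch, insertion = insertion,
                 deletion = deletion, type_weights = type_weights,
                 stretch_mean = stretch_mean, substitution = substitution),
            class = "error_model_params")
}

#' @rdname error_model_params
#' @details `default_substitution()` encodes the qualitative trend observed
#'   in nanopore substitution profiles: A and T are more stable than C and
#'   G, and bases are preferentially substituted by C and G.
#' @export
default_substitution <- function() {
  m <- matrix(c(0.00, 0.35, 0.45, 0.20,
                0.15, 0.00, 0.55, 0.30,
                0.15, 0.55, 0.00, 0.30,
                0.20, 0.45, 0.35, 0.00),
              nrow = 4, byrow = TRUE,
              dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  m
}

#' R7-like nanopore error preset
#'
#' Calibrated (not transcribed from any fitted table) so that simulated
#' reads reproduce the printed summary statistics of R7-chemistry 2D
#' nanopore data: mean identity near 77 % with correct stretches of ~14 bp
#' on average. Mixture components are deliberately well separated so the
#' model is identifiable from samples.
#'
#' @return An `error_model_params` object.
#' @export
preset_nanopore_r7 <- function() {
  error_model_params(
    mismatch = list(a = 0.4, lambda = 2.5, p = 0.7),
    insertion = list(a = 0.55, shape = 1.3, scale = 9, p = 0.35),
    deletion = list(a = 0.55, shape = 1.3, scale = 9, p = 0.35),
    type_weights = c(mismatch = 0.5, insertion = 0.25, deletion = 0.25),
    stretch_mean = 14
  )
}

#' Sample error run lengths from the mixture model
#'
#' With probability `a` the structured component is drawn (Poisson for
#' mismatches; Weibull rounded to the nearest integer, minimum 1, for
#' indels), otherwise the geometric. Mismatch draws are zero-indexed,
#' indel draws one-indexed.
#'
#' @param params An `error_model_params`.
#' @param type One of `"mismatch"`, `"insertion"`, `"deletion"`.
#' @param n Number of draws.
#' @param seed Optional integer seed (local to this call).
#' @return Integer vector of `n` run lengths.
#' @export
sample_run_lengths <- function(params, type = c("mismatch", "insertion",
                                                "deletion"),
                               n, seed = NULL) {
  type <- match.arg(type)
  stopifnot(inherits(params, "error_model_params"), n >= 1)
  cmp <- params[[type]]
  with_opt_seed(seed, {
    structured <- stats::runif(n) < cmp$a
    out <- integer(n)
    ns <- sum(structured)
    if (type == "mismatch") {
      out[structured] <- stats::rpois(ns, cmp$lambda)
      out[!structured] <- stats::rgeom(n - ns, cmp$p)
    } else {
      out[structured] <- pmax(1L, as.integer(round(
        stats::rweibull(ns, shape = cmp$shape, scale = cmp$scale))))
      out[!structured] <- stats::rgeom(n - ns, cmp$p) + 1L
    }
    out
  })
}

# Discretised mixture pmf/cdf used by sampling checks and fitting.
mixture_pmf <- function(x, cmp, type) {
  if (type == "mismatch") {
    cmp$a * stats::dpois(x, cmp$lambda) + (1 - cmp$a) * stats::dgeom(x, cmp$p)
  } else {
    wb <- ifelse(x == 1,
                 stats::pweibull(1.5, cmp$shape, cmp$scale),
                 stats::pweibull(x + 0.5, cmp$shape, cmp$scale) -
                   stats::pweibull(x - 0.5, cmp$shape, cmp$scale))
    wb[x < 1] <- 0
    cmp$a * wb + (1 - cmp$a) * stats::dgeom(x - 1, cmp$p)
  }
}

mixture_cdf <- function(q, cmp, type) {
  lo <- if (type == "mismatch") 0L else 1L
  vapply(q, function(v) {
    if (v < lo) return(0)
    sum(mixture_pmf(lo:floor(v), cmp, type))
  }, double(1))
}

#' Simulate one error-containing read
#'
#' Corrupts `genome[start, start+span)` by alternating correct stretches
#' (geometric lengths, mean `params$stretch_mean`) with error events whose
#' type follows `params$type_weights` and whose run length comes from
#' [sample_run_lengths()]. Mismatched bases are drawn from the substitution
#' profile; insertions add uniform random bases consuming no genome;
#' deletions consume genome without emitting. Returns the read together
#' with its true alignment footprint, so identity is known without an
#' aligner.
#'
#' @param genome A single DNA string.
#' @param start 1-based start of the simulated fragment on the genome.
#' @param span Number of genome bases the read consumes.
#' @param params An `error_model_params`, or `NULL` for an error-free read
#'   (the identity case: the read equals the genome fragment verbatim).
#' @param seed Optional integer seed (local to this call).
#' @return A list: `seq` (the read), `g_start`, `g_end` (1-based inclusive
#'   genome interval consumed), `n_match`, `n_mismatch`, `n_ins`, `n_del`,
#'   and `identity` = matches / alignment columns.
#' @export
simulate_read <- function(genome, start, span, params = NULL, seed = NULL) {
  stopifnot(start >= 1, start + span - 1 <= nchar(genome))
  if (is.null(params)) {
    return(list(seq = substr(genome, start, start + span - 1L),
                g_start = start, g_end = start + span - 1L,
                n_match = span, n_mismatch = 0L, n_ins = 0L, n_del = 0L,
                identity = 1))
  }
  with_opt_seed(seed, {
    # overdraw cycles, then truncate to the target consumed span
    n_cyc <- ceiling(span / max(params$stretch_mean, 1)) + 50L
    repeat {
      stretch <- stats::rgeom(n_cyc, 1 / (params$stretch_mean + 1))
      type <- sample(c("mismatch", "insertion", "deletion"), n_cyc,
                     replace = TRUE, prob = params$type_weights)
      run <- integer(n_cyc)
      for (ty in c("mismatch", "insertion", "deletion")) {
        idx <- which(type == ty)
        if (length(idx)) run[idx] <- sample_run_lengths(params, ty, length(idx))
      }
      # genome bases consumed: stretch + run+1 (mismatch, zero-indexed) or
      # run (deletion); insertions consume nothing
      consume_evt <- ifelse(type == "mismatch", run + 1L,
                            ifelse(type == "deletion", run, 0L))
      if (sum(stretch) + sum(consume_evt) >= span) break
      n_cyc <- n_cyc * 2L
    }

    # walk cycles until span genome bases are consumed, clamping the last
    seg_type <- character(0); seg_len <- integer(0)
    consumed <- 0L
    for (i in seq_len(n_cyc)) {
      s <- min(stretch[i], span - consumed)
      if (s > 0) { seg_type <- c(seg_type, "M"); seg_len <- c(seg_len, s) }
      consumed <- consumed + s
      if (consumed >= span) break
      cl <- consume_evt[i]
      if (cl > span - consumed) {  # clamp a consuming event at the end
        cl <- span - consumed
        if (type[i] == "insertion") cl <- 0L
        if (cl > 0) {
          seg_type <- c(seg_type, if (type[i] == "mismatch") "X" else "D")
          seg_len <- c(seg_len, cl)
          consumed <- consumed + cl
        }
        break
      }
      code <- c(mismatch = "X", insertion = "I", deletion = "D")[[type[i]]]
      el <- if (type[i] == "insertion") run[i] else cl
      if (el > 0 || (type[i] == "mismatch" && cl > 0)) {
        seg_type <- c(seg_type, code)
        seg_len <- c(seg_len, if (type[i] == "mismatch") cl else el)
      }
      consumed <- consumed + cl
      if (consumed >= span) break
    }

    gchars <- strsplit(substr(genome, start, start + span - 1), "")[[1]]
    emit_len <- ifelse(seg_type == "D", 0L, seg_len)
    cons_len <- ifelse(seg_type == "I", 0L, seg_len)
    g_off <- cumsum(c(0L, cons_len))[seq_along(seg_len)]  # 0-based starts
    out <- character(sum(emit_len))
    o_off <- cumsum(c(0L, emit_len))[seq_along(seg_len)]
    for (i in seq_along(seg_type)) {
      if (emit_len[i] == 0L) next
      pos <- o_off[i] + seq_len(emit_len[i])
      if (seg_type[i] == "M") {
        out[pos] <- gchars[g_off[i] + seq_len(seg_len[i])]
      } else if (seg_type[i] == "X") {
        orig <- gchars[g_off[i] + seq_len(seg_len[i])]
        out[pos] <- substitute_bases(orig, params$substitution)
      } else {
        out[pos] <- sample(c("A", "C", "G", "T"), emit_len[i], replace = TRUE)
      }
    }
    n_match <- sum(seg_len[seg_type == "M"])
    n_mm <- sum(seg_len[seg_type == "X"])
    n_ins <- sum(seg_len[seg_type == "I"])
    n_del <- sum(seg_len[seg_type == "D"])
    list(seq = paste(out, collapse = ""),
         g_start = start, g_end = start + span - 1L,
         n_match = n_match, n_mismatch = n_mm, n_ins = n_ins, n_del = n_del,
         identity = n_match / (n_match + n_mm + n_ins + n_del))
  })
}

# Vectorised substitution of bases via the row-stochastic profile; non-ACGT
# originals are replaced uniformly.
substitute_bases <- function(orig, profile) {
  out <- character(length(orig))
  for (b in c("A", "C", "G", "T")) {
    idx <- which(orig == b)
    if (length(idx)) {
      out[idx] <- sample(colnames(profile), length(idx), replace = TRUE,
                         prob = profile[b, ])
    }
  }
  other <- which(!orig %in% c("A", "C", "G", "T"))
  if (length(other)) {
    out[other] <- sample(c("A", "C", "G", "T"), length(other), replace = TRUE)
  }
  out
}

#' Simulate a set of reads over a genome
#'
#' Draws `n` fragments of length `span` at uniform random starts and
#' corrupts each with [simulate_read()]. With `params = NULL` the reads are
#' error-free genome substrings.
#'
#' @param genome A single DNA string.
#' @param n Number of reads.
#' @param span Genome bases consumed per read.
#' @param params An `error_model_params`, or `NULL` for error-free reads.
#' @param seed Optional integer seed (local to this call).
#' @return Tibble `id`, `seq`, `length`, `g_start`, `g_end`, `identity`
#'   (identity 1 for error-free reads).
#' @export
simulate_read_set <- function(genome, n, span, params = NULL, seed = NULL) {
  stopifnot(span <= nchar(genome))
  with_opt_seed(seed, {
    starts <- sample.int(nchar(genome) - span + 1L, n, replace = TRUE)
    if (is.null(params)) {
      tibble::tibble(id = paste0("read", seq_len(n), "_", starts),
                     seq = substring(genome, starts, starts + span - 1L),
                     length = span, g_start = starts,
                     g_end = starts + span - 1L, identity = 1)
    } else {
      sims <- lapply(starts, function(s) simulate_read(genome, s, span, params))
      tibble::tibble(id = paste0("read", seq_len(n), "_", starts),
                     seq = vapply(sims, `[[`, character(1), "seq"),
                     length = nchar(seq),
                     g_start = starts, g_end = starts + span - 1L,
                     identity = vapply(sims, `[[`, double(1), "identity"))
    }
  })
}

#' Synthetic genome, fragmented contigs, and ground truth
#'
#' Generates a uniform-random genome, cuts it into `n_contigs` contigs
#' separated by gaps drawn uniformly from `gap_range` (gap bases exist in
#' the genome but in no contig), and optionally stores some contigs
#' reverse-complemented (recorded as orientation `-`). Re-assembling the
#' contigs in true order/orientation with the true gaps reproduces the
#' genome.
#'
#' @param genome_len Genome length in bases.
#' @param n_contigs Number of contigs to cut.
#' @param gap_range Length-2 integer vector: inclusive range of gap sizes.
#' @param seed Optional integer seed (local to this call).
#' @param flip_prob Probability a contig is stored reverse-complemented
#'   (default 0: all `+`).
#' @param min_contig Minimum contig length (default 1000).
#' @return A `synthetic_truth` list: `genome`, `contigs` (tibble `id`,
#'   `seq`, `length`), `truth` (tibble `id`, `start`, `end`, `orient`,
#'   `gap_to_next`, in genome order).
#' @export
make_truth <- function(genome_len, n_contigs, gap_range, seed = NULL,
                       flip_prob = 0, min_contig = 1000) {
  stopifnot(length(gap_range) == 2, gap_range[1] <= gap_range[2],
            gap_range[1] >= 0, n_contigs >= 1)
  n_gaps <- n_contigs - 1L
  if (n_contigs * min_contig + n_gaps * gap_range[2] > genome_len) {
    stop("infeasible geometry: ", n_contigs, " contigs of >= ", min_contig,
         " bp plus gaps cannot fit in ", genome_len, " bp")
  }
  with_opt_seed(seed, {
    genome <- random_dna(genome_len)
    gaps <- if (n_gaps > 0) {
      sample.int(gap_range[2] - gap_range[1] + 1L, n_gaps,
                 replace = TRUE) + gap_range[1] - 1L
    } else integer(0)
    contig_total <- genome_len - sum(gaps)
    # random composition with a floor: floor + multinomial remainder
    extra <- contig_total - n_contigs * min_contig
    add <- if (extra > 0) {
      as.integer(stats::rmultinom(1, extra, rep(1, n_contigs)))
    } else rep(0L, n_contigs)
    clens <- min_contig + add
    starts <- cumsum(c(1L, clens[-n_contigs] + gaps))
    ends <- starts + clens - 1L
    orient <- ifelse(stats::runif(n_contigs) < flip_prob, "-", "+")
    seqs <- substring(genome, starts, ends)
    seqs[orient == "-"] <- revcomp_dna(seqs[orient == "-"])
    ids <- paste0("ctg", seq_len(n_contigs))
    structure(list(
      genome = genome,
      contigs = tibble::tibble(id = ids, seq = seqs, length = clens),
      truth = tibble::tibble(id = ids, start = starts, end = ends,
                             orient = orient,
                             gap_to_next = c(gaps, NA_integer_))),
      class = "synthetic_truth")
  })
}
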