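#' Extract spaced k-mer pairs from long sequences
#'
#' For each read and each window start `w` in `0, t, 2t, ...` with
#' `w + d <= nchar(read)`, the pair `(read[w, w+k), read[w+d-k, w+d))` is a
#' candidate: two k-mers spanning exactly `d` bases from the 5' end of the
#' first to the 3' end of the second, emulating a mate pair of insert size
#' `d`. (This outer-span convention is what makes the gap formula of
#' [calc_gap()] exact: two abutting contigs give a calculated distance of
#' exactly `d`.) A candidate is kept iff both k-mers are pure A/C/G/T and both
#' are members of the assembly k-mer index; kept pairs accumulate
#' observation counts across all reads.
#'
#' @param reads Read tibble (`id`, `seq`) from [read_long_reads()] or
#'   [simulate_read_set()].
#' @param index A `bloom_filter` or `exact_kmer_index` over the assembly.
#' @param k K-mer length (>= 4, must match the index).
#' @param d Target pair span in bases, 5' end of the first k-mer to 3' end
#'   of the second (> k).
#' @param t Sliding-window step in bases (>= 1, default 2).
#' @return A `kmer_pair_store`: tibble with columns `kmer_a`, `kmer_b`,
#'   `n_obs`, plus attributes `k`, `d`, `t`, `n_candidates`, `n_kept`.
#' @export
extract_pairs <- function(reads, index, k, d, t = 2) {
  stopifnot(k >= 4, d > k, t >= 1)
  n_candidates <- 0
  kept <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    s <- reads$seq[i]
    L <- nchar(s)
    if (L < d) next
    w <- seq.int(0L, L - d, by = t)
    n_candidates <- n_candidates + length(w)
    a <- substring(s, w + 1L, w + k)
    b <- substring(s, w + d - k + 1L, w + d)
    ok <- is_acgt(a) & is_acgt(b)
    if (!any(ok)) next
    a <- a[ok]; b <- b[ok]
    hit <- kmer_query(index, a) & kmer_query(index, b)
    if (any(hit)) kept[[i]] <- tibble::tibble(kmer_a = a[hit], kmer_b = b[hit])
  }
  store <- dplyr::bind_rows(kept)
  store <- if (nrow(store) == 0) {
    tibble::tibble(kmer_a = character(0), kmer_b = character(0),
                   n_obs = integer(0))
  } else {
    dplyr::count(store, .data$kmer_a, .data$kmer_b, name = "n_obs")
  }
  structure(store, class = c("kmer_pair_store", class(store)),
            k = as.integer(k), d = as.integer(d), t = as.integer(t),
            n_candidates = n_candidates, n_kept = sum(store$n_obs))
}

#' Place stored k-mers on contigs
#'
#' Shreds the contigs once more at the store's `k` and records every
#' occurrence, on either strand, of each k-mer appearing in the pair store
#' (as either pair member). `start` is the 0-based start of the occurrence
#' in forward-strand contig coordinates; `multiplicity` counts a k-mer's
#' occurrences across all contigs and both strands, and is what the linking
#' stage uses to demand unique placement.
#'
#' @param contigs Contig tibble (`id`, `seq`, `length`).
#' @param k K-mer length (must equal the store's).
#' @param store A `kmer_pair_store` from [extract_pairs()].
#' @return A `kmer_placement`: tibble with columns `kmer`, `contig`,
#'   `strand` (`+`/`-`), `start`, `multiplicity`.
#' @export
place_kmers <- function(contigs, k, store) {
  stopifnot(identical(as.integer(k), as.integer(attr(store, "k"))))
  needed <- unique(c(store$kmer_a, store$kmer_b))
  rows <- vector("list", nrow(contigs))
  for (i in seq_len(nrow(contigs))) {
    km <- kmerize(contigs$seq[i], k)
    if (length(km) == 0) next
    start0 <- seq_along(km) - 1L
    fwd_hit <- km %in% needed
    rc <- revcomp_dna(km)
    rev_hit <- rc %in% needed
    rows[[i]] <- tibble::tibble(
      kmer = c(km[fwd_hit], rc[rev_hit]),
      contig = contigs$id[i],
      strand = rep(c("+", "-"), c(sum(fwd_hit), sum(rev_hit))),
      start = c(start0[fwd_hit], start0[rev_hit])
    )
  }
  plc <- dplyr::bind_rows(rows)
  if (nrow(plc) == 0) {
    plc <- tibble::tibble(kmer = character(0), contig = character(0),
                          strand = character(0), start = integer(0),
                          multiplicity = integer(0))
  } else {
    plc <- dplyr::mutate(dplyr::group_by(plc, .data$kmer),
                         multiplicity = dplyr::n())
    plc <- dplyr::ungroup(plc)
  }
  structure(plc, class = c("kmer_placement", class(plc)), k = as.integer(k))
}

#' Gap or overlap estimate between two linked contigs
#'
#' With k-mer a starting at 0-based `p1` on contig 1 (length `L1`, in link
#' orientation) and k-mer b at `p2` on contig 2, the spacing `d` implies a
#' gap of `d - ((L1 - p1) + (p2 + k))` bases between the contig ends:
#' positive is a gap, negative an overlap, zero abutting. Exact integer
#' arithmetic.
#'
#' @param d Target 5'-to-5' k-mer spacing in bases.
#' @param L1 Length of the first contig.
#' @param p1,p2 0-based k-mer starts on contig 1 and 2, measured in the
#'   orientation the link uses.
#' @param k K-mer length.
#' @return Integer gap (negative = overlap).
#' @export
#' @examples
#' calc_gap(4000, 2000, 1000, 385, 15)  # 2600
calc_gap <- function(d, L1, p1, p2, k) {
  stopifnot(p1 >= 0, p1 < L1, p2 >= 0)
  d - ((L1 - p1) + (p2 + k))
}

#' Convert k-mer pairs into oriented contig links
#'
#' A pair observation becomes one link observation iff (i) both k-mers are
#' placed with multiplicity exactly 1 (unique across all contigs, both
#' strands), (ii) on two different contigs, and (iii) the calculated
#' footprint `D = (L1 - p1) + (p2 + k)` satisfies `|D - d| < e * d`
#' (strict: a footprint of 4,400 at `d = 4000`, `e = 0.1` is rejected).
#' The strand of each k-mer fixes its contig's orientation in the link; a
#' reverse observation accumulates onto the canonical direction (smaller
#' contig rank first) with both orientations flipped. Rejected observations
#' are tallied by reason; accepted + rejected equals the observations with
#' both k-mers placed.
#'
#' @param store A `kmer_pair_store`.
#' @param placement A `kmer_placement` over the same `k`.
#' @param contigs Contig tibble.
#' @param d Target spacing (defaults to the store's).
#' @param e Allowed fractional deviation of the calculated distance
#'   (default 0.1, i.e. 4000 +/- 400).
#' @return A list of class `contig_link_set`:
#'   * `links`: tibble `contig1`, `orient1`, `contig2`, `orient2`,
#'     `n_links`, `mean_gap` (half-away-from-zero rounded), `gaps`
#'     (list-column of per-observation estimates);
#'   * `issues`: list with `counts` (tibble `reason`, `n`) and `records`;
#'   * `distances`: integer vector of calculated footprints for cross-contig
#'     uniquely-placed observations (pre-tolerance), for the pairing
#'     distribution output.
#' @export
build_links <- function(store, placement, contigs, d = attr(store, "d"),
                        e = 0.1) {
  stopifnot(identical(as.integer(attr(store, "k")),
                      as.integer(attr(placement, "k"))))
  k <- attr(store, "k")
  empty_links <- tibble::tibble(
    contig1 = character(0), orient1 = character(0), contig2 = character(0),
    orient2 = character(0), n_links = integer(0), mean_gap = double(0),
    gaps = list())
  empty_issues <- list(
    counts = tibble::tibble(
      reason = c("same_contig", "orientation_conflict", "non_unique",
                 "out_of_tolerance"),
      n = 0L),
    records = tibble::tibble(reason = character(0), contig_a = character(0),
                             contig_b = character(0), distance = integer(0),
                             target_d = integer(0)))
  if (nrow(store) == 0) {
    return(structure(list(links = empty_links, issues = empty_issues,
                          distances = integer(0), n_placed_obs = 0L),
                     class = "contig_link_set"))
  }

  # one placement summary row per k-mer (position meaningful only if unique)
  plc <- dplyr::distinct(placement, .data$kmer, .keep_all = TRUE)
  a <- dplyr::inner_join(store,
         dplyr::rename(plc, kmer_a = "kmer", ctg_a = "contig",
                       str_a = "strand", pos_a = "start", mult_a = "multiplicity"),
         by = "kmer_a")
  ab <- dplyr::inner_join(a,
         dplyr::rename(plc, kmer_b = "kmer", ctg_b = "contig",
                       str_b = "strand", pos_b = "start", mult_b = "multiplicity"),
         by = "kmer_b")
  if (nrow(ab) == 0) {
    return(structure(list(links = empty_links, issues = empty_issues,
                          distances = integer(0), n_placed_obs = 0L),
                     class = "contig_link_set"))
  }

  len_of <- stats::setNames(contigs$length, contigs$id)
  rank_of <- stats::setNames(seq_len(nrow(contigs)), contigs$id)
  L1 <- unname(len_of[ab$ctg_a])
  L2 <- unname(len_of[ab$ctg_b])
  # positions in link orientation: '-' strand hits flip the coordinate
  p1 <- ifelse(ab$str_a == "+", ab$pos_a, L1 - ab$pos_a - k)
  p2 <- ifelse(ab$str_b == "+", ab$pos_b, L2 - ab$pos_b - k)
  D <- (L1 - p1) + (p2 + k)

  same <- ab$ctg_a == ab$ctg_b
  ab$reason <- dplyr::case_when(
    ab$mult_a > 1 | ab$mult_b > 1 ~ "non_unique",
    same & ab$str_a != ab$str_b ~ "orientation_conflict",
    same ~ "same_contig",
    abs(D - d) >= e * d ~ "out_of_tolerance",
    .default = "accepted"
  )
  ab$D <- as.integer(D)
  ab$gap <- as.integer(d - D)

  cross_unique <- !same & ab$mult_a == 1 & ab$mult_b == 1
  distances <- rep(ab$D[cross_unique], ab$n_obs[cross_unique])

  rej <- ab[ab$reason != "accepted", ]
  issues <- list(
    counts = tidyr::complete(
      dplyr::count(rej, .data$reason, wt = .data$n_obs, name = "n"),
      reason = c("same_contig", "orientation_conflict", "non_unique",
                 "out_of_tolerance"),
      fill = list(n = 0L)),
    records = tibble::tibble(reason = rep(rej$reason, rej$n_obs),
                             contig_a = rep(rej$ctg_a, rej$n_obs),
                             contig_b = rep(rej$ctg_b, rej$n_obs),
                             distance = rep(rej$D, rej$n_obs),
                             target_d = d))

  acc <- ab[ab$reason == "accepted", ]
  links <- empty_links
  if (nrow(acc) > 0) {
    # canonical direction: contig of smaller input rank first
    flip <- unname(rank_of[acc$ctg_a] > rank_of[acc$ctg_b])
    links_tbl <- tibble::tibble(
      contig1 = ifelse(flip, acc$ctg_b, acc$ctg_a),
      orient1 = ifelse(flip, flip_orient(acc$str_b), acc$str_a),
      contig2 = ifelse(flip, acc$ctg_a, acc$ctg_b),
      orient2 = ifelse(flip, flip_orient(acc$str_a), acc$str_b),
      gap = acc$gap, n_obs = acc$n_obs)
    links <- links_tbl |>
      dplyr::group_by(.data$contig1, .data$orient1, .data$contig2,
                      .data$orient2) |>
      dplyr::summarise(
        n_links = sum(.data$n_obs),
        mean_gap = round_half_away(sum(.data$gap * .data$n_obs) /
                                     sum(.data$n_obs)),
        gaps = list(rep(.data$gap, .data$n_obs)),
        .groups = "drop") |>
      dplyr::arrange(rank_of[.data$contig1], rank_of[.data$contig2],
                     .data$orient1, .data$orient2)
  }

  structure(list(links = links, issues = issues, distances = distances,
                 n_placed_obs = sum(ab$n_obs)),
            class = "contig_link_set")
}

#' @export
print.contig_link_set <- function(x, ...) {
  cat("<contig_link_set>", nrow(x$links), "oriented link(s);",
      sum(x$links$n_links), "accepted of", x$n_placed_obs,
      "placed pair observations\n")
  print(x$issues$counts)
  invisible(x)
}

#' Fraction of read k-mers supported by the assembly
#'
#' Queries every A/C/G/T k-mer of every read against the assembly index and
#' returns the matching fraction — the k-mer support diagnostic used to
#' choose `k` (for nanopore-like data, k = 15 balances specificity against
#' error-induced loss).
#'
#' @inheritParams extract_pairs
#' @return A one-row tibble: `k`, `n_kmers`, `n_matching`, `fraction`
#'   (`fraction` is `NA` when no queryable k-mer exists).
#' @export
profile_kmer_support <- function(reads, index, k) {
  tot <- 0; hit <- 0
  for (s in reads$seq) {
    km <- kmerize(s, k)
    km <- km[is_acgt(km)]
    if (length(km) == 0) next
    tot <- tot + length(km)
    hit <- hit + sum(kmer_query(index, km))
  }
  tibble::tibble(k = k, n_kmers = tot, n_matching = hit,
                 fraction = if (tot == 0) NA_real_ else hit / tot)
}
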