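#' Choose the neighbour to merge, or none
#'
#' Given the link counts of all candidate neighbours at one scaffold
#' extremity, picks the best-supported candidate and merges only when it
#' has at least `l` links and the runner-up's support divided by the best's
#' is at most `a` (the alternate-to-primary link ratio). A tie for best is
#' ambiguous and merges nothing.
#'
#' @param candidates Named numeric vector: candidate identifier -> link
#'   count.
#' @param l Minimum number of links to merge (default 5).
#' @param a Maximum alternate-to-primary link ratio (default 0.3).
#' @return The name of the chosen candidate, or `NA_character_`.
#' @export
#' @examples
#' select_neighbor(c(B = 10, C = 2), l = 5, a = 0.3)  # "B"
#' select_neighbor(c(B = 10, C = 4), l = 5, a = 0.3)  # ambiguous: NA
select_neighbor <- function(candidates, l = 5, a = 0.3) {
  stopifnot(l >= 1, a > 0, a <= 1)
  if (length(candidates) == 0) return(NA_character_)
  ord <- order(candidates, decreasing = TRUE)
  best <- candidates[ord[1]]
  if (best < l) return(NA_character_)
  if (length(candidates) >= 2) {
    second <- candidates[ord[2]]
    if (second == best) return(NA_character_)        # tie: ambiguous
    if (second / best > a) return(NA_character_)     # dominant-link guard
  }
  names(candidates)[ord[1]]
}

# Expand undirected oriented links into directed half-links usable for
# extension: (c1,o1)->(c2,o2) and its mirror (c2,-o2)->(c1,-o1).
directed_links <- function(links) {
  fwd <- tibble::tibble(from = links$contig1, from_or = links$orient1,
                        to = links$contig2, to_or = links$orient2,
                        n_links = links$n_links, mean_gap = links$mean_gap)
  rev <- tibble::tibble(from = links$contig2, from_or = flip_orient(links$orient2),
                        to = links$contig1, to_or = flip_orient(links$orient1),
                        n_links = links$n_links, mean_gap = links$mean_gap)
  dplyr::bind_rows(fwd, rev)
}

#' Build scaffolds from contig links
#'
#' Greedy layout: unused contigs seed scaffolds in descending length order
#' (ties broken by input order). Each scaffold grows rightward, then
#' leftward, from its open extremity: the links leaving that extremity in
#' the current orientation are the candidates, [select_neighbor()] arbitrates,
#' and a chosen neighbour already consumed by any scaffold stops the
#' extension. Orientations compose: extending from a reversed contig flips
#' the link's orientation sense. Every contig ends up in exactly one
#' scaffold (singletons allowed).
#'
#' @param links Link tibble from [build_links()] (the `links` element), or a
#'   `contig_link_set`.
#' @param contigs Contig tibble (`id`, `seq`, `length`).
#' @param l Minimum links to merge (default 5).
#' @param a Maximum alternate-to-primary ratio (default 0.3).
#' @return A `scaffold_layout` tibble: `scaffold`, `position`, `contig`,
#'   `orient`, `gap_to_next` (`NA` after the last contig of each scaffold).
#' @export
build_scaffolds <- function(links, contigs, l = 5, a = 0.3) {
  if (inherits(links, "contig_link_set")) links <- links$links
  dl <- directed_links(links)
  used <- stats::setNames(rep(FALSE, nrow(contigs)), contigs$id)

  # pick the extension out of the directed links leaving (ctg, orient)
  step_from <- function(ctg, orient) {
    cand <- dl[dl$from == ctg & dl$from_or == orient, ]
    if (nrow(cand) == 0) return(NULL)
    key <- paste0(cand$to, "\r", cand$to_or)
    counts <- stats::setNames(cand$n_links, key)
    pick <- select_neighbor(counts, l = l, a = a)
    if (is.na(pick)) return(NULL)
    row <- cand[key == pick, ][1, ]
    if (used[[row$to]]) return(NULL)   # consumed elsewhere: treated as none
    row
  }

  seeds <- contigs$id[order(-contigs$length, seq_len(nrow(contigs)))]
  out <- list()
  sc_num <- 0L
  for (seed in seeds) {
    if (used[[seed]]) next
    sc_num <- sc_num + 1L
    used[[seed]] <- TRUE
    chain <- tibble::tibble(contig = seed, orient = "+", gap_to_next = NA_real_)
    repeat {  # extend right
      tail_row <- chain[nrow(chain), ]
      nxt <- step_from(tail_row$contig, tail_row$orient)
      if (is.null(nxt)) break
      used[[nxt$to]] <- TRUE
      chain$gap_to_next[nrow(chain)] <- nxt$mean_gap
      chain <- dplyr::bind_rows(chain, tibble::tibble(
        contig = nxt$to, orient = nxt$to_or, gap_to_next = NA_real_))
    }
    repeat {  # extend left: walk right off the flipped head, then unflip
      head_row <- chain[1, ]
      nxt <- step_from(head_row$contig, flip_orient(head_row$orient))
      if (is.null(nxt)) break
      used[[nxt$to]] <- TRUE
      chain <- dplyr::bind_rows(tibble::tibble(
        contig = nxt$to, orient = flip_orient(nxt$to_or),
        gap_to_next = nxt$mean_gap), chain)
    }
    chain$scaffold <- paste0("scaffold", sc_num)
    chain$position <- seq_len(nrow(chain))
    out[[sc_num]] <- chain
  }
  res <- dplyr::bind_rows(out)
  res <- res[, c("scaffold", "position", "contig", "orient", "gap_to_next")]
  structure(res, class = c("scaffold_layout", class(res)))
}

#' Render scaffold sequences
#'
#' Concatenates each scaffold's oriented contig sequences (`-` means
#' reverse complement), separated by the gap encoding: an estimated gap
#' `g >= 1` becomes `g` literal `N`s; `g <= 0` (overlap or abutting)
#' becomes a single lowercase `n`.
#'
#' @param layouts A `scaffold_layout` tibble.
#' @param contigs Contig tibble (`id`, `seq`, `length`).
#' @return Tibble `id`, `seq`, `length`, one row per scaffold.
#' @export
emit_sequences <- function(layouts, contigs) {
  seq_of <- stats::setNames(contigs$seq, contigs$id)
  layouts |>
    dplyr::group_by(.data$scaffold) |>
    dplyr::summarise(seq = {
      s <- seq_of[.data$contig]
      s[.data$orient == "-"] <- revcomp_dna(s[.data$orient == "-"])
      g <- .data$gap_to_next[-length(s)]
      paste0(paste0(s[-length(s)], gap_pad(g), collapse = ""),
             s[length(s)])
    }, .groups = "drop") |>
    dplyr::rename(id = "scaffold") |>
    dplyr::arrange(match(.data$id, unique(layouts$scaffold))) |>
    dplyr::mutate(length = nchar(.data$seq))
}
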