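#' Score a scaffold layout against synthetic ground truth
#'
#' Compares the adjacencies of a layout with the true contig order,
#' orientations and gaps of a [make_truth()] fixture. An adjacency
#' `(A, qa) -> (B, qb)` is a recovered true junction when both contigs are
#' presented in a consistent genome direction (`qa` equals A's stored
#' orientation exactly when `qb` equals B's) and B is A's true neighbour on
#' that side; anything else is a false join. Whole-scaffold reverse
#' complements are therefore counted as correct.
#'
#' @param layouts A `scaffold_layout` from [build_scaffolds()].
#' @param truth The `truth` tibble of a `synthetic_truth` (columns `id`,
#'   `orient`, `gap_to_next` in genome order).
#' @return One-row tibble: `n_scaffolds`, `n_junctions_true`,
#'   `n_adjacencies`, `n_true_joins`, `n_false_joins`,
#'   `junction_recovery` (fraction of true junctions present),
#'   `max_abs_gap_error`, `mean_abs_gap_error` (over true joins; `NA` when
#'   none).
#' @export
score_against_truth <- function(layouts, truth) {
  idx_of <- stats::setNames(seq_len(nrow(truth)), truth$id)
  or_of <- stats::setNames(truth$orient, truth$id)
  adj <- layouts |>
    dplyr::group_by(.data$scaffold) |>
    dplyr::mutate(contig_b = dplyr::lead(.data$contig),
                  orient_b = dplyr::lead(.data$orient)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$contig_b))
  n_true_junc <- nrow(truth) - 1L

  if (nrow(adj) == 0) {
    return(tibble::tibble(
      n_scaffolds = length(unique(layouts$scaffold)),
      n_junctions_true = n_true_junc, n_adjacencies = 0L,
      n_true_joins = 0L, n_false_joins = 0L, junction_recovery = 0,
      max_abs_gap_error = NA_real_, mean_abs_gap_error = NA_real_))
  }

  ia <- idx_of[adj$contig]
  ib <- idx_of[adj$contig_b]
  # +1 when the layout presents the contig genome-forward
  sa <- ifelse(adj$orient == or_of[adj$contig], 1L, -1L)
  sb <- ifelse(adj$orient_b == or_of[adj$contig_b], 1L, -1L)
  ok <- !is.na(ia) & !is.na(ib) & sa == sb & ib == ia + sa
  ok[is.na(ok)] <- FALSE  # contigs unknown to the truth are false joins
  true_gap <- truth$gap_to_next[pmin(ia, ib)]
  gap_err <- abs(adj$gap_to_next - true_gap)[ok]

  tibble::tibble(
    n_scaffolds = length(unique(layouts$scaffold)),
    n_junctions_true = n_true_junc,
    n_adjacencies = nrow(adj),
    n_true_joins = sum(ok),
    n_false_joins = sum(!ok),
    junction_recovery = length(unique(pmin(ia, ib)[ok])) /
      max(n_true_junc, 1L),
    max_abs_gap_error = if (any(ok)) max(gap_err) else NA_real_,
    mean_abs_gap_error = if (any(ok)) mean(gap_err) else NA_real_)
}
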