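#' Plot a fitted run-length mixture against its data
#'
#' Empirical run-length frequencies (bars) with the fitted mixture pmf
#' overlaid (points and line).
#'
#' @param object A `run_length_fit`.
#' @param tally The `fragment_tally` the fit was computed from.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.run_length_fit <- function(object, tally, ...) {
  n <- sum(tally$count)
  emp <- dplyr::mutate(tally, freq = .data$count / n)
  fit <- tibble::tibble(
    length = emp$length,
    freq = mixture_pmf(emp$length, as.list(object$params), object$type))
  ggplot2::ggplot(emp, ggplot2::aes(x = .data$length, y = .data$freq)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_line(data = fit, colour = "firebrick") +
    ggplot2::geom_point(data = fit, colour = "firebrick", size = 1) +
    ggplot2::labs(x = paste0(object$type, " run length (",
                             attr(tally, "indexing"), "-indexed)"),
                  y = "relative frequency",
                  title = sprintf("%s mixture fit (KS p = %.3g)",
                                  object$type, object$ks_p)) +
    ggplot2::theme_minimal()
}

#' Plot the calculated-distance distribution of pair observations
#'
#' Histogram of the calculated footprints of cross-contig, uniquely placed
#' k-mer pair observations, with the target distance and the accepted band
#' marked. Pairs outside the band are rejected by the distance logic.
#'
#' @param link_set A `contig_link_set` from [build_links()].
#' @param d Target distance (for the reference lines).
#' @param e Deviation fraction (default 0.1).
#' @param binwidth Histogram bin width (default `max(10, e*d/20)`).
#' @return A ggplot object.
#' @export
plot_pairing_distribution <- function(link_set, d, e = 0.1,
                                      binwidth = NULL) {
  tb <- tibble::tibble(distance = link_set$distances)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(binwidth = binwidth %||% max(10, e * d / 20),
                            fill = "steelblue") +
    ggplot2::geom_vline(xintercept = d, linetype = 1) +
    ggplot2::geom_vline(xintercept = d * c(1 - e, 1 + e), linetype = 2) +
    ggplot2::labs(x = "calculated distance (bp)", y = "pair observations",
                  title = sprintf("accepted band %d +/- %d bp",
                                  as.integer(d), as.integer(e * d))) +
    ggplot2::theme_minimal()
}

#' Plot a scaffold layout
#'
#' One horizontal bar per scaffold, contigs drawn to scale in layout order
#' and coloured by orientation, separated by their estimated gaps
#' (overlaps draw as single-base separators).
#'
#' @param object A `scaffold_layout` from [build_scaffolds()].
#' @param contigs Contig tibble (`id`, `seq`, `length`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scaffold_layout <- function(object, contigs, ...) {
  len_of <- stats::setNames(contigs$length, contigs$id)
  df <- object |>
    dplyr::group_by(.data$scaffold) |>
    dplyr::mutate(
      clen = len_of[.data$contig],
      sep = pmax(dplyr::lag(.data$gap_to_next, default = 0), 1),
      xend = cumsum(.data$clen + .data$sep),
      xstart = .data$xend - .data$clen) |>
    dplyr::ungroup()
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$xstart, xmax = .data$xend,
                                    ymin = 0.1, ymax = 0.9,
                                    fill = .data$orient)) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$scaffold), switch = "y") +
    ggplot2::scale_fill_manual(values = c(`+` = "steelblue",
                                          `-` = "indianred")) +
    ggplot2::labs(x = "position (bp)", fill = "orientation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   strip.text.y.left = ggplot2::element_text(angle = 0))
}

#' @export
ggplot2::autoplot

#' Summary of a scaffold layout
#'
#' @param x A `scaffold_layout`.
#' @param ... Unused.
#' @return One-row tibble: `n_scaffolds`, `n_contigs`, `n_merges`,
#'   `largest_chain` (most contigs in one scaffold).
#' @export
glance.scaffold_layout <- function(x, ...) {
  per <- dplyr::count(x, .data$scaffold)
  tibble::tibble(n_scaffolds = nrow(per), n_contigs = nrow(x),
                 n_merges = nrow(x) - nrow(per),
                 largest_chain = max(per$n))
}
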