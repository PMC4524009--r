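#' Read a draft assembly from FASTA
#'
#' Loads contigs (or scaffolds) to be linked. Record ids are the first
#' whitespace-delimited token of each header; bases are upper-cased; records
#' shorter than `min_len` are dropped before any k-mer work, following the
#' usual >= 500 bp reporting convention for draft assemblies.
#'
#' @param path Path to a FASTA file.
#' @param min_len Minimum contig length in bases to retain (default 500).
#' @return A tibble with columns `id`, `seq`, `length`, in file order.
#' @export
read_assembly <- function(path, min_len = 500) {
  stopifnot(min_len >= 0)
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x) %||% character(0))
  tb <- tibble::tibble(
    id = ids,
    seq = unname(toupper(as.character(x))),
    length = nchar(seq)
  )
  if (anyDuplicated(tb$id)) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(tb$id[duplicated(tb$id)]), collapse = ", "))
  }
  dplyr::filter(tb, .data$length >= min_len)
}

as_contig_tbl <- function(ids, seqs) {
  tibble::tibble(id = unname(ids), seq = unname(toupper(seqs)),
                 length = nchar(seqs))
}

#' Read long sequences via a file-of-filenames
#'
#' Each non-empty, non-comment (`#`) line of `fof_path` names a FASTA or
#' FASTQ file; the format is auto-detected from the first character of the
#' file (`>` vs `@`). Reads are returned in listed-file order, then record
#' order. FASTQ quality strings are discarded.
#'
#' @param fof_path Path to the file-of-filenames.
#' @return A tibble with columns `id`, `seq`, `length`.
#' @export
read_long_reads <- function(fof_path) {
  lines <- trimws(readLines(fof_path))
  files <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- lapply(files, function(f) {
    if (!file.exists(f)) stop("listed sequence file not found: ", f)
    first <- substr(readLines(f, n = 1L), 1L, 1L)
    fmt <- if (identical(first, ">")) "fasta" else if (identical(first, "@")) "fastq"
           else stop("unrecognized sequence format in ", f,
                     " (first character ", dQuote(first), ")")
    x <- Biostrings::readDNAStringSet(f, format = fmt)
    as_contig_tbl(sub("\\s.*$", "", names(x)), as.character(x))
  })
  dplyr::bind_rows(parts)
}

#' Write sequences as FASTA
#'
#' Minimal writer that preserves character case exactly (needed for the
#' single lowercase `n` flagging contig overlaps in scaffold output).
#'
#' @param ids,seqs Character vectors of record ids and sequences.
#' @param path Output path.
#' @param width Line width for sequence wrapping (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ids, seqs, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(ids)) {
    writeLines(paste0(">", ids[i]), con)
    n <- nchar(seqs[i])
    if (n == 0L) next
    starts <- seq(1L, n, by = width)
    writeLines(substring(seqs[i], starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

# Gap encoding between merged neighbours: estimated gap g >= 1 becomes g 'N'
# pads; g <= 0 (overlap or abutting) becomes a single lowercase 'n'.
gap_pad <- function(g) ifelse(g >= 1, strrep("N", pmax(g, 0)), "n")

#' Write the scaffolder output file family
#'
#' Writes, under prefix `base`:
#' * `base.scaffold` — one line per scaffold: `scaffoldN,totalSize,chain`,
#'   where the chain is `_`-joined tokens `<f|r><contigId>z<contigLen>`
#'   (f = forward, r = reverse) and each token merged to a right neighbour
#'   carries `m<gapEstimate>`;
#' * `base.scaffold.fa` — scaffold sequences, gaps as `N` pads, overlaps as a
#'   single `n`, 60-column lines;
#' * `base.log` — appended plain-text run log;
#' * `base.pairing_issues` — one rejected pair observation per line;
#' * `base.pairing_distribution.csv` — `distance,count` histogram of
#'   calculated distances.
#'
#' @param layouts A scaffold layout tibble from [build_scaffolds()].
#' @param contigs Contig tibble (`id`, `seq`, `length`).
#' @param base Output path prefix.
#' @param issues Optional pairing issue log from [build_links()].
#' @param distances Optional integer vector of calculated distances.
#' @param log_lines Optional character vector appended to `base.log`.
#' @return Named character vector of the five paths, invisibly.
#' @export
write_outputs <- function(layouts, contigs, base,
                          issues = NULL, distances = NULL, log_lines = NULL) {
  stopifnot(all(layouts$contig %in% contigs$id))
  seqs <- emit_sequences(layouts, contigs)

  # .scaffold summary
  len_of <- stats::setNames(contigs$length, contigs$id)
  chain_lines <- layouts |>
    dplyr::group_by(.data$scaffold) |>
    dplyr::summarise(chain = {
      tok <- paste0(ifelse(.data$orient == "+", "f", "r"),
                    .data$contig, "z", len_of[.data$contig])
      merged <- !is.na(.data$gap_to_next)
      tok[merged] <- paste0(tok[merged], "m", .data$gap_to_next[merged])
      paste(tok, collapse = "_")
    }, .groups = "drop")
  sc_line <- dplyr::left_join(seqs, chain_lines, by = c(id = "scaffold"))
  writeLines(paste(sc_line$id, sc_line$length, sc_line$chain, sep = ","),
             paste0(base, ".scaffold"))

  write_fasta(seqs$id, seqs$seq, paste0(base, ".scaffold.fa"))

  cat(paste0(c(paste0("[", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "] ",
                      "wrote ", nrow(seqs), " scaffold(s) from ",
                      nrow(layouts), " contig(s)"),
               log_lines), "\n", collapse = ""),
      file = paste0(base, ".log"), append = TRUE)

  issue_path <- paste0(base, ".pairing_issues")
  if (!is.null(issues) && nrow(issues$records) > 0) {
    r <- issues$records
    writeLines(paste(r$reason, r$contig_a, r$contig_b, r$distance, r$target_d,
                     sep = "\t"), issue_path)
  } else {
    writeLines(character(0), issue_path)
  }

  dist_path <- paste0(base, ".pairing_distribution.csv")
  dist_tbl <- if (is.null(distances) || length(distances) == 0) {
    tibble::tibble(distance = integer(0), count = integer(0))
  } else {
    dplyr::count(tibble::tibble(distance = distances), .data$distance,
                 name = "count")
  }
  utils::write.csv(dist_tbl, dist_path, row.names = FALSE, quote = FALSE)

  invisible(c(scaffold = paste0(base, ".scaffold"),
              fasta = paste0(base, ".scaffold.fa"),
              log = paste0(base, ".log"),
              pairing_issues = issue_path,
              pairing_distribution = dist_path))
}
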