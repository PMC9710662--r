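# Relaxed-Phylip input/output.  Names may be any length (whitespace
# terminated) -- the strict 10-character dialect would truncate exactly the
# tokens concatenation matches on.  Sequential layout is one record per line
# ("name seq"); interleaved layout repeats names in every block.  Reading
# auto-detects the layout.

#' Read a relaxed Phylip file
#'
#' The first line must be \code{ntax nchar}.  Sequential files carry one
#' record per line; interleaved files carry blocks of \code{ntax} lines each,
#' with or without repeated name tokens in continuation blocks.  Both layouts
#' are auto-detected.
#'
#' @param input File path or Phylip text.
#' @param marker_name Marker name; defaults to the file-name stem.
#' @return A \code{\link{marker_block}} with exactly \code{ntax} records of
#'   \code{nchar} columns.
#' @export
read_phylip <- function(input, marker_name = NULL) {
  if (is.null(marker_name)) {
    marker_name <- input_stem(input)
    if (is.null(marker_name)) marker_name <- "marker"
  }
  lines <- as_lines(input)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    abort_genecat("genecat_format_error", "Phylip input has no sequence rows")
  }
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) != 2L || anyNA(suppressWarnings(as.integer(hdr)))) {
    abort_genecat("genecat_format_error",
                  "Phylip header must be 'ntax nchar'")
  }
  ntax <- as.integer(hdr[1]); nchr <- as.integer(hdr[2])
  body <- lines[-1]
  if (length(body) %% ntax != 0L || length(body) < ntax) {
    abort_genecat("genecat_format_error", sprintf(
      "expected a multiple of %d sequence rows, found %d", ntax, length(body)))
  }
  nblock <- length(body) %/% ntax
  names_out <- character(ntax)
  seqs <- character(ntax)
  for (b in seq_len(nblock)) {
    for (i in seq_len(ntax)) {
      toks <- strsplit(trimws(body[(b - 1L) * ntax + i]), "\\s+")[[1]]
      if (b == 1L) {
        if (length(toks) < 2L) {
          abort_genecat("genecat_format_error", sprintf(
            "row %d lacks a sequence after the name token", i))
        }
        names_out[i] <- toks[1]
        seqs[i] <- paste(toks[-1], collapse = "")
      } else {
        # continuation block: name token optional
        if (toks[1] == names_out[i] && length(toks) > 1L) {
          seqs[i] <- paste0(seqs[i], paste(toks[-1], collapse = ""))
        } else {
          seqs[i] <- paste0(seqs[i], paste(toks, collapse = ""))
        }
      }
    }
  }
  if (any(nchar(seqs) != nchr)) {
    abort_genecat("genecat_format_error", sprintf(
      "header declares %d columns but sequence '%s' has %d",
      nchr, names_out[which(nchar(seqs) != nchr)[1]],
      nchar(seqs)[which(nchar(seqs) != nchr)[1]]))
  }
  names(seqs) <- names_out
  marker_block(marker_name, seqs)
}

#' Write a marker block or alignment as relaxed Phylip
#'
#' @param x A uniform-length \code{marker_block} or \code{concat_alignment}.
#' @param interleaved Write interleaved blocks of \code{block_width} columns
#'   (names repeated in every block) instead of one record per line.
#' @param block_width Columns per interleaved block. Default 60.
#' @param file Optional path to write to.
#' @return The Phylip text, invisibly when \code{file} is given.
#' @export
write_phylip <- function(x, interleaved = FALSE, block_width = 60L, file = NULL) {
  seqs <- seqs_of(x)
  if (length(seqs) == 0L) {
    abort_genecat("genecat_empty_input_error", "refusing to write an empty Phylip file")
  }
  lens <- nchar(seqs)
  if (any(lens != lens[1])) {
    abort_genecat("genecat_not_aligned_error",
                  "Phylip requires records of uniform length; align the marker first")
  }
  L <- lens[1]
  header <- sprintf("%d %d", length(seqs), L)
  if (!interleaved || L <= block_width) {
    rows <- paste(names(seqs), seqs)
    return(emit_text(paste0(header, "\n", paste(rows, collapse = "\n"), "\n"), file))
  }
  starts <- seq.int(1L, L, by = block_width)
  blocks <- vapply(starts, function(s) {
    chunk <- substring(seqs, s, min(s + block_width - 1L, L))
    paste(paste(names(seqs), chunk), collapse = "\n")
  }, character(1))
  emit_text(paste0(header, "\n", paste(blocks, collapse = "\n\n"), "\n"), file)
}
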