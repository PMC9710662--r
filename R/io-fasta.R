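# FASTA input/output.  One file carries one marker; the header token up to
# the first whitespace is the sample name (concatenation matches on exact
# tokens, so trailing description text is dropped).

#' Read a FASTA file into a marker block
#'
#' Parsing is delegated to \code{Biostrings::readBStringSet}; sequences are
#' upper-cased and validated against the IUPAC nucleotide alphabet (plus
#' \code{-} and \code{?}).
#'
#' @param input File path or FASTA text.
#' @param marker_name Marker name; defaults to the file-name stem when
#'   \code{input} is a path.
#' @return A \code{\link{marker_block}}.
#' @examples
#' read_fasta(">A\nACGT\n>B\nAC-T\n", marker_name = "COI")
#' @export
read_fasta <- function(input, marker_name = NULL) {
  if (is.null(marker_name)) {
    marker_name <- input_stem(input)
    if (is.null(marker_name)) marker_name <- "marker"
  }
  path <- if (looks_like_path(input)) {
    input
  } else {
    tmp <- tempfile(fileext = ".fasta")
    writeLines(as_lines(input), tmp)
    tmp
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) abort_genecat(
                    "genecat_format_error",
                    sprintf("not a readable FASTA file: %s", conditionMessage(e))))
  if (length(set) == 0L) {
    abort_genecat("genecat_empty_input_error", "FASTA input contains no sequences")
  }
  headers <- names(set)
  samples <- vapply(strsplit(headers, "[ \t]+"), `[[`, character(1), 1L)
  if (anyDuplicated(samples)) {
    abort_genecat("genecat_duplicate_sample_error", sprintf(
      "duplicate FASTA header(s): %s",
      paste(unique(samples[duplicated(samples)]), collapse = ", ")))
  }
  seqs <- as.character(set)
  names(seqs) <- samples
  marker_block(marker_name, seqs)
}

#' Write a marker block or alignment as FASTA
#'
#' @param x A \code{marker_block} or \code{concat_alignment}.
#' @param line_width Residues per line; 0 means unwrapped. Default 60.
#' @param file Optional path to write to.
#' @return The FASTA text, invisibly when \code{file} is given.
#' @export
write_fasta <- function(x, line_width = 60L, file = NULL) {
  seqs <- seqs_of(x)
  if (length(seqs) == 0L) {
    abort_genecat("genecat_empty_input_error", "refusing to write an empty FASTA file")
  }
  if (line_width < 0L) {
    abort_genecat("genecat_format_error", "line_width must be >= 0")
  }
  body <- vapply(seq_along(seqs), function(i) {
    paste0(">", names(seqs)[i], "\n", wrap_residues(seqs[[i]], line_width))
  }, character(1))
  emit_text(paste0(paste(body, collapse = "\n"), "\n"), file)
}
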