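# Shared reader/writer plumbing.  Every reader accepts either a file path or
# literal text (a string containing newlines, or a character vector of lines);
# every writer returns the full file content as a single string ending in
# "\n" and can optionally write it to a file.

# TRUE when `input` looks like a path rather than file content.
looks_like_path <- function(input) {
  is.character(input) && length(input) == 1L && !grepl("[\n>\t]", input) &&
    file.exists(input)
}

# Normalize any reader input to a character vector of lines.
as_lines <- function(input) {
  if (looks_like_path(input)) {
    lines <- tryCatch(readLines(input, warn = FALSE),
                      error = function(e) abort_genecat(
                        "genecat_format_error",
                        sprintf("cannot read '%s': %s", input, conditionMessage(e))))
    return(lines)
  }
  if (!is.character(input)) {
    abort_genecat("genecat_format_error", "input must be a file path or text")
  }
  if (length(input) == 1L) strsplit(input, "\n", fixed = TRUE)[[1]] else input
}

input_stem <- function(input) {
  if (looks_like_path(input)) {
    stem <- tools::file_path_sans_ext(basename(input))
    stem <- gsub("[^A-Za-z0-9_.-]", "_", stem)
    if (nzchar(stem)) return(stem)
  }
  NULL
}

# Writers funnel through this: returns `text` invisibly, writes it if asked.
emit_text <- function(text, file = NULL) {
  if (!is.null(file)) {
    con <- base::file(file, open = "wb")
    on.exit(close(con))
    writeChar(text, con, eos = NULL)
  }
  invisible(text)
}

wrap_residues <- function(seq, width) {
  if (width <= 0L || nchar(seq) <= width) return(seq)
  starts <- seq.int(1L, nchar(seq), by = width)
  paste(substring(seq, starts, pmin(starts + width - 1L, nchar(seq))),
        collapse = "\n")
}

# Extract the named residue vector from a marker_block or concat_alignment.
seqs_of <- function(x) {
  if (inherits(x, "marker_block") || inherits(x, "concat_alignment")) {
    return(x$sequences)
  }
  abort_genecat("genecat_format_error",
                "expected a marker_block or concat_alignment")
}

#' Sniff the format of an input file or text
#'
#' Classification is content-based: a leading \code{>} means FASTA,
#' \code{#NEXUS} means Nexus, a numeric \code{ntax nchar} header means
#' Phylip, a tab-containing header row means TSV, and \code{DNA, name = ...}
#' lines mean a RAxML-style partition file.
#'
#' @param input File path or text.
#' @return One of \code{"fasta"}, \code{"nexus"}, \code{"phylip"},
#'   \code{"tsv"}, \code{"partition"}.
#' @export
detect_format <- function(input) {
  lines <- tryCatch(as_lines(input), error = function(e) character(0))
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines)) {
    first <- trimws(lines[1])
    if (startsWith(first, ">")) return("fasta")
    if (grepl("^#NEXUS", first, ignore.case = TRUE)) return("nexus")
    if (grepl("^\\d+\\s+\\d+$", first)) return("phylip")
    if (grepl("^(DNA|AA)\\s*,", first, ignore.case = TRUE)) return("partition")
    if (grepl("\t", lines[1], fixed = TRUE)) return("tsv")
  }
  abort_genecat("genecat_unknown_format_error",
                "could not recognize the input as fasta, phylip, nexus, tsv or partition")
}
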