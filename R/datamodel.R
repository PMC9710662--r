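# Core data model: marker blocks, the multi-marker data matrix, charsets and
# concatenated alignments.  Everything downstream (readers, writers, the
# concatenation engine, validation) speaks these types.
#
# Representation choices:
#  * a marker block holds its records as a named character vector
#    (names = sample names, values = residue strings);
#  * a data matrix is an ordered list of marker blocks plus an optional
#    metadata data.frame keyed by sample name;
#  * sample-name matching is exact and case-sensitive everywhere.

# IUPAC nucleotide codes, alignment gap '-' and missing '?'.
# Spelled as a regex character-class body ('-' last so it is literal).
GENECAT_ALPHABET <- "ACGTRYSWKMBDHVN?-"
TOKEN_REGEX <- "^[A-Za-z0-9_.-]+$"

is_token <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) && grepl(TOKEN_REGEX, x)
}

check_token <- function(x, what) {
  if (!is_token(x)) {
    abort_genecat("genecat_token_error", sprintf(
      "%s %s is not a valid token (must match [A-Za-z0-9_.-]+, no whitespace)",
      what, deparse(as.character(x)[1])))
  }
  invisible(x)
}

#' Create a marker block
#'
#' A marker block is one genetic marker (locus) together with the sequences of
#' all samples that carry it.  Residues are upper-cased on ingestion and must
#' be IUPAC nucleotide codes, the gap character \code{-} or the missing
#' character \code{?}.
#'
#' @param name Marker name; a token matching \code{[A-Za-z0-9_.-]+}.
#' @param sequences Named character vector: names are sample names (tokens,
#'   unique within the block), values are residue strings.
#' @return An object of class \code{marker_block}.
#' @examples
#' b <- marker_block("COI", c(sampleA = "ACGT", sampleB = "AC-T"))
#' marker_length(b)
#' @export
marker_block <- function(name, sequences) {
  check_token(name, "marker name")
  if (!is.character(sequences)) {
    abort_genecat("genecat_format_error", "sequences must be a character vector")
  }
  sn <- names(sequences)
  if (length(sequences) > 0L && (is.null(sn) || anyNA(sn) || any(!nzchar(sn)))) {
    abort_genecat("genecat_token_error", "every sequence must carry a sample name")
  }
  for (s in sn) check_token(s, "sample name")
  if (anyDuplicated(sn)) {
    abort_genecat("genecat_duplicate_sample_error", sprintf(
      "duplicate sample name(s) in marker '%s': %s", name,
      paste(unique(sn[duplicated(sn)]), collapse = ", ")))
  }
  sequences <- toupper(sequences)
  bad <- grepl(sprintf("[^%s]", GENECAT_ALPHABET), sequences)
  if (any(bad)) {
    chars <- unique(unlist(strsplit(
      gsub(sprintf("[%s]", GENECAT_ALPHABET), "", sequences[bad]), "")))
    abort_genecat("genecat_alphabet_error", sprintf(
      "illegal residue character(s) %s in marker '%s' (sample %s)",
      paste(sQuote(chars), collapse = ", "), name, sn[bad][1]))
  }
  structure(list(name = name, sequences = sequences), class = "marker_block")
}

#' @export
print.marker_block <- function(x, ...) {
  lens <- nchar(x$sequences)
  cat(sprintf("<marker_block '%s': %d sequence(s), %s>\n", x$name,
              length(x$sequences),
              if (is_uniform(x)) sprintf("%d columns", marker_length(x))
              else sprintf("ragged (%d-%d columns)", min(lens), max(lens))))
  invisible(x)
}

#' Marker block length helpers
#'
#' \code{is_uniform} reports whether all records of a block have the same
#' number of columns (i.e. the marker is aligned); \code{marker_length}
#' returns that common length, or \code{NA} for a ragged block.
#'
#' @param block A \code{marker_block}.
#' @return \code{is_uniform}: logical; \code{marker_length}: integer or
#'   \code{NA_integer_}.
#' @export
is_uniform <- function(block) {
  lens <- nchar(block$sequences)
  length(lens) == 0L || all(lens == lens[1])
}

#' @rdname is_uniform
#' @export
marker_length <- function(block) {
  if (length(block$sequences) == 0L || !is_uniform(block)) return(NA_integer_)
  nchar(block$sequences[[1]])
}

#' Assemble a data matrix from marker blocks
#'
#' A data matrix is an ordered collection of marker blocks over a shared,
#' possibly sparse, sample universe: a sample need not occur in every marker.
#' Marker order is significant and preserved by all operations.
#'
#' @param blocks List of \code{marker_block} objects with unique marker names.
#' @param metadata Optional \code{data.frame} of per-sample metadata.  The
#'   identifier column is taken from \code{attr(metadata, "id_column")} or,
#'   absent that, the first column; its values must be unique.
#' @return An object of class \code{data_matrix}.
#' @examples
#' m <- make_matrix(list(
#'   marker_block("16S", c(A = "ACGTT", B = "ACGTA")),
#'   marker_block("COI", c(B = "TGC", C = "TGA"))))
#' sample_names(m)
#' @export
make_matrix <- function(blocks, metadata = NULL) {
  if (!is.list(blocks) || !all(vapply(blocks, inherits, logical(1), "marker_block"))) {
    abort_genecat("genecat_format_error", "blocks must be a list of marker_block objects")
  }
  nm <- vapply(blocks, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    abort_genecat("genecat_duplicate_marker_error", sprintf(
      "duplicate marker name(s): %s", paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  names(blocks) <- nm
  if (!is.null(metadata)) {
    if (!is.data.frame(metadata) || ncol(metadata) < 1L) {
      abort_genecat("genecat_format_error", "metadata must be a data.frame with at least one column")
    }
    idc <- attr(metadata, "id_column")
    if (is.null(idc)) idc <- names(metadata)[1]
    if (!idc %in% names(metadata)) {
      abort_genecat("genecat_format_error", sprintf("metadata lacks identifier column '%s'", idc))
    }
    ids <- as.character(metadata[[idc]])
    if (anyDuplicated(ids)) {
      abort_genecat("genecat_duplicate_sample_error", sprintf(
        "duplicate sample identifier(s) in metadata: %s",
        paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    }
    attr(metadata, "id_column") <- idc
  }
  structure(list(markers = blocks, metadata = metadata), class = "data_matrix")
}

#' @export
print.data_matrix <- function(x, ...) {
  cat(sprintf("<data_matrix: %d marker(s), %d sample(s)>\n",
              length(x$markers), length(sample_names(x))))
  if (length(x$markers)) print(marker_overview(x))
  invisible(x)
}

#' Marker and sample accessors
#'
#' @param matrix A \code{data_matrix}.
#' @return \code{marker_names}: character vector of marker names in matrix
#'   order.  \code{sample_names}: the sample universe (union over markers) in
#'   first-appearance order.
#' @export
marker_names <- function(matrix) {
  vapply(matrix$markers, `[[`, character(1), "name", USE.NAMES = FALSE)
}

#' @rdname marker_names
#' @export
sample_names <- function(matrix) {
  unique(unlist(lapply(matrix$markers, function(b) names(b$sequences)),
                use.names = FALSE))
}

#' Per-marker summary table
#'
#' One row per marker, in matrix order: number of records, alignment length
#' (or range when ragged), and the missing-data census.  The headline
#' \code{pct_missing} counts \code{?}, \code{N} and \code{-} together; the
#' three counts are also reported separately so either convention (gaps as
#' missing or not) is recoverable.
#'
#' @param matrix A \code{data_matrix}.
#' @return A \code{data.frame} with columns \code{marker}, \code{n_samples},
#'   \code{length_min}, \code{length_max}, \code{is_uniform},
#'   \code{n_question}, \code{n_n}, \code{n_gap}, \code{pct_missing}.
#' @export
marker_overview <- function(matrix) {
  stopifnot(inherits(matrix, "data_matrix"))
  rows <- lapply(matrix$markers, function(b) {
    s <- b$sequences
    total <- sum(nchar(s))
    nq <- sum(nchar(s) - nchar(gsub("?", "", s, fixed = TRUE)))
    nn <- sum(nchar(s) - nchar(gsub("N", "", s, fixed = TRUE)))
    ng <- sum(nchar(s) - nchar(gsub("-", "", s, fixed = TRUE)))
    lens <- nchar(s)
    data.frame(
      marker = b$name, n_samples = length(s),
      length_min = if (length(s)) min(lens) else 0L,
      length_max = if (length(s)) max(lens) else 0L,
      is_uniform = is_uniform(b),
      n_question = nq, n_n = nn, n_gap = ng,
      pct_missing = if (total > 0) 100 * (nq + nn + ng) / total else 0,
      stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(marker = character(), n_samples = integer(),
               length_min = integer(), length_max = integer(),
               is_uniform = logical(), n_question = integer(),
               n_n = integer(), n_gap = integer(),
               pct_missing = numeric(), stringsAsFactors = FALSE)
  }
  out
}

#' Delete, reorder or rename markers
#'
#' Pure transformations of a data matrix: the input is never modified.
#'
#' @param matrix A \code{data_matrix}.
#' @param names Character vector of marker names to remove.
#' @return A new \code{data_matrix}.
#' @export
delete_markers <- function(matrix, names) {
  stopifnot(inherits(matrix, "data_matrix"))
  names <- as.character(names)
  unknown <- setdiff(names, marker_names(matrix))
  if (length(unknown)) {
    abort_genecat("genecat_unknown_marker_error", sprintf(
      "unknown marker(s): %s", paste(unknown, collapse = ", ")))
  }
  keep <- !(marker_names(matrix) %in% names)
  make_matrix(matrix$markers[keep], matrix$metadata)
}

#' @rdname delete_markers
#' @param order Character vector: a permutation of the matrix's marker names.
#' @export
reorder_markers <- function(matrix, order) {
  stopifnot(inherits(matrix, "data_matrix"))
  cur <- marker_names(matrix)
  if (length(order) != length(cur) || anyDuplicated(order) ||
      !setequal(order, cur)) {
    abort_genecat("genecat_invalid_order_error",
                  "order must be a permutation of the matrix's marker names")
  }
  make_matrix(matrix$markers[match(order, cur)], matrix$metadata)
}

#' @rdname delete_markers
#' @param old,new Old and new marker name (\code{new} must be an unused token).
#' @export
rename_marker <- function(matrix, old, new) {
  stopifnot(inherits(matrix, "data_matrix"))
  cur <- marker_names(matrix)
  if (!old %in% cur) {
    abort_genecat("genecat_unknown_marker_error", sprintf("unknown marker '%s'", old))
  }
  check_token(new, "marker name")
  if (new %in% setdiff(cur, old)) {
    abort_genecat("genecat_duplicate_marker_error", sprintf(
      "cannot rename '%s' to '%s': marker '%s' already exists", old, new, new))
  }
  blocks <- matrix$markers
  i <- match(old, cur)
  blocks[[i]] <- marker_block(new, blocks[[i]]$sequences)
  make_matrix(blocks, matrix$metadata)
}

#' Create a charset (named column range)
#'
#' A charset names a 1-based, inclusive column range of a concatenated
#' alignment.  Whole-marker charsets have \code{step = 1}; codon-position
#' subsets have \code{step = 3} and may be empty (\code{start > end}) for
#' markers shorter than the reading-frame offset.
#'
#' @param name Charset name (token).
#' @param start,end First and last column, 1-based inclusive.
#' @param step 1 (whole-marker) or 3 (codon subset).
#' @param marker For codon subsets, the source marker's name.
#' @return An object of class \code{charset}.
#' @export
charset <- function(name, start, end, step = 1L, marker = NULL) {
  check_token(name, "charset name")
  start <- as.integer(start); end <- as.integer(end); step <- as.integer(step)
  if (!step %in% c(1L, 3L)) {
    abort_genecat("genecat_partition_error", "charset step must be 1 or 3")
  }
  if (is.na(start) || start < 1L ||
      (step == 1L && end < start) ||
      (step == 3L && end < start - 3L)) {
    abort_genecat("genecat_partition_error", sprintf(
      "invalid charset range %d-%d for '%s'", start, end, name))
  }
  structure(list(name = name, start = start, end = end, step = step,
                 marker = marker),
            class = "charset")
}

#' Columns covered by a charset
#'
#' @param cs A \code{charset}.
#' @return Integer vector of 1-based column indices (empty for an empty codon
#'   subset).
#' @export
charset_columns <- function(cs) {
  if (cs$start > cs$end) return(integer(0))
  seq.int(cs$start, cs$end, by = cs$step)
}

#' @export
print.charset <- function(x, ...) {
  cat(sprintf("<charset %s = %d-%d%s>\n", x$name, x$start, x$end,
              if (x$step == 3L) "\\3" else ""))
  invisible(x)
}

# Internal constructor; validates that whole-marker charsets tile 1..L.
new_concat_alignment <- function(sequences, charsets, codon_charsets = list()) {
  lens <- nchar(sequences)
  if (length(sequences) == 0L) {
    abort_genecat("genecat_empty_input_error", "alignment has no sequences")
  }
  if (any(lens != lens[1])) {
    abort_genecat("genecat_not_aligned_error", "alignment records differ in length")
  }
  check_tiling(charsets, lens[1])
  structure(list(sequences = sequences, charsets = charsets,
                 codon_charsets = codon_charsets),
            class = "concat_alignment")
}

# Whole-marker charsets must be contiguous, non-overlapping and exactly tile
# 1..L.  Raises genecat_partition_error otherwise.
check_tiling <- function(charsets, L) {
  if (!length(charsets)) {
    abort_genecat("genecat_partition_error", "no charsets given")
  }
  starts <- vapply(charsets, `[[`, integer(1), "start")
  ends <- vapply(charsets, `[[`, integer(1), "end")
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  if (starts[1] != 1L || ends[length(ends)] != L ||
      (length(starts) > 1L && any(starts[-1] != ends[-length(ends)] + 1L))) {
    abort_genecat("genecat_partition_error", sprintf(
      "charsets do not tile columns 1..%d without gaps or overlaps", L))
  }
  invisible(TRUE)
}

#' Build a concatenated alignment from sequences and charsets
#'
#' Mostly used by readers; \code{\link{concatenate}} is the usual way to
#' obtain a \code{concat_alignment}.
#'
#' @param sequences Named character vector of equal-length residue strings.
#' @param charsets List of whole-marker \code{charset}s tiling the columns.
#' @param codon_charsets Optional list of step-3 \code{charset}s.
#' @return An object of class \code{concat_alignment}.
#' @export
concat_alignment <- function(sequences, charsets, codon_charsets = list()) {
  blk <- marker_block("x", sequences)  # token/alphabet/duplicate validation
  new_concat_alignment(blk$sequences, charsets, codon_charsets)
}

#' @export
print.concat_alignment <- function(x, ...) {
  cat(sprintf("<concat_alignment: %d sample(s) x %d columns, %d marker(s)%s>\n",
              length(x$sequences), nchar(x$sequences[[1]]), length(x$charsets),
              if (length(x$codon_charsets))
                sprintf(", %d codon charset(s)", length(x$codon_charsets)) else ""))
  invisible(x)
}

#' Total alignment length
#'
#' @param alignment A \code{concat_alignment}.
#' @return Integer number of columns.
#' @export
alignment_length <- function(alignment) {
  nchar(alignment$sequences[[1]])
}
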