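# Tab-delimited multi-marker tables: one row per sample, free-form metadata
# columns (specimen voucher, locality, ...) plus one sequence column per
# marker.  This is the spreadsheet-curation format; empty sequence cells mean
# "this sample was never sequenced for this marker" and produce no record.

#' Read a multi-marker TSV table
#'
#' The first row is a header.  Columns whose names start with
#' \code{marker_prefix} (default \code{"sequence_"}) are sequence columns and
#' the suffix is the marker name; all other columns are metadata.  Sample
#' names come from \code{id_column} and are sanitized to the token alphabet.
#'
#' @param input File path or TSV text.
#' @param marker_prefix Prefix identifying sequence columns.
#' @param id_column Name of the identifier column. Default
#'   \code{"specimen_voucher"}.
#' @return A \code{\link{make_matrix}} result whose metadata holds all
#'   non-sequence columns.
#' @export
read_tsv <- function(input, marker_prefix = "sequence_",
                     id_column = "specimen_voucher") {
  lines <- as_lines(input)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    abort_genecat("genecat_empty_input_error", "TSV input is empty")
  }
  tab <- utils::read.delim(text = paste(lines, collapse = "\n"), sep = "\t",
                           header = TRUE, colClasses = "character",
                           check.names = FALSE, quote = "",
                           na.strings = character(0))
  hdr <- names(tab)
  seq_cols <- hdr[startsWith(hdr, marker_prefix)]
  if (!length(seq_cols)) {
    abort_genecat("genecat_format_error", sprintf(
      "no sequence columns found (expected headers starting with '%s')",
      marker_prefix))
  }
  if (!id_column %in% hdr) {
    abort_genecat("genecat_format_error", sprintf(
      "identifier column '%s' not found in the header", id_column))
  }
  ids <- sanitize_tokens(tab[[id_column]])
  if (any(!nzchar(ids))) {
    abort_genecat("genecat_token_error", "empty sample identifier in TSV input")
  }
  if (anyDuplicated(ids)) {
    abort_genecat("genecat_duplicate_sample_error", sprintf(
      "duplicate sample identifier(s): %s",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  blocks <- lapply(seq_cols, function(col) {
    vals <- tab[[col]]
    present <- !is.na(vals) & nzchar(trimws(vals))
    seqs <- toupper(trimws(vals[present]))
    names(seqs) <- ids[present]
    marker_block(substring(col, nchar(marker_prefix) + 1L), seqs)
  })
  blocks <- blocks[vapply(blocks, function(b) length(b$sequences) > 0L, logical(1))]
  meta <- tab[, setdiff(hdr, seq_cols), drop = FALSE]
  meta[[id_column]] <- ids
  attr(meta, "id_column") <- id_column
  make_matrix(blocks, meta)
}

#' Write a data matrix as a multi-marker TSV table
#'
#' Metadata columns come first, then one \code{sequence_<marker>} column per
#' marker in matrix order; samples lacking a marker get an empty cell.  A
#' matrix without metadata gets a synthesized \code{specimen_voucher} column
#' holding the sample names.  \code{read_tsv(write_tsv(x))} reproduces the
#' markers of \code{x}.
#'
#' @param matrix A \code{data_matrix}.
#' @param marker_prefix Prefix for sequence column headers.
#' @param file Optional path to write to.
#' @return The TSV text, invisibly when \code{file} is given.
#' @export
write_tsv <- function(matrix, marker_prefix = "sequence_", file = NULL) {
  stopifnot(inherits(matrix, "data_matrix"))
  samples <- sample_names(matrix)
  if (!length(samples)) {
    abort_genecat("genecat_empty_input_error", "refusing to write an empty TSV file")
  }
  meta <- matrix$metadata
  if (is.null(meta)) {
    meta <- data.frame(specimen_voucher = samples, stringsAsFactors = FALSE)
    attr(meta, "id_column") <- "specimen_voucher"
  }
  idc <- attr(meta, "id_column")
  if (is.null(idc)) idc <- names(meta)[1]
  # rows follow the sample universe; metadata looked up by identifier
  idx <- match(samples, as.character(meta[[idc]]))
  cols <- lapply(names(meta), function(cn) {
    v <- as.character(meta[[cn]])[idx]
    v[is.na(v)] <- ""
    v
  })
  names(cols) <- names(meta)
  cols[[idc]] <- samples
  for (b in matrix$markers) {
    v <- unname(b$sequences[samples])
    v[is.na(v)] <- ""
    cols[[paste0(marker_prefix, b$name)]] <- v
  }
  header <- paste(names(cols), collapse = "\t")
  rows <- do.call(paste, c(cols, sep = "\t"))
  emit_text(paste0(header, "\n", paste(rows, collapse = "\n"), "\n"), file)
}

#' Build display names from metadata fields
#'
#' Joins the chosen metadata fields with \code{separator} (empty fields are
#' skipped), sanitizes the result to the token alphabet and enforces
#' uniqueness.  The returned map feeds \code{\link{apply_display_names}} so
#' curated metadata (voucher, species, locality, ...) becomes the sequence
#' names of the concatenated output.
#'
#' @param metadata A metadata \code{data.frame} (see \code{\link{make_matrix}}).
#' @param fields Ordered character vector of metadata column names.
#' @param separator Joining string. Default \code{"_"}.
#' @return Named character vector: sample identifier -> display name.
#' @export
build_sequence_names <- function(metadata, fields, separator = "_") {
  stopifnot(is.data.frame(metadata), length(fields) >= 1L)
  missing_f <- setdiff(fields, names(metadata))
  if (length(missing_f)) {
    abort_genecat("genecat_format_error", sprintf(
      "metadata lacks field(s): %s", paste(missing_f, collapse = ", ")))
  }
  idc <- attr(metadata, "id_column")
  if (is.null(idc)) idc <- names(metadata)[1]
  ids <- as.character(metadata[[idc]])
  parts <- lapply(fields, function(f) {
    v <- as.character(metadata[[f]])
    v[is.na(v)] <- ""
    v
  })
  joined <- vapply(seq_along(ids), function(i) {
    vals <- vapply(parts, `[[`, character(1), i)
    paste(vals[nzchar(vals)], collapse = separator)
  }, character(1))
  out <- sanitize_tokens(joined)
  if (anyDuplicated(out)) {
    dup <- unique(out[duplicated(out)])
    rows <- which(out %in% dup)
    abort_genecat("genecat_name_collision_error", sprintf(
      "display name collision for rows %s (names: %s)",
      paste(rows, collapse = ", "), paste(dup, collapse = ", ")))
  }
  names(out) <- ids
  out
}

# Replace characters outside the token alphabet by '_' and trim whitespace.
sanitize_tokens <- function(x) {
  gsub("[^A-Za-z0-9_.-]", "_", trimws(as.character(x)))
}
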