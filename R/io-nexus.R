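# NEXUS input/output: DATA/CHARACTERS block (sequential or interleaved) plus
# the SETS block that records where each marker lies in the supermatrix.
# Keywords are matched case-insensitively; MISSING/GAP symbols from the
# FORMAT line are honored and canonicalized to '?' and '-'.

#' Read a Nexus file
#'
#' The DATA (or CHARACTERS) matrix is parsed, then sliced into one marker
#' block per whole-marker charset of the SETS block, in charset order.
#' Records that are entirely missing (\code{?}/\code{N}) within a marker's
#' columns are dropped from that marker, mirroring
#' \code{\link{deconcatenate}}.  Without a SETS block the whole matrix
#' becomes a single marker.  Codon-style charsets (\code{start-end\\3}) are
#' returned separately and do not participate in slicing.
#'
#' @param input File path or Nexus text.
#' @param marker_name Fallback marker name when no SETS block is present;
#'   defaults to the file-name stem.
#' @param allow_partition_gaps Keep columns not covered by any charset as
#'   markers named \code{unassigned_<i>} instead of raising an error.
#' @param drop_empty Drop all-missing records per marker (default TRUE).
#' @return A list with elements \code{matrix} (a \code{data_matrix}),
#'   \code{charsets} (whole-marker \code{charset}s) and \code{codon_charsets}.
#' @export
read_nexus <- function(input, marker_name = NULL,
                       allow_partition_gaps = FALSE, drop_empty = TRUE) {
  if (is.null(marker_name)) {
    marker_name <- input_stem(input)
    if (is.null(marker_name)) marker_name <- "concatenated"
  }
  lines <- as_lines(input)
  if (!length(lines) || !grepl("^\\s*#NEXUS", lines[1], ignore.case = TRUE)) {
    abort_genecat("genecat_format_error", "not a Nexus file (missing #NEXUS)")
  }
  text <- paste(lines, collapse = "\n")

  dat <- parse_nexus_data_block(text)
  sets <- parse_nexus_sets_block(text)
  L <- dat$nchar

  whole <- Filter(function(cs) cs$step == 1L, sets)
  codon <- Filter(function(cs) cs$step == 3L, sets)

  if (!length(whole)) {
    whole <- list(charset(marker_name, 1L, L))
  } else {
    whole <- resolve_partition(whole, L, allow_partition_gaps)
  }

  blocks <- lapply(whole, function(cs) {
    sub <- substring(dat$sequences, cs$start, cs$end)
    names(sub) <- names(dat$sequences)
    if (drop_empty) sub <- sub[!grepl("^[?N]+$", sub)]
    marker_block(cs$name, sub)
  })
  blocks <- blocks[vapply(blocks, function(b) length(b$sequences) > 0L, logical(1))]
  if (!length(blocks)) {
    abort_genecat("genecat_empty_input_error", "Nexus matrix contains no usable records")
  }
  list(matrix = make_matrix(blocks), charsets = whole, codon_charsets = codon)
}

# Fill uncovered runs with unassigned_<i> markers, or raise on gaps/overlap.
resolve_partition <- function(whole, L, allow_gaps) {
  starts <- vapply(whole, `[[`, integer(1), "start")
  ends <- vapply(whole, `[[`, integer(1), "end")
  o <- order(starts)
  if (any(ends > L)) {
    abort_genecat("genecat_partition_error", sprintf(
      "charset extends past the last column (%d)", L))
  }
  if (any(starts[o][-1] <= ends[o][-length(o)])) {
    abort_genecat("genecat_partition_error", "charsets overlap")
  }
  covered <- rep(FALSE, L)
  for (cs in whole) covered[cs$start:cs$end] <- TRUE
  if (all(covered)) return(whole)
  if (!allow_gaps) {
    abort_genecat("genecat_partition_error",
                  "charsets do not cover every column; set allow_partition_gaps = TRUE to keep uncovered runs")
  }
  # append unassigned markers for each maximal uncovered run, in column order
  runs <- rle(covered)
  pos <- cumsum(c(1L, runs$lengths))
  k <- 0L
  extra <- list()
  for (i in seq_along(runs$values)) {
    if (!runs$values[i]) {
      k <- k + 1L
      extra[[k]] <- charset(sprintf("unassigned_%d", k),
                            pos[i], pos[i] + runs$lengths[i] - 1L)
    }
  }
  all_cs <- c(whole, extra)
  all_cs[order(vapply(all_cs, `[[`, integer(1), "start"))]
}

parse_nexus_data_block <- function(text) {
  block <- extract_nexus_block(text, c("data", "characters"))
  if (is.null(block)) {
    abort_genecat("genecat_format_error", "no DATA or CHARACTERS block found")
  }
  dim_m <- regmatches(block, regexpr(
    "dimensions[^;]*;", block, ignore.case = TRUE))
  if (!length(dim_m)) {
    abort_genecat("genecat_format_error", "DATA block lacks a DIMENSIONS command")
  }
  ntax <- nexus_keyval(dim_m, "ntax")
  nchr <- nexus_keyval(dim_m, "nchar")
  if (is.na(ntax) || is.na(nchr)) {
    abort_genecat("genecat_format_error", "DIMENSIONS must state ntax and nchar")
  }
  fmt_m <- regmatches(block, regexpr("format[^;]*;", block, ignore.case = TRUE))
  missing_sym <- "?"; gap_sym <- "-"
  if (length(fmt_m)) {
    ms <- nexus_symval(fmt_m, "missing"); if (!is.na(ms)) missing_sym <- ms
    gs <- nexus_symval(fmt_m, "gap"); if (!is.na(gs)) gap_sym <- gs
  }
  mat_m <- regmatches(block, regexpr("(?is)matrix\\s.*?;", block, perl = TRUE))
  if (!length(mat_m)) {
    abort_genecat("genecat_format_error", "DATA block lacks a MATRIX command")
  }
  body <- sub(";\\s*$", "", sub("^matrix\\s*", "", mat_m, ignore.case = TRUE))
  rows <- strsplit(body, "\n", fixed = TRUE)[[1]]
  rows <- trimws(rows)
  rows <- rows[nzchar(rows) & !grepl("^\\[", rows)]
  seqs <- character(0)
  for (row in rows) {
    toks <- strsplit(row, "\\s+")[[1]]
    if (length(toks) < 2L) {
      abort_genecat("genecat_format_error", sprintf(
        "matrix row '%s' lacks a sequence", row))
    }
    nm <- toks[1]
    chunk <- paste(toks[-1], collapse = "")
    if (nm %in% names(seqs)) {
      seqs[[nm]] <- paste0(seqs[[nm]], chunk)   # interleaved continuation
    } else {
      seqs[[nm]] <- chunk
    }
  }
  if (length(seqs) != ntax) {
    abort_genecat("genecat_format_error", sprintf(
      "DIMENSIONS declares ntax=%d but matrix has %d taxa", ntax, length(seqs)))
  }
  if (any(nchar(seqs) != nchr)) {
    bad <- names(seqs)[nchar(seqs) != nchr][1]
    abort_genecat("genecat_format_error", sprintf(
      "DIMENSIONS declares nchar=%d but '%s' has %d columns",
      nchr, bad, nchar(seqs[[bad]])))
  }
  seqs <- toupper(seqs)
  if (toupper(missing_sym) != "?") seqs <- chartr(toupper(missing_sym), "?", seqs)
  if (gap_sym != "-") seqs <- chartr(gap_sym, "-", seqs)
  list(sequences = seqs, ntax = ntax, nchar = nchr)
}

parse_nexus_sets_block <- function(text) {
  block <- extract_nexus_block(text, "sets")
  if (is.null(block)) return(list())
  out <- list()
  m <- gregexpr("charset\\s+([A-Za-z0-9_.-]+)\\s*=\\s*(\\d+)\\s*-\\s*(\\d+)\\s*(\\\\3)?\\s*;",
                block, ignore.case = TRUE)
  if (m[[1]][1] == -1L) return(list())
  pieces <- regmatches(block, m)[[1]]
  for (piece in pieces) {
    g <- regmatches(piece, regexec(
      "charset\\s+([A-Za-z0-9_.-]+)\\s*=\\s*(\\d+)\\s*-\\s*(\\d+)\\s*(\\\\3)?\\s*;",
      piece, ignore.case = TRUE))[[1]]
    step <- if (nzchar(g[5])) 3L else 1L
    out[[length(out) + 1L]] <- charset(g[2], as.integer(g[3]), as.integer(g[4]),
                                       step = step)
  }
  out
}

# Return the text of "begin <name>; ... end;" (case-insensitive), or NULL.
extract_nexus_block <- function(text, names) {
  for (nm in names) {
    pat <- sprintf("(?is)begin\\s+%s\\s*;.*?\\bend\\s*;", nm)
    m <- regexpr(pat, text, perl = TRUE)
    if (m[1] != -1L) return(regmatches(text, m))
  }
  NULL
}

#' Write a concatenated alignment as Nexus
#'
#' Emits a DATA block (\code{datatype=dna missing=? gap=-}) and a SETS block
#' with one charset per marker plus any codon charsets (empty codon subsets
#' are omitted).  \code{read_nexus(write_nexus(x))} reproduces markers,
#' names, residues and charset boundaries.
#'
#' @param alignment A \code{concat_alignment}.
#' @param interleaved Write the matrix in interleaved blocks.
#' @param block_width Columns per interleaved block. Default 60.
#' @param file Optional path to write to.
#' @return The Nexus text, invisibly when \code{file} is given.
#' @export
write_nexus <- function(alignment, interleaved = FALSE, block_width = 60L,
                        file = NULL) {
  stopifnot(inherits(alignment, "concat_alignment"))
  seqs <- alignment$sequences
  L <- alignment_length(alignment)
  w <- max(nchar(names(seqs)))
  pad <- function(nm) formatC(nm, width = -w)
  if (interleaved && L > block_width) {
    starts <- seq.int(1L, L, by = block_width)
    chunks <- vapply(starts, function(s) {
      part <- substring(seqs, s, min(s + block_width - 1L, L))
      paste(sprintf("    %s %s", pad(names(seqs)), part), collapse = "\n")
    }, character(1))
    matrix_txt <- paste(chunks, collapse = "\n\n")
    fmt <- "  format datatype=dna missing=? gap=- interleave=yes;"
  } else {
    matrix_txt <- paste(sprintf("    %s %s", pad(names(seqs)), seqs),
                        collapse = "\n")
    fmt <- "  format datatype=dna missing=? gap=-;"
  }
  sets <- c(
    vapply(alignment$charsets, function(cs)
      sprintf("  charset %s = %d-%d;", cs$name, cs$start, cs$end), character(1)),
    vapply(Filter(function(cs) cs$start <= cs$end, alignment$codon_charsets),
           function(cs) sprintf("  charset %s = %d-%d\\3;", cs$name, cs$start, cs$end),
           character(1)))
  text <- paste0(
    "#NEXUS\n\n",
    "begin data;\n",
    sprintf("  dimensions ntax=%d nchar=%d;\n", length(seqs), L),
    fmt, "\n",
    "  matrix\n",
    matrix_txt, "\n",
    "  ;\n",
    "end;\n\n",
    "begin sets;\n",
    paste(sets, collapse = "\n"), "\n",
    "end;\n")
  emit_text(text, file)
}

nexus_keyval <- function(cmd, key) {
  m <- regexec(sprintf("%s\\s*=\\s*(\\d+)", key), cmd, ignore.case = TRUE)[[1]]
  if (m[1] == -1L) return(NA_integer_)
  as.integer(regmatches(cmd, regexec(sprintf("%s\\s*=\\s*(\\d+)", key),
                                     cmd, ignore.case = TRUE))[[1]][2])
}

nexus_symval <- function(cmd, key) {
  g <- regmatches(cmd, regexec(sprintf("%s\\s*=\\s*(\\S)", key),
                               cmd, ignore.case = TRUE))[[1]]
  if (length(g) < 2L) return(NA_character_)
  g[2]
}
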