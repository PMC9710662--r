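# The concatenation / de-concatenation core.  Samples are matched across
# markers by exact, case-sensitive name equality; a sample missing from a
# marker is padded with the fill character over that marker's columns.

#' Concatenate a multi-marker matrix into a supermatrix
#'
#' All markers must be aligned (uniform length).  The output sample order is
#' first-appearance order across markers (or lexicographic with
#' \code{sort_samples = TRUE}); residues are joined in matrix marker order
#' with \code{fill} substituted where a sample lacks a marker.  Whole-marker
#' charsets record each marker's column range.
#'
#' @param matrix A \code{data_matrix} with uniform-length markers.
#' @param fill Fill character for absent sample-marker cells: \code{"?"}
#'   (default; the Nexus missing symbol, distinguishing "never sequenced"
#'   from a sequenced \code{N}), \code{"N"} or \code{"-"}.
#' @param sort_samples Sort output samples lexicographically instead of
#'   first-appearance order.
#' @return A \code{concat_alignment}.
#' @examples
#' m <- make_matrix(list(
#'   marker_block("M1", c(A = "ACGTA", B = "ACCTA")),
#'   marker_block("M2", c(B = "TGC", C = "TGA"))))
#' aln <- concatenate(m)
#' aln$sequences
#' @export
concatenate <- function(matrix, fill = "?", sort_samples = FALSE) {
  stopifnot(inherits(matrix, "data_matrix"))
  if (!length(matrix$markers)) {
    abort_genecat("genecat_empty_input_error", "cannot concatenate an empty matrix")
  }
  if (!fill %in% c("?", "N", "-")) {
    abort_genecat("genecat_format_error", "fill must be one of '?', 'N', '-'")
  }
  for (b in matrix$markers) {
    if (length(b$sequences) && !is_uniform(b)) {
      abort_genecat("genecat_not_aligned_error", sprintf(
        "marker '%s' has records of unequal length; align it before concatenating",
        b$name))
    }
  }
  samples <- sample_names(matrix)
  if (!length(samples)) {
    abort_genecat("genecat_empty_input_error", "matrix contains no records")
  }
  if (sort_samples) samples <- sort(samples)
  lens <- vapply(matrix$markers, marker_length, integer(1))
  lens[is.na(lens)] <- 0L  # markers with zero records contribute no columns
  keep <- lens > 0L
  if (!any(keep)) {
    abort_genecat("genecat_empty_input_error", "matrix contains no records")
  }
  blocks <- matrix$markers[keep]
  lens <- lens[keep]
  pieces <- lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    v <- b$sequences[samples]
    v[is.na(v)] <- strrep(fill, lens[i])
    unname(v)
  })
  seqs <- do.call(paste0, pieces)
  names(seqs) <- samples
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  charsets <- lapply(seq_along(blocks), function(i)
    charset(blocks[[i]]$name, starts[i], ends[i]))
  new_concat_alignment(seqs, charsets)
}

#' Split a supermatrix back into per-marker blocks
#'
#' The inverse of \code{\link{concatenate}}: slices the alignment by its
#' whole-marker charsets (which must tile the columns).  With
#' \code{drop_empty = TRUE} (default) records consisting entirely of missing
#' symbols (\code{?}/\code{N}) are omitted from a marker's block, so padding
#' introduced at concatenation time does not fabricate data rows.
#'
#' @param alignment A \code{concat_alignment}.
#' @param drop_empty Drop all-missing records per marker.
#' @return A \code{data_matrix}.
#' @export
deconcatenate <- function(alignment, drop_empty = TRUE) {
  stopifnot(inherits(alignment, "concat_alignment"))
  check_tiling(alignment$charsets, alignment_length(alignment))
  blocks <- lapply(alignment$charsets, function(cs) {
    sub <- substring(alignment$sequences, cs$start, cs$end)
    names(sub) <- names(alignment$sequences)
    if (drop_empty) sub <- sub[!grepl("^[?N]+$", sub)]
    marker_block(cs$name, sub)
  })
  blocks <- blocks[vapply(blocks, function(b) length(b$sequences) > 0L, logical(1))]
  if (!length(blocks)) {
    abort_genecat("genecat_empty_input_error",
                  "de-concatenation produced no non-empty markers")
  }
  make_matrix(blocks)
}

#' Codon-position subsets of a marker charset
#'
#' Splits a whole-marker charset into three step-3 charsets named
#' \code{<marker>_pos1/2/3}.  \code{reading_frame_offset} gives the codon
#' position of the marker's first column (e.g. 2 means the marker starts at
#' the second position of a codon).  The three sets partition the marker's
#' columns exactly; for markers shorter than 3 columns some sets are empty.
#'
#' @param marker_name Source marker name.
#' @param marker_charset The marker's whole-marker \code{charset}.
#' @param reading_frame_offset 1, 2 or 3.
#' @return List of three step-3 \code{charset}s.
#' @examples
#' cs <- charset("COI", 1, 6)
#' codon_subsets("COI", cs, 1)
#' @export
codon_subsets <- function(marker_name, marker_charset, reading_frame_offset = 1L) {
  stopifnot(inherits(marker_charset, "charset"))
  f <- as.integer(reading_frame_offset)
  if (!f %in% 1:3) {
    abort_genecat("genecat_format_error", "reading_frame_offset must be 1, 2 or 3")
  }
  lapply(1:3, function(k) {
    off <- (f - 1L + k - 1L) %% 3L
    charset(sprintf("%s_pos%d", marker_name, k),
            marker_charset$start + off, marker_charset$end,
            step = 3L, marker = marker_name)
  })
}

#' Attach codon charsets to a concatenated alignment
#'
#' @param alignment A \code{concat_alignment}.
#' @param frames Named integer vector: marker name -> reading frame offset
#'   (1, 2 or 3).
#' @return The alignment with \code{codon_charsets} extended.
#' @export
add_codon_charsets <- function(alignment, frames) {
  stopifnot(inherits(alignment, "concat_alignment"))
  known <- vapply(alignment$charsets, `[[`, character(1), "name")
  unknown <- setdiff(names(frames), known)
  if (length(unknown)) {
    abort_genecat("genecat_unknown_marker_error", sprintf(
      "unknown marker(s) in codon assignment: %s", paste(unknown, collapse = ", ")))
  }
  extra <- list()
  for (nm in names(frames)) {
    cs <- alignment$charsets[[match(nm, known)]]
    extra <- c(extra, codon_subsets(nm, cs, frames[[nm]]))
  }
  alignment$codon_charsets <- c(alignment$codon_charsets, extra)
  alignment
}

#' Rename alignment records via a display-name map
#'
#' @param alignment A \code{concat_alignment}.
#' @param name_map Named character vector: current sample name -> display
#'   name.  Unmapped samples keep their names; the result must be collision
#'   free.
#' @return The renamed alignment.
#' @export
apply_display_names <- function(alignment, name_map) {
  stopifnot(inherits(alignment, "concat_alignment"))
  if (!length(name_map)) return(alignment)
  cur <- names(alignment$sequences)
  new <- cur
  hit <- cur %in% names(name_map)
  new[hit] <- unname(name_map[cur[hit]])
  if (anyDuplicated(new)) {
    abort_genecat("genecat_name_collision_error", sprintf(
      "display names collide: %s",
      paste(unique(new[duplicated(new)]), collapse = ", ")))
  }
  for (nm in new) check_token(nm, "sample name")
  names(alignment$sequences) <- new
  alignment
}
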