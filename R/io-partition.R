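# Partition command files for downstream model selection (IQ-TREE,
# PartitionFinder, RAxML).  Two styles: a Nexus SETS file and RAxML's
# "DNA, name = start-end" lines.  Coordinates are 1-based inclusive; codon
# subsets use the \3 step notation.

#' Write a partition command file
#'
#' For markers that carry codon charsets, the three \code{pos1/2/3} sets
#' replace the whole-marker set so the emitted partition stays non-overlapping
#' (as IQ-TREE and RAxML require); markers without codon assignments keep
#' their whole-marker set.  Empty codon subsets are omitted.
#'
#' @param alignment A \code{concat_alignment}.
#' @param style \code{"nexus_sets"} (IQ-TREE \code{-p} input) or
#'   \code{"raxml"}.
#' @param file Optional path to write to.
#' @return The partition text, invisibly when \code{file} is given.
#' @export
write_partition_file <- function(alignment, style = c("nexus_sets", "raxml"),
                                 file = NULL) {
  stopifnot(inherits(alignment, "concat_alignment"))
  style <- match.arg(style)
  sets <- effective_partition(alignment)
  lines <- vapply(sets, function(cs) {
    range <- sprintf("%d-%d%s", cs$start, cs$end,
                     if (cs$step == 3L) "\\3" else "")
    switch(style,
           nexus_sets = sprintf("  charset %s = %s;", cs$name, range),
           raxml = sprintf("DNA, %s = %s", cs$name, range))
  }, character(1))
  text <- switch(style,
    nexus_sets = paste0("#nexus\nbegin sets;\n",
                        paste(lines, collapse = "\n"), "\nend;\n"),
    raxml = paste0(paste(lines, collapse = "\n"), "\n"))
  emit_text(text, file)
}

# Whole-marker sets, with codon triplets substituted where assigned.
effective_partition <- function(alignment) {
  codon_by_marker <- split(
    alignment$codon_charsets,
    vapply(alignment$codon_charsets, function(cs)
      if (is.null(cs$marker)) NA_character_ else cs$marker, character(1)))
  out <- list()
  for (cs in alignment$charsets) {
    trip <- codon_by_marker[[cs$name]]
    if (is.null(trip)) {
      out[[length(out) + 1L]] <- cs
    } else {
      for (sub in trip) {
        if (sub$start <= sub$end) out[[length(out) + 1L]] <- sub
      }
    }
  }
  out
}

#' Read a partition file (either style)
#'
#' Accepts both the Nexus SETS style (\code{charset name = start-end;}) and
#' the RAxML style (\code{DNA, name = start-end}); \code{\\3} ranges are
#' returned as codon charsets.
#'
#' @param input File path or partition text.
#' @return List with \code{charsets} (step 1) and \code{codon_charsets}
#'   (step 3).
#' @export
read_partition_file <- function(input) {
  lines <- as_lines(input)
  text <- paste(lines, collapse = "\n")
  out <- list()
  pat <- "(?i)(?:charset\\s+|DNA\\s*,\\s*)([A-Za-z0-9_.-]+)\\s*=\\s*(\\d+)\\s*-\\s*(\\d+)\\s*(\\\\3)?"
  m <- gregexpr(pat, text, perl = TRUE)
  if (m[[1]][1] == -1L) {
    abort_genecat("genecat_partition_error", "no charset definitions found")
  }
  for (piece in regmatches(text, m)[[1]]) {
    g <- regmatches(piece, regexec(pat, piece, perl = TRUE))[[1]]
    step <- if (nzchar(g[5])) 3L else 1L
    out[[length(out) + 1L]] <- charset(g[2], as.integer(g[3]), as.integer(g[4]),
                                       step = step)
  }
  list(charsets = Filter(function(cs) cs$step == 1L, out),
       codon_charsets = Filter(function(cs) cs$step == 3L, out))
}
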