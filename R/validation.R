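# Output-data validation: per-marker outlier sequences via a column-entropy /
# IQR procedure (SequenceBouncer-style), and detection of blocks of samples
# with non-overlapping sequence information (the typical footprint of a
# misspelled sample name).
#
# Counted states are A, C, G, T and the gap '-' (a fifth state: gaps are
# alignment signal); '?', 'N' and the other IUPAC ambiguity codes are
# treated as absence of signal and excluded everywhere.

COUNTED_STATES <- c("A", "C", "G", "T", "-")

# n x L integer code matrix (1..5 for counted states, NA otherwise).
residue_codes <- function(seqs) {
  L <- nchar(seqs[[1]])
  chars <- strsplit(seqs, "", fixed = TRUE)
  m <- matrix(match(unlist(chars, use.names = FALSE), COUNTED_STATES),
              nrow = length(seqs), ncol = L, byrow = TRUE)
  rownames(m) <- names(seqs)
  m
}

entropy_from_codes <- function(codes) {
  apply(codes, 2L, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(0)
    p <- tabulate(col, nbins = 5L)
    p <- p[p > 0] / length(col)
    -sum(p * log2(p))
  })
}

#' Shannon entropy of one alignment column
#'
#' Frequencies are taken over the counted states A, C, G, T and gap
#' \code{-}; \code{?}, \code{N} and other ambiguity codes are excluded.  A
#' column with no counted state has entropy 0 by convention.
#'
#' @param column String: the column's residues, one character per sequence.
#' @return Entropy in bits (0 to log2(5)).
#' @examples
#' column_entropy("ACGT")  # 2 bits
#' @export
column_entropy <- function(column) {
  stopifnot(is.character(column), length(column) == 1L, nchar(column) >= 1L)
  codes <- match(strsplit(toupper(column), "")[[1]], COUNTED_STATES)
  codes <- codes[!is.na(codes)]
  if (!length(codes)) return(0)
  p <- tabulate(codes, nbins = 5L)
  p <- p[p > 0] / length(codes)
  -sum(p * log2(p))
}

#' Entropy-weighted mismatch cost between two aligned sequences
#'
#' Sums the per-column entropies over columns where both sequences carry
#' counted states that differ (gap vs base is a mismatch); columns where
#' either sequence is missing/ambiguous are skipped.
#'
#' @param seq_i,seq_j Equal-length residue strings.
#' @param entropies Numeric vector of per-column entropies.
#' @return Non-negative cost.
#' @export
pairwise_cost <- function(seq_i, seq_j, entropies) {
  if (nchar(seq_i) != nchar(seq_j) || nchar(seq_i) != length(entropies)) {
    abort_genecat("genecat_not_aligned_error",
                  "sequences and entropy vector must have equal lengths")
  }
  ci <- match(strsplit(toupper(seq_i), "")[[1]], COUNTED_STATES)
  cj <- match(strsplit(toupper(seq_j), "")[[1]], COUNTED_STATES)
  keep <- !is.na(ci) & !is.na(cj)
  sum(entropies[keep & (ci != cj)], na.rm = TRUE)
}

#' Flag outlier sequences in a marker block
#'
#' For every sequence, the cost is the median of its entropy-weighted
#' mismatch costs against all other sequences of the block (full pairwise
#' analysis, no sampling).  The outlier threshold is
#' \code{Q3 + iqr_coefficient * (Q3 - Q1)} over the per-sequence cost
#' distribution, with quartiles by linear interpolation (type 7); a sequence
#' is an outlier iff its cost exceeds the threshold.  Smaller coefficients
#' are more sensitive; the default 20 suits conserved barcoding markers,
#' values down to 1 suit highly variable alignments.
#'
#' @param block A uniform-length \code{marker_block} with at least 4 records.
#' @param iqr_coefficient Positive multiplier of the interquartile range.
#'   Default 20.
#' @return A \code{data.frame} with columns \code{sample_name},
#'   \code{marker_name}, \code{cost}, \code{threshold}, \code{is_outlier},
#'   one row per sequence in block order.
#' @export
detect_outliers <- function(block, iqr_coefficient = 20) {
  stopifnot(inherits(block, "marker_block"))
  if (!is_uniform(block)) {
    abort_genecat("genecat_not_aligned_error", sprintf(
      "marker '%s' must be aligned before outlier detection", block$name))
  }
  n <- length(block$sequences)
  if (n < 4L) {
    abort_genecat("genecat_insufficient_data_error", sprintf(
      "marker '%s' has %d record(s); outlier detection needs at least 4", block$name, n))
  }
  if (!is.numeric(iqr_coefficient) || iqr_coefficient <= 0) {
    abort_genecat("genecat_format_error", "iqr_coefficient must be positive")
  }
  codes <- residue_codes(block$sequences)
  ent <- entropy_from_codes(codes)
  C <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      keep <- !is.na(codes[i, ]) & !is.na(codes[j, ])
      cost <- sum(ent[keep & (codes[i, ] != codes[j, ])], na.rm = TRUE)
      C[i, j] <- cost
      C[j, i] <- cost
    }
  }
  costs <- vapply(seq_len(n), function(i) stats::median(C[i, -i]), numeric(1))
  q <- stats::quantile(costs, c(0.25, 0.75), type = 7, names = FALSE)
  threshold <- q[2] + iqr_coefficient * (q[2] - q[1])
  data.frame(sample_name = names(block$sequences),
             marker_name = block$name,
             cost = costs,
             threshold = threshold,
             is_outlier = costs > threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Detect blocks of samples with non-overlapping sequence information
#'
#' Two samples are connected when some marker contains both with at least one
#' shared column where both carry a counted (non-missing) state; connected
#' components of this graph are reported sorted by decreasing size.  More
#' than one component means subsets of samples share no sequence evidence at
#' all -- the classic signature of misspelled sample names -- and downstream
#' phylogenetic analysis of the concatenated matrix would be unsupported.
#'
#' @param matrix A \code{data_matrix}.
#' @return An object of class \code{overlap_report}: list with
#'   \code{components} (list of character vectors) and \code{n_components}.
#' @export
find_nonoverlapping_blocks <- function(matrix) {
  stopifnot(inherits(matrix, "data_matrix"))
  samples <- sample_names(matrix)
  if (!length(samples)) {
    abort_genecat("genecat_empty_input_error", "matrix contains no records")
  }
  edges_from <- character(0); edges_to <- character(0)
  for (b in matrix$markers) {
    if (length(b$sequences) < 2L || !is_uniform(b)) next
    counted <- !is.na(residue_codes(b$sequences))
    ov <- tcrossprod(counted * 1L) > 0
    idx <- which(ov & upper.tri(ov), arr.ind = TRUE)
    if (nrow(idx)) {
      edges_from <- c(edges_from, names(b$sequences)[idx[, 1]])
      edges_to <- c(edges_to, names(b$sequences)[idx[, 2]])
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(samples), name = samples)
  if (length(edges_from)) {
    g <- igraph::add_edges(g, rbind(edges_from, edges_to))
  }
  comp <- igraph::components(g)
  groups <- split(samples, comp$membership[samples])
  ord <- order(-vapply(groups, length, integer(1)),
               vapply(groups, function(x) sort(x)[1], character(1)))
  groups <- lapply(unname(groups[ord]), function(x) unname(x))
  structure(list(components = groups, n_components = length(groups)),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  if (x$n_components <= 1L) {
    cat("All samples share overlapping sequence information (1 component).\n")
  } else {
    cat(sprintf("WARNING: %d non-overlapping sample blocks detected:\n",
                x$n_components))
    for (i in seq_along(x$components)) {
      cat(sprintf("  block %d (%d samples): %s\n", i, length(x$components[[i]]),
                  paste(x$components[[i]], collapse = ", ")))
    }
  }
  invisible(x)
}

#' Full validation report for a data matrix
#'
#' Bundles the marker overview, per-marker outlier calls (markers with fewer
#' than 4 records are skipped with a notice) and the sample-overlap report.
#'
#' @param matrix A \code{data_matrix}.
#' @param iqr_coefficient Outlier sensitivity; see
#'   \code{\link{detect_outliers}}.
#' @return An object of class \code{validation_report}.
#' @export
validation_report <- function(matrix, iqr_coefficient = 20) {
  stopifnot(inherits(matrix, "data_matrix"))
  if (!length(matrix$markers)) {
    abort_genecat("genecat_empty_input_error", "cannot validate an empty matrix")
  }
  overview <- marker_overview(matrix)
  outliers <- list()
  skipped <- character(0)
  for (b in matrix$markers) {
    if (length(b$sequences) < 4L || !is_uniform(b)) {
      skipped <- c(skipped, b$name)
    } else {
      outliers[[b$name]] <- detect_outliers(b, iqr_coefficient)
    }
  }
  calls <- if (length(outliers)) {
    do.call(rbind, c(unname(outliers), list(make.row.names = FALSE)))
  } else {
    data.frame(sample_name = character(), marker_name = character(),
               cost = numeric(), threshold = numeric(),
               is_outlier = logical(), stringsAsFactors = FALSE)
  }
  structure(list(overview = overview, outlier_calls = calls,
                 skipped_markers = skipped,
                 overlap = find_nonoverlapping_blocks(matrix),
                 iqr_coefficient = iqr_coefficient),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("== Marker overview ==\n")
  print(x$overview)
  cat(sprintf("\n== Outlier sequences (IQR coefficient %g) ==\n",
              x$iqr_coefficient))
  flagged <- x$outlier_calls[x$outlier_calls$is_outlier, , drop = FALSE]
  if (nrow(flagged)) print(flagged) else cat("none flagged\n")
  if (length(x$skipped_markers)) {
    cat(sprintf("skipped (fewer than 4 records or unaligned): %s\n",
                paste(x$skipped_markers, collapse = ", ")))
  }
  cat("\n== Sample overlap ==\n")
  print(x$overlap)
  invisible(x)
}

#' Does a validation report contain findings?
#'
#' @param report A \code{validation_report}.
#' @return TRUE when any outlier was flagged or the samples split into more
#'   than one non-overlapping block.
#' @export
has_findings <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  any(report$outlier_calls$is_outlier) || report$overlap$n_components > 1L
}

#' Write a machine-readable validation report
#'
#' One JSON document with the overview table, every outlier call and the
#' overlap components.
#'
#' @param report A \code{validation_report}.
#' @param file Path to write to.
#' @return \code{file}, invisibly.
#' @export
write_validation_json <- function(report, file) {
  stopifnot(inherits(report, "validation_report"))
  payload <- list(
    iqr_coefficient = report$iqr_coefficient,
    markers = report$overview,
    outlier_calls = report$outlier_calls,
    skipped_markers = report$skipped_markers,
    components = report$overlap$components,
    n_components = report$overlap$n_components,
    has_findings = has_findings(report))
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(file)
}
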