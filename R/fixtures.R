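# Deterministic synthetic multi-marker datasets.  The generator emulates a
# star phylogeny: per marker a random ancestral sequence, per sample
# independent per-site substitutions.  Planted defects (uniformly re-drawn
# outlier sequences, misspelled-name sample splits, absent cells) come with
# truth labels so validators can be tested against known ground truth.
#
# A single integer seed drives everything, but each (marker, sample) cell
# draws from its own sub-stream (seeded by a stable string hash), so adding
# a marker or sample never reshuffles the data of existing ones.

#' Describe a synthetic multi-marker dataset
#'
#' @param n_samples Number of samples.
#' @param n_markers Number of markers.
#' @param marker_lengths Integer vector of alignment lengths, recycled to
#'   \code{n_markers}. Default 300 (a typical barcoding fragment).
#' @param missing_fraction Probability that a sample x marker cell is absent
#'   (never sequenced). In [0, 1).
#' @param divergence Per-site substitution probability from the marker's
#'   ancestral sequence. In [0, 1]. Default 0.02, a low within-genus
#'   divergence under which planted outliers are cleanly separable.
#' @param n_outliers Number of samples whose sequence in the first marker is
#'   re-drawn uniformly at random instead of mutated (planted outliers).
#' @param split_fraction Fraction of samples planted as a disjoint block: the
#'   second half of the markers contains only these samples, renamed with a
#'   \code{_2} suffix (emulating a second input file whose sample names were
#'   misspelled wholesale), so they share no sequence evidence with the
#'   original names.
#' @param seed Integer seed.
#' @return An object of class \code{fixture_spec}.
#' @export
fixture_spec <- function(n_samples, n_markers = 1L, marker_lengths = 300L,
                         missing_fraction = 0, divergence = 0.02,
                         n_outliers = 0L, split_fraction = 0, seed = 1L) {
  n_samples <- as.integer(n_samples); n_markers <- as.integer(n_markers)
  marker_lengths <- as.integer(rep_len(marker_lengths, n_markers))
  if (n_samples < 1L || n_markers < 1L || any(marker_lengths < 1L)) {
    abort_genecat("genecat_spec_error",
                  "n_samples, n_markers and marker_lengths must be positive")
  }
  if (missing_fraction < 0 || missing_fraction >= 1) {
    abort_genecat("genecat_spec_error", "missing_fraction must be in [0, 1)")
  }
  if (divergence < 0 || divergence > 1) {
    abort_genecat("genecat_spec_error", "divergence must be in [0, 1]")
  }
  if (n_outliers < 0L || n_outliers >= n_samples) {
    abort_genecat("genecat_spec_error", "n_outliers must be < n_samples")
  }
  if (split_fraction < 0 || split_fraction >= 1) {
    abort_genecat("genecat_spec_error", "split_fraction must be in [0, 1)")
  }
  if (split_fraction > 0 && n_markers < 2L) {
    abort_genecat("genecat_spec_error",
                  "split_fraction needs at least 2 markers")
  }
  structure(list(n_samples = n_samples, n_markers = n_markers,
                 marker_lengths = marker_lengths,
                 missing_fraction = missing_fraction, divergence = divergence,
                 n_outliers = as.integer(n_outliers),
                 split_fraction = split_fraction, seed = as.integer(seed)),
            class = "fixture_spec")
}

# Stable polynomial string hash -> seed in [0, 2^31 - 2].
substream_seed <- function(...) {
  s <- paste(c(...), collapse = "/")
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

draw_sequence <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

mutate_sequence <- function(ancestral, divergence) {
  if (divergence <= 0) return(ancestral)
  chars <- strsplit(ancestral, "")[[1]]
  hit <- stats::runif(length(chars)) < divergence
  if (any(hit)) {
    bases <- c("A", "C", "G", "T")
    chars[hit] <- vapply(chars[hit], function(b)
      sample(setdiff(bases, b), 1L), character(1))
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic data matrix with truth labels
#'
#' Reproducible for a fixed spec: the same spec yields byte-identical data.
#' Planted outliers live in the first marker and are never dropped as
#' missing.  When a split is planted, the first half of the markers carries
#' all samples under their original names while the second half carries only
#' the chosen samples under their perturbed \code{_2} names, so the perturbed
#' block shares no marker (hence no sequence evidence) with the originals.
#'
#' @param spec A \code{\link{fixture_spec}}.
#' @return List with \code{matrix} (a \code{data_matrix}) and \code{truth}:
#'   \code{outliers} (data.frame sample/marker), \code{absent} (data.frame
#'   sample/marker), \code{split_samples} (original names of renamed
#'   samples), and \code{components} (expected overlap components, or NULL
#'   when no split was planted or cells are missing).
#' @export
generate_matrix <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  samples <- sprintf("sample_%02d", seq_len(spec$n_samples))
  markers <- sprintf("marker_%02d", seq_len(spec$n_markers))
  outlier_samples <- if (spec$n_outliers > 0L) {
    utils::tail(samples, spec$n_outliers)
  } else character(0)
  n_split <- floor(spec$split_fraction * spec$n_samples)
  split_samples <- if (n_split > 0L) samples[seq_len(n_split)] else character(0)
  second_half <- if (n_split > 0L) {
    markers[seq.int(spec$n_markers %/% 2L + 1L, spec$n_markers)]
  } else character(0)

  absent_s <- character(0); absent_m <- character(0)
  out_s <- character(0); out_m <- character(0)
  blocks <- vector("list", spec$n_markers)
  for (mi in seq_along(markers)) {
    m <- markers[mi]
    L <- spec$marker_lengths[mi]
    set.seed(substream_seed(spec$seed, m, "ancestral"))
    ancestral <- draw_sequence(L)
    in_second_half <- m %in% second_half
    seqs <- character(0)
    for (s in samples) {
      renamed <- in_second_half && s %in% split_samples
      if (in_second_half && !renamed && n_split > 0L) next
      set.seed(substream_seed(spec$seed, m, s))
      is_outlier <- mi == 1L && s %in% outlier_samples
      if (!is_outlier && spec$missing_fraction > 0 &&
          stats::runif(1) < spec$missing_fraction) {
        absent_s <- c(absent_s, s); absent_m <- c(absent_m, m)
        next
      }
      seq <- if (is_outlier) {
        out_s <- c(out_s, s); out_m <- c(out_m, m)
        draw_sequence(L)
      } else {
        mutate_sequence(ancestral, spec$divergence)
      }
      seqs[[if (renamed) paste0(s, "_2") else s]] <- seq
    }
    blocks[[mi]] <- marker_block(m, seqs)
  }
  blocks <- blocks[vapply(blocks, function(b) length(b$sequences) > 0L, logical(1))]
  components <- NULL
  if (n_split > 0L && spec$missing_fraction == 0) {
    components <- list(samples, paste0(split_samples, "_2"))
  }
  list(matrix = make_matrix(blocks),
       truth = list(
         outliers = data.frame(sample = out_s, marker = out_m,
                               stringsAsFactors = FALSE),
         absent = data.frame(sample = absent_s, marker = absent_m,
                             stringsAsFactors = FALSE),
         split_samples = split_samples,
         components = components))
}
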