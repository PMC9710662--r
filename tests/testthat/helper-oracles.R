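# Independent brute-force oracles and small fixture helpers.  The oracles
# deliberately use explicit per-column loops and their own entropy counting
# so they share no code path with the package implementation.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random small matrix for round-trip / algebra properties.
random_fixture <- function(seed, max_missing = 0.4) {
  set.seed(seed)
  spec <- fixture_spec(
    n_samples = sample(3:8, 1),
    n_markers = sample(1:3, 1),
    marker_lengths = sample(5:30, 3, replace = TRUE),
    missing_fraction = stats::runif(1, 0, max_missing),
    divergence = stats::runif(1, 0, 0.3),
    seed = seed)
  generate_matrix(spec)$matrix
}

# Marker-block equality up to record order (sparse concatenation does not
# preserve within-marker record order).
block_seqs_sorted <- function(block) {
  s <- block$sequences
  s[order(names(s))]
}

expect_same_matrix <- function(a, b) {
  expect_identical(marker_names(a), marker_names(b))
  for (nm in marker_names(a)) {
    expect_identical(block_seqs_sorted(a$markers[[nm]]),
                     block_seqs_sorted(b$markers[[nm]]))
  }
}

# Brute-force column entropy: count characters in an explicit loop.
bf_entropy <- function(chars) {
  counted <- c("A", "C", "G", "T", "-")
  counts <- setNames(numeric(5), counted)
  for (ch in chars) if (ch %in% counted) counts[ch] <- counts[ch] + 1
  tot <- sum(counts)
  if (tot == 0) return(0)
  h <- 0
  for (ch in counted) {
    p <- counts[[ch]] / tot
    if (p > 0) h <- h - p * log2(p)
  }
  h
}

# Brute-force outlier detection: explicit double loop over pairs and columns.
bf_outliers <- function(block, k) {
  seqs <- block$sequences
  n <- length(seqs)
  L <- nchar(seqs[[1]])
  rows <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  counted <- c("A", "C", "G", "T", "-")
  ent <- numeric(L)
  for (col in seq_len(L)) {
    ent[col] <- bf_entropy(vapply(rows, `[[`, character(1), col))
  }
  C <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    cost <- 0
    for (col in seq_len(L)) {
      a <- rows[[i]][col]; b <- rows[[j]][col]
      if (a %in% counted && b %in% counted && a != b) cost <- cost + ent[col]
    }
    C[i, j] <- cost
  }
  costs <- vapply(seq_len(n), function(i) stats::median(C[i, -i]), numeric(1))
  q <- stats::quantile(costs, c(0.25, 0.75), type = 7, names = FALSE)
  thr <- q[2] + k * (q[2] - q[1])
  list(costs = costs, threshold = thr, calls = costs > thr)
}

# Brute-force connected components via transitive closure of the
# shared-counted-column relation.
bf_components <- function(matrix) {
  samples <- sample_names(matrix)
  n <- length(samples)
  adj <- diag(TRUE, n)
  dimnames(adj) <- list(samples, samples)
  counted <- c("A", "C", "G", "T", "-")
  for (b in matrix$markers) {
    if (!is_uniform(b)) next
    nms <- names(b$sequences)
    rows <- lapply(b$sequences, function(s) strsplit(s, "")[[1]])
    for (i in seq_along(nms)) for (j in seq_along(nms)) {
      if (i == j) next
      share <- FALSE
      for (col in seq_len(nchar(b$sequences[[1]]))) {
        if (rows[[i]][col] %in% counted && rows[[j]][col] %in% counted) {
          share <- TRUE
          break
        }
      }
      if (share) adj[nms[i], nms[j]] <- TRUE
    }
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comps <- unique(lapply(seq_len(n), function(i) sort(samples[adj[i, ]])))
  comps[order(-vapply(comps, length, integer(1)),
              vapply(comps, `[[`, character(1), 1L))]
}

# Brute-force codon position of each column in a marker charset.
bf_codon_columns <- function(start, end, frame) {
  cols <- start:end
  pos <- ((cols - start - (frame - 1)) %% 3) + 1
  split(cols, pos)
}

# Inject missing/ambiguous characters into a block (for skip-rule coverage).
degrade_block <- function(block, prob, seed) {
  set.seed(seed)
  seqs <- vapply(block$sequences, function(s) {
    chars <- strsplit(s, "")[[1]]
    hit <- stats::runif(length(chars)) < prob
    chars[hit] <- sample(c("?", "N", "-"), sum(hit), replace = TRUE)
    paste(chars, collapse = "")
  }, character(1))
  marker_block(block$name, seqs)
}

golden_matrix <- function() {
  make_matrix(list(marker_block("M1", c(A = "ACGTA", B = "ACCTA")),
                   marker_block("M2", c(B = "TGC", C = "TGA"))))
}

golden_path <- function(file) {
  system.file("extdata", "golden", file, package = "genecat", mustWork = TRUE)
}

read_golden <- function(file) {
  paste0(paste(readLines(golden_path(file)), collapse = "\n"), "\n")
}
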