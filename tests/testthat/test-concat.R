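test_that("concatenate pads absent samples and records charset offsets", {
  aln <- concatenate(golden_matrix())
  expect_identical(aln$sequences,
                   c(A = "ACGTA???", B = "ACCTATGC", C = "?????TGA"))
  expect_identical(vapply(aln$charsets, `[[`, character(1), "name"), c("M1", "M2"))
  expect_identical(vapply(aln$charsets, `[[`, integer(1), "start"), c(1L, 6L))
  expect_identical(vapply(aln$charsets, `[[`, integer(1), "end"), c(5L, 8L))

  # alternative fill characters
  expect_identical(concatenate(golden_matrix(), fill = "-")$sequences[["A"]],
                   "ACGTA---")

  # single marker: alignment identical to the block, one charset 1-L
  single <- concatenate(make_matrix(list(marker_block("m", c(A = "ACGT")))))
  expect_identical(single$sequences, c(A = "ACGT"))
  expect_identical(single$charsets[[1]]$end, 4L)

  ragged <- make_matrix(list(marker_block("r", c(A = "ACG", B = "AC"))))
  expect_error(concatenate(ragged), class = "genecat_not_aligned_error")
  expect_error(concatenate(make_matrix(list())),
               class = "genecat_empty_input_error")
})

test_that("length and padding are conserved on random sparse fixtures", {
  for (seed in 1:10) {
    m <- random_fixture(seed, max_missing = 0.6)
    aln <- concatenate(m)
    lens <- vapply(m$markers, marker_length, integer(1))
    expect_identical(alignment_length(aln), sum(lens))
    for (s in sample_names(m)) {
      absent <- vapply(m$markers, function(b) !s %in% names(b$sequences),
                       logical(1))
      got <- nchar(gsub("[^?]", "", aln$sequences[[s]]))
      expect_identical(got, sum(lens[absent]))
    }
  }
})

test_that("deconcatenate inverts concatenate and validates tiling", {
  for (seed in 1:8) {
    m <- random_fixture(seed, max_missing = 0.5)
    expect_same_matrix(deconcatenate(concatenate(m)), m)
  }
  # drop_empty = FALSE keeps padded rows in every marker
  aln <- concatenate(golden_matrix())
  full <- deconcatenate(aln, drop_empty = FALSE)
  expect_identical(names(full$markers$M1$sequences), c("A", "B", "C"))

  bad <- charset("M2", 7, 8)
  expect_error(
    deconcatenate(structure(list(sequences = aln$sequences,
                                 charsets = list(aln$charsets[[1]], bad),
                                 codon_charsets = list()),
                            class = "concat_alignment")),
    class = "genecat_partition_error")
})

test_that("concatenating after a reorder permutes segments consistently", {
  for (seed in 1:5) {
    m <- random_fixture(seed)
    if (length(m$markers) < 2L) next
    set.seed(seed)
    perm <- sample(marker_names(m))
    a1 <- deconcatenate(concatenate(m))
    a2 <- deconcatenate(concatenate(reorder_markers(m, perm)))
    for (nm in marker_names(m)) {
      expect_identical(block_seqs_sorted(a2$markers[[nm]]),
                       block_seqs_sorted(a1$markers[[nm]]))
    }
  }
})

test_that("codon subsets partition the marker columns for any frame", {
  # frame 1 on 1-6: pos1=1-6\3 etc., cardinalities 2/2/2
  trip <- codon_subsets("M1", charset("M1", 1, 6), 1)
  expect_identical(vapply(trip, `[[`, character(1), "name"),
                   c("M1_pos1", "M1_pos2", "M1_pos3"))
  expect_identical(lapply(trip, charset_columns),
                   list(c(1L, 4L), c(2L, 5L), c(3L, 6L)))

  # frame 2 wraps: pos3 owns the first column
  trip2 <- codon_subsets("M1", charset("M1", 1, 6), 2)
  expect_identical(vapply(trip2, `[[`, integer(1), "start"), c(2L, 3L, 1L))

  # offset marker 10-16: cardinalities 3/2/2, disjoint, union = 10..16
  trip3 <- codon_subsets("M1", charset("M1", 10, 16), 1)
  cols <- lapply(trip3, charset_columns)
  expect_identical(lengths(cols), c(3L, 2L, 2L))
  expect_identical(sort(unlist(cols)), 10:16)

  # brute force over random charsets and frames
  set.seed(42)
  for (i in 1:25) {
    start <- sample(1:200, 1); len <- sample(1:40, 1); frame <- sample(1:3, 1)
    cs <- charset("m", start, start + len - 1L)
    got <- lapply(codon_subsets("m", cs, frame), charset_columns)
    truth <- bf_codon_columns(cs$start, cs$end, frame)
    for (k in 1:3) {
      expect_identical(got[[k]], unname(truth[[as.character(k)]]) %||% integer(0))
    }
    all_cols <- unlist(got)
    expect_identical(sort(all_cols), cs$start:cs$end)
    expect_identical(anyDuplicated(all_cols), 0L)
  }
})

test_that("apply_display_names renames injectively", {
  aln <- concatenate(golden_matrix())
  r <- apply_display_names(aln, c(A = "ZSM123_Boophis"))
  expect_identical(names(r$sequences), c("ZSM123_Boophis", "B", "C"))
  expect_identical(names(apply_display_names(aln, character(0))$sequences),
                   c("A", "B", "C"))
  expect_error(apply_display_names(aln, c(A = "X", B = "X")),
               class = "genecat_name_collision_error")
})
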