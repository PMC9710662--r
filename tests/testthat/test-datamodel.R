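test_that("marker_block validates names, residues and uniqueness", {
  b <- marker_block("COI", c(A = "acgt", B = "AC-T"))
  expect_identical(unname(b$sequences), c("ACGT", "AC-T"))  # upper-cased
  expect_true(is_uniform(b))
  expect_identical(marker_length(b), 4L)

  expect_error(marker_block("COI", c(A = "AC", A = "GT")),
               class = "genecat_duplicate_sample_error")
  expect_error(marker_block("COI", c(A = "AC@T")),
               class = "genecat_alphabet_error")
  expect_error(marker_block("bad name", c(A = "ACGT")),
               class = "genecat_token_error")
  expect_error(marker_block("COI", c(`A B` = "ACGT")),
               class = "genecat_token_error")
})

test_that("make_matrix builds a sparse sample universe and rejects duplicates", {
  m <- make_matrix(list(marker_block("16S", c(A = "ACGT", B = "ACGA")),
                        marker_block("COI", c(C = "TTT", D = "TTA"))))
  expect_identical(marker_names(m), c("16S", "COI"))
  expect_identical(sample_names(m), c("A", "B", "C", "D"))

  expect_error(make_matrix(list(marker_block("x", c(A = "A")),
                                marker_block("x", c(B = "C")))),
               class = "genecat_duplicate_marker_error")
})

test_that("marker_overview reports taxa, lengths and the missing census", {
  m <- make_matrix(list(
    marker_block("clean", c(A = "ACGT", B = "ACGT", C = "ACGT", D = "ACGT")),
    marker_block("holey", c(A = "AC??", B = "ACGT"))))
  ov <- marker_overview(m)
  expect_identical(nrow(ov), 2L)
  expect_identical(ov$n_samples, c(4L, 2L))
  expect_equal(ov$pct_missing, c(0, 25))
  expect_identical(ov$n_question, c(0L, 2L))

  # ragged marker reports a length range
  r <- marker_overview(make_matrix(list(marker_block("r", c(A = "ACG", B = "AC")))))
  expect_false(r$is_uniform)
  expect_identical(c(r$length_min, r$length_max), c(2L, 3L))

  expect_identical(nrow(marker_overview(make_matrix(list()))), 0L)
})

test_that("delete/reorder/rename are pure and validated", {
  m <- make_matrix(list(marker_block("16S", c(A = "AA")),
                        marker_block("COI", c(A = "CC")),
                        marker_block("RAG1", c(A = "GG"))))
  d <- delete_markers(m, "COI")
  expect_identical(marker_names(d), c("16S", "RAG1"))
  expect_identical(marker_names(m), c("16S", "COI", "RAG1"))  # unchanged
  expect_identical(marker_names(delete_markers(m, character(0))),
                   marker_names(m))
  expect_error(delete_markers(m, "ND4"), class = "genecat_unknown_marker_error")

  r <- reorder_markers(m, c("COI", "RAG1", "16S"))
  expect_identical(marker_names(r), c("COI", "RAG1", "16S"))
  expect_error(reorder_markers(m, c("COI", "16S")),
               class = "genecat_invalid_order_error")

  rn <- rename_marker(m, "16S", "16S_rRNA")
  expect_identical(marker_names(rn), c("16S_rRNA", "COI", "RAG1"))
  expect_error(rename_marker(m, "16S", "COI"),
               class = "genecat_duplicate_marker_error")
  expect_error(rename_marker(m, "16S", "bad name"),
               class = "genecat_token_error")
})

test_that("reorder with the inverse permutation restores the original", {
  for (seed in 1:5) {
    m <- random_fixture(seed)
    if (length(m$markers) < 2L) next
    set.seed(seed + 100)
    perm <- sample(marker_names(m))
    r <- reorder_markers(m, perm)
    back <- reorder_markers(r, marker_names(m))
    expect_same_matrix(back, m)
    expect_identical(nrow(marker_overview(m)), length(m$markers))
  }
})

test_that("charsets validate their coordinates and enumerate columns", {
  cs <- charset("M1", 3, 9)
  expect_identical(charset_columns(cs), 3:9)
  expect_error(charset("M1", 5, 2), class = "genecat_partition_error")
  expect_error(charset("M1", 1, 5, step = 2), class = "genecat_partition_error")
  # empty codon subset is representable
  empty <- charset("M1_pos2", 5, 4, step = 3)
  expect_identical(charset_columns(empty), integer(0))
})
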