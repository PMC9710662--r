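test_that("column entropy counts A/C/G/T/- and excludes ?/N/ambiguity codes", {
  expect_equal(column_entropy("AAAA"), 0)
  expect_equal(column_entropy("ACGT"), 2)
  expect_equal(column_entropy("AACC"), 1)
  expect_equal(column_entropy("A-A-"), 1)        # gap is a fifth state
  expect_equal(column_entropy("A?N?"), 0)        # only one counted state left
  expect_equal(column_entropy("??NN"), 0)        # all-excluded convention
  expect_equal(column_entropy("ACGT-"), log2(5))
  expect_equal(column_entropy("ACRT"), log2(3))  # 'R' ambiguity excluded
})

test_that("pairwise cost sums entropies at mismatching counted columns", {
  expect_equal(pairwise_cost("AC", "AT", c(0.5, 1.0)), 1.0)
  expect_equal(pairwise_cost("ACGT", "ACGT", runif(4)), 0)
  expect_equal(pairwise_cost("A?", "AT", c(0.5, 1.0)), 0)  # missing skipped
  expect_equal(pairwise_cost("A-", "AT", c(0.5, 1.0)), 1.0)  # gap vs base mismatches
  expect_error(pairwise_cost("AC", "ACG", c(1, 1, 1)),
               class = "genecat_not_aligned_error")
  # symmetry on random degraded sequences
  set.seed(9)
  for (i in 1:10) {
    a <- paste(sample(c("A", "C", "G", "T", "-", "?", "N"), 20, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T", "-", "?", "N"), 20, TRUE), collapse = "")
    e <- runif(20)
    expect_equal(pairwise_cost(a, b, e), pairwise_cost(b, a, e))
  }
})

test_that("detect_outliers matches the brute-force oracle exactly", {
  for (seed in 1:10) {
    set.seed(seed)
    g <- generate_matrix(fixture_spec(
      n_samples = sample(4:12, 1), n_markers = 1,
      marker_lengths = sample(10:30, 1),
      divergence = runif(1, 0.05, 0.4), seed = seed))
    block <- degrade_block(g$matrix$markers[[1]], prob = 0.1, seed = seed)
    k <- sample(c(1, 2, 20), 1)
    got <- detect_outliers(block, k)
    truth <- bf_outliers(block, k)
    expect_equal(got$cost, truth$costs)
    expect_equal(got$threshold, rep(truth$threshold, nrow(got)))
    expect_identical(got$is_outlier, unname(truth$calls))
  }
})

test_that("identical sequences yield zero costs and no outliers", {
  b <- marker_block("m", setNames(rep("ACGTACGT", 10), sprintf("s%02d", 1:10)))
  oc <- detect_outliers(b)
  expect_true(all(oc$cost == 0))
  expect_false(any(oc$is_outlier))
  expect_error(detect_outliers(marker_block("m", c(a = "AC", b = "AC", c = "AC"))),
               class = "genecat_insufficient_data_error")
  expect_error(detect_outliers(marker_block("m", c(a = "AC", b = "ACG",
                                                   c = "AC", d = "AC"))),
               class = "genecat_not_aligned_error")
})

test_that("outlier calls are monotone in the IQR coefficient", {
  for (seed in 1:6) {
    g <- generate_matrix(fixture_spec(n_samples = 15, n_markers = 1,
                                      marker_lengths = 150, divergence = 0.05,
                                      n_outliers = 1, seed = seed))
    b <- g$matrix$markers[[1]]
    flagged <- lapply(c(1, 5, 20), function(k) {
      oc <- detect_outliers(b, k)
      oc$sample_name[oc$is_outlier]
    })
    expect_true(all(flagged[[2]] %in% flagged[[1]]))
    expect_true(all(flagged[[3]] %in% flagged[[2]]))
  }
})

test_that("non-overlapping sample blocks are detected via shared columns", {
  # samples in different markers only -> two components
  m <- make_matrix(list(marker_block("M1", c(A = "ACGT", B = "ACGA")),
                        marker_block("M2", c(C = "TTTT", D = "TTTA"))))
  ov <- find_nonoverlapping_blocks(m)
  expect_identical(ov$n_components, 2L)
  expect_identical(ov$components, list(c("A", "B"), c("C", "D")))

  # all samples in all markers -> one component
  full <- make_matrix(list(marker_block("M1", c(A = "ACGT", B = "ACGA", C = "ACGT"))))
  expect_identical(find_nonoverlapping_blocks(full)$n_components, 1L)

  # co-membership without a shared counted column is NOT an edge
  disjoint <- make_matrix(list(marker_block("M1", c(A = "AC??", C = "??GT"))))
  expect_identical(find_nonoverlapping_blocks(disjoint)$n_components, 2L)
})

test_that("components agree with brute-force transitive closure", {
  for (seed in 1:6) {
    g <- generate_matrix(fixture_spec(
      n_samples = 8, n_markers = 4, marker_lengths = 12,
      missing_fraction = 0.5, split_fraction = if (seed %% 2) 0.3 else 0,
      seed = seed))
    m <- g$matrix
    got <- find_nonoverlapping_blocks(m)$components
    truth <- bf_components(m)
    expect_identical(lapply(got, sort), truth)
  }
})

test_that("validation_report bundles overview, outliers and overlap", {
  g <- generate_matrix(fixture_spec(n_samples = 12, n_markers = 2,
                                    marker_lengths = c(120, 90),
                                    divergence = 0.02, n_outliers = 1,
                                    split_fraction = 0.25, seed = 5))
  rep <- validation_report(g$matrix, iqr_coefficient = 1)
  expect_s3_class(rep, "validation_report")
  expect_true(g$truth$outliers$sample[1] %in%
              rep$outlier_calls$sample_name[rep$outlier_calls$is_outlier])
  expect_gt(rep$overlap$n_components, 1L)
  expect_true(has_findings(rep))
  expect_identical(nrow(rep$overview), 2L)

  # clean fixture: one component, no outliers
  clean <- generate_matrix(fixture_spec(n_samples = 8, n_markers = 2,
                                        marker_lengths = 100,
                                        divergence = 0.01, seed = 2))
  rep2 <- validation_report(clean$matrix, iqr_coefficient = 20)
  expect_false(has_findings(rep2))
  expect_identical(rep2$overlap$n_components, 1L)

  expect_error(validation_report(make_matrix(list())),
               class = "genecat_empty_input_error")

  # machine-readable report
  f <- tempfile(fileext = ".json")
  write_validation_json(rep, f)
  parsed <- jsonlite::read_json(f)
  expect_true(parsed$has_findings)
  expect_identical(length(parsed$components), rep$overlap$n_components)
})
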