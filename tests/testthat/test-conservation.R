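test_that("column information reproduces closed-form values", {
  expect_equal(column_information(rep("G", 20)), log2(20), tolerance = 1e-9)
  expect_equal(column_information(rep(c("A", "G"), 10)), log2(20) - 1,
               tolerance = 1e-9)
  expect_equal(column_information(c("A", "C", "D", "E")), log2(20) - 2,
               tolerance = 1e-9)
  # gaps excluded; gap-dominated and all-gap columns score 0
  expect_equal(column_information(c("G", "G", "-", "G")), log2(20))
  expect_equal(column_information(c("G", "-", "-", "-")), 0)
  expect_equal(column_information(rep("-", 5)), 0)
})

test_that("small-sample correction subtracts (s-1)/(2 ln2 n) and floors at 0", {
  n <- 20
  expect_equal(column_information(rep("G", n), correction = TRUE),
               log2(20) - 19 / (2 * log(2) * n), tolerance = 1e-9)
  # highly entropic small column: correction would go negative, floored
  expect_equal(column_information(c("A", "C", "D", "E"), correction = TRUE),
               max(log2(20) - 2 - 19 / (2 * log(2) * 4), 0))
  expect_gte(column_information(c("A", "C", "D", "E"), correction = TRUE), 0)
})

test_that("information is always within [0, log2 20]", {
  set.seed(5)
  aa <- c(rownames(blosum62_matrix())[1:20])
  for (k in 1:50) {
    col <- sample(c(aa, "-"), sample(2:40, 1), replace = TRUE)
    for (corr in c(FALSE, TRUE)) {
      r <- column_information(col, correction = corr)
      expect_gte(r, 0)
      expect_lte(r, log2(20))
    }
  }
})

test_that("a single invariant stretch yields exactly one block", {
  set.seed(3)
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  rows <- replicate(20, paste(sample(aa, 30, TRUE), collapse = ""))
  motif <- "WYWYKKW"
  rows <- vapply(rows, function(r) {
    paste0(substr(r, 1, 5), motif, substr(r, 13, 30))
  }, character(1))
  names(rows) <- paste0("s", 1:20)
  b <- detect_blocks(rows)
  expect_equal(nrow(b), 1)
  expect_equal(b$start_col, 5)
  expect_equal(b$end_col, 12)
  expect_error(detect_blocks(rows[1]), ">= 2 rows")
})

test_that("synthetic MocF and CinA alignments reconstruct the 7- and 9-block inventories", {
  pan_m <- simulate_lineage_panel("1.3", n = 20, seed = 42)
  aln_m <- generate_truth_alignment(pan_m)$alignment
  bm <- label_blocks(detect_blocks(aln_m), CATALOG)
  m_labels <- bm$label[grepl("^M-", bm$label)]
  expect_equal(m_labels, paste0("M-", c("I","II","III","IV","V","VI","VII")))

  pan_p <- simulate_lineage_panel("2.2.3.1", n = 20, seed = 42)
  aln_p <- generate_truth_alignment(pan_p)$alignment
  bp <- label_blocks(detect_blocks(aln_p), CATALOG)
  expect_equal(bp$label,
               paste0("P-", c("I","II","III","IV","V","VI","VII","VIII","IX")))
})

test_that("zero-noise block boundaries match the generator's core coordinates", {
  pan <- simulate_lineage_panel("2.2.3.1", n = 24, seed = 21,
                                substitution_rate = 0)
  ta <- generate_truth_alignment(pan)
  b <- label_blocks(detect_blocks(ta$alignment), CATALOG)
  truth <- ta$block_columns
  for (i in seq_len(nrow(truth))) {
    row <- b[b$label == truth$block_id[i], ]
    expect_equal(row$start_col, truth$core_start_col[i])
    expect_equal(row$end_col, truth$core_end_col[i])
  }
})

test_that("block detection is invariant under row shuffles", {
  pan <- simulate_lineage_panel("2.2.3.1", n = 10, seed = 8)
  aln <- generate_truth_alignment(pan)$alignment
  b1 <- detect_blocks(aln)
  set.seed(1)
  b2 <- detect_blocks(aln[sample(length(aln))])
  expect_equal(b1[, c("start_col", "end_col", "mean_information")],
               b2[, c("start_col", "end_col", "mean_information")])
})

test_that("consensus tokens follow the strict/majority/bracket/class rules", {
  # 100% G column
  aln <- matrix(c(rep("G", 20)), ncol = 1)
  expect_identical(render_pattern(consensus_string(aln, c(0, 1))), "G!")
  # 55% T / 40% D -> bracket (jointly above majority)
  col <- c(rep("T", 11), rep("D", 8), "A")
  expect_identical(render_pattern(consensus_string(matrix(col, ncol = 1),
                                                   c(0, 1))), "[TD]")
  # mixed hydrophobics -> class code
  col <- c(rep("A", 6), rep("V", 5), rep("L", 5), rep("I", 4))
  expect_identical(render_pattern(consensus_string(matrix(col, ncol = 1),
                                                   c(0, 1))), "h")
  # unstructured column -> wildcard
  col <- c("A", "C", "D", "E", "F", "G", "H", "K", "R", "S",
           "T", "N", "Q", "W", "Y", "P", "M", "I", "L", "V")
  expect_identical(render_pattern(consensus_string(matrix(col, ncol = 1),
                                                   c(0, 1))), "x")
  expect_error(consensus_string(aln, c(0, 1), strict_threshold = 0.9,
                                majority_threshold = 0.9))
})

test_that("labels map detected consensus to the right catalog block", {
  b <- data.frame(start_col = 0, end_col = 11, mean_information = 4,
                  consensus = "GGLGPTxDDxT", label = NA_character_,
                  stringsAsFactors = FALSE)
  lb <- label_blocks(b, CATALOG)
  expect_equal(lb$label, "M-III")
  # junk consensus stays unlabeled
  b2 <- data.frame(start_col = 0, end_col = 5, mean_information = 4,
                   consensus = "QQQQQ", label = NA_character_,
                   stringsAsFactors = FALSE)
  expect_true(is.na(label_blocks(b2, CATALOG)$label))
})

test_that("label ties resolve in canonical order", {
  toy <- toy_tie_catalog()
  b <- data.frame(start_col = c(0, 10), end_col = c(4, 14),
                  mean_information = 4, consensus = c("WWWW", "WWWW"),
                  label = NA_character_, stringsAsFactors = FALSE)
  lb <- label_blocks(b, toy)
  expect_equal(lb$label, c("X-1", "X-2"))
})
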