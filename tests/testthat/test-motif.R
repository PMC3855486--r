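test_that("pattern grammar parses majority, strict, set, class and wildcard tokens", {
  p <- parse_pattern("G[TD]E!xxxG!xxx[DN]TxN!", "M-I")
  expect_length(p$positions, 14)
  strict <- which(vapply(p$positions, `[[`, logical(1), "strict")) - 1L
  expect_equal(strict, c(2L, 6L, 13L))
  expect_equal(p$positions[[2]]$allowed, c("T", "D"))
  expect_equal(p$positions[[4]]$kind, "wildcard")

  w <- parse_pattern("x", "wild")
  expect_length(w$positions, 1)
  expect_false(w$positions[[1]]$strict)

  p8 <- parse_pattern("Rxx[VI]R", "P-VIII")
  expect_length(p8$positions, 5)
  expect_equal(p8$positions[[4]]$allowed, c("V", "I"))

  cls <- parse_pattern("chp", "classes")
  expect_equal(cls$positions[[1]]$allowed, residue_classes()$c)
  expect_equal(cls$positions[[2]]$allowed, residue_classes()$h)
  expect_equal(cls$positions[[3]]$allowed, residue_classes()$p)
})

test_that("parse errors name the offending offset", {
  expect_error(parse_pattern("AC?E", "bad"), "offset 2")
  expect_error(parse_pattern("A[]C", "bad"), "empty bracket")
  expect_error(parse_pattern("A[XY", "bad"), "unterminated")
  expect_error(parse_pattern("Ax!", "bad"), "strict")
})

test_that("render is the exact inverse of parse", {
  pats <- c("G[TD]E!xxxG!xxx[DN]TxN!", "A!E!S!CTGG!", "GhGE!SxhA!P!",
            "EVxh[RK]h", "x", "Rxx[VI]R", "[ST]G[IV]A!G!P!xG!G!")
  for (txt in pats) {
    expect_identical(render_pattern(parse_pattern(txt, "p")), txt)
  }
})

test_that("scan finds exact and partial matches with the announced score", {
  pat <- parse_pattern("AESCTGG", "P-I")
  hit <- scan_motif("MAESCTGGWG", pat, 1.0)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$start, 1)
  expect_equal(hit$end, 8)
  expect_equal(hit$score, 1.0)
  expect_equal(hit$matched_subsequence, "AESCTGG")

  # one mismatch in a 7-informative-position pattern scores 6/7
  hit2 <- scan_motif("MAESCAGGWG", pat, 0.7)
  expect_equal(nrow(hit2), 1)
  expect_equal(hit2$score, 6 / 7)
})

test_that("strict positions veto a hit only at their own offset", {
  seq <- "MAESCAGGWG"
  # strict S (position 2) matches even though T (position 4) is mutated
  lenient <- scan_motif(seq, parse_pattern("AES!CTGG", "p"), 0.7)
  expect_equal(nrow(lenient), 1)
  # strict T at the mutated position kills the hit
  strictT <- scan_motif(seq, parse_pattern("AESCT!GG", "p"), 0.7)
  expect_equal(nrow(strictT), 0)
  # enforce_strict = FALSE restores it (signature-probe mode)
  relaxed <- scan_motif(seq, parse_pattern("AESCT!GG", "p"), 0.7,
                        enforce_strict = FALSE)
  expect_equal(nrow(relaxed), 1)
})

test_that("empty sequences, unknown residues and windows behave as documented", {
  pat <- parse_pattern("AC", "p")
  expect_equal(nrow(scan_motif("", pat)), 0)
  expect_warning(hits <- scan_motif("ACZAC", pat, 1.0), "invalid residue")
  expect_equal(hits$start, c(0, 3))
  # X counts as mismatch at non-wildcard positions
  expect_equal(nrow(scan_motif("AXC", parse_pattern("AEC", "p"), 1.0)), 0)
  expect_equal(nrow(scan_motif("AXC", parse_pattern("AxC", "p"), 1.0)), 1)
  # window restricts match starts (0-based half-open)
  win <- scan_motif("ACAC", pat, 1.0, window = c(1, 4))
  expect_equal(win$start, 2)
})

test_that("score is invariant under wildcard-only flanks", {
  set.seed(11)
  for (k in 1:10) {
    seqv <- paste(sample(residue_classes()$h, 30, TRUE), collapse = "")
    core <- parse_pattern("M[AV]xG", "core")
    flank <- parse_pattern("xxM[AV]xGx", "flank")
    h1 <- scan_motif(seqv, core, 1e-9)
    h2 <- scan_motif(seqv, flank, 1e-9)
    # compare scores of placements whose core aligns
    shared <- intersect(h1$start, h2$start + 2)
    expect_true(length(shared) > 0)
    expect_equal(h1$score[match(shared, h1$start)],
                 h2$score[match(shared - 2, h2$start)])
  }
})

test_that("all-strict exact scan equals naive substring search", {
  set.seed(7)
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  for (k in 1:20) {
    s <- paste(sample(aa, 200, TRUE), collapse = "")
    probe <- substr(s, 60, 65)
    pat <- parse_pattern(paste0(strsplit(probe, "")[[1]], "!", collapse = ""),
                         "probe")
    hits <- scan_motif(s, pat, 1.0)
    naive <- c()
    for (i in 1:(200 - 5)) {
      if (substr(s, i, i + 5) == probe) naive <- c(naive, i - 1)
    }
    expect_equal(hits$start, naive)
  }
})
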