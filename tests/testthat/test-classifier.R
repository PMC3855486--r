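test_that("architectures are called from block content and extension length", {
  two_dom <- simulate_lineage_panel("1.2", n = 2, seed = 31,
                                    substitution_rate = 0)
  for (s in two_dom$sequences) {
    expect_equal(call_architecture(s, CATALOG)$class, "MOCF_CINA")
  }
  single <- simulate_lineage_panel("2.2.3.1", n = 2, seed = 31,
                                   substitution_rate = 0)
  for (s in single$sequences) {
    a <- call_architecture(s, CATALOG)
    expect_equal(a$class, "CINA_ONLY")
    expect_lte(a$extension_length, 30)
  }
  split <- simulate_lineage_panel("2.2.3.4", n = 2, seed = 31,
                                  substitution_rate = 0)
  for (s in split$sequences) {
    expect_equal(call_architecture(s, CATALOG)$class, "SPLIT_CINA")
  }
  mocf_only <- simulate_lineage_panel("1.3", n = 2, seed = 31,
                                      substitution_rate = 0)
  for (s in mocf_only$sequences) {
    expect_equal(call_architecture(s, CATALOG)$class, "MOCF_ONLY")
  }
  ext <- simulate_lineage_panel("2.2.3.2", n = 2, seed = 31,
                                substitution_rate = 0)
  for (s in ext$sequences) {
    a <- call_architecture(s, CATALOG)
    expect_equal(a$class, "CINA_NEXT_SHORT")
    expect_true(a$extension_length > 30 && a$extension_length <= 80)
  }
  long <- simulate_lineage_panel("2.2.3.3", n = 2, seed = 31,
                                 substitution_rate = 0)
  for (s in long$sequences) {
    expect_equal(call_architecture(s, CATALOG)$class, "CINA_NEXT_LONG")
  }
  expect_warning(short <- call_architecture("MAESCTGG", CATALOG), "shorter")
  expect_equal(short$class, "UNKNOWN")
})

test_that("architecture calls survive a short random C-terminal tail", {
  set.seed(77)
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  for (lin in c("2.2.3.1", "1.2", "1.3")) {
    pan <- simulate_lineage_panel(lin, n = 2, seed = 55)
    for (s in pan$sequences) {
      base <- call_architecture(s, CATALOG)$class
      tail <- paste(sample(aa, sample(1:10, 1), TRUE), collapse = "")
      expect_equal(call_architecture(paste0(s, tail), CATALOG)$class, base)
    }
  }
})

test_that("functionality checklist passes 10/10 on active sequences", {
  pan <- simulate_lineage_panel("2.2.3.1", n = 3, seed = 13,
                                substitution_rate = 0)
  for (s in pan$sequences) {
    fc <- call_functionality(s, CATALOG)
    expect_equal(fc$verdict, "active")
    expect_equal(nrow(fc$checklist), 10)
    expect_true(all(fc$checklist$result == "pass"))
    expect_length(fc$signatures_fired, 0)
  }
})

test_that("documented mutants are called inactive with the right signature", {
  ydej <- simulate_lineage_panel("2.2.2.2", n = 3, seed = 13,
                                 substitution_rate = 0)
  for (s in ydej$sequences) {
    fc <- call_functionality(s, CATALOG)
    expect_equal(fc$verdict, "inactive")
    expect_true("YdeJ-like" %in% fc$signatures_fired)
  }
  yfay <- simulate_lineage_panel("2.2.1.2", n = 3, seed = 13,
                                 substitution_rate = 0)
  for (s in yfay$sequences) {
    fc <- call_functionality(s, CATALOG)
    expect_equal(fc$verdict, "inactive")
    expect_true("YfaY-like" %in% fc$signatures_fired)
  }
})

test_that("an unresolved X at a key residue gives an indeterminate call", {
  pan <- simulate_lineage_panel("2.2.3.1", n = 1, seed = 17,
                                substitution_rate = 0)
  s <- pan$sequences[[1]]
  b <- pan$blocks
  k63_pos <- b$start[b$entry_id == "P-III"] + 5 + 1   # 1-based K63 offset
  substr(s, k63_pos, k63_pos) <- "X"
  fc <- call_functionality(s, CATALOG)
  expect_equal(fc$verdict, "indeterminate")
  expect_length(fc$signatures_fired, 0)
  expect_true("absent" %in%
                fc$checklist$result[fc$checklist$entry_id == "P-III"])
})

test_that("no record is active with a fired signature, across a noisy panel", {
  pan <- simulate_panel(n_per = 2, seed = 19, substitution_rate = 0.05)
  rec <- classify_sequences(pan$sequences, CATALOG)
  expect_false(any(rec$functionality == "active" & nzchar(rec$signatures)))
})

test_that("architecture-driven lineages follow the decision table", {
  cases <- list(c("1.3", "MOCF_ONLY"), c("2.2.1.2", "MOCF_CINA"),
                c("2.2.2.2", "CINA_ONLY"), c("2.2.3.2", "CINA_NEXT_SHORT"),
                c("2.2.3.3", "CINA_NEXT_LONG"), c("2.2.3.4", "SPLIT_CINA"))
  for (cs in cases) {
    pan <- simulate_lineage_panel(cs[1], n = 2, seed = 23,
                                  substitution_rate = 0)
    rec <- classify_sequences(pan$sequences, CATALOG)
    expect_equal(unique(rec$architecture), cs[2])
    expect_equal(unique(rec$lineage), cs[1])
  }
})

test_that("fingerprint-ambiguous lineages resolve by taxonomy hint", {
  pan <- simulate_lineage_panel("1.2", n = 2, seed = 29,
                                substitution_rate = 0)
  tax <- stats::setNames(pan$truth$taxonomy, pan$truth$sequence_id)
  rec <- classify_sequences(pan$sequences, CATALOG, taxonomy = tax)
  expect_equal(unique(rec$lineage), "1.2")
  expect_true(all(rec$taxonomy_hint_used))
  # without a hint the tie is reported, not forced
  rec0 <- classify_sequences(pan$sequences, CATALOG)
  expect_true(all(rec0$lineage == "unassigned" | rec0$confidence < 1))
})

test_that("the 13-lineage confusion matrix is diagonal at zero noise", {
  pan <- simulate_panel(n_per = 3, seed = 7, substitution_rate = 0)
  tax <- stats::setNames(pan$truth$taxonomy, pan$truth$sequence_id)
  rec <- classify_sequences(pan$sequences, CATALOG, taxonomy = tax)
  expect_identical(rec$lineage, pan$truth$lineage)
  expect_identical(rec$functionality, pan$truth$functionality)
})

test_that("recovery stays at or above 95% under 5% substitution noise", {
  pan <- simulate_panel(n_per = 4, seed = 33, substitution_rate = 0.05)
  tax <- stats::setNames(pan$truth$taxonomy, pan$truth$sequence_id)
  rec <- classify_sequences(pan$sequences, CATALOG, taxonomy = tax)
  expect_gte(mean(rec$lineage == pan$truth$lineage), 0.95)
  expect_gte(mean(rec$functionality == pan$truth$functionality), 0.95)
})

test_that("classification reports round-trip through TSV and JSON", {
  pan <- simulate_lineage_panel("2.2.3.1", n = 2, seed = 3)
  rec <- classify_sequences(pan$sequences, CATALOG)
  tsv <- tempfile(fileext = ".tsv")
  js <- tempfile(fileext = ".json")
  write_classification(rec, tsv = tsv, json = js)
  back <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  expect_equal(back$lineage, rec$lineage)
  jl <- jsonlite::read_json(js)
  expect_length(jl, nrow(rec))
})
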