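# Shared fixtures, built in code at test time.

CATALOG <- load_catalog()

# Fig S4-style NMN grid (0.01 to 1 mM) and the sigmoidal-assay grid.
mm_grid <- function(n = 8) 10^seq(log10(0.01), log10(1), length.out = n)
hill_grid <- function(n = 8) 10^seq(log10(0.5), log10(60), length.out = n)

# A tiny two-entry catalog whose entries share one pattern, to probe label
# tie-breaking.
toy_tie_catalog <- function() {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "id\tblock_id\tdomain_tag\torder_index\tlineage_tag\tvariant_of\tpattern\tkey_residues\tnote",
    "X-1\tX-1\tCinA\t1\t\t \tW!W!W!W!\t \ttoy",
    "X-2\tX-2\tCinA\t2\t\t \tW!W!W!W!\t \ttoy"), path)
  load_catalog(path)
}

# Exhaustive enumeration oracle for the global affine-gap alignment score:
# walks every alignment path (diagonal / gap-in-b / gap-in-a), scoring gaps
# as open + extend per residue, and keeps the maximum. Independent of the
# Gotoh dynamic program under test.
brute_force_global_score <- function(a, b, S, gap_open = 11, gap_extend = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  memo <- new.env(hash = TRUE)
  go <- gap_open + gap_extend
  rec <- function(i, j, state) {
    if (i > length(A) && j > length(B)) return(0)
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- -Inf
    if (i <= length(A) && j <= length(B)) {
      best <- max(best, S[A[i], B[j]] + rec(i + 1, j + 1, "M"))
    }
    if (i <= length(A)) {
      cost <- if (state == "X") gap_extend else go
      best <- max(best, -cost + rec(i + 1, j, "X"))
    }
    if (j <= length(B)) {
      cost <- if (state == "Y") gap_extend else go
      best <- max(best, -cost + rec(i, j + 1, "Y"))
    }
    memo[[key]] <- best
    best
  }
  rec(1, 1, "M")
}

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}
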