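# Degenerate block-consensus pattern language and scanner.
#
# Grammar (one token per alignment position):
#   A        uppercase letter  = majority residue (counts toward score)
#   A!       letter + '!'      = strictly conserved (must match in any hit)
#   [XY]     bracket set       = alternative residues at that position
#   c h p    lowercase class   = charged / hydrophobic / polar residue
#   x        wildcard          = any residue (never strict, never scored)

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Physicochemical class membership. The class codes come from the block
# figures' legend; membership is this package's (auditable) partition.
RESIDUE_CLASSES <- list(
  c = c("D", "E", "K", "R", "H"),
  h = c("A", "V", "L", "I", "M", "F", "W", "C", "Y"),
  p = c("S", "T", "N", "Q", "G")
)

#' Residue class membership table
#'
#' Returns the partition of the 20 amino acids behind the class codes used in
#' consensus patterns: `c` charged, `h` hydrophobic, `p` polar/small.
#'
#' @return Named list of character vectors of one-letter residue codes.
#' @export
residue_classes <- function() RESIDUE_CLASSES

new_position_spec <- function(kind, allowed, strict = FALSE, class = NA_character_) {
  stopifnot(kind %in% c("literal", "set", "class", "wildcard"))
  if (kind == "wildcard" && strict) {
    stop("wildcard positions cannot be strict")
  }
  if (kind != "wildcard" && (length(allowed) == 0L || !all(allowed %in% AA_ALPHABET))) {
    stop("allowed set must be non-empty and drawn from the 20-residue alphabet")
  }
  structure(list(kind = kind, allowed = allowed, strict = strict, class = class),
            class = "position_spec")
}

#' Parse a block-consensus pattern string
#'
#' Parses the degenerate consensus grammar used for the conserved-block
#' catalog into a motif pattern: uppercase letters are majority residues, a
#' trailing `!` marks a strictly conserved position, `[XY]` is an alternative
#' set, lowercase `c`/`h`/`p` are residue classes and `x` is a wildcard.
#'
#' @param text Pattern string, e.g. `"G[TD]E!xxxG!xxx[DN]TxN!"`.
#' @param id Pattern identifier (e.g. `"M-I"`).
#' @param lineage_tag Optional lineage label the variant belongs to.
#' @return A `motif_pattern` object (ordered list of position specs).
#' @examples
#' p <- parse_pattern("Rxx[VI]R", "P-VIII")
#' length(p$positions)  # 5
#' @export
parse_pattern <- function(text, id, lineage_tag = NA_character_) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  chars <- strsplit(text, "")[[1]]
  positions <- list()
  i <- 1L
  n <- length(chars)
  take_bang <- function(i) i <= n && chars[i] == "!"
  while (i <= n) {
    ch <- chars[i]
    if (ch == "x") {
      if (take_bang(i + 1L)) {
        stop(sprintf("parse error at offset %d: wildcard cannot be strict", i - 1L))
      }
      positions[[length(positions) + 1L]] <-
        new_position_spec("wildcard", AA_ALPHABET)
      i <- i + 1L
    } else if (ch %in% names(RESIDUE_CLASSES)) {
      strict <- take_bang(i + 1L)
      positions[[length(positions) + 1L]] <-
        new_position_spec("class", RESIDUE_CLASSES[[ch]], strict, class = ch)
      i <- i + 1L + strict
    } else if (ch == "[") {
      close <- which(chars == "]" & seq_len(n) > i)
      if (length(close) == 0L) {
        stop(sprintf("parse error at offset %d: unterminated bracket", i - 1L))
      }
      close <- close[1L]
      members <- chars[seq(i + 1L, length.out = close - i - 1L)]
      if (length(members) == 0L) {
        stop(sprintf("parse error at offset %d: empty bracket", i - 1L))
      }
      if (!all(members %in% AA_ALPHABET)) {
        stop(sprintf("parse error at offset %d: invalid residue in bracket", i - 1L))
      }
      strict <- take_bang(close + 1L)
      positions[[length(positions) + 1L]] <-
        new_position_spec("set", members, strict)
      i <- close + 1L + strict
    } else if (ch %in% AA_ALPHABET) {
      strict <- take_bang(i + 1L)
      positions[[length(positions) + 1L]] <-
        new_position_spec("literal", ch, strict)
      i <- i + 1L + strict
    } else {
      stop(sprintf("parse error at offset %d: unknown character '%s'", i - 1L, ch))
    }
  }
  structure(list(id = id, positions = positions, lineage_tag = lineage_tag),
            class = "motif_pattern")
}

#' Render a motif pattern back to its grammar string
#'
#' Inverse of [parse_pattern()]: `parse_pattern(render_pattern(p), p$id)`
#' reproduces `p` exactly.
#'
#' @param pattern A `motif_pattern`.
#' @return Single pattern string.
#' @export
render_pattern <- function(pattern) {
  stopifnot(inherits(pattern, "motif_pattern"))
  toks <- vapply(pattern$positions, function(ps) {
    bang <- if (ps$strict) "!" else ""
    switch(ps$kind,
           wildcard = "x",
           class = paste0(ps$class, bang),
           literal = paste0(ps$allowed, bang),
           set = paste0("[", paste(ps$allowed, collapse = ""), "]", bang))
  }, character(1))
  paste(toks, collapse = "")
}

#' @export
print.motif_pattern <- function(x, ...) {
  n_strict <- sum(vapply(x$positions, `[[`, logical(1), "strict"))
  cat(sprintf("<motif_pattern %s> %s (%d positions, %d strict%s)\n",
              x$id, render_pattern(x), length(x$positions), n_strict,
              if (!is.na(x$lineage_tag)) paste0(", lineage ", x$lineage_tag) else ""))
  invisible(x)
}

pattern_length <- function(pattern) length(pattern$positions)

# Offsets (0-based) of non-wildcard positions.
informative_offsets <- function(pattern) {
  which(vapply(pattern$positions, function(p) p$kind != "wildcard", logical(1))) - 1L
}

#' Scan a protein sequence for a motif pattern
#'
#' Slides the pattern over the sequence and reports every placement whose
#' fraction of matched non-wildcard positions reaches `min_score` and whose
#' strict positions all match exactly. Unknown residues (`X`) count as
#' mismatches at non-wildcard positions.
#'
#' @param sequence Amino-acid string (20-letter alphabet, optional `X`).
#' @param pattern A `motif_pattern` from [parse_pattern()].
#' @param min_score Minimum fraction of matched non-wildcard positions,
#'   in (0, 1]. Default 0.7 permits one mismatch in short blocks.
#' @param sequence_id Identifier recorded in the result.
#' @param window Optional `c(start, end)` 0-based half-open range restricting
#'   the allowed match start positions.
#' @param enforce_strict If `FALSE`, strict positions lose their veto and only
#'   count toward the score (used by signature probes on mutant sequences).
#' @return `data.frame` with columns `pattern_id`, `sequence_id`, `start`
#'   (0-based inclusive), `end` (exclusive), `score`, `matched_subsequence`,
#'   sorted by `start` then descending `score`.
#' @examples
#' scan_motif("MAESCTGGWG", parse_pattern("AESCTGG", "P-I"), 1.0)
#' @export
scan_motif <- function(sequence, pattern, min_score = 0.7, sequence_id = "seq",
                       window = NULL, enforce_strict = TRUE) {
  stopifnot(inherits(pattern, "motif_pattern"),
            is.numeric(min_score), min_score > 0, min_score <= 1)
  empty <- data.frame(pattern_id = character(), sequence_id = character(),
                      start = integer(), end = integer(), score = numeric(),
                      matched_subsequence = character(),
                      stringsAsFactors = FALSE)
  if (!nzchar(sequence)) return(empty)
  res <- strsplit(toupper(sequence), "")[[1]]
  bad <- !(res %in% c(AA_ALPHABET, "X"))
  if (any(bad)) {
    warning(sprintf("invalid residue letter(s) %s treated as mismatch",
                    paste(unique(res[bad]), collapse = ",")))
  }
  L <- length(res)
  m <- pattern_length(pattern)
  if (m > L) return(empty)
  starts <- 0:(L - m)                       # 0-based
  if (!is.null(window)) {
    stopifnot(length(window) == 2L)
    starts <- starts[starts >= window[1] & starts < window[2]]
    if (length(starts) == 0L) return(empty)
  }
  info <- informative_offsets(pattern)
  n_info <- length(info)
  keep_start <- integer(0)
  keep_score <- numeric(0)
  for (s in starts) {
    ok <- TRUE
    matched <- 0L
    for (k in info) {
      ps <- pattern$positions[[k + 1L]]
      hit <- res[s + k + 1L] %in% ps$allowed
      if (hit) matched <- matched + 1L
      if (!hit && ps$strict && enforce_strict) { ok <- FALSE; break }
    }
    if (!ok) next
    score <- if (n_info == 0L) 1 else matched / n_info
    if (score >= min_score) {
      keep_start <- c(keep_start, s)
      keep_score <- c(keep_score, score)
    }
  }
  if (length(keep_start) == 0L) return(empty)
  out <- data.frame(pattern_id = pattern$id, sequence_id = sequence_id,
                    start = keep_start, end = keep_start + m,
                    score = keep_score,
                    matched_subsequence = vapply(keep_start, function(s)
                      paste(res[(s + 1L):(s + m)], collapse = ""), character(1)),
                    stringsAsFactors = FALSE)
  out[order(out$start, -out$score), , drop = FALSE]
}
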