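# Per-column conservation (sequence-logo information content), contiguous
# conserved-block detection on multiple alignments, and consensus strings in
# the block-catalog grammar.

# Accepts a named character vector of aligned sequences or a residue matrix;
# returns a character matrix (rows = sequences, cols = alignment columns).
alignment_matrix <- function(alignment) {
  if (is.matrix(alignment)) return(alignment)
  stopifnot(is.character(alignment))
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L) {
    stop("aligned rows have unequal lengths")
  }
  m <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(m) <- names(alignment)
  m
}

#' Information content of one alignment column
#'
#' Sequence-logo column height basis: `log2(20)` minus the Shannon entropy of
#' the observed residue frequencies, gaps excluded. Columns that are more
#' than half gaps (or all gaps) score 0. The optional small-sample correction
#' subtracts `(s - 1) / (2 ln(2) n)` with `s = 20` and `n` the number of
#' non-gap residues; the result is floored at 0.
#'
#' @param column Character vector of residues and `-` gaps.
#' @param correction Apply the small-sample correction? Default `FALSE`.
#' @return Information content in bits, in `[0, log2(20)]`.
#' @examples
#' column_information(rep("G", 20))              # log2(20) = 4.32 bits
#' column_information(rep(c("A", "G"), 10))      # log2(20) - 1
#' @export
column_information <- function(column, correction = FALSE) {
  stopifnot(length(column) > 0)
  res <- column[column != "-"]
  n <- length(res)
  if (n == 0L || n <= length(column) / 2) return(0)
  p <- table(res) / n
  H <- -sum(p * log2(p))
  R <- log2(20) - H
  if (correction) R <- R - (20 - 1) / (2 * log(2) * n)
  max(R, 0)
}

#' Per-column information content of an alignment
#'
#' @param alignment Named character vector of equal-length aligned sequences,
#'   or a residue matrix.
#' @inheritParams column_information
#' @return Numeric vector, one value in bits per alignment column.
#' @export
alignment_information <- function(alignment, correction = FALSE) {
  m <- alignment_matrix(alignment)
  apply(m, 2, column_information, correction = correction)
}

#' Detect contiguous conserved blocks in an alignment
#'
#' A conserved block is a maximal run of columns that starts and ends at a
#' column with information content at least `min_bits` and contains no more
#' than `max_low_cols` consecutive sub-threshold columns internally. Blocks
#' shorter than `min_len` columns are discarded.
#'
#' @inheritParams alignment_information
#' @param min_bits Conservation threshold in bits (default 2).
#' @param max_low_cols Longest run of sub-threshold columns tolerated inside
#'   a block (default 3, the longest wildcard run in the canonical catalog).
#' @param min_len Minimum block length in columns (default 3).
#' @param strict_threshold,majority_threshold Passed to [consensus_string()].
#' @return `data.frame` with 0-based half-open `start_col`/`end_col`,
#'   `mean_information` (bits), `consensus` (pattern grammar) and an `label`
#'   column initialized to `NA` (see [label_blocks()]); sorted by start.
#' @export
detect_blocks <- function(alignment, min_bits = 2, max_low_cols = 3,
                          min_len = 3, correction = FALSE,
                          strict_threshold = 0.95, majority_threshold = 0.6) {
  m <- alignment_matrix(alignment)
  if (nrow(m) < 2L) stop("block detection needs an alignment with >= 2 rows")
  stopifnot(min_bits > 0, min_len > 0, max_low_cols >= 0)
  bits <- apply(m, 2, column_information, correction = correction)
  high <- which(bits >= min_bits)
  empty <- data.frame(start_col = integer(), end_col = integer(),
                      mean_information = numeric(), consensus = character(),
                      label = character(), stringsAsFactors = FALSE)
  if (length(high) == 0L) return(empty)
  # group high columns whose internal low runs are short enough
  breaks <- which(diff(high) - 1L > max_low_cols)
  grp_start <- high[c(1L, breaks + 1L)]
  grp_end <- high[c(breaks, length(high))]
  keep <- (grp_end - grp_start + 1L) >= min_len
  grp_start <- grp_start[keep]
  grp_end <- grp_end[keep]
  if (length(grp_start) == 0L) return(empty)
  out <- data.frame(
    start_col = grp_start - 1L,               # to 0-based
    end_col = grp_end,                        # half-open
    mean_information = mapply(function(s, e) mean(bits[s:e]), grp_start, grp_end),
    stringsAsFactors = FALSE)
  out$consensus <- vapply(seq_len(nrow(out)), function(i) {
    render_pattern(consensus_string(m, c(out$start_col[i], out$end_col[i]),
                                    strict_threshold, majority_threshold))
  }, character(1))
  out$label <- NA_character_
  out[order(out$start_col), , drop = FALSE]
}

#' Consensus pattern of an alignment slice
#'
#' Summarizes each column of a block in the catalog grammar: a residue at
#' frequency `>= strict_threshold` becomes a strict literal (`G!`), one at
#' `>= majority_threshold` a plain literal, two residues jointly reaching the
#' majority threshold a bracket set, a column dominated by one
#' physicochemical class its class code, anything else a wildcard. Gaps are
#' excluded from the frequency denominator.
#'
#' @inheritParams alignment_information
#' @param block `c(start_col, end_col)` 0-based half-open, or a one-row
#'   block table from [detect_blocks()].
#' @param strict_threshold Frequency for a strictly conserved call
#'   (default 0.95).
#' @param majority_threshold Frequency for a majority call (default 0.6);
#'   must satisfy `0.5 <= majority < strict <= 1`.
#' @return A `motif_pattern`.
#' @export
consensus_string <- function(alignment, block, strict_threshold = 0.95,
                             majority_threshold = 0.6) {
  stopifnot(majority_threshold >= 0.5, majority_threshold < strict_threshold,
            strict_threshold <= 1)
  m <- alignment_matrix(alignment)
  if (is.data.frame(block)) block <- c(block$start_col[1], block$end_col[1])
  cols <- (block[1] + 1L):block[2]
  toks <- vapply(cols, function(j) {
    res <- m[, j]
    res <- res[res != "-" & res != "X"]
    if (length(res) == 0L) return("x")
    p <- sort(table(res) / length(res), decreasing = TRUE)
    if (p[1] >= strict_threshold) return(paste0(names(p)[1], "!"))
    if (p[1] >= majority_threshold) return(names(p)[1])
    if (length(p) >= 2 && p[1] + p[2] >= majority_threshold) {
      return(paste0("[", names(p)[1], names(p)[2], "]"))
    }
    cls_freq <- vapply(RESIDUE_CLASSES, function(cl)
      sum(p[names(p) %in% cl]), numeric(1))
    if (max(cls_freq) >= majority_threshold) {
      return(names(cls_freq)[which.max(cls_freq)])
    }
    "x"
  }, character(1))
  parse_pattern(paste(toks, collapse = ""), id = "consensus")
}

# Positional agreement between two patterns: best gapless offset alignment,
# per-position Jaccard overlap of allowed sets, normalized by the longer
# pattern's length.
pattern_agreement <- function(a, b) {
  sets_a <- lapply(a$positions, `[[`, "allowed")
  sets_b <- lapply(b$positions, `[[`, "allowed")
  na <- length(sets_a); nb <- length(sets_b)
  if (na > nb) { tmp <- sets_a; sets_a <- sets_b; sets_b <- tmp; tmp <- na; na <- nb; nb <- tmp }
  best <- 0
  for (off in 0:(nb - na)) {
    s <- sum(vapply(seq_len(na), function(i) {
      A <- sets_a[[i]]; B <- sets_b[[i + off]]
      length(intersect(A, B)) / length(union(A, B))
    }, numeric(1)))
    best <- max(best, s)
  }
  best / nb
}

#' Assign catalog block labels to detected blocks
#'
#' Each detected block receives the block label of the catalog entry whose
#' pattern agrees best with the block's consensus (highest positional
#' agreement over the best gapless offset). Near-ties are resolved in favor
#' of the candidate that keeps the canonical block order increasing along the
#' alignment; blocks agreeing with nothing (below `min_agreement`) keep an
#' `NA` label.
#'
#' @param blocks Block table from [detect_blocks()].
#' @param catalog A `block_catalog`.
#' @param min_agreement Minimum agreement to accept a label (default 0.5).
#' @param tie_tol Agreement difference treated as a tie (default 0.05).
#' @return `blocks` with the `label` column filled (canonical block ids such
#'   as `"M-III"`), plus an `agreement` column.
#' @export
label_blocks <- function(blocks, catalog, min_agreement = 0.5, tie_tol = 0.05) {
  stopifnot(inherits(catalog, "block_catalog"))
  if (nrow(blocks) == 0L) {
    blocks$agreement <- numeric(0)
    return(blocks)
  }
  blocks <- blocks[order(blocks$start_col), , drop = FALSE]
  entries <- catalog$entries
  blocks$agreement <- NA_real_
  last_order <- list(MocF = -Inf, interdomain = -Inf, CinA = -Inf)
  for (i in seq_len(nrow(blocks))) {
    cons <- parse_pattern(blocks$consensus[i], "detected")
    agr <- vapply(entries, function(e) pattern_agreement(cons, e$pattern),
                  numeric(1))
    if (max(agr) < min_agreement) next
    cand <- which(agr >= max(agr) - tie_tol)
    # prefer candidates continuing the canonical order within their domain
    ord_ok <- vapply(cand, function(k) {
      e <- entries[[k]]
      e$order_index > last_order[[e$domain_tag]]
    }, logical(1))
    if (any(ord_ok)) cand <- cand[ord_ok]
    # among remaining ties: highest agreement, then lowest canonical order
    agr_c <- agr[cand]
    cand <- cand[agr_c == max(agr_c)]
    ord_c <- vapply(cand, function(k) entries[[k]]$order_index, numeric(1))
    pick <- entries[[cand[which.min(ord_c)]]]
    blocks$label[i] <- pick$block_id
    blocks$agreement[i] <- max(agr)
    last_order[[pick$domain_tag]] <- pick$order_index
  }
  blocks
}

#' Write a detected-block table as TSV
#'
#' @param blocks Block table from [detect_blocks()] / [label_blocks()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_block_table <- function(blocks, path) {
  utils::write.table(blocks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
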