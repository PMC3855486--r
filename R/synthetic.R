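# Seeded generator of labeled PncC-family test data: per-lineage protein
# sequences assembled from the block catalog's lineage variants with random
# linkers and configurable substitution noise, known-truth alignments, and
# noisy Michaelis-Menten / Hill initial-rate datasets.

# Evaluate expr with a private RNG stream; the caller's RNG state is
# untouched.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

linker <- function(lo, hi) list(type = "linker", lo = lo, hi = hi)
blk <- function(entry_id) list(type = "block", entry_id = entry_id)

# Segment plan per lineage: alternating linkers (length ranges chosen so
# realized lengths land in the family's observed length classes: ~165 aa
# single domain, ~210-250 aa extended, ~420 aa two-domain, ~170 aa
# MocF-only) and catalog blocks (lineage variants where documented).
lineage_plan <- function(lineage) {
  mocf <- function(m4 = "M-IV", inter = c(14, 22)) {
    list(blk("M-I"), linker(inter[1], inter[2]), blk("M-II"),
         linker(inter[1], inter[2]), blk("M-III"), linker(inter[1], inter[2]),
         blk(m4), linker(inter[1], inter[2]), blk("M-V"),
         linker(inter[1], inter[2]), blk("M-VI"), linker(inter[1], inter[2]),
         blk("M-VII"))
  }
  cina <- function(ids = c("P-I", "P-II", "P-III", "P-IV", "P-V", "P-VI",
                           "P-VII", "P-VIII", "P-IX"),
                   inter = c(7, 13), spacer_after = NULL,
                   spacer_range = c(45, 60)) {
    segs <- list()
    for (i in seq_along(ids)) {
      if (i > 1) {
        rng <- if (!is.null(spacer_after) &&
                   sub("\\(.*", "", ids[i - 1]) == spacer_after)
          spacer_range else inter
        segs <- c(segs, list(linker(rng[1], rng[2])))
      }
      segs <- c(segs, list(blk(ids[i])))
    }
    segs
  }
  two_domain <- function(cina_ids = NULL, ...) {
    core <- if (is.null(cina_ids)) cina(inter = c(10, 16), ...)
            else cina(cina_ids, inter = c(10, 16), ...)
    c(list(linker(10, 16)), mocf(), list(linker(12, 18), blk("i-I"),
      linker(10, 16), blk("i-II"), linker(16, 24)), core,
      list(linker(20, 30)))
  }
  single_domain <- function(nterm = c(9, 15), ...) {
    c(list(linker(nterm[1], nterm[2])), cina(...), list(linker(17, 23)))
  }
  td_act <- list(architecture = "MOCF_CINA", functionality = "active",
                 target_length = 420)
  plans <- list(
    "1.1" = c(list(segments = two_domain(), taxonomy = "Bacteroidetes"), td_act),
    "1.2" = c(list(segments = two_domain(), taxonomy = "Firmicutes"), td_act),
    "1.3" = list(segments = c(list(linker(10, 16)),
                              mocf(m4 = "M-IV(1.3)", inter = c(8, 14)),
                              list(linker(8, 14), blk("i-I(1.3)"),
                                   linker(12, 18))),
                 taxonomy = "Euryarchaeota", architecture = "MOCF_ONLY",
                 functionality = "indeterminate", target_length = 170),
    "2.1" = c(list(segments = two_domain(), taxonomy = "Cyanobacteria"), td_act),
    "2.2.1.1" = c(list(segments = two_domain(),
                       taxonomy = "Gammaproteobacteria"), td_act),
    "2.2.1.2" = list(
      segments = two_domain(cina_ids = c("P-I(2.2.1.2)", "P-II(2.2.1.2)",
                                         "P-IV(2.2.1.2)", "P-VI(2.2.1.2)",
                                         "P-VIII", "P-IX")),
      taxonomy = "Gammaproteobacteria", architecture = "MOCF_CINA",
      functionality = "inactive", target_length = 360),
    "2.2.2.1" = list(segments = single_domain(),
                     taxonomy = "Gammaproteobacteria",
                     architecture = "CINA_ONLY", functionality = "active",
                     target_length = 165),
    "2.2.2.2" = list(
      segments = single_domain(ids = c("P-I", "P-II(2.2.2.2)",
                                       "P-III(2.2.2.2)", "P-IV(2.2.2.2)",
                                       "P-V", "P-VI(2.2.2.2)", "P-VII",
                                       "P-VIII", "P-IX")),
      taxonomy = "Gammaproteobacteria", architecture = "CINA_ONLY",
      functionality = "inactive", target_length = 162),
    "2.2.2.3" = c(list(segments = two_domain(), taxonomy = "Actinobacteria"),
                  td_act),
    "2.2.3.1" = list(segments = single_domain(),
                     taxonomy = "Alphaproteobacteria",
                     architecture = "CINA_ONLY", functionality = "active",
                     target_length = 165),
    "2.2.3.2" = list(segments = single_domain(nterm = c(45, 65)),
                     taxonomy = "Epsilonproteobacteria",
                     architecture = "CINA_NEXT_SHORT", functionality = "active",
                     target_length = 210),
    "2.2.3.3" = list(segments = single_domain(nterm = c(85, 115)),
                     taxonomy = "Gammaproteobacteria",
                     architecture = "CINA_NEXT_LONG", functionality = "active",
                     target_length = 250),
    "2.2.3.4" = list(
      segments = single_domain(ids = c("P-I(2.2.3.4)", "P-II",
                                       "P-III(2.2.3.4)", "P-IV(2.2.3.4)",
                                       "P-V", "P-VI", "P-VII", "P-VIII",
                                       "P-IX"),
                               spacer_after = "P-IV"),
      taxonomy = "Fungi", architecture = "SPLIT_CINA",
      functionality = "inactive", target_length = 215))
  if (!lineage %in% names(plans)) stop("unknown lineage '", lineage, "'")
  plans[[lineage]]
}

# One realization of a pattern: strict positions and documented key-residue
# offsets are emitted from their allowed set and never mutated (catalytic
# residues are conserved by definition of the lineage's functionality
# label); other majority/set/class positions draw from their allowed set and
# are substituted at `rate` from the uniform residue background; wildcards
# are background draws.
realize_pattern <- function(pattern, rate, protected_offsets = integer(0)) {
  vapply(seq_along(pattern$positions), function(k) {
    ps <- pattern$positions[[k]]
    if (ps$kind == "wildcard") return(sample(AA_ALPHABET, 1L))
    r <- if (length(ps$allowed) == 1L) ps$allowed else sample(ps$allowed, 1L)
    if (!ps$strict && !((k - 1L) %in% protected_offsets) &&
        rate > 0 && stats::runif(1) < rate) {
      r <- sample(AA_ALPHABET, 1L)
    }
    r
  }, character(1))
}

#' Generate a labeled panel of synthetic lineage sequences
#'
#' Assembles `n` protein sequences for one named lineage from the block
#' catalog's lineage variant set: linkers are drawn from a uniform residue
#' background with per-gap length ranges calibrated to the family's length
#' classes, strict block positions are never mutated, and all other block
#' positions are substituted at `substitution_rate`. Inactive lineages carry
#' their documented signatures by construction (Y58F+N60D with the DTP block
#' in 2.2.2.2; P-III/P-V/P-VII deletion in 2.2.1.2; the SEAACGG form of P-I
#' plus a >= 40-residue internal spacer in 2.2.3.4).
#'
#' @param lineage One of [lineage_labels()].
#' @param n Number of sequences.
#' @param seed Integer seed (mandatory; same seed, same panel).
#' @param substitution_rate Substitution probability at non-strict block
#'   positions (default 0.05).
#' @param indel_rate Per-linker-residue insertion/deletion probability
#'   (default 0; linker lengths already vary within their ranges).
#' @param catalog Block catalog (defaults to the shipped one).
#' @return A `labeled_panel`: `sequences` (named character), `truth`
#'   (per-sequence lineage/architecture/functionality/taxonomy/length) and
#'   `blocks` (per-sequence 0-based half-open block coordinates, with
#'   wildcard-trimmed core coordinates).
#' @export
simulate_lineage_panel <- function(lineage, n = 20, seed,
                                   substitution_rate = 0.05, indel_rate = 0,
                                   catalog = load_catalog()) {
  stopifnot(!missing(seed), n >= 1,
            substitution_rate >= 0, substitution_rate < 1,
            indel_rate >= 0, indel_rate < 1)
  plan <- lineage_plan(lineage)
  with_seed(seed, {
    seqs <- character(n)
    ids <- sprintf("%s_%02d", gsub(".", "_", lineage, fixed = TRUE), seq_len(n))
    block_rows <- list()
    for (si in seq_len(n)) {
      parts <- character(0)
      pos <- 0L
      for (seg in plan$segments) {
        if (seg$type == "linker") {
          len <- sample(seg$lo:seg$hi, 1L)
          if (indel_rate > 0) {
            len <- max(1L, len + stats::rbinom(1, len, indel_rate) -
                               stats::rbinom(1, len, indel_rate))
          }
          parts <- c(parts, paste(sample(AA_ALPHABET, len, replace = TRUE),
                                  collapse = ""))
          pos <- pos + len
        } else {
          e <- catalog_entry(catalog, seg$entry_id)
          realized <- realize_pattern(e$pattern, substitution_rate,
                                      protected_offsets = e$key_residues$offset)
          m <- length(realized)
          info <- informative_offsets(e$pattern)
          block_rows[[length(block_rows) + 1L]] <- data.frame(
            sequence_id = ids[si], entry_id = e$id, block_id = e$block_id,
            domain_tag = e$domain_tag, start = pos, end = pos + m,
            core_start = pos + min(info), core_end = pos + max(info) + 1L,
            stringsAsFactors = FALSE)
          parts <- c(parts, paste(realized, collapse = ""))
          pos <- pos + m
        }
      }
      seqs[si] <- paste(parts, collapse = "")
    }
    names(seqs) <- ids
    truth <- data.frame(sequence_id = ids, lineage = lineage,
                        architecture = plan$architecture,
                        functionality = plan$functionality,
                        taxonomy = plan$taxonomy,
                        length = nchar(seqs), stringsAsFactors = FALSE)
    structure(list(sequences = seqs, truth = truth,
                   blocks = do.call(rbind, block_rows),
                   lineage = lineage, seed = seed,
                   substitution_rate = substitution_rate,
                   indel_rate = indel_rate,
                   target_length = plan$target_length,
                   plan = plan),
              class = "labeled_panel")
  })
}

#' Generate a multi-lineage labeled panel
#'
#' Concatenates one [simulate_lineage_panel()] per requested lineage, with
#' per-lineage sub-seeds derived from `seed`.
#'
#' @param lineages Lineage labels (default: all thirteen).
#' @param n_per Sequences per lineage.
#' @inheritParams simulate_lineage_panel
#' @return A `labeled_panel` covering all requested lineages.
#' @export
simulate_panel <- function(lineages = lineage_labels(), n_per = 5, seed,
                           substitution_rate = 0.05, indel_rate = 0,
                           catalog = load_catalog()) {
  stopifnot(!missing(seed))
  panels <- lapply(seq_along(lineages), function(i) {
    simulate_lineage_panel(lineages[i], n = n_per,
                           seed = (seed + 101L * i) %% .Machine$integer.max,
                           substitution_rate = substitution_rate,
                           indel_rate = indel_rate, catalog = catalog)
  })
  structure(list(sequences = do.call(c, lapply(panels, `[[`, "sequences")),
                 truth = do.call(rbind, lapply(panels, `[[`, "truth")),
                 blocks = do.call(rbind, lapply(panels, `[[`, "blocks")),
                 lineage = lineages, seed = seed,
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate),
            class = "labeled_panel")
}

#' @export
print.labeled_panel <- function(x, ...) {
  cat(sprintf("<labeled_panel> %d sequences, %d lineage(s), seed %d, substitution rate %.3g\n",
              length(x$sequences), length(unique(x$truth$lineage)), x$seed,
              x$substitution_rate))
  invisible(x)
}

#' Known-truth alignment of a single-lineage panel
#'
#' Because every sequence of a lineage panel shares the same segment plan,
#' the alignment is exact by construction: block columns align one-to-one and
#' each linker is padded on the right with gaps to the panel's longest
#' realization of that linker.
#'
#' @param panel A single-lineage `labeled_panel`.
#' @return List with `alignment` (named character vector of aligned rows) and
#'   `block_columns` (0-based half-open aligned coordinates of every block,
#'   with wildcard-trimmed core coordinates).
#' @export
generate_truth_alignment <- function(panel) {
  stopifnot(inherits(panel, "labeled_panel"))
  if (length(unique(panel$truth$lineage)) != 1L) {
    stop("truth alignments are defined per lineage; got a multi-lineage panel")
  }
  ids <- panel$truth$sequence_id
  n <- length(ids)
  plan <- panel$plan
  # per-sequence segment lengths, recovered from the block coordinate table
  rows <- vector("list", n)
  for (si in seq_len(n)) rows[[si]] <- character(0)
  col_rows <- list()
  seg_ptr <- rep(1L, n)  # current 0-based position per sequence
  aligned_pos <- 0L
  blocks_seen <- 0L
  for (seg in plan$segments) {
    if (seg$type == "block") {
      blocks_seen <- blocks_seen + 1L
      width <- NULL
      for (si in seq_len(n)) {
        b <- panel$blocks[panel$blocks$sequence_id == ids[si], ]
        b <- b[order(b$start), ][blocks_seen, ]
        piece <- substr(panel$sequences[[si]], b$start + 1L, b$end)
        rows[[si]] <- c(rows[[si]], piece)
        width <- b$end - b$start
        if (si == 1L) {
          col_rows[[length(col_rows) + 1L]] <- data.frame(
            entry_id = b$entry_id, block_id = b$block_id,
            start_col = aligned_pos, end_col = aligned_pos + width,
            core_start_col = aligned_pos + (b$core_start - b$start),
            core_end_col = aligned_pos + (b$core_end - b$start),
            stringsAsFactors = FALSE)
        }
        seg_ptr[si] <- seg_ptr[si] + width
      }
      aligned_pos <- aligned_pos + width
    } else {
      # linker: infer each sequence's linker span from the next block start
      # (or sequence end), pad to the maximum
      pieces <- character(n)
      for (si in seq_len(n)) {
        b <- panel$blocks[panel$blocks$sequence_id == ids[si], ]
        b <- b[order(b$start), ]
        to <- if (blocks_seen + 1L <= nrow(b)) b$start[blocks_seen + 1L]
              else nchar(panel$sequences[[si]])
        pieces[si] <- substr(panel$sequences[[si]], seg_ptr[si] + 1L, to)
        seg_ptr[si] <- to
      }
      w <- max(nchar(pieces))
      for (si in seq_len(n)) {
        rows[[si]] <- c(rows[[si]],
                        paste0(pieces[si],
                               strrep("-", w - nchar(pieces[si]))))
      }
      aligned_pos <- aligned_pos + w
    }
  }
  aln <- vapply(rows, paste, character(1), collapse = "")
  names(aln) <- ids
  list(alignment = aln, block_columns = do.call(rbind, col_rows))
}

#' Generate a noisy initial-rate dataset
#'
#' Draws initial rates from the Michaelis-Menten or Hill rate law with
#' multiplicative Gaussian noise: `v_obs = v * (1 + e)`, `e ~ N(0, noise_cv)`.
#'
#' @param model `"mm"` or `"hill"`.
#' @param params For `"mm"`: list with `Km`, `kcat`, `E0` (or `Vmax`).
#'   For `"hill"`: list with `S50`, `nH`, `Vmax`.
#' @param grid Substrate concentrations (same units as `Km`/`S50`).
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param replicates Replicates per concentration.
#' @param seed Integer seed.
#' @return `data.frame` with `conc`, `rate`, `replicate` (a rate table).
#' @export
simulate_rates <- function(model = c("mm", "hill"), params, grid,
                           noise_cv = 0.02, replicates = 3, seed) {
  model <- match.arg(model)
  stopifnot(!missing(seed), all(grid > 0), noise_cv >= 0, replicates >= 1)
  v <- if (model == "mm") {
    Vmax <- if (!is.null(params$Vmax)) params$Vmax else params$kcat * params$E0
    mm_rate(grid, Km = params$Km, kcat = Vmax, E0 = 1)
  } else {
    hill_rate(grid, S50 = params$S50, nH = params$nH, Vmax = params$Vmax)
  }
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(replicates), function(r) {
      eps <- stats::rnorm(length(grid), 0, noise_cv)
      data.frame(conc = grid, rate = v * (1 + eps), replicate = r)
    }))
    rownames(out) <- NULL
    out
  })
}

#' Write a labeled panel to FASTA plus truth TSVs
#'
#' @param panel A `labeled_panel`.
#' @param dir Output directory (created if needed).
#' @param stem File stem (default `"panel"`).
#' @return Named character vector of the files written, invisibly.
#' @export
write_panel <- function(panel, dir, stem = "panel") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(stem, ".fasta"))
  tr <- file.path(dir, paste0(stem, "_truth.tsv"))
  bl <- file.path(dir, paste0(stem, "_blocks.tsv"))
  write_fasta(panel$sequences, fa)
  utils::write.table(panel$truth, tr, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(panel$blocks, bl, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fa, truth = tr, blocks = bl))
}
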