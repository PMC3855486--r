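# Domain-architecture calling, functionality prediction and lineage
# assignment for PncC-family sequences, from block-catalog motif matches.

ARCHITECTURES <- c("CINA_ONLY", "MOCF_CINA", "CINA_NEXT_SHORT",
                   "CINA_NEXT_LONG", "MOCF_ONLY", "SPLIT_CINA", "UNKNOWN")

# Order of the domains along a two-domain enzyme; used to put every block
# slot on one global canonical axis so the chain is selected jointly (a
# chance MocF hit inside the CinA region cannot then displace a true block).
domain_order_offset <- c(MocF = 0, interdomain = 7, CinA = 9)

# Longest chain of block slots in canonical order with non-overlapping,
# increasing coordinates, over all domains jointly. Among equal-length
# chains the highest total match score wins. Returns the selected rows
# (at most one per block slot).
slot_chain <- function(matches) {
  if (nrow(matches) == 0L) return(matches)
  g <- matches$order_index + domain_order_offset[matches$domain_tag]
  m <- matches[order(g, matches$start), , drop = FALSE]
  g <- sort(g)
  n <- nrow(m)
  best_len <- integer(n)
  best_score <- numeric(n)
  prev <- integer(n)
  for (i in seq_len(n)) {
    best_len[i] <- 1L
    best_score[i] <- m$score[i]
    prev[i] <- 0L
    for (j in seq_len(i - 1L)) {
      if (g[j] < g[i] && m$end[j] <= m$start[i]) {
        cand_len <- best_len[j] + 1L
        cand_score <- best_score[j] + m$score[i]
        if (cand_len > best_len[i] ||
            (cand_len == best_len[i] && cand_score > best_score[i])) {
          best_len[i] <- cand_len
          best_score[i] <- cand_score
          prev[i] <- j
        }
      }
    }
  }
  tops <- which(best_len == max(best_len))
  i <- tops[which.max(best_score[tops])]
  path <- integer(0)
  while (i != 0L) { path <- c(i, path); i <- prev[i] }
  m[path, , drop = FALSE]
}

#' Call the domain architecture of a sequence
#'
#' Decides among the family's architectures from catalog block matches: the
#' MocF domain is called present when at least `mocf_min` of its 7 blocks
#' match in canonical order, the CinA domain when at least `cina_min` of its
#' 9 blocks do. A CinA-only sequence is classed by the length of the region
#' upstream of its first CinA block (`<= ext_short` plain single domain,
#' `<= ext_long` short N-terminal extension, beyond that long extension), and
#' called split when an internal spacer of `>= split_gap` residues separates
#' consecutive matched CinA blocks.
#'
#' @param sequence Amino-acid string.
#' @param catalog A `block_catalog`.
#' @param matches Optional precomputed [scan_catalog()] table.
#' @param min_score Match threshold for scanning (default 0.7).
#' @param mocf_min,cina_min Block-count thresholds (defaults 4 of 7, 5 of 9).
#' @param ext_short,ext_long Extension cutoffs in residues (defaults 30, 80).
#' @param split_gap Internal spacer length that signals a split domain
#'   (default 40).
#' @return A `domain_architecture`: `class`, `extension_length`, counts of
#'   chained MocF/CinA blocks, and the selected matches as `evidence`.
#' @export
call_architecture <- function(sequence, catalog = load_catalog(),
                              matches = NULL, min_score = 0.7,
                              mocf_min = 4, cina_min = 5,
                              ext_short = 30, ext_long = 80, split_gap = 40) {
  out <- function(class, ext = NA_integer_, mocf = 0L, cina = 0L,
                  evidence = NULL) {
    structure(list(class = class, extension_length = ext,
                   mocf_blocks = mocf, cina_blocks = cina,
                   evidence = evidence), class = "domain_architecture")
  }
  if (nchar(sequence) < 50) {
    warning("sequence shorter than 50 residues; architecture UNKNOWN")
    return(out("UNKNOWN"))
  }
  if (is.null(matches)) {
    matches <- scan_catalog(sequence, catalog, min_score = min_score)
  }
  chain <- slot_chain(matches)
  chain_m <- chain[chain$domain_tag == "MocF", , drop = FALSE]
  chain_p <- chain[chain$domain_tag == "CinA", , drop = FALSE]
  n_m <- nrow(chain_m)
  n_p <- nrow(chain_p)
  mocf_present <- n_m >= mocf_min
  cina_present <- n_p >= cina_min
  evidence <- rbind(chain_m, chain_p)
  if (mocf_present && cina_present) {
    # require the MocF region upstream of the CinA region
    if (max(chain_m$end) <= min(chain_p$start)) {
      return(out("MOCF_CINA", ext = min(chain_p$start), mocf = n_m,
                 cina = n_p, evidence = evidence))
    }
    return(out("UNKNOWN", mocf = n_m, cina = n_p, evidence = evidence))
  }
  if (cina_present) {
    ext <- min(chain_p$start)
    gaps <- chain_p$start[-1] - chain_p$end[-nrow(chain_p)]
    if (length(gaps) > 0 && max(gaps) >= split_gap) {
      return(out("SPLIT_CINA", ext = ext, cina = n_p, evidence = evidence))
    }
    cls <- if (ext <= ext_short) "CINA_ONLY"
           else if (ext <= ext_long) "CINA_NEXT_SHORT"
           else "CINA_NEXT_LONG"
    return(out(cls, ext = ext, cina = n_p, evidence = evidence))
  }
  if (mocf_present) {
    return(out("MOCF_ONLY", mocf = n_m, evidence = evidence))
  }
  out("UNKNOWN", mocf = n_m, cina = n_p, evidence = evidence)
}

#' @export
print.domain_architecture <- function(x, ...) {
  cat(sprintf("<domain_architecture> %s (MocF blocks: %d, CinA blocks: %d, N-extension: %s)\n",
              x$class, x$mocf_blocks, x$cina_blocks,
              ifelse(is.na(x$extension_length), "-", x$extension_length)))
  invisible(x)
}

# Keep only matches that are positionally consistent with the selected
# block chain: a match for slot order o must lie after every chained block
# of lower order and before every chained block of higher order. Chance
# motif hits far from their canonical position would otherwise defeat the
# absence conditions of the inactivating signatures.
chain_consistent_matches <- function(matches, chain) {
  if (nrow(matches) == 0L || is.null(chain) || nrow(chain) == 0L) {
    return(matches)
  }
  keep <- vapply(seq_len(nrow(matches)), function(i) {
    oi <- matches$order_index[i]
    prev_end <- suppressWarnings(max(chain$end[chain$order_index < oi]))
    next_start <- suppressWarnings(min(chain$start[chain$order_index > oi]))
    matches$start[i] >= max(prev_end, -Inf) &&
      matches$end[i] <= min(next_start, Inf)
  }, logical(1))
  matches[keep, , drop = FALSE]
}

# Checklist blocks and their key residues come from the canonical catalog
# entries; an entry contributes one check per key residue.
functional_checklist <- function(catalog) {
  ids <- c("P-I", "P-II", "P-III", "P-VI", "P-VII", "P-VIII")
  do.call(rbind, lapply(ids, function(id) {
    e <- catalog_entry(catalog, id)
    kr <- e$key_residues
    kr$entry_id <- id
    kr
  }))
}

#' Predict deamidase functionality from CinA block matches
#'
#' Checks the ten active-site residues (single-domain reference numbering
#' S31, G46, S48, Y58, N60, K63, S/T105, G106, G120, R145) at their
#' pattern-relative offsets inside the matched canonical CinA blocks, and
#' evaluates the documented inactivating signatures. All checks passing
#' yields `active`; any fired signature yields `inactive`; anything else
#' (missing blocks, ambiguous `X` residues) is `indeterminate`.
#'
#' @inheritParams call_architecture
#' @param architecture Optional precomputed [call_architecture()] result.
#' @return A `functional_call`: `verdict`, per-residue `checklist`
#'   (pass/fail/absent) and `signatures_fired`.
#' @export
call_functionality <- function(sequence, catalog = load_catalog(),
                               matches = NULL, min_score = 0.7,
                               architecture = NULL) {
  if (is.null(matches)) {
    matches <- scan_catalog(sequence, catalog, min_score = min_score)
  }
  if (is.null(architecture)) {
    architecture <- call_architecture(sequence, catalog, matches = matches,
                                      min_score = min_score)
  }
  res <- strsplit(toupper(sequence), "")[[1]]
  if (!architecture$class %in% c("CINA_ONLY", "MOCF_CINA", "CINA_NEXT_SHORT",
                                 "CINA_NEXT_LONG", "SPLIT_CINA")) {
    return(structure(list(verdict = "indeterminate",
                          reason = "no CinA domain",
                          checklist = NULL, signatures_fired = character(0)),
                     class = "functional_call"))
  }
  cina_chain <- if (!is.null(architecture$evidence)) {
    architecture$evidence[architecture$evidence$domain_tag == "CinA", ,
                          drop = FALSE]
  } else NULL
  matches <- chain_consistent_matches(
    matches[matches$domain_tag == "CinA", , drop = FALSE], cina_chain)
  chk <- functional_checklist(catalog)
  chk$residue <- NA_character_
  chk$result <- "absent"
  # a checklist block whose match was lost to substitutions is still located
  # by a relaxed scan between its chained neighbors, so its key residues can
  # be checked at the homologous offsets
  locate_relaxed <- function(entry_id) {
    if (is.null(cina_chain) || nrow(cina_chain) == 0L) return(NULL)
    e <- catalog_entry(catalog, entry_id)
    oi <- e$order_index
    mlen <- pattern_length(e$pattern)
    prev_end <- suppressWarnings(max(cina_chain$end[cina_chain$order_index < oi]))
    next_start <- suppressWarnings(min(cina_chain$start[cina_chain$order_index > oi]))
    lo <- if (is.finite(prev_end)) prev_end else 0
    hi <- (if (is.finite(next_start)) next_start else nchar(sequence)) - mlen + 1
    if (hi <= lo) return(NULL)
    hit <- scan_motif(sequence, e$pattern, min_score = 1e-9,
                      window = c(lo, hi), enforce_strict = FALSE)
    if (nrow(hit) == 0L) return(NULL)
    hit[which.max(hit$score), , drop = FALSE]
  }
  located <- list()
  for (i in seq_len(nrow(chk))) {
    id <- chk$entry_id[i]
    hit <- matches[matches$entry_id == id, , drop = FALSE]
    if (nrow(hit) > 0L) {
      hit <- hit[which.max(hit$score), , drop = FALSE]
    } else {
      if (is.null(located[[id]])) located[[id]] <- list(locate_relaxed(id))
      hit <- located[[id]][[1]]
      if (is.null(hit)) next
    }
    aa <- res[hit$start + chk$offset[i] + 1L]
    chk$residue[i] <- aa
    if (aa == "X") { chk$result[i] <- "absent"; next }
    allowed <- strsplit(chk$allowed[i], "")[[1]]
    chk$result[i] <- if (aa %in% allowed) "pass" else "fail"
  }
  fired <- Filter(function(sig) sig$predicate(matches),
                  inactivating_signatures())
  fired_ids <- vapply(fired, `[[`, character(1), "id")
  verdict <- if (length(fired_ids) > 0) "inactive"
             else if (all(chk$result == "pass")) "active"
             else "indeterminate"
  stopifnot(!(verdict == "active" && length(fired_ids) > 0))
  structure(list(verdict = verdict, reason = NA_character_,
                 checklist = chk, signatures_fired = fired_ids),
            class = "functional_call")
}

#' @export
print.functional_call <- function(x, ...) {
  n_pass <- if (is.null(x$checklist)) 0 else sum(x$checklist$result == "pass")
  n_tot <- if (is.null(x$checklist)) 0 else nrow(x$checklist)
  cat(sprintf("<functional_call> %s (%d/%d residue checks pass%s)\n",
              x$verdict, n_pass, n_tot,
              if (length(x$signatures_fired)) paste0("; signatures: ",
                paste(x$signatures_fired, collapse = ", ")) else ""))
  invisible(x)
}

# Taxonomy-hint preference per ambiguous candidate set. The family's
# lineages partly track phyla: hints never override the architecture-driven
# part of the decision table, they only break fingerprint ties.
hint_preference <- function(hint, candidates) {
  if (is.null(hint) || is.na(hint)) return(NA_character_)
  maps <- list(
    mocf_cina = c(Firmicutes = "1.2", Cyanobacteria = "2.1",
                  Aquificae = "2.1", Fusobacteria = "2.1", Chlorobi = "2.1",
                  Actinobacteria = "2.2.2.3", Mycobacterium = "2.2.2.3",
                  Bacteroidetes = "1.1", Spirochaetes = "1.1",
                  Thermotogae = "1.1", Proteobacteria = "1.1",
                  Gammaproteobacteria = "2.2.1.1"),
    cina_only = c(Alphaproteobacteria = "2.2.3.1",
                  Gammaproteobacteria = "2.2.2.1"))
  for (map in maps) {
    if (hint %in% names(map) && map[[hint]] %in% candidates) {
      return(map[[hint]])
    }
  }
  NA_character_
}

# Fraction of shared 3-mers (Jaccard) -- cheap proxy for placement next to a
# reference exemplar.
kmer_similarity <- function(a, b, k = 3) {
  km <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1), k:n))
  }
  ka <- km(a); kb <- km(b)
  if (length(ka) == 0 || length(kb) == 0) return(0)
  length(intersect(ka, kb)) / length(union(ka, kb))
}

#' Assign a lineage label
#'
#' Applies the family's decision table: architecture and functionality pin
#' most lineages directly (MocF-only is the archaeal lineage 1.3, inactive
#' two-domain 2.2.1.2, inactive single-domain 2.2.2.2, short/long extension
#' 2.2.3.2/2.2.3.3, split 2.2.3.4). The remaining active two-domain and
#' single-domain sequences are scored against lineage-specific fingerprint
#' variants; ties are broken by the taxonomy hint, then by the most similar
#' reference exemplar, else the sequence is reported `unassigned`.
#'
#' @param architecture A [call_architecture()] result.
#' @param functionality A [call_functionality()] result.
#' @param matches [scan_catalog()] table for the sequence.
#' @param catalog A `block_catalog`.
#' @param taxonomy_hint Optional phylum/class hint for the sequence.
#' @param references Optional reference `labeled_panel` of exemplar
#'   sequences used for nearest-exemplar tie-breaking.
#' @param sequence The sequence (needed for exemplar comparison only).
#' @return List with `lineage`, `confidence` (margin between the two best
#'   candidates, in [0, 1]), `candidates` and `hint_used`.
#' @export
assign_lineage <- function(architecture, functionality, matches,
                           catalog = load_catalog(), taxonomy_hint = NULL,
                           references = NULL, sequence = NULL) {
  fixed <- function(lab) list(lineage = lab, confidence = 1,
                              candidates = lab, hint_used = FALSE)
  cls <- architecture$class
  verdict <- functionality$verdict
  if (cls == "UNKNOWN") {
    return(list(lineage = "unassigned", confidence = 0,
                candidates = character(0), hint_used = FALSE))
  }
  if (cls == "MOCF_ONLY") return(fixed("1.3"))
  if (cls == "MOCF_CINA" && verdict == "inactive") return(fixed("2.2.1.2"))
  if (cls %in% c("CINA_ONLY") && verdict == "inactive") return(fixed("2.2.2.2"))
  if (cls == "CINA_NEXT_SHORT") return(fixed("2.2.3.2"))
  if (cls == "CINA_NEXT_LONG") return(fixed("2.2.3.3"))
  if (cls == "SPLIT_CINA") return(fixed("2.2.3.4"))
  candidates <- if (cls == "MOCF_CINA") {
    c("1.1", "1.2", "2.1", "2.2.1.1", "2.2.2.3")
  } else {
    c("2.2.2.1", "2.2.3.1")
  }
  # fingerprint score: matched lineage-variant entries vote for their lineage
  scores <- stats::setNames(numeric(length(candidates)), candidates)
  var_hits <- matches[!is.na(matches$lineage_tag), , drop = FALSE]
  for (lt in var_hits$lineage_tag) {
    if (lt %in% candidates) scores[lt] <- scores[lt] + 1
  }
  top <- sort(scores, decreasing = TRUE)
  if (top[1] > top[2]) {
    return(list(lineage = names(top)[1],
                confidence = min(1, top[1] - top[2]),
                candidates = candidates, hint_used = FALSE))
  }
  tied <- names(scores)[scores == top[1]]
  pref <- hint_preference(taxonomy_hint, tied)
  if (!is.na(pref)) {
    return(list(lineage = pref, confidence = 0.5, candidates = tied,
                hint_used = TRUE))
  }
  if (!is.null(references) && !is.null(sequence)) {
    ref_truth <- references$truth
    keep <- ref_truth$lineage %in% tied
    if (any(keep)) {
      sims <- vapply(ref_truth$sequence_id[keep], function(id)
        kmer_similarity(sequence, references$sequences[[id]]), numeric(1))
      best <- ref_truth$lineage[keep][which.max(sims)]
      s <- sort(sims, decreasing = TRUE)
      conf <- if (length(s) > 1) min(1, max(0, s[1] - s[2])) else 0.25
      return(list(lineage = best, confidence = conf, candidates = tied,
                  hint_used = FALSE))
    }
  }
  list(lineage = "unassigned", confidence = 0, candidates = tied,
       hint_used = FALSE)
}

#' Classify a set of sequences end to end
#'
#' Scans each sequence against the block catalog, calls architecture and
#' functionality, and assigns a lineage. One row per sequence.
#'
#' @param sequences Named character vector of protein sequences.
#' @param catalog A `block_catalog`.
#' @param taxonomy Optional named vector mapping sequence id to a
#'   phylum/class hint.
#' @param references Optional reference `labeled_panel` for tie-breaking.
#' @param min_score Match threshold (default 0.7).
#' @param ... Passed to [call_architecture()].
#' @return `data.frame` with one classification record per sequence:
#'   id, length, architecture, extension length, block counts, functionality
#'   verdict, fired signatures, lineage, confidence, and whether a taxonomy
#'   hint was used. Per-sequence details (evidence, checklist) are attached
#'   as the `"details"` attribute.
#' @export
classify_sequences <- function(sequences, catalog = load_catalog(),
                               taxonomy = NULL, references = NULL,
                               min_score = 0.7, ...) {
  stopifnot(length(sequences) > 0, !is.null(names(sequences)))
  details <- vector("list", length(sequences))
  names(details) <- names(sequences)
  rows <- lapply(names(sequences), function(id) {
    seq <- sequences[[id]]
    matches <- scan_catalog(seq, catalog, min_score = min_score,
                            sequence_id = id)
    arch <- call_architecture(seq, catalog, matches = matches,
                              min_score = min_score, ...)
    func <- call_functionality(seq, catalog, matches = matches,
                               min_score = min_score, architecture = arch)
    hint <- if (!is.null(taxonomy) && id %in% names(taxonomy))
      taxonomy[[id]] else NULL
    lin <- assign_lineage(arch, func, matches, catalog,
                          taxonomy_hint = hint, references = references,
                          sequence = seq)
    details[[id]] <<- list(matches = matches, architecture = arch,
                           functionality = func, lineage = lin)
    data.frame(sequence_id = id, length = nchar(seq),
               architecture = arch$class,
               extension_length = arch$extension_length,
               mocf_blocks = arch$mocf_blocks,
               cina_blocks = arch$cina_blocks,
               functionality = func$verdict,
               signatures = paste(func$signatures_fired, collapse = ","),
               lineage = lin$lineage, confidence = lin$confidence,
               taxonomy_hint_used = lin$hint_used,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "details") <- details
  out
}

#' Write a classification report
#'
#' @param records Table from [classify_sequences()].
#' @param tsv,json Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_classification <- function(records, tsv = NULL, json = NULL) {
  if (!is.null(tsv)) {
    utils::write.table(records, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(records, json, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(c(tsv = tsv, json = json))
}
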