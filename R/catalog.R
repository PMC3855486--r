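# Conserved-block catalog for the PncC / NMN-deamidase family:
# 7 MocF blocks (M-I..M-VII), 2 interdomain blocks (i-I, i-II), 9 CinA
# blocks (P-I..P-IX), per-lineage variants, and active-site key residues.

#' Named lineage labels of the PncC family
#'
#' The thirteen terminal lineage labels of the family's phylogeny. Lineages
#' 1.x descend from the MocF-carrying origin; 2.x from the second origin
#' holding all biochemically characterized deamidases.
#'
#' @return Character vector of lineage labels.
#' @export
lineage_labels <- function() {
  c("1.1", "1.2", "1.3", "2.1",
    "2.2.1.1", "2.2.1.2",
    "2.2.2.1", "2.2.2.2", "2.2.2.3",
    "2.2.3.1", "2.2.3.2", "2.2.3.3", "2.2.3.4")
}

parse_key_residues <- function(txt) {
  if (is.na(txt) || !nzchar(trimws(txt))) {
    return(data.frame(offset = integer(), allowed = character(),
                      role = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(trimws(txt), ";", fixed = TRUE)[[1]]
  fields <- strsplit(parts, ":", fixed = TRUE)
  data.frame(offset = vapply(fields, function(f) as.integer(f[1]), integer(1)),
             allowed = vapply(fields, `[`, character(1), 2),
             role = vapply(fields, `[`, character(1), 3),
             stringsAsFactors = FALSE)
}

#' Load the conserved-block catalog
#'
#' Reads the shipped catalog of block-consensus patterns: the seven MocF
#' blocks, two interdomain blocks and nine CinA blocks, plus per-lineage
#' variants (archaeal M-IV/i-I fingerprints; inactive-lineage replacement
#' blocks) and pattern-relative key-residue annotations.
#'
#' @param path Catalog TSV; defaults to the copy shipped with the package.
#' @return A `block_catalog`: list of catalog entries, each holding a parsed
#'   `motif_pattern`, its domain tag (`MocF`, `interdomain`, `CinA`),
#'   canonical order index, optional lineage tag and key-residue table.
#' @export
load_catalog <- function(path = system.file("extdata", "block_catalog.tsv",
                                            package = "pncctools")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  if (anyDuplicated(tab$id)) {
    stop("catalog load error: duplicate entry id(s): ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  }
  entries <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    pat <- parse_pattern(row$pattern, row$id,
                         lineage_tag = if (is.na(row$lineage_tag)) NA_character_
                                       else trimws(row$lineage_tag))
    kr <- parse_key_residues(row$key_residues)
    if (nrow(kr) > 0 && any(kr$offset >= pattern_length(pat))) {
      stop("catalog load error: key residue offset beyond pattern in ", row$id)
    }
    structure(list(id = row$id, block_id = row$block_id,
                   domain_tag = row$domain_tag,
                   order_index = row$order_index,
                   lineage_tag = if (is.na(row$lineage_tag)) NA_character_
                                 else trimws(row$lineage_tag),
                   variant_of = if (is.na(row$variant_of) ||
                                    !nzchar(trimws(row$variant_of))) NA_character_
                                else trimws(row$variant_of),
                   pattern = pat, key_residues = kr, note = row$note),
              class = "catalog_entry")
  })
  names(entries) <- tab$id
  structure(list(entries = entries), class = "block_catalog")
}

#' @export
print.block_catalog <- function(x, ...) {
  tags <- vapply(x$entries, `[[`, character(1), "domain_tag")
  canon <- vapply(x$entries, function(e) is.na(e$lineage_tag), logical(1))
  cat(sprintf("<block_catalog> %d entries (%d canonical: %d MocF, %d interdomain, %d CinA; %d lineage variants)\n",
              length(x$entries), sum(canon),
              sum(canon & tags == "MocF"), sum(canon & tags == "interdomain"),
              sum(canon & tags == "CinA"), sum(!canon)))
  invisible(x)
}

catalog_entry <- function(catalog, id) {
  e <- catalog$entries[[id]]
  if (is.null(e)) stop("no catalog entry '", id, "'")
  e
}

# Canonical entries of one domain, in canonical order.
canonical_entries <- function(catalog, domain_tag) {
  ent <- Filter(function(e) e$domain_tag == domain_tag && is.na(e$lineage_tag),
                catalog$entries)
  ent[order(vapply(ent, `[[`, numeric(1), "order_index"))]
}

# All entries (canonical + variants) for one block slot.
slot_entries <- function(catalog, block_id) {
  Filter(function(e) e$block_id == block_id, catalog$entries)
}

#' Scan a sequence against every catalog entry
#'
#' @param sequence Amino-acid string.
#' @param catalog A `block_catalog`.
#' @param min_score Passed to [scan_motif()].
#' @param sequence_id Identifier recorded in the result.
#' @return `data.frame` of motif matches with catalog annotation columns
#'   `entry_id`, `block_id`, `domain_tag`, `order_index`, `lineage_tag`.
#' @export
scan_catalog <- function(sequence, catalog, min_score = 0.7,
                         sequence_id = "seq") {
  stopifnot(inherits(catalog, "block_catalog"))
  out <- lapply(catalog$entries, function(e) {
    m <- scan_motif(sequence, e$pattern, min_score = min_score,
                    sequence_id = sequence_id)
    if (nrow(m) == 0L) return(NULL)
    m$entry_id <- e$id
    m$block_id <- e$block_id
    m$domain_tag <- e$domain_tag
    m$order_index <- e$order_index
    m$lineage_tag <- e$lineage_tag
    m
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(pattern_id = character(), sequence_id = character(),
                      start = integer(), end = integer(), score = numeric(),
                      matched_subsequence = character(), entry_id = character(),
                      block_id = character(), domain_tag = character(),
                      order_index = numeric(), lineage_tag = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out[order(out$start, -out$score), , drop = FALSE]
}

#' Active-site key residues in a reference numbering
#'
#' Positions of the residues forming the deamidase (CinA) or pyrophosphatase
#' (MocF) site in one of the three reference numbering systems: the
#' crystallized single-domain enzyme (2A9S), the crystallized MocF-only
#' enzyme (3KBQ), or the two-domain O. iheyensis enzyme (OiPncC).
#'
#' @param reference One of `"2A9S"`, `"3KBQ"`, `"OiPncC"`.
#' @return `data.frame` with `position`, `residue`, `role`.
#' @export
key_residue_map <- function(reference = c("2A9S", "3KBQ", "OiPncC")) {
  reference <- match.arg(reference)
  maps <- list(
    `2A9S` = data.frame(
      position = c(31, 46, 48, 58, 60, 63, 105, 106, 120, 145),
      residue = c("S", "G", "S", "Y", "N", "K", "S/T", "G", "G", "R"),
      role = c("NMN amide contact (P-I)", "cavity wall (P-II)",
               "cavity wall (P-II)", "catalytic (P-III)",
               "catalytic (P-III)", "catalytic (P-III)",
               "NMN amino contact (P-VI)", "NMN amino contact (P-VI)",
               "pocket rim (P-VII)", "phosphate binding (P-VIII)"),
      stringsAsFactors = FALSE),
    OiPncC = data.frame(
      position = c(281, 282, 284, 286, 299, 309, 314, 356, 357, 394),
      residue = c("E", "S", "T", "G", "S", "Y", "K", "S/T", "G", "R"),
      role = c("active site (P-I)", "active site (P-I)", "active site (P-I)",
               "active site (P-I)", "active site (P-II)", "catalytic (P-III)",
               "catalytic (P-III)", "active site (P-VI)", "active site (P-VI)",
               "active site (P-VIII)"),
      stringsAsFactors = FALSE),
    `3KBQ` = data.frame(
      position = c(44, 75, 114, 115, 148, 149),
      residue = c("D", "D", "K", "M", "P", "G"),
      role = c("adenosine binding (M-II)", "pyrophosphate binding (M-III)",
               "substrate surface (M-IV)", "substrate surface (M-IV)",
               "ribose binding (M-VI)", "ribose binding (M-VI)"),
      stringsAsFactors = FALSE))
  maps[[reference]]
}

has_entry_match <- function(matches, entry_id) {
  any(matches$entry_id == entry_id)
}

#' Documented inactivating signatures
#'
#' The block-level substitution/deletion combinations that predict loss of
#' NMN deamidase activity: the Y58F+N60D double substitution with the DTP
#' replacement of P-II (YdeJ-like single-domain enzymes, lineage 2.2.2.2),
#' the loss of blocks P-III/P-V/P-VII with a degenerate P-II (YfaY-like
#' two-domain enzymes, lineage 2.2.1.2), and the alanine substitution at the
#' S31-homologous position of P-I (fungal split enzymes, lineage 2.2.3.4).
#'
#' @return List of signatures; each has `id`, `lineage`, `description` and a
#'   `predicate` taking a [scan_catalog()] match table.
#' @export
inactivating_signatures <- function() {
  list(
    structure(list(
      id = "YdeJ-like", lineage = "2.2.2.2",
      description = "Y58F + N60D substitutions in block P-III; P-II replaced by the DTP block",
      predicate = function(matches) {
        !has_entry_match(matches, "P-III") &&
          has_entry_match(matches, "P-III(2.2.2.2)") &&
          !has_entry_match(matches, "P-II") &&
          has_entry_match(matches, "P-II(2.2.2.2)")
      }), class = "inactivating_signature"),
    structure(list(
      id = "YfaY-like", lineage = "2.2.1.2",
      description = "blocks P-III, P-V and P-VII deleted; P-II present only as its degenerate variant",
      predicate = function(matches) {
        piii_any <- any(matches$block_id == "P-III")
        !piii_any &&
          !has_entry_match(matches, "P-V") &&
          !has_entry_match(matches, "P-VII") &&
          !has_entry_match(matches, "P-II") &&
          has_entry_match(matches, "P-II(2.2.1.2)")
      }), class = "inactivating_signature"),
    structure(list(
      id = "fungal-split", lineage = "2.2.3.4",
      description = "alanine at the S31-homologous position of P-I (SEAACGG form)",
      predicate = function(matches) {
        !has_entry_match(matches, "P-I") &&
          has_entry_match(matches, "P-I(2.2.3.4)")
      }), class = "inactivating_signature")
  )
}

#' Export the catalog as JSON
#'
#' @param catalog A `block_catalog`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_catalog_json <- function(catalog, path) {
  stopifnot(inherits(catalog, "block_catalog"))
  lst <- lapply(catalog$entries, function(e) {
    list(id = e$id, block_id = e$block_id, domain_tag = e$domain_tag,
         order_index = e$order_index, lineage_tag = e$lineage_tag,
         variant_of = e$variant_of, pattern = render_pattern(e$pattern),
         key_residues = e$key_residues, note = e$note)
  })
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}
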