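# FASTA and table I/O. Parsing is delegated to Biostrings; these wrappers
# add the family pipeline's validity checks (unique ids, residue alphabet,
# equal-length aligned rows).

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of sequences. Duplicate ids are an error;
#'   characters outside the amino-acid alphabet (plus `X` and `-`) raise a
#'   warning; an empty file returns an empty vector with a warning.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) {
    warning("no FASTA records in ", path)
    return(stats::setNames(character(0), character(0)))
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  bad <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "X*-]"), seqs)
  if (any(bad)) {
    warning("non-amino-acid characters in record(s): ",
            paste(ids[bad], collapse = ", "))
  }
  seqs
}

#' Write protein sequences to FASTA
#'
#' Deterministic, line-wrapped output; `read_fasta(write_fasta(x))`
#' reproduces `x` exactly.
#'
#' @param sequences Named character vector.
#' @param path Output file.
#' @param wrap Line width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, wrap = 60) {
  stopifnot(!is.null(names(sequences)), all(nzchar(names(sequences))))
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = wrap)
  invisible(path)
}

#' Read an aligned FASTA file
#'
#' Like [read_fasta()] but enforces equal row lengths.
#'
#' @param path Aligned FASTA file.
#' @return Named character vector of aligned rows.
#' @export
read_aligned_fasta <- function(path) {
  seqs <- read_fasta(path)
  lens <- nchar(seqs)
  if (length(seqs) > 0 && length(unique(lens)) != 1L) {
    off <- names(seqs)[lens != lens[1]][1]
    stop("ragged alignment in ", path, ": record '", off,
         "' has length ", nchar(seqs[[off]]), " (expected ", lens[1], ")")
  }
  seqs
}

#' Write an alignment as aligned FASTA
#'
#' @param alignment Named character vector of equal-length rows.
#' @param path Output file.
#' @param wrap Line width.
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(alignment, path, wrap = 60) {
  if (length(unique(nchar(alignment))) > 1L) {
    stop("aligned rows have unequal lengths")
  }
  write_fasta(alignment, path, wrap = wrap)
}

#' Read an initial-rate table from TSV
#'
#' @param path TSV with columns `conc`, `rate` and optional `replicate`.
#' @return Validated rate `data.frame`.
#' @export
read_rate_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_rate_table(tab)
}

#' Write an initial-rate table as TSV
#'
#' @param rates Rate `data.frame` (`conc`, `rate`, optional `replicate`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(rates, path) {
  utils::write.table(rates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a kinetics fit report as JSON
#'
#' @param fit An `mm_fit` or `hill_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  keep <- setdiff(names(fit), "fit")
  lst <- fit[keep]
  lst$model <- if (inherits(fit, "mm_fit")) "michaelis-menten" else "hill"
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
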