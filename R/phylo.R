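# Pairwise alignment (Needleman-Wunsch / Smith-Waterman with affine gaps),
# alignment distances, neighbor-joining tree construction and bootstrap
# supports. The agglomeration and the dynamic programs are implemented here;
# ape supplies only the tree container and Newick serialization.

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Optimal pairwise alignment with affine gap penalties
#'
#' Gotoh dynamic program under score `sum(substitutions) - (gap_open +
#' gap_extend * k)` per gap of length `k`, with BLAST-comparable defaults
#' (BLOSUM62, open 11, extend 1). Traceback ties prefer the diagonal, then
#' the gap in the second sequence, then the gap in the first, so results are
#' deterministic.
#'
#' @param a,b Protein sequences (non-empty strings).
#' @param mode `"global"` (Needleman-Wunsch) or `"local"`
#'   (Smith-Waterman).
#' @param substitution_matrix Scoring matrix; default BLOSUM62.
#' @param gap_open,gap_extend Affine gap parameters (positive costs).
#' @return List with `alignment` (two gapped strings), `score`, `identity`
#'   (identical columns over aligned columns; for local alignments over the
#'   local span) and `mode`.
#' @export
pairwise_align <- function(a, b, mode = c("global", "local"),
                           substitution_matrix = NULL,
                           gap_open = 11, gap_extend = 1) {
  mode <- match.arg(mode)
  stopifnot(nzchar(a), nzchar(b), gap_open >= 0, gap_extend > 0)
  S <- if (is.null(substitution_matrix)) blosum62() else substitution_matrix
  A <- strsplit(toupper(a), "")[[1]]
  B <- strsplit(toupper(b), "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  local <- mode == "local"
  go <- gap_open + gap_extend       # cost of a gap of length 1
  ge <- gap_extend
  M <- matrix(NEG, n + 1, m + 1)    # match/mismatch state
  X <- matrix(NEG, n + 1, m + 1)    # gap in b (consume A)
  Y <- matrix(NEG, n + 1, m + 1)    # gap in a (consume B)
  M[1, 1] <- 0
  if (!local) {
    for (i in 2:(n + 1)) X[i, 1] <- -go - ge * (i - 2)
    for (j in 2:(m + 1)) Y[1, j] <- -go - ge * (j - 2)
  } else {
    M[, 1] <- 0; M[1, ] <- 0
  }
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- S[A[i - 1], B[j - 1]]
      best_prev <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      M[i, j] <- best_prev + s
      if (local && M[i, j] < 0) M[i, j] <- 0
      X[i, j] <- max(M[i - 1, j] - go, X[i - 1, j] - ge)
      Y[i, j] <- max(M[i, j - 1] - go, Y[i, j - 1] - ge)
    }
  }
  # terminal cell
  if (local) {
    sc <- max(M)
    idx <- which(M == sc, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]  # deterministic
    i <- idx[1]; j <- idx[2]; state <- "M"
  } else {
    i <- n + 1; j <- m + 1
    sc <- max(M[i, j], X[i, j], Y[i, j])
    state <- c("M", "X", "Y")[which.max(c(M[i, j], X[i, j], Y[i, j]))]
  }
  ra <- character(0); rb <- character(0)
  repeat {
    if (local && state == "M" && M[i, j] == 0) break
    if (!local && i == 1 && j == 1) break
    if (state == "M") {
      s <- S[A[i - 1], B[j - 1]]
      ra <- c(A[i - 1], ra); rb <- c(B[j - 1], rb)
      prevs <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      target <- M[i, j] - s
      state <- if (local && all(prevs < target)) "M"  # started from 0
               else c("M", "X", "Y")[which(abs(prevs - target) < 1e-9)[1]]
      i <- i - 1; j <- j - 1
      if (local && i >= 1 && j >= 1 && state == "M" &&
          M[i, j] == 0 && (i == 1 || j == 1)) break
    } else if (state == "X") {
      ra <- c(A[i - 1], ra); rb <- c("-", rb)
      state <- if (abs(M[i - 1, j] - go - X[i, j]) < 1e-9) "M" else "X"
      i <- i - 1
    } else {
      ra <- c("-", ra); rb <- c(B[j - 1], rb)
      state <- if (abs(M[i, j - 1] - go - Y[i, j]) < 1e-9) "M" else "Y"
      j <- j - 1
    }
  }
  ncol_al <- length(ra)
  ident <- if (ncol_al == 0) 0 else sum(ra == rb & ra != "-") / ncol_al
  list(alignment = c(a = paste(ra, collapse = ""),
                     b = paste(rb, collapse = "")),
       score = unname(sc), identity = ident, mode = mode)
}

#' Pairwise distance matrix from a multiple alignment
#'
#' p-distance (mismatches over compared columns, pairwise gap columns
#' excluded) or its Poisson correction `d = -ln(1 - p)`.
#'
#' @param alignment Named character vector of aligned sequences, or matrix.
#' @param model `"p"` or `"poisson"`.
#' @return Symmetric numeric matrix with zero diagonal, taxa as dimnames.
#' @export
msa_distance <- function(alignment, model = c("p", "poisson")) {
  model <- match.arg(model)
  m <- alignment_matrix(alignment)
  n <- nrow(m)
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("t", seq_len(n))
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(ok)) stop("no comparable columns between ", ids[i], " and ", ids[j])
      p <- mean(m[i, ok] != m[j, ok])
      d <- if (model == "p") p else {
        if (p >= 1) stop("poisson distance undefined (p = 1) for pair ",
                         ids[i], " / ", ids[j])
        -log(1 - p)
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration: at each step the pair minimizing
#' `Q(i,j) = (m - 2) d(i,j) - r_i - r_j` is joined, with the standard
#' branch-length formulas; ties pick the lowest-index pair. The final three
#' nodes are resolved by the three-point formulas, giving an unrooted tree.
#' On an additive matrix the tree's path-length matrix reproduces the input
#' exactly. Negative branch-length estimates are clamped to 0 and flagged in
#' the `"clamped"` attribute.
#'
#' @param dm Symmetric distance matrix with taxa dimnames (>= 3 taxa).
#' @return An [ape::ape-package] `phylo` tree (unrooted).
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3) stop("neighbor joining needs at least 3 taxa")
  if (!isSymmetric(unname(dm), tol = 1e-8)) {
    stop("distance matrix must be symmetric")
  }
  taxa <- rownames(dm)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(dm)))
  n <- length(taxa)
  # nodes: 1..n tips; children bookkeeping for final phylo assembly
  children <- vector("list", n)       # grows as internal nodes are created
  active <- seq_len(n)
  D <- dm
  rownames(D) <- colnames(D) <- NULL
  node_of <- seq_len(n)               # node id per active row
  clamped <- FALSE
  cl <- function(x) { if (x < 0) { clamped <<- TRUE; 0 } else x }
  while (length(node_of) > 3) {
    m <- length(node_of)
    r <- rowSums(D)
    best <- c(NA, NA); bestq <- Inf
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        q <- (m - 2) * D[i, j] - r[i] - r[j]
        if (q < bestq - 1e-12) { bestq <- q; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    new_id <- length(children) + 1L
    children[[new_id]] <- list(list(node = node_of[i], length = cl(bi)),
                               list(node = node_of[j], length = cl(bj)))
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    node_of <- c(node_of[keep], new_id)
  }
  # resolve the last three nodes around one central vertex
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  root_id <- length(children) + 1L
  children[[root_id]] <- list(list(node = node_of[1], length = cl(b1)),
                              list(node = node_of[2], length = cl(b2)),
                              list(node = node_of[3], length = cl(b3)))
  # assemble an ape phylo: tips 1..n, internals numbered in preorder from root
  n_internal <- sum(!vapply(children, is.null, logical(1)))
  edge <- matrix(0L, 0, 2)
  edge_len <- numeric(0)
  next_internal <- n + 1L
  renum <- integer(length(children))
  assemble <- function(id) {
    my <- next_internal; next_internal <<- next_internal + 1L
    renum[id] <<- my
    for (ch in children[[id]]) {
      child_new <- if (ch$node <= n) ch$node else NA_integer_
      if (is.na(child_new)) {
        child_new <- next_internal   # will be assigned in recursive call
        edge <<- rbind(edge, c(my, child_new))
        edge_len <<- c(edge_len, ch$length)
        assemble(ch$node)
      } else {
        edge <<- rbind(edge, c(my, child_new))
        edge_len <<- c(edge_len, ch$length)
      }
    }
  }
  assemble(root_id)
  tr <- structure(list(edge = edge, edge.length = edge_len,
                       tip.label = taxa, Nnode = n_internal),
                  class = "phylo", order = "cladewise")
  attr(tr, "clamped") <- clamped
  if (clamped) warning("negative NJ branch length(s) clamped to 0")
  tr
}

# Canonical keys for the non-trivial bipartitions (internal edges) of an
# unrooted tree: for each internal edge, the tip set on the far side of the
# root, represented by the side not containing the first tip label.
tree_bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  all_tips <- sort(tree$tip.label)
  desc <- function(node) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, function(k) if (k <= n) tree$tip.label[k] else desc(k)))
  }
  internal_children <- tree$edge[tree$edge[, 2] > n, 2]
  keys <- vapply(internal_children, function(node) {
    side <- sort(desc(node))
    if (all_tips[1] %in% side) side <- setdiff(all_tips, side)
    if (length(side) < 2 || length(side) > n - 2) return(NA_character_)
    paste(side, collapse = "|")
  }, character(1))
  data.frame(node = internal_children, key = keys,
             stringsAsFactors = FALSE)[!is.na(keys), , drop = FALSE]
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal edge of the point-estimate tree
#' the percentage of replicates containing the same bipartition. Taxa are
#' ordered canonically (sorted ids) before resampling, so supports do not
#' depend on input order.
#'
#' @param alignment Named character vector of aligned sequences, or matrix.
#' @param n_replicates Bootstrap replicates (the reference analysis used
#'   1000 generations; smaller values are fine for quick checks).
#' @param seed Integer seed (mandatory).
#' @param model Distance model, see [msa_distance()].
#' @return List with `tree` (the point-estimate `phylo`, supports stored as
#'   `node.label` in [0, 100]) and `supports` (per-bipartition table).
#' @export
bootstrap_support <- function(alignment, n_replicates = 100, seed,
                              model = "p") {
  stopifnot(!missing(seed), n_replicates >= 1)
  m <- alignment_matrix(alignment)
  m <- m[order(rownames(m)), , drop = FALSE]
  point <- nj_tree(msa_distance(m, model = model))
  bip <- tree_bipartitions(point)
  counts <- stats::setNames(numeric(nrow(bip)), bip$key)
  ncol_a <- ncol(m)
  with_seed(seed, {
    for (b in seq_len(n_replicates)) {
      cols <- sample.int(ncol_a, ncol_a, replace = TRUE)
      tr <- nj_tree(msa_distance(m[, cols, drop = FALSE], model = model))
      rep_keys <- tree_bipartitions(tr)$key
      hit <- names(counts) %in% rep_keys
      counts[hit] <- counts[hit] + 1
    }
  })
  support <- 100 * counts / n_replicates
  labels <- rep(NA_character_, point$Nnode)
  n_tip <- length(point$tip.label)
  labels[bip$node - n_tip] <- format(support, trim = TRUE)
  point$node.label <- labels
  list(tree = point,
       supports = data.frame(bipartition = bip$key, support = unname(support),
                             stringsAsFactors = FALSE))
}

#' Write a tree in Newick format
#'
#' @param tree A `phylo` tree (supports, if any, as node labels).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
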