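#' Build a concatenated protein supermatrix
#'
#' Column-wise concatenation of per-gene aligned protein blocks in the given
#' gene order. A taxon absent from a block is gap-filled there and flagged in
#' the missing mask.
#'
#' @param blocks Named list of aligned blocks; each block is a named character
#'   vector of equal-length aligned amino-acid sequences (taxon -> row).
#' @return A `supermatrix`: list with `mat` (character matrix, taxa x columns),
#'   `blocks` (tibble `gene`, `start`, `end`), `missing` (logical matrix, taxa
#'   x genes).
#' @export
build_supermatrix <- function(blocks) {
  if (length(blocks) == 0L) stop("no alignment blocks supplied", call. = FALSE)
  if (is.null(names(blocks))) names(blocks) <- paste0("gene", seq_along(blocks))
  taxa <- sort(unique(unlist(lapply(blocks, names))))
  if (length(taxa) == 0L) stop("blocks carry no taxon names", call. = FALSE)
  widths <- integer(length(blocks))
  rows <- matrix("", nrow = length(taxa), ncol = 0,
                 dimnames = list(taxa, NULL))
  boundaries <- tibble::tibble(gene = names(blocks), start = NA_integer_,
                               end = NA_integer_)
  missing <- matrix(FALSE, nrow = length(taxa), ncol = length(blocks),
                    dimnames = list(taxa, names(blocks)))
  col0 <- 0L
  parts <- list()
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]
    w <- unique(nchar(blk))
    if (length(w) != 1L) {
      stop(sprintf("block '%s' has conflicting row lengths (%s)",
                   names(blocks)[b], paste(w, collapse = ", ")), call. = FALSE)
    }
    widths[b] <- w
    filled <- vapply(taxa, function(tx) {
      if (tx %in% names(blk)) toupper(blk[[tx]]) else strrep("-", w)
    }, character(1))
    missing[, b] <- !(taxa %in% names(blk))
    parts[[b]] <- do.call(rbind, strsplit(filled, "", fixed = TRUE))
    boundaries$start[b] <- col0 + 1L
    boundaries$end[b] <- col0 + w
    col0 <- col0 + w
  }
  mat <- do.call(cbind, parts)
  rownames(mat) <- taxa
  structure(list(mat = mat, blocks = boundaries, missing = missing),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d taxa x %d columns (%d gene blocks)\n",
              nrow(x$mat), ncol(x$mat), nrow(x$blocks)))
  invisible(x)
}

#' @export
glance.supermatrix <- function(x, ...) {
  tibble::tibble(n_taxa = nrow(x$mat), n_columns = ncol(x$mat),
                 n_genes = nrow(x$blocks),
                 missing_fraction = mean(x$missing))
}

#' Poisson-corrected pairwise protein distances
#'
#' For each taxon pair, `p` is the mismatch proportion over mutually non-gap
#' columns (pairwise deletion; `gap_handling = "complete"` first drops every
#' column containing a gap) and the distance is `-ln(1 - p)`. Saturated pairs
#' (`p >= 1`, impossible for finite alignments but guarded) and distances above
#' `max_dist` are capped at `max_dist`.
#'
#' @param sm A [build_supermatrix()] result, or a character matrix of aligned
#'   residues (taxa x columns).
#' @param max_dist Saturation cap (default 10).
#' @param gap_handling `"pairwise"` (default) or `"complete"`.
#' @return Symmetric numeric matrix with zero diagonal and taxa dimnames.
#' @export
protein_distance <- function(sm, max_dist = 10,
                             gap_handling = c("pairwise", "complete")) {
  gap_handling <- match.arg(gap_handling)
  mat <- if (inherits(sm, "supermatrix")) sm$mat else sm
  if (nrow(mat) < 2L) stop("need at least 2 taxa", call. = FALSE)
  gap <- mat == "-" | mat == "." | mat == "X"
  if (gap_handling == "complete") {
    keep <- !apply(gap, 2, any)
    mat <- mat[, keep, drop = FALSE]
    gap <- gap[, keep, drop = FALSE]
  }
  n <- nrow(mat)
  taxa <- rownames(mat)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !gap[i, ] & !gap[j, ]
      n_ok <- sum(ok)
      if (n_ok == 0L) {
        stop(sprintf("taxa '%s' and '%s' share no comparable columns",
                     taxa[i], taxa[j]), call. = FALSE)
      }
      p <- sum(mat[i, ok] != mat[j, ok]) / n_ok
      dij <- if (p >= 1) max_dist else min(-log(1 - p), max_dist)
      d[i, j] <- dij
      d[j, i] <- dij
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei neighbor joining (via [ape::nj()]); negative branch
#' lengths, which NJ can produce on non-additive inputs, are clamped to zero
#' with the deficit moved to the sibling edge so path lengths are preserved as
#' far as possible.
#'
#' @param dist_matrix Symmetric nonnegative matrix with zero diagonal (>= 3
#'   taxa).
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(dist_matrix) {
  m <- as.matrix(dist_matrix)
  if (nrow(m) < 3L) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  if (any(m < 0)) stop("distance matrix has negative entries", call. = FALSE)
  phy <- ape::nj(stats::as.dist(m))
  neg <- which(phy$edge.length < 0)
  for (e in neg) {
    parent <- phy$edge[e, 1]
    sibs <- which(phy$edge[, 1] == parent)
    sibs <- setdiff(sibs, e)
    deficit <- phy$edge.length[e]
    phy$edge.length[e] <- 0
    if (length(sibs) > 0) {
      phy$edge.length[sibs[1]] <- phy$edge.length[sibs[1]] + deficit
    }
  }
  phy
}

#' Bootstrap support for the concatenated-protein NJ tree
#'
#' Resamples alignment columns with replacement `n_replicates` times, rebuilds
#' the distance + NJ tree per replicate, and reports for each internal
#' bipartition of the point-estimate tree the percentage of replicates
#' containing it. Deterministic for a given `seed`.
#'
#' @param sm A [build_supermatrix()] result.
#' @param n_replicates Number of bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @param max_dist,gap_handling Passed to [protein_distance()].
#' @return The point-estimate tree (`ape::phylo`) with `node.label` holding
#'   support percentages (root label `NA`) and attribute `n_replicates`.
#' @export
bootstrap_support <- function(sm, n_replicates = 100L, seed = 1L,
                              max_dist = 10, gap_handling = "pairwise") {
  stopifnot(inherits(sm, "supermatrix"))
  if (n_replicates < 1L) stop("need at least one replicate", call. = FALSE)
  point <- nj_tree(protein_distance(sm$mat, max_dist, gap_handling))
  n_col <- ncol(sm$mat)
  set.seed(as.integer(seed))
  rep_trees <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cols <- sample.int(n_col, n_col, replace = TRUE)
    rep_trees[[r]] <- nj_tree(protein_distance(sm$mat[, cols, drop = FALSE],
                                               max_dist, gap_handling))
  }
  counts <- ape::prop.clades(point, rep_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / n_replicates)
  support[1] <- NA # root of the unrooted representation carries no bipartition
  point$node.label <- as.character(support)
  attr(point, "n_replicates") <- n_replicates
  point
}

#' Align a block of protein sequences
#'
#' Equal-length inputs are accepted as already aligned; otherwise the block is
#' aligned with mafft (which must be on the PATH).
#'
#' @param seqs Named character vector of amino-acid sequences.
#' @return Named character vector of aligned sequences (equal lengths).
#' @export
align_protein_block <- function(seqs) {
  if (length(unique(nchar(seqs))) == 1L) return(seqs)
  mafft <- Sys.which("mafft")
  if (!nzchar(mafft)) {
    stop("sequences are unaligned and mafft is not on the PATH", call. = FALSE)
  }
  fin <- tempfile(fileext = ".faa")
  fout <- tempfile(fileext = ".afa")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, fin)
  system2(mafft, c("--auto", "--quiet", fin), stdout = fout)
  aln <- Biostrings::readAAStringSet(fout)
  stats::setNames(as.character(aln), names(aln))
}

#' Write a tree to Newick
#'
#' Support values (node labels) are written as internal node labels.
#' @param tree An `ape::phylo`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
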