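# Independent oracles used across the suite. These deliberately share no code
# with the package internals: literal walks, exhaustive recursion, and
# Biostrings' own aligner.

ORACLE_STOPS <- c("TAA", "TAG", "TGA")

# Literal six-frame maximal-ORF scan on the doubled sequence, deduplicated
# modulo length. Walks positions one codon at a time.
oracle_orfs <- function(seq, min_nt = 150L) {
  L <- nchar(seq)
  found <- list()
  scan_strand <- function(s, strand) {
    dbl <- paste0(s, s)
    n <- nchar(dbl)
    for (f in 0:2) {
      pos <- 1L + f
      last_stop_end <- NA_integer_ # codon end of previous stop; NA = none yet
      atg_after_stop <- NA_integer_
      while (pos + 2L <= n) {
        cod <- substr(dbl, pos, pos + 2L)
        if (is.na(atg_after_stop) && !is.na(last_stop_end) && cod == "ATG") {
          atg_after_stop <- pos
        }
        if (cod %in% ORACLE_STOPS) {
          if (!is.na(atg_after_stop)) {
            len <- pos + 2L - atg_after_stop + 1L
            if (len >= min_nt && len <= L) {
              start_fwd <- ((atg_after_stop - 1L) %% L) + 1L
              end_fwd <- ((pos + 2L - 1L) %% L) + 1L
              if (strand == "+") {
                found[[length(found) + 1L]] <<- c(start_fwd, end_fwd, 1L)
              } else {
                found[[length(found) + 1L]] <<- c(L - start_fwd + 1L,
                                                  L - end_fwd + 1L, -1L)
              }
            }
          }
          last_stop_end <- pos + 2L
          atg_after_stop <- NA_integer_
        }
        pos <- pos + 3L
      }
    }
  }
  scan_strand(seq, "+")
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
  scan_strand(rc, "-")
  if (length(found) == 0L) {
    return(data.frame(start = integer(0), end = integer(0), strand = character(0)))
  }
  m <- unique(do.call(rbind, found))
  df <- data.frame(start = m[, 1], end = m[, 2],
                   strand = ifelse(m[, 3] == 1L, "+", "-"))
  df[!duplicated(df[, c("start", "strand")]), ]
}

# Exhaustive nested-structure maximizer (Watson-Crick only, min loop), by
# direct recursion over "position i unpaired, or paired with some k".
oracle_max_pairs <- function(seq, min_loop = 3L) {
  ch <- strsplit(toupper(seq), "")[[1]]
  wc <- function(a, b) {
    (a == "A" && b == "T") || (a == "T" && b == "A") ||
      (a == "G" && b == "C") || (a == "C" && b == "G")
  }
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (wc(ch[i], ch[k])) {
        v <- 1L + rec(i + 1L, k - 1L) +
          (if (k < j) rec(k + 1L, j) else 0L)
        if (v > best) best <- v
      }
    }
    memo[[key]] <- best
    best
  }
  rec(1L, length(ch))
}

# Biostrings aligner as score oracle (same scoring convention: BLOSUM62,
# gap of length L costs 11 + L).
oracle_align_score <- function(a, b, mode = "local") {
  type <- if (mode == "local") "local" else "global"
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
    type = type, scoreOnly = TRUE)
}

# Per-base bitmap coding fraction
oracle_coding_fraction <- function(annot) {
  L <- annot$genome$length
  cov <- logical(L)
  o <- annot$orfs
  for (i in seq_len(nrow(o))) {
    fs <- o$fp_start[i]; fe <- o$fp_end[i]
    idx <- if (fs <= fe) fs:fe else c(fs:L, 1:fe)
    cov[idx] <- TRUE
  }
  mean(cov)
}

random_dna <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# random tree with positive edge lengths and its additive distance matrix
random_additive_tree <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE, br = NULL)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
  d <- ape::cophenetic.phylo(tr)
  ord <- sort(rownames(d))
  list(tree = tr, dist = d[ord, ord])
}
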