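#' Annotation configuration
#'
#' Parameters of the methionine-initiated ORF selection rule: ORFs of at least
#' `min_orf_nt` nucleotides (stop codon included) are enumerated on both strands
#' in all six frames, and a greedy longest-first selection keeps an ORF only if
#' its nucleotide overlap with every already-kept ORF does not exceed
#' `max_overlap_fraction` of the shorter of the two.
#'
#' @param min_orf_nt Minimum ORF length in nt including the stop codon
#'   (default 150, i.e. 49 aa + stop). Must be a positive multiple of 3.
#' @param max_overlap_fraction Pairwise overlap cap as a fraction of the shorter
#'   ORF (default 0.5).
#' @param allow_wraparound Detect ORFs crossing the circular origin
#'   (default `TRUE`).
#' @param all_starts Enumerate every internal ATG instead of only the first
#'   in-frame ATG after the preceding stop (default `FALSE`: one ORF per locus).
#' @return A list of class `annotation_config`.
#' @export
annotation_config <- function(min_orf_nt = 150L, max_overlap_fraction = 0.5,
                              allow_wraparound = TRUE, all_starts = FALSE) {
  min_orf_nt <- as.integer(min_orf_nt)
  if (min_orf_nt < 3L || min_orf_nt %% 3L != 0L) {
    stop("`min_orf_nt` must be a positive multiple of 3", call. = FALSE)
  }
  if (max_overlap_fraction < 0 || max_overlap_fraction > 1) {
    stop("`max_overlap_fraction` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(min_orf_nt = min_orf_nt,
                 max_overlap_fraction = max_overlap_fraction,
                 allow_wraparound = isTRUE(allow_wraparound),
                 all_starts = isTRUE(all_starts)),
            class = "annotation_config")
}

mod1 <- function(x, L) ((x - 1L) %% L) + 1L

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Genomic footprint of an ORF: the clockwise interval from fp_start to fp_end.
# For '+' ORFs fp_start = start (ATG) and fp_end = end (stop); for '-' ORFs the
# coding strand runs counterclockwise, so the clockwise footprint starts at the
# stop coordinate.
orf_fp <- function(start, end, strand) {
  fp_start <- ifelse(strand == "+", start, end)
  fp_end <- ifelse(strand == "+", end, start)
  list(fp_start = fp_start, fp_end = fp_end, wraps = fp_start > fp_end)
}

# Footprint as a 2-column matrix of linear intervals (1 row, or 2 when the ORF
# wraps the origin).
fp_intervals <- function(fp_start, fp_end, L) {
  if (fp_start <= fp_end) {
    matrix(c(fp_start, fp_end), ncol = 2)
  } else {
    matrix(c(fp_start, L, 1L, fp_end), ncol = 2, byrow = TRUE)
  }
}

fp_iranges <- function(orfs, L) {
  parts <- purrr::map(seq_len(nrow(orfs)), function(i) {
    fp_intervals(orfs$fp_start[i], orfs$fp_end[i], L)
  })
  m <- do.call(rbind, parts)
  IRanges::IRanges(start = m[, 1], end = m[, 2])
}

# Total circular overlap in nt between two footprints given as interval
# matrices.
overlap_nt_intervals <- function(m1, m2) {
  tot <- 0L
  for (i in seq_len(nrow(m1))) {
    lo <- pmax(m1[i, 1], m2[, 1])
    hi <- pmin(m1[i, 2], m2[, 2])
    tot <- tot + sum(pmax(0L, hi - lo + 1L))
  }
  tot
}

translate_cds <- function(cds) {
  if (length(cds) == 0L) return(character(0))
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(cds),
                                           if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}

#' Enumerate candidate ORFs in all six frames
#'
#' Walks every frame on both strands of the (doubled, for circular topology)
#' sequence and reports each maximal ORF: from the first in-frame ATG after the
#' preceding in-frame stop through the next in-frame stop, stop codon included.
#' Wraparound ORFs are detected on the doubled sequence and deduplicated by
#' start position modulo the genome length; ORFs longer than the genome are
#' rejected as degenerate.
#'
#' @param genome A [circular_genome()].
#' @param config An [annotation_config()].
#' @return Tibble of candidate ORFs: `start` (A of the ATG), `end` (last base of
#'   the stop codon), `strand`, `length_nt`, `length_aa`, `protein`,
#'   `fp_start`, `fp_end`, `wraps`. Coordinates are 1-based genome positions;
#'   for minus-strand ORFs `start > end` numerically unless the ORF wraps.
#' @export
enumerate_candidate_orfs <- function(genome, config = annotation_config()) {
  stopifnot(inherits(genome, "circular_genome"))
  L <- genome$length
  if (L < config$min_orf_nt) return(empty_orf_tibble())
  circular <- genome$topology == "circular" && config$allow_wraparound

  scan_one <- function(seq_scan, require_preceding_stop) {
    n <- nchar(seq_scan)
    res <- list()
    for (f in 0:2) {
      if (n - 2L < 1L + f) next
      starts <- seq.int(1L + f, n - 2L, by = 3L)
      if (length(starts) < 2L) next
      codons <- substring(seq_scan, starts, starts + 2L)
      stop_i <- which(codons %in% STOP_CODONS)
      atg_i <- which(codons == "ATG")
      if (length(stop_i) == 0L || length(atg_i) == 0L) next
      bounds <- if (require_preceding_stop) stop_i else c(0L, stop_i)
      if (length(bounds) < 2L) next
      prev <- bounds[-length(bounds)]
      nxt <- bounds[-1]
      for (k in seq_along(prev)) {
        if (config$all_starts) {
          a_all <- atg_i[atg_i > prev[k] & atg_i < nxt[k]]
        } else {
          a_all <- atg_i[atg_i > prev[k] & atg_i < nxt[k]][1]
        }
        for (a in a_all) {
          if (is.na(a)) next
          res[[length(res) + 1L]] <- c(starts[a], starts[nxt[k]] + 2L)
        }
      }
    }
    if (length(res) == 0L) matrix(integer(0), ncol = 2) else do.call(rbind, res)
  }

  seq_fwd <- if (circular) strrep(genome$seq, 2L) else genome$seq
  seq_rev <- reverse_complement(seq_fwd) # revcomp of doubled == doubled revcomp

  recs <- list()
  fwd <- scan_one(seq_fwd, require_preceding_stop = circular)
  if (nrow(fwd) > 0) {
    recs[[1]] <- tibble::tibble(
      start_raw = fwd[, 1], end_raw = fwd[, 2], strand = "+"
    )
  }
  rev <- scan_one(seq_rev, require_preceding_stop = circular)
  if (nrow(rev) > 0) {
    n_scan <- nchar(seq_fwd)
    # map reverse-strand scan coordinates back onto the forward genome
    recs[[length(recs) + 1L]] <- tibble::tibble(
      start_raw = n_scan - rev[, 1] + 1L, end_raw = n_scan - rev[, 2] + 1L,
      strand = "-"
    )
  }
  if (length(recs) == 0L) return(empty_orf_tibble())
  cand <- dplyr::bind_rows(recs)
  cand$length_nt <- abs(cand$end_raw - cand$start_raw) + 1L
  cand <- dplyr::filter(cand, .data$length_nt >= config$min_orf_nt,
                        .data$length_nt <= L)
  if (nrow(cand) == 0L) return(empty_orf_tibble())
  cand$start <- mod1(cand$start_raw, L)
  cand$end <- mod1(cand$end_raw, L)
  cand <- dplyr::distinct(cand, .data$start, .data$strand, .keep_all = TRUE)

  fp <- orf_fp(cand$start, cand$end, cand$strand)
  cand$fp_start <- fp$fp_start
  cand$fp_end <- fp$fp_end
  cand$wraps <- fp$wraps
  cds <- purrr::pmap_chr(list(fp$fp_start, fp$fp_end, cand$strand),
                         function(s, e, st) circular_subsequence(genome, s, e, st))
  cand$protein <- translate_cds(cds)
  cand$length_aa <- cand$length_nt %/% 3L - 1L
  orf_cols(cand)
}

orf_cols <- function(x) {
  x <- dplyr::arrange(x, .data$fp_start, .data$strand)
  tibble::as_tibble(x[, c("start", "end", "strand", "length_nt", "length_aa",
                          "protein", "fp_start", "fp_end", "wraps")])
}

empty_orf_tibble <- function() {
  tibble::tibble(start = integer(0), end = integer(0), strand = character(0),
                 length_nt = integer(0), length_aa = integer(0),
                 protein = character(0), fp_start = integer(0),
                 fp_end = integer(0), wraps = logical(0))
}

#' Greedy minimal-overlap ORF selection
#'
#' Candidates are taken longest first (ties: smaller start, then `+` strand); a
#' candidate is kept only if its circular nucleotide overlap with every
#' already-kept ORF is at most `max_overlap_fraction` of the shorter of the
#' two. This operationalizes the "minimal overlap" selection used when
#' annotating densely packed baculovirus genomes.
#'
#' @param candidates Tibble from [enumerate_candidate_orfs()].
#' @param config An [annotation_config()].
#' @param genome_length Genome length in nt (needed for circular overlap
#'   arithmetic).
#' @return The selected subset, ordered by footprint start.
#' @export
resolve_minimal_overlap <- function(candidates, config = annotation_config(),
                                    genome_length) {
  if (nrow(candidates) == 0L) return(candidates)
  L <- as.integer(genome_length)
  ord <- order(-candidates$length_nt, candidates$start,
               match(candidates$strand, c("+", "-")))
  cand <- candidates[ord, ]
  ivs <- purrr::map(seq_len(nrow(cand)), function(i) {
    fp_intervals(cand$fp_start[i], cand$fp_end[i], L)
  })
  keep <- logical(nrow(cand))
  acc_iv <- list()
  acc_len <- integer(0)
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    if (length(acc_iv) > 0) {
      for (j in seq_along(acc_iv)) {
        ov <- overlap_nt_intervals(ivs[[i]], acc_iv[[j]])
        if (ov > config$max_overlap_fraction * min(cand$length_nt[i], acc_len[j])) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) {
      keep[i] <- TRUE
      acc_iv[[length(acc_iv) + 1L]] <- ivs[[i]]
      acc_len <- c(acc_len, cand$length_nt[i])
    }
  }
  orf_cols(cand[keep, ])
}

#' Anchor an ORF set at a designated gene and number the ORFs
#'
#' Rotates (and, for a minus-strand anchor, reverse-complements) the genome so
#' that the anchor gene's ATG starts at nt 1 on the plus strand — the
#' granulovirus convention that designates the granulin gene *orf1* with the
#' first nt of its start codon as nt 1 — then renumbers all ORFs 1..n by
#' ascending footprint start in the new coordinate system.
#'
#' @param orfs Selected ORF tibble.
#' @param genome The [circular_genome()] the ORFs were called on.
#' @param anchor A single row of `orfs` (or an index into `orfs`) identifying
#'   the anchor gene.
#' @param config The [annotation_config()] used (stored for provenance).
#' @return A `genome_annotation` object: list with `genome` (re-anchored),
#'   `orfs` (tibble with `orf_id` 1..n), `anchor_orf_id` (always 1) and
#'   `config`.
#' @export
anchor_and_number <- function(orfs, genome, anchor, config = annotation_config()) {
  stopifnot(inherits(genome, "circular_genome"))
  if (is.numeric(anchor) && length(anchor) == 1L) {
    if (anchor < 1 || anchor > nrow(orfs)) stop("anchor index out of range", call. = FALSE)
    anchor_row <- orfs[anchor, ]
  } else {
    anchor_row <- tibble::as_tibble(anchor)
    hit <- which(orfs$start == anchor_row$start & orfs$strand == anchor_row$strand)
    if (length(hit) == 0L) {
      stop("anchor ORF is not one of the supplied ORFs", call. = FALSE)
    }
    anchor_row <- orfs[hit[1], ]
  }
  L <- genome$length
  g <- genome
  o <- orfs
  if (anchor_row$strand == "-") {
    g <- flip_genome(g)
    new_start <- L - o$start + 1L
    new_end <- L - o$end + 1L
    o$start <- new_start
    o$end <- new_end
    o$strand <- ifelse(o$strand == "+", "-", "+")
    anchor_row$start <- L - anchor_row$start + 1L
    anchor_row$strand <- "+"
  }
  shift <- anchor_row$start - 1L
  if (shift != 0L) {
    if (g$topology != "circular") {
      stop("cannot re-anchor a linear genome at an internal position", call. = FALSE)
    }
    g <- rotate_genome(g, anchor_row$start)
    o$start <- mod1(o$start - shift, L)
    o$end <- mod1(o$end - shift, L)
  }
  fp <- orf_fp(o$start, o$end, o$strand)
  o$fp_start <- as.integer(fp$fp_start)
  o$fp_end <- as.integer(fp$fp_end)
  o$wraps <- fp$wraps
  o <- dplyr::arrange(o, .data$fp_start, .data$strand)
  o <- dplyr::bind_cols(tibble::tibble(orf_id = seq_len(nrow(o))), o)
  structure(list(genome = g, orfs = o, anchor_orf_id = 1L, config = config),
            class = "genome_annotation")
}

#' Annotate a circular genome end to end
#'
#' Convenience wrapper: [enumerate_candidate_orfs()], then
#' [resolve_minimal_overlap()], then optional homology-rescue of sub-threshold
#' ORFs, then [anchor_and_number()].
#'
#' @param genome A [circular_genome()].
#' @param config An [annotation_config()].
#' @param anchor_protein Optional amino-acid sequence of the anchor gene
#'   (e.g. granulin); the selected ORF with the best local alignment score to it
#'   becomes *orf1*. When `NULL` the ORF with the smallest footprint start is
#'   the anchor and the genome is not rotated onto a gene.
#' @param rescue Optional tibble with columns `start`, `end`, `strand` naming
#'   sub-threshold candidate ORFs to force into the annotation (the published
#'   practice of adding a short ORF on homology evidence).
#' @return A `genome_annotation`.
#' @export
annotate_genome <- function(genome, config = annotation_config(),
                            anchor_protein = NULL, rescue = NULL) {
  cand <- enumerate_candidate_orfs(genome, config)
  sel <- resolve_minimal_overlap(cand, config, genome$length)
  if (!is.null(rescue) && nrow(rescue) > 0) {
    extra <- rescue_records(genome, rescue)
    sel <- orf_cols(dplyr::distinct(dplyr::bind_rows(sel, extra),
                                    .data$start, .data$strand, .keep_all = TRUE))
  }
  if (nrow(sel) == 0L) stop("no ORFs found at the configured threshold", call. = FALSE)
  if (!is.null(anchor_protein)) {
    sc <- align_score_matrix(stats::setNames(sel$protein, seq_len(nrow(sel))),
                             c(anchor = anchor_protein), mode = "local")
    anchor <- which.max(sc[, 1])
  } else {
    anchor <- which.min(sel$fp_start)
  }
  anchor_and_number(sel, genome, anchor, config)
}

rescue_records <- function(genome, rescue) {
  fp <- orf_fp(rescue$start, rescue$end, rescue$strand)
  cds <- purrr::pmap_chr(list(fp$fp_start, fp$fp_end, rescue$strand),
                         function(s, e, st) circular_subsequence(genome, s, e, st))
  len <- nchar(cds)
  if (any(len %% 3L != 0L)) stop("rescue ORF length not a multiple of 3", call. = FALSE)
  tibble::tibble(
    start = as.integer(rescue$start), end = as.integer(rescue$end),
    strand = rescue$strand, length_nt = as.integer(len),
    length_aa = as.integer(len %/% 3L - 1L), protein = translate_cds(cds),
    fp_start = as.integer(fp$fp_start), fp_end = as.integer(fp$fp_end),
    wraps = fp$wraps
  )
}

#' Orientation, overlap and coding statistics of an annotation
#'
#' @param annot A `genome_annotation`.
#' @return List with `summary` (one-row tibble: `n_orfs`, `n_plus`, `n_minus`,
#'   `coding_fraction`, `n_adjacent_overlaps`) and `overlaps` (tibble of
#'   adjacent ORF pairs in anchored order — including the circular last-first
#'   pair — with `overlap_nt > 0`).
#' @export
annotation_stats <- function(annot) {
  stopifnot(inherits(annot, "genome_annotation"))
  o <- annot$orfs
  L <- annot$genome$length
  covered <- sum(IRanges::width(IRanges::reduce(fp_iranges(o, L))))
  n <- nrow(o)
  ov <- tibble::tibble(orf_id_a = integer(0), orf_id_b = integer(0),
                       overlap_nt = integer(0))
  if (n >= 2) {
    ivs <- purrr::map(seq_len(n), function(i) fp_intervals(o$fp_start[i], o$fp_end[i], L))
    nxt <- c(seq_len(n)[-1], 1L)
    rows <- purrr::map(seq_len(n), function(i) {
      j <- nxt[i]
      if (i == j) return(NULL)
      if (n == 2L && i == 2L) return(NULL) # the two relations coincide
      x <- overlap_nt_intervals(ivs[[i]], ivs[[j]])
      if (x > 0) tibble::tibble(orf_id_a = o$orf_id[i], orf_id_b = o$orf_id[j],
                                overlap_nt = as.integer(x)) else NULL
    })
    ov <- dplyr::bind_rows(rows)
    if (nrow(ov) == 0L) {
      ov <- tibble::tibble(orf_id_a = integer(0), orf_id_b = integer(0),
                           overlap_nt = integer(0))
    }
  }
  list(
    summary = tibble::tibble(
      n_orfs = n,
      n_plus = sum(o$strand == "+"),
      n_minus = sum(o$strand == "-"),
      coding_fraction = covered / L,
      n_adjacent_overlaps = nrow(ov)
    ),
    overlaps = ov
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  s <- annotation_stats(x)$summary
  cat(sprintf("<genome_annotation> %s: %d ORFs (%d '+', %d '-'), coding %.1f%%\n",
              x$genome$id, s$n_orfs, s$n_plus, s$n_minus, 100 * s$coding_fraction))
  invisible(x)
}

#' Tidy an annotation into its ORF table
#'
#' @param x A `genome_annotation`.
#' @param ... Unused.
#' @return The ORF tibble.
#' @export
tidy.genome_annotation <- function(x, ...) x$orfs

#' One-row summary of an annotation
#'
#' @param x A `genome_annotation`.
#' @param ... Unused.
#' @export
glance.genome_annotation <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(id = x$genome$id, genome_length = x$genome$length,
                   gc_fraction = gc_content(x$genome$seq)),
    annotation_stats(x)$summary
  )
}

#' Write annotated CDS features as GFF3
#'
#' Features are typed `CDS` in 1-based inclusive coordinates; an ORF wrapping
#' the circular origin is split into two location lines joined by a shared
#' `ID`.
#'
#' @param annot A `genome_annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(annot, path) {
  stopifnot(inherits(annot, "genome_annotation"))
  o <- annot$orfs
  L <- annot$genome$length
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", annot$genome$id, L))
  for (i in seq_len(nrow(o))) {
    iv <- fp_intervals(o$fp_start[i], o$fp_end[i], L)
    for (r in seq_len(nrow(iv))) {
      lines <- c(lines, paste(
        annot$genome$id, "gvcompare", "CDS", iv[r, 1], iv[r, 2], ".",
        o$strand[i], "0", sprintf("ID=orf%d", o$orf_id[i]), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write annotated protein sequences as FASTA
#'
#' @param annot A `genome_annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(annot, path) {
  stopifnot(inherits(annot, "genome_annotation"))
  aa <- Biostrings::AAStringSet(annot$orfs$protein)
  names(aa) <- sprintf("%s_orf%d", annot$genome$id, annot$orfs$orf_id)
  Biostrings::writeXStringSet(aa, path, width = 70L)
  invisible(path)
}
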