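#' Repeat-scan configuration
#'
#' Parameters for locating candidate replication-origin architecture in
#' intergenic spacers: tandem imperfect direct repeats, imperfect palindromes
#' and AT-rich context.
#'
#' @param min_unit_nt Minimum direct-repeat unit length (default 15).
#' @param max_mismatch_fraction Maximum per-copy mismatch fraction against the
#'   array consensus, and maximum arm mismatch fraction for palindromes
#'   (default 0.2).
#' @param min_copies Minimum number of full repeat copies to report an array
#'   (default 2).
#' @param min_palindrome_arm Minimum palindrome arm length (default 6).
#' @param max_loop_nt Maximum palindrome loop length (default 10).
#' @param at_window_nt Window for AT-richness scans (default 100).
#' @param at_threshold AT fraction above which a region counts as AT-rich
#'   (default 0.6).
#' @param seed_k Exact seed length for repeat detection (default 8).
#' @return A list of class `repeat_config`.
#' @export
repeat_config <- function(min_unit_nt = 15L, max_mismatch_fraction = 0.2,
                          min_copies = 2L, min_palindrome_arm = 6L,
                          max_loop_nt = 10L, at_window_nt = 100L,
                          at_threshold = 0.6, seed_k = 8L) {
  cfg <- list(min_unit_nt = as.integer(min_unit_nt),
              max_mismatch_fraction = max_mismatch_fraction,
              min_copies = as.integer(min_copies),
              min_palindrome_arm = as.integer(min_palindrome_arm),
              max_loop_nt = as.integer(max_loop_nt),
              at_window_nt = as.integer(at_window_nt),
              at_threshold = at_threshold,
              seed_k = as.integer(seed_k))
  if (any(unlist(cfg[c("min_unit_nt", "min_copies", "min_palindrome_arm",
                       "at_window_nt", "seed_k")]) < 1L)) {
    stop("repeat_config counts must be positive", call. = FALSE)
  }
  if (max_mismatch_fraction < 0 || max_mismatch_fraction > 1 ||
      at_threshold < 0 || at_threshold > 1) {
    stop("repeat_config fractions must lie in [0, 1]", call. = FALSE)
  }
  structure(cfg, class = "repeat_config")
}

#' Intergenic spacers of an annotation
#'
#' Maximal regions not covered by any ORF footprint, with circular wrap
#' handled (a spacer crossing the origin is reported with `start > end`).
#'
#' @param annot A `genome_annotation`.
#' @param min_len Minimum spacer length to report (default 1).
#' @return Tibble: `start`, `end`, `length`, `left_orf`, `right_orf` (the
#'   flanking ORF ids in anchored numbering).
#' @export
intergenic_spacers <- function(annot, min_len = 1L) {
  stopifnot(inherits(annot, "genome_annotation"))
  o <- annot$orfs
  L <- annot$genome$length
  empty <- tibble::tibble(start = integer(0), end = integer(0),
                          length = integer(0), left_orf = integer(0),
                          right_orf = integer(0))
  if (nrow(o) == 0L) {
    return(tibble::tibble(start = 1L, end = L, length = L,
                          left_orf = NA_integer_, right_orf = NA_integer_))
  }
  covered <- IRanges::reduce(fp_iranges(o, L))
  gaps <- IRanges::gaps(covered, start = 1L, end = L)
  if (length(gaps) == 0L) return(empty)
  gs <- IRanges::start(gaps)
  ge <- IRanges::end(gaps)
  # merge a terminal and an initial gap across the circular origin
  wrap_merge <- annot$genome$topology == "circular" && length(gaps) >= 2L &&
    gs[1] == 1L && ge[length(ge)] == L
  if (wrap_merge) {
    merged_start <- gs[length(gs)]
    merged_end <- ge[1]
    gs <- c(gs[-c(1L, length(gs))], merged_start)
    ge <- c(ge[-c(1L, length(ge))], merged_end)
  }
  len <- ifelse(gs <= ge, ge - gs + 1L, L - gs + 1L + ge)
  spacers <- tibble::tibble(start = gs, end = ge, length = as.integer(len))
  spacers <- dplyr::filter(spacers, .data$length >= min_len)
  if (nrow(spacers) == 0L) return(empty)
  flank <- function(pos) {
    pos <- mod1(pos, L)
    hit <- which(purrr::map_lgl(seq_len(nrow(o)), function(i) {
      iv <- fp_intervals(o$fp_start[i], o$fp_end[i], L)
      any(pos >= iv[, 1] & pos <= iv[, 2])
    }))
    if (length(hit) == 0L) NA_integer_ else o$orf_id[hit[1]]
  }
  spacers$left_orf <- purrr::map_int(spacers$start, ~ flank(.x - 1L))
  spacers$right_orf <- purrr::map_int(spacers$end, ~ flank(.x + 1L))
  spacers
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Find tandem arrays of imperfect direct repeats
#'
#' Seed-and-extend scan: exact `seed_k`-mer matches at candidate periods are
#' extended into maximal self-alignments of the sequence against itself at that
#' period, then validated copy-by-copy against the array consensus (majority
#' base per unit position; each full copy must stay within
#' `max_mismatch_fraction` of the consensus). A trailing partial copy of at
#' least 40% of the unit length sets `has_truncated_copy`. Overlapping reports
#' are merged to the highest-scoring array, so output regions never overlap.
#'
#' @param seq Nucleotide string (a spacer, typically).
#' @param config A [repeat_config()].
#' @return Tibble: `start`, `end` (1-based in `seq`), `unit_len`,
#'   `n_full_copies`, `has_truncated_copy`, `unit_consensus`, `at_fraction`.
#' @export
find_direct_repeats <- function(seq, config = repeat_config()) {
  seq <- as_seq(seq)
  n <- nchar(seq)
  empty <- tibble::tibble(start = integer(0), end = integer(0),
                          unit_len = integer(0), n_full_copies = integer(0),
                          has_truncated_copy = logical(0),
                          unit_consensus = character(0),
                          at_fraction = numeric(0))
  if (n < 2L * config$min_unit_nt) return(empty)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  k <- config$seed_k
  kmers <- substring(seq, 1:(n - k + 1L), k:n)
  occ <- split(seq_along(kmers), kmers)
  occ <- occ[lengths(occ) >= 2L]
  seeds <- list()
  for (pos in occ) {
    d <- diff(pos)
    ok <- which(d >= config$min_unit_nt & d <= n %/% 2L)
    for (i in ok) seeds[[length(seeds) + 1L]] <- c(pos[i], d[i])
  }
  if (length(seeds) == 0L) return(empty)
  seeds <- unique(do.call(rbind, seeds))
  if (nrow(seeds) > 5000L) seeds <- seeds[seq_len(5000L), , drop = FALSE]

  thr <- config$max_mismatch_fraction
  cands <- list()
  for (r in seq_len(nrow(seeds))) {
    p <- seeds[r, 1]
    d <- seeds[r, 2]
    tmax <- n - d
    m <- chars[1:tmax] == chars[(1 + d):(d + tmax)]
    # X-drop extension of the seeded self-match [a, b]: match +1, mismatch -2,
    # stop when the running score falls max(15, unit) below its maximum; the
    # reported bound is the score maximum, which keeps array boundaries tight
    # while tolerating the local mismatch clusters that ~15-20% inter-copy
    # divergence produces
    xdrop <- max(15L, d)
    grow <- function(from, step) {
      pos <- from
      score <- 0
      best_score <- 0
      best <- from - step
      while (pos >= 1L && pos <= tmax) {
        score <- score + (if (m[pos]) 1 else -2)
        if (score > best_score) { best_score <- score; best <- pos }
        if (score < best_score - xdrop) break
        pos <- pos + step
      }
      best
    }
    b <- grow(p, 1L)
    a <- grow(p, -1L)
    if (b < a) next
    n_full <- (b + d - a + 1L) %/% d

    # consensus validation: every reported full copy must stay within the
    # mismatch bound; edge offenders are trimmed, an interior offender splits
    # the array (the longer side is kept)
    validate <- function(a, n_full) {
      cons <- NULL
      repeat {
        if (n_full < config$min_copies) break
        copy_start <- a + (seq_len(n_full) - 1L) * d
        copies <- matrix(chars[rep(copy_start, each = d) + rep(0:(d - 1L), n_full)],
                         nrow = d)
        cons <- apply(copies, 1, function(col) {
          tab <- sort(table(col), decreasing = TRUE)
          names(tab)[1]
        })
        mism <- colSums(copies != cons)
        bad <- which(mism > thr * d)
        if (length(bad) == 0L) break
        if (bad[length(bad)] == n_full) { n_full <- n_full - 1L; next }
        if (bad[1] == 1L) { a <- a + d; n_full <- n_full - 1L; next }
        if (bad[1] - 1L >= n_full - bad[1]) {
          n_full <- bad[1] - 1L
        } else {
          a <- a + bad[1] * d
          n_full <- n_full - bad[1]
        }
      }
      list(a = a, n_full = n_full, cons = cons)
    }

    v <- validate(a, n_full)
    if (v$n_full < config$min_copies) next

    # polish both edges against the validated consensus: the self-alignment
    # can start/end a few bases inside the array when copy edges carry
    # mismatch clusters; walk outward while the consensus keeps matching.
    # The +1/-1 scoring tolerates noisy copy edges (random background still
    # trends downhill at ~25% matches); at least 2 net matches to extend.
    polish <- function(anchor, from, dir, cons) {
      sc <- 0L; best_sc <- 1L; best_k <- 0L
      kmax <- if (dir < 0L) min(2L * d, from - 1L) else min(2L * d, n - from)
      for (k in seq_len(kmax)) {
        p <- from + dir * k
        off <- ((p - anchor) %% d) + 1L
        sc <- sc + (if (chars[p] == cons[off]) 1L else -1L)
        if (sc > best_sc) { best_sc <- sc; best_k <- k }
      }
      best_k
    }
    end_full <- v$a + v$n_full * d - 1L
    lead_ext <- polish(v$a, v$a, -1L, v$cons)
    tail_ext <- polish(v$a, end_full, 1L, v$cons)

    # re-validate on the polished grid (the consensus re-derivation absorbs
    # any unit rotation the leading extension implies)
    a2 <- v$a - lead_ext
    span <- lead_ext + v$n_full * d + tail_ext
    v <- validate(a2, span %/% d)
    if (v$n_full < config$min_copies) next
    a <- v$a
    n_full <- v$n_full
    cons <- v$cons
    end_full <- a + n_full * d - 1L
    trailing <- max(0L, min(a2 + span - 1L, n) - end_full)
    trailing <- min(trailing, d - 1L)
    truncated <- trailing >= 0.4 * d
    region_end <- if (truncated) end_full + trailing else end_full
    region_seq <- substr(seq, a, region_end)
    cands[[length(cands) + 1L]] <- tibble::tibble(
      start = a, end = region_end, unit_len = d, n_full_copies = n_full,
      has_truncated_copy = truncated,
      unit_consensus = paste(cons, collapse = ""),
      at_fraction = at_content(region_seq),
      score = n_full * d
    )
  }
  if (length(cands) == 0L) return(empty)
  cands <- dplyr::distinct(dplyr::bind_rows(cands))
  # prefer the fundamental period: most full copies first (a k-copy array is
  # always also a k/2-copy array at twice the unit), then extent, then start
  cands <- dplyr::arrange(cands, dplyr::desc(.data$n_full_copies),
                          dplyr::desc(.data$score), .data$start,
                          .data$unit_len)
  keep <- rep(FALSE, nrow(cands))
  for (i in seq_len(nrow(cands))) {
    clash <- keep & !(cands$end < cands$start[i] | cands$start > cands$end[i])
    if (!any(clash)) keep[i] <- TRUE
  }
  out <- dplyr::arrange(cands[keep, ], .data$start)
  dplyr::select(out, -"score")
}

#' Find imperfect palindromes (inverted repeats)
#'
#' All maximal inverted repeats with arm length at least `min_palindrome_arm`,
#' loop at most `max_loop_nt`, and arm mismatch fraction at most
#' `max_mismatch_fraction`; overlapping reports are collapsed to the
#' highest-scoring (most matching arm positions).
#'
#' @param seq Nucleotide string.
#' @param config A [repeat_config()].
#' @return Tibble: `start`, `end`, `arm_len`, `loop_len`, `mismatches`.
#' @export
find_palindromes <- function(seq, config = repeat_config()) {
  seq <- as_seq(seq)
  n <- nchar(seq)
  empty <- tibble::tibble(start = integer(0), end = integer(0),
                          arm_len = integer(0), loop_len = integer(0),
                          mismatches = integer(0))
  if (n < 2L * config$min_palindrome_arm) return(empty)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  comp <- unname(COMPLEMENT[chars])
  thr <- config$max_mismatch_fraction
  hits <- list()
  # parametrize by loop placement and grow arms outward; pairs are then
  # incremental in the arm length
  for (c1 in seq_len(n + 1L)) {
    for (loop in 0:config$max_loop_nt) {
      c2 <- c1 + loop - 1L # loop occupies [c1, c2]; empty when loop == 0
      if (c2 > n) break
      max_arm <- min(c1 - 1L, n - c2)
      if (max_arm < config$min_palindrome_arm) next
      mm <- 0L
      best_arm <- 0L
      best_mm <- 0L
      for (a in seq_len(max_arm)) {
        if (comp[c1 - a] != chars[c2 + a]) mm <- mm + 1L
        if (a >= config$min_palindrome_arm && mm <= thr * a) {
          best_arm <- a
          best_mm <- mm
        }
      }
      if (best_arm >= config$min_palindrome_arm) {
        hits[[length(hits) + 1L]] <- tibble::tibble(
          start = c1 - best_arm, end = c2 + best_arm,
          arm_len = best_arm, loop_len = loop, mismatches = best_mm,
          score = best_arm - best_mm
        )
      }
    }
  }
  if (length(hits) == 0L) return(empty)
  hits <- dplyr::bind_rows(hits)
  hits <- dplyr::arrange(hits, dplyr::desc(.data$score), .data$start,
                         .data$loop_len)
  keep <- rep(FALSE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    clash <- keep & !(hits$end < hits$start[i] | hits$start > hits$end[i])
    if (!any(clash)) keep[i] <- TRUE
  }
  out <- dplyr::arrange(hits[keep, ], .data$start)
  dplyr::select(out, -"score")
}

#' Predict the maximum-base-pair hairpin structure of a DNA segment
#'
#' Nussinov-style base-pair maximization over Watson-Crick pairs (A:T, G:C; no
#' G:U — the substrate is DNA) with a minimum hairpin loop of 3 nt. Among
#' co-optimal structures the traceback deterministically prefers pairing the
#' 5'-most base with its most distal admissible partner, which favors
#' contiguous stems. No thermodynamic parameters are used: the prediction is a
#' structural sketch, not a folding energy.
#'
#' @param seq Nucleotide string, 5-2000 nt.
#' @param min_loop Minimum loop length (default 3).
#' @return A `hairpin_structure`: list with `pairs` (tibble `i`, `j`),
#'   `n_pairs`, `loop_len` (innermost loop; `NA` when unpaired) and
#'   `dot_bracket`.
#' @export
predict_hairpin <- function(seq, min_loop = 3L) {
  seq <- as_seq(seq)
  n <- nchar(seq)
  if (n < 5L || n > 2000L) {
    stop("hairpin prediction supports sequences of 5 to 2000 nt", call. = FALSE)
  }
  enc <- match(strsplit(seq, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
  enc[is.na(enc)] <- 0L # N never pairs
  partner <- nussinov_cpp(enc, as.integer(min_loop))
  i <- which(partner > seq_along(partner))
  pairs <- tibble::tibble(i = i, j = partner[i])
  db <- rep(".", n)
  db[pairs$i] <- "("
  db[pairs$j] <- ")"
  structure(list(
    pairs = pairs,
    n_pairs = nrow(pairs),
    loop_len = if (nrow(pairs) == 0L) NA_integer_ else min(pairs$j - pairs$i - 1L),
    dot_bracket = paste(db, collapse = "")
  ), class = "hairpin_structure")
}

#' @export
print.hairpin_structure <- function(x, ...) {
  cat(sprintf("<hairpin_structure> %d pairs, innermost loop %s\n%s\n",
              x$n_pairs, x$loop_len, x$dot_bracket))
  invisible(x)
}

#' Classify a repeat region as non-hr, hr-like or neither
#'
#' A region is a putative non-hr replication origin when it carries at least
#' `min_copies` direct-repeat copies, is AT-rich (`at_fraction >=
#' at_threshold`), and has a palindrome or a hairpin of at least 4 base pairs
#' within or adjacent to it. It is hr-like when each repeat unit carries a
#' centered palindrome (the canonical hr architecture, which takes precedence).
#' Otherwise it is classified `none`.
#'
#' @param region One row of [find_direct_repeats()] output, augmented with
#'   `n_palindromes` (palindromes within/adjacent) and optionally
#'   `max_hairpin_pairs` and `centered_palindrome_in_each_unit`.
#' @param config A [repeat_config()].
#' @return One of `"hr_like"`, `"non_hr"`, `"none"`.
#' @export
classify_region <- function(region, config = repeat_config()) {
  region <- as.list(region)
  n_pal <- region$n_palindromes %||% 0L
  hp <- region$max_hairpin_pairs %||% 0L
  centered <- isTRUE(region$centered_palindrome_in_each_unit)
  if (centered && region$n_full_copies >= config$min_copies) return("hr_like")
  if (region$n_full_copies >= config$min_copies &&
      region$at_fraction >= config$at_threshold &&
      (n_pal >= 1L || hp >= 4L)) {
    return("non_hr")
  }
  "none"
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a[1])) b else a

#' Scan a genome's intergenic spacers for candidate repeat regions
#'
#' Runs [find_direct_repeats()] and [find_palindromes()] over every intergenic
#' spacer of at least `min_spacer_len` nt, predicts a hairpin for each repeat
#' region, and classifies each region via [classify_region()]. Coordinates are
#' reported in genome coordinates.
#'
#' @param annot A `genome_annotation`.
#' @param config A [repeat_config()].
#' @param min_spacer_len Minimum spacer length to scan (default 50).
#' @return Tibble of class `repeat_region_table`: spacer flanks, region
#'   coordinates, repeat copy statistics, `at_fraction`, `n_palindromes`,
#'   `max_hairpin_pairs`, `classification`.
#' @export
find_repeat_regions <- function(annot, config = repeat_config(),
                                min_spacer_len = 50L) {
  stopifnot(inherits(annot, "genome_annotation"))
  L <- annot$genome$length
  spacers <- intergenic_spacers(annot, min_len = min_spacer_len)
  rows <- purrr::map(seq_len(nrow(spacers)), function(si) {
    sp <- spacers[si, ]
    sp_seq <- circular_subsequence(annot$genome, sp$start, sp$end, "+")
    reps <- find_direct_repeats(sp_seq, config)
    if (nrow(reps) == 0L) return(NULL)
    pals <- find_palindromes(sp_seq, config)
    purrr::map(seq_len(nrow(reps)), function(ri) {
      rg <- reps[ri, ]
      adj <- max(1L, rg$start - 2L * config$min_palindrome_arm - config$max_loop_nt)
      adj_end <- min(nchar(sp_seq), rg$end + 2L * config$min_palindrome_arm +
                       config$max_loop_nt)
      near <- pals[pals$start >= adj & pals$end <= adj_end, ]
      hp <- if (rg$end - rg$start + 1L >= 5L && rg$end - rg$start + 1L <= 2000L) {
        predict_hairpin(substr(sp_seq, rg$start, rg$end))$n_pairs
      } else 0L
      # hr architecture: the same (period-consistent) palindrome sits mid-unit
      # in every full copy
      centered <- FALSE
      in_region <- near[near$start >= rg$start & near$end <= rg$end &
                          near$arm_len >= max(8L, config$min_palindrome_arm), ]
      if (nrow(in_region) >= rg$n_full_copies) {
        centers <- (in_region$start + in_region$end) / 2
        copy_idx <- pmin((centers - rg$start) %/% rg$unit_len,
                         rg$n_full_copies - 1L)
        offset <- (centers - rg$start) %% rg$unit_len
        mid <- offset >= 0.3 * rg$unit_len & offset <= 0.7 * rg$unit_len
        # one disrupted unit is tolerated in arrays of 3+ copies: these are
        # imperfect palindromes and a copy can lose its palindrome to drift
        need <- if (rg$n_full_copies >= 3L) rg$n_full_copies - 1L else
          rg$n_full_copies
        for (o in unique(round(offset[mid]))) {
          grp <- mid & abs(offset - o) <= 2
          if (length(unique(copy_idx[grp])) >= need) {
            centered <- TRUE
            break
          }
        }
      }
      aug <- dplyr::mutate(rg,
        n_palindromes = nrow(near),
        max_hairpin_pairs = hp,
        centered_palindrome_in_each_unit = centered)
      aug$classification <- classify_region(aug, config)
      dplyr::mutate(aug,
        left_orf = sp$left_orf, right_orf = sp$right_orf,
        genome_start = mod1(sp$start + rg$start - 1L, L),
        genome_end = mod1(sp$start + rg$end - 1L, L))
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  if (nrow(out) == 0L) {
    out <- tibble::tibble(start = integer(0), end = integer(0),
                          unit_len = integer(0), n_full_copies = integer(0),
                          has_truncated_copy = logical(0),
                          unit_consensus = character(0),
                          at_fraction = numeric(0), n_palindromes = integer(0),
                          max_hairpin_pairs = integer(0),
                          centered_palindrome_in_each_unit = logical(0),
                          classification = character(0),
                          left_orf = integer(0), right_orf = integer(0),
                          genome_start = integer(0), genome_end = integer(0))
  }
  tibble::new_tibble(out, class = "repeat_region_table")
}
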