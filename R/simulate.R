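#' Simulation configuration
#'
#' Describes a synthetic circular genome in the style of a betabaculovirus:
#' densely packed ATG-initiated ORFs on both strands with occasional small
#' overlaps, an AT-rich background (default G+C 37.8%), and planted promoter
#' motifs. All quantities are drawn deterministically from `seed`.
#'
#' @param genome_len Genome length in nt (default 60000; betabaculovirus
#'   genomes run 80-180 kb, scaled down so a full test cycle stays fast).
#' @param n_orfs Number of planted ORFs (default 60).
#' @param gc_target Background G+C fraction (default 0.378).
#' @param orf_len_range ORF length range in nt, stop included (default
#'   `c(300, 1500)`).
#' @param overlap_prob Probability that consecutive ORFs overlap by a small
#'   amount (default 0.15; overlaps are drawn in 3..45 nt, well under the 50%
#'   selection cap).
#' @param late_frac,early_frac Fractions of eligible ORFs given a planted late
#'   (TAAG) or early (TATA + initiator) promoter (defaults 0.5 and 0.3).
#' @param min_gap Minimum intergenic gap at non-overlapping junctions (default
#'   45 nt; leaves room for the in-frame guard stop and a late promoter motif
#'   even when the packing is tight).
#' @param big_spacer_extra Extra lengths added to two designated intergenic
#'   gaps (default `c(900, 550)`), emulating the large spacers in which
#'   granulovirus non-hr repeat regions sit; repeat arrays are planted there.
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_len = 60000L, n_orfs = 60L, gc_target = 0.378,
                       orf_len_range = c(300L, 1500L), overlap_prob = 0.15,
                       late_frac = 0.5, early_frac = 0.3, min_gap = 45L,
                       big_spacer_extra = c(900L, 550L), seed = 1L) {
  cfg <- list(genome_len = as.integer(genome_len), n_orfs = as.integer(n_orfs),
              gc_target = gc_target, orf_len_range = as.integer(orf_len_range),
              overlap_prob = overlap_prob, late_frac = late_frac,
              early_frac = early_frac, min_gap = as.integer(min_gap),
              big_spacer_extra = as.integer(big_spacer_extra),
              seed = as.integer(seed))
  if (cfg$gc_target < 0 || cfg$gc_target > 1 || cfg$overlap_prob < 0 ||
      cfg$overlap_prob > 1) {
    stop("sim_config fractions must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_orfs * cfg$orf_len_range[1] + cfg$n_orfs * cfg$min_gap > cfg$genome_len) {
    stop("infeasible sim_config: planted ORFs cannot fit in the genome", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

random_bases <- function(n, gc) {
  sample(BASES, n, replace = TRUE, prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# Excluding stop codons from base-wise draws biases the realized GC upward
# (the excluded codons are AT-rich). Solve for the base-level GC that yields
# the target GC after stop rejection.
adjust_gc_for_stops <- function(target) {
  realized <- function(g) {
    t <- (1 - g) / 2
    c <- g / 2
    ps <- t^3 + 2 * t^2 * c        # P(TAA) + P(TAG) + P(TGA)
    sgc <- 2 * t^2 * c             # expected GC bases landing in stop draws
    (3 * g - sgc) / (3 * (1 - ps))
  }
  stats::uniroot(function(g) realized(g) - target, c(0.01, 0.99),
                 tol = 1e-9)$root
}

# random coding interior: codons drawn base-wise at the GC target, stop codons
# rejected and redrawn
random_codons <- function(n_codons, gc) {
  if (n_codons == 0L) return(character(0))
  draw <- function(k) {
    m <- matrix(random_bases(3L * k, gc), nrow = 3L)
    paste0(m[1, ], m[2, ], m[3, ])
  }
  cod <- draw(n_codons)
  repeat {
    bad <- which(cod %in% STOP_CODONS)
    if (length(bad) == 0L) break
    cod[bad] <- draw(length(bad))
  }
  cod
}

# genomic positions of the m-th codon upstream of an ORF's ATG, in coding
# orientation (m = 1 is the codon immediately 5' of the ATG)
upstream_codon_pos <- function(orf, m, L) {
  if (orf$strand == "+") {
    mod1(orf$start - 3L * m + 0:2, L)
  } else {
    mod1(orf$start + 3L * m - 0:2, L)
  }
}

# genomic position of upstream coding-strand offset t (t = 1 is the base
# immediately 5' of the ATG)
upstream_pos <- function(orf, t, L) {
  if (orf$strand == "+") mod1(orf$start - t, L) else mod1(orf$start + t, L)
}

# pos is in coding (5'->3') order; for '-' each base is complemented in place
codon_from_chars <- function(chars, pos, strand) {
  if (strand == "+") {
    paste(chars[pos], collapse = "")
  } else {
    paste(COMPLEMENT[chars[pos]], collapse = "")
  }
}

# write a codon at coding-order positions
write_codon <- function(chars, pos, codon, strand) {
  ch <- strsplit(codon, "", fixed = TRUE)[[1]]
  if (strand == "+") {
    chars[pos] <- ch
  } else {
    chars[pos] <- unname(COMPLEMENT[ch])
  }
  chars
}

#' Simulate an annotated circular genome with a full truth table
#'
#' Plants `n_orfs` ATG-initiated ORFs around a circle on both strands (the
#' first ORF is the plus-strand anchor at position 1, mimicking the granulin
#' convention), with configurable small overlaps, an in-frame stop guard
#' immediately upstream of each non-overlapped ORF (so the maximal-ORF
#' convention recovers the planted start), promoter motifs in intergenic gaps,
#' and an i.i.d. background at the GC target. The emitted truth table is
#' verified against the package's own annotation (`verify = TRUE`): every
#' planted ORF must be recovered exactly, else the packing is retried with a
#' perturbed layout and eventually an error is thrown.
#'
#' @param config A [sim_config()].
#' @param verify Check truth recoverability via the annotation pipeline
#'   (default `TRUE`).
#' @param max_attempts Packing retries before giving up (default 5).
#' @return A list of class `sim_genome`: `genome` (a [circular_genome()]) and
#'   `truth` (list: `orfs`, `promoters`, `repeats`, `protected` intervals).
#' @export
simulate_annotated_genome <- function(config = sim_config(), verify = TRUE,
                                      max_attempts = 5L) {
  for (attempt in seq_len(max_attempts)) {
    set.seed(config$seed + 7919L * (attempt - 1L))
    sim <- try(simulate_once(config), silent = TRUE)
    if (inherits(sim, "try-error")) next
    if (!verify || truth_recoverable(sim)) return(sim)
  }
  stop("infeasible packing: could not build a self-consistent simulated genome",
       call. = FALSE)
}

simulate_once <- function(config) {
  L <- config$genome_len
  n <- config$n_orfs
  lens <- 3L * sample(seq(config$orf_len_range[1] %/% 3L,
                          config$orf_len_range[2] %/% 3L), n, replace = TRUE)
  # Overlapping junctions use canonical frame-compatible patterns so that both
  # reading frames stay intact where the ORFs share sequence:
  #   pp: +/+ head-on-tail, shared ATGA (next ORF's ATG inside TGA stop), 4 nt
  #   mm: -/- mirror of pp, shared TCAT, 4 nt
  #   mp: -/+ head-to-head, shared AT (the two start codons abut), 2 nt
  strands <- character(n)
  strands[1] <- "+"
  jtype <- rep("gap", n) # type of the junction AFTER orf k (n = wrap, always gap)
  ov <- integer(n - 1L)
  want_overlap <- stats::runif(n - 1L) < config$overlap_prob
  for (k in seq_len(n - 1L)) {
    if (want_overlap[k]) {
      if (strands[k] == "+") {
        jtype[k] <- "pp"; strands[k + 1L] <- "+"; ov[k] <- 4L
      } else if (stats::runif(1) < 0.5) {
        jtype[k] <- "mm"; strands[k + 1L] <- "-"; ov[k] <- 4L
      } else {
        jtype[k] <- "mp"; strands[k + 1L] <- "+"; ov[k] <- 2L
      }
    } else {
      strands[k + 1L] <- sample(c("+", "-"), 1L)
    }
  }
  n_gaps <- sum(ov == 0L) + 1L
  big <- config$big_spacer_extra
  extra_total <- L - sum(lens) + sum(ov) - n_gaps * config$min_gap - sum(big)
  # if the drawn lengths oversum, shrink the longest ORFs (in codon steps)
  # until the layout fits
  while (extra_total < 0L) {
    i <- which.max(lens)
    red <- min(lens[i] - config$orf_len_range[1],
               3L * as.integer(ceiling(-extra_total / 3)))
    if (red <= 0L) stop("infeasible packing for this configuration", call. = FALSE)
    lens[i] <- lens[i] - red
    extra_total <- extra_total + red
  }
  extra <- as.integer(stats::rmultinom(1, extra_total, rep(1, n_gaps)))
  # widen two interior gaps into large spacers (repeat-region real estate)
  open_gaps <- which(c(ov == 0L, TRUE))
  if (length(big) > 0 && length(open_gaps) >= length(big) + 2L) {
    picks <- open_gaps[round(length(open_gaps) * seq_along(big) / (length(big) + 1L))]
  } else {
    picks <- integer(0)
  }
  gaps <- integer(n) # gap AFTER orf k (gap n wraps back to orf 1)
  gi <- 1L
  for (k in seq_len(n)) {
    if (k == n || ov[k] == 0L) {
      gaps[k] <- config$min_gap + extra[gi]
      gi <- gi + 1L
    } else {
      gaps[k] <- -ov[k]
    }
  }
  for (b in seq_along(picks)) gaps[picks[b]] <- gaps[picks[b]] + big[b]

  fp_start <- integer(n)
  fp_end <- integer(n)
  fp_start[1] <- 1L
  for (k in seq_len(n)) {
    fp_end[k] <- fp_start[k] + lens[k] - 1L
    if (k < n) fp_start[k + 1L] <- fp_end[k] + gaps[k] + 1L
  }
  if (fp_end[n] + gaps[n] != L) {
    stop("internal packing arithmetic error", call. = FALSE)
  }

  chars <- random_bases(L, config$gc_target)
  gc_cod <- adjust_gc_for_stops(config$gc_target)
  jbefore <- c("gap", jtype[seq_len(n - 1L)]) # junction before orf k (genomic)
  jafter <- jtype                             # junction after orf k (genomic)
  for (k in seq_len(n)) {
    n_cod <- lens[k] %/% 3L
    interior <- random_codons(n_cod - 2L, gc_cod)
    stop_cod <- sample(STOP_CODONS, 1L)
    if (strands[k] == "+") {
      # stop sits at the after-junction; ATG at the before-junction
      if (jafter[k] == "pp") {
        stop_cod <- "TGA"
        # overwritten 3rd base becomes 'A'; first base must not be T
        repeat {
          c3 <- random_codons(1L, gc_cod)
          if (substr(c3, 1, 1) != "T") break
        }
        interior[length(interior)] <- c3
      }
      if (jbefore[k] == "pp") {
        # first interior codon's first base is the shared 'A' of the TGA stop
        repeat {
          c1 <- random_codons(1L, gc_cod)
          if (substr(c1, 1, 1) == "A") break
        }
        interior[1] <- c1
      }
    } else {
      # '-' ORF: stop sits at the before-junction; ATG at the after-junction
      if (jbefore[k] == "mm") {
        stop_cod <- "TGA"
        repeat {
          c3 <- random_codons(1L, gc_cod)
          if (substr(c3, 3, 3) == "A") break
        }
        interior[length(interior)] <- c3
      }
    }
    cds <- paste(c("ATG", interior, stop_cod), collapse = "")
    if (strands[k] == "+") {
      chars[fp_start[k]:fp_end[k]] <- strsplit(cds, "", fixed = TRUE)[[1]]
    } else {
      chars[fp_start[k]:fp_end[k]] <-
        strsplit(reverse_complement(cds), "", fixed = TRUE)[[1]]
    }
  }

  orfs <- tibble::tibble(
    rank = seq_len(n),
    start = ifelse(strands == "+", fp_start, fp_end),
    end = ifelse(strands == "+", fp_end, fp_start),
    strand = strands,
    length_nt = lens,
    fp_start = fp_start, fp_end = fp_end
  )

  # For a '+' ORF the 5' flank (guard stop + promoters) lies in the junction
  # BEFORE it in genomic order; for a '-' ORF it is the junction AFTER it.
  upstream_junction <- ifelse(strands == "+", c(n, seq_len(n - 1L)), seq_len(n))
  upstream_gap <- ifelse(jtype[upstream_junction] == "gap",
                         gaps[upstream_junction], 0L)

  protected <- list()
  prot_vec <- integer(0)
  for (k in seq_len(n)) {
    if (upstream_gap[k] < 3L) next
    o <- orfs[k, ]
    pos <- upstream_codon_pos(o, 1L, L) # coding order
    chars <- write_codon(chars, pos, "TAA", o$strand)
    protected[[length(protected) + 1L]] <- pos
    prot_vec <- c(prot_vec, pos)
  }

  # promoter planting in sufficiently large upstream gaps
  promoters <- list()
  for (k in seq_len(n)) {
    if (upstream_gap[k] < 45L) next
    o <- orfs[k, ]
    avail <- upstream_gap[k] - 3L # offsets 1..3 hold the guard stop
    write_motif <- function(q, motif) {
      ch <- strsplit(motif, "", fixed = TRUE)[[1]]
      pos <- vapply(seq_along(ch) - 1L, function(d) upstream_pos(o, q - d, L),
                    integer(1))
      if (any(pos %in% prot_vec)) return(NULL)
      for (d in seq_along(ch)) {
        chars[pos[d]] <<- if (o$strand == "+") ch[d] else COMPLEMENT[[ch[d]]]
      }
      pos
    }
    if (stats::runif(1) < config$late_frac) {
      q <- sample(8:min(40L, 3L + avail), 1L)
      pos <- write_motif(q, "TAAG")
      if (!is.null(pos)) {
        promoters[[length(promoters) + 1L]] <- tibble::tibble(
          rank = k, kind = "late", position = q, motif = "TAAG")
        protected[[length(protected) + 1L]] <- pos
        prot_vec <- c(prot_vec, pos)
      }
    }
    if (avail >= 110L && stats::runif(1) < config$early_frac) {
      g <- sample(20:40, 1L)
      q2 <- sample(48:60, 1L) # initiator start offset
      q1 <- q2 + 4L + g       # TATA start offset
      if (q1 <= min(147L, 3L + avail)) {
        init <- sample(c("CAGT", "CATT"), 1L)
        p1 <- write_motif(q1, "TATA")
        p2 <- if (!is.null(p1)) write_motif(q2, init) else NULL
        if (!is.null(p1) && !is.null(p2)) {
          promoters[[length(promoters) + 1L]] <- tibble::tibble(
            rank = k, kind = "early", position = q1,
            motif = paste0("TATA..", init))
          protected[[length(protected) + 1L]] <- c(p1, p2)
          prot_vec <- c(prot_vec, p1, p2)
        }
      }
    }
  }
  promoters <- if (length(promoters)) dplyr::bind_rows(promoters) else
    tibble::tibble(rank = integer(0), kind = character(0),
                   position = integer(0), motif = character(0))

  sim <- list(
    genome = NULL,
    truth = list(orfs = orfs, promoters = promoters,
                 repeats = tibble::tibble(), protected = protected)
  )
  chars <- fix_upstream_atgs(chars, orfs, protected, L)
  genome <- circular_genome(paste(chars, collapse = ""), id = "sim", topology = "circular")
  orfs$protein <- extract_truth_proteins(genome, orfs)
  orfs$length_aa <- orfs$length_nt %/% 3L - 1L
  sim$genome <- genome
  sim$truth$orfs <- orfs
  class(sim) <- "sim_genome"
  sim
}

extract_truth_proteins <- function(genome, orfs) {
  cds <- purrr::pmap_chr(list(orfs$fp_start, orfs$fp_end, orfs$strand),
                         function(s, e, st) circular_subsequence(genome, s, e, st))
  translate_cds(cds)
}

# Walk upstream in frame from each planted ATG; if an ATG appears before the
# first in-frame stop, the maximal-ORF convention would move the start, so the
# offending codon is mutated away under coding constraints.
fix_upstream_atgs <- function(chars, orfs, protected, L, max_steps = 400L) {
  prot <- if (length(protected)) unique(unlist(protected)) else integer(0)
  for (k in seq_len(nrow(orfs))) {
    o <- orfs[k, ]
    for (pass in 1:10) {
      offend <- NULL
      for (m in seq_len(max_steps)) {
        pos <- upstream_codon_pos(o, m, L) # coding order
        cod <- codon_from_chars(chars, pos, o$strand)
        if (cod %in% STOP_CODONS) break
        if (cod == "ATG") { offend <- pos; break }
      }
      if (is.null(offend)) break
      chars <- mutate_destroy_atg(chars, offend, o$strand, orfs, prot, L)
      if (is.null(chars)) stop("could not repair an upstream ATG", call. = FALSE)
    }
  }
  chars
}

# Change one base of the offending codon so it is no longer ATG (and not a
# stop in the offended frame), without breaking any planted ORF covering it.
mutate_destroy_atg <- function(chars, pos3, offended_strand, orfs, prot, L) {
  for (pi in seq_along(pos3)) {
    p <- pos3[pi]
    if (p %in% prot) next
    for (b in BASES) {
      if (b == chars[p]) next
      new_chars <- chars
      new_chars[p] <- b
      new_cod <- codon_from_chars(new_chars, pos3, offended_strand)
      if (!new_cod %in% c("ATG", STOP_CODONS) &&
          codon_valid_everywhere(new_chars, p, orfs, L)) {
        return(new_chars)
      }
    }
  }
  NULL
}

codon_valid_everywhere <- function(chars, p, orfs, L) {
  for (k in seq_len(nrow(orfs))) {
    o <- orfs[k, ]
    inside <- if (o$fp_start <= o$fp_end) {
      p >= o$fp_start && p <= o$fp_end
    } else {
      p >= o$fp_start || p <= o$fp_end
    }
    if (!inside) next
    # codon index within the ORF (0-based from the ATG)
    offset <- if (o$strand == "+") {
      (p - o$fp_start) %% L
    } else {
      (o$fp_end - p) %% L
    }
    ci <- offset %/% 3L
    n_cod <- o$length_nt %/% 3L
    if (ci == 0L || ci == n_cod - 1L) return(FALSE) # ATG or stop codon touched
    cod_pos <- if (o$strand == "+") {
      mod1(o$fp_start + 3L * ci + 0:2, L)
    } else {
      mod1(o$fp_end - 3L * ci - 0:2, L)
    }
    cod <- codon_from_chars(chars, cod_pos, o$strand)
    if (cod %in% STOP_CODONS) return(FALSE)
  }
  TRUE
}

# The generator's contract: the package's own annotation recovers every
# planted ORF exactly.
truth_recoverable <- function(sim) {
  cand <- enumerate_candidate_orfs(sim$genome, annotation_config())
  sel <- resolve_minimal_overlap(cand, annotation_config(), sim$genome$length)
  key <- paste(sel$start, sel$end, sel$strand)
  all(paste(sim$truth$orfs$start, sim$truth$orfs$end, sim$truth$orfs$strand) %in% key)
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("<sim_genome> %d nt, %d planted ORFs, %d planted promoters, %d repeat regions\n",
              x$genome$length, nrow(x$truth$orfs), nrow(x$truth$promoters),
              nrow(x$truth$repeats)))
  invisible(x)
}

#' Plant a tandem repeat region into an intergenic position
#'
#' Overwrites part of an intergenic spacer with `n_copies` of a randomly drawn
#' repeat unit at the requested AT composition, mutating each copy at
#' `mismatch_rate` per base; optionally appends a truncated half-copy and
#' plants a palindrome (centered in each unit for hr-style arrays, or
#' immediately adjacent for non-hr style). Truth records the exact
#' coordinates.
#'
#' @param sim A `sim_genome`.
#' @param unit_len Repeat unit length in nt.
#' @param n_copies Number of full copies.
#' @param mismatch_rate Per-base substitution rate applied to each copy.
#' @param at_fraction AT composition of the unit (default 0.74).
#' @param truncated Append a half-copy (default `TRUE`).
#' @param palindrome `"none"`, `"adjacent"` or `"centered"`.
#' @param position Genome coordinate of the region start; must lie in an
#'   intergenic spacer (error otherwise).
#' @param seed Integer seed.
#' @return The updated `sim_genome`.
#' @export
plant_repeat_region <- function(sim, unit_len, n_copies, mismatch_rate = 0.1,
                                at_fraction = 0.74, truncated = TRUE,
                                palindrome = c("adjacent", "centered", "none"),
                                position, seed = 1L) {
  palindrome <- match.arg(palindrome)
  stopifnot(inherits(sim, "sim_genome"))
  set.seed(as.integer(seed))
  L <- sim$genome$length
  unit_len <- as.integer(unit_len)
  trunc_len <- if (truncated) as.integer(ceiling(unit_len * 0.5)) else 0L
  pal_arm <- 10L
  pal_loop <- 4L
  pal_len <- 2L * pal_arm + pal_loop
  total <- n_copies * unit_len + trunc_len +
    if (palindrome == "adjacent") pal_len + 2L else 0L

  # every copy opens with an AT-rich cassette holding stop codons in all six
  # frames (TAA at three consecutive frame offsets on both strands), so the
  # array cannot spawn spurious long ORFs
  cassette <- strsplit("TAATTAATTAA", "", fixed = TRUE)[[1]]
  if (unit_len < length(cassette) + 4L) {
    stop("repeat unit too short (need >= 15 nt)", call. = FALSE)
  }
  unit <- random_bases(unit_len, gc = 1 - at_fraction)
  unit[seq_along(cassette)] <- cassette
  frozen <- seq_along(cassette)
  if (palindrome == "centered") {
    arm <- random_bases(pal_arm, gc = 1 - at_fraction)
    ins <- c(arm, random_bases(pal_loop, gc = 1 - at_fraction),
             strsplit(reverse_complement(paste(arm, collapse = "")), "")[[1]])
    at <- max(length(cassette) + 1L, (unit_len - length(ins)) %/% 2L + 1L)
    if (at + length(ins) - 1L > unit_len) {
      stop("repeat unit too short for a centered palindrome", call. = FALSE)
    }
    unit[at:(at + length(ins) - 1L)] <- ins
  } else {
    # a unit with a palindrome at its center IS the hr architecture, and
    # AT-rich sequence grows palindromes by chance; scrub the unit's middle so
    # the array stays architecturally non-hr
    scrub_cfg <- repeat_config(min_palindrome_arm = 7L)
    for (iter in 1:50) {
      pals <- find_palindromes(paste(unit, collapse = ""), scrub_cfg)
      ctr <- (pals$start + pals$end) / 2
      bad <- which(ctr >= 0.22 * unit_len & ctr <= 0.78 * unit_len)
      if (length(bad) == 0L) break
      p <- pals[bad[1], ]
      # break complementarity at an arm position outside the frozen cassette
      cand <- setdiff(c(p$end - seq_len(p$arm_len) + 1L, p$start + seq_len(p$arm_len) - 1L),
                      frozen)
      cand <- cand[cand >= 1L & cand <= unit_len]
      if (length(cand) == 0L) break
      i <- cand[1]
      j <- p$start + p$end - i # the base it pairs with
      repl <- setdiff(c("A", "T"), c(unit[i], COMPLEMENT[[unit[min(max(j, 1L), unit_len)]]]))
      if (length(repl) == 0L) repl <- setdiff(BASES, unit[i])
      unit[i] <- repl[1]
    }
  }
  mutate_copy <- function(u) {
    hit <- stats::runif(length(u)) < mismatch_rate
    hit[frozen] <- FALSE
    u[hit] <- vapply(u[hit], function(b) sample(setdiff(BASES, b), 1L), character(1))
    u
  }
  body <- unlist(lapply(seq_len(n_copies), function(i) mutate_copy(unit)))
  if (trunc_len > 0L) body <- c(body, mutate_copy(unit)[seq_len(trunc_len)])
  if (palindrome == "adjacent") {
    arm <- random_bases(pal_arm, gc = 1 - at_fraction)
    pal <- c(arm, random_bases(pal_loop, gc = 1 - at_fraction),
             strsplit(reverse_complement(paste(arm, collapse = "")), "")[[1]])
    body <- c(body, c("T", "T"), pal)
  }

  idx <- mod1(seq.int(position, length.out = length(body)), L)
  # the whole region must be intergenic
  for (k in seq_len(nrow(sim$truth$orfs))) {
    o <- sim$truth$orfs[k, ]
    iv <- fp_positions(o$fp_start, o$fp_end, L)
    if (any(idx %in% iv)) {
      stop("repeat region position overlaps a planted ORF", call. = FALSE)
    }
  }
  prot <- unique(unlist(sim$truth$protected))
  if (any(idx %in% prot)) {
    stop("repeat region position overlaps a guard stop or planted promoter motif",
         call. = FALSE)
  }
  chars <- strsplit(sim$genome$seq, "", fixed = TRUE)[[1]]
  chars[idx] <- body
  sim$genome <- circular_genome(paste(chars, collapse = ""), id = sim$genome$id,
                                topology = "circular")
  sim$truth$orfs$protein <- extract_truth_proteins(sim$genome, sim$truth$orfs)
  rep_row <- tibble::tibble(
    start = mod1(position, L),
    end = idx[n_copies * unit_len + trunc_len],
    unit_len = unit_len, n_copies = as.integer(n_copies),
    truncated = trunc_len > 0L, at_fraction = at_fraction,
    palindrome = palindrome,
    unit_consensus = paste(unit, collapse = "")
  )
  sim$truth$repeats <- dplyr::bind_rows(sim$truth$repeats, rep_row)
  sim$truth$protected <- c(sim$truth$protected, list(idx))
  sim
}

#' Evolve a simulated genome into a diverged relative
#'
#' Coding regions are mutated codon-wise: each interior codon is replaced,
#' with probability `aa_divergence`, by a codon for a different amino acid
#' (never a stop), so the expected per-site protein divergence equals
#' `aa_divergence`. Codons inside overlaps of two planted ORFs are left
#' untouched to keep both frames valid. Listed rank blocks are then
#' reverse-complemented in place (a genome-segment inversion). The child truth
#' carries the updated coordinates, the parent-child ortholog map and the
#' inversion boundaries.
#'
#' @param sim A `sim_genome` (the parent).
#' @param aa_divergence Per-site amino-acid substitution probability.
#' @param inversion_blocks List of rank ranges `c(first, last)` to invert;
#'   blocks must not overlap and must not start at rank 1 (the anchor stays
#'   put).
#' @param seed Integer seed.
#' @param verify Re-check truth recoverability; if a mutation draw breaks it,
#'   the draw is retried deterministically before giving up (default `TRUE`).
#' @param max_attempts Mutation-draw retries (default 5).
#' @return A `sim_genome` with `truth$orthologs` (`parent_rank`, `child_rank`,
#'   `same_strand`) and `truth$inversions`.
#' @export
evolve_genome <- function(sim, aa_divergence = 0.2, inversion_blocks = NULL,
                          seed = 1L, verify = TRUE, max_attempts = 5L) {
  for (attempt in seq_len(max_attempts)) {
    child <- evolve_once(sim, aa_divergence, inversion_blocks,
                         as.integer(seed) + 7919L * (attempt - 1L))
    if (!verify || truth_recoverable(child)) return(child)
  }
  stop("evolved genome lost truth recoverability; use a different seed",
       call. = FALSE)
}

evolve_once <- function(sim, aa_divergence, inversion_blocks, seed) {
  stopifnot(inherits(sim, "sim_genome"))
  if (length(inversion_blocks) > 1) {
    rngs <- do.call(rbind, inversion_blocks)
    rngs <- rngs[order(rngs[, 1]), , drop = FALSE]
    if (any(rngs[-1, 1] <= rngs[-nrow(rngs), 2])) {
      stop("inversion blocks overlap", call. = FALSE)
    }
  }
  set.seed(as.integer(seed))
  L <- sim$genome$length
  chars <- strsplit(sim$genome$seq, "", fixed = TRUE)[[1]]
  orfs <- sim$truth$orfs

  # positions covered by >1 ORF are frozen
  cover <- integer(L)
  for (k in seq_len(nrow(orfs))) {
    iv <- fp_positions(orfs$fp_start[k], orfs$fp_end[k], L)
    cover[iv] <- cover[iv] + 1L
  }

  for (k in seq_len(nrow(orfs))) {
    o <- orfs[k, ]
    n_cod <- o$length_nt %/% 3L
    for (ci in seq_len(n_cod - 2L)) { # interior codons only
      if (stats::runif(1) >= aa_divergence) next
      cod_pos <- if (o$strand == "+") {
        mod1(o$fp_start + 3L * ci + 0:2, L)
      } else {
        mod1(o$fp_end - 3L * ci - 0:2, L)
      }
      if (any(cover[cod_pos] > 1L)) next
      old <- codon_from_chars(chars, cod_pos, o$strand)
      old_aa <- GENETIC_CODE_TABLE[[old]]
      new <- sample(NONSTOP_CODONS, 1L)
      tries <- 0L
      while (GENETIC_CODE_TABLE[[new]] == old_aa && tries < 20L) {
        new <- sample(NONSTOP_CODONS, 1L)
        tries <- tries + 1L
      }
      if (GENETIC_CODE_TABLE[[new]] == old_aa) next
      chars <- write_codon(chars, cod_pos, new, o$strand)
    }
  }

  inversions <- tibble::tibble(first_rank = integer(0), last_rank = integer(0),
                               seg_start = integer(0), seg_end = integer(0))
  for (blk in inversion_blocks) {
    r1 <- blk[1]; r2 <- blk[2]
    if (r1 <= 1L) stop("inversion block may not include the anchor gene", call. = FALSE)
    if (r2 >= nrow(orfs)) stop("inversion block may not reach the last gene", call. = FALSE)
    if (orfs$fp_start[r1] <= orfs$fp_end[r1 - 1L] ||
        orfs$fp_start[r2 + 1L] <= orfs$fp_end[r2]) {
      stop("inversion block boundary lies inside an ORF overlap; pick ranks at clean junctions",
           call. = FALSE)
    }
    a <- orfs$fp_start[r1]
    b <- orfs$fp_end[r2]
    if (a > b) stop("inversion segment may not wrap the origin", call. = FALSE)
    seg <- strsplit(reverse_complement(paste(chars[a:b], collapse = "")), "",
                    fixed = TRUE)[[1]]
    chars[a:b] <- seg
    inside <- orfs$rank >= r1 & orfs$rank <= r2
    mirror <- function(p) a + b - p
    orfs$start[inside] <- mirror(orfs$start[inside])
    orfs$end[inside] <- mirror(orfs$end[inside])
    orfs$strand[inside] <- ifelse(orfs$strand[inside] == "+", "-", "+")
    fp <- orf_fp(orfs$start, orfs$end, orfs$strand)
    orfs$fp_start <- as.integer(fp$fp_start)
    orfs$fp_end <- as.integer(fp$fp_end)
    # planted promoters of inverted ORFs sit upstream of the old start; they
    # no longer apply after the flip
    sim$truth$promoters <- sim$truth$promoters[
      !(sim$truth$promoters$rank %in% orfs$rank[inside]), ]
    inversions <- dplyr::bind_rows(inversions, tibble::tibble(
      first_rank = r1, last_rank = r2, seg_start = a, seg_end = b))
  }

  # inversion-boundary ORFs lose their planted guard stop; repair any upstream
  # in-frame ATG that would shift the annotated start
  prot <- sim$truth$protected
  if (nrow(inversions) > 0) {
    inside_seg <- function(p) any(p >= inversions$seg_start & p <= inversions$seg_end)
    prot <- purrr::keep(prot, function(pp) !any(vapply(pp, inside_seg, logical(1))))
  }
  chars <- fix_upstream_atgs(chars, orfs, prot, L)

  genome <- circular_genome(paste(chars, collapse = ""), id = paste0(sim$genome$id, "_desc"),
                            topology = "circular")
  orfs <- dplyr::arrange(orfs, .data$fp_start)
  child_rank <- seq_len(nrow(orfs))
  ortho <- tibble::tibble(parent_rank = orfs$rank, child_rank = child_rank,
                          same_strand = orfs$strand ==
                            sim$truth$orfs$strand[match(orfs$rank, sim$truth$orfs$rank)])
  orfs$rank <- child_rank
  orfs$protein <- extract_truth_proteins(genome, orfs)

  child <- structure(list(
    genome = genome,
    truth = list(orfs = orfs,
                 promoters = sim$truth$promoters,
                 repeats = sim$truth$repeats,
                 protected = sim$truth$protected,
                 orthologs = ortho,
                 inversions = inversions)
  ), class = "sim_genome")
  child
}

GENETIC_CODE_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  as.list(gc)
})

NONSTOP_CODONS <- names(GENETIC_CODE_TABLE)[unlist(GENETIC_CODE_TABLE) != "*"]

#' Simulate a small genome family with known relationships
#'
#' Builds an ancestor with two planted repeat regions (one non-hr style with 2
#' copies + truncated, one with 7 copies + truncated, echoing the two-spacer
#' architecture of granulovirus non-hr origins), then evolves two descendants:
#' one collinear, one carrying a planted inversion block.
#'
#' @param config A [sim_config()].
#' @param aa_divergence Divergence for both descendants (default 0.15).
#' @param inversion_block Rank range inverted in the second descendant
#'   (default `c(20, 31)`, a 12-gene block).
#' @param seed Integer seed.
#' @return List of class `sim_family`: `ancestor`, `collinear`, `inverted`.
#' @export
simulate_genome_family <- function(config = sim_config(),
                                   aa_divergence = 0.15,
                                   inversion_block = c(20L, 31L),
                                   seed = config$seed) {
  anc <- simulate_annotated_genome(config)
  # plant the two repeat regions into the two largest gaps, clear of any
  # guard stop or promoter motif already sitting in the gap
  gaps <- truth_spacers(anc)
  gaps <- gaps[order(-gaps$length), ]
  prot <- unique(unlist(anc$truth$protected))
  pick_pos <- function(gs) {
    if (any(prot >= gs & prot <= gs + 154L)) gs + 158L else gs + 5L
  }
  if (nrow(gaps) >= 1 && gaps$length[1] >= 780) {
    anc <- plant_repeat_region(anc, unit_len = 55L, n_copies = 7L,
                               mismatch_rate = 0.08, at_fraction = 0.66,
                               truncated = TRUE, palindrome = "adjacent",
                               position = pick_pos(gaps$start[1]),
                               seed = seed + 11L)
  }
  if (nrow(gaps) >= 2 && gaps$length[2] >= 480) {
    anc <- plant_repeat_region(anc, unit_len = 45L, n_copies = 2L,
                               mismatch_rate = 0.08, at_fraction = 0.74,
                               truncated = TRUE, palindrome = "adjacent",
                               position = pick_pos(gaps$start[2]),
                               seed = seed + 13L)
  }
  if (!truth_recoverable(anc)) {
    stop("repeat planting broke ORF recoverability; use a different seed",
         call. = FALSE)
  }
  collinear <- evolve_genome(anc, aa_divergence = aa_divergence,
                             inversion_blocks = NULL, seed = seed + 101L)
  # shift the requested block to the nearest clean (non-overlapping) junctions
  o <- dplyr::arrange(anc$truth$orfs, .data$rank)
  clean_before <- function(r) r >= 2L && r <= nrow(o) &&
    o$fp_start[r] > o$fp_end[r - 1L]
  shift_to_clean <- function(r, dir) {
    for (d in 0:6) {
      for (s in unique(c(d, -d))) {
        if (clean_before(r + s * dir)) return(r + s * dir)
      }
    }
    stop("no clean inversion boundary near the requested ranks", call. = FALSE)
  }
  r1 <- shift_to_clean(inversion_block[1], 1L)
  r2c <- shift_to_clean(inversion_block[2] + 1L, -1L) - 1L
  inverted <- evolve_genome(anc, aa_divergence = aa_divergence,
                            inversion_blocks = list(c(r1, r2c)),
                            seed = seed + 202L)
  structure(list(ancestor = anc, collinear = collinear, inverted = inverted),
            class = "sim_family")
}

# intergenic gaps of a sim truth (before annotation exists); `length` is the
# full gap, of which only the upstream part is plantable (guards and promoter
# motifs occupy the downstream ~150 nt)
truth_spacers <- function(sim) {
  L <- sim$genome$length
  o <- dplyr::arrange(sim$truth$orfs, .data$fp_start)
  n <- nrow(o)
  nxt <- c(seq_len(n)[-1], 1L)
  gap_len <- (o$fp_start[nxt] - o$fp_end[seq_len(n)] - 2L) %% L + 1L
  out <- tibble::tibble(start = mod1(o$fp_end + 1L, L),
                        end = mod1(o$fp_start[nxt] - 1L, L),
                        length = as.integer(gap_len))
  dplyr::filter(out, .data$length > 0L, .data$length < L %/% 2L)
}

#' Annotate a simulated genome with its planted anchor
#'
#' Convenience: runs [annotate_genome()] anchored at the planted first ORF's
#' protein, so ORF numbering matches the truth ranks when all planted ORFs are
#' recovered and no extra ORF survives selection before the anchor.
#'
#' @param sim A `sim_genome`.
#' @param config An [annotation_config()].
#' @return A `genome_annotation`.
#' @export
annotate_sim <- function(sim, config = annotation_config()) {
  stopifnot(inherits(sim, "sim_genome"))
  annotate_genome(sim$genome, config,
                  anchor_protein = sim$truth$orfs$protein[sim$truth$orfs$rank == 1L])
}
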