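test_that("intergenic spacers complement the ORF footprints, wrap included", {
  g <- circular_genome(random_dna(300))
  orfs <- tibble::tibble(
    orf_id = 1:2, start = c(1L, 151L), end = c(100L, 300L), strand = "+",
    length_nt = c(100L, 150L), length_aa = c(32L, 49L), protein = "M",
    fp_start = c(1L, 151L), fp_end = c(100L, 300L), wraps = FALSE)
  ann <- structure(list(genome = g, orfs = orfs, anchor_orf_id = 1L,
                        config = annotation_config()),
                   class = "genome_annotation")
  sp <- intergenic_spacers(ann)
  expect_equal(nrow(sp), 1L)
  expect_equal(c(sp$start, sp$end), c(101L, 150L))
  expect_equal(c(sp$left_orf, sp$right_orf), c(1L, 2L))

  # fully coding genome -> no spacers
  orfs2 <- orfs
  orfs2$end[2] <- 300L; orfs2$fp_end[2] <- 300L
  orfs2$start[2] <- 101L; orfs2$fp_start[2] <- 101L
  ann2 <- ann; ann2$orfs <- orfs2
  expect_equal(nrow(intergenic_spacers(ann2)), 0L)

  # a gap spanning the origin is merged into one wrap spacer
  orfs3 <- tibble::tibble(
    orf_id = 1L, start = 51L, end = 250L, strand = "+", length_nt = 200L,
    length_aa = 65L, protein = "M", fp_start = 51L, fp_end = 250L, wraps = FALSE)
  ann3 <- ann; ann3$orfs <- orfs3
  sp3 <- intergenic_spacers(ann3)
  expect_equal(nrow(sp3), 1L)
  expect_equal(c(sp3$start, sp3$end, sp3$length), c(251L, 50L, 100L))
})

test_that("a perfect tandem array is reported with its unit and copy number", {
  r <- find_direct_repeats("ACGTACGTACGT",
                           repeat_config(min_unit_nt = 4L, seed_k = 4L,
                                         max_mismatch_fraction = 0))
  expect_equal(nrow(r), 1L)
  expect_equal(r$unit_len, 4L)
  expect_equal(r$n_full_copies, 3L)
  expect_equal(c(r$start, r$end), c(1L, 12L))
  expect_equal(r$unit_consensus, "ACGT")
})

test_that("i.i.d. random sequence rarely produces a reportable array", {
  set.seed(60)
  hits <- vapply(1:40, function(i) {
    nrow(find_direct_repeats(random_dna(500), repeat_config()))
  }, integer(1))
  expect_gte(mean(hits == 0L), 0.95)
})

test_that("reported repeat regions never overlap and copies obey the mismatch bound", {
  set.seed(61)
  for (i in 1:5) {
    # two planted arrays in one spacer-like sequence
    unit1 <- random_dna(24); unit2 <- random_dna(30)
    s <- paste0(random_dna(60), strrep(unit1, 4), random_dna(80),
                strrep(unit2, 3), random_dna(60))
    r <- find_direct_repeats(s, repeat_config())
    if (nrow(r) >= 2) {
      ord <- order(r$start)
      expect_true(all(r$start[ord][-1] > r$end[ord][-nrow(r)]))
    }
    cfg <- repeat_config()
    for (j in seq_len(nrow(r))) {
      cons <- strsplit(r$unit_consensus[j], "")[[1]]
      for (cp in seq_len(r$n_full_copies[j])) {
        cs <- r$start[j] + (cp - 1L) * r$unit_len[j]
        copy <- strsplit(substr(s, cs, cs + r$unit_len[j] - 1L), "")[[1]]
        expect_lte(sum(copy != cons), cfg$max_mismatch_fraction * r$unit_len[j])
      }
    }
  }
})

test_that("planted imperfect arrays are recovered within 5 nt of their boundaries", {
  set.seed(62)
  ok <- 0L; n_cases <- 25L
  for (i in seq_len(n_cases)) {
    u <- sample(20:50, 1)
    copies <- sample(3:8, 1)
    unit <- strsplit(random_dna(u), "")[[1]]
    body <- unlist(lapply(seq_len(copies), function(k) {
      hit <- runif(u) < 0.08
      unit[hit] <- sapply(unit[hit], function(b) sample(setdiff(c("A","C","G","T"), b), 1))
      unit
    }))
    lead <- sample(30:120, 1)
    s <- paste0(random_dna(lead), paste(body, collapse = ""), random_dna(100))
    r <- find_direct_repeats(s, repeat_config())
    planted_start <- lead + 1L
    planted_end <- lead + copies * u
    if (nrow(r) > 0) {
      best <- r[which.min(abs(r$start - planted_start)), ]
      if (abs(best$start - planted_start) <= 5 && abs(best$end - planted_end) <= 5) {
        ok <- ok + 1L
      }
    }
  }
  expect_gte(ok / n_cases, 0.9)
})

test_that("palindromes are found, collapsed, and strand-symmetric", {
  p <- find_palindromes("GAATTC", repeat_config(min_palindrome_arm = 3L,
                                                max_loop_nt = 0L))
  expect_equal(nrow(p), 1L)
  expect_equal(c(p$start, p$end, p$arm_len, p$mismatches), c(1L, 6L, 3L, 0L))
  expect_equal(nrow(find_palindromes("AAAAAAAA",
                                     repeat_config(min_palindrome_arm = 3L))), 0L)

  # planted 12 bp arm with 1 mismatch in a GC-skewed background
  set.seed(63)
  arm <- random_dna(12, gc = 0.8)
  pal <- paste0(arm, "AATT", reverse_complement(arm))
  pal_ch <- strsplit(pal, "")[[1]]
  pal_ch[5] <- setdiff(c("A", "C", "G", "T"), pal_ch[5])[1]
  s <- paste0(random_dna(80, gc = 0.8), paste(pal_ch, collapse = ""),
              random_dna(80, gc = 0.8))
  hits <- find_palindromes(s, repeat_config(min_palindrome_arm = 8L,
                                            max_loop_nt = 6L))
  best <- hits[which.max(hits$arm_len), ]
  # arms may extend a few bases by chance complementarity in the background
  expect_lte(abs(best$start - 81L), 4L)
  expect_lte(abs(best$end - (81L + 27L)), 4L)
  expect_gte(best$arm_len, 12L)

  # strand symmetry: coordinates mirror on the reverse complement
  rc_hits <- find_palindromes(reverse_complement(s),
                              repeat_config(min_palindrome_arm = 8L,
                                            max_loop_nt = 6L))
  n <- nchar(s)
  mirrored <- sort(paste(n - rc_hits$end + 1L, n - rc_hits$start + 1L))
  expect_equal(sort(paste(hits$start, hits$end)), mirrored)
})

test_that("hairpin prediction maximizes base pairs with deterministic stems", {
  hp <- predict_hairpin("GGGAAACCC")
  expect_equal(hp$n_pairs, 3L)
  expect_equal(hp$loop_len, 3L)
  expect_equal(hp$dot_bracket, "(((...)))")
  expect_equal(predict_hairpin("AAAAAA")$n_pairs, 0L)
  # perfect 8 bp inverted repeat with a 4 nt loop pairs fully
  arm <- "GCGCATAT"
  hp2 <- predict_hairpin(paste0(arm, "TTTT", reverse_complement(arm)))
  expect_equal(hp2$n_pairs, 8L)
  expect_error(predict_hairpin("AAA"), "5 to 2000")
  expect_error(predict_hairpin(strrep("A", 2001)), "5 to 2000")
})

test_that("hairpin pair counts equal the exhaustive enumeration optimum", {
  set.seed(64)
  for (i in 1:100) {
    s <- random_dna(sample(5:22, 1))
    expect_equal(predict_hairpin(s)$n_pairs, oracle_max_pairs(s),
                 info = paste("case", i, s))
  }
})

test_that("hairpin structures are nested with Watson-Crick pairs and legal loops", {
  set.seed(65)
  for (i in 1:20) {
    s <- random_dna(sample(10:60, 1))
    hp <- predict_hairpin(s)
    if (hp$n_pairs == 0) next
    ch <- strsplit(s, "")[[1]]
    comp <- c(A = "T", T = "A", G = "C", C = "G")
    expect_true(all(ch[hp$pairs$j] == comp[ch[hp$pairs$i]]))
    expect_true(all(hp$pairs$j - hp$pairs$i >= 4L)) # min loop 3
    # non-crossing
    if (nrow(hp$pairs) >= 2) {
      for (a in 1:(nrow(hp$pairs) - 1)) for (b in (a + 1):nrow(hp$pairs)) {
        pa <- hp$pairs[a, ]; pb <- hp$pairs[b, ]
        nested <- (pb$i > pa$j) || (pb$i > pa$i && pb$j < pa$j) ||
          (pa$i > pb$j) || (pa$i > pb$i && pa$j < pb$j)
        expect_true(nested)
      }
    }
  }
})

test_that("region classification follows the non-hr and hr rules", {
  cfg <- repeat_config()
  non_hr <- list(n_full_copies = 7L, at_fraction = 0.74, n_palindromes = 2L,
                 max_hairpin_pairs = 10L, centered_palindrome_in_each_unit = FALSE)
  expect_equal(classify_region(non_hr, cfg), "non_hr")
  gc_rich <- list(n_full_copies = 4L, at_fraction = 0.3, n_palindromes = 0L,
                  max_hairpin_pairs = 2L, centered_palindrome_in_each_unit = FALSE)
  expect_equal(classify_region(gc_rich, cfg), "none")
  hr <- list(n_full_copies = 5L, at_fraction = 0.7, n_palindromes = 5L,
             max_hairpin_pairs = 12L, centered_palindrome_in_each_unit = TRUE)
  expect_equal(classify_region(hr, cfg), "hr_like")
  # AT-rich repeats without any palindrome or hairpin stay unclassified
  bare <- list(n_full_copies = 3L, at_fraction = 0.8, n_palindromes = 0L,
               max_hairpin_pairs = 0L, centered_palindrome_in_each_unit = FALSE)
  expect_equal(classify_region(bare, cfg), "none")
})

test_that("planted family repeat regions are recovered at +-5 nt with truth attributes", {
  fam <- get_family()
  anns <- get_family_annotations()
  rr <- find_repeat_regions(anns$ancestor)
  truth <- fam$ancestor$truth$repeats
  expect_equal(nrow(truth), 2L)
  for (i in seq_len(nrow(truth))) {
    hit <- rr[abs(rr$genome_start - truth$start[i]) <= 5, ]
    expect_equal(nrow(hit), 1L)
    expect_lte(abs(hit$genome_end - truth$end[i]), 6L)
    expect_equal(hit$n_full_copies, truth$n_copies[i])
    expect_equal(hit$unit_len, truth$unit_len[i])
    expect_true(hit$has_truncated_copy)
    expect_equal(hit$classification, "non_hr")
    expect_equal(hit$at_fraction, truth$at_fraction[i], tolerance = 0.12)
  }
})

test_that("a single copy is below the reporting threshold", {
  sim <- simulate_annotated_genome(sim_config(genome_len = 20000L, n_orfs = 20L,
                                              seed = 42L))
  g <- gvcompare:::truth_spacers(sim)
  g <- g[order(-g$length), ]
  sim1 <- plant_repeat_region(sim, unit_len = 40L, n_copies = 1L,
                              mismatch_rate = 0, truncated = FALSE,
                              palindrome = "none", position = g$start[1] + 5L,
                              seed = 4L)
  reg <- sim1$truth$repeats
  sp_seq <- circular_subsequence(sim1$genome, reg$start, reg$start + 120L, "+")
  r <- find_direct_repeats(sp_seq, repeat_config())
  expect_false(any(r$start <= 5 & r$n_full_copies >= 2))
})
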