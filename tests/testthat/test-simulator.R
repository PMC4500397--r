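test_that("the generator is a pure function of its seed", {
  cfg <- sim_config(genome_len = 15000L, n_orfs = 15L, seed = 99L,
                    big_spacer_extra = integer(0))
  s1 <- simulate_annotated_genome(cfg, verify = FALSE)
  s2 <- simulate_annotated_genome(cfg, verify = FALSE)
  expect_identical(s1$genome$seq, s2$genome$seq)
  expect_identical(s1$truth$orfs, s2$truth$orfs)
  expect_identical(s1$truth$promoters, s2$truth$promoters)
  s3 <- simulate_annotated_genome(sim_config(genome_len = 15000L, n_orfs = 15L,
                                             seed = 100L,
                                             big_spacer_extra = integer(0)),
                                  verify = FALSE)
  expect_false(identical(s1$genome$seq, s3$genome$seq))
})

test_that("realized GC composition hits the target within binomial tolerance", {
  sim <- simulate_annotated_genome(sim_config(genome_len = 50000L, n_orfs = 50L,
                                              gc_target = 0.378, seed = 8L),
                                   verify = FALSE)
  expect_equal(gc_content(sim$genome$seq), 0.378, tolerance = 0.01 / 0.378)
})

test_that("disjoint planted ORFs are recovered exactly by annotation", {
  cfg <- sim_config(genome_len = 12000L, n_orfs = 10L, overlap_prob = 0,
                    big_spacer_extra = integer(0), seed = 5L)
  sim <- simulate_annotated_genome(cfg)
  ann <- annotate_sim(sim)
  ids <- truth_to_orf_ids(sim, ann)
  expect_false(anyNA(ids))
  # disjoint: planted footprints must not overlap
  o <- dplyr::arrange(sim$truth$orfs, fp_start)
  expect_true(all(o$fp_start[-1] > o$fp_end[-nrow(o)]))
})

test_that("every truth entry is verifiable against the emitted sequence", {
  fam <- get_family()
  sim <- fam$ancestor
  g <- sim$genome
  for (i in seq_len(nrow(sim$truth$orfs))) {
    o <- sim$truth$orfs[i, ]
    cds <- circular_subsequence(g, o$fp_start, o$fp_end, o$strand)
    expect_equal(substr(cds, 1, 3), "ATG")
    expect_true(substr(cds, nchar(cds) - 2, nchar(cds)) %in% c("TAA", "TAG", "TGA"))
    prot <- sub("\\*$", "", as.character(
      Biostrings::translate(Biostrings::DNAString(cds))))
    expect_equal(prot, o$protein)
    expect_false(grepl("*", prot, fixed = TRUE)) # no internal stops
  }
  # planted promoter motifs are literally present upstream
  for (i in seq_len(nrow(sim$truth$promoters))) {
    p <- sim$truth$promoters[i, ]
    o <- sim$truth$orfs[sim$truth$orfs$rank == p$rank, ]
    L <- g$length
    win <- if (o$strand == "+") {
      circular_subsequence(g, gvcompare:::mod1(o$start - 150L, L),
                           gvcompare:::mod1(o$start - 1L, L), "+")
    } else {
      circular_subsequence(g, gvcompare:::mod1(o$start + 1L, L),
                           gvcompare:::mod1(o$start + 150L, L), "-")
    }
    at <- 150L - p$position + 1L
    if (p$kind == "late") {
      expect_equal(substr(win, at, at + 3L), "TAAG")
    } else {
      expect_equal(substr(win, at, at + 3L), "TATA")
    }
  }
  # planted repeat regions sit where the truth says
  for (i in seq_len(nrow(sim$truth$repeats))) {
    r <- sim$truth$repeats[i, ]
    first_copy <- circular_subsequence(g, r$start, r$start + r$unit_len - 1L, "+")
    cons <- strsplit(r$unit_consensus, "")[[1]]
    expect_lte(sum(strsplit(first_copy, "")[[1]] != cons), 0.25 * r$unit_len)
  }
})

test_that("zero divergence reproduces the parent proteins; 20% diverges as expected", {
  sim <- simulate_annotated_genome(sim_config(genome_len = 15000L, n_orfs = 15L,
                                              big_spacer_extra = integer(0),
                                              seed = 13L))
  same <- evolve_genome(sim, aa_divergence = 0, seed = 1L)
  # no inversion: gene order is unchanged, proteins identical
  expect_identical(same$truth$orfs$protein, sim$truth$orfs$protein)

  div <- evolve_genome(sim, aa_divergence = 0.2, seed = 2L, verify = FALSE)
  ident <- vapply(seq_len(nrow(sim$truth$orfs)), function(r) {
    a <- strsplit(sim$truth$orfs$protein[r], "")[[1]]
    ch_rank <- div$truth$orthologs$child_rank[div$truth$orthologs$parent_rank == r]
    b <- strsplit(div$truth$orfs$protein[div$truth$orfs$rank == ch_rank], "")[[1]]
    mean(a == b)
  }, numeric(1))
  expect_equal(stats::weighted.mean(ident, nchar(sim$truth$orfs$protein)),
               0.8, tolerance = 0.025)
})

test_that("overlapping inversion blocks and anchor-spanning blocks are rejected", {
  sim <- simulate_annotated_genome(sim_config(genome_len = 15000L, n_orfs = 15L,
                                              big_spacer_extra = integer(0),
                                              seed = 13L))
  expect_error(evolve_genome(sim, 0.1, list(c(3L, 8L), c(6L, 10L)), seed = 1L),
               "overlap")
  expect_error(evolve_genome(sim, 0.1, list(c(1L, 5L)), seed = 1L), "anchor")
})

test_that("repeat planting refuses coding positions and records coordinates", {
  sim <- simulate_annotated_genome(sim_config(genome_len = 15000L, n_orfs = 15L,
                                              big_spacer_extra = 200L,
                                              seed = 13L))
  inside <- sim$truth$orfs$fp_start[2] + 10L
  expect_error(plant_repeat_region(sim, 30L, 3L, position = inside, seed = 1L),
               "overlaps a planted ORF")
  g <- gvcompare:::truth_spacers(sim)
  g <- g[order(-g$length), ]
  ok <- plant_repeat_region(sim, 20L, 3L, mismatch_rate = 0,
                            truncated = FALSE, palindrome = "none",
                            position = g$start[1] + 3L, seed = 1L)
  r <- ok$truth$repeats
  expect_equal(r$end - r$start + 1L, 60L)
  planted <- circular_subsequence(ok$genome, r$start, r$end, "+")
  expect_equal(planted, strrep(r$unit_consensus, 3L))
})

test_that("an infeasible configuration errors out", {
  expect_error(sim_config(genome_len = 5000L, n_orfs = 60L), "infeasible")
})
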