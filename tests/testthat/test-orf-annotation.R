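# small builder: a circular genome with one planted ORF at a known position,
# guarded by an in-frame stop so the maximal-ORF rule starts at the planted ATG
planted_orf_genome <- function(L = 400L, at = 55L, n_codons = 52L, strand = "+",
                               background = NULL, seed = 1L) {
  set.seed(seed)
  bg <- background %||% random_dna(L, gc = 0.3)
  cds <- paste0("ATG", strrep("GCC", n_codons - 2L), "TAA")
  chars <- strsplit(bg, "")[[1]]
  idx <- ((seq.int(at - 3L, length.out = nchar(cds) + 3L) - 1L) %% L) + 1L
  payload <- paste0("TAA", cds) # guard stop then the ORF
  if (strand == "-") {
    payload <- gvcompare::reverse_complement(payload)
    idx <- rev((L - idx + 1L))
  }
  chars[idx] <- strsplit(payload, "")[[1]]
  gvcompare::circular_genome(paste(chars, collapse = ""))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("a single planted ORF is found with exact coordinates", {
  # poly-A background has no ATG and no GC; only the planted ORF exists
  g <- planted_orf_genome(background = strrep("A", 400))
  cand <- enumerate_candidate_orfs(g, annotation_config())
  planted <- cand[cand$strand == "+" & cand$length_nt == 156L, ]
  expect_equal(nrow(planted), 1L)
  expect_equal(planted$start, 55L)
  expect_equal(planted$end, 210L)
  expect_equal(planted$length_aa, 51L)
  expect_match(planted$protein, "^MA+$")
})

test_that("wraparound ORFs crossing the origin are detected once", {
  g <- planted_orf_genome(at = 390L, background = strrep("A", 400))
  cand <- enumerate_candidate_orfs(g, annotation_config())
  hit <- cand[cand$start == 390L & cand$strand == "+", ]
  expect_equal(nrow(hit), 1L)
  expect_true(hit$wraps)
  expect_equal(hit$end, (390L + 156L - 1L - 1L) %% 400L + 1L)
  # no duplicate report of the same locus
  expect_equal(anyDuplicated(paste(cand$start, cand$strand)), 0L)
})

test_that("ATG-free and too-short genomes yield no candidates", {
  expect_equal(nrow(enumerate_candidate_orfs(circular_genome(strrep("A", 400)))), 0L)
  expect_equal(nrow(enumerate_candidate_orfs(circular_genome("ATGC"))), 0L)
})

test_that("six-frame enumeration matches the literal scan oracle on random circles", {
  set.seed(2024)
  for (i in 1:30) {
    L <- sample(200:2000, 1)
    s <- random_dna(L, gc = runif(1, 0.3, 0.6))
    got <- enumerate_candidate_orfs(circular_genome(s), annotation_config())
    want <- oracle_orfs(s, 150L)
    key_got <- sort(paste(got$start, got$end, got$strand))
    key_want <- sort(paste(want$start, want$end, want$strand))
    expect_identical(key_got, key_want)
  }
})

test_that("greedy minimal-overlap selection keeps the longer of two heavy overlappers", {
  g <- circular_genome(random_dna(1000))
  two <- tibble::tibble(
    start = c(1L, 31L), end = c(300L, 330L), strand = c("+", "+"),
    length_nt = c(300L, 300L), length_aa = c(99L, 99L),
    protein = c("M", "M"), fp_start = c(1L, 31L), fp_end = c(300L, 330L),
    wraps = c(FALSE, FALSE))
  sel <- resolve_minimal_overlap(two, annotation_config(), 1000L)
  expect_equal(nrow(sel), 1L) # 270/300 = 90% overlap of the shorter
  expect_equal(sel$start, 1L) # tie on length broken by smaller start

  disjoint <- two
  disjoint$start[2] <- 501L; disjoint$end[2] <- 800L
  disjoint$fp_start[2] <- 501L; disjoint$fp_end[2] <- 800L
  expect_equal(nrow(resolve_minimal_overlap(disjoint, annotation_config(), 1000L)), 2L)
})

test_that("no selected pair violates the pairwise overlap cap", {
  sim <- simulate_annotated_genome(sim_config(genome_len = 20000L, n_orfs = 20L,
                                              seed = 42L))
  g <- sim$genome
  cfg <- annotation_config()
  sel <- resolve_minimal_overlap(enumerate_candidate_orfs(g, cfg), cfg, g$length)
  expect_gte(nrow(sel), 20L)
  if (nrow(sel) >= 2) {
    for (i in 1:(nrow(sel) - 1)) {
      for (j in (i + 1):nrow(sel)) {
        ov <- gvcompare:::overlap_nt_intervals(
          gvcompare:::fp_intervals(sel$fp_start[i], sel$fp_end[i], g$length),
          gvcompare:::fp_intervals(sel$fp_start[j], sel$fp_end[j], g$length))
        expect_lte(ov, 0.5 * min(sel$length_nt[i], sel$length_nt[j]))
      }
    }
  }
})

test_that("anchoring rotates coordinates but never changes any protein", {
  sim <- simulate_annotated_genome(sim_config(genome_len = 20000L, n_orfs = 20L,
                                              seed = 42L))
  cfg <- annotation_config()
  cand <- enumerate_candidate_orfs(sim$genome, cfg)
  sel <- resolve_minimal_overlap(cand, cfg, sim$genome$length)
  for (anchor_idx in c(1L, 5L)) {
    ann <- anchor_and_number(sel, sim$genome, anchor_idx, cfg)
    expect_equal(sort(ann$orfs$protein), sort(sel$protein))
    expect_equal(ann$orfs$orf_id, seq_len(nrow(sel)))
    # anchor sits at nt 1 on '+'
    a <- ann$orfs[ann$orfs$orf_id == 1L, ]
    expect_equal(a$fp_start, 1L)
    # re-extraction from the rotated genome reproduces each protein
    re <- vapply(seq_len(nrow(ann$orfs)), function(i) {
      o <- ann$orfs[i, ]
      cds <- circular_subsequence(ann$genome, o$fp_start, o$fp_end, o$strand)
      sub("\\*$", "", as.character(Biostrings::translate(Biostrings::DNAString(cds))))
    }, character(1))
    expect_equal(re, ann$orfs$protein)
  }
  # a minus-strand anchor flips the genome; proteins still unchanged
  minus_idx <- which(sel$strand == "-")[1]
  ann2 <- anchor_and_number(sel, sim$genome, minus_idx, cfg)
  expect_equal(sort(ann2$orfs$protein), sort(sel$protein))
  expect_equal(ann2$orfs$strand[ann2$orfs$orf_id == 1L], "+")
  expect_error(anchor_and_number(sel, sim$genome,
                                 tibble::tibble(start = 99999L, strand = "+")),
               "not one of")
})

test_that("annotation_stats reports adjacent overlaps and span-union coding fraction", {
  # two '+' ORFs at 1..100 and 81..200 on a 300 nt circle
  g <- circular_genome(random_dna(300))
  orfs <- tibble::tibble(
    orf_id = 1:2, start = c(1L, 81L), end = c(100L, 200L), strand = "+",
    length_nt = c(100L, 120L), length_aa = c(32L, 39L), protein = "M",
    fp_start = c(1L, 81L), fp_end = c(100L, 200L), wraps = FALSE)
  ann <- structure(list(genome = g, orfs = orfs, anchor_orf_id = 1L,
                        config = annotation_config()),
                   class = "genome_annotation")
  st <- annotation_stats(ann)
  expect_equal(st$overlaps$overlap_nt, 20L)
  expect_equal(st$summary$coding_fraction, 200 / 300)
  expect_equal(st$summary$n_plus, 2L)
  expect_equal(st$summary$coding_fraction, oracle_coding_fraction(ann))
})

test_that("annotation statistics of a simulated genome match the planted truth", {
  fam <- get_family()
  anns <- get_family_annotations()
  sim <- fam$ancestor
  ann <- anns$ancestor
  ids <- truth_to_orf_ids(sim, ann)
  expect_false(anyNA(ids)) # every planted ORF recovered exactly
  expect_equal(oracle_coding_fraction(ann),
               annotation_stats(ann)$summary$coding_fraction)
  # planted strand counts agree on the truth-matched subset
  matched <- ann$orfs[ids, ]
  expect_equal(sum(matched$strand == "+"), sum(sim$truth$orfs$strand == "+"))
})

test_that("a homology-rescued sub-threshold ORF enters the annotation", {
  sim <- simulate_annotated_genome(sim_config(genome_len = 20000L, n_orfs = 20L,
                                              seed = 42L))
  g <- sim$genome
  # take a planted ORF and pretend it were below threshold: rescue by coords
  o <- sim$truth$orfs[3, ]
  big_cfg <- annotation_config(min_orf_nt = 999L)
  ann <- annotate_genome(g, big_cfg,
                         rescue = tibble::tibble(start = o$start, end = o$end,
                                                 strand = o$strand))
  # the annotation is re-anchored, so compare by protein (rotation-invariant)
  expect_true(o$protein %in% ann$orfs$protein)
  expect_true(all(ann$orfs$length_nt >= 999L | ann$orfs$protein == o$protein))
})

test_that("GFF3 and protein FASTA writers emit consistent features", {
  sim <- simulate_annotated_genome(sim_config(genome_len = 20000L, n_orfs = 20L,
                                              seed = 42L))
  ann <- annotate_sim(sim)
  gff <- withr::local_tempfile(fileext = ".gff3")
  faa <- withr::local_tempfile(fileext = ".faa")
  write_annotation_gff3(ann, gff)
  write_protein_fasta(ann, faa)
  lines <- readLines(gff)
  expect_equal(lines[1], "##gff-version 3")
  body <- read.delim(gff, header = FALSE, comment.char = "#")
  expect_true(all(body$V4 <= body$V5)) # 1-based inclusive, split wraps
  expect_gte(nrow(body), nrow(ann$orfs))
  aa <- Biostrings::readAAStringSet(faa)
  expect_equal(length(aa), nrow(ann$orfs))
  expect_equal(unname(as.character(aa[1])), ann$orfs$protein[1])
})
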