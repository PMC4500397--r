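test_that("supermatrix concatenation tracks block boundaries and missing taxa", {
  b1 <- c(t1 = "MKVLAAAAAA", t2 = "MKVLAAAAAT", t3 = "MKVLAAAAAC")
  b2 <- c(t1 = "WWWWWDDDDDDDDDD", t2 = "WWWWWDDDDDDDDDC")
  sm <- build_supermatrix(list(geneA = b1, geneB = b2))
  expect_equal(ncol(sm$mat), 25L)
  expect_equal(sm$blocks$start, c(1L, 11L))
  expect_equal(sm$blocks$end, c(10L, 25L))
  expect_equal(paste(sm$mat["t1", ], collapse = ""), paste0(b1[["t1"]], b2[["t1"]]))
  # t3 missing from geneB: gap-filled and masked
  expect_equal(paste(sm$mat["t3", 11:25], collapse = ""), strrep("-", 15))
  expect_true(sm$missing["t3", "geneB"])
  expect_false(sm$missing["t1", "geneB"])
  expect_error(build_supermatrix(list(g = c(a = "MK", b = "MKV"))),
               "conflicting row lengths")
})

test_that("Poisson-corrected distances follow the closed form", {
  rows <- c(a = strrep("A", 100), b = strrep("A", 100))
  sm <- build_supermatrix(list(g = rows))
  expect_equal(protein_distance(sm)["a", "b"], 0)

  # 10 mismatches in 100 columns -> p = 0.1 -> -ln(0.9)
  b <- paste0(strrep("K", 10), strrep("A", 90))
  sm2 <- build_supermatrix(list(g = c(a = strrep("A", 100), b = b)))
  expect_equal(protein_distance(sm2)["a", "b"], -log(0.9), tolerance = 1e-9)

  # disjoint gap patterns leave no comparable columns
  sm3 <- build_supermatrix(list(g = c(a = "AA--", b = "--AA")))
  expect_error(protein_distance(sm3), "no comparable columns")

  # pairwise vs complete deletion differ when gaps hide mismatches
  sm4 <- build_supermatrix(list(g = c(a = "AAKA", b = "AA-A")))
  expect_equal(protein_distance(sm4)["a", "b"], 0)
})

test_that("neighbor joining solves the 3-taxon system in closed form", {
  d <- matrix(c(0, 5, 9,
                5, 0, 10,
                9, 10, 0), 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  tr <- nj_tree(d)
  expect_equal(ape::Ntip(tr), 3L)
  # closed form: la = (dab + dac - dbc)/2 etc.
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl["a"]), (5 + 9 - 10) / 2)
  expect_equal(unname(bl["b"]), (5 + 10 - 9) / 2)
  expect_equal(unname(bl["c"]), (9 + 10 - 5) / 2)
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
  dd <- d; dd[1, 2] <- 7
  expect_error(nj_tree(dd), "not symmetric")
  dn <- d; dn[1, 2] <- dn[2, 1] <- -1
  expect_error(nj_tree(dn), "negative")
})

test_that("NJ recovers topology and path lengths exactly from additive matrices", {
  set.seed(2718)
  for (n_taxa in 4:8) {
    for (rep in 1:4) {
      ref <- random_additive_tree(n_taxa)
      tr <- nj_tree(ref$dist)
      expect_equal(ape::dist.topo(ape::unroot(ref$tree), tr), 0,
                   ignore_attr = TRUE)
      got <- ape::cophenetic.phylo(tr)
      ord <- rownames(ref$dist)
      expect_equal(got[ord, ord], ref$dist, tolerance = 1e-9)
      expect_true(all(tr$edge.length >= -1e-12))
    }
  }
})

test_that("bootstrap supports are deterministic, bounded, and order-invariant", {
  set.seed(31)
  # two well-separated clusters of 3 taxa, each taxon carrying its own block
  # of private substitutions (zero homoplasy, all internal edges positive);
  # the clusters sit at moderate divergence so Poisson correction stays far
  # from saturation and replicate distances are stable
  base1 <- random_protein(120)
  jitter <- function(s, idx) {
    ch <- strsplit(s, "")[[1]]
    ch[idx] <- vapply(ch[idx], function(x)
      sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], x), 1), "x")
    paste(ch, collapse = "")
  }
  base2 <- jitter(base1, 41:80)
  # within each cluster, taxa 2 and 3 form a cherry: they share a block of
  # common substitutions on top of their private ones
  base1_23 <- jitter(base1, 31:40)
  base2_23 <- jitter(base2, 81:90)
  rows <- c(a1 = jitter(base1, 1:10), a2 = jitter(base1_23, 11:20),
            a3 = jitter(base1_23, 21:30),
            b1 = jitter(base2, 1:10), b2 = jitter(base2_23, 11:20),
            b3 = jitter(base2_23, 21:30))
  sm <- build_supermatrix(list(g = rows))
  tr <- bootstrap_support(sm, n_replicates = 60L, seed = 7L)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(sup[-1] >= 0 & sup[-1] <= 100, na.rm = TRUE))
  expect_true(all(sup[-1] == 100, na.rm = TRUE))
  expect_equal(attr(tr, "n_replicates"), 60L)

  tr2 <- bootstrap_support(sm, n_replicates = 60L, seed = 7L)
  expect_equal(ape::write.tree(tr), ape::write.tree(tr2))

  # taxon input order must not change supports
  sm_r <- build_supermatrix(list(g = rows[c(4, 2, 6, 1, 3, 5)]))
  tr3 <- bootstrap_support(sm_r, n_replicates = 60L, seed = 7L)
  sup3 <- suppressWarnings(as.numeric(tr3$node.label))
  expect_true(all(sup3[-1] == 100, na.rm = TRUE))
})

test_that("a signal-free alignment yields weak supports", {
  set.seed(33)
  meds <- vapply(1:5, function(s) {
    rows <- setNames(replicate(6, random_protein(80)), paste0("t", 1:6))
    sm <- build_supermatrix(list(g = rows))
    tr <- bootstrap_support(sm, n_replicates = 40L, seed = s)
    stats::median(suppressWarnings(as.numeric(tr$node.label)), na.rm = TRUE)
  }, numeric(1))
  expect_lt(stats::median(meds), 70)
})

test_that("family tree groups the descendants against the more distant pair", {
  fam <- get_family()
  blocks <- lapply(setNames(1:12, paste0("g", 1:12)), function(r) {
    sapply(fam, function(s) {
      rk <- if (is.null(s$truth$orthologs)) r else
        s$truth$orthologs$child_rank[s$truth$orthologs$parent_rank == r]
      s$truth$orfs$protein[s$truth$orfs$rank == rk]
    })
  })
  sm <- build_supermatrix(blocks)
  d <- protein_distance(sm)
  # the two descendants diverged independently: both are closer to the
  # ancestor than to each other, and distances match the Poisson expectation
  expect_lt(d["ancestor", "collinear"], d["collinear", "inverted"])
  expect_equal(unname(d["ancestor", "inverted"]), -log(1 - 0.15), tolerance = 0.1)
})

test_that("unequal-length blocks go through the external aligner", {
  seqs <- c(a = "MKVLIVAAAGGHHLL", b = "MKVLIVAAAGGHHLL", c = "MKVLIVGGHHLL")
  aln <- align_protein_block(seqs)
  expect_equal(length(unique(nchar(aln))), 1L)
  expect_true(grepl("-", aln[["c"]], fixed = TRUE))
})
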