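# gvcompare

Comparative genomics of granulovirus (betabaculovirus) genomes in R.

Betabaculoviruses are insect-pathogenic viruses with circular double-stranded
DNA genomes of roughly 80–180 kb, densely packed with ATG-initiated ORFs on
both strands. Characterizing a newly sequenced isolate follows a
well-established recipe: annotate methionine-initiated ORFs of ≥ 150 nt with
minimal overlap, anchor the numbering at the granulin gene (*orf1*, with the
first nucleotide of its start codon as nt 1 of the genome), classify each ORF
against the reference gene sets of the family (the 37 baculovirus core genes,
the 25 lepidopteran-shared genes, the 19 betabaculovirus-specific genes),
compare gene order with related genomes via gene parity plots, scan large
intergenic spacers for non-hr replication-origin architecture (tandem
imperfect direct repeats, imperfect palindromes and AT-rich context, with
predicted hairpins), annotate early/late promoter motifs, and place the
isolate on a phylogeny built from concatenated core proteins.

`gvcompare` implements that whole workflow as composable, tidyverse-style R
functions, with a synthetic-genome simulator that plants every feature with a
known truth table so the entire pipeline is testable offline.

## Methods at the core

* **ORF annotation** — a six-frame maximal-ORF scan on the doubled circular
  sequence (first in-frame ATG after the preceding in-frame stop, stop codon
  included in the length), greedy longest-first selection under a pairwise
  overlap cap (default: ≤ 50% of the shorter ORF), anchored renumbering.
* **Homology** — exact affine-gap alignment (Gotoh; BLOSUM62, gap open 11,
  extend 1) in C++; orthologs by reciprocal best hit; gene classes by
  panel priority (core > lepidopteran-shared > betabaculovirus-specific >
  other; no hit = unique).
* **Synteny** — parity coordinates are ORF ranks; the collinearity score is
  the fraction of consecutive ortholog pairs whose partner rank advances by
  +1 (mod n); inversions are maximal anti-diagonal runs of ≥ 3 pairs.
* **Repeats** — seed-and-extend tandem-array discovery with X-drop extension
  and per-copy consensus validation; imperfect palindrome scan; Nussinov
  base-pair maximization (Watson–Crick only, min loop 3) for hairpins;
  rule-based non-hr / hr-like classification.
* **Phylogeny** — Poisson-corrected distances, `d = −ln(1 − p)`, on a
  concatenated protein supermatrix with pairwise deletion; neighbor joining;
  bootstrap support over column resampling.

## A worked example

```r
library(gvcompare)

fam <- simulate_genome_family(sim_config(seed = 1234))
ann <- annotate_sim(fam$ancestor)
ann
#> <genome_annotation> sim: 61 ORFs (32 '+', 29 '-'), coding 94.2%

glance(ann)[, c("n_orfs", "n_plus", "n_minus", "coding_fraction")]
#> # A tibble: 1 × 4
#>   n_orfs n_plus n_minus coding_fraction
#>    <int>  <int>   <int>           <dbl>
#> 1     61     32      29           0.942

orth <- ortholog_map(ann, annotate_sim(fam$inverted))
par  <- parity_coordinates(orth, ann, annotate_sim(fam$inverted))
collinearity_score(par)
#> [1] 0.8
detect_inversions(par, ann)
#> # A tibble: 1 × 4
#>   a_start_rank a_end_rank n_genes span_nt
#>          <int>      <int>   <int>   <int>
#> 1           22         31      10    8690

find_repeat_regions(ann)[, c("genome_start", "genome_end", "unit_len",
                             "n_full_copies", "classification")]
#> # A tibble: 2 × 5
#>   genome_start genome_end unit_len n_full_copies classification
#>          <int>      <int>    <int>         <int> <chr>
#> 1        17697      18114       55             7 non_hr
#> 2        42091      42205       45             2 non_hr
```

All sixty planted ORFs are recovered exactly (one conserved extra ORF also
survives selection); the descendant genome carrying a planted 10-gene
inversion scores 0.80 collinearity with an anti-diagonal block detected at
exactly the planted ranks (8.7 kb span); both planted repeat arrays are
found at their planted coordinates and classified as putative non-hr
origins. `plot_parity(par)` and `autoplot(ann)` draw the
parity plot and a linear genome map.

For a real analysis, point `run_pipeline()` at FASTA/GenBank files:

```r
run_pipeline(list(
  genome = "isolate.gb",
  comparators = c("erelgv.fa", "clangv.fa"),
  panels = list(core37 = "core37.faa", beta19 = "beta19.faa"),
  anchor_protein = "granulin.faa",
  phylogeny = list(bootstrap = 1000),
  seed = 42
), out_dir = "results/")
```

which writes GFF3, protein FASTA, TSV tables, a Newick tree, a JSON report
and a run manifest.

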