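#' Build a reference protein panel
#'
#' A panel is a set of reference gene families (e.g. the 37 baculovirus core
#' genes, the 25 lepidopteran-shared genes, the 19 betabaculovirus-specific
#' genes), each represented by one or more member protein sequences.
#'
#' @param sequences Named character vector of amino-acid sequences. Names use
#'   the `family|member` syntax; a bare name is both family and member.
#' @param panel_id Panel label, e.g. `"core37"`, `"lepidopteran25"`, `"beta19"`,
#'   `"other"`.
#' @return Tibble of class `protein_panel`: `panel_id`, `family`, `member`,
#'   `protein`.
#' @export
protein_panel <- function(sequences, panel_id) {
  if (length(sequences) == 0L) stop("panel has no sequences", call. = FALSE)
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("panel sequences must be named", call. = FALSE)
  }
  if (any(!nzchar(sequences))) stop("panel contains an empty sequence", call. = FALSE)
  parts <- stringr::str_split_fixed(names(sequences), stringr::fixed("|"), 2)
  family <- parts[, 1]
  member <- ifelse(nzchar(parts[, 2]), parts[, 2], parts[, 1])
  tibble::new_tibble(
    tibble::tibble(panel_id = panel_id, family = family, member = member,
                   protein = toupper(unname(sequences))),
    class = "protein_panel"
  )
}

#' Read a protein panel from FASTA
#'
#' Record ids use the `family|member` convention; everything after the first
#' whitespace is ignored.
#'
#' @param path FASTA file of amino-acid sequences.
#' @param panel_id Panel label.
#' @return A [protein_panel()].
#' @export
read_protein_panel <- function(path, panel_id) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop(sprintf("no sequences in %s", path), call. = FALSE)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  protein_panel(stats::setNames(as.character(set), ids), panel_id)
}

#' Map orthologs between two annotated genomes by reciprocal best hit
#'
#' All ORF proteins of genome A are aligned against all of genome B (local
#' affine-gap alignment); a pair is an ortholog iff each is the other's single
#' best-scoring hit and the score reaches `min_score`. The mapping is
#' one-to-one.
#'
#' @param annot_a,annot_b `genome_annotation` objects.
#' @param min_score Minimum alignment score (default 50, the package's
#'   stand-in for a BLAST E-value cutoff at these scales).
#' @return Tibble of class `ortholog_table`: `orf_a`, `orf_b`, `score`,
#'   `same_strand`.
#' @export
ortholog_map <- function(annot_a, annot_b, min_score = 50) {
  stopifnot(inherits(annot_a, "genome_annotation"),
            inherits(annot_b, "genome_annotation"))
  oa <- annot_a$orfs
  ob <- annot_b$orfs
  empty <- tibble::new_tibble(
    tibble::tibble(orf_a = integer(0), orf_b = integer(0), score = numeric(0),
                   same_strand = logical(0)),
    class = "ortholog_table", n_a = nrow(oa), n_b = nrow(ob))
  if (nrow(oa) == 0L || nrow(ob) == 0L) return(empty)
  sc <- align_score_matrix(stats::setNames(oa$protein, oa$orf_id),
                           stats::setNames(ob$protein, ob$orf_id),
                           mode = "local")
  best_b_for_a <- apply(sc, 1, which.max)
  best_a_for_b <- apply(sc, 2, which.max)
  ia <- seq_len(nrow(oa))
  recip <- best_a_for_b[best_b_for_a] == ia
  score <- sc[cbind(ia, best_b_for_a)]
  keep <- recip & score >= min_score
  out <- tibble::tibble(
    orf_a = oa$orf_id[ia[keep]],
    orf_b = ob$orf_id[best_b_for_a[keep]],
    score = score[keep],
    same_strand = oa$strand[ia[keep]] == ob$strand[best_b_for_a[keep]]
  )
  tibble::new_tibble(out, class = "ortholog_table",
                     n_a = nrow(oa), n_b = nrow(ob))
}

#' Classify annotated ORFs against reference panels
#'
#' Each ORF receives the class of the highest-priority panel in which it has a
#' local alignment hit of at least `min_score`; panel priority is the order of
#' `panels` (conventionally core > lepidopteran-shared > betabaculovirus-
#' specific > other). ORFs with no hit in any panel are `unique`.
#'
#' @param annot A `genome_annotation`.
#' @param panels List of [protein_panel()] objects, highest priority first.
#' @param min_score Minimum alignment score (default 50).
#' @return A list of class `gene_class_table`: `classes` (per-ORF tibble with
#'   `orf_id`, `class`, `panel_id`, `family`, `score`), `counts` (per-class
#'   tally), `family_presence` (per panel family: matched or not).
#' @export
classify_genes <- function(annot, panels, min_score = 50) {
  stopifnot(inherits(annot, "genome_annotation"))
  o <- annot$orfs
  class_of_panel <- function(panel_id) {
    switch(panel_id,
           core37 = "core",
           lepidopteran25 = "lepidopteran_shared",
           beta19 = "beta_specific",
           "other_homolog")
  }
  assigned <- tibble::tibble(orf_id = o$orf_id, class = "unique",
                             panel_id = NA_character_, family = NA_character_,
                             score = NA_real_)
  presence <- list()
  if (length(panels) > 0 && nrow(o) > 0) {
    queries <- stats::setNames(o$protein, o$orf_id)
    for (p in panels) {
      sc <- align_score_matrix(queries, stats::setNames(p$protein, p$member),
                               mode = "local")
      best_j <- apply(sc, 1, which.max)
      best_s <- sc[cbind(seq_len(nrow(sc)), best_j)]
      hit <- best_s >= min_score
      open <- assigned$class == "unique" # not claimed by a higher-priority panel
      take <- hit & open
      assigned$class[take] <- class_of_panel(p$panel_id[1])
      assigned$panel_id[take] <- p$panel_id[1]
      assigned$family[take] <- p$family[best_j[take]]
      assigned$score[take] <- best_s[take]
      fam_hit <- vapply(split(seq_len(nrow(p)), p$family), function(idx) {
        any(apply(sc[, idx, drop = FALSE] >= min_score, 1, any))
      }, logical(1))
      presence[[p$panel_id[1]]] <- tibble::tibble(
        panel_id = p$panel_id[1], family = names(fam_hit), present = unname(fam_hit))
    }
  }
  counts <- dplyr::count(assigned, .data$class, name = "n")
  structure(list(classes = assigned, counts = counts,
                 family_presence = dplyr::bind_rows(presence)),
            class = "gene_class_table")
}

#' @export
print.gene_class_table <- function(x, ...) {
  cat("<gene_class_table>\n")
  print(x$counts)
  invisible(x)
}

#' @export
tidy.gene_class_table <- function(x, ...) x$classes

#' @export
glance.gene_class_table <- function(x, ...) {
  tidyr::pivot_wider(x$counts, names_from = "class", values_from = "n",
                     values_fill = 0L)
}
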