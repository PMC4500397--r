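#' Gene parity coordinates for two annotated genomes
#'
#' A gene parity plot places each ortholog pair at its ordinal (rank) position
#' in the two genomes: diagonal runs indicate collinearity, anti-diagonal runs
#' indicate inversions. Ranks are the anchored ORF numbers. The rank origin of
#' genome B is rotated so the anchor gene (rank 1 in A, e.g. the granulin
#' homolog) also gets rank 1 in B when it is paired; otherwise the rotation
#' minimizing the summed circular rank discrepancy is applied (deterministic:
#' smallest such rotation).
#'
#' @param orthologs An [ortholog_map()] result.
#' @param annot_a,annot_b The `genome_annotation` objects the table refers to.
#' @return Tibble of class `parity_data`: `rank_a`, `rank_b`, `same_strand`,
#'   with attributes `n_a`, `n_b`.
#' @export
parity_coordinates <- function(orthologs, annot_a, annot_b) {
  n_a <- nrow(annot_a$orfs)
  n_b <- nrow(annot_b$orfs)
  if (!all(orthologs$orf_a %in% annot_a$orfs$orf_id)) {
    stop("ortholog table names ORF ids missing from annotation A", call. = FALSE)
  }
  if (!all(orthologs$orf_b %in% annot_b$orfs$orf_id)) {
    stop("ortholog table names ORF ids missing from annotation B", call. = FALSE)
  }
  pairs <- tibble::tibble(rank_a = as.integer(orthologs$orf_a),
                          rank_b = as.integer(orthologs$orf_b),
                          same_strand = orthologs$same_strand)
  pairs <- dplyr::arrange(pairs, .data$rank_a)
  if (nrow(pairs) > 0) {
    anchor_b <- pairs$rank_b[pairs$rank_a == 1L]
    if (length(anchor_b) == 1L) {
      shift <- anchor_b - 1L
    } else {
      cost <- vapply(0:(n_b - 1L), function(s) {
        rb <- mod1(pairs$rank_b - s, n_b)
        sum(pmin(abs(pairs$rank_a - rb),
                 n_b - abs(pairs$rank_a - rb)))
      }, numeric(1))
      shift <- which.min(cost) - 1L
    }
    pairs$rank_b <- mod1(pairs$rank_b - shift, n_b)
  }
  tibble::new_tibble(pairs, class = "parity_data", n_a = n_a, n_b = n_b)
}

#' Collinearity score of a parity table
#'
#' Fraction of consecutive ortholog pairs (sorted by rank in genome A, the
#' circular wrap pair included) whose genome-B ranks advance by exactly +1
#' modulo the genome-B ORF count. 1.0 for perfectly conserved gene order.
#'
#' @param parity A [parity_coordinates()] result.
#' @return Fraction in `[0, 1]`.
#' @export
collinearity_score <- function(parity) {
  if (nrow(parity) < 2L) {
    stop("collinearity is undefined for fewer than 2 ortholog pairs", call. = FALSE)
  }
  n_b <- attr(parity, "n_b")
  p <- dplyr::arrange(tibble::as_tibble(parity), .data$rank_a)
  nxt <- c(p$rank_b[-1], p$rank_b[1])
  step <- (nxt - p$rank_b) %% n_b
  mean(step == 1L)
}

#' Detect inverted gene blocks in a parity table
#'
#' Reports every maximal run of at least `min_run` consecutive ortholog pairs
#' (by genome-A rank order) whose genome-B ranks strictly decrease — the
#' anti-diagonal signature of a genome-segment inversion. The nucleotide span
#' is measured in genome-A coordinates, boundary genes inclusive.
#'
#' @param parity A [parity_coordinates()] result.
#' @param annot_a The genome-A annotation (for nucleotide spans).
#' @param min_run Minimum number of reversed consecutive pairs (default 3,
#'   suppressing singleton transpositions).
#' @return Tibble of class `inversion_table`: `a_start_rank`, `a_end_rank`,
#'   `n_genes`, `span_nt`.
#' @export
detect_inversions <- function(parity, annot_a, min_run = 3L) {
  p <- dplyr::arrange(tibble::as_tibble(parity), .data$rank_a)
  out <- tibble::tibble(a_start_rank = integer(0), a_end_rank = integer(0),
                        n_genes = integer(0), span_nt = integer(0))
  n <- nrow(p)
  if (n >= min_run) {
    dec <- diff(p$rank_b) < 0
    runs <- rle(dec)
    idx_end <- cumsum(runs$lengths)
    idx_start <- idx_end - runs$lengths + 1L
    segs <- which(runs$values & runs$lengths >= (min_run - 1L))
    rows <- purrr::map(segs, function(k) {
      i0 <- idx_start[k]           # first pair of the decreasing stretch
      i1 <- idx_end[k] + 1L        # last pair
      tibble::tibble(a_start_rank = p$rank_a[i0], a_end_rank = p$rank_a[i1],
                     n_genes = i1 - i0 + 1L)
    })
    if (length(rows) > 0) {
      out <- dplyr::bind_rows(rows)
      L <- annot_a$genome$length
      o <- annot_a$orfs
      first <- o$fp_start[match(out$a_start_rank, o$orf_id)]
      last <- o$fp_end[match(out$a_end_rank, o$orf_id)]
      out$span_nt <- as.integer((last - first) %% L + 1L)
    }
  }
  tibble::new_tibble(out, class = "inversion_table")
}

#' Detect strand flips without order reversal
#'
#' Runs of consecutive ortholog pairs transcribed from opposite strands in the
#' two genomes but whose gene order is preserved; reported separately from
#' inversions.
#'
#' @inheritParams detect_inversions
#' @param min_run Minimum run length (default 2).
#' @return Tibble with `a_start_rank`, `a_end_rank`, `n_genes`.
#' @export
detect_strand_flips <- function(parity, min_run = 2L) {
  p <- dplyr::arrange(tibble::as_tibble(parity), .data$rank_a)
  out <- tibble::tibble(a_start_rank = integer(0), a_end_rank = integer(0),
                        n_genes = integer(0))
  if (nrow(p) == 0L) return(out)
  ordered_fwd <- c(diff(p$rank_b) > 0, TRUE)
  flip <- !p$same_strand & ordered_fwd
  runs <- rle(flip)
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1L
  segs <- which(runs$values & runs$lengths >= min_run)
  if (length(segs) == 0L) return(out)
  dplyr::bind_rows(purrr::map(segs, function(k) {
    tibble::tibble(a_start_rank = p$rank_a[idx_start[k]],
                   a_end_rank = p$rank_a[idx_end[k]],
                   n_genes = idx_end[k] - idx_start[k] + 1L)
  }))
}

#' @export
glance.parity_data <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x),
    n_a = attr(x, "n_a"),
    n_b = attr(x, "n_b"),
    collinearity = if (nrow(x) >= 2) collinearity_score(x) else NA_real_
  )
}

#' Gene parity plot
#'
#' @param object A [parity_coordinates()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.parity_data <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank_a, y = .data$rank_b,
                                   shape = .data$same_strand)) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = "same strand") +
    ggplot2::labs(x = "ORF rank, genome A", y = "ORF rank, genome B",
                  title = "Gene parity plot") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.parity_data
#' @param parity A [parity_coordinates()] result.
#' @export
plot_parity <- function(parity) autoplot.parity_data(parity)
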