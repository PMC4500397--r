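#' Linearized map of an annotated genome
#'
#' ORFs are drawn as horizontal segments on the linearized circle, plus-strand
#' above and minus-strand below the axis; an ORF wrapping the origin appears as
#' two segments.
#'
#' @param object A `genome_annotation`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.genome_annotation <- function(object, ...) {
  L <- object$genome$length
  o <- object$orfs
  segs <- purrr::map(seq_len(nrow(o)), function(i) {
    iv <- fp_intervals(o$fp_start[i], o$fp_end[i], L)
    tibble::tibble(orf_id = o$orf_id[i], strand = o$strand[i],
                   x = iv[, 1], xend = iv[, 2])
  })
  df <- dplyr::bind_rows(segs)
  df$y <- ifelse(df$strand == "+", 1, -1)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$x / 1000, xend = .data$xend / 1000,
                   y = .data$y, yend = .data$y, colour = .data$strand),
      linewidth = 3, lineend = "butt") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey50") +
    ggplot2::scale_y_continuous(limits = c(-2, 2), breaks = NULL) +
    ggplot2::labs(x = "genome position (kb)", y = NULL,
                  title = sprintf("%s (%s nt)", object$genome$id,
                                  format(L, big.mark = ","))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.genome_annotation
#' @param annot A `genome_annotation`.
#' @export
plot_genome_map <- function(annot) autoplot.genome_annotation(annot)

#' Plot repeat-region architecture along the genome
#'
#' @param object A `repeat_region_table` from [find_repeat_regions()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.repeat_region_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$genome_start / 1000,
                                   y = .data$n_full_copies,
                                   colour = .data$classification,
                                   size = .data$at_fraction)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "genome position (kb)", y = "full repeat copies",
                  title = "Candidate repeat regions") +
    ggplot2::theme_minimal()
}
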