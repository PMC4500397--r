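#' Promoter-scan configuration
#'
#' Standard baculovirus promoter conventions: a late promoter is the TAAG
#' motif; an early promoter is a TATA box followed by a CAGT or CATT initiator
#' at a 20-40 nt gap. Both are sought within `window_nt` bases upstream of the
#' start codon on the coding strand.
#'
#' @param window_nt Upstream window (default 150 nt).
#' @param late_motif Late promoter motif (default `"TAAG"`).
#' @param early_tata TATA-box motif (default `"TATA"`).
#' @param early_initiator Early initiator motifs (default `c("CAGT", "CATT")`).
#' @param tata_initiator_gap Allowed gap (nt between TATA end and initiator
#'   start), default `c(20, 40)`.
#' @param intergenic_only Restrict the window to intergenic sequence (exclude
#'   bases covered by an upstream ORF); default `FALSE` — baculovirus genomes
#'   are compact and promoters routinely overlap upstream coding sequence.
#' @return A list of class `promoter_config`.
#' @export
promoter_config <- function(window_nt = 150L, late_motif = "TAAG",
                            early_tata = "TATA",
                            early_initiator = c("CAGT", "CATT"),
                            tata_initiator_gap = c(20L, 40L),
                            intergenic_only = FALSE) {
  if (window_nt < 1L) stop("`window_nt` must be positive", call. = FALSE)
  structure(list(window_nt = as.integer(window_nt),
                 late_motif = toupper(late_motif),
                 early_tata = toupper(early_tata),
                 early_initiator = toupper(early_initiator),
                 tata_initiator_gap = as.integer(tata_initiator_gap),
                 intergenic_only = isTRUE(intergenic_only)),
            class = "promoter_config")
}

#' Scan upstream windows for early and late promoter motifs
#'
#' For each ORF the `window_nt` bases immediately upstream of the ATG on the
#' coding strand (wrapping the circular origin when needed) are scanned. Every
#' occurrence of the late motif is a late hit. An early hit requires the TATA
#' box followed by an initiator with a gap inside `tata_initiator_gap`;
#' the reported motif spans TATA through the initiator.
#'
#' @param annot A `genome_annotation`.
#' @param config A [promoter_config()].
#' @return Tibble of class `promoter_hits`: `orf_id`, `kind`
#'   (`"early"`/`"late"`), `position` (nt upstream of the ATG of the motif's
#'   first base; 1 = immediately adjacent), `motif_seq`.
#' @export
scan_promoters <- function(annot, config = promoter_config()) {
  stopifnot(inherits(annot, "genome_annotation"))
  g <- annot$genome
  L <- g$length
  o <- annot$orfs
  W <- min(config$window_nt, L - 1L)
  rows <- purrr::map(seq_len(nrow(o)), function(i) {
    # upstream window on the coding strand, 5'->3', ending just before the ATG
    if (o$strand[i] == "+") {
      w_end <- mod1(o$start[i] - 1L, L)
      w_start <- mod1(o$start[i] - W, L)
      win <- circular_subsequence(g, w_start, w_end, "+")
    } else {
      w_start <- mod1(o$start[i] + 1L, L)
      w_end <- mod1(o$start[i] + W, L)
      win <- circular_subsequence(g, w_start, w_end, "-")
    }
    if (config$intergenic_only) {
      cov <- coverage_mask(annot)
      idx <- if (o$strand[i] == "+") {
        mod1(seq(o$start[i] - W, o$start[i] - 1L), L)
      } else {
        rev(mod1(seq(o$start[i] + 1L, o$start[i] + W), L))
      }
      own <- fp_positions(o$fp_start[i], o$fp_end[i], L)
      keep_from <- max(c(0L, which(cov[idx] & !(idx %in% own)))) + 1L
      if (keep_from > 1L) win <- substr(win, keep_from, nchar(win))
    }
    nw <- nchar(win)
    hits <- list()
    late <- stringr::str_locate_all(win, stringr::fixed(config$late_motif))[[1]]
    if (nrow(late) > 0) {
      hits[[1]] <- tibble::tibble(
        orf_id = o$orf_id[i], kind = "late",
        position = as.integer(nw - unname(late[, "start"]) + 1L),
        motif_seq = substring(win, late[, "start"], late[, "end"]))
    }
    tatas <- stringr::str_locate_all(win, stringr::fixed(config$early_tata))[[1]]
    inits <- do.call(rbind, stringr::str_locate_all(
      win, stringr::str_c(config$early_initiator, collapse = "|"))[1])
    if (nrow(tatas) > 0 && !is.null(inits) && nrow(inits) > 0) {
      early <- purrr::map(seq_len(nrow(tatas)), function(t) {
        gap <- inits[, "start"] - tatas[t, "end"] - 1L
        ok <- which(gap >= config$tata_initiator_gap[1] &
                      gap <= config$tata_initiator_gap[2])
        if (length(ok) == 0L) return(NULL)
        tibble::tibble(
          orf_id = o$orf_id[i], kind = "early",
          position = as.integer(nw - unname(tatas[t, "start"]) + 1L),
          motif_seq = substring(win, tatas[t, "start"], inits[ok, "end"]))
      })
      hits[[length(hits) + 1L]] <- dplyr::bind_rows(early)
    }
    dplyr::bind_rows(hits)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(orf_id = integer(0), kind = character(0),
                          position = integer(0), motif_seq = character(0))
  }
  tibble::new_tibble(dplyr::arrange(out, .data$orf_id, dplyr::desc(.data$position)),
                     class = "promoter_hits")
}

coverage_mask <- function(annot) {
  L <- annot$genome$length
  cov <- logical(L)
  for (i in seq_len(nrow(annot$orfs))) {
    cov[fp_positions(annot$orfs$fp_start[i], annot$orfs$fp_end[i], L)] <- TRUE
  }
  cov
}

fp_positions <- function(fp_start, fp_end, L) {
  if (fp_start <= fp_end) fp_start:fp_end else c(fp_start:L, 1:fp_end)
}
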