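#' Construct a circular genome object
#'
#' Baculovirus genomes are closed circles of double-stranded DNA, conventionally
#' reported in a linearized form anchored at the granulin start codon. A
#' `circular_genome` stores the linearized sequence together with its topology so
#' that downstream coordinate arithmetic can wrap through the origin.
#'
#' @param seq Nucleotide string over `A`, `C`, `G`, `T`, `N` (case-insensitive;
#'   normalized to upper case). `U` is rejected: this is a DNA-only toolkit.
#' @param id Character label for the genome.
#' @param topology `"circular"` (default) or `"linear"`.
#'
#' @return An object of class `circular_genome`: a list with elements `id`,
#'   `seq`, `topology` and `length`.
#' @export
#' @examples
#' g <- circular_genome("atgcatgc", id = "toy")
#' g$length
circular_genome <- function(seq, id = "genome", topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop("`seq` must be a single nucleotide string", call. = FALSE)
  }
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop("genome sequence is empty", call. = FALSE)
  bad <- stringr::str_locate(seq, "[^ACGTN]")[1, "start"]
  if (!is.na(bad)) {
    stop(sprintf("illegal character '%s' at position %d of '%s' (alphabet is A/C/G/T/N)",
                 substr(seq, bad, bad), bad, id), call. = FALSE)
  }
  structure(
    list(id = id, seq = seq, topology = topology, length = nchar(seq)),
    class = "circular_genome"
  )
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %s nt, %s, GC %.1f%%\n",
              x$id, format(x$length, big.mark = ","), x$topology,
              100 * gc_content(x$seq)))
  invisible(x)
}

#' @export
format.circular_genome <- function(x, ...) {
  sprintf("%s (%d nt, %s)", x$id, x$length, x$topology)
}

#' Read a genome from FASTA or GenBank
#'
#' Reads a single-record sequence file. FASTA parsing goes through
#' [Biostrings::readDNAStringSet()]; GenBank flat files are handled by a minimal
#' single-record reader (LOCUS line and ORIGIN block) because viral genome
#' records are routinely exchanged in this format. The LOCUS topology field
#' (`circular`/`linear`) is honored when present.
#'
#' @param path Path to the sequence file.
#' @param format `"auto"` (by extension/first character), `"fasta"` or
#'   `"genbank"`.
#' @param topology Topology to assume when the file does not state one.
#' @return A [circular_genome()].
#' @export
read_genome <- function(path, format = c("auto", "fasta", "genbank"),
                        topology = c("circular", "linear")) {
  format <- match.arg(format)
  topology <- match.arg(topology)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    if (length(first) == 0L) stop(sprintf("empty file: %s", path), call. = FALSE)
    format <- if (startsWith(first, ">")) "fasta" else "genbank"
  }
  if (format == "fasta") {
    set <- Biostrings::readDNAStringSet(path)
    if (length(set) == 0L) stop(sprintf("no sequence records in %s", path), call. = FALSE)
    if (length(set) > 1L) {
      stop(sprintf("expected exactly one record in %s, found %d (first two: %s, %s)",
                   path, length(set), names(set)[1], names(set)[2]), call. = FALSE)
    }
    id <- stringr::str_split_1(names(set)[1], "\\s+")[1]
    circular_genome(as.character(set[[1]]), id = id, topology = topology)
  } else {
    read_genbank_record(path, default_topology = topology)
  }
}

# Minimal single-record GenBank flat-file reader: LOCUS (name, topology) and
# ORIGIN block only. Feature tables are intentionally ignored; annotation is
# recomputed by this package.
read_genbank_record <- function(path, default_topology = "circular") {
  lines <- readLines(path, warn = FALSE)
  locus_idx <- grep("^LOCUS", lines)
  if (length(locus_idx) == 0L) {
    stop(sprintf("%s: no LOCUS line; not a GenBank record", path), call. = FALSE)
  }
  if (length(locus_idx) > 1L) {
    stop(sprintf("%s: %d LOCUS lines; expected exactly one record", path, length(locus_idx)),
         call. = FALSE)
  }
  locus <- lines[locus_idx]
  fields <- stringr::str_split_1(stringr::str_trim(locus), "\\s+")
  id <- if (length(fields) >= 2) fields[2] else "genbank_record"
  topology <- default_topology
  if (any(grepl("\\bcircular\\b", locus, ignore.case = TRUE))) topology <- "circular"
  if (any(grepl("\\blinear\\b", locus, ignore.case = TRUE))) topology <- "linear"
  origin_idx <- grep("^ORIGIN", lines)
  if (length(origin_idx) == 0L) {
    stop(sprintf("%s: no ORIGIN block", path), call. = FALSE)
  }
  end_idx <- grep("^//", lines)
  end_idx <- end_idx[end_idx > origin_idx[1]][1]
  if (is.na(end_idx)) end_idx <- length(lines) + 1L
  body <- lines[seq(origin_idx[1] + 1L, end_idx - 1L)]
  seq <- gsub("[0-9 /]", "", paste(body, collapse = ""))
  if (nchar(seq) == 0L) stop(sprintf("%s: ORIGIN block holds no sequence", path), call. = FALSE)
  circular_genome(seq, id = id, topology = topology)
}

#' Write a genome to FASTA
#'
#' @param genome A [circular_genome()].
#' @param path Output path.
#' @param width Line wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  stopifnot(inherits(genome, "circular_genome"))
  x <- Biostrings::DNAStringSet(genome$seq)
  names(x) <- genome$id
  Biostrings::writeXStringSet(x, path, width = as.integer(width))
  invisible(path)
}

#' G+C content of a nucleotide sequence
#'
#' Fraction (G+C)/(A+C+G+T); `N` characters are excluded from the denominator,
#' so assemblies with ambiguity positions still yield a well-defined
#' composition.
#'
#' @param seq Nucleotide string, or a [circular_genome()].
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' gc_content("ATGC") # 0.5
gc_content <- function(seq) {
  seq <- as_seq(seq)
  if (nchar(seq) == 0L) stop("cannot compute composition of an empty sequence", call. = FALSE)
  counts <- base_counts(seq)
  denom <- sum(counts[c("A", "C", "G", "T")])
  if (denom == 0L) stop("sequence contains no unambiguous bases", call. = FALSE)
  unname((counts[["G"]] + counts[["C"]]) / denom)
}

#' A+T content of a nucleotide sequence
#'
#' Complement of [gc_content()] over unambiguous bases.
#' @inheritParams gc_content
#' @return Fraction in `[0, 1]`.
#' @export
at_content <- function(seq) 1 - gc_content(seq)

base_counts <- function(seq) {
  tab <- table(strsplit(seq, "", fixed = TRUE)[[1]])
  out <- c(A = 0L, C = 0L, G = 0L, T = 0L, N = 0L)
  common <- intersect(names(tab), names(out))
  out[common] <- as.integer(tab[common])
  out
}

as_seq <- function(x) {
  if (inherits(x, "circular_genome")) return(x$seq)
  if (!is.character(x) || length(x) != 1L) stop("expected a single sequence string", call. = FALSE)
  toupper(x)
}

#' Reverse complement
#'
#' @param seq Nucleotide string over `A/C/G/T/N`.
#' @return The reverse complement; `N` maps to `N`. The empty string maps to
#'   itself.
#' @export
#' @examples
#' reverse_complement("ATGC") # "GCAT"
reverse_complement <- function(seq) {
  seq <- as_seq(seq)
  if (nchar(seq) == 0L) return("")
  if (grepl("[^ACGTN]", seq)) {
    stop("reverse_complement: sequence contains characters outside A/C/G/T/N", call. = FALSE)
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Extract a (possibly wrapping) subsequence in circular coordinates
#'
#' Coordinates are 1-based and inclusive throughout the package. When
#' `start > end` on a circular genome the extraction wraps through the origin
#' (positions `start..length` followed by `1..end`). On the minus strand the
#' reverse complement of the extracted region is returned.
#'
#' @param genome A [circular_genome()].
#' @param start,end 1-based inclusive positions in `[1, length]`.
#' @param strand `"+"` or `"-"`.
#' @return Nucleotide string.
#' @export
#' @examples
#' g <- circular_genome("AAACCC")
#' circular_subsequence(g, 5, 2) # wraps: "CCAA"
circular_subsequence <- function(genome, start, end, strand = "+") {
  stopifnot(inherits(genome, "circular_genome"))
  L <- genome$length
  if (!(start >= 1 && start <= L && end >= 1 && end <= L)) {
    stop(sprintf("positions must lie in [1, %d]; got start=%s end=%s", L, start, end),
         call. = FALSE)
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  if (start <= end) {
    out <- substr(genome$seq, start, end)
  } else {
    if (genome$topology != "circular") {
      stop("subsequence wraps the origin but the genome topology is linear", call. = FALSE)
    }
    out <- paste0(substr(genome$seq, start, L), substr(genome$seq, 1, end))
  }
  if (strand == "-") out <- reverse_complement(out) else out
}

#' Summary statistics for a genome
#'
#' @param genome A [circular_genome()].
#' @return One-row tibble with `id`, `length`, `topology`, `gc_fraction`,
#'   `at_fraction`, `n_count`.
#' @export
genome_stats <- function(genome) {
  stopifnot(inherits(genome, "circular_genome"))
  counts <- base_counts(genome$seq)
  tibble::tibble(
    id = genome$id,
    length = genome$length,
    topology = genome$topology,
    gc_fraction = gc_content(genome$seq),
    at_fraction = at_content(genome$seq),
    n_count = unname(counts[["N"]])
  )
}

#' @rdname genome_stats
#' @param x A `circular_genome`.
#' @param ... Unused.
#' @export
glance.circular_genome <- function(x, ...) genome_stats(x)

#' Rotate a circular genome so that `new_origin` becomes position 1
#'
#' @param genome A [circular_genome()].
#' @param new_origin 1-based position that becomes nt 1.
#' @return A rotated [circular_genome()].
#' @export
rotate_genome <- function(genome, new_origin) {
  stopifnot(inherits(genome, "circular_genome"))
  L <- genome$length
  if (genome$topology != "circular" && new_origin != 1L) {
    stop("cannot rotate a linear genome", call. = FALSE)
  }
  if (!(new_origin >= 1 && new_origin <= L)) {
    stop(sprintf("new_origin must lie in [1, %d]", L), call. = FALSE)
  }
  if (new_origin == 1L) return(genome)
  seq <- paste0(substr(genome$seq, new_origin, L), substr(genome$seq, 1, new_origin - 1L))
  circular_genome(seq, id = genome$id, topology = genome$topology)
}

#' Reverse-complement a whole genome object
#'
#' Position `p` maps to `length - p + 1` and strands flip.
#' @param genome A [circular_genome()].
#' @return A [circular_genome()] of the opposite strand.
#' @export
flip_genome <- function(genome) {
  stopifnot(inherits(genome, "circular_genome"))
  circular_genome(reverse_complement(genome$seq), id = genome$id, topology = genome$topology)
}
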