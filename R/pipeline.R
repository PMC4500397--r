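PIPELINE_KEYS <- c("genome", "comparators", "panels", "anchor_protein",
                   "annotation", "repeats", "promoters", "phylogeny",
                   "min_score", "out_dir", "seed")

#' Run the full comparative-genomics pipeline
#'
#' Orchestrates annotation, gene classification, promoter scanning, repeat
#' discovery, parity/collinearity against comparator genomes and — with at
#' least three genomes — a concatenated-protein NJ bootstrap phylogeny.
#' Stages run in dependency order; a stage failure aborts with an error naming
#' the stage. All outputs plus a machine-readable report and a run manifest
#' are written under `out_dir`.
#'
#' @param config A named list, or the path of a YAML/JSON configuration file.
#'   Recognized keys: `genome` (path, required), `comparators` (paths),
#'   `panels` (named list `panel_id = path`), `anchor_protein` (FASTA path),
#'   `annotation`/`repeats`/`promoters` (parameter lists passed to
#'   [annotation_config()], [repeat_config()], [promoter_config()]),
#'   `phylogeny` (list: `bootstrap`, `max_genes`), `min_score`, `out_dir`,
#'   `seed`.
#' @param out_dir Output directory (overrides the config key).
#' @return The run manifest (list), invisibly; the report is in
#'   `<out_dir>/report.json`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown) > 0) {
    stop(sprintf("configuration error: unknown key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (is.null(config$genome)) {
    stop("configuration error: 'genome' is required", call. = FALSE)
  }
  out_dir <- out_dir %||% config$out_dir %||% stop(
    "configuration error: no output directory given", call. = FALSE)
  inputs <- c(config$genome, unlist(config$comparators), unlist(config$panels),
              config$anchor_protein)
  missing_in <- inputs[!file.exists(inputs)]
  if (length(missing_in) > 0) {
    stop(sprintf("configuration error: missing input file(s): %s",
                 paste(missing_in, collapse = ", ")), call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  min_score <- config$min_score %||% 50

  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  outputs <- character(0)
  emit <- function(x, file) {
    path <- file.path(out_dir, file)
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <<- c(outputs, path)
    path
  }
  report <- list()
  stage_params <- list()

  genome <- stage("read_genome", read_genome(config$genome))
  report$genome <- as.list(genome_stats(genome))

  ann_cfg <- do.call(annotation_config, as.list(config$annotation %||% list()))
  anchor_protein <- NULL
  if (!is.null(config$anchor_protein)) {
    aa <- Biostrings::readAAStringSet(config$anchor_protein)
    anchor_protein <- as.character(aa[[1]])
  }
  annot <- stage("annotate", annotate_genome(genome, ann_cfg,
                                             anchor_protein = anchor_protein))
  st <- annotation_stats(annot)
  report$annotation <- c(as.list(st$summary), list(n_candidates = NA))
  emit(annot$orfs[, setdiff(names(annot$orfs), "protein")], "orfs.tsv")
  write_annotation_gff3(annot, file.path(out_dir, "annotation.gff3"))
  write_protein_fasta(annot, file.path(out_dir, "proteins.faa"))
  outputs <- c(outputs, file.path(out_dir, c("annotation.gff3", "proteins.faa")))
  stage_params$annotation <- unclass(ann_cfg)

  if (!is.null(config$panels)) {
    panels <- stage("classify", purrr::imap(config$panels,
                                            ~ read_protein_panel(.x, .y)))
    cls <- stage("classify", classify_genes(annot, unname(panels), min_score))
    report$gene_classes <- stats::setNames(as.list(cls$counts$n), cls$counts$class)
    emit(cls$classes, "gene_classes.tsv")
    emit(cls$family_presence, "family_presence.tsv")
  }

  prom_cfg <- do.call(promoter_config, as.list(config$promoters %||% list()))
  proms <- stage("promoters", scan_promoters(annot, prom_cfg))
  report$promoters <- list(n_hits = nrow(proms),
                           n_late = sum(proms$kind == "late"),
                           n_early = sum(proms$kind == "early"))
  emit(proms, "promoters.tsv")
  stage_params$promoters <- unclass(prom_cfg)

  rep_cfg <- do.call(repeat_config, as.list(config$repeats %||% list()))
  reps <- stage("repeats", find_repeat_regions(annot, rep_cfg))
  report$repeat_regions <- list(
    n_regions = nrow(reps),
    n_non_hr = sum(reps$classification == "non_hr"))
  emit(tibble::as_tibble(reps), "repeat_regions.tsv")
  stage_params$repeats <- unclass(rep_cfg)

  comp_annots <- list()
  if (length(config$comparators) > 0) {
    report$parity <- list()
    for (cp in config$comparators) {
      cg <- stage("parity", read_genome(cp))
      ca <- stage("parity", annotate_genome(cg, ann_cfg,
                                            anchor_protein = anchor_protein))
      comp_annots[[cg$id]] <- ca
      orth <- stage("parity", ortholog_map(annot, ca, min_score))
      par <- stage("parity", parity_coordinates(orth, annot, ca))
      inv <- detect_inversions(par, annot)
      report$parity[[cg$id]] <- list(
        n_orthologs = nrow(orth),
        collinearity = if (nrow(par) >= 2) collinearity_score(par) else NA,
        n_inversions = nrow(inv),
        max_inversion_span_nt = if (nrow(inv)) max(inv$span_nt) else 0)
      emit(tibble::as_tibble(par), sprintf("parity_%s.tsv", cg$id))
    }
  }

  if (length(comp_annots) >= 2) {
    phy_cfg <- config$phylogeny %||% list()
    n_boot <- as.integer(phy_cfg$bootstrap %||% 100L)
    tree <- stage("phylogeny", {
      blocks <- common_gene_blocks(annot, comp_annots, min_score,
                                   max_genes = phy_cfg$max_genes %||% 40L)
      sm <- build_supermatrix(blocks)
      bootstrap_support(sm, n_replicates = n_boot, seed = seed)
    })
    write_tree_newick(tree, file.path(out_dir, "tree.nwk"))
    outputs <- c(outputs, file.path(out_dir, "tree.nwk"))
    report$phylogeny <- list(n_taxa = length(tree$tip.label),
                             n_bootstrap = n_boot,
                             newick = ape::write.tree(tree))
    stage_params$phylogeny <- list(bootstrap = n_boot, seed = seed)
  } else {
    report$skipped_stages <- c(
      if (length(comp_annots) == 0) "parity",
      if (length(comp_annots) < 2) "phylogeny")
  }

  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  outputs <- c(outputs, report_path)
  manifest <- list(
    tool = paste("gvcompare", as.character(utils::packageVersion("gvcompare"))),
    config = config,
    input_checksums = as.list(tools::md5sum(inputs)),
    stage_params = stage_params,
    seed = seed,
    outputs = basename(outputs)
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

# per-gene aligned blocks for genes with an ortholog in every genome
common_gene_blocks <- function(annot, comp_annots, min_score, max_genes = 40L) {
  maps <- purrr::map(comp_annots, ~ ortholog_map(annot, .x, min_score))
  common <- Reduce(intersect, purrr::map(maps, "orf_a"))
  common <- utils::head(sort(common), max_genes)
  if (length(common) < 2L) {
    stop("fewer than 2 gene families shared by all genomes", call. = FALSE)
  }
  ref_id <- annot$genome$id
  purrr::map(stats::setNames(common, paste0("gene_orf", common)), function(g) {
    seqs <- c(stats::setNames(
      annot$orfs$protein[annot$orfs$orf_id == g], ref_id))
    for (nm in names(comp_annots)) {
      m <- maps[[nm]]
      ob <- m$orf_b[m$orf_a == g]
      seqs[nm] <- comp_annots[[nm]]$orfs$protein[comp_annots[[nm]]$orfs$orf_id == ob]
    }
    align_protein_block(seqs)
  })
}
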