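#' Read per-locus FASTA alignments from a directory
#'
#' @param dir Directory containing one aligned FASTA file per locus.
#' @param pattern Filename regexp (default `"\\.fa(sta)?$"`).
#' @return Tibble with `locus_id` (filename sans extension) and an
#'   `alignment` list-column of character matrices.
#' @export
read_locus_alignments <- function(dir, pattern = "\\.fa(sta)?$") {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (length(files) == 0) stop(sprintf("no FASTA files found in '%s'", dir),
                               call. = FALSE)
  tibble::tibble(
    locus_id = sub(pattern, "", basename(files)),
    alignment = lapply(files, function(f) {
      as_alignment_matrix(Biostrings::readDNAStringSet(f))
    })
  )
}

#' Write a simulated (or processed) locus table to disk
#'
#' Emits one FASTA per locus, a single Newick file of the gene trees, and
#' a tab-separated truth table (`locus_id`, `topology_truth`,
#' `introgressed`, `tree_height`) when those columns are present.
#'
#' @param loci Loci tibble (e.g. from [simulate_alignments()]).
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(loci, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (("alignment" %in% names(loci))) {
    for (r in seq_len(nrow(loci))) {
      write_alignment_fasta(loci$alignment[[r]],
                            file.path(dir, paste0(loci$locus_id[r], ".fasta")))
    }
  }
  if (("tree" %in% names(loci))) {
    trees <- loci$tree
    class(trees) <- "multiPhylo"
    ape::write.tree(trees, file.path(dir, "gene_trees.nwk"))
  }
  truth_cols <- intersect(c("locus_id", "topology_truth", "introgressed",
                            "tree_height"), names(loci))
  if (length(truth_cols) > 1) {
    readr::write_tsv(loci[truth_cols], file.path(dir, "truth.tsv"))
  }
  invisible(dir)
}

write_alignment_fasta <- function(alignment, path) {
  m <- as_alignment_matrix(alignment)
  seqs <- Biostrings::DNAStringSet(apply(m, 1, paste, collapse = ""))
  names(seqs) <- rownames(m)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read gene trees from Newick files
#'
#' Accepts either a single file with one tree per line or a directory of
#' one-tree files. Bootstrap values stored as node labels are preserved.
#'
#' @param path Newick file or directory.
#' @param pattern Filename regexp used when `path` is a directory.
#' @return Tibble with `locus_id` and a `tree` list-column.
#' @export
read_gene_trees <- function(path, pattern = "\\.(nwk|tre|treefile)$") {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = pattern, full.names = TRUE))
    if (length(files) == 0) stop(sprintf("no tree files found in '%s'", path),
                                 call. = FALSE)
    trees <- lapply(files, function(f) ape::read.tree(f))
    return(tibble::tibble(locus_id = sub(pattern, "", basename(files)),
                          tree = trees))
  }
  trees <- ape::read.tree(path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  as_trees_tbl(trees)
}

#' Read paired terminal-repeat sequences
#'
#' Two input layouts are supported. A paired FASTA holds two records per
#' element, `<element_id>/5prime` and `<element_id>/3prime`. A coordinate
#' table is tab-separated with columns `element_id`, `contig`,
#' `ltr5_start`, `ltr5_end`, `ltr3_start`, `ltr3_end`, `superfamily`
#' (1-based inclusive coordinates, the convention of LTR annotation
#' output) and requires the genome FASTA to slice from.
#'
#' @param path Paired FASTA, or coordinate TSV when `genome` is given.
#' @param genome Optional genome FASTA path.
#' @return Tibble with `element_id`, `seq5`, `seq3`, `superfamily`.
#' @export
read_ltr_pairs <- function(path, genome = NULL) {
  if (is.null(genome)) {
    seqs <- Biostrings::readDNAStringSet(path)
    nm <- names(seqs)
    ids5 <- sub("/5prime$", "", nm[grepl("/5prime$", nm)])
    ids3 <- sub("/3prime$", "", nm[grepl("/3prime$", nm)])
    ids <- intersect(ids5, ids3)
    if (length(ids) == 0) {
      stop("no '<id>/5prime' + '<id>/3prime' record pairs found", call. = FALSE)
    }
    return(tibble::tibble(
      element_id = ids,
      seq5 = as.character(seqs[paste0(ids, "/5prime")]),
      seq3 = as.character(seqs[paste0(ids, "/3prime")]),
      superfamily = NA_character_
    ))
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("element_id", "contig", "ltr5_start", "ltr5_end",
            "ltr3_start", "ltr3_end")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop(sprintf("coordinate table missing column(s): %s",
                                 paste(miss, collapse = ", ")), call. = FALSE)
  gen <- Biostrings::readDNAStringSet(genome)
  names(gen) <- sub("\\s.*", "", names(gen))
  slice <- function(contig, from, to) {
    as.character(Biostrings::subseq(gen[[contig]], start = from, end = to))
  }
  tibble::tibble(
    element_id = tab$element_id,
    seq5 = mapply(slice, tab$contig, tab$ltr5_start, tab$ltr5_end),
    seq3 = mapply(slice, tab$contig, tab$ltr3_start, tab$ltr3_end),
    superfamily = if ("superfamily" %in% names(tab)) tab$superfamily
                  else NA_character_
  )
}

#' Read / write a simulation configuration as JSON
#'
#' @param path JSON file.
#' @return [read_sim_config()] returns a [sim_config()];
#'   [write_sim_config()] returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @param config A [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
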