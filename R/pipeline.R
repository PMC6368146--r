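#' Configuration for the end-to-end introgression analysis
#'
#' @param alignment_dir Directory of per-locus FASTA alignments.
#' @param tree_file Newick file (one tree per line, ids matching the
#'   alignment order) or directory of per-locus tree files with filenames
#'   matching the alignment locus ids.
#' @param taxon_map Named character vector mapping roles `A`, `B`, `C`,
#'   `O` to tip/sequence labels.
#' @param masking A [masking_config()].
#' @param cutoffs Mean-bootstrap cutoffs for the concordance summary.
#' @param depth A [depth_config()].
#' @param n_boot Bootstrap resamples for the depth test.
#' @param seed Integer seed (depth-test resampling).
#' @param out_dir Output directory; created by the run.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(alignment_dir, tree_file, taxon_map,
                            masking = masking_config(),
                            cutoffs = c(50, 60, 70, 80, 90),
                            depth = depth_config(),
                            n_boot = 1000, seed = 1,
                            out_dir = "introdepth_run") {
  structure(
    list(alignment_dir = alignment_dir, tree_file = tree_file,
         taxon_map = taxon_map, masking = masking, cutoffs = cutoffs,
         depth = depth, n_boot = n_boot, seed = seed, out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Validate a pipeline configuration
#'
#' Collects every violated invariant rather than stopping at the first;
#' an empty report means the configuration is runnable.
#'
#' @param config A [pipeline_config()].
#' @return Tibble with `field` and `message`, zero rows when valid.
#' @examples
#' cfg <- pipeline_config("missing_dir", "missing.nwk",
#'                        c(A = "a", B = "b", C = "c", O = "o"))
#' validate_config(cfg)
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  probs <- list()
  flag <- function(field, message) {
    probs[[length(probs) + 1L]] <<- tibble::tibble(field = field,
                                                   message = message)
  }
  roles <- c("A", "B", "C", "O")
  tm <- config$taxon_map
  missing_roles <- setdiff(roles, names(tm))
  for (r in missing_roles) flag("taxon_map", sprintf("role '%s' missing", r))
  if (length(missing_roles) == 0 && anyDuplicated(tm[roles])) {
    flag("taxon_map", "two roles map to the same tip label")
  }
  if (!dir.exists(config$alignment_dir)) {
    flag("alignment_dir", sprintf("directory '%s' not found", config$alignment_dir))
  }
  if (!file.exists(config$tree_file) && !dir.exists(config$tree_file)) {
    flag("tree_file", sprintf("path '%s' not found", config$tree_file))
  }
  if (!inherits(config$masking, "masking_config")) {
    flag("masking", "not a masking_config object")
  }
  if (!inherits(config$depth, "depth_config")) {
    flag("depth", "not a depth_config object")
  }
  if (!is.numeric(config$cutoffs) || length(config$cutoffs) == 0) {
    flag("cutoffs", "must be a non-empty numeric vector")
  }
  if (!is.numeric(config$n_boot) || length(config$n_boot) != 1L ||
      is.na(config$n_boot) || config$n_boot < 100) {
    flag("n_boot", "must be a single number >= 100")
  }
  if (!is.numeric(config$seed) || length(config$seed) != 1L ||
      is.na(config$seed)) {
    flag("seed", "must be a single integer")
  }
  if (length(probs) == 0) {
    tibble::tibble(field = character(), message = character())
  } else {
    dplyr::bind_rows(probs)
  }
}

#' Run the full mask / classify / concordance / depth-test analysis
#'
#' Chains the pipeline stages on a directory of loci: window-masks each
#' alignment and drops heavily masked loci, classifies each retained gene
#' tree's triplet topology, summarizes concordance across bootstrap
#' cutoffs, estimates per-locus node depths for the two most prevalent
#' conflicting topology classes (at the lowest cutoff, unless overridden),
#' and runs the depth test. All tabular outputs, the verdict JSON, an
#' exclusion log, and a reproducibility manifest are written under
#' `config$out_dir`; outputs contain no timestamps, so a rerun with the
#' same config and seed is byte-identical.
#'
#' @param config A [pipeline_config()]; must validate cleanly.
#' @param classes Optional length-2 character vector fixing the two
#'   topology classes compared by the depth test.
#' @return A list (`introgression_analysis`) with `concordance`, `depths`,
#'   `test` (the [compare_depth_classes()] result), `exclusions`,
#'   `manifest`, and `out_dir`.
#' @export
run_introgression_analysis <- function(config, classes = NULL) {
  report <- validate_config(config)
  if (nrow(report) > 0) {
    stop(paste0("invalid pipeline config:\n",
                paste(sprintf("  %s: %s", report$field, report$message),
                      collapse = "\n")), call. = FALSE)
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  exclusions <- list()
  note_excl <- function(stage, locus_id, reason) {
    exclusions[[length(exclusions) + 1L]] <<-
      tibble::tibble(stage = stage, locus_id = locus_id, reason = reason)
  }

  ## stage 1: load
  loci <- read_locus_alignments(config$alignment_dir)
  trees <- read_gene_trees(config$tree_file)
  if (nrow(trees) == nrow(loci)) {
    ## single multi-tree file: pair by order; directory input: pair by id
    if (!all(trees$locus_id %in% loci$locus_id)) {
      trees$locus_id <- loci$locus_id
    }
  }
  loci <- dplyr::inner_join(loci, trees, by = "locus_id")
  n_loaded <- nrow(loci)

  ## drop loci missing any mapped taxon
  tm <- config$taxon_map[c("A", "B", "C", "O")]
  has_taxa <- vapply(seq_len(nrow(loci)), function(r) {
    all(tm %in% rownames(loci$alignment[[r]])) &&
      all(tm %in% loci$tree[[r]]$tip.label)
  }, logical(1))
  for (id in loci$locus_id[!has_taxa]) note_excl("load", id, "missing_taxon")
  loci <- loci[has_taxa, , drop = FALSE]
  if (nrow(loci) == 0) stop("no locus carries all four mapped taxa", call. = FALSE)

  ## reduce alignments to the four roles, in role order
  loci$alignment <- lapply(loci$alignment, function(m) {
    m <- m[tm, , drop = FALSE]
    rownames(m) <- names(tm)
    m
  })

  ## stage 2: masking + drop rule
  loci <- mask_loci(loci, config$masking)
  for (id in loci$locus_id[loci$dropped]) note_excl("mask", id, "masked_fraction_exceeded")
  masked_report <- loci[c("locus_id", "masked_fraction", "dropped")]
  loci <- loci[!loci$dropped, , drop = FALSE]
  if (nrow(loci) == 0) stop("no locus survived masking", call. = FALSE)
  n_masked <- nrow(loci)

  ## stage 3: classification + concordance
  loci <- classify_topologies(loci, config$taxon_map)
  conc <- summarize_concordance(loci, cutoffs = config$cutoffs)

  ## stage 4: depth estimation on the two most prevalent conflicting classes
  if (is.null(classes)) {
    counts <- c("AB|C" = conc$n_ab_c[1], "AC|B" = conc$n_ac_b[1],
                "BC|A" = conc$n_bc_a[1])
    classes <- names(sort(counts, decreasing = TRUE))[1:2]
  }
  in_classes <- loci$topology %in% classes
  for (id in loci$locus_id[!in_classes]) note_excl("depth", id, "topology_not_compared")
  depths <- estimate_depths(loci[in_classes, , drop = FALSE], config = config$depth)
  dexcl <- attr(depths, "excluded")
  for (r in seq_len(nrow(dexcl))) note_excl("depth", dexcl$locus_id[r], dexcl$reason[r])

  ## stage 5: depth test
  test <- compare_depth_classes(depths, classes[1], classes[2],
                                n_boot = config$n_boot, seed = config$seed)

  excl_tbl <- if (length(exclusions)) dplyr::bind_rows(exclusions) else
    tibble::tibble(stage = character(), locus_id = character(), reason = character())

  manifest <- list(
    package_version = as.character(utils::packageVersion("introdepth")),
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    seed = config$seed,
    taxon_map = as.list(tm),
    depth_classes = classes,
    locus_counts = list(loaded = n_loaded,
                        after_taxon_check = n_loaded - sum(!has_taxa),
                        after_masking = n_masked,
                        depth_tested = nrow(depths))
  )

  readr::write_tsv(masked_report, file.path(out_dir, "masking_report.tsv"))
  readr::write_tsv(tibble::as_tibble(conc), file.path(out_dir, "concordance.tsv"))
  readr::write_tsv(depths, file.path(out_dir, "depths.tsv"))
  readr::write_tsv(excl_tbl, file.path(out_dir, "exclusions.tsv"))
  jsonlite::write_json(
    list(verdict = test$verdict,
         inferred_species_topology = test$inferred_species_topology,
         inferred_introgressed_topology = test$inferred_introgressed_topology,
         class_means = test$class_means, differences = test$differences),
    file.path(out_dir, "verdict.json"),
    auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(
    list(concordance = conc, depths = depths, test = test,
         exclusions = excl_tbl, manifest = manifest, out_dir = out_dir),
    class = "introgression_analysis"
  )
}

#' @export
print.introgression_analysis <- function(x, ...) {
  cat("<introgression_analysis>\n")
  cnt <- x$manifest$locus_counts
  cat(sprintf("  loci: %d loaded -> %d after masking -> %d depth-tested\n",
              cnt$loaded, cnt$after_masking, cnt$depth_tested))
  print(x$test)
  invisible(x)
}
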