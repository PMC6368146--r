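#' Biallelic parsimony-informative sites of a four-taxon alignment
#'
#' Returns the alignment columns carrying exactly two distinct character
#' states, each present in at least two of the four sequences — the
#' biallelic informative site patterns (xxyy, xyxy, xyyx up to labelling).
#' Columns containing gaps or mask characters are excluded, as are
#' singleton and tri-/quadra-allelic columns.
#'
#' @param alignment Character matrix with the four rows A, B, C, O (any
#'   row order; matched by rowname when present).
#' @param mask_char Mask symbol treated as missing (default `"N"`).
#' @return Integer vector of column indices.
#' @examples
#' aln <- rbind(A = c("T", "T"), B = c("T", "G"),
#'              C = c("G", "C"), O = c("G", "A"))
#' biallelic_informative_sites(aln) # first column only
#' @export
biallelic_informative_sites <- function(alignment, mask_char = "N") {
  m <- as_alignment_matrix(alignment)
  if (nrow(m) < 4L) stop("alignment must contain 4 taxa", call. = FALSE)
  miss <- is_missing_char(m, mask_char)
  alphabet <- setdiff(unique(as.vector(m)), c("-", mask_char, "?", "n"))
  if (length(alphabet) == 0) return(integer(0))
  counts <- vapply(alphabet, function(ch) colSums(m == ch),
                   numeric(ncol(m)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  no_miss <- colSums(miss) == 0L
  n_alleles <- rowSums(counts > 0)
  min_present <- rep(Inf, nrow(counts)) # running minimum over alleles present
  for (k in seq_len(ncol(counts))) {
    ck <- counts[, k]
    min_present <- pmin(min_present, ifelse(ck > 0, ck, Inf))
  }
  which(no_miss & n_alleles == 2 & min_present >= 2)
}

#' Depth-estimation settings
#'
#' @param min_sites Minimum count of biallelic informative sites for a
#'   locus to be dated (default 10; below this the per-locus variance of
#'   the depth estimates dominates any signal).
#' @param correction Distance correction: `"JC"` (one-parameter model,
#'   default) or `"raw"`.
#' @param site_set Columns over which pairwise divergences are computed:
#'   `"resolved"` (default) uses every ungapped, unmasked column;
#'   `"informative"` restricts to the biallelic informative subset, a
#'   sensitivity-analysis mode — note that on that subset cross-pair
#'   divergences approach saturation, so it is best combined with
#'   `correction = "raw"`.
#' @param normalize_by_outgroup If `TRUE`, divide both depths by the mean
#'   ingroup-outgroup divergence, removing locus-specific rate variation.
#' @return A `depth_config` object.
#' @export
depth_config <- function(min_sites = 10, correction = c("JC", "raw"),
                         site_set = c("resolved", "informative"),
                         normalize_by_outgroup = FALSE) {
  check_scalar(min_sites, "min_sites", lower = 1, integer = TRUE)
  structure(
    list(min_sites = as.integer(min_sites),
         correction = match.arg(correction),
         site_set = match.arg(site_set),
         normalize_by_outgroup = isTRUE(normalize_by_outgroup)),
    class = "depth_config"
  )
}

#' Per-gene node depths T1 and T2 from informative sites
#'
#' Estimates the depths of the two internal nodes of a rooted triplet gene
#' tree from sequence divergence under a molecular clock. With cherry pair
#' (X, Y) and third taxon Z given by the locus topology:
#' `T1 = d(X,Y) / 2` (shallow node) and `T2 = (d(X,Z) + d(Y,Z)) / 4`
#' (deep node), where `d` is the corrected pairwise divergence computed
#' over the fully-resolved columns. A locus is dated only when it carries
#' at least `min_sites` biallelic informative sites — the columns that
#' actually anchor the internal structure of the quartet — so noisy,
#' signal-poor loci are excluded rather than averaged in. Because
#' introgression replaces one lineage with a recently diverged copy,
#' introgressed loci show systematically smaller depths — the signal
#' exploited by [compare_depth_classes()].
#'
#' The data-frame method maps over a loci table and returns a depth table;
#' loci failing the `min_sites` requirement (or without a resolved
#' topology) are excluded and listed in the `"excluded"` attribute with a
#' reason code.
#'
#' @param x A four-taxon alignment matrix, or a tibble of loci with
#'   `alignment` and `topology` columns.
#' @param topology The locus's triplet topology (matrix method).
#' @param config A [depth_config()].
#' @param ... Passed between methods.
#' @return Matrix method: one-row tibble `topology`, `t1`, `t2`,
#'   `n_sites_used` (`t1`/`t2` are `NA` when too few sites). Data-frame
#'   method: tibble with `locus_id`, `topology`, `t1`, `t2`,
#'   `n_sites_used` for the dated loci.
#' @examples
#' cfg <- sim_config(n_loci = 5, seq_length = 2000, seed = 3)
#' loci <- simulate_alignments(simulate_gene_trees(cfg), cfg)
#' loci$topology <- loci$topology_truth
#' estimate_depths(loci)
#' @export
estimate_depths <- function(x, ...) UseMethod("estimate_depths")

#' @rdname estimate_depths
#' @export
estimate_depths.matrix <- function(x, topology, config = depth_config(), ...) {
  m <- as_alignment_matrix(x)
  if (nrow(m) < 4L) stop("alignment must contain 4 taxa", call. = FALSE)
  if (!topology %in% TRIPLET_TOPOLOGIES[1:3]) {
    stop("'topology' must be a resolved triplet class", call. = FALSE)
  }
  pair <- strsplit(sub("\\|.*", "", topology), "")[[1]]
  third <- sub(".*\\|", "", topology)
  informative <- biallelic_informative_sites(m)
  n_used <- length(informative)
  if (n_used < config$min_sites) {
    return(tibble::tibble(topology = topology, t1 = NA_real_, t2 = NA_real_,
                          n_sites_used = n_used))
  }
  sites <- if (config$site_set == "informative") {
    informative
  } else {
    which(colSums(matrix(is_missing_char(m, "N"), nrow = nrow(m))) == 0L)
  }
  d <- function(a, b) {
    p <- mean(m[a, sites] != m[b, sites])
    if (config$correction == "JC") jc_correct(p) else p
  }
  t1 <- d(pair[1], pair[2]) / 2
  t2 <- (d(pair[1], third) + d(pair[2], third)) / 4
  if (config$normalize_by_outgroup) {
    d_out <- mean(c(d("A", "O"), d("B", "O"), d("C", "O")))
    t1 <- t1 / d_out
    t2 <- t2 / d_out
  }
  tibble::tibble(topology = topology, t1 = t1, t2 = t2, n_sites_used = n_used)
}

#' @rdname estimate_depths
#' @export
estimate_depths.data.frame <- function(x, config = depth_config(), ...) {
  if (!("alignment" %in% names(x))) stop("'x' has no 'alignment' column", call. = FALSE)
  if (!("topology" %in% names(x))) stop("'x' has no 'topology' column", call. = FALSE)
  rows <- vector("list", nrow(x))
  excl <- list()
  for (r in seq_len(nrow(x))) {
    id <- if (("locus_id" %in% names(x))) x$locus_id[r] else sprintf("L%d", r)
    topo <- x$topology[r]
    if (!topo %in% TRIPLET_TOPOLOGIES[1:3]) {
      excl[[length(excl) + 1L]] <- tibble::tibble(locus_id = id,
                                                  reason = "unresolved_topology")
      next
    }
    est <- estimate_depths(x$alignment[[r]], topology = topo, config = config)
    if (is.na(est$t1)) {
      excl[[length(excl) + 1L]] <- tibble::tibble(locus_id = id,
                                                  reason = "too_few_informative_sites")
      next
    }
    rows[[r]] <- dplyr::bind_cols(tibble::tibble(locus_id = id), est)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "excluded") <- if (length(excl)) dplyr::bind_rows(excl) else
    tibble::tibble(locus_id = character(), reason = character())
  out
}
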