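#' Classify which rooted triplet topology a gene tree supports
#'
#' Reduces a gene tree to the focal taxa A, B, C and outgroup O (via
#' `taxon_map` when tip labels differ from the role names), roots it on O,
#' and reports which pair of the triplet forms a cherry exclusive of the
#' third taxon. A polytomy at the relevant node gives `"UNRESOLVED"`.
#'
#' @param tree An `ape::phylo`, rooted or unrooted, containing each mapped
#'   tip exactly once.
#' @param taxon_map Named character vector mapping roles `A`, `B`, `C`, `O`
#'   to tip labels, e.g. `c(A = "Jaltomata", B = "Solanum", C = "Capsicum",
#'   O = "Nicotiana")`. Defaults to the identity map. Multi-tip genera must
#'   be reduced to one representative tip through this map.
#' @return One of `"AB|C"`, `"AC|B"`, `"BC|A"`, `"UNRESOLVED"`.
#' @examples
#' classify_triplet(ape::read.tree(text = "(((A,B),C),O);"))
#' classify_triplet(ape::read.tree(text = "((A,B,C),O);"))
#' @export
classify_triplet <- function(tree, taxon_map = NULL) {
  stopifnot(inherits(tree, "phylo"))
  taxon_map <- check_taxon_map(taxon_map)
  for (role in names(taxon_map)) {
    hits <- sum(tree$tip.label == taxon_map[[role]])
    if (hits == 0L) stop(sprintf("tip for role '%s' (label '%s') missing from tree",
                                 role, taxon_map[[role]]), call. = FALSE)
    if (hits > 1L) stop(sprintf("tip label '%s' (role '%s') duplicated in tree",
                                taxon_map[[role]], role), call. = FALSE)
  }
  tr <- ape::keep.tip(tree, unname(taxon_map))
  tr$tip.label <- names(taxon_map)[match(tr$tip.label, taxon_map)]
  tr$node.label <- NULL
  if (!ape::is.rooted(tr) || !is_outgroup_basal(tr)) {
    tr <- tryCatch(ape::root(tr, outgroup = "O", resolve.root = TRUE),
                   error = function(e) NULL)
    if (is.null(tr)) return("UNRESOLVED")
  }
  for (pair in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
    mrca <- ape::getMRCA(tr, pair)
    clade <- ape::extract.clade(tr, mrca)$tip.label
    if (setequal(clade, pair)) {
      third <- setdiff(c("A", "B", "C"), pair)
      return(paste0(pair[1], pair[2], "|", third))
    }
  }
  "UNRESOLVED"
}

is_outgroup_basal <- function(tr) {
  mrca <- ape::getMRCA(tr, c("A", "B", "C"))
  !("O" %in% ape::extract.clade(tr, mrca)$tip.label)
}

check_taxon_map <- function(taxon_map) {
  if (is.null(taxon_map)) {
    taxon_map <- c(A = "A", B = "B", C = "C", O = "O")
  }
  roles <- c("A", "B", "C", "O")
  missing <- setdiff(roles, names(taxon_map))
  if (length(missing) > 0) {
    stop(sprintf("taxon map missing role(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(taxon_map[roles])) {
    stop("taxon map assigns the same tip to two roles", call. = FALSE)
  }
  taxon_map[roles]
}

#' Mean bootstrap support of a gene tree
#'
#' Arithmetic mean of the numeric support values on the internal branches
#' of a tree, read from Newick node labels (the usual place bootstrap
#' proportions are stored). Non-numeric or empty labels (typically the
#' root) are skipped.
#'
#' @param tree An `ape::phylo` with support-annotated internal nodes.
#' @return Mean support (same scale as the annotations, normally 0-100).
#' @examples
#' mean_bootstrap(ape::read.tree(text = "(((A:1,B:1)90:1,C:2)70:1,O:3);"))
#' @export
mean_bootstrap <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$node.label
  vals <- suppressWarnings(as.numeric(labs))
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) {
    stop("tree carries no numeric support values", call. = FALSE)
  }
  mean(vals)
}

#' Internode certainty from the two most prevalent conflicting bipartitions
#'
#' `IC = 1 + p log2 p + q log2 q` with `p = n1/(n1+n2)`, `q = 1 - p` and
#' `0 log2 0 = 0`: one minus the entropy of the head-to-head frequencies of
#' the most common bipartition (`n1` gene trees) and its most common
#' conflicting bipartition (`n2`). IC is 1 when no tree conflicts and 0
#' when the two bipartitions are equally represented; an IC near zero
#' (e.g. the 42% vs 38% split gives 0.0018) signals a genuinely contested
#' internode.
#'
#' @param n1 Count supporting the most prevalent bipartition (`n1 >= n2`).
#' @param n2 Count supporting the most prevalent conflicting bipartition.
#' @param n3 Optional third-bipartition count; when supplied with
#'   `method = "entropy3"` the three-way variant
#'   `1 - H(p1, p2, p3) / log2(3)` is returned instead.
#' @param method `"top2"` (default, the definition above) or `"entropy3"`.
#' @return IC in `[0, 1]`.
#' @examples
#' internode_certainty(100, 0)
#' internode_certainty(50, 50)
#' internode_certainty(42, 38)
#' @export
internode_certainty <- function(n1, n2, n3 = NULL,
                                method = c("top2", "entropy3")) {
  method <- match.arg(method)
  if (!is.numeric(n1) || !is.numeric(n2) || n1 < 0 || n2 < 0) {
    stop("counts must be nonnegative numbers", call. = FALSE)
  }
  if (n1 < n2) stop("n1 must be the larger count (n1 >= n2)", call. = FALSE)
  if (n1 == 0) stop("both counts are zero", call. = FALSE)
  xlog2x <- function(x) ifelse(x > 0, x * log2(x), 0)
  if (method == "top2") {
    p <- n1 / (n1 + n2)
    1 + xlog2x(p) + xlog2x(1 - p)
  } else {
    if (is.null(n3)) stop("method 'entropy3' needs n3", call. = FALSE)
    ps <- c(n1, n2, n3) / sum(n1, n2, n3)
    1 + sum(xlog2x(ps)) / log2(3)
  }
}

#' Classify and annotate a table of gene trees
#'
#' Adds the triplet topology and mean bootstrap support of every tree to a
#' loci table; the workhorse behind [summarize_concordance()].
#'
#' @param trees Tibble with `locus_id` and a `tree` list-column, or a bare
#'   list / `multiPhylo` of trees.
#' @param taxon_map See [classify_triplet()].
#' @return Tibble with `locus_id`, `tree`, `topology`, `mean_support`
#'   (`NA` when a tree has no support annotations).
#' @export
classify_topologies <- function(trees, taxon_map = NULL) {
  trees <- as_trees_tbl(trees)
  trees$topology <- vapply(trees$tree, classify_triplet, character(1),
                           taxon_map = taxon_map)
  trees$mean_support <- vapply(trees$tree, function(tr) {
    tryCatch(mean_bootstrap(tr), error = function(e) NA_real_)
  }, numeric(1))
  trees
}

as_trees_tbl <- function(trees) {
  if (is.data.frame(trees)) {
    if (!("tree" %in% names(trees))) stop("'trees' has no 'tree' column", call. = FALSE)
    return(trees)
  }
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  tibble::tibble(locus_id = sprintf("L%d", seq_along(trees)), tree = trees)
}

#' Concordance summary across bootstrap-support cutoffs
#'
#' For each cutoff, retains the gene trees whose mean bootstrap support
#' exceeds it, tabulates the three triplet topologies (and unresolved
#' trees), normalizes proportions over the resolved trees, and computes the
#' internode certainty of the most prevalent vs the most prevalent
#' conflicting bipartition.
#'
#' @param trees Tibble of trees (see [classify_topologies()]); a
#'   `topology` column is computed if absent. Trees without support
#'   annotations are treated as fully supported (mean support 100), which
#'   is the natural reading for simulated true genealogies.
#' @param cutoffs Mean-bootstrap thresholds (default `c(50, 60, 70, 80, 90)`).
#' @param taxon_map See [classify_triplet()].
#' @return A `concordance_summary` tibble with one row per cutoff:
#'   `cutoff`, `n_retained`, `n_ab_c`, `n_ac_b`, `n_bc_a`, `n_unresolved`,
#'   `p_ab_c`, `p_ac_b`, `p_bc_a`, `ic`. Cutoffs that retain no tree keep
#'   zero counts and `NA` proportions.
#' @examples
#' trs <- lapply(c("(((A,B),C),O);", "(((A,C),B),O);", "(((A,B),C),O);"),
#'               function(s) ape::read.tree(text = s))
#' summarize_concordance(trs, cutoffs = 50)
#' @export
summarize_concordance <- function(trees, cutoffs = c(50, 60, 70, 80, 90),
                                  taxon_map = NULL) {
  if (!is.numeric(cutoffs) || length(cutoffs) == 0) {
    stop("'cutoffs' must be a numeric vector", call. = FALSE)
  }
  trees <- as_trees_tbl(trees)
  if (!("topology" %in% names(trees))) {
    trees <- classify_topologies(trees, taxon_map)
  }
  if (!("mean_support" %in% names(trees))) trees$mean_support <- NA_real_
  trees$mean_support[is.na(trees$mean_support)] <- 100

  rows <- lapply(sort(cutoffs), function(cut) {
    kept <- trees[trees$mean_support > cut, , drop = FALSE]
    n <- c(
      ab_c = sum(kept$topology == "AB|C"),
      ac_b = sum(kept$topology == "AC|B"),
      bc_a = sum(kept$topology == "BC|A")
    )
    n_res <- sum(n)
    p <- if (n_res > 0) n / n_res else rep(NA_real_, 3)
    top2 <- sort(n, decreasing = TRUE)[1:2]
    ic <- if (top2[1] > 0) unname(internode_certainty(top2[1], top2[2])) else NA_real_
    tibble::tibble(
      cutoff = cut, n_retained = nrow(kept),
      n_ab_c = n[["ab_c"]], n_ac_b = n[["ac_b"]], n_bc_a = n[["bc_a"]],
      n_unresolved = sum(kept$topology == "UNRESOLVED"),
      p_ab_c = p[[1]], p_ac_b = p[[2]], p_bc_a = p[[3]], ic = ic
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("concordance_summary", class(out))
  out
}
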