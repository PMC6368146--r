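#' Evolve alignments along simulated gene trees
#'
#' Adds a nucleotide alignment to each simulated locus by evolving sites
#' independently along the locus genealogy under the one-parameter
#' equal-rates (Jukes-Cantor) substitution model. Branch lengths in
#' coalescent units are converted to expected substitutions per site by the
#' factor `theta / 2`, so a branch of `t` coalescent units carries
#' `theta/2 * t` expected substitutions. Sequences are gap-free; each
#' locus's sites are drawn from its own seed stream derived from
#' `(config$seed, locus index)`, so alignments for a subset of loci are
#' identical to those simulated in a full run.
#'
#' @param loci Tibble from [simulate_gene_trees()] (or any tibble with
#'   `locus_id` and a `tree` list-column of `phylo` objects).
#' @param config The same [sim_config()] used to simulate the trees.
#' @return `loci` with an `alignment` list-column of character matrices
#'   (rows `A`, `B`, `C`, `O`; columns sites; values `A`/`C`/`G`/`T`).
#' @examples
#' cfg <- sim_config(n_loci = 3, seq_length = 50, seed = 2)
#' loci <- simulate_alignments(simulate_gene_trees(cfg), cfg)
#' loci$alignment[[1]][, 1:8]
#' @export
simulate_alignments <- function(loci, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.data.frame(loci) || nrow(loci) == 0) {
    stop("'loci' must be a non-empty tibble of simulated loci", call. = FALSE)
  }
  if (!("tree" %in% names(loci))) stop("'loci' has no 'tree' column", call. = FALSE)
  idx <- as.integer(sub("^L", "", loci$locus_id))
  aln <- vector("list", nrow(loci))
  for (r in seq_len(nrow(loci))) {
    set.seed(derive_seed(config$seed, idx[r], stage = 2L))
    aln[[r]] <- evolve_alignment(loci$tree[[r]], config$seq_length,
                                 rate = config$theta / 2)
  }
  loci$alignment <- aln
  loci
}

## JC evolution of one alignment: root states uniform, then along each
## edge every site switches to one of the other three bases with the exact
## transition probability 3/4 (1 - exp(-4/3 d)), d = edge length in
## expected substitutions/site. Vectorized over sites (a whole 4-taxon
## locus costs a handful of runif/sample calls), which is what makes the
## replicate experiments with tens of thousands of loci affordable.
evolve_alignment <- function(tree, seq_length, rate) {
  tree <- stats::reorder(tree) # cladewise: parents precede children
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  states <- matrix(NA_integer_, n_tip + tree$Nnode, seq_length)
  states[root, ] <- sample.int(4L, seq_length, replace = TRUE)
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    d <- tree$edge.length[e] * rate
    p <- 0.75 * (1 - exp(-4 / 3 * d))
    s <- states[parent, ]
    hit <- stats::runif(seq_length) < p
    if (any(hit)) {
      shift <- sample.int(3L, sum(hit), replace = TRUE)
      s[hit] <- (s[hit] - 1L + shift) %% 4L + 1L
    }
    states[child, ] <- s
  }
  m <- matrix(DNA_BASES[states[seq_len(n_tip), ]], nrow = n_tip)
  rownames(m) <- tree$tip.label
  ord <- intersect(c("A", "B", "C", "O"), rownames(m))
  if (length(ord) == nrow(m)) m <- m[ord, , drop = FALSE]
  m
}
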