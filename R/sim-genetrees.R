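#' Simulate gene trees under the multispecies coalescent with introgression
#'
#' Draws one genealogy per locus for the four sampled lineages A, B, C, O
#' on the species tree `(((A,B),C),O)` described by a [sim_config()].
#' Backwards in time, each lineage starts in its own population; populations
#' merge at the split times, and within a population containing `k` lineages
#' coalescences occur at rate `choose(k, 2)` per coalescent unit. With
#' probability `gamma`, the recipient lineage is relocated into the donor
#' population at `t_gamma`, the instantaneous-pulse model of introgression:
#' such loci can coalesce with the donor lineage well before `tau1`, which
#' both inflates the donor-recipient cherry topology and shortens its depth.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per locus:
#' \describe{
#'   \item{locus_id}{`"L<index>"`.}
#'   \item{tree}{list-column of rooted `ape::phylo` objects with branch
#'     lengths in coalescent units; tips `A`, `B`, `C`, `O`.}
#'   \item{topology_truth}{which pair of A, B, C coalesces first
#'     (`"AB|C"`, `"AC|B"`, `"BC|A"`), read from the genealogy itself.}
#'   \item{introgressed}{whether the pulse relocated the recipient lineage
#'     at this locus.}
#'   \item{tree_height}{root (grand-MRCA) time, coalescent units.}
#' }
#' @examples
#' loci <- simulate_gene_trees(sim_config(n_loci = 20, seed = 7))
#' table(loci$topology_truth)
#' @export
simulate_gene_trees <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_loci
  out <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(derive_seed(config$seed, i, stage = 1L))
    out[[i]] <- simulate_one_genealogy(config)
  }
  tibble::tibble(
    locus_id = sprintf("L%d", seq_len(n)),
    tree = lapply(out, `[[`, "tree"),
    topology_truth = vapply(out, `[[`, character(1), "topology"),
    introgressed = vapply(out, `[[`, logical(1), "introgressed"),
    tree_height = vapply(out, `[[`, numeric(1), "height")
  )
}

## One genealogy for lineages A,B,C,O. Pure R; a locus costs three
## coalescence draws plus bookkeeping, so tens of thousands of loci are
## simulated in seconds.
simulate_one_genealogy <- function(config) {
  ## lineage state: newick fragment, node time, population, tip set
  lab <- c("A", "B", "C", "O")
  nwk <- lab
  node_time <- c(0, 0, 0, 0)
  pop <- c("A", "B", "C", "O")
  tips <- list("A", "B", "C", "O")

  introgressed <- FALSE
  if (config$gamma > 0 && stats::runif(1) < config$gamma) introgressed <- TRUE

  ## pairwise TMRCAs among A,B,C fix the realised topology
  tmrca <- c(AB = NA_real_, AC = NA_real_, BC = NA_real_)

  coalesce_upto <- function(t_start, t_end) {
    t_now <- t_start
    repeat {
      ## total coalescence rate over populations
      pops <- unique(pop)
      kk <- vapply(pops, function(p) sum(pop == p), integer(1))
      rates <- kk * (kk - 1) / 2
      total <- sum(rates)
      if (total == 0) break
      t_now <- t_now + stats::rexp(1, total)
      if (t_now > t_end) break
      p_sel <- pops[sample.int(length(pops), 1L, prob = rates)]
      idx <- which(pop == p_sel)
      pair <- if (length(idx) == 2L) idx else sample(idx, 2L)
      i <- pair[1]; j <- pair[2]
      for (a in tips[[i]]) {
        for (b in tips[[j]]) {
          key <- paste0(sort(c(a, b)), collapse = "")
          if (key %in% names(tmrca) && is.na(tmrca[[key]])) tmrca[[key]] <<- t_now
        }
      }
      nwk[i] <<- sprintf("(%s:%.10g,%s:%.10g)",
                         nwk[i], t_now - node_time[i],
                         nwk[j], t_now - node_time[j])
      node_time[i] <<- t_now
      tips[[i]] <<- c(tips[[i]], tips[[j]])
      keep <- seq_along(pop) != j
      nwk <<- nwk[keep]; node_time <<- node_time[keep]
      pop <<- pop[keep]; tips <<- tips[keep]
    }
    invisible(NULL)
  }

  ## epoch 1: below the pulse nothing can coalesce (one lineage per pop)
  if (introgressed) {
    r <- which(vapply(tips, function(ts) config$recipient %in% ts, logical(1)))
    pop[r] <- config$donor
  }
  ## epoch 2: t_gamma -> tau1 (donor pop may now hold two lineages)
  coalesce_upto(config$t_gamma, config$tau1)
  ## epoch 3: tau1 -> tau2, populations A and B merge
  pop[pop %in% c("A", "B")] <- "AB"
  coalesce_upto(config$tau1, config$tau2)
  ## epoch 4: tau2 -> tau_out
  pop[pop %in% c("AB", "C")] <- "ABC"
  coalesce_upto(config$tau2, config$tau_out)
  ## root population
  pop[] <- "ROOT"
  coalesce_upto(config$tau_out, Inf)

  topology <- c(AB = "AB|C", AC = "AC|B", BC = "BC|A")[[names(which.min(tmrca))]]
  tree <- ape::read.tree(text = paste0(nwk[1], ";"))
  list(tree = tree, topology = topology,
       introgressed = introgressed, height = node_time[1])
}
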