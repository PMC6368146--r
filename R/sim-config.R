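#' Simulation configuration for the coalescent gene-tree generator
#'
#' Bundles the species-tree history, the introgression pulse, and the
#' mutation process used by [simulate_gene_trees()] and
#' [simulate_alignments()]. Three lineages A, B, C and an outgroup O are
#' simulated under a multispecies coalescent on the species tree
#' `(((A,B),C),O)` with split times `tau1 < tau2 < tau_out` in coalescent
#' units (one unit = 2N generations, all populations sharing one effective
#' size N). Optionally, at time `t_gamma < tau1` the sampled lineage of the
#' recipient taxon is relocated into the donor population with probability
#' `gamma` — a single instantaneous pulse of introgression.
#'
#' The default split times describe a history with substantial incomplete
#' lineage sorting (internal branch `tau2 - tau1 = 0.45` coalescent units,
#' i.e. about 43% discordant gene trees) and a recent pulse
#' (`t_gamma = 0.1`, long after the splits when viewed forwards in time);
#' with `gamma` near 0.3 this regime yields the two leading topology
#' classes at roughly equal frequency of about 40% each, the situation the
#' node-depth test is designed for. Note the direction of the pulse
#' matters for the depth signature: only when the third lineage's alleles
#' join the ingroup population (default `donor = "A"`, `recipient = "C"`)
#' are both T1 and T2 of the introgressed class reduced; the reverse
#' direction reduces T1 only.
#'
#' @param tau1 Time of the (A,B) split, coalescent units; `> t_gamma`.
#' @param tau2 Time of the ((A,B),C) split; `> tau1`. The internal branch
#'   `tau2 - tau1` controls how much incomplete lineage sorting occurs:
#'   the probability that a locus is discordant is `(2/3) exp(-(tau2 - tau1))`.
#' @param tau_out Outgroup split time; `> tau2`.
#' @param gamma Introgression probability per locus in `[0, 1]`; `gamma = 0`
#'   gives the pure ILS null.
#' @param t_gamma Time of the introgression pulse, `0 < t_gamma < tau1`.
#' @param donor,recipient Taxon roles from `"A"`, `"B"`, `"C"`; at the pulse
#'   the recipient's lineage moves into the donor's population (looking
#'   backwards in time, this is donor-to-recipient gene flow forwards in
#'   time). The outgroup never participates.
#' @param n_loci Number of loci to simulate.
#' @param seq_length Alignment length in sites per locus.
#' @param theta Population-scaled mutation rate per site: a branch of length
#'   `t` coalescent units carries `theta/2 * t` expected substitutions per
#'   site.
#' @param seed Master integer seed. Per-locus random streams are derived
#'   deterministically from `(seed, locus index)`, so locus `i` of a run is
#'   reproducible regardless of `n_loci`.
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(tau1 = 1, tau2 = 2, tau_out = 4, gamma = 0.3,
#'                   n_loci = 100, seed = 1)
#' cfg$gamma
#' @seealso [simulate_gene_trees()], [simulate_alignments()]
#' @export
sim_config <- function(tau1 = 1.5, tau2 = 1.95, tau_out = 4,
                       gamma = 0, t_gamma = 0.1,
                       donor = "A", recipient = "C",
                       n_loci = 100, seq_length = 1000,
                       theta = 0.02, seed = 1) {
  check_scalar(tau1, "tau1", lower = 0, strict_lower = TRUE)
  check_scalar(tau2, "tau2", lower = tau1, strict_lower = TRUE)
  check_scalar(tau_out, "tau_out", lower = tau2, strict_lower = TRUE)
  check_scalar(gamma, "gamma", lower = 0, upper = 1)
  check_scalar(t_gamma, "t_gamma", lower = 0, upper = tau1, strict_lower = TRUE)
  if (t_gamma >= tau1) stop("field 't_gamma' must be < tau1", call. = FALSE)
  check_scalar(n_loci, "n_loci", lower = 1, integer = TRUE)
  check_scalar(seq_length, "seq_length", lower = 1, integer = TRUE)
  check_scalar(theta, "theta", lower = 0, strict_lower = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  if (!is.character(donor) || length(donor) != 1L || !donor %in% c("A", "B", "C")) {
    stop("field 'donor' must be one of \"A\", \"B\", \"C\"", call. = FALSE)
  }
  if (!is.character(recipient) || length(recipient) != 1L ||
      !recipient %in% c("A", "B", "C")) {
    stop("field 'recipient' must be one of \"A\", \"B\", \"C\"", call. = FALSE)
  }
  if (donor == recipient) {
    stop("fields 'donor' and 'recipient' must differ", call. = FALSE)
  }
  structure(
    list(tau1 = tau1, tau2 = tau2, tau_out = tau_out,
         gamma = gamma, t_gamma = t_gamma,
         donor = donor, recipient = recipient,
         n_loci = as.integer(n_loci), seq_length = as.integer(seq_length),
         theta = theta, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  species tree (((A,B):%g,C):%g,O):%g  [coalescent units]\n",
              x$tau2 - x$tau1, x$tau_out - x$tau2, 0))
  cat(sprintf("  splits: tau1=%g tau2=%g tau_out=%g\n", x$tau1, x$tau2, x$tau_out))
  if (x$gamma > 0) {
    cat(sprintf("  introgression pulse: gamma=%g at t=%g, %s -> %s\n",
                x$gamma, x$t_gamma, x$donor, x$recipient))
  } else {
    cat("  no introgression (ILS null)\n")
  }
  cat(sprintf("  %d loci x %d sites, theta=%g, seed=%d\n",
              x$n_loci, x$seq_length, x$theta, x$seed))
  invisible(x)
}
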