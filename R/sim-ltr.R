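#' Simulate diverged terminal-repeat pairs of known insertion age
#'
#' At insertion the two long terminal repeats (LTRs) of a retrotransposon
#' are identical; afterwards each copy accumulates substitutions
#' independently. This generator draws an ancestral repeat sequence and
#' mutates the two copies for `true_age_years` at `mu` substitutions per
#' site per year under the one-parameter equal-rates model (site-wise
#' Poisson substitution process, so the per-site probability of ending in a
#' different state after time `T` is `3/4 * (1 - exp(-4/3 * mu * T))`).
#' No indels are simulated, so the pair stays alignable column-for-column.
#'
#' @param n Number of element pairs.
#' @param true_age_years Insertion age in years; `>= 0`.
#' @param mu Substitution rate per site per year (default the conventional
#'   plant LTR rate `1.3e-8`).
#' @param length Repeat length in bp.
#' @param seed Integer seed.
#' @return Tibble with `element_id`, `seq5`, `seq3` (character sequences),
#'   `true_age_years`, `mu`.
#' @examples
#' pairs <- simulate_ltr_pairs(3, true_age_years = 1e6, length = 200, seed = 1)
#' substr(pairs$seq5[1], 1, 40)
#' @seealso [estimate_insertion_age()] for the round trip.
#' @export
simulate_ltr_pairs <- function(n, true_age_years, mu = 1.3e-8,
                               length = 5000, seed = 1) {
  check_scalar(n, "n", lower = 1, integer = TRUE)
  if (!is.numeric(true_age_years) || length(true_age_years) != 1L ||
      is.na(true_age_years) || true_age_years < 0) {
    stop("field 'true_age_years' must be a single number >= 0", call. = FALSE)
  }
  check_scalar(mu, "mu", lower = 0, strict_lower = TRUE)
  check_scalar(length, "length", lower = 1, integer = TRUE)
  check_scalar(seed, "seed", integer = TRUE)

  p_diff <- 0.75 * (1 - exp(-4 / 3 * mu * true_age_years))
  seqs5 <- character(n)
  seqs3 <- character(n)
  for (i in seq_len(n)) {
    set.seed(derive_seed(seed, i, stage = 3L))
    anc <- sample(DNA_BASES, length, replace = TRUE)
    seqs5[i] <- paste(mutate_jc(anc, p_diff), collapse = "")
    seqs3[i] <- paste(mutate_jc(anc, p_diff), collapse = "")
  }
  tibble::tibble(
    element_id = sprintf("LTR%d", seq_len(n)),
    seq5 = seqs5, seq3 = seqs3,
    true_age_years = true_age_years, mu = mu
  )
}

## Apply the JC site-wise transition: with probability p_diff a site moves
## to one of the three other bases, uniformly.
mutate_jc <- function(seq, p_diff) {
  hit <- stats::runif(length(seq)) < p_diff
  if (any(hit)) {
    cur <- seq[hit]
    shift <- sample.int(3L, sum(hit), replace = TRUE)
    seq[hit] <- DNA_BASES[(match(cur, DNA_BASES) - 1L + shift) %% 4L + 1L]
  }
  seq
}
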