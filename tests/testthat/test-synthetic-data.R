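test_that("invalid configuration fields are rejected by name", {
  expect_error(sim_config(tau1 = 2, tau2 = 1), "tau2")
  expect_error(sim_config(tau2 = 5, tau_out = 4), "tau_out")
  expect_error(sim_config(gamma = 1.2), "gamma")
  expect_error(sim_config(t_gamma = 2, tau1 = 1.5), "t_gamma")
  expect_error(sim_config(n_loci = 0), "n_loci")
  expect_error(sim_config(seq_length = 0), "seq_length")
  expect_error(sim_config(theta = 0), "theta")
  expect_error(sim_config(donor = "O"), "donor")
  expect_error(sim_config(donor = "A", recipient = "A"), "donor")
})

test_that("a vanishing internal branch gives full topology symmetry", {
  cfg <- sim_config(tau1 = 1, tau2 = 1 + 1e-9, tau_out = 3,
                    n_loci = 6000, seed = 11)
  loci <- simulate_gene_trees(cfg)
  freqs <- table(factor(loci$topology_truth,
                        levels = c("AB|C", "AC|B", "BC|A"))) / nrow(loci)
  expect_equal(sum(freqs), 1)
  mc_se <- sqrt((1 / 3) * (2 / 3) / nrow(loci))
  for (f in freqs) expect_lt(abs(f - 1 / 3), 3 * mc_se)
})

test_that("a long internal branch suppresses discordance", {
  cfg <- sim_config(tau1 = 1, tau2 = 11, tau_out = 13, n_loci = 2000, seed = 12)
  loci <- simulate_gene_trees(cfg)
  expect_gt(mean(loci$topology_truth == "AB|C"), 0.999)
})

test_that("discordance at internal branch t = 1 matches the coalescent closed form", {
  # P(each minority topology) = (1/3) exp(-t); cross-checked by brute-force
  # lineage bookkeeping: below the deep split only the cherry pair can
  # coalesce, so discordance requires no coalescence in the internal
  # window (prob exp(-1)) and then a uniform choice among three pairings.
  cfg <- sim_config(tau1 = 1, tau2 = 2, tau_out = 4, n_loci = 10000, seed = 13)
  loci <- simulate_gene_trees(cfg)
  expected <- exp(-1) / 3
  mc_se <- sqrt(expected * (1 - expected) / nrow(loci))
  for (topo in c("AC|B", "BC|A")) {
    expect_lt(abs(mean(loci$topology_truth == topo) - expected), 3 * mc_se)
  }
})

test_that("the recorded truth matches the topology read off each tree", {
  cfg <- sim_config(n_loci = 300, gamma = 0.4, seed = 14)
  loci <- simulate_gene_trees(cfg)
  classified <- vapply(loci$tree, classify_triplet, character(1))
  expect_identical(classified, loci$topology_truth)
  expect_true(all(vapply(loci$tree, function(tr) {
    setequal(tr$tip.label, c("A", "B", "C", "O"))
  }, logical(1))))
})

test_that("seeded runs are bit-reproducible and per-locus streams are stable", {
  cfg <- sim_config(n_loci = 30, seq_length = 200, gamma = 0.3, seed = 15)
  a <- simulate_alignments(simulate_gene_trees(cfg), cfg)
  b <- simulate_alignments(simulate_gene_trees(cfg), cfg)
  expect_identical(lapply(a$tree, ape::write.tree),
                   lapply(b$tree, ape::write.tree))
  expect_identical(a$alignment, b$alignment)

  # locus i is unchanged when fewer loci are simulated under the same seed
  cfg_small <- sim_config(n_loci = 10, seq_length = 200, gamma = 0.3, seed = 15)
  small <- simulate_alignments(simulate_gene_trees(cfg_small), cfg_small)
  expect_identical(small$alignment, a$alignment[1:10])
  expect_identical(ape::write.tree(small$tree[[7]]),
                   ape::write.tree(a$tree[[7]]))
})

test_that("the mutation-free limit yields identical sequences", {
  cfg <- sim_config(n_loci = 5, seq_length = 300, theta = 1e-12, seed = 16)
  loci <- simulate_alignments(simulate_gene_trees(cfg), cfg)
  for (m in loci$alignment) {
    expect_true(all(m["A", ] == m["B", ]))
    expect_true(all(m["A", ] == m["O", ]))
  }
})

test_that("observed pairwise divergence matches the substitution model expectation", {
  # oracle: per-locus expectation from the tree path length and the exact
  # JC transition probability, independent of the sequence evolver
  cfg <- sim_config(n_loci = 1000, seq_length = 500, seed = 17)
  loci <- simulate_alignments(simulate_gene_trees(cfg), cfg)
  p_obs <- vapply(loci$alignment, function(m) mean(m["A", ] != m["B", ]),
                  numeric(1))
  p_exp <- vapply(loci$tree, function(tr) {
    d_subs <- ape::cophenetic.phylo(tr)["A", "B"] * cfg$theta / 2
    0.75 * (1 - exp(-4 / 3 * d_subs))
  }, numeric(1))
  diffs <- p_obs - p_exp
  expect_lt(abs(mean(diffs)), 3 * stats::sd(diffs) / sqrt(length(diffs)))
})

test_that("alignment simulation rejects empty or treeless input", {
  cfg <- sim_config(n_loci = 2, seed = 1)
  expect_error(simulate_alignments(tibble::tibble(), cfg), "non-empty")
  expect_error(simulate_alignments(tibble::tibble(locus_id = "L1"), cfg),
               "tree")
})

test_that("terminal-repeat pairs of age zero are identical", {
  pairs <- simulate_ltr_pairs(10, true_age_years = 0, length = 300, seed = 18)
  expect_true(all(pairs$seq5 == pairs$seq3))
  expect_error(simulate_ltr_pairs(5, true_age_years = -1), "true_age_years")
})

test_that("repeat-pair divergence matches the K = 2 mu T expectation", {
  # oracle: the expected observed difference proportion after two
  # independent JC branches of mu*T, corrected back to K
  pairs <- simulate_ltr_pairs(300, true_age_years = 1e6, mu = 1.3e-8,
                              length = 5000, seed = 19)
  est <- estimate_insertion_age(pairs, method = "as_is")
  k_hat <- est$k
  expect_lt(abs(mean(k_hat) - 2.6e-2),
            3 * stats::sd(k_hat) / sqrt(length(k_hat)))
})
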