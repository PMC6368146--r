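test_that("terminal-repeat alignment handles identity, substitutions and bad input", {
  same <- align_terminal_repeats("ACGTACGT", "ACGTACGT")
  expect_equal(same$mismatches, 0)
  expect_equal(same$gaps, 0)
  expect_equal(same$aligned_length, 8)

  one <- align_terminal_repeats("ACGT", "AGGT")
  expect_equal(one$mismatches, 1)
  expect_equal(one$gaps, 0)

  expect_error(align_terminal_repeats("AC!T", "ACGT"), "IUPAC")
  expect_error(align_terminal_repeats("", "ACGT"), "non-empty")
})

test_that("aligned divergence of a simulated pair matches the generator truth", {
  pairs <- simulate_ltr_pairs(1, true_age_years = 1e6, mu = 1.3e-8,
                              length = 1000, seed = 110)
  aln <- align_terminal_repeats(pairs$seq5, pairs$seq3)
  p <- aln$mismatches / aln$aligned_length
  p_exp <- 0.75 * (1 - exp(-4 / 3 * 2.6e-2)) # observable share of K = 2 mu T
  expect_lt(abs(p - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 1000))
})

test_that("insertion ages follow T = K / (2 mu) exactly", {
  ident <- tibble::tibble(seq5 = strrep("ACGT", 100), seq3 = strrep("ACGT", 100))
  est0 <- estimate_insertion_age(ident)
  expect_equal(est0$k, 0)
  expect_equal(est0$t_years, 0)

  # 26 substitutions over 1000 columns: raw k = 0.026 -> exactly 1 Myr
  s5 <- strrep("A", 1000)
  s3 <- paste0(strrep("C", 26), strrep("A", 974))
  raw <- estimate_insertion_age(tibble::tibble(seq5 = s5, seq3 = s3),
                                mu = 1.3e-8, correction = "raw",
                                method = "as_is")
  expect_equal(raw$k, 0.026)
  expect_equal(raw$t_years, 0.026 / (2 * 1.3e-8))
  expect_equal(raw$t_years, 1.0e6)

  # the one-parameter correction can only raise k above the raw value
  jc <- estimate_insertion_age(tibble::tibble(seq5 = s5, seq3 = s3),
                               mu = 1.3e-8, method = "as_is")
  expect_gt(jc$k, raw$k)
  expect_equal(jc$t_years, jc$k / (2 * jc$mu))
})

test_that("saturated and too-short elements are flagged, not silently dropped", {
  sat <- tibble::tibble(seq5 = strrep("A", 200), seq3 = strrep("C", 200))
  est <- estimate_insertion_age(sat, method = "as_is")
  expect_true(is.na(est$t_years))
  expect_equal(est$reason, "divergence_saturated")

  short <- tibble::tibble(seq5 = "ACGTACGT", seq3 = "ACGTACGT")
  est2 <- estimate_insertion_age(short, method = "as_is")
  expect_equal(est2$reason, "overlap_too_short")
  expect_error(estimate_insertion_age(tibble::tibble(x = 1)), "seq5")
})

test_that("a simulated cohort's mean age is recovered within five percent", {
  pairs <- simulate_ltr_pairs(200, true_age_years = 2e6, mu = 1.3e-8,
                              length = 5000, seed = 111)
  est <- estimate_insertion_age(pairs, method = "as_is")
  expect_lt(abs(mean(est$t_years) - 2e6) / 2e6, 0.05)
})

test_that("age histograms use half-open bins, superfamily fallback and undatable counts", {
  est <- tibble::tibble(element_id = "e1", superfamily = "Gypsy",
                        k = 0.0364, mu = 1.3e-8, t_years = 1.4e6,
                        aligned_length = 1000L, reason = NA_character_)
  h <- age_histogram(est, bin_width_years = 1e6)
  expect_equal(h$n[h$bin_lo == 1e6], 1L)
  expect_equal(sum(h$n), 1L)

  # two cohorts centred inside distinct bins give a bimodal landscape
  young <- simulate_ltr_pairs(120, 1.5e6, length = 2000, seed = 112)
  old <- simulate_ltr_pairs(120, 3.5e6, length = 2000, seed = 113)
  old$element_id <- paste0("old_", old$element_id)
  both <- estimate_insertion_age(rbind(young, old), method = "as_is")
  h2 <- age_histogram(both, bin_width_years = 1e6, by_superfamily = FALSE)
  modes <- sort(h2$bin_lo[order(h2$n, decreasing = TRUE)][1:2])
  expect_equal(modes, c(1e6, 3e6))

  est$superfamily <- ""
  h3 <- age_histogram(est, bin_width_years = 1e6)
  expect_equal(unique(h3$superfamily), "unknown")

  est_sat <- rbind(est, tibble::tibble(element_id = "e2", superfamily = "",
                                       k = NA_real_, mu = 1.3e-8,
                                       t_years = NA_real_,
                                       aligned_length = 500L,
                                       reason = "divergence_saturated"))
  h4 <- age_histogram(est_sat, bin_width_years = 1e6)
  expect_equal(attr(h4, "n_undatable"), 1L)
  expect_equal(sum(h4$n), 1L)
  expect_error(age_histogram(est, bin_width_years = 0), "positive")
})

test_that("ages increase in divergence and decrease in the assumed rate", {
  s5 <- strrep("A", 1000)
  mk <- function(nmut) tibble::tibble(
    seq5 = s5, seq3 = paste0(strrep("C", nmut), strrep("A", 1000 - nmut)))
  t_by_k <- vapply(c(5, 15, 40), function(nm) {
    estimate_insertion_age(mk(nm), method = "as_is")$t_years
  }, numeric(1))
  expect_true(all(diff(t_by_k) > 0))
  t_by_mu <- vapply(c(1e-8, 1.3e-8, 2e-8), function(mu) {
    estimate_insertion_age(mk(15), mu = mu, method = "as_is")$t_years
  }, numeric(1))
  expect_true(all(diff(t_by_mu) < 0))
})
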