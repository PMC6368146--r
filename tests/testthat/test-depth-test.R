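test_that("biallelic informative site detection matches exhaustive pattern enumeration", {
  # oracle: all 4^4 site patterns, classified straight from the definition
  bases <- c("A", "C", "G", "T")
  patterns <- expand.grid(a = bases, b = bases, c = bases, o = bases,
                          stringsAsFactors = FALSE)
  for (i in seq_len(nrow(patterns))) {
    col <- unlist(patterns[i, ])
    tab <- table(col)
    want <- length(tab) == 2 && all(tab >= 2)
    m <- matrix(col, ncol = 1, dimnames = list(c("A", "B", "C", "O"), NULL))
    got <- length(biallelic_informative_sites(m)) == 1
    expect_identical(got, want)
  }
})

test_that("gapped or masked columns are never informative and small inputs error", {
  m <- quartet_aln("TT", "-T", "G-", "GG") # every column touches a gap
  expect_identical(biallelic_informative_sites(m), integer(0))
  m2 <- quartet_aln("TNT", "TTT", "GTG", "GGG") # masked column 2 excluded
  expect_identical(biallelic_informative_sites(m2), c(1L, 3L))
  expect_identical(biallelic_informative_sites(quartet_aln("TTT", "TTT", "TTT", "TTT")),
                   integer(0))
  expect_equal(biallelic_informative_sites(quartet_aln("TA", "TC", "GG", "GT")), 1L)
  expect_error(biallelic_informative_sites(aln_rows("AC", "AC", "AC")), "4 taxa")
})

test_that("node depths follow the clock formulas on constructed alignments", {
  # ten informative columns where the cherry pair is identical: t1 = 0
  inf_same <- strrep("T", 10)
  m0 <- quartet_aln(paste0(inf_same, strrep("A", 90)),
                    paste0(inf_same, strrep("A", 90)),
                    paste0(strrep("G", 10), strrep("A", 90)),
                    paste0(strrep("G", 10), strrep("A", 90)))
  d0 <- estimate_depths(m0, topology = "AB|C")
  expect_equal(d0$t1, 0)
  expect_equal(d0$n_sites_used, 10L)

  # 500 resolved sites, cherry pair differing at 10 informative columns:
  # raw d = 0.02 so t1 = 0.01 uncorrected; the one-parameter correction
  # can only increase it
  m1 <- quartet_aln(paste0(strrep("T", 10), strrep("A", 490)),
                    paste0(strrep("G", 10), strrep("A", 490)),
                    paste0(strrep("T", 10), strrep("A", 490)),
                    paste0(strrep("G", 10), strrep("A", 490)))
  raw <- estimate_depths(m1, topology = "AB|C",
                         config = depth_config(correction = "raw"))
  expect_equal(raw$t1, 0.01)
  jc <- estimate_depths(m1, topology = "AB|C")
  expect_gt(jc$t1, 0.01)
  expect_equal(jc$t1, jc_correct(0.02) / 2)
})

test_that("depths are invariant to row order and loci below min_sites are excluded", {
  cfg <- sim_config(n_loci = 4, seq_length = 1500, seed = 106)
  loci <- simulate_alignments(simulate_gene_trees(cfg), cfg)
  m <- loci$alignment[[1]]
  topo <- loci$topology_truth[1]
  shuffled <- m[c("O", "C", "A", "B"), ]
  expect_equal(estimate_depths(m, topology = topo),
               estimate_depths(shuffled, topology = topo))

  few <- quartet_aln("TTAA", "TTAA", "GGAA", "GGAA") # 2 informative sites
  tbl <- tibble::tibble(locus_id = "x", alignment = list(few), topology = "AB|C")
  out <- estimate_depths(tbl)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "excluded")$reason, "too_few_informative_sites")
})

test_that("clock-like simulations put the deep node above the shallow node", {
  cfg <- sim_config(n_loci = 300, seq_length = 1000, seed = 107)
  loci <- simulate_alignments(simulate_gene_trees(cfg), cfg)
  loci$topology <- loci$topology_truth
  d <- estimate_depths(loci)
  expect_gt(mean(d$t2), mean(d$t1))
})

test_that("identical depth distributions give an ambiguous verdict", {
  base <- tibble::tibble(
    locus_id = sprintf("L%d", 1:40),
    topology = rep(c("AB|C", "AC|B"), each = 20),
    t1 = rep(seq(0.01, 0.2, length.out = 20), 2),
    t2 = rep(seq(0.21, 0.4, length.out = 20), 2)
  )
  tst <- compare_depth_classes(base, "AB|C", "AC|B", n_boot = 200, seed = 1)
  expect_equal(tst$verdict, "ambiguous")
  expect_true(is.na(tst$inferred_species_topology))
})

test_that("cleanly separated classes resolve to the deeper topology", {
  sep <- tibble::tibble(
    locus_id = sprintf("L%d", 1:24),
    topology = rep(c("AB|C", "AC|B"), each = 12),
    t1 = rep(c(1.0, 0.5), each = 12),
    t2 = rep(c(2.0, 1.5), each = 12)
  )
  tst <- compare_depth_classes(sep, "AB|C", "AC|B", n_boot = 200, seed = 1)
  expect_equal(tst$verdict, "resolved")
  expect_equal(tst$inferred_species_topology, "AB|C")
  expect_equal(tst$inferred_introgressed_topology, "AC|B")

  g <- glance(tst)
  expect_equal(g$species_topology, "AB|C")
  td <- tidy(tst)
  expect_equal(td$depth, c("t1", "t2", "combined"))
  expect_true(all(td$conf_low <= td$estimate & td$estimate <= td$conf_high))
})

test_that("empty classes and undersized resampling are rejected", {
  d <- tibble::tibble(locus_id = "L1", topology = "AB|C", t1 = 1, t2 = 2)
  expect_error(compare_depth_classes(d, "AB|C", "AC|B", n_boot = 200),
               "AC\\|B")
  expect_error(compare_depth_classes(d, "AB|C", "AC|B", n_boot = 10),
               "n_boot")
})

test_that("mean shallow depth of the introgressed class falls as the pulse strengthens", {
  t1_means <- vapply(c(0.1, 0.2, 0.4), function(g) {
    cfg <- sim_config(n_loci = 400, seq_length = 1000, gamma = g, seed = 108)
    loci <- simulate_alignments(simulate_gene_trees(cfg), cfg)
    loci$topology <- loci$topology_truth
    d <- estimate_depths(loci)
    mean(d$t1[d$topology == "AC|B"])
  }, numeric(1))
  expect_true(all(diff(t1_means) < 0))
})

test_that("the literal donor-to-third-taxon pulse still biases topology and shallows T1", {
  # lineage of A relocated into population C: the cherry excess and the
  # shallow-node reduction hold even though the deep node barely moves
  cfg <- sim_config(n_loci = 6000, gamma = 0.3, donor = "C", recipient = "A",
                    seed = 109)
  loci <- simulate_gene_trees(cfg)
  counts <- table(factor(loci$topology_truth, levels = c("AB|C", "AC|B", "BC|A")))
  expect_gt(counts[["AC|B"]], counts[["BC|A"]])
  t1_true <- vapply(seq_len(nrow(loci)), function(r) {
    tr <- loci$tree[[r]]
    pair <- strsplit(sub("\\|.*", "", loci$topology_truth[r]), "")[[1]]
    ape::cophenetic.phylo(tr)[pair[1], pair[2]] / 2
  }, numeric(1))
  expect_lt(mean(t1_true[loci$topology_truth == "AC|B"]),
            mean(t1_true[loci$topology_truth == "AB|C"]))
})
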