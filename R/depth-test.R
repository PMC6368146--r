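#' Compare node depths between two gene-tree topology classes
#'
#' The decision rule for separating the speciation topology from an
#' introgression-inflated one: gene trees carrying the original branching
#' order retain deeper mean node depths (T1 and T2) than gene trees built
#' from introgressed sequence, because gene flow after speciation lowers
#' the divergence between the exchanging lineages. The test bootstraps
#' loci within each class and calls the deeper class the species topology
#' only when the two point differences (mean T1, mean T2) agree in sign
#' and the bootstrap interval of the combined depth difference
#' `(dT1 + dT2) / 2` excludes zero; otherwise the verdict is
#' `"ambiguous"` — the expected outcome under pure incomplete lineage
#' sorting, where the two minority classes have identical depth
#' distributions and the combined interval covers zero at the nominal
#' rate. Pooling the two depths into one resampled contrast is deliberate:
#' they are strongly correlated within loci and the introgression signal
#' is a joint shift, so the combined statistic keeps an exact null level
#' while gaining power over requiring each depth to clear significance
#' separately. Per-depth intervals are reported alongside for inspection.
#'
#' @param depths Depth table from [estimate_depths()] (columns `locus_id`,
#'   `topology`, `t1`, `t2`).
#' @param class1,class2 The two topology classes to compare (default: the
#'   two most frequent classes in `depths`).
#' @param n_boot Bootstrap resamples over loci (default 1000; at least 100).
#' @param seed Integer seed for the resampling.
#' @param conf_level Confidence level of the percentile intervals
#'   (default 0.95).
#' @return An `introgression_test` object with components
#'   `class_means` (per-class mean t1/t2 and locus counts),
#'   `differences` (bootstrap estimate and CI of the class1 - class2
#'   difference for t1, t2, and their combination), `verdict`,
#'   `inferred_species_topology` / `inferred_introgressed_topology`
#'   (`NA` when ambiguous), and `wilcox_p` (two-sided rank-test p-values as
#'   an assumption-light cross-check). Methods: `print()`, [tidy()],
#'   [glance()], [autoplot()].
#' @examples
#' cfg <- sim_config(n_loci = 120, seq_length = 2000, gamma = 0.4, seed = 5)
#' loci <- simulate_alignments(simulate_gene_trees(cfg), cfg)
#' loci$topology <- loci$topology_truth
#' compare_depth_classes(estimate_depths(loci), "AB|C", "AC|B", seed = 1)
#' @export
compare_depth_classes <- function(depths, class1 = NULL, class2 = NULL,
                                  n_boot = 1000, seed = 1, conf_level = 0.95) {
  stopifnot(is.data.frame(depths))
  check_scalar(n_boot, "n_boot", lower = 100, integer = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  check_scalar(conf_level, "conf_level", lower = 0, upper = 1, strict_lower = TRUE)
  if (is.null(class1) || is.null(class2)) {
    tab <- sort(table(depths$topology), decreasing = TRUE)
    if (length(tab) < 2) stop("fewer than two topology classes present", call. = FALSE)
    class1 <- names(tab)[1]
    class2 <- names(tab)[2]
  }
  d1 <- depths[depths$topology == class1, , drop = FALSE]
  d2 <- depths[depths$topology == class2, , drop = FALSE]
  if (nrow(d1) == 0) stop(sprintf("class '%s' is empty", class1), call. = FALSE)
  if (nrow(d2) == 0) stop(sprintf("class '%s' is empty", class2), call. = FALSE)

  class_means <- tibble::tibble(
    topology = c(class1, class2),
    n_loci = c(nrow(d1), nrow(d2)),
    mean_t1 = c(mean(d1$t1), mean(d2$t1)),
    mean_t2 = c(mean(d1$t2), mean(d2$t2))
  )

  set.seed(seed)
  ## joint resampling: one pair of index draws per bootstrap replicate so
  ## the combined contrast respects the within-locus t1/t2 correlation
  n1 <- nrow(d1); n2 <- nrow(d2)
  reps <- matrix(NA_real_, n_boot, 3,
                 dimnames = list(NULL, c("t1", "t2", "combined")))
  for (b in seq_len(n_boot)) {
    i1 <- sample.int(n1, replace = TRUE)
    i2 <- sample.int(n2, replace = TRUE)
    dt1 <- mean(d1$t1[i1]) - mean(d2$t1[i2])
    dt2 <- mean(d1$t2[i1]) - mean(d2$t2[i2])
    reps[b, ] <- c(dt1, dt2, (dt1 + dt2) / 2)
  }
  a <- (1 - conf_level) / 2
  est <- c(t1 = mean(d1$t1) - mean(d2$t1),
           t2 = mean(d1$t2) - mean(d2$t2))
  est <- c(est, combined = unname((est[["t1"]] + est[["t2"]]) / 2))
  differences <- tibble::tibble(
    depth = colnames(reps),
    estimate = unname(est[colnames(reps)]),
    conf_low = apply(reps, 2, stats::quantile, probs = a),
    conf_high = apply(reps, 2, stats::quantile, probs = 1 - a)
  )

  comb <- differences[differences$depth == "combined", ]
  combined_excludes_zero <- (comb$conf_low > 0 && comb$conf_high > 0) ||
    (comb$conf_low < 0 && comb$conf_high < 0)
  same_sign <- sign(est[["t1"]]) == sign(est[["t2"]]) && est[["t1"]] != 0
  if (combined_excludes_zero && same_sign) {
    deeper <- if (est[["combined"]] > 0) class1 else class2
    shallower <- setdiff(c(class1, class2), deeper)
    verdict <- "resolved"
  } else {
    deeper <- NA_character_
    shallower <- NA_character_
    verdict <- "ambiguous"
  }

  wilcox_p <- c(
    t1 = suppressWarnings(stats::wilcox.test(d1$t1, d2$t1)$p.value),
    t2 = suppressWarnings(stats::wilcox.test(d1$t2, d2$t2)$p.value)
  )

  structure(
    list(class_means = class_means, differences = differences,
         verdict = verdict,
         inferred_species_topology = deeper,
         inferred_introgressed_topology = shallower,
         wilcox_p = wilcox_p,
         n_boot = as.integer(n_boot), conf_level = conf_level,
         seed = as.integer(seed)),
    class = "introgression_test"
  )
}

#' @export
print.introgression_test <- function(x, ...) {
  cat("<introgression_test> node-depth comparison\n")
  cm <- x$class_means
  for (i in seq_len(nrow(cm))) {
    cat(sprintf("  %-6s n=%4d  mean T1=%.4g  mean T2=%.4g\n",
                cm$topology[i], cm$n_loci[i], cm$mean_t1[i], cm$mean_t2[i]))
  }
  df <- x$differences
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  diff %-3s %+.4g  [%.4g, %.4g] (%.0f%% bootstrap CI, %d reps)\n",
                df$depth[i], df$estimate[i], df$conf_low[i], df$conf_high[i],
                100 * x$conf_level, x$n_boot))
  }
  if (x$verdict == "resolved") {
    cat(sprintf("  verdict: species topology %s; %s attributed to introgression\n",
                x$inferred_species_topology, x$inferred_introgressed_topology))
  } else {
    cat("  verdict: ambiguous (depth difference does not exclude zero)\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the bootstrap depth differences of an introgression test
#'
#' @param x An `introgression_test`.
#' @param ... Unused.
#' @return Tibble with one row per depth statistic (`t1`, `t2`): the
#'   class1 - class2 difference of means, its bootstrap CI, and the
#'   rank-test p-value.
#' @export
tidy.introgression_test <- function(x, ...) {
  out <- x$differences
  out$wilcox_p <- unname(x$wilcox_p[out$depth])
  out
}

#' One-row summary of an introgression test
#'
#' @param x An `introgression_test`.
#' @param ... Unused.
#' @return One-row tibble: verdict, inferred topologies, per-class means,
#'   resampling settings.
#' @export
glance.introgression_test <- function(x, ...) {
  cm <- x$class_means
  tibble::tibble(
    verdict = x$verdict,
    species_topology = x$inferred_species_topology,
    introgressed_topology = x$inferred_introgressed_topology,
    class1 = cm$topology[1], class2 = cm$topology[2],
    n_class1 = cm$n_loci[1], n_class2 = cm$n_loci[2],
    mean_t1_class1 = cm$mean_t1[1], mean_t1_class2 = cm$mean_t1[2],
    mean_t2_class1 = cm$mean_t2[1], mean_t2_class2 = cm$mean_t2[2],
    n_boot = x$n_boot, conf_level = x$conf_level
  )
}
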