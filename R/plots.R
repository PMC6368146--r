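#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot topology proportions across bootstrap cutoffs
#'
#' Stacked bars of the three triplet-topology proportions per
#' mean-bootstrap cutoff, with the internode certainty printed above each
#' bar — the standard way to show that a discordance pattern is stable
#' across gene-tree quality strata.
#'
#' @param object A `concordance_summary` from [summarize_concordance()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.concordance_summary <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("cutoff", "p_ab_c", "p_ac_b", "p_bc_a")],
    cols = -"cutoff", names_to = "topology", values_to = "proportion")
  df$topology <- c(p_ab_c = "AB|C", p_ac_b = "AC|B",
                   p_bc_a = "BC|A")[df$topology]
  ic_lab <- tibble::tibble(cutoff = object$cutoff,
                           label = sprintf("IC=%.3f", object$ic))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$cutoff),
                                   y = .data$proportion,
                                   fill = .data$topology)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(data = ic_lab, inherit.aes = FALSE, vjust = -0.4,
                       ggplot2::aes(x = factor(.data$cutoff), y = 1.02,
                                    label = .data$label), size = 3) +
    ggplot2::scale_fill_brewer(palette = "Set2", name = "Topology") +
    ggplot2::labs(x = "Mean bootstrap cutoff (%)",
                  y = "Proportion of resolved gene trees") +
    ggplot2::ylim(0, 1.08) +
    ggplot2::theme_minimal()
}

#' Plot the node-depth comparison behind an introgression test
#'
#' Per-class mean T1 and T2 with the bootstrap interval of the
#' between-class difference annotated; the deeper class is the inferred
#' speciation topology.
#'
#' @param object An `introgression_test` from [compare_depth_classes()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.introgression_test <- function(object, ...) {
  cm <- tidyr::pivot_longer(object$class_means, cols = c("mean_t1", "mean_t2"),
                            names_to = "depth", values_to = "mean")
  cm$depth <- toupper(sub("mean_", "", cm$depth))
  subtitle <- if (object$verdict == "resolved") {
    sprintf("species topology: %s", object$inferred_species_topology)
  } else {
    "verdict: ambiguous"
  }
  ggplot2::ggplot(cm, ggplot2::aes(x = .data$depth, y = .data$mean,
                                   fill = .data$topology)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::labs(x = NULL, y = "Mean node depth (substitutions/site)",
                  fill = "Gene-tree class", subtitle = subtitle) +
    ggplot2::scale_fill_brewer(palette = "Set1") +
    ggplot2::theme_minimal()
}

#' Plot an LTR insertion-age distribution
#'
#' Age landscape of dated full-length elements: element counts per
#' half-open age bin, coloured by superfamily.
#'
#' @param object An `age_distribution` from [age_histogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.age_distribution <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$age_myr <- (df$bin_lo + df$bin_hi) / 2 / 1e6
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age_myr, y = .data$n,
                                   fill = .data$superfamily)) +
    ggplot2::geom_col(position = "stack",
                      width = attr(object, "bin_width_years") / 1e6 * 0.95) +
    ggplot2::labs(x = "Insertion age (Myr)", y = "Full-length elements",
                  fill = "Superfamily") +
    ggplot2::scale_fill_brewer(palette = "Dark2") +
    ggplot2::theme_minimal()
}
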