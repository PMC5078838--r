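#' Plot mean family diversity per population
#'
#' Bar chart of the unweighted mean per-gene theta-pi within each gene
#' family, split by population — the family-level view of how the
#' domestication contrast redistributed diversity.
#'
#' @param family_summary Output of [family_summary()].
#' @return A ggplot object.
#' @export
plot_family_diversity <- function(family_summary) {
  ggplot2::ggplot(family_summary,
                  ggplot2::aes(x = .data$family, y = .data$mean_pi,
                               fill = .data$population)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Gene family", y = expression("Mean nucleotide diversity" ~ (theta[pi])),
                  fill = "Population") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the per-gene domestication diversity contrast
#'
#' Scatter of descendant against ancestral per-gene diversity on log axes,
#' coloured by the gene-level selection call; the diagonal marks no change.
#'
#' @param report A `scan_report`.
#' @return A ggplot object.
#' @export
plot_diversity_contrast <- function(report) {
  d <- report$calls |>
    left_join(report$pair_stats |> select("gene_id", "pi_a", "pi_b"), by = "gene_id")
  eps <- 1e-6
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pi_a + eps, y = .data$pi_b + eps,
                                  colour = .data$call)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(theta[pi] ~ "ancestral (wild)"),
                  y = expression(theta[pi] ~ "descendant (landrace)"),
                  colour = "Call") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a haplotype network
#'
#' Nodes are placed by classical multidimensional scaling of the Hamming
#' distances; node area scales with haplotype frequency, spanning-tree
#' edges are solid and alternative (equal-length) links dashed.
#'
#' @param object A `haplo_network` from [network_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.haplo_network <- function(object, ...) {
  ids <- object$nodes$haplotype
  seqs <- strsplit(object$seqs[ids], "")
  k <- length(ids)
  d <- matrix(0, k, k, dimnames = list(ids, ids))
  if (k > 1) for (i in 1:(k - 1)) for (j in (i + 1):k) {
    d[i, j] <- d[j, i] <- sum(seqs[[i]] != seqs[[j]])
  }
  xy <- if (k > 2) cmdscale(d, k = 2) else cbind(seq_len(k), 0)
  nodes <- tibble(haplotype = ids, x = xy[, 1], y = xy[, 2],
                  freq = object$nodes$freq)
  ed <- object$edges |>
    mutate(x = nodes$x[match(.data$from, ids)], y = nodes$y[match(.data$from, ids)],
           xend = nodes$x[match(.data$to, ids)], yend = nodes$y[match(.data$to, ids)])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                                       yend = .data$yend,
                                       linetype = !.data$in_spanning_tree),
                          colour = "firebrick") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y, size = .data$freq),
                        colour = "steelblue", alpha = 0.85) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$haplotype),
                       vjust = -1.2, size = 3) +
    ggplot2::scale_size_area(max_size = 14) +
    ggplot2::guides(linetype = "none") +
    ggplot2::labs(size = "Accessions") +
    ggplot2::theme_void()
}
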