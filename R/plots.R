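#' Plot an IDR fit
#'
#' Rank-rank scatter of the two replicates' scores, coloured by whether
#' each pair passes the global IDR threshold.
#'
#' @param object An [fit_idr()] result.
#' @param threshold Global IDR cutoff to colour by.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.idr_fit <- function(object, threshold = 0.05, ...) {
  d <- object$pairs %>%
    mutate(rank1 = rank(.data$score_rep1),
           rank2 = rank(.data$score_rep2),
           passing = .data$global_idr <= threshold)
  ggplot2::ggplot(d, ggplot2::aes(.data$rank1, .data$rank2,
                                  colour = .data$passing)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#1b7837",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(x = "score rank, replicate 1",
                  y = "score rank, replicate 2",
                  colour = sprintf("IDR <= %.2g", threshold)) +
    ggplot2::theme_minimal()
}

#' Plot a motif-enrichment null distribution
#'
#' Histogram of shuffle counts with the observed count marked.
#'
#' @param object A [kmer_enrichment()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.motif_enrichment <- function(object, ...) {
  nulls <- tibble(count = attr(object, "null_counts"))
  ggplot2::ggplot(nulls, ggplot2::aes(.data$count)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed,
                        colour = "#c51b7d", linewidth = 1) +
    ggplot2::labs(x = sprintf("%s occurrences per shuffle", object$motif),
                  y = "shuffles",
                  title = sprintf("observed %d, z = %.1f, p = %.3g",
                                  object$observed, object$z,
                                  object$p_empirical)) +
    ggplot2::theme_minimal()
}

#' Bar chart of a bound-gene partition
#'
#' @param object A [venn_partition()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.venn_partition <- function(object, ...) {
  d <- as_tibble(object) %>%
    mutate(region = factor(.data$region, levels = .data$region))
  ggplot2::ggplot(d, ggplot2::aes(.data$region, .data$percent)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = NULL, y = "% of bound-gene union") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot genic region proportions
#'
#' @param proportions A [genic_region_proportions()] result.
#' @return A ggplot object.
#' @export
plot_region_proportions <- function(proportions) {
  ggplot2::ggplot(as_tibble(proportions),
                  ggplot2::aes(.data$region, .data$proportion)) +
    ggplot2::geom_col(fill = "#5aae61") +
    ggplot2::labs(x = NULL, y = "proportion of assigned footprints") +
    ggplot2::theme_minimal()
}
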