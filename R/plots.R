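#' @exportS3Method ggplot2::autoplot
autoplot.mutsel_profile <- function(object, ...) {
  d <- mutate(object, bin = factor(.data$bin, levels = unique(.data$bin)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$mu,
                                  fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "mutation class / FIS bin",
                  y = expression(paste("non-uniformity ", mu)),
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.mutsel_fraction <- function(object, ...) {
  d <- mutate(object, bin = factor(.data$bin, levels = unique(.data$bin)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$pct,
                                  fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "mutation class / FIS bin",
                  y = paste0("% of mutations in ", object$category[1], " genes"),
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.mutsel_concurrency <- function(object, ...) {
  d <- mutate(object, bin = factor(.data$bin, levels = unique(.data$bin)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$pct,
                                  group = .data$group, colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "FIS bin",
                  y = "% of genes also carrying a truncating mutation",
                  colour = "gene group") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.mutsel_cna <- function(object, ...) {
  d <- tidyr::pivot_longer(object,
                           c("pct_loss", "pct_neutral", "pct_gain", "pct_amp"),
                           names_to = "state", values_to = "pct") |>
    mutate(state = factor(.data$state,
                          levels = c("pct_loss", "pct_neutral", "pct_gain", "pct_amp"),
                          labels = c("-1", "0", "+1", "+2")),
           bin = factor(.data$bin, levels = unique(.data$bin)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$pct,
                                  fill = .data$state)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mutation class / FIS bin",
                  y = "% of mutations by copy-number state",
                  fill = "CNA state") +
    ggplot2::theme_minimal()
}

#' Plot a gene-burden ranking
#'
#' Bar chart of high-functional mutation counts for the top-ranked genes,
#' with passenger-flagged genes marked.
#'
#' @param burdens A [rank_gene_burden()] result.
#' @param top Number of genes to show.
#' @return A ggplot object.
#' @export
plot_gene_burden <- function(burdens, top = 30) {
  stopifnot(inherits(burdens, "gene_burden"))
  d <- head(burdens, top) |>
    mutate(gene = factor(.data$gene, levels = rev(.data$gene)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n_high, y = .data$gene,
                                  fill = .data$is_passenger_flagged)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey30", `TRUE` = "firebrick"),
                               labels = c(`FALSE` = "candidate", `TRUE` = "passenger-flagged")) +
    ggplot2::labs(x = "high-functional mutations (FIS > 2.5 + truncating)",
                  y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
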