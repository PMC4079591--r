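# ggplot2 displays for the main result types.

#' Volcano-style plot of the dual DE result
#'
#' Log2 fold change (fragmented minus continuous) against the
#' permutation-test FDR, with the genes passing the intersection rule
#' highlighted.
#'
#' @param object an `ml_de` tibble from [landscape_de_genes()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ml_de <- function(object, ...) {
  df <- as_tibble(object)
  df$perm_q <- pmax(df$perm_q, 1e-12)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(.data$perm_q),
                                   colour = .data$de)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 name = "landscape DE") +
    ggplot2::labs(x = "log2 fold change (fragmented - continuous)",
                  y = "-log10 permutation FDR")
}

#' Bar chart of partition log marginal likelihoods
#'
#' @param object an `ml_partitions` tibble from [score_partitions()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ml_partitions <- function(object, ...) {
  df <- tidy(object)
  df$partition <- factor(df$partition, levels = df$partition[order(df$log_ml)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log_ml, y = .data$partition,
                                   fill = .data$rank == 1)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "steelblue")) +
    ggplot2::labs(x = "total log marginal likelihood", y = NULL)
}

#' Histogram with fitted mixture components
#'
#' @param object an `ml_vbgmm` fit.
#' @param data the data vector the model was fitted to.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ml_vbgmm <- function(object, data, ...) {
  grid <- seq(min(data), max(data), length.out = 200)
  comp <- purrr::map_dfr(seq_len(object$K), function(k) {
    tibble(x = grid, component = factor(k),
           density = object$weights[k] *
             stats::dnorm(grid, object$means[k], 1 / sqrt(object$precisions[k])))
  })
  ggplot2::ggplot() +
    ggplot2::geom_histogram(
      data = tibble(x = data),
      ggplot2::aes(x = .data$x, y = ggplot2::after_stat(density)),
      bins = 30, fill = "grey80", colour = "grey50") +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(x = .data$x, y = .data$density,
                                    colour = .data$component)) +
    ggplot2::labs(x = "standardized expression", y = "density")
}

#' Scatter plot of a concordance result
#'
#' @param object an `ml_concordance` from [concordance_test()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ml_concordance <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$delta_a, y = .data$delta_b)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(
      x = "contrast A (log2)", y = "contrast B (log2)",
      subtitle = sprintf("%s r = %.3f (n = %d)", object$method,
                         object$estimate, object$n))
}
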