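#' Plot a gene score profile
#'
#' Scree-style plot of scores against rank, highlighting degenerate genes.
#' For smaller-is-better scores the curve rises with rank; an elbow
#' suggests how many genes carry signal.
#'
#' @param object A `"feature_scores"` tibble.
#' @param top Show only the top-ranked `top` genes (default: all finite).
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.feature_scores <- function(object, top = NULL, ...) {
  df <- object[order(object$rank), ]
  df <- df[is.finite(df$score), ]
  if (!is.null(top)) df <- df[seq_len(min(top, nrow(df))), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$score)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "rank",
      y = sprintf("score (%s-is-better)", attr(object, "direction")),
      title = sprintf("%s gene scores", attr(object, "method"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot benchmark accuracy curves
#'
#' Mean metric versus number of selected genes, one curve per method,
#' faceted by the number of labeled samples per class.
#'
#' @param object A `"semimm_benchmark"` tibble from [run_benchmark()].
#' @param metric Which metric to draw (default `"accuracy"`).
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.semimm_benchmark <- function(object, metric = "accuracy", ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$metric == !!metric)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_genes, y = .data$mean,
                                   colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::facet_wrap(~L, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "number of selected genes", y = sprintf("mean %s", metric)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.feature_scores
#' @param scores A `"feature_scores"` tibble.
#' @export
plot_scores <- function(scores, top = NULL) autoplot.feature_scores(scores, top = top)

#' @rdname autoplot.semimm_benchmark
#' @param report A `"semimm_benchmark"` tibble.
#' @export
plot_benchmark <- function(report, metric = "accuracy") {
  autoplot.semimm_benchmark(report, metric = metric)
}
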