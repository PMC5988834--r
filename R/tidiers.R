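#' Tidy a gene score table
#'
#' Returns the plain tibble of per-gene results, dropping the class
#' attributes, so the output slots into ordinary dplyr pipelines.
#'
#' @param x A `"feature_scores"` tibble.
#' @param ... Ignored.
#' @return Tibble with `gene_id`, `score`, `rank`, `degenerate`.
#' @exportS3Method generics::tidy
tidy.feature_scores <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("gene_id", "score", "rank", "degenerate")])
}

#' Summarise a gene score table in one row
#'
#' @param x A `"feature_scores"` tibble.
#' @param ... Ignored.
#' @return One-row tibble: `method`, `direction`, `n_genes`,
#'   `n_degenerate`, `best_gene`.
#' @exportS3Method generics::glance
glance.feature_scores <- function(x, ...) {
  tibble::tibble(method = attr(x, "method"),
                 direction = attr(x, "direction"),
                 n_genes = nrow(x),
                 n_degenerate = sum(x$degenerate),
                 best_gene = x$gene_id[x$rank == 1])
}

#' Tidy a benchmark report
#'
#' Returns the per-repeat raw metrics in long format.
#'
#' @param x A `"semimm_benchmark"` tibble.
#' @param ... Ignored.
#' @return Tibble with `method`, `L`, `rep`, `n_genes` and one column per
#'   metric.
#' @exportS3Method generics::tidy
tidy.semimm_benchmark <- function(x, ...) {
  tibble::as_tibble(attr(x, "raw"))
}

#' Summarise a benchmark in one row per method
#'
#' Reports, per method and L, the best mean accuracy over the gene grid and
#' the subset size achieving it.
#'
#' @param x A `"semimm_benchmark"` tibble.
#' @param ... Ignored.
#' @return Tibble with `method`, `L`, `best_accuracy`, `best_n_genes`.
#' @exportS3Method generics::glance
glance.semimm_benchmark <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::filter(.data$metric == "accuracy") |>
    dplyr::group_by(.data$method, .data$L) |>
    dplyr::slice_max(.data$mean, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(method = "method", L = "L",
                  best_accuracy = "mean", best_n_genes = "n_genes")
}
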