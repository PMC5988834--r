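#' @keywords internal
new_feature_scores <- function(gene_id, score, degenerate, direction, method,
                               config = list()) {
  stopifnot(direction %in% c("smaller", "larger"))
  score <- unname(score)
  degenerate <- unname(degenerate)
  key <- if (direction == "smaller") score else -score
  # degenerate genes always rank last; remaining ties resolve by gene index
  key[degenerate] <- Inf
  ord <- order(key, seq_along(key))
  rank <- integer(length(key))
  rank[ord] <- seq_along(key)
  out <- tibble::tibble(gene_id = gene_id, score = score, rank = rank,
                        degenerate = degenerate)
  attr(out, "direction") <- direction
  attr(out, "method") <- method
  attr(out, "config") <- config
  class(out) <- c("feature_scores", class(out))
  out
}

#' Center a feature by its degree-weighted mean
#'
#' Subtracts the weighted mean `sum(f * d) / sum(d)`, where `d` is the
#' diagonal of the signed Laplacian's degree matrix. When the total degree
#' is zero the weighted mean is undefined; the function falls back to the
#' ordinary mean and flags the result via the `"degenerate"` attribute.
#'
#' @param f Numeric feature vector, one value per sample.
#' @param d Numeric vector: diagonal of the degree matrix (or a
#'   `"signed_laplacian"` object).
#' @return Centered numeric vector with logical attribute `"degenerate"`.
#' @export
center_feature <- function(f, d) {
  if (inherits(d, "signed_laplacian")) d <- d$d
  stopifnot(length(f) == length(d))
  total <- sum(d)
  if (abs(total) < 1e-12) {
    out <- f - mean(f)
    attr(out, "degenerate") <- TRUE
  } else {
    out <- f - sum(f * d) / total
    attr(out, "degenerate") <- FALSE
  }
  out
}

#' Margin-to-variance term of the semi-supervised score
#'
#' Computes `f' L f / (f~' D f~)` where `L` and `D` come from the signed
#' Laplacian and `f~` is the degree-weighted centered feature. The numerator
#' is the local margin (within-class smoothness minus between-class
#' separation); the denominator is the degree-weighted variance. If the
#' denominator is not positive (zero-variance gene, or negative degrees
#' dominating) the term is undefined: the value is `Inf` and the degenerate
#' flag is set, which ranks the gene last downstream.
#'
#' @param f Numeric feature vector.
#' @param lap A `"signed_laplacian"` object.
#' @return List with `value` and logical `degenerate`.
#' @export
margin_variance_term <- function(f, lap) {
  stopifnot(inherits(lap, "signed_laplacian"))
  num <- drop(crossprod(f, lap$L %*% f))
  fc <- center_feature(f, lap$d)
  den <- sum(fc^2 * lap$d)
  if (den <= 1e-12) {
    list(value = Inf, degenerate = TRUE)
  } else {
    list(value = num / den, degenerate = FALSE)
  }
}

#' Semi-supervised maximum discriminative local margin gene scores
#'
#' Scores every gene by blending (i) its local margin on the signed
#' within-minus-between-class neighbour graph, normalized by degree-weighted
#' variance, with (ii) one minus the normalized mutual information between
#' the discretized gene and the class labels:
#'
#' \deqn{score_r = \lambda \frac{f_r^T L f_r}{\tilde f_r^T D \tilde f_r}
#'   + (1-\lambda)\,(1 - NMI(f_r, C))}
#'
#' Smaller scores indicate more discriminative genes. Both labeled and
#' unlabeled samples shape the graph term; only labeled samples enter the
#' mutual-information term. Genes are standardized (zero mean, unit
#' population variance) before graph construction unless `standardize =
#' FALSE`.
#'
#' @param x Expression data: numeric matrix (genes x samples) or data frame
#'   with a gene-id first column.
#' @param labels Partial class labels: a data frame with `sample_id` and
#'   `label` columns, a named vector, or a vector aligned with the samples;
#'   `NA` marks unlabeled samples. `NULL` means fully unlabeled.
#' @param lambda Blend weight in `[0, 1]`; the defaults follow common
#'   practice for this criterion (`0.6`). The endpoints are allowed for
#'   diagnostics: `lambda = 1` is the pure margin term, `lambda = 0` pure
#'   mutual information.
#' @param k Neighbour count for the sample graph (default 5).
#' @param gamma Within-class weight for same-labeled pairs (default 100).
#' @param mi_bins Bin count for the mutual-information discretization;
#'   `NULL` uses `max(2, ceiling(sqrt(n_labeled)))`.
#' @param metric Distance metric for the neighbour graph.
#' @param within_labeled_requires_neighbor See [split_margin_weights()].
#' @param standardize Standardize genes before graph construction.
#' @return A `"feature_scores"` tibble with columns `gene_id`, `score`,
#'   `rank`, `degenerate`; direction is smaller-is-better. Degenerate genes
#'   (undefined margin term) carry an `Inf` score and rank last.
#' @examples
#' sim <- simulate_expression(n_genes = 40, n_informative = 4, n_classes = 2,
#'                            samples_per_class = 10, effect = 3, seed = 1)
#' y <- mask_labels(sim$labels, L = 4, seed = 1)
#' head(semimm_score(sim$expression, y, k = 3))
#' @export
semimm_score <- function(x, labels = NULL, lambda = 0.6, k = 5, gamma = 100,
                         mi_bins = NULL, metric = "euclidean",
                         within_labeled_requires_neighbor = FALSE,
                         standardize = TRUE) {
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]", call. = FALSE)
  x <- as_expr_matrix(x)
  y <- as_partial_labels(labels, colnames(x))
  if (all(is.na(y)) && lambda < 1) {
    warning("no labeled samples: mutual-information term is identically zero",
            call. = FALSE)
  }
  xs <- if (standardize) standardize_genes(x) else x
  g <- build_knn_graph(xs, k = k, metric = metric)
  w <- split_margin_weights(g, y, gamma = gamma,
                            within_labeled_requires_neighbor =
                              within_labeled_requires_neighbor)
  lap <- signed_laplacian(w)

  num <- rowSums((xs %*% lap$L) * xs)
  d_total <- sum(lap$d)
  mu <- if (abs(d_total) < 1e-12) rowMeans(xs) else drop(xs %*% lap$d) / d_total
  xc <- xs - mu
  den <- drop(xc^2 %*% lap$d)
  degenerate <- den <= 1e-12
  term <- ifelse(degenerate, Inf, num / den)

  nmi <- apply(xs, 1, function(f) {
    names(f) <- colnames(xs)
    normalized_mi(f, y, bins = mi_bins)
  })
  score <- ifelse(degenerate, Inf, lambda * term + (1 - lambda) * (1 - nmi))
  new_feature_scores(rownames(x), score, degenerate,
                     direction = "smaller", method = "semimm",
                     config = list(lambda = lambda, k = k, gamma = gamma,
                                   mi_bins = mi_bins, metric = metric))
}

#' Top-ranked gene ids from a score table
#'
#' @param scores A `"feature_scores"` tibble.
#' @param top_g Number of genes to return; must not exceed the gene count.
#' @return Character vector of `top_g` gene ids in rank order (best first).
#' @export
rank_features <- function(scores, top_g) {
  stopifnot(inherits(scores, "feature_scores"))
  if (top_g > nrow(scores) || top_g < 1) {
    stop("top_g must be between 1 and the number of genes", call. = FALSE)
  }
  scores$gene_id[order(scores$rank)][seq_len(top_g)]
}

#' @export
print.feature_scores <- function(x, ...) {
  cat(sprintf("<feature_scores: %s, %d genes, %s-is-better, %d degenerate>\n",
              attr(x, "method"), nrow(x),
              attr(x, "direction"), sum(x$degenerate)))
  NextMethod()
}
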