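#' Laplacian score (unsupervised)
#'
#' Ranks genes by the quotient of local non-smoothness to degree-weighted
#' variance on a heat-kernel k-nearest-neighbour graph:
#' `L_r = f~' L f~ / (f~' D f~)`, smaller is better. Neighbour pairs get
#' weight `exp(-dist^2 / t)`; `t = Inf` yields the binary-weight variant
#' (all neighbour weights 1). `f~` is the degree-weighted centered gene.
#'
#' @inheritParams semimm_score
#' @param t Heat-kernel bandwidth; `NULL` (default) uses the mean squared
#'   neighbour distance. `Inf` gives binary weights.
#' @return A `"feature_scores"` tibble, direction smaller-is-better;
#'   zero-variance genes are degenerate and rank last.
#' @export
laplacian_score <- function(x, k = 5, t = NULL, metric = "euclidean",
                            standardize = TRUE) {
  x <- as_expr_matrix(x)
  xs <- if (standardize) standardize_genes(x) else x
  g <- build_knn_graph(xs, k = k, metric = metric)
  adj <- g$adjacency
  d2 <- g$dist^2
  if (is.null(t)) {
    t <- mean(d2[adj])
    if (!is.finite(t) || t <= 0) t <- 1
  }
  if (t <= 0) stop("bandwidth t must be positive", call. = FALSE)
  W <- matrix(0, nrow(adj), ncol(adj), dimnames = dimnames(adj))
  W[adj] <- if (is.infinite(t)) 1 else exp(-d2[adj] / t)
  d <- rowSums(W)
  L <- diag(d, nrow = nrow(W)) - W

  d_total <- sum(d)
  mu <- if (d_total < 1e-12) rowMeans(xs) else drop(xs %*% d) / d_total
  xc <- xs - mu
  num <- rowSums((xc %*% L) * xc)
  den <- drop(xc^2 %*% d)
  degenerate <- den <= 1e-12
  score <- ifelse(degenerate, Inf, num / den)
  new_feature_scores(rownames(x), score, degenerate,
                     direction = "smaller", method = "laplacian",
                     config = list(k = k, t = t, metric = metric))
}

#' Fisher score (supervised)
#'
#' Ratio of between-class to within-class scatter per gene, computed over
#' the labeled samples only:
#' `F_r = sum_c n_c (mu_rc - mu_r)^2 / (sum_c n_c sigma^2_rc + eps)`,
#' with class-wise population variances and `eps = 1e-12` guarding perfectly
#' separated genes. Larger is better.
#'
#' @inheritParams semimm_score
#' @return A `"feature_scores"` tibble, direction larger-is-better.
#' @export
fisher_score <- function(x, labels, standardize = TRUE) {
  x <- as_expr_matrix(x)
  y <- as_partial_labels(labels, colnames(x))
  keep <- !is.na(y)
  if (length(unique(y[keep])) < 2) {
    stop("Fisher score requires >=2 classes", call. = FALSE)
  }
  xs <- if (standardize) standardize_genes(x) else x
  xl <- xs[, keep, drop = FALSE]
  yl <- y[keep]
  mu <- rowMeans(xl)
  between <- numeric(nrow(xl))
  within <- numeric(nrow(xl))
  for (cls in unique(yl)) {
    xc <- xl[, yl == cls, drop = FALSE]
    n_c <- ncol(xc)
    mu_c <- rowMeans(xc)
    between <- between + n_c * (mu_c - mu)^2
    within <- within + rowSums((xc - mu_c)^2)  # = n_c * population variance
  }
  score <- between / (within + 1e-12)
  new_feature_scores(rownames(x), score, degenerate = rep(FALSE, nrow(x)),
                     direction = "larger", method = "fisher",
                     config = list())
}

#' Locality-sensitive semi-supervised margin ratio (LSDF-style)
#'
#' Semi-supervised baseline that scores each gene by the ratio of its
#' between-class to within-class graph smoothness,
#' `f' L_b f / (f' L_w f + eps)`, where `L_w` and `L_b` are the Laplacians
#' of the within-class and between-class margin graphs built exactly as in
#' [split_margin_weights()] with same-class weight `alpha`. Larger is
#' better. With no labeled samples the between-class graph is empty and all
#' scores are 0. This is a reconstruction from the method's published
#' description and stated settings, not a line-by-line port of the original
#' algorithm.
#'
#' @inheritParams semimm_score
#' @param alpha Same-class within-graph weight (default 100).
#' @return A `"feature_scores"` tibble, direction larger-is-better.
#' @export
lsdf_score <- function(x, labels, k = 5, alpha = 100, metric = "euclidean",
                       standardize = TRUE) {
  x <- as_expr_matrix(x)
  y <- as_partial_labels(labels, colnames(x))
  xs <- if (standardize) standardize_genes(x) else x
  g <- build_knn_graph(xs, k = k, metric = metric)
  w <- split_margin_weights(g, y, gamma = alpha)
  L_w <- diag(rowSums(w$W_w), nrow = nrow(w$W_w)) - w$W_w
  L_b <- diag(rowSums(w$W_b), nrow = nrow(w$W_b)) - w$W_b
  num <- rowSums((xs %*% L_b) * xs)
  den <- rowSums((xs %*% L_w) * xs)
  score <- num / (den + 1e-12)
  new_feature_scores(rownames(x), score, degenerate = rep(FALSE, nrow(x)),
                     direction = "larger", method = "lsdf",
                     config = list(k = k, alpha = alpha, metric = metric))
}
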