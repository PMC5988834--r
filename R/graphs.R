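#' Build a k-nearest-neighbour graph over samples
#'
#' Computes pairwise distances between samples (columns) and connects each
#' sample to its `k` nearest others. The edge set is OR-symmetrized: an edge
#' exists if either endpoint lists the other among its k nearest. Distance
#' ties are broken toward the lower sample index so the graph is fully
#' deterministic.
#'
#' @param x Expression data, genes x samples.
#' @param k Number of neighbours per sample; must satisfy `1 <= k <= m - 1`.
#' @param metric Distance metric passed to [stats::dist()] (default
#'   `"euclidean"`).
#' @return An object of class `"knn_graph"`: a list with `adjacency`
#'   (m x m symmetric logical matrix, zero diagonal), `dist` (m x m distance
#'   matrix), `k`, and `metric`.
#' @examples
#' x <- rbind(c(0, 1, 10, 11))
#' g <- build_knn_graph(x, k = 1)
#' which(g$adjacency, arr.ind = TRUE)
#' @export
build_knn_graph <- function(x, k, metric = "euclidean") {
  x <- as_expr_matrix(x)
  m <- ncol(x)
  if (k >= m) stop("k must be smaller than sample count", call. = FALSE)
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  dmat <- as.matrix(stats::dist(t(x), method = metric))
  adj <- matrix(FALSE, m, m, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(m)) {
    others <- setdiff(seq_len(m), i)
    # order() is stable on the second key, giving the ascending-index tie rule
    nn <- others[order(dmat[i, others], others)][seq_len(k)]
    adj[i, nn] <- TRUE
  }
  adj <- adj | t(adj)
  diag(adj) <- FALSE
  structure(list(adjacency = adj, dist = dmat, k = k, metric = metric),
            class = "knn_graph")
}

#' Split a neighbour graph into within-class and between-class weights
#'
#' Partitions sample pairs into the two margin graphs used by the
#' semi-supervised criterion. A pair of labeled neighbours with different
#' classes goes to the between-class matrix `W_b` (weight 1). A same-labeled
#' pair receives the within-class weight `gamma` regardless of adjacency
#' (its defining clause states no neighbourhood condition; set
#' `within_labeled_requires_neighbor = TRUE` for the restrictive reading).
#' A neighbour pair with at least one unlabeled endpoint receives
#' within-class weight 1. The two matrices are mutually exclusive and both
#' symmetric with zero diagonals.
#'
#' @param graph A `"knn_graph"` from [build_knn_graph()].
#' @param labels Partial labels (see [semimm_score()]); `NA` = unlabeled.
#' @param gamma Positive same-class weight (default 100).
#' @param within_labeled_requires_neighbor If `TRUE`, same-labeled pairs are
#'   weighted `gamma` only when they are also graph neighbours.
#' @return An object of class `"margin_weights"`: list with `W_w`, `W_b`
#'   (m x m symmetric matrices) and `gamma`.
#' @export
split_margin_weights <- function(graph, labels, gamma = 100,
                                 within_labeled_requires_neighbor = FALSE) {
  stopifnot(inherits(graph, "knn_graph"))
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0) {
    stop("gamma must be a positive number", call. = FALSE)
  }
  adj <- graph$adjacency
  m <- nrow(adj)
  y <- as_partial_labels(labels, rownames(adj))
  labeled <- !is.na(y)
  both <- outer(labeled, labeled, `&`)
  same <- both
  same[both] <- outer(y, y, `==`)[both]
  diff_lab <- both & !same

  W_b <- (adj & diff_lab) * 1
  W_w <- matrix(0, m, m, dimnames = dimnames(adj))
  within_lab <- if (within_labeled_requires_neighbor) same & adj else same
  W_w[within_lab] <- gamma
  W_w[adj & !both] <- 1
  diag(W_w) <- 0
  diag(W_b) <- 0
  structure(list(W_w = W_w, W_b = W_b, gamma = gamma),
            class = "margin_weights")
}

#' Signed Laplacian of the margin graphs
#'
#' Forms `S = W_w - W_b`, the diagonal degree matrix `D` with
#' `D_ii = sum_j S_ij`, and the signed Laplacian `L = D - S`. The quadratic
#' form `f' L f` then equals half the within-class weighted sum of squared
#' feature differences minus the between-class one, which is the local
#' margin the score minimizes. Every row of `L` sums to zero.
#'
#' @param w A `"margin_weights"` object from [split_margin_weights()].
#' @return An object of class `"signed_laplacian"`: list with `S`, `d`
#'   (diagonal of `D` as a vector), `D` (diagonal matrix), and `L`.
#' @export
signed_laplacian <- function(w) {
  stopifnot(inherits(w, "margin_weights"))
  S <- w$W_w - w$W_b
  d <- rowSums(S)
  L <- diag(d, nrow = nrow(S)) - S
  dimnames(L) <- dimnames(S)
  structure(list(S = S, d = d, D = diag(d, nrow = nrow(S)), L = L),
            class = "signed_laplacian")
}
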