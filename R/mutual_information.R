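#' Equal-width discretization of a continuous feature
#'
#' Bins feature values into `bins` equal-width intervals spanning
#' `[min, max]`, with the top edge inclusive. A constant feature collapses
#' to a single bin. Bin indices are 0-based.
#'
#' @param values Finite numeric vector (typically a gene's values over the
#'   labeled samples).
#' @param bins Number of bins, at least 2.
#' @return List with `bin_index` (integer in `[0, B)` per value), `B`
#'   (effective bin count), and `edges` (B + 1 ascending breakpoints).
#' @export
discretize_feature <- function(values, bins) {
  if (length(values) == 0) stop("no labeled samples", call. = FALSE)
  if (!all(is.finite(values))) stop("values must be finite", call. = FALSE)
  if (bins < 2) stop("bins must be at least 2", call. = FALSE)
  lo <- min(values)
  hi <- max(values)
  if (hi == lo) {
    return(list(bin_index = rep(0L, length(values)), B = 1L, edges = c(lo, hi)))
  }
  width <- (hi - lo) / bins
  idx <- pmin(as.integer(floor((values - lo) / width)), bins - 1L)
  list(bin_index = idx, B = as.integer(bins),
       edges = seq(lo, hi, length.out = bins + 1))
}

#' Shannon entropy in bits
#'
#' @param p Probability vector: nonnegative, summing to 1 within 1e-9.
#' @return Entropy `-sum(p * log2(p))` with the `0 log 0 = 0` convention.
#' @examples
#' entropy_bits(c(0.5, 0.25, 0.25)) # 1.5
#' @export
entropy_bits <- function(p) {
  if (any(p < 0)) stop("probabilities must be nonnegative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9) stop("probabilities must sum to 1", call. = FALSE)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mutual information of a contingency table, in bits
#'
#' Plug-in estimate over the joint counts: `sum p(x,y) log2( p(x,y) /
#' (p(x) p(y)) )` over nonzero cells.
#'
#' @param counts Nonnegative integer matrix of joint counts (e.g. feature
#'   bin by class label), total at least 1.
#' @return Mutual information in bits (nonnegative).
#' @export
mutual_information_bits <- function(counts) {
  counts <- as.matrix(counts)
  total <- sum(counts)
  if (total < 1) stop("contingency table must contain at least one count", call. = FALSE)
  p <- counts / total
  px <- rowSums(p)
  py <- colSums(p)
  terms <- p * log2(p / outer(px, py))
  sum(terms[p > 0])
}

#' Normalized mutual information between a feature and class labels
#'
#' Discretizes the feature over the labeled samples, forms the joint
#' bin-by-class table, and returns `MI / max(H(feature), H(classes))`,
#' clamped to `[0, 1]`. Only labeled samples participate: the class variable
#' is undefined elsewhere. If either marginal entropy is zero (constant
#' feature, single class, or no labeled samples) the result is 0 by
#' convention, so such features contribute a constant to any blended score.
#'
#' @param f Numeric feature values, one per sample.
#' @param labels Partial labels aligned with `f` (`NA` = unlabeled), in any
#'   form accepted by [semimm_score()].
#' @param bins Bin count for discretization; default
#'   `max(2, ceiling(sqrt(n_labeled)))`.
#' @return Normalized mutual information in `[0, 1]`.
#' @export
normalized_mi <- function(f, labels, bins = NULL) {
  ids <- names(f)
  if (is.null(ids)) ids <- sprintf("sample_%d", seq_along(f))
  y <- as_partial_labels(labels, ids)
  keep <- !is.na(y)
  f <- f[keep]
  y <- y[keep]
  if (length(f) == 0) return(0)
  if (is.null(bins)) bins <- max(2L, ceiling(sqrt(length(f))))
  disc <- discretize_feature(f, bins)
  tab <- table(factor(disc$bin_index, levels = 0:(disc$B - 1)), factor(y))
  mi <- mutual_information_bits(tab)
  h_f <- entropy_bits(rowSums(tab) / sum(tab))
  h_c <- entropy_bits(colSums(tab) / sum(tab))
  denom <- max(h_f, h_c)
  if (denom == 0) return(0)
  min(max(mi / denom, 0), 1)
}
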