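#' Coerce expression input to the canonical genes x samples matrix
#'
#' User-facing functions accept either a numeric matrix (genes in rows,
#' samples in columns) or a data frame whose first column holds gene
#' identifiers and whose remaining columns are one sample each. This helper
#' normalizes both to a numeric matrix with unique gene and sample ids.
#'
#' @param x Numeric matrix or data frame in genes-by-samples orientation.
#' @return Numeric matrix with `rownames` (gene ids) and `colnames`
#'   (sample ids).
#' @keywords internal
as_expr_matrix <- function(x) {
  if (is.data.frame(x)) {
    if (ncol(x) < 3) {
      stop("expression data frame needs an id column plus at least 2 samples",
           call. = FALSE)
    }
    ids <- as.character(x[[1]])
    vals <- x[-1]
    bad <- !vapply(vals, is.numeric, logical(1))
    if (any(bad)) {
      stop("non-numeric expression column(s): ",
           paste(names(vals)[bad], collapse = ", "), call. = FALSE)
    }
    x <- as.matrix(vals)
    rownames(x) <- ids
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expression data must be a numeric matrix or a data frame", call. = FALSE)
  }
  if (is.null(rownames(x))) {
    rownames(x) <- sprintf("gene_%d", seq_len(nrow(x)))
  }
  if (is.null(colnames(x))) {
    colnames(x) <- sprintf("sample_%d", seq_len(ncol(x)))
  }
  if (anyDuplicated(rownames(x))) stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(colnames(x))) stop("duplicate sample ids", call. = FALSE)
  if (nrow(x) < 1 || ncol(x) < 2) {
    stop("need at least 1 gene and 2 samples", call. = FALSE)
  }
  if (!all(is.finite(x))) stop("expression values must all be finite", call. = FALSE)
  x
}

#' Align partial class labels with the samples of an expression matrix
#'
#' @param labels A data frame with columns `sample_id` and `label` (extra
#'   columns ignored), a named character vector, or an unnamed vector already
#'   aligned with `sample_ids`. `NA` or empty labels mark unlabeled samples.
#' @param sample_ids Character vector of sample ids in matrix column order.
#' @return Character vector of length `length(sample_ids)`, named by sample
#'   id, with `NA` for unlabeled samples.
#' @keywords internal
as_partial_labels <- function(labels, sample_ids) {
  if (is.null(labels)) {
    out <- rep(NA_character_, length(sample_ids))
    names(out) <- sample_ids
    return(out)
  }
  if (is.data.frame(labels)) {
    ids <- as.character(labels[[1]])
    lab <- as.character(labels[[2]])
    if (anyDuplicated(ids)) stop("duplicate sample_id in labels", call. = FALSE)
    unknown <- setdiff(ids, sample_ids)
    if (length(unknown) > 0) {
      stop("label(s) for unknown sample id(s): ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
    out <- rep(NA_character_, length(sample_ids))
    names(out) <- sample_ids
    out[ids] <- lab
  } else if (!is.null(names(labels))) {
    out <- as_partial_labels(
      data.frame(sample_id = names(labels), label = as.character(labels)),
      sample_ids
    )
    return(out)
  } else {
    if (length(labels) != length(sample_ids)) {
      stop("unnamed label vector must have one entry per sample", call. = FALSE)
    }
    out <- as.character(labels)
    names(out) <- sample_ids
  }
  out[!is.na(out) & out == ""] <- NA_character_
  out
}

#' Standardize each gene to zero mean and unit variance
#'
#' Each gene (row) is centered and scaled by its population standard
#' deviation, the usual per-gene z-score preprocessing applied before graph
#' construction. Genes whose expression is constant across samples carry no
#' scale and are returned as all-zero rows, flagged in the `"degenerate"`
#' attribute rather than producing `NaN`.
#'
#' @param x Expression data, genes x samples (matrix or data frame; see
#'   [semimm_score()] for accepted forms).
#' @return Numeric matrix of the same dimensions with attribute
#'   `"degenerate"`: a named logical vector marking zero-variance genes.
#' @examples
#' x <- matrix(c(1, 2, 3, 5, 5, 5), nrow = 2, byrow = TRUE)
#' standardize_genes(x)
#' @export
standardize_genes <- function(x) {
  x <- as_expr_matrix(x)
  m <- ncol(x)
  mu <- rowMeans(x)
  centered <- x - mu
  sd_pop <- sqrt(rowSums(centered^2) / m)
  degenerate <- sd_pop == 0
  scale_by <- ifelse(degenerate, 1, sd_pop)
  out <- centered / scale_by
  out[degenerate, ] <- 0
  names(degenerate) <- rownames(x)
  attr(out, "degenerate") <- degenerate
  out
}
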