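#' Simulate small-sample, high-dimension multi-class expression data
#'
#' Generates a genes x samples matrix emulating the structure of tumour
#' expression benchmarks: many exchangeable noise genes plus a small set of
#' informative genes with class-dependent mean shifts. Informative genes are
#' split round-robin among the classes, each up-shifted by
#' `effect * noise_sd` in exactly one class (a one-vs-rest marker-gene
#' pattern). All values are otherwise i.i.d. `Normal(0, noise_sd^2)`. The
#' generator draws from a single RNG stream seeded explicitly, so identical
#' seeds reproduce the matrix bit for bit; the caller's RNG state is left
#' untouched.
#'
#' @param n_genes Total number of genes.
#' @param n_informative Number of genes carrying class signal
#'   (`<= n_genes`).
#' @param n_classes Number of classes (>= 2).
#' @param samples_per_class Samples per class: a single count or one per
#'   class.
#' @param effect Mean shift of an informative gene in its marked class, in
#'   units of `noise_sd`.
#' @param noise_sd Standard deviation of the background noise.
#' @param seed Integer seed.
#' @return List of class `"semimm_sim"`: `expression` (tibble, `gene_id`
#'   plus one column per sample), `labels` (tibble `sample_id`, `label`),
#'   and `informative` (character vector of informative gene ids).
#' @examples
#' sim <- simulate_expression(n_genes = 100, n_informative = 5,
#'                            n_classes = 2, samples_per_class = 10,
#'                            effect = 3, seed = 1)
#' sim$informative
#' @export
simulate_expression <- function(n_genes = 500, n_informative = 20,
                                n_classes = 3, samples_per_class = 20,
                                effect = 2, noise_sd = 1, seed = 0) {
  stopifnot(n_genes >= 1, n_informative >= 0, n_informative <= n_genes,
            n_classes >= 2, all(samples_per_class >= 1), noise_sd > 0)
  if (length(samples_per_class) == 1) {
    samples_per_class <- rep(samples_per_class, n_classes)
  }
  stopifnot(length(samples_per_class) == n_classes)
  m <- sum(samples_per_class)
  class_names <- sprintf("class_%d", seq_len(n_classes))
  y <- rep(class_names, times = samples_per_class)
  gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
  sample_ids <- sprintf("sample_%03d", seq_len(m))

  x <- with_seed(seed, {
    mat <- matrix(stats::rnorm(n_genes * m, sd = noise_sd), n_genes, m)
    if (n_informative > 0) {
      marked_class <- ((seq_len(n_informative) - 1) %% n_classes) + 1
      for (r in seq_len(n_informative)) {
        in_class <- y == class_names[marked_class[r]]
        mat[r, in_class] <- mat[r, in_class] + effect * noise_sd
      }
    }
    mat
  })
  dimnames(x) <- list(gene_ids, sample_ids)

  expression <- tibble::as_tibble(x, rownames = "gene_id")
  labels <- tibble::tibble(sample_id = sample_ids, label = y)
  structure(list(expression = expression, labels = labels,
                 informative = gene_ids[seq_len(n_informative)]),
            class = "semimm_sim")
}

#' Mask class labels to a stratified semi-supervised subset
#'
#' Keeps exactly `L` labeled samples per class, drawn uniformly without
#' replacement, and marks the remainder as unlabeled (`NA`). This is the
#' stratified partial-labelling used throughout the semi-supervised
#' protocol, where the labeled count per dataset is `L` times the number of
#' classes.
#'
#' @param labels Full labels: tibble with `sample_id`/`label` columns or a
#'   named vector.
#' @param L Labeled samples to keep per class; must not exceed any class
#'   size.
#' @param seed Integer seed.
#' @return Tibble with `sample_id` and `label` (`NA` for masked samples),
#'   in the input sample order.
#' @export
mask_labels <- function(labels, L, seed = 0) {
  if (is.data.frame(labels)) {
    ids <- as.character(labels[[1]])
    y <- as.character(labels[[2]])
  } else {
    ids <- names(labels)
    y <- as.character(labels)
    if (is.null(ids)) ids <- sprintf("sample_%d", seq_along(y))
  }
  if (anyNA(y)) stop("mask_labels expects fully labeled input", call. = FALSE)
  sizes <- table(y)
  if (any(sizes < L)) {
    stop(sprintf("L = %d exceeds the size of class '%s' (%d)",
                 L, names(sizes)[which.min(sizes)], min(sizes)), call. = FALSE)
  }
  keep <- with_seed(seed, {
    unlist(lapply(unique(y), function(cls) {
      idx <- which(y == cls)
      sample(idx, L)
    }))
  })
  out <- rep(NA_character_, length(y))
  out[keep] <- y[keep]
  tibble::tibble(sample_id = ids, label = out)
}

#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
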