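#' Stratified train/test split
#'
#' Splits samples into train and test sets class by class. Each class
#' contributes `round(ratio * size)` training samples, clamped so that every
#' class keeps at least one sample on each side; the remainder goes to the
#' test set. Sampling is uniform without replacement under `seed`.
#'
#' @param labels Full labels: tibble with `sample_id`/`label` columns, a
#'   named vector, or a plain vector.
#' @param ratio Training fraction in (0, 1); default 0.6.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test` (positions in
#'   the input order); disjoint and exhaustive.
#' @export
stratified_split <- function(labels, ratio = 0.6, seed = 0) {
  if (ratio <= 0 || ratio >= 1) stop("ratio must lie in (0, 1)", call. = FALSE)
  y <- if (is.data.frame(labels)) as.character(labels[[2]]) else as.character(labels)
  if (anyNA(y)) stop("stratified_split expects fully labeled input", call. = FALSE)
  sizes <- table(y)
  if (any(sizes < 2)) {
    stop(sprintf("class '%s' has fewer than 2 samples",
                 names(sizes)[which.min(sizes)]), call. = FALSE)
  }
  train <- with_seed(seed, {
    unlist(lapply(unique(y), function(cls) {
      idx <- which(y == cls)
      n_tr <- min(max(round(ratio * length(idx)), 1L), length(idx) - 1L)
      sample(idx, n_tr)
    }))
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}

#' Binary classification metrics from a confusion matrix
#'
#' Computes accuracy, precision, recall and F-score from true/false
#' positive/negative counts. Precision, recall and F-score are defined as 0
#' when their denominator is 0; which metrics hit that convention is
#' recorded in the `"undefined"` attribute.
#'
#' @param tp,tn,fp,fn Nonnegative counts; their total must be at least 1.
#' @return One-row tibble with columns `accuracy`, `precision`, `recall`,
#'   `f_score`, plus attribute `"undefined"`.
#' @examples
#' binary_metrics(tp = 40, tn = 45, fp = 5, fn = 10)
#' @export
binary_metrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0, tp + tn + fp + fn >= 1)
  undefined <- character(0)
  accuracy <- (tp + tn) / (tp + tn + fn + fp)
  if (tp + fp == 0) {
    precision <- 0
    undefined <- c(undefined, "precision")
  } else precision <- tp / (tp + fp)
  if (tp + fn == 0) {
    recall <- 0
    undefined <- c(undefined, "recall")
  } else recall <- tp / (tp + fn)
  if (precision + recall == 0) {
    f_score <- 0
    undefined <- c(undefined, "f_score")
  } else f_score <- 2 * precision * recall / (precision + recall)
  out <- tibble::tibble(accuracy = accuracy, precision = precision,
                        recall = recall, f_score = f_score)
  attr(out, "undefined") <- undefined
  out
}

#' One-against-rest evaluation with AUC
#'
#' Evaluates multiclass predictions by binarizing each class against the
#' rest. Hard predictions are taken as `decision score > 0`; the four
#' confusion metrics come from [binary_metrics()] and the AUC from the
#' continuous decision values. The report is the unweighted mean over
#' classes. With exactly two classes a single binary evaluation is used,
#' the positive class being the lexicographically second label. A class
#' absent from `y_true` has no defined AUC and is dropped from the AUC mean
#' with a warning.
#'
#' @param y_true Character vector of true class labels.
#' @param decision_scores Numeric matrix (samples x classes, columns named
#'   by class) of continuous decision values oriented so larger favours the
#'   class; for the two-class case a single vector for the positive class is
#'   also accepted.
#' @param classes Optional ordered class set; default
#'   `sort(unique(y_true))` extended by the score columns.
#' @return One-row tibble: `accuracy`, `precision`, `recall`, `f_score`,
#'   `auc`.
#' @export
one_vs_rest_report <- function(y_true, decision_scores, classes = NULL) {
  if (is.null(dim(decision_scores))) {
    decision_scores <- matrix(decision_scores, ncol = 1)
  }
  if (is.null(classes)) {
    classes <- sort(unique(c(y_true, colnames(decision_scores))))
  }
  if (length(classes) < 2) stop("need at least 2 classes", call. = FALSE)

  eval_one <- function(truth, score) {
    pred <- score > 0
    met <- binary_metrics(tp = sum(pred & truth), tn = sum(!pred & !truth),
                          fp = sum(pred & !truth), fn = sum(!pred & truth))
    auc <- if (length(unique(truth)) < 2) NA_real_ else auc_binary(truth, score)
    cbind(met, tibble::tibble(auc = auc))
  }

  if (length(classes) == 2) {
    pos <- classes[2]
    score <- if (ncol(decision_scores) == 1) decision_scores[, 1] else
      decision_scores[, pos]
    rows <- eval_one(y_true == pos, score)
  } else {
    rows <- dplyr::bind_rows(lapply(classes, function(cls) {
      eval_one(y_true == cls, decision_scores[, cls])
    }))
  }
  if (anyNA(rows$auc)) {
    warning("AUC undefined for class(es) absent from the test fold; excluded from the mean",
            call. = FALSE)
  }
  tibble::tibble(accuracy = mean(rows$accuracy),
                 precision = mean(rows$precision),
                 recall = mean(rows$recall),
                 f_score = mean(rows$f_score),
                 auc = mean(rows$auc, na.rm = TRUE))
}

# AUC of a binary problem from continuous scores.
auc_binary <- function(truth, score) {
  r <- pROC::roc(response = factor(truth, levels = c(FALSE, TRUE)),
                 predictor = as.numeric(score),
                 levels = c("FALSE", "TRUE"), direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

# Fit one linear SVM per class (class vs rest) on the training samples and
# return test-set decision values oriented so positive favours the class.
svm_ovr_decision <- function(x_train, y_train, x_test, cost = 1) {
  classes <- sort(unique(y_train))
  dv <- sapply(classes, function(cls) {
    ybin <- factor(ifelse(y_train == cls, "pos", "rest"),
                   levels = c("rest", "pos"))
    fit <- e1071::svm(x = t(x_train), y = ybin, kernel = "linear",
                      cost = cost, scale = FALSE)
    pred <- stats::predict(fit, t(x_test), decision.values = TRUE)
    v <- attr(pred, "decision.values")
    if (startsWith(colnames(v)[1], "pos")) v[, 1] else -v[, 1]
  })
  dv <- matrix(dv, ncol = length(classes),
               dimnames = list(colnames(x_test), classes))
  dv
}

#' Benchmark feature-selection methods with a semi-supervised SVM protocol
#'
#' Reproduces the standard evaluation loop for semi-supervised gene
#' selection. For each repeat: (1) the samples are split 6:4 (configurable)
#' into train and test by stratified sampling; (2) a stratified partial
#' label mask keeping `L` labels per class is drawn from the *training*
#' portion, so no scoring method ever sees a test sample; (3) each method
#' ranks the genes on the training samples; (4) for every subset size in
#' `gene_grid`, a linear one-vs-rest SVM is trained on the top genes of the
#' training set (with its full labels) and evaluated on the test set.
#' Genes are z-scored with training-set statistics before classification.
#' Seeds for splits and masks derive deterministically from `seed` per
#' (L, repeat), so method arms are paired.
#'
#' The extra method `"random"` ranks genes by a seeded uniform shuffle and
#' serves as a negative control.
#'
#' @inheritParams semimm_score
#' @param labels Full labels for every sample (tibble, named vector, or
#'   aligned vector).
#' @param methods Subset of `c("semimm", "laplacian", "fisher", "lsdf",
#'   "random")`.
#' @param L_values Labeled samples kept per class during scoring.
#' @param gene_grid Gene subset sizes to evaluate; entries exceeding the
#'   gene count are skipped with a warning.
#' @param repeats Number of split/mask repetitions.
#' @param split_ratio Training fraction of the stratified split.
#' @param seed Master seed.
#' @param alpha Same-class weight for the LSDF-style baseline.
#' @param svm_cost Linear SVM cost parameter.
#' @return A `"semimm_benchmark"` tibble with columns `method`, `L`,
#'   `n_genes`, `metric`, `mean`, `sd` (means over repeats). Attributes:
#'   `"raw"` (per-repeat metric tibble) and `"splits"` (per (L, repeat):
#'   train/test sample ids and the sample ids passed to scoring).
#' @export
run_benchmark <- function(x, labels,
                          methods = c("semimm", "laplacian", "fisher", "lsdf"),
                          L_values = c(2, 4, 6),
                          gene_grid = seq(5, 300, by = 5),
                          repeats = 10, split_ratio = 0.6, seed = 0,
                          lambda = 0.6, k = 5, gamma = 100, alpha = 100,
                          mi_bins = NULL, svm_cost = 1) {
  x <- as_expr_matrix(x)
  y <- as_partial_labels(labels, colnames(x))
  if (anyNA(y)) stop("run_benchmark expects fully labeled input", call. = FALSE)
  methods <- match.arg(methods,
                       c("semimm", "laplacian", "fisher", "lsdf", "random"),
                       several.ok = TRUE)
  n <- nrow(x)
  bad_grid <- gene_grid > n
  if (any(bad_grid)) {
    warning(sprintf("%d grid point(s) exceed the gene count and were skipped",
                    sum(bad_grid)), call. = FALSE)
    gene_grid <- gene_grid[!bad_grid]
  }
  if (length(gene_grid) == 0) stop("empty gene grid", call. = FALSE)

  raw <- list()
  splits_log <- list()
  for (L in L_values) {
    for (rep_i in seq_len(repeats)) {
      split_seed <- (seed + 7919L * rep_i) %% 2147483647L
      mask_seed <- (seed + 104729L * rep_i + 31L * match(L, L_values)) %% 2147483647L
      sp <- stratified_split(y, ratio = split_ratio, seed = split_seed)
      x_tr <- x[, sp$train, drop = FALSE]
      x_te <- x[, sp$test, drop = FALSE]
      y_tr <- y[sp$train]
      y_te <- y[sp$test]
      partial <- mask_labels(tibble::tibble(sample_id = colnames(x_tr),
                                            label = unname(y_tr)),
                             L = L, seed = mask_seed)

      # z-score with training statistics only
      mu <- rowMeans(x_tr)
      sd_tr <- sqrt(rowSums((x_tr - mu)^2) / ncol(x_tr))
      sd_tr[sd_tr == 0] <- 1
      x_tr_s <- (x_tr - mu) / sd_tr
      x_te_s <- (x_te - mu) / sd_tr

      k_eff <- min(k, ncol(x_tr) - 1)
      rankings <- lapply(stats::setNames(methods, methods), function(method) {
        scores <- switch(
          method,
          semimm = semimm_score(x_tr, partial, lambda = lambda, k = k_eff,
                                gamma = gamma, mi_bins = mi_bins),
          laplacian = laplacian_score(x_tr, k = k_eff),
          fisher = fisher_score(x_tr, partial),
          lsdf = lsdf_score(x_tr, partial, k = k_eff, alpha = alpha),
          random = NULL
        )
        if (method == "random") {
          rnd_seed <- (seed + 1299709L * rep_i + 97L * match(L, L_values)) %% 2147483647L
          with_seed(rnd_seed, sample(rownames(x_tr)))
        } else {
          scores$gene_id[order(scores$rank)]
        }
      })
      splits_log[[sprintf("L%d_rep%d", L, rep_i)]] <-
        list(train = colnames(x_tr), test = colnames(x_te),
             scored_samples = colnames(x_tr))

      for (method in methods) {
        ranking <- rankings[[method]]
        for (g in gene_grid) {
          top <- ranking[seq_len(g)]
          dv <- svm_ovr_decision(x_tr_s[top, , drop = FALSE], y_tr,
                                 x_te_s[top, , drop = FALSE], cost = svm_cost)
          rep_row <- suppressWarnings(one_vs_rest_report(y_te, dv))
          raw[[length(raw) + 1]] <- dplyr::bind_cols(
            tibble::tibble(method = method, L = L, rep = rep_i, n_genes = g),
            rep_row
          )
        }
      }
    }
  }
  raw <- dplyr::bind_rows(raw)
  summary <- raw |>
    tidyr::pivot_longer(cols = c("accuracy", "precision", "recall",
                                 "f_score", "auc"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$method, .data$L, .data$n_genes, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")
  attr(summary, "raw") <- raw
  attr(summary, "splits") <- splits_log
  class(summary) <- c("semimm_benchmark", class(summary))
  summary
}
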