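#' Read a delimited expression matrix
#'
#' Reads a TSV or CSV (sniffed by extension) with a header row and an id
#' column, returning the canonical genes x samples matrix. Files with
#' samples in rows are transposed via `orientation`.
#'
#' @param path Path to a `.tsv`/`.txt` (tab) or `.csv` file.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`.
#' @return Numeric matrix, genes x samples, with gene and sample ids as
#'   dimnames.
#' @export
read_expression <- function(path,
                            orientation = c("genes_in_rows", "samples_in_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read_delim_sniffed(path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)])[1:min(3, sum(duplicated(ids)))],
               collapse = ", "), call. = FALSE)
  }
  vals <- df[-1]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad) == 0 && !anyNA(col)) {
        vals[[j]] <- num
        next
      }
      i <- if (length(bad) > 0) bad[1] else which(is.na(col))[1]
      stop(sprintf("non-numeric value at row id '%s', column '%s'",
                   ids[i], names(vals)[j]), call. = FALSE)
    }
    if (anyNA(col)) {
      i <- which(is.na(col))[1]
      stop(sprintf("non-numeric value at row id '%s', column '%s'",
                   ids[i], names(vals)[j]), call. = FALSE)
    }
  }
  x <- as.matrix(vals)
  rownames(x) <- ids
  if (orientation == "samples_in_rows") x <- t(x)
  as_expr_matrix(x)
}

#' Write an expression matrix as TSV
#'
#' @param x Expression data (matrix or data frame, genes x samples).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(x, path) {
  x <- as_expr_matrix(x)
  df <- tibble::as_tibble(x, rownames = "gene_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read partial class labels
#'
#' Reads a two-column delimited file (`sample_id`, `label`); empty or `NA`
#' labels mark unlabeled samples. When `sample_ids` is supplied the labels
#' are matched by id (order-independent) and unknown ids are an error.
#'
#' @param path Path to a TSV/CSV label file.
#' @param sample_ids Optional sample ids of the expression matrix to
#'   validate and order against.
#' @return Tibble with columns `sample_id` and `label` (`NA` = unlabeled).
#' @export
read_labels <- function(path, sample_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read_delim_sniffed(path)
  if (ncol(df) < 2) stop("label file needs two columns: sample_id, label", call. = FALSE)
  out <- tibble::tibble(sample_id = as.character(df[[1]]),
                        label = as.character(df[[2]]))
  out$label[!is.na(out$label) & out$label == ""] <- NA_character_
  if (anyDuplicated(out$sample_id)) {
    stop("duplicate sample_id in ", path, call. = FALSE)
  }
  if (!is.null(sample_ids)) {
    y <- as_partial_labels(out, sample_ids)
    if (all(is.na(y)) && any(!is.na(out$label))) {
      stop("labels share no sample ids with the expression matrix", call. = FALSE)
    }
    out <- tibble::tibble(sample_id = sample_ids, label = unname(y))
  }
  out
}

#' Write a gene ranking as TSV
#'
#' Writes columns `gene_id`, `score` (6 significant digits), `rank`,
#' `degenerate` sorted by rank. Output bytes are deterministic for a given
#' ranking.
#'
#' @param scores A `"feature_scores"` tibble.
#' @param path Output path.
#' @param top Optional: write only the top-ranked `top` genes.
#' @return Invisibly, `path`.
#' @export
write_ranking <- function(scores, path, top = NULL) {
  stopifnot(inherits(scores, "feature_scores"))
  out <- scores[order(scores$rank), c("gene_id", "score", "rank", "degenerate")]
  if (!is.null(top)) out <- out[seq_len(min(top, nrow(out))), ]
  out$score <- trimws(formatC(out$score, digits = 6, format = "g"))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write a benchmark report as TSV
#'
#' @param report A `"semimm_benchmark"` tibble from [run_benchmark()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  out <- tibble::as_tibble(report)
  out$mean <- formatC(out$mean, digits = 6, format = "g")
  out$sd <- formatC(out$sd, digits = 6, format = "g")
  readr::write_tsv(out, path)
  invisible(path)
}

read_delim_sniffed <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, na = c("", "NA"))
}
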