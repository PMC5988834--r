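# Independent brute-force oracles, written straight from the defining sums
# with explicit loops. They share no code with the package internals and are
# only run on tiny instances.

oracle_knn_adj <- function(x, k) {
  m <- ncol(x)
  adj <- matrix(FALSE, m, m)
  for (i in seq_len(m)) {
    d <- rep(Inf, m)
    for (j in seq_len(m)) if (j != i) d[j] <- sqrt(sum((x[, i] - x[, j])^2))
    # nearest k, ties toward the lower index
    ord <- order(d, seq_len(m))
    nn <- ord[seq_len(k)]
    adj[i, nn] <- TRUE
  }
  adj <- adj | t(adj)
  diag(adj) <- FALSE
  adj
}

oracle_margin_weights <- function(adj, y, gamma) {
  m <- length(y)
  W_w <- matrix(0, m, m)
  W_b <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) next
      bi <- !is.na(y[i]); bj <- !is.na(y[j])
      if (adj[i, j] && bi && bj && y[i] != y[j]) {
        W_b[i, j] <- 1
      } else if (bi && bj && y[i] == y[j]) {
        W_w[i, j] <- gamma
      } else if (adj[i, j] && (!bi || !bj)) {
        W_w[i, j] <- 1
      }
    }
  }
  list(W_w = W_w, W_b = W_b)
}

oracle_nmi <- function(f, y, bins = NULL) {
  keep <- !is.na(y)
  f <- f[keep]; y <- y[keep]
  if (length(f) == 0) return(0)
  if (is.null(bins)) bins <- max(2, ceiling(sqrt(length(f))))
  lo <- min(f); hi <- max(f)
  if (hi == lo) {
    b <- rep(1L, length(f))
    B <- 1L
  } else {
    edges <- lo + (0:bins) * (hi - lo) / bins
    edges[bins + 1] <- hi  # guard the inclusive top edge against round-off
    B <- bins
    b <- integer(length(f))
    for (i in seq_along(f)) {
      for (u in seq_len(B)) {
        top <- if (u == B) f[i] <= edges[u + 1] else f[i] < edges[u + 1]
        if (f[i] >= edges[u] && top) { b[i] <- u; break }
      }
    }
  }
  classes <- sort(unique(y))
  counts <- matrix(0, B, length(classes))
  for (i in seq_along(f)) {
    counts[b[i], match(y[i], classes)] <- counts[b[i], match(y[i], classes)] + 1
  }
  n <- sum(counts)
  h <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  mi <- 0
  for (u in seq_len(nrow(counts))) {
    for (v in seq_len(ncol(counts))) {
      pxy <- counts[u, v] / n
      if (pxy > 0) {
        mi <- mi + pxy * log2(pxy / (sum(counts[u, ]) / n * sum(counts[, v]) / n))
      }
    }
  }
  denom <- max(h(rowSums(counts) / n), h(colSums(counts) / n))
  if (denom == 0) return(0)
  min(max(mi / denom, 0), 1)
}

# Full criterion, straight from the defining equations (half the ordered
# double sum over S in the numerator, degree-weighted centering in the
# denominator, blended with 1 - NMI).
oracle_semimm_scores <- function(x, y, lambda = 0.6, k = 5, gamma = 100,
                                 bins = NULL) {
  adj <- oracle_knn_adj(x, k)
  w <- oracle_margin_weights(adj, y, gamma)
  S <- w$W_w - w$W_b
  m <- ncol(x)
  D <- rowSums(S)
  sapply(seq_len(nrow(x)), function(r) {
    f <- x[r, ]
    num <- 0
    for (i in seq_len(m)) for (j in seq_len(m)) {
      num <- num + 0.5 * (f[i] - f[j])^2 * S[i, j]
    }
    mu <- if (abs(sum(D)) < 1e-12) mean(f) else sum(f * D) / sum(D)
    den <- sum((f - mu)^2 * D)
    if (den <= 1e-12) return(Inf)
    lambda * num / den + (1 - lambda) * (1 - oracle_nmi(f, y, bins))
  })
}

oracle_laplacian_scores <- function(x, k, t) {
  adj <- oracle_knn_adj(x, k)
  m <- ncol(x)
  W <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (adj[i, j]) {
      d2 <- sum((x[, i] - x[, j])^2)
      W[i, j] <- if (is.infinite(t)) 1 else exp(-d2 / t)
    }
  }
  D <- rowSums(W)
  sapply(seq_len(nrow(x)), function(r) {
    f <- x[r, ]
    mu <- if (sum(D) < 1e-12) mean(f) else sum(f * D) / sum(D)
    fc <- f - mu
    num <- 0
    for (i in seq_len(m)) for (j in seq_len(m)) {
      num <- num + 0.5 * (fc[i] - fc[j])^2 * W[i, j]
    }
    den <- sum(fc^2 * D)
    if (den <= 1e-12) return(Inf)
    num / den
  })
}

oracle_lsdf_scores <- function(x, y, k, alpha) {
  adj <- oracle_knn_adj(x, k)
  w <- oracle_margin_weights(adj, y, alpha)
  m <- ncol(x)
  sapply(seq_len(nrow(x)), function(r) {
    f <- x[r, ]
    num <- 0; den <- 0
    for (i in seq_len(m)) for (j in seq_len(m)) {
      num <- num + 0.5 * (f[i] - f[j])^2 * w$W_b[i, j]
      den <- den + 0.5 * (f[i] - f[j])^2 * w$W_w[i, j]
    }
    num / (den + 1e-12)
  })
}

# Small random instance: genes x samples matrix plus random partial labels.
rand_instance <- function(m, n, n_classes = 2, p_labeled = 0.5, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * m), n, m,
              dimnames = list(sprintf("g%d", seq_len(n)),
                              sprintf("s%d", seq_len(m))))
  y <- sample(sprintf("c%d", seq_len(n_classes)), m, replace = TRUE)
  y[runif(m) > p_labeled] <- NA
  names(y) <- colnames(x)
  list(x = x, y = y)
}
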