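test_that("degree-weighted centering matches hand-computed means", {
  expect_equal(as.numeric(center_feature(c(1, 1, 1, 1), c(5, 2, 1, 1))),
               c(0, 0, 0, 0))
  expect_equal(as.numeric(center_feature(c(1, 2), c(1, 1))), c(-0.5, 0.5))
  expect_equal(as.numeric(center_feature(c(1, 2), c(3, 1))), c(-0.25, 0.75))
  # zero total degree falls back to the unweighted mean, flagged
  out <- center_feature(c(1, 3), c(1, -1))
  expect_true(attr(out, "degenerate"))
  expect_equal(as.numeric(out), c(-1, 1))
})

test_that("margin variance term matches the brute-force quotient", {
  x <- rbind(c(0, 1, 2, 3))
  g <- build_knn_graph(x, k = 1)
  lap <- signed_laplacian(split_margin_weights(g, c("A", "A", "B", NA),
                                               gamma = 100))
  f <- c(1, 0, 0, 0)
  got <- margin_variance_term(f, lap)
  brute_num <- 0
  for (i in 1:4) for (j in 1:4) {
    brute_num <- brute_num + 0.5 * (f[i] - f[j])^2 * lap$S[i, j]
  }
  mu <- sum(f * lap$d) / sum(lap$d)
  brute_den <- sum((f - mu)^2 * lap$d)
  expect_false(got$degenerate)
  expect_equal(got$value, brute_num / brute_den, tolerance = 1e-10)

  # shift invariance: numerator unchanged, denominator centered
  shifted <- margin_variance_term(f + 7, lap)
  expect_equal(got$value, shifted$value, tolerance = 1e-8)

  # constant gene: 0/0 is degenerate
  const <- margin_variance_term(rep(2, 4), lap)
  expect_true(const$degenerate)
  expect_identical(const$value, Inf)
})

test_that("lambda endpoints reduce to single-term rankings", {
  inst <- rand_instance(m = 12, n = 6, n_classes = 2, seed = 3)
  s1 <- semimm_score(inst$x, inst$y, lambda = 1, k = 3, standardize = FALSE)
  # margin term alone
  g <- build_knn_graph(inst$x, k = 3)
  lap <- signed_laplacian(split_margin_weights(g, inst$y, gamma = 100))
  terms <- apply(inst$x, 1, function(f) margin_variance_term(f, lap)$value)
  expect_equal(order(s1$rank), order(terms, seq_along(terms)))

  s0 <- semimm_score(inst$x, inst$y, lambda = 0, k = 3, standardize = FALSE)
  nmi <- apply(inst$x, 1, function(f) {
    names(f) <- colnames(inst$x)
    normalized_mi(f, inst$y)
  })
  expect_equal(order(s0$rank), order(1 - nmi, seq_along(nmi)))
})

test_that("scores match the straight-from-the-equations oracle end to end", {
  inst <- rand_instance(m = 6, n = 3, n_classes = 2, p_labeled = 0.7, seed = 9)
  got <- semimm_score(inst$x, inst$y, lambda = 0.6, k = 2, gamma = 100,
                      mi_bins = 2, standardize = FALSE)
  want <- oracle_semimm_scores(inst$x, inst$y, lambda = 0.6, k = 2,
                               gamma = 100, bins = 2)
  expect_equal(unname(got$score), unname(want), tolerance = 1e-10)
})

test_that("a lower-NMI gene with the same margin term scores strictly worse", {
  # two genes engineered to share graph geometry: scores differ only via NMI
  inst <- rand_instance(m = 10, n = 4, n_classes = 2, seed = 5)
  x <- inst$x
  y <- c("A", "A", "A", "B", "B", "B", NA, NA, NA, NA)
  names(y) <- colnames(x)
  x[1, ] <- c(0, 0.1, -0.1, 5, 5.1, 4.9, 0.05, 5.05, -0.02, 5.02) # NMI = 1
  g <- build_knn_graph(x, k = 3)
  lap <- signed_laplacian(split_margin_weights(g, y, gamma = 100))
  t1 <- margin_variance_term(x[1, ], lap)$value
  nmi1 <- normalized_mi(x[1, ], y)
  expect_equal(nmi1, 1)
  for (lam in c(0.2, 0.6, 0.9)) {
    score_low_nmi <- lam * t1 + (1 - lam) * (1 - 0)
    score_high_nmi <- lam * t1 + (1 - lam) * (1 - nmi1)
    expect_lt(score_high_nmi, score_low_nmi)
  }
})

test_that("gene permutation permutes scores; degenerate genes rank last", {
  inst <- rand_instance(m = 8, n = 6, seed = 13)
  x <- inst$x
  x[4, ] <- 3  # constant gene
  s <- semimm_score(x, inst$y, k = 2)
  perm <- c(6, 4, 1, 3, 2, 5)
  sp <- semimm_score(x[perm, ], inst$y, k = 2)
  expect_equal(sp$score, s$score[perm])
  expect_true(s$degenerate[4])
  expect_equal(s$rank[4], 6L)

  expect_equal(rank_features(s, 6)[6], rownames(x)[4])
})

test_that("rank_features sorts in the stated direction with index ties", {
  s <- semimm:::new_feature_scores(c("g1", "g2", "g3"), c(0.2, 0.1, 0.3),
                                   rep(FALSE, 3), "smaller", "test")
  expect_equal(rank_features(s, 2), c("g2", "g1"))
  tied <- semimm:::new_feature_scores(c("g1", "g2", "g3"), c(0.5, 0.5, 0.5),
                                      rep(FALSE, 3), "smaller", "test")
  expect_equal(rank_features(tied, 3), c("g1", "g2", "g3"))
  expect_error(rank_features(s, 4), "top_g")
})

test_that("no labeled samples warns when the NMI term is active", {
  inst <- rand_instance(m = 8, n = 4, seed = 17)
  expect_warning(semimm_score(inst$x, NULL, lambda = 0.6, k = 2),
                 "no labeled samples")
  expect_silent(semimm_score(inst$x, NULL, lambda = 1, k = 2))
})
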