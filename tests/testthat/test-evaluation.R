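test_that("stratified split honours the ratio and the remainder rule", {
  y <- rep(c("A", "B"), each = 5)
  sp <- stratified_split(y, ratio = 0.6, seed = 1)
  expect_length(sp$train, 6)
  expect_length(sp$test, 4)
  expect_equal(sort(c(sp$train, sp$test)), 1:10)
  expect_equal(unname(table(y[sp$train])), c(3L, 3L), ignore_attr = TRUE)

  # a tiny class still lands at least one sample on each side
  y2 <- c("A", "A", "B", "B", "B", "B", "B", "B", "B", "B")
  sp2 <- stratified_split(y2, ratio = 0.9, seed = 2)
  expect_equal(sum(y2[sp2$test] == "A"), 1)

  expect_identical(stratified_split(y, 0.6, seed = 7),
                   stratified_split(y, 0.6, seed = 7))
  expect_error(stratified_split(c("A", "B", "B"), 0.6), "fewer than 2")
})

test_that("confusion metrics reproduce the worked example and conventions", {
  m <- binary_metrics(tp = 40, tn = 45, fp = 5, fn = 10)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$precision, 0.888889, tolerance = 1e-6)
  expect_equal(m$recall, 0.80)
  expect_equal(m$f_score, 0.842105, tolerance = 1e-6)

  perfect <- binary_metrics(tp = 10, tn = 10, fp = 0, fn = 0)
  expect_true(all(unlist(perfect) == 1))

  deg <- binary_metrics(tp = 0, tn = 5, fp = 0, fn = 2)
  expect_equal(deg$precision, 0)
  expect_true("precision" %in% attr(deg, "undefined"))
})

test_that("one-vs-rest report averages classes and handles two-class input", {
  # c = 2, perfect separation on the lexicographically second label
  y <- c("A", "A", "B", "B")
  rep2 <- one_vs_rest_report(y, c(-1, -2, 1, 2), classes = c("A", "B"))
  expect_true(all(unlist(rep2) == 1))

  # decision scores equal to 0/1 membership give AUC 1 per class
  y3 <- c("a", "b", "c", "a", "b", "c")
  dv <- sapply(c("a", "b", "c"), function(cl) as.numeric(y3 == cl) - 0.5)
  rep3 <- one_vs_rest_report(y3, dv)
  expect_equal(rep3$auc, 1)
  expect_equal(rep3$accuracy, 1)

  # random scores on balanced classes hover near AUC 0.5
  set.seed(21)
  yr <- sample(rep(c("a", "b", "c"), each = 100))
  dvr <- matrix(rnorm(900), 300, 3, dimnames = list(NULL, c("a", "b", "c")))
  repr <- one_vs_rest_report(yr, dvr)
  expect_lt(abs(repr$auc - 0.5), 0.08)

  # a class missing from the fold drops out of the AUC mean with a warning
  expect_warning(
    one_vs_rest_report(c("a", "a", "b", "b"),
                       matrix(rnorm(12), 4, 3,
                              dimnames = list(NULL, c("a", "b", "c")))),
    "excluded"
  )
})

test_that("benchmark harness is deterministic and never leaks test samples", {
  sim <- simulate_expression(n_genes = 40, n_informative = 6, n_classes = 2,
                             samples_per_class = 8, effect = 3, seed = 11)
  run <- function() {
    run_benchmark(sim$expression, sim$labels,
                  methods = c("semimm", "fisher"), L_values = 3,
                  gene_grid = c(5, 10), repeats = 2, seed = 4, k = 3)
  }
  r1 <- run()
  r2 <- run()
  expect_equal(tibble::as_tibble(r1), tibble::as_tibble(r2))

  # 2 methods x 1 L x 2 grid points x 5 metrics
  expect_equal(nrow(r1), 2 * 1 * 2 * 5)
  expect_true(all(r1$mean >= 0 & r1$mean <= 1))

  # reported means agree with the retained raw values
  raw <- tidy(r1)
  chk <- dplyr::filter(r1, metric == "accuracy")
  for (i in seq_len(nrow(chk))) {
    sub <- raw[raw$method == chk$method[i] & raw$n_genes == chk$n_genes[i], ]
    expect_equal(mean(sub$accuracy), chk$mean[i], tolerance = 1e-12)
  }

  # leakage guard: scoring only ever saw training samples
  for (sp in attr(r1, "splits")) {
    expect_length(intersect(sp$scored_samples, sp$test), 0)
    expect_setequal(c(sp$train, sp$test), sim$labels$sample_id)
  }
})

test_that("oversized grid points are skipped with a warning", {
  sim <- simulate_expression(n_genes = 12, n_informative = 2, n_classes = 2,
                             samples_per_class = 6, effect = 3, seed = 2)
  expect_warning(
    r <- run_benchmark(sim$expression, sim$labels, methods = "fisher",
                       L_values = 2, gene_grid = c(5, 50), repeats = 1,
                       seed = 1, k = 3),
    "skipped"
  )
  expect_equal(unique(r$n_genes), 5)
})

test_that("strong signal beats random gene picks under paired seeds", {
  # few informative genes among many, so a random pick rarely catches one
  sim <- simulate_expression(n_genes = 200, n_informative = 5, n_classes = 2,
                             samples_per_class = 10, effect = 2.5, seed = 5)
  r <- run_benchmark(sim$expression, sim$labels,
                     methods = c("semimm", "random"), L_values = 4,
                     gene_grid = 5, repeats = 3, seed = 2, k = 3)
  acc <- dplyr::filter(tibble::as_tibble(r), metric == "accuracy")
  expect_gt(acc$mean[acc$method == "semimm"], acc$mean[acc$method == "random"])
})
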