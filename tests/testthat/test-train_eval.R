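make_tiny_data <- function(n_per_class = 6L, seed = 1L) {
  g <- make_class_graphs(2L, 6L, 0.3, seed = 40L)
  ds <- synthetic_dataset_spec(n_channels = 6L, clip_seconds = 2,
                               sample_rate = 32,
                               class_counts = stats::setNames(
                                 rep(n_per_class, 2), names(g)),
                               seed = seed)
  d <- generate_dataset(ds, g)
  list(prep = prepare_clips(d$clips, levels = names(g)), raw = d, graphs = g)
}

test_that("weighted F1 and the confusion matrix match hand computation", {
  # y_true = (0,0,0,1), y_pred = (0,0,1,1):
  # class 1: P=1, R=2/3, F1=0.8; class 2: P=0.5, R=1, F1=2/3
  m <- classification_metrics(c(1L, 1L, 1L, 2L), c(1L, 1L, 2L, 2L), 2L)
  expect_equal(m$f1_weighted, (3 * 0.8 + 1 * 2 / 3) / 4, tolerance = 1e-12)
  expect_equal(m$f1_weighted, 0.7667, tolerance = 1e-4)
  expect_equal(m$accuracy, 0.75)
  expect_equal(rowSums(m$confusion), c(1, 1))

  perfect <- classification_metrics(c(1L, 2L, 3L), c(1L, 2L, 3L), 3L)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1_weighted, 1)
  expect_equal(perfect$confusion, diag(3))
})

test_that("the rank AUC agrees with pROC on random data", {
  set.seed(77)
  for (i in 1:20) {
    n <- 60L
    lab <- rbinom(n, 1, 0.4)
    if (length(unique(lab)) < 2) next
    sc <- rnorm(n) + lab * runif(1, 0, 2)
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = factor(lab, levels = c(0, 1)), predictor = sc,
      quiet = TRUE, direction = "<", levels = c("0", "1"))))
    expect_equal(iggcn:::rank_auc(sc, lab), ref, tolerance = 1e-10)
  }
})

test_that("seed ensembles use the normal-approximation interval", {
  runs <- list(c(acc = 0.8), c(acc = 0.9))
  i <- 0
  out <- seed_ensemble(c(1L, 2L), function(s) {
    i <<- i + 1
    runs[[i]]
  })
  expect_equal(out$mean, 0.85)
  expect_equal(out$ci_halfwidth, 1.96 * sd(c(0.8, 0.9)) / sqrt(2),
               tolerance = 1e-12)
  expect_equal(out$ci_halfwidth, 0.098, tolerance = 1e-3)

  # identical values across seeds collapse the interval
  same <- seed_ensemble(1:3, function(s) c(acc = 0.7))
  expect_equal(same$ci_halfwidth, 0)
  # single seed: mean only
  expect_true(is.na(seed_ensemble(1L, function(s) c(acc = 0.7))$ci_halfwidth))
})

test_that("graph recovery scores perfect, anti and random rankings", {
  set.seed(5)
  truth <- make_class_graphs(2L, 8L, 0.3, seed = 3L,
                             self_coupling = FALSE)[[1]]$adjacency
  expect_equal(graph_recovery_score(list(truth), truth), 1)
  anti <- max(truth) - truth
  diag(anti) <- 0
  expect_equal(graph_recovery_score(list(anti), truth), 0)
  rand <- replicate(200, matrix(runif(64), 8, 8), simplify = FALSE)
  expect_equal(graph_recovery_score(rand, truth), 0.5, tolerance = 0.05)
  expect_warning(
    expect_true(is.na(graph_recovery_score(list(truth), matrix(1, 8, 8)))),
    "degenerate")
})

test_that("training is reproducible and records its history", {
  td <- make_tiny_data()
  cfg <- iggcn_config(hidden_size = 8L, M = 2L, K = 2L, epoch = 2L,
                      batch_size = 4L, num_node = 6L, n_classes = 2L)
  m1 <- iggcn_train(td$prep, td$prep, cfg, seed = 5L)
  m2 <- iggcn_train(td$prep, td$prep, cfg, seed = 5L)
  expect_identical(m1$history, m2$history)
  expect_identical(unlist(m1$params), unlist(m2$params))
  expect_equal(nrow(m1$history), 2L)
  expect_true(all(is.finite(m1$history$train_loss)))

  ev <- iggcn_evaluate(m1, td$prep)
  expect_true(all(ev$recall >= 0 & ev$recall <= 1))
  expect_equal(rowSums(ev$confusion), rep(1, 2))
  expect_length(ev$auroc, 2L)

  pred <- iggcn_predict(m1, td$prep, keep_graphs = TRUE)
  expect_equal(dim(pred$A_final[[1]]), c(6L, 6L))
  A_exp <- export_graph(m1, td$prep, clip = 1L, role = "learned")
  expect_equal(A_exp, pred$A_final[[1]], tolerance = 1e-12)
})

test_that("inverse-frequency weighting responds to imbalance", {
  td <- make_tiny_data()
  cfg <- iggcn_config(hidden_size = 8L, M = 1L, K = 1L, epoch = 1L,
                      batch_size = 4L, num_node = 6L, n_classes = 2L)
  keep <- c(1:6, 7:8)   # 6 vs 2 clips
  sub <- lapply(td$prep[c("X", "A0", "L0")], function(l) l[keep])
  sub$y <- td$prep$y[keep]
  sub$levels <- td$prep$levels
  m <- iggcn_train(sub, sub, cfg, seed = 1L, class_weighting = "inverse")
  expect_equal(m$alpha[2] / m$alpha[1], 3, tolerance = 1e-12)
  mu <- iggcn_train(sub, sub, cfg, seed = 1L, class_weighting = "uniform")
  expect_equal(mu$alpha, c(1, 1))
})
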