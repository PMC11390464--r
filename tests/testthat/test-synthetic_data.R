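test_that("class graphs honor density, symmetry and distinctness", {
  g <- make_class_graphs(2L, 4L, 1.0, seed = 5L)
  for (gs in g) {
    off <- gs$adjacency[upper.tri(gs$adjacency)]
    expect_true(all(off > 0))  # full density couples every pair
    expect_equal(gs$adjacency, t(gs$adjacency))
    expect_true(all(gs$adjacency >= 0))
  }

  # expected nonzero off-diagonal pair count = round(density * C(6,2))
  g3 <- make_class_graphs(3L, 6L, 0.2, seed = 9L)
  for (gs in g3) {
    expect_equal(sum(gs$adjacency[upper.tri(gs$adjacency)] > 0),
                 round(0.2 * choose(6, 2)))
  }

  # pairwise distinct
  keys <- vapply(g3, function(gs) paste(gs$adjacency, collapse = ","), "")
  expect_equal(length(unique(keys)), 3L)

  # deterministic given seed
  expect_identical(make_class_graphs(2L, 19L, 0.2, seed = 3L),
                   make_class_graphs(2L, 19L, 0.2, seed = 3L))

  expect_error(make_class_graphs(2L, 1L, 0.5, seed = 1L), "n_channels")
  expect_error(class_graph_spec("a", diag(3), 0.1, 1.0), "stationary")
})

test_that("simulated clips are stationary, seeded, and class-coupled", {
  ds <- synthetic_dataset_spec(n_channels = 4L, clip_seconds = 4,
                               sample_rate = 64, noise_sd = 1, seed = 0L)

  # decoupled limit: zero coupling gives near-independent white noise
  free <- class_graph_spec("free", matrix(0, 4, 4), 0, 0)
  clip <- simulate_clip(free, ds, seed = 21L)
  cc <- cor(t(clip$signal))
  expect_lt(mean(abs(cc[upper.tri(cc)])), 0.12)

  # bitwise determinism
  expect_identical(simulate_clip(free, ds, seed = 8L),
                   simulate_clip(free, ds, seed = 8L))

  # coupled pair correlates more strongly than uncoupled pair (50 clips)
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 1] <- 1
  coupled <- class_graph_spec("coupled", A, NA, 0.9)
  d12 <- d34 <- numeric(50)
  for (i in 1:50) {
    s <- simulate_clip(coupled, ds, seed = 100L + i)$signal
    cc <- cor(t(s))
    d12[i] <- abs(cc[1, 2])
    d34[i] <- abs(cc[3, 4])
  }
  expect_gt(mean(d12), mean(d34))

  # bounded variance under accepted specs
  g <- make_class_graphs(2L, 6L, 0.3, seed = 2L)
  ds6 <- synthetic_dataset_spec(n_channels = 6L, clip_seconds = 4,
                                sample_rate = 64, seed = 0L)
  s <- simulate_clip(g[[1L]], ds6, seed = 4L)$signal
  expect_true(all(is.finite(s)))
  expect_lt(max(abs(s)), 50)
})

test_that("generate_dataset returns requested counts and ground truth", {
  g <- make_class_graphs(2L, 5L, 0.4, seed = 7L)
  ds <- synthetic_dataset_spec(n_channels = 5L, clip_seconds = 2,
                               sample_rate = 32,
                               class_counts = c(class1 = 10L, class2 = 10L),
                               seed = 1L)
  out <- generate_dataset(ds, g)
  expect_length(out$clips, 20L)
  expect_equal(as.vector(table(out$labels)), c(10L, 10L))
  expect_named(out$truth, c("class1", "class2"))

  # imbalance is expressible
  ds_im <- synthetic_dataset_spec(n_channels = 5L, clip_seconds = 2,
                                  sample_rate = 32,
                                  class_counts = c(class1 = 100L, class2 = 5L),
                                  seed = 1L)
  expect_equal(sum(generate_dataset(ds_im, g)$labels == "class1"), 100L)

  # degenerate: empty class_counts
  ds0 <- synthetic_dataset_spec(n_channels = 5L, clip_seconds = 2,
                                sample_rate = 32, seed = 1L)
  expect_length(generate_dataset(ds0, g)$clips, 0L)

  # serialized determinism
  a <- serialize(generate_dataset(ds, g), NULL)
  b <- serialize(generate_dataset(ds, g), NULL)
  expect_identical(a, b)
})

test_that("correlation-matrix nearest-centroid separates classes above 80%", {
  # solvability guarantee for the learning task: rho >= 0.8, density <= 0.3
  g <- make_class_graphs(3L, 19L, 0.3, seed = 50L, coupling_strength = 0.8)
  mk <- function(n, s) {
    generate_dataset(synthetic_dataset_spec(
      class_counts = stats::setNames(rep(n, 3), names(g)),
      noise_sd = 1, seed = s), g)
  }
  train <- mk(12L, 1L)
  test <- mk(34L, 2L)   # 102 held-out clips
  cors <- function(d) lapply(d$clips, function(cl) cor(t(cl$signal)))
  ctr <- cors(train)
  cte <- cors(test)
  cent <- lapply(names(g), function(lv) {
    Reduce(`+`, ctr[train$labels == lv]) / sum(train$labels == lv)
  })
  pred <- vapply(cte, function(A) {
    which.min(vapply(cent, function(ct) sum((A - ct)^2), numeric(1)))
  }, integer(1))
  expect_gt(mean(names(g)[pred] == test$labels), 0.8)
})
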