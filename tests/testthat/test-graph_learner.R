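test_that("attention scores match a hand-evaluated 2-node instance", {
  # scalar features: e_ij = aL * (w h_i) + aR * (w h_j)
  p <- list(w = rbind(0.7), aL = rbind(1.3), aR = rbind(-0.4))
  H <- rbind(2, -1)
  e <- attention_scores(H, p, 1L)
  hand <- matrix(NA_real_, 2, 2)
  for (i in 1:2) {
    for (j in 1:2) hand[i, j] <- 1.3 * 0.7 * H[i] + (-0.4) * 0.7 * H[j]
  }
  expect_equal(e, hand, tolerance = 1e-12)

  # zero score map gives all-zero scores
  p0 <- list(w = rbind(c(1, 1)), aL = rbind(c(0, 0)), aR = rbind(c(0, 0)))
  expect_true(all(attention_scores(matrix(runif(6), 3, 2), p0, 1L) == 0))

  # symmetric halves + identical features give symmetric scores
  ps <- list(w = rbind(c(1, 2)), aL = rbind(c(0.5, 0.1)), aR = rbind(c(0.5, 0.1)))
  es <- attention_scores(matrix(runif(8), 4, 2), ps, 1L)
  expect_equal(es, t(es), tolerance = 1e-12)

  expect_error(attention_scores(matrix(0, 2, 3), p, 1L), "parameter error")
})

test_that("softmax normalization is row-stochastic, shifts out, saturates", {
  # worked example: positive scores (1, 2) -> (1/(1+e), e/(1+e))
  a <- normalize_attention(rbind(c(1, 2), c(1, 2)))
  expect_equal(a[1, ], c(1, exp(1)) / (1 + exp(1)), tolerance = 1e-10)
  expect_equal(a[1, ], c(0.2689, 0.7311), tolerance = 1e-4)

  # equal scores over 4 neighbors -> 0.25 each
  expect_equal(normalize_attention(matrix(3, 4, 4))[1, ], rep(0.25, 4))

  # single-neighbor row gets weight 1
  expect_equal(normalize_attention(matrix(0.3, 1, 1))[1, 1], 1)

  # row-stochastic on random inputs (1000 trials)
  set.seed(42)
  for (i in 1:1000) {
    n <- sample(2:8, 1)
    a <- normalize_attention(matrix(rnorm(n * n, sd = 3), n, n))
    expect_true(max(abs(rowSums(a) - 1)) < 1e-8)
    expect_true(all(a > 0 & a <= 1))
  }

  # adding a row constant to post-LReLU scores leaves the result unchanged
  e <- matrix(rnorm(25), 5, 5)
  shifted <- e + c(1, -2, 0.5, 100, -50)
  expect_equal(normalize_attention(shifted, slope = 1),
               normalize_attention(e, slope = 1), tolerance = 1e-10)
})

test_that("head aggregation averages and preserves row sums", {
  a1 <- matrix(0.25, 4, 4)
  a2 <- diag(4)
  agg <- aggregate_heads(list(a1, a2))
  expect_equal(rowSums(agg), rep(1, 4))
  expect_identical(aggregate_heads(list(a2)), a2)

  set.seed(1)
  heads <- lapply(1:8, function(k) {
    m <- matrix(rexp(36), 6, 6)
    m / rowSums(m)
  })
  expect_lt(max(abs(rowSums(aggregate_heads(heads)) - 1)), 1e-8)
})

test_that("attention on all-equal features yields the uniform graph", {
  set.seed(2)
  p <- attention_params(3L, 4L)
  H <- matrix(1, 5, 4) * rep(1, 5)
  heads <- lapply(1:3, function(k) {
    normalize_attention(attention_scores(H, p, k))
  })
  expect_equal(aggregate_heads(heads), matrix(1 / 5, 5, 5), tolerance = 1e-12)
})

test_that("weighted cosine similarity matches direct evaluation", {
  H <- rbind(c(1, 0), c(1, 1))
  expect_equal(cosine_similarity_graph(H, c(1, 1))[1, 2], 1 / sqrt(2),
               tolerance = 1e-12)
  expect_equal(diag(cosine_similarity_graph(H, c(2, 3))), c(1, 1))
  expect_equal(cosine_similarity_graph(rbind(c(1, 0), c(0, 1)), c(1, 1))[1, 2], 0)
  # negatives clipped for adjacency use
  expect_equal(cosine_similarity_graph(rbind(c(1, 0), c(-1, 0)), c(1, 1))[1, 2], 0)
  expect_error(cosine_similarity_graph(rbind(c(0, 0), c(1, 1)), c(1, 1)),
               "similarity undefined")
})

test_that("graph mixing honors its boundary and worked cases", {
  L0 <- matrix(0.5, 2, 2)
  A_m <- diag(2)
  A_1 <- rbind(c(0, 1), c(1, 0))
  expect_equal(mix_graphs(A_m, A_1, L0, lambda = 1, eta = 0.3), L0)
  expect_equal(mix_graphs(A_m, A_1, L0, lambda = 0, eta = 1), diag(2))
  expect_equal(mix_graphs(A_m, A_1, L0, lambda = 0.5, eta = 0.5),
               matrix(0.5, 2, 2))

  # entries bounded by the max entry of the (normalized) inputs
  set.seed(9)
  for (i in 1:25) {
    n <- sample(2:6, 1)
    Am <- matrix(rexp(n * n), n, n)
    A1 <- matrix(rexp(n * n), n, n)
    L <- normalize_adjacency(rand_sym_adj(n))
    lam <- runif(1); eta <- runif(1)
    mx <- mix_graphs(Am, A1, L, lam, eta)
    bound <- max(L, Am / rowSums(Am), A1 / rowSums(A1))
    expect_lte(max(mx), bound + 1e-12)
    expect_true(all(mx >= 0))
  }
})

test_that("convergence test uses the relative Frobenius criterion", {
  A <- rand_sym_adj(3, seed = 1)
  expect_true(graph_converged(A, A, delta = 1e-12))
  expect_false(graph_converged(diag(2), matrix(0, 2, 2), delta = 0.5)) # ratio 1
  expect_false(graph_converged(A, A, delta = 0))  # strict inequality
  expect_error(graph_converged(matrix(0, 2, 2), diag(2), 0.1),
               "convergence-undefined")
})
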