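test_that("scaled scores match hand-computed dot products", {
  Z <- matrix(0, 2, 4)
  expect_equal(scaled_scores(Z, Z, 4), matrix(0, 2, 2))

  Q <- matrix(c(1, 0, 0, 0), 1, 4)
  K <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  expect_equal(as.vector(scaled_scores(Q, K, 4)), c(0.5, 0))

  set.seed(7)
  A <- matrix(rnorm(20), 4, 5); B <- matrix(rnorm(20), 4, 5)
  ref <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) ref[i, j] <- sum(A[i, ] * B[j, ]) / sqrt(20)
  expect_equal(scaled_scores(A, B, 20), ref, tolerance = 1e-9)

  expect_error(scaled_scores(matrix(0, 2, 3), matrix(0, 2, 4), 4),
               class = "pepattn_bad_shape")
})

test_that("attention weights are masked row-stochastic distributions", {
  expect_equal(as.vector(attention_weights(matrix(0, 1, 2), c(1, 1))),
               c(0.5, 0.5))
  expect_equal(as.vector(attention_weights(matrix(c(5, 100), 1), c(1, 0))),
               c(1, 0))
  expect_error(attention_weights(matrix(0, 2, 2), c(0, 0)),
               class = "pepattn_all_masked")
  set.seed(13)
  for (i in 1:10) {
    n <- sample(2:8, 1)
    mask <- c(rep(1, n - 1), sample(0:1, 1))
    w <- attention_weights(matrix(rnorm(n * n, sd = 3), n), mask)
    expect_equal(rowSums(w), rep(1, n), tolerance = 1e-9)
    expect_true(all(w[, mask == 0] == 0))
  }
})

test_that("single head reduces to the value projection for one position", {
  set.seed(3)
  S <- matrix(rnorm(4), 1, 4)
  W <- diag(4)
  expect_equal(single_head(S, W, W, W), S)   # softmax over one key is 1
  Wv <- matrix(rnorm(16), 4, 4)
  expect_equal(single_head(S, W, W, Wv), tcrossprod(S, Wv))
  expect_equal(single_head(matrix(0, 3, 4), W, W, Wv), matrix(0, 3, 4))
})

test_that("multi-head output matches the scalar-loop reference", {
  set.seed(17)
  for (h in c(1L, 2L, 4L)) {
    for (rep in 1:5) {
      n <- sample(2:10, 1)
      params <- attention_params(h = h, d_w = 20L)
      S <- matrix(rnorm(n * 20), n, 20)
      mask <- c(rep(1, max(1, n - 2)), rep(0, min(2, n - 1)))[1:n]
      got <- multi_head_self_attention(S, params, mask)
      ref <- oracle_attention(S, params, mask)
      expect_equal(got$enhanced, ref$enhanced, tolerance = 1e-6)
      for (i in seq_len(h))
        expect_equal(got$weights[[i]], ref$weights[[i]], tolerance = 1e-6)
    }
  }
})

test_that("identity projections with one head reproduce the input", {
  params <- attention_params(h = 1L, d_w = 4L)
  params$Wq[[1]] <- params$Wk[[1]] <- params$Wv[[1]] <- diag(4)
  params$Wm <- diag(4)
  S <- matrix(c(2, -1, 0.5, 3), 1, 4)
  expect_equal(multi_head_self_attention(S, params)$enhanced, S)
})

test_that("attention is permutation-equivariant over valid positions", {
  set.seed(23)
  params <- attention_params(h = 2L, d_w = 20L)
  n <- 7
  S <- matrix(rnorm(n * 20), n, 20)
  perm <- sample(n)
  out1 <- multi_head_self_attention(S, params)$enhanced
  out2 <- multi_head_self_attention(S[perm, ], params)$enhanced
  expect_equal(out2, out1[perm, ], tolerance = 1e-6)
})

test_that("head count must divide the model width", {
  expect_error(attention_params(h = 3L, d_w = 20L),
               class = "pepattn_bad_shape")
  p <- attention_params(h = 2L, d_w = 20L)
  expect_equal(dim(p$Wq[[1]]), c(10L, 20L))
  expect_equal(dim(p$Wm), c(20L, 20L))
})

test_that("head disagreement penalty measures cosine alignment", {
  A <- matrix(rnorm(12), 3, 4)
  expect_equal(head_disagreement_penalty(list(A, A)), 1)
  B1 <- matrix(c(1, 0, 0, 0), 2, 2)
  B2 <- matrix(c(0, 0, 1, 0), 2, 2)
  expect_equal(head_disagreement_penalty(list(B1, B2)), 0)
  expect_equal(head_disagreement_penalty(list(A)), 0)
  expect_equal(head_disagreement_penalty(list(A * 0, A)), 0)

  ## analytic gradient agrees with finite differences
  set.seed(9)
  heads <- list(matrix(rnorm(6), 2), matrix(rnorm(6), 2), matrix(rnorm(6), 2))
  gr <- pepattn:::head_disagreement_grad(heads)
  for (hh in 1:3) for (ii in 1:6) {
    hp <- heads; hp[[hh]][ii] <- hp[[hh]][ii] + 1e-6
    hm <- heads; hm[[hh]][ii] <- hm[[hh]][ii] - 1e-6
    num <- (head_disagreement_penalty(hp) - head_disagreement_penalty(hm)) / 2e-6
    expect_equal(gr[[hh]][ii], num, tolerance = 1e-5)
  }
})

test_that("exported attention tables are row-stochastic per query", {
  ds <- separable_fixture(6, seed = 2)
  b <- batch_encode(ds)
  cfg <- tiny_config()
  m <- build_model(cfg, b$max_len)
  tab <- attention_weight_table(m, b)
  expect_setequal(unique(tab$id), ds$records$id)
  sums <- tapply(tab$weight,
                 interaction(tab$id, tab$head, tab$query_position, drop = TRUE),
                 sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})
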