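test_that("conv branch matches inner products and the naive-loop oracle", {
  X0 <- matrix(0, 6, 20)
  K1 <- array(rnorm(25 * 2), dim = c(5, 5, 2))
  expect_equal(conv_branch(X0, K1), rep(0, 2 * 2 * 16))

  patch <- matrix(c(1, 0, 1, 0, 1, 0, 1, 1, 0), 3, 3)
  ones <- array(1, dim = c(3, 3, 1))
  expect_equal(conv_branch(patch, ones), sum(patch))

  set.seed(41)
  for (i in 1:10) {
    L <- sample(5:12, 1); F <- sample(5:20, 1); k <- sample(3:5, 1)
    nk <- sample(1:4, 1)
    X <- matrix(rnorm(L * F), L, F)
    K <- array(rnorm(k * k * nk), dim = c(k, k, nk))
    expect_equal(conv_branch(X, K), oracle_conv(X, K), tolerance = 1e-5)
  }
  expect_error(conv_branch(matrix(0, 2, 2), ones), class = "pepattn_bad_shape")
})

test_that("lstm_step follows the peephole gate equations", {
  p <- lstm_params(3L, 2L)
  for (nm in c("Wxi", "Whi", "wci", "bi", "Wxf", "Whf", "wcf", "bf",
               "Wxc", "Whc", "bc", "Wxo", "Who", "wco", "bo"))
    p[[nm]] <- p[[nm]] * 0
  st <- lstm_step(c(1, -1, 2), rep(0, 2), rep(0, 2), p)
  expect_equal(st$h, rep(0, 2))    # tanh(0) kills the output
  expect_equal(st$c, rep(0, 2))

  ## saturated forget gate, closed input gate: the cell carries its memory
  p$bf <- rep(60, 2); p$bi <- rep(-60, 2)
  c_prev <- c(0.3, -0.8)
  st2 <- lstm_step(c(1, -1, 2), c(0.1, 0.2), c_prev, p)
  expect_equal(st2$c, c_prev, tolerance = 1e-10)

  set.seed(43)
  for (i in 1:10) {
    p <- lstm_params(4L, 3L)
    p$wci <- rnorm(3); p$wcf <- rnorm(3); p$wco <- rnorm(3)
    x <- rnorm(4); h0 <- rnorm(3); c0 <- rnorm(3)
    got <- lstm_step(x, h0, c0, p)
    ref <- oracle_lstm_step(x, h0, c0, p)
    expect_equal(got$h, ref$h, tolerance = 1e-7)
    expect_equal(got$c, ref$c, tolerance = 1e-7)
  }
})

test_that("lstm_encode scans valid steps only and matches iterated steps", {
  set.seed(47)
  p <- lstm_params(5L, 4L)
  p$wci <- rnorm(4); p$wcf <- rnorm(4); p$wco <- rnorm(4)
  X <- matrix(rnorm(6 * 5), 6, 5)

  ## base case: single timestep
  expect_equal(lstm_encode(X[1, , drop = FALSE], NULL, p),
               lstm_step(X[1, ], rep(0, 4), rep(0, 4), p)$h)

  ## padding appended changes nothing
  Xpad <- rbind(X, matrix(99, 3, 5))
  mask <- c(rep(1, 6), rep(0, 3))
  expect_identical(lstm_encode(Xpad, mask, p), lstm_encode(X, NULL, p))

  ## equals the explicit step loop
  h <- rep(0, 4); cc <- rep(0, 4)
  for (t in 1:6) {
    st <- lstm_step(X[t, ], h, cc, p)
    h <- st$h; cc <- st$c
  }
  expect_equal(lstm_encode(X, NULL, p), h, tolerance = 1e-6)
})

test_that("batched LSTM agrees with the per-sample recurrence", {
  set.seed(53)
  p <- lstm_params(4L, 3L)
  p$wci <- rnorm(3); p$wcf <- rnorm(3); p$wco <- rnorm(3)
  n <- 5; L <- 7
  arr <- array(rnorm(n * L * 4), dim = c(n, L, 4))
  lens <- sample(2:L, n, replace = TRUE)
  mask <- t(vapply(lens, function(l) c(rep(1, l), rep(0, L - l)), numeric(L)))
  out <- pepattn:::lstm_forward_batch(arr, mask, p)$h_final
  for (i in 1:n) {
    Xi <- matrix(arr[i, , ], L)
    expect_equal(out[i, ], lstm_encode(Xi, mask[i, ], p), tolerance = 1e-10)
  }
})

test_that("binary cross-entropy matches its closed form and stays finite", {
  expect_lt(binary_cross_entropy(1, 1), 1e-6)
  expect_equal(binary_cross_entropy(1, 0.5), log(2))
  expect_equal(binary_cross_entropy(0, 0.5), log(2))
  expect_equal(binary_cross_entropy(1, 0), -log(1e-7))
  expect_true(is.finite(binary_cross_entropy(0, 1)))
  expect_equal(binary_cross_entropy(c(1, 0), c(0.8, 0.3)),
               mean(c(-log(0.8), -log(0.7))))
})

test_that("model assembly follows the toggles and prunes parameters", {
  full <- build_model(tiny_config(), 12L)
  expect_equal(sum(full$layout > 0), 5L)   # five concatenated feature blocks

  n_full <- pepattn:::n_params(full$params)
  for (drop in list(list(use_cnn = FALSE), list(use_lstm = FALSE),
                    list(use_attention = FALSE),
                    list(use_structure = FALSE))) {
    m <- build_model(do.call(tiny_config, drop), 12L)
    expect_lt(pepattn:::n_params(m$params), n_full)
  }

  ## LSTM-only baseline
  m0 <- build_model(tiny_config(use_cnn = FALSE, use_attention = FALSE,
                                use_structure = FALSE), 12L)
  expect_equal(names(m0$layout)[m0$layout > 0], "lstm_seq")

  expect_error(model_config(use_cnn = FALSE, use_lstm = FALSE,
                            use_attention = FALSE),
               class = "pepattn_bad_config")
  expect_error(model_config(fusion = "cascade", use_attention = FALSE),
               class = "pepattn_bad_config")

  ## structure absent at build time prunes structure branches
  m1 <- build_model(tiny_config(), 12L, structure_available = FALSE)
  expect_equal(unname(m1$layout[c("conv_struct", "lstm_struct")]), c(0L, 0L))
})

test_that("analytic gradients match finite differences in both fusion modes", {
  ds <- separable_fixture(6, seed = 11)
  b <- batch_encode(ds)
  for (fusion in c("skip", "cascade")) {
    cfg <- model_config(seq_kernels = 3, struct_kernels = 2,
                        seq_lstm_units = 4, struct_lstm_units = 3,
                        dense_hidden = 5, heads = 2, dropout = 0,
                        head_reg_weight = if (fusion == "skip") 0.3 else 0,
                        fusion = fusion, seed = 7)
    m <- build_model(cfg, b$max_len)
    data <- pepattn:::nn_prepare_data(m, b)
    y <- data$labels
    loss_at <- function(flat) {
      m1 <- m
      m1$params <- pepattn:::unflatten_params(m$params, flat)
      fw <- pepattn:::nn_forward(m1, data)
      binary_cross_entropy(y, fw$prob) + cfg$head_reg_weight * fw$penalty
    }
    fw <- pepattn:::nn_forward(m, data)
    grads <- pepattn:::nn_backward(m, data, fw)
    flat <- pepattn:::flatten_params(m$params)
    set.seed(19)
    for (nm in names(grads)) {
      g <- grads[[nm]]
      for (ii in sample(length(g), min(3, length(g)))) {
        f <- lapply(flat, function(x) x + 0)
        f[[nm]][ii] <- f[[nm]][ii] + 1e-5
        lp <- loss_at(f)
        f[[nm]][ii] <- f[[nm]][ii] - 2e-5
        lm <- loss_at(f)
        num <- (lp - lm) / 2e-5
        expect_lt(abs(num - g[ii]) / max(abs(num), abs(g[ii]), 1e-8), 1e-3)
      }
    }
  }
})

test_that("prediction contracts: sigma(0) start, range, per-record independence", {
  ds <- separable_fixture(8, seed = 13)
  b <- batch_encode(ds)
  m <- build_model(tiny_config(), b$max_len)
  m$params$dense$w2 <- m$params$dense$w2 * 0
  m$params$dense$b2 <- 0
  p <- predict_proba(m, b)
  expect_equal(unname(p), rep(0.5, 8))

  m2 <- build_model(tiny_config(seed = 3), b$max_len)
  p2 <- predict_proba(m2, b)
  expect_true(all(p2 > 0 & p2 < 1))

  ## duplicated record scores identically at both positions
  rec <- ds$records[c(1:4, 1), ]
  rec$id[5] <- "dup"
  prof <- ds$profiles[rec$id[1:4]]
  prof$dup <- ds$profiles[[rec$id[1]]]
  bdup <- batch_encode(build_dataset(rec, prof), max_len = b$max_len)
  pd <- predict_proba(m2, bdup)
  expect_equal(unname(pd[5]), unname(pd[1]))
})

test_that("training is deterministic, dropout-free at inference, mask-safe", {
  ds <- separable_fixture(16, seed = 29)
  b <- batch_encode(ds)
  cfg <- tiny_config(dropout = 0.3, max_epochs = 3, val_fraction = 0.2,
                     seed = 11)
  m1 <- train_model(build_model(cfg, 40L), b)
  m2 <- train_model(build_model(cfg, 40L), b)
  expect_identical(pepattn:::flatten_params(m1$params),
                   pepattn:::flatten_params(m2$params))
  expect_identical(m1$history, m2$history)

  p1 <- predict_proba(m1, b)
  expect_identical(p1, predict_proba(m1, b))   # dropout off at inference

  ## batch composition does not change a record's prediction
  psub <- predict_proba(m1, pepattn:::batch_subset(b, 3:5))
  expect_equal(psub, p1[3:5], tolerance = 1e-12)

  ## padding wider than needed (up to the fitted width) changes nothing
  b30 <- batch_encode(ds, max_len = 31)
  expect_equal(predict_proba(m1, b30), p1, tolerance = 1e-12)

  ## and garbage hidden behind the mask never leaks through LSTM/attention
  p <- m1$params$lstm_seq
  Xi <- matrix(rnorm(40 * 20), 40, 20)
  mask <- c(rep(1, 12), rep(0, 28))
  Xg <- Xi; Xg[13:40, ] <- 77
  expect_identical(lstm_encode(Xi, mask, p), lstm_encode(Xg, mask, p))
  ao1 <- multi_head_self_attention(Xi, m1$params$attn, mask)$enhanced
  ao2 <- multi_head_self_attention(Xg, m1$params$attn, mask)$enhanced
  expect_equal(ao1[1:12, ], ao2[1:12, ], tolerance = 1e-12)
})

test_that("early stopping halts after patience is exhausted", {
  ds <- separable_fixture(12, seed = 5)
  b <- batch_encode(ds)
  ## zero learning rate: the monitored loss can never improve after epoch 1
  cfg <- tiny_config(lr = 0, max_epochs = 10, seed = 2)
  cfg$patience <- 0L
  m <- train_model(build_model(cfg, b$max_len), b)
  expect_equal(nrow(m$history), 2L)
})

test_that("training loss decreases on the separable fixture", {
  ds <- separable_fixture(16, seed = 7)
  b <- batch_encode(ds)
  cfg <- tiny_config(max_epochs = 12, seed = 4, dropout = 0)
  m <- train_model(build_model(cfg, b$max_len), b)
  h <- m$history$train_loss
  expect_lt(h[length(h)], h[1])
})

test_that("checkpoints round-trip through disk", {
  ds <- separable_fixture(8, seed = 3)
  b <- batch_encode(ds)
  cfg <- tiny_config(max_epochs = 2, seed = 9)
  m <- train_model(build_model(cfg, b$max_len), b)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  expect_true(file.exists(paste0(f, ".config.txt")))
  m2 <- load_checkpoint(f)
  expect_identical(predict_proba(m2, b), predict_proba(m, b))
  cfgtxt <- read_config_file(paste0(f, ".config.txt"))
  expect_equal(cfgtxt$seq_kernels, 4)
  expect_equal(cfgtxt$fusion, "skip")
})
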