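#' Model and training configuration
#'
#' Collects every architecture and optimisation hyperparameter. Defaults
#' are the reference configuration of the classifier: 300 sequence-branch
#' and 150 structure-branch convolution kernels of sizes 5x5 and 3x3, 45
#' and 20 LSTM memory units, 2 attention heads over the 20-wide one-hot
#' representation, dropout 0.45 after the hidden dense layer, Adam with
#' learning rate 1e-3, and early stopping on validation loss with
#' patience 10.
#'
#' The toggles prune branches for ablation studies: `use_cnn`,
#' `use_lstm`, `use_attention`, `use_structure`, and `fusion` which is
#' either `"skip"` (the attention-enhanced representation feeds the dense
#' head directly) or `"cascade"` (it replaces the raw one-hot input of
#' the sequence CNN/LSTM branches).
#'
#' @param seq_kernels,struct_kernels Kernel counts of the two conv branches.
#' @param seq_kernel_size,struct_kernel_size Square kernel sizes.
#' @param seq_lstm_units,struct_lstm_units LSTM memory units per branch.
#' @param heads Attention head count (must divide 20).
#' @param head_reg_weight Weight of the head-disagreement penalty
#'   (0 = off).
#' @param dropout Dropout rate in `[0, 1)` applied after the hidden dense
#'   layer during training only.
#' @param dense_hidden Width of the hidden dense layer.
#' @param lr,beta1,beta2,epsilon Adam hyperparameters.
#' @param max_epochs,batch_size Optimisation budget.
#' @param patience Early-stopping patience (epochs without improvement of
#'   the monitored loss).
#' @param val_fraction Stratified fraction of the training data held out
#'   for early-stopping validation (0 = monitor training loss).
#' @param target_train_acc Optional training-accuracy level at which
#'   training stops early (used by overfitting smoke tests).
#' @param seed Integer seed controlling initialisation, shuffling and
#'   dropout; fixed seed gives bit-reproducible training.
#' @param use_cnn,use_lstm,use_attention,use_structure,fusion Branch
#'   toggles (see Details).
#' @param peephole Use trained peephole connections in the LSTM cells.
#' @return Object of class `model_config`.
#' @export
model_config <- function(seq_kernels = 300L, seq_kernel_size = 5L,
                         struct_kernels = 150L, struct_kernel_size = 3L,
                         seq_lstm_units = 45L, struct_lstm_units = 20L,
                         heads = 2L, head_reg_weight = 0,
                         dropout = 0.45, dense_hidden = 64L,
                         lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-8,
                         max_epochs = 100L, batch_size = 32L,
                         patience = 10L, val_fraction = 0.1,
                         target_train_acc = NULL,
                         seed = 1L,
                         use_cnn = TRUE, use_lstm = TRUE,
                         use_attention = TRUE, use_structure = TRUE,
                         fusion = c("skip", "cascade"),
                         peephole = TRUE) {
  fusion <- match.arg(fusion)
  cfg <- list(seq_kernels = as.integer(seq_kernels),
              seq_kernel_size = as.integer(seq_kernel_size),
              struct_kernels = as.integer(struct_kernels),
              struct_kernel_size = as.integer(struct_kernel_size),
              seq_lstm_units = as.integer(seq_lstm_units),
              struct_lstm_units = as.integer(struct_lstm_units),
              heads = as.integer(heads), head_reg_weight = head_reg_weight,
              dropout = dropout, dense_hidden = as.integer(dense_hidden),
              lr = lr, beta1 = beta1, beta2 = beta2, epsilon = epsilon,
              max_epochs = as.integer(max_epochs),
              batch_size = as.integer(batch_size),
              patience = as.integer(patience), val_fraction = val_fraction,
              target_train_acc = target_train_acc,
              seed = as.integer(seed),
              use_cnn = isTRUE(use_cnn), use_lstm = isTRUE(use_lstm),
              use_attention = isTRUE(use_attention),
              use_structure = isTRUE(use_structure),
              fusion = fusion, peephole = isTRUE(peephole), d_w = 20L)
  counts <- c(cfg$seq_kernels, cfg$struct_kernels, cfg$seq_lstm_units,
              cfg$struct_lstm_units, cfg$heads, cfg$dense_hidden,
              cfg$max_epochs, cfg$batch_size)
  if (any(counts < 1L))
    pep_stop("all counts must be positive", "pepattn_bad_config")
  if (cfg$dropout < 0 || cfg$dropout >= 1)
    pep_stop("dropout must lie in [0, 1)", "pepattn_bad_config")
  if (!cfg$use_cnn && !cfg$use_lstm && !cfg$use_attention)
    pep_stop("all branches toggled off", "pepattn_bad_config")
  if (cfg$fusion == "cascade" &&
      (!cfg$use_attention || (!cfg$use_cnn && !cfg$use_lstm)))
    pep_stop("cascade fusion needs attention plus at least one of CNN/LSTM",
             "pepattn_bad_config")
  if (cfg$d_w %% cfg$heads != 0L)
    pep_stop("heads must divide the one-hot width (20)", "pepattn_bad_config")
  structure(cfg, class = "model_config")
}

## widths of the concatenated feature blocks for a given max_len
feature_layout <- function(config, max_len, structure) {
  L <- max_len
  ks <- config$seq_kernel_size; kt <- config$struct_kernel_size
  w <- c(conv_seq = 0L, conv_struct = 0L, lstm_seq = 0L, lstm_struct = 0L,
         attn = 0L)
  if (config$use_cnn) {
    if (L < ks) pep_stop("max_len smaller than the sequence kernel",
                         "pepattn_bad_shape")
    w["conv_seq"] <- config$seq_kernels * (L - ks + 1L) * (20L - ks + 1L)
    if (structure && config$use_structure) {
      if (kt > 3L) pep_stop("structure kernel larger than the 3-state plane",
                            "pepattn_bad_shape")
      w["conv_struct"] <- config$struct_kernels * (L - kt + 1L) * (3L - kt + 1L)
    }
  }
  if (config$use_lstm) {
    w["lstm_seq"] <- config$seq_lstm_units
    if (structure && config$use_structure)
      w["lstm_struct"] <- config$struct_lstm_units
  }
  if (config$use_attention && config$fusion == "skip")
    w["attn"] <- L * 20L
  w
}

#' Assemble an untrained classification model
#'
#' Builds the parameter set of the network for a fixed padded length:
#' parallel CNN and peephole-LSTM branches over the one-hot sequence plane
#' and (optionally) the secondary-structure plane, a multi-head
#' self-attention encoder fused by skip connection (or cascaded into the
#' sequence branches), and a dense ReLU hidden layer followed by a single
#' sigmoid output unit. Initialisation is Glorot-uniform, seeded from
#' `config$seed`.
#'
#' @param config A [model_config()].
#' @param max_len Padded sequence length the model is built for.
#' @param structure_available Are structure profiles present? When
#'   `FALSE`, structure branches are pruned regardless of
#'   `config$use_structure`.
#' @return Object of class `pep_model` (untrained).
#' @export
build_model <- function(config, max_len, structure_available = TRUE) {
  max_len <- as.integer(max_len)
  structure <- structure_available && config$use_structure
  layout <- feature_layout(config, max_len, structure)
  D <- sum(layout)
  if (D == 0L) pep_stop("all branches toggled off", "pepattn_bad_config")
  set.seed(config$seed)
  params <- list()
  if (config$use_attention)
    params$attn <- attention_params(config$heads, config$d_w,
                                    config$head_reg_weight)
  if (config$use_cnn) {
    ks <- config$seq_kernel_size
    params$conv_seq <- list(K = glorot(ks * ks, config$seq_kernels,
                                       fan_in = ks * ks,
                                       fan_out = config$seq_kernels))
    if (structure) {
      kt <- config$struct_kernel_size
      params$conv_struct <- list(K = glorot(kt * kt, config$struct_kernels,
                                            fan_in = kt * kt,
                                            fan_out = config$struct_kernels))
    }
  }
  if (config$use_lstm) {
    params$lstm_seq <- lstm_params(20L, config$seq_lstm_units,
                                   peephole = config$peephole)
    if (structure)
      params$lstm_struct <- lstm_params(3L, config$struct_lstm_units,
                                        peephole = config$peephole)
  }
  params$dense <- list(W1 = glorot(D, config$dense_hidden, fan_in = D,
                                   fan_out = config$dense_hidden),
                       b1 = rep(0, config$dense_hidden),
                       w2 = glorot(config$dense_hidden, 1L,
                                   fan_in = config$dense_hidden, fan_out = 1L),
                       b2 = 0)
  structure(list(config = config, params = params, max_len = max_len,
                 structure = structure, layout = layout,
                 trained = FALSE, history = NULL),
            class = "pep_model")
}

#' @export
print.pep_model <- function(x, ...) {
  cat(sprintf("<pep_model> max_len %d, %s, %d parameters, %s\n",
              x$max_len,
              paste(names(x$layout)[x$layout > 0], collapse = "+"),
              n_params(x$params),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Binary cross-entropy loss
#'
#' `-((1 - t) log(1 - p) + t log(p))`, with predictions clipped to
#' `[eps, 1 - eps]` so the loss stays finite; for vector inputs the mean
#' over elements is returned (the batch loss).
#'
#' @param t Labels in `{0, 1}`.
#' @param p Predicted probabilities.
#' @param eps Clipping constant.
#' @return Nonnegative scalar.
#' @export
binary_cross_entropy <- function(t, p, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  mean(-((1 - t) * log(1 - p) + t * log(p)))
}

## ---- internal forward / backward over prepared data ----

## precompute everything about a batch that does not depend on parameters
nn_prepare_data <- function(model, batch) {
  cfg <- model$config
  if (batch$max_len < model$max_len) batch <- batch_repad(batch, model$max_len)
  if (batch$max_len != model$max_len)
    pep_stop(sprintf("batch max_len %d exceeds the fitted max_len %d",
                     batch$max_len, model$max_len),
             "pepattn_maxlen_mismatch")
  if (model$structure && !batch$has_structure)
    pep_stop("model uses structure branches but the batch has no profiles",
             "pepattn_partial_structure")
  data <- list(seq = batch$seq, struct = batch$struct, mask = batch$mask,
               labels = batch$labels, n = length(batch$labels))
  if (cfg$use_cnn && cfg$fusion == "skip")
    data$ic_seq <- batch_im2col(batch$seq, cfg$seq_kernel_size, sparse = TRUE)
  if (cfg$use_cnn && model$structure)
    data$ic_struct <- batch_im2col(batch$struct, cfg$struct_kernel_size)
  data
}

## forward pass for the samples `idx`; drop_mask: NULL or n x dense_hidden
## matrix of 0 / 1/(1-p) inverted-dropout factors
nn_forward <- function(model, data, idx = seq_len(data$n), drop_mask = NULL,
                       keep_cache = TRUE) {
  cfg <- model$config
  pr <- model$params
  n <- length(idx)
  L <- model$max_len
  mask_sub <- data$mask[idx, , drop = FALSE]
  cache <- list(idx = idx)
  blocks <- list()

  attn_caches <- NULL
  Sprime_arr <- NULL
  if (cfg$use_attention) {
    attn_caches <- vector("list", n)
    if (cfg$fusion == "cascade") Sprime_arr <- array(0, dim = c(n, L, 20))
    Zf <- if (cfg$fusion == "skip") matrix(0, n, L * 20L) else NULL
    for (j in seq_len(n)) {
      S <- matrix(data$seq[idx[j], , ], L)
      fwj <- attn_forward(S, mask_sub[j, ], pr$attn)
      attn_caches[[j]] <- fwj
      if (cfg$fusion == "skip") Zf[j, ] <- as.vector(fwj$Sprime)
      else Sprime_arr[j, , ] <- fwj$Sprime
    }
  }

  seq_input <- if (cfg$fusion == "cascade") Sprime_arr else NULL

  if (cfg$use_cnn) {
    ks <- cfg$seq_kernel_size
    if (cfg$fusion == "skip") {
      rows <- im2col_rows(data$ic_seq, idx)
      Pm <- data$ic_seq$P[rows, , drop = FALSE]
      npos <- data$ic_seq$npos
      Hout <- data$ic_seq$Hout; Wout <- data$ic_seq$Wout
    } else {
      icl <- batch_im2col(seq_input, ks)
      Pm <- icl$P; npos <- icl$npos; Hout <- icl$Hout; Wout <- icl$Wout
    }
    act <- relu_inplace(as.matrix(Pm %*% pr$conv_seq$K))
    dim(act) <- c(n, npos * ncol(pr$conv_seq$K))
    blocks$conv_seq <- act
    if (keep_cache)
      cache$conv_seq <- list(P = Pm, act = act, npos = npos,
                             Hout = Hout, Wout = Wout)
    if (model$structure) {
      rows <- im2col_rows(data$ic_struct, idx)
      Pt <- data$ic_struct$P[rows, , drop = FALSE]
      act_t <- relu_inplace(Pt %*% pr$conv_struct$K)
      dim(act_t) <- c(n, data$ic_struct$npos * ncol(pr$conv_struct$K))
      blocks$conv_struct <- act_t
      if (keep_cache)
        cache$conv_struct <- list(P = Pt, act = act_t,
                                  npos = data$ic_struct$npos)
    }
  }
  if (cfg$use_lstm) {
    Xs <- if (cfg$fusion == "cascade") seq_input
          else data$seq[idx, , , drop = FALSE]
    lf <- lstm_forward_batch(Xs, mask_sub, pr$lstm_seq)
    blocks$lstm_seq <- lf$h_final
    if (keep_cache) cache$lstm_seq <- lf
    if (model$structure) {
      lft <- lstm_forward_batch(data$struct[idx, , , drop = FALSE], mask_sub,
                                pr$lstm_struct)
      blocks$lstm_struct <- lft$h_final
      if (keep_cache) cache$lstm_struct <- lft
    }
  }
  if (cfg$use_attention && cfg$fusion == "skip") blocks$attn <- Zf

  Z <- do.call(cbind, blocks[names(model$layout)[model$layout > 0]])
  H1 <- relu_inplace(sweep(Z %*% pr$dense$W1, 2L, pr$dense$b1, `+`))
  H1d <- if (is.null(drop_mask)) H1 else H1 * drop_mask
  logit <- drop(H1d %*% pr$dense$w2) + pr$dense$b2
  prob <- sigmoid(logit)

  penalty <- 0
  if (cfg$use_attention && cfg$head_reg_weight > 0 && cfg$heads > 1L)
    penalty <- mean(vapply(attn_caches,
                           function(cj) head_disagreement_penalty(cj$heads),
                           numeric(1)))
  if (keep_cache) {
    cache$attn <- attn_caches
    cache$mask_sub <- mask_sub
    cache$Z <- Z; cache$H1 <- H1; cache$H1d <- H1d
    cache$drop_mask <- drop_mask
  }
  list(prob = prob, penalty = penalty, cache = if (keep_cache) cache else NULL)
}

## backward pass; returns gradients as a flat named list aligned with
## flatten_params(model$params)
nn_backward <- function(model, data, fw) {
  cfg <- model$config
  pr <- model$params
  ca <- fw$cache
  idx <- ca$idx
  n <- length(idx)
  L <- model$max_len
  y <- data$labels[idx]

  dlogit <- (fw$prob - y) / n
  dw2 <- crossprod(ca$H1d, dlogit)
  db2 <- sum(dlogit)
  dH1d <- matrix(dlogit, ncol = 1L) %*% t(pr$dense$w2)
  if (!is.null(ca$drop_mask)) dH1d <- dH1d * ca$drop_mask
  dPre1 <- dH1d * (ca$H1 > 0)
  dW1 <- crossprod(ca$Z, dPre1)
  db1 <- colSums(dPre1)
  dZ <- tcrossprod(dPre1, pr$dense$W1)

  grads <- list(dense = list(W1 = dW1, b1 = db1, w2 = dw2, b2 = db2))

  ## split dZ into the live blocks, in layout order
  off <- 0L
  take <- function(w) {
    m <- dZ[, (off + 1L):(off + w), drop = FALSE]
    off <<- off + w
    m
  }
  dSprime_arr <- if (cfg$use_attention && cfg$fusion == "cascade")
    array(0, dim = c(n, L, 20)) else NULL
  attn_flat_grad <- NULL

  for (blk in names(model$layout)) {
    w <- model$layout[[blk]]
    if (w == 0L) next
    dB <- take(w)
    if (blk == "conv_seq") {
      cc <- ca$conv_seq
      dim(dB) <- c(n * cc$npos, ncol(pr$conv_seq$K))
      relu_backward_inplace(dB, cc$act)
      grads$conv_seq <- list(K = as.matrix(crossprod(cc$P, dB)))
      if (cfg$fusion == "cascade") {
        dP <- dB %*% t(pr$conv_seq$K)
        dSprime_arr <- dSprime_arr +
          col2im_add(dP, n, cc$Hout, cc$Wout, L, 20L, cfg$seq_kernel_size)
      }
    } else if (blk == "conv_struct") {
      cc <- ca$conv_struct
      dim(dB) <- c(n * cc$npos, ncol(pr$conv_struct$K))
      relu_backward_inplace(dB, cc$act)
      grads$conv_struct <- list(K = as.matrix(crossprod(cc$P, dB)))
    } else if (blk == "lstm_seq") {
      bw <- lstm_backward_batch(ca$lstm_seq, dB, pr$lstm_seq,
                                need_input_grad = cfg$fusion == "cascade")
      grads$lstm_seq <- bw$grads
      if (cfg$fusion == "cascade") dSprime_arr <- dSprime_arr + bw$dX
    } else if (blk == "lstm_struct") {
      bw <- lstm_backward_batch(ca$lstm_struct, dB, pr$lstm_struct)
      grads$lstm_struct <- bw$grads
    } else if (blk == "attn") {
      ## handled below sample-by-sample (needs reshape per row)
      attn_flat_grad <- dB
    }
  }

  if (cfg$use_attention) {
    h <- cfg$heads
    hn <- paste0("h", seq_len(h))
    zero <- function() stats::setNames(
      lapply(seq_len(h), function(i) matrix(0, cfg$d_w %/% h, cfg$d_w)), hn)
    ag <- list(Wq = zero(), Wk = zero(), Wv = zero(),
               Wm = matrix(0, cfg$d_w, cfg$d_w))
    use_reg <- cfg$head_reg_weight > 0 && h > 1L
    for (j in seq_len(n)) {
      dSp <- if (cfg$fusion == "skip")
        matrix(attn_flat_grad[j, ], L, 20L)
      else matrix(dSprime_arr[j, , ], L)
      extra <- NULL
      if (use_reg) {
        pg <- head_disagreement_grad(ca$attn[[j]]$heads)
        extra <- lapply(pg, function(g) g * (cfg$head_reg_weight / n))
      }
      bj <- attn_backward(ca$attn[[j]], dSp, pr$attn, dheads_extra = extra)
      for (i in seq_len(h)) {
        ag$Wq[[i]] <- ag$Wq[[i]] + bj$Wq[[i]]
        ag$Wk[[i]] <- ag$Wk[[i]] + bj$Wk[[i]]
        ag$Wv[[i]] <- ag$Wv[[i]] + bj$Wv[[i]]
      }
      ag$Wm <- ag$Wm + bj$Wm
    }
    grads$attn <- ag
  }
  flatten_params(grads)
}

## ---- Adam ----

adam_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0),
       t = 0L)
}

## stratified split of indices into train/validation parts
stratified_val_split <- function(labels, fraction) {
  if (fraction <= 0) return(list(train = seq_along(labels), val = integer()))
  val <- integer()
  for (cl in unique(labels)) {
    ids <- which(labels == cl)
    k <- floor(length(ids) * fraction)
    if (k >= 1L && length(ids) - k >= 1L)
      val <- c(val, sample(ids, k))
  }
  list(train = setdiff(seq_along(labels), val), val = sort(val))
}

#' Train a model on an encoded batch
#'
#' Minimises the mean binary cross-entropy (plus the optional
#' head-disagreement penalty) with Adam over shuffled minibatches.
#' A stratified fraction of the batch is held out to monitor validation
#' loss for early stopping; the weights from the best monitored epoch are
#' restored. Fully seeded: the same seed gives bit-identical weights and
#' history.
#'
#' @param model An untrained (or trained) `pep_model`.
#' @param batch A `pep_batch` with labels, encoded at the model's
#'   `max_len` (smaller batches are re-padded).
#' @param verbose Print per-epoch progress?
#' @return The trained `pep_model`, with `history` (one row per epoch:
#'   `epoch`, `train_loss`, `val_loss`, `train_acc`, `val_acc`) attached.
#' @export
train_model <- function(model, batch, verbose = FALSE) {
  cfg <- model$config
  if (anyNA(batch$labels))
    pep_stop("training requires labels for every record", "pepattn_unlabeled")
  set.seed(cfg$seed)
  split <- stratified_val_split(batch$labels, cfg$val_fraction)
  has_val <- length(split$val) > 0L
  if (batch$max_len < model$max_len) batch <- batch_repad(batch, model$max_len)
  data_tr <- nn_prepare_data(model, batch_subset(batch, split$train))
  data_va <- if (has_val) nn_prepare_data(model, batch_subset(batch, split$val))
  n_tr <- data_tr$n
  y_tr <- data_tr$labels

  ## deep-copy the parameters, then keep the flat list and the nested
  ## view aliased so the in-place Adam step updates both at once
  flat <- lapply(flatten_params(model$params), function(x) x + 0)
  model$params <- unflatten_params(model$params, flat)
  if (!cfg$peephole)   # peephole vectors frozen at zero
    flat <- flat[!grepl("\\.(wci|wcf|wco)$", names(flat))]
  st <- adam_init(flat)

  best_loss <- Inf
  best_flat <- lapply(flat, function(x) x + 0)
  wait <- 0L
  hist <- list()
  keep_p <- 1 - cfg$dropout

  for (epoch in seq_len(cfg$max_epochs)) {
    perm <- sample(n_tr)
    mbs <- split(perm, ceiling(seq_along(perm) / cfg$batch_size))
    tr_loss_sum <- 0; tr_correct <- 0
    for (mb in mbs) {
      drop_mask <- NULL
      if (cfg$dropout > 0)
        drop_mask <- matrix((stats::runif(length(mb) * cfg$dense_hidden) <
                               keep_p) / keep_p,
                            length(mb), cfg$dense_hidden)
      fw <- nn_forward(model, data_tr, mb, drop_mask = drop_mask)
      loss <- binary_cross_entropy(y_tr[mb], fw$prob) +
        cfg$head_reg_weight * fw$penalty
      if (!is.finite(loss))
        pep_stop(sprintf("training loss diverged (non-finite) at epoch %d", epoch),
                 "pepattn_divergence")
      grads <- nn_backward(model, data_tr, fw)
      st$t <- st$t + 1L
      adam_step_inplace(flat, grads[names(flat)], st$m, st$v,
                        cfg$lr, cfg$beta1, cfg$beta2, cfg$epsilon, st$t)
      tr_loss_sum <- tr_loss_sum + loss * length(mb)
      tr_correct <- tr_correct + sum((fw$prob >= 0.5) == (y_tr[mb] == 1L))
    }
    train_loss <- tr_loss_sum / n_tr
    train_acc <- tr_correct / n_tr
    val_loss <- NA_real_; val_acc <- NA_real_
    if (has_val) {
      pv <- predict_chunked(model, data_va)
      val_loss <- binary_cross_entropy(data_va$labels, pv)
      val_acc <- mean((pv >= 0.5) == (data_va$labels == 1L))
    }
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss,
                                val_loss = val_loss, train_acc = train_acc,
                                val_acc = val_acc)
    if (verbose)
      message(sprintf("epoch %3d  train_loss %.4f acc %.3f  val_loss %s",
                      epoch, train_loss, train_acc,
                      ifelse(has_val, sprintf("%.4f", val_loss), "-")))
    monitored <- if (has_val) val_loss else train_loss
    if (monitored < best_loss - 1e-8) {
      best_loss <- monitored
      best_flat <- lapply(flat, function(x) x + 0)   # snapshot copy
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait > cfg$patience) break
    }
    if (!is.null(cfg$target_train_acc) &&
        train_acc >= cfg$target_train_acc) {
      best_flat <- lapply(flat, function(x) x + 0)
      break
    }
  }
  model$params <- unflatten_params(model$params, best_flat)
  model$history <- do.call(rbind, hist)
  model$trained <- TRUE
  model
}

## forward over prepared data in memory-bounded chunks, dropout off
predict_chunked <- function(model, data, chunk = 64L) {
  n <- data$n
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    out[idx] <- nn_forward(model, data, idx, drop_mask = NULL,
                           keep_cache = FALSE)$prob
  }
  out
}

#' Predict class probabilities
#'
#' Runs the trained network on an encoded batch with dropout disabled;
#' two calls on the same input return identical results. Batches encoded
#' at a smaller padded length than the model's `max_len` are zero-padded
#' up; batches wider than the model error out.
#'
#' @param model A trained `pep_model`.
#' @param batch A `pep_batch`.
#' @return Named numeric vector of probabilities in `(0, 1)`, one per
#'   record; values `>= 0.5` are conventionally called positive.
#' @export
predict_proba <- function(model, batch) {
  data <- nn_prepare_data(model, batch)
  stats::setNames(predict_chunked(model, data), batch$ids)
}

#' @export
predict.pep_model <- function(object, batch, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  p <- predict_proba(object, batch)
  if (type == "class") return(as.integer(p >= 0.5))
  p
}
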