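## Independent scalar-loop oracles. These deliberately avoid the package's
## vectorised code paths: everything is written as plain elementwise loops
## over the defining formulas, so agreement is evidence of correctness.

## multi-head self-attention by scalar loops
oracle_attention <- function(S, params, mask = NULL) {
  n <- nrow(S); dw <- ncol(S)
  if (is.null(mask)) mask <- rep(1, n)
  h <- params$h; dh <- dw %/% h
  heads <- vector("list", h)
  weights <- vector("list", h)
  for (hh in seq_len(h)) {
    Wq <- params$Wq[[hh]]; Wk <- params$Wk[[hh]]; Wv <- params$Wv[[hh]]
    Q <- matrix(0, n, dh); K <- matrix(0, n, dh); V <- matrix(0, n, dh)
    for (i in 1:n) for (j in 1:dh) {
      for (k in 1:dw) {
        Q[i, j] <- Q[i, j] + S[i, k] * Wq[j, k]
        K[i, j] <- K[i, j] + S[i, k] * Wk[j, k]
        V[i, j] <- V[i, j] + S[i, k] * Wv[j, k]
      }
    }
    sc <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      for (k in 1:dh) sc[i, j] <- sc[i, j] + Q[i, k] * K[j, k]
      sc[i, j] <- sc[i, j] / sqrt(dw)
    }
    A <- matrix(0, n, n)
    for (i in 1:n) {
      if (mask[i] > 0) {
        mx <- max(sc[i, mask > 0])
        den <- 0
        for (j in 1:n) if (mask[j] > 0) den <- den + exp(sc[i, j] - mx)
        for (j in 1:n) if (mask[j] > 0) A[i, j] <- exp(sc[i, j] - mx) / den
      } else {
        for (j in 1:n) if (mask[j] > 0) A[i, j] <- 1 / sum(mask > 0)
      }
    }
    hd <- matrix(0, n, dh)
    for (i in 1:n) for (j in 1:dh)
      for (k in 1:n) hd[i, j] <- hd[i, j] + A[i, k] * V[k, j]
    heads[[hh]] <- hd
    weights[[hh]] <- A
  }
  H <- do.call(cbind, heads)
  Sp <- matrix(0, n, dw)
  for (i in 1:n) for (j in 1:dw)
    for (k in 1:dw) Sp[i, j] <- Sp[i, j] + params$Wm[j, k] * H[i, k]
  for (i in 1:n) if (mask[i] == 0) Sp[i, ] <- 0
  list(enhanced = Sp, weights = weights)
}

## one peephole LSTM step by scalar loops
oracle_lstm_step <- function(x, h, c, p) {
  U <- p$units
  sig <- function(z) 1 / (1 + exp(-z))
  hi <- numeric(U); ci <- numeric(U)
  for (u in 1:U) {
    ai <- sum(p$Wxi[u, ] * x) + sum(p$Whi[u, ] * h) + p$wci[u] * c[u] + p$bi[u]
    af <- sum(p$Wxf[u, ] * x) + sum(p$Whf[u, ] * h) + p$wcf[u] * c[u] + p$bf[u]
    ag <- sum(p$Wxc[u, ] * x) + sum(p$Whc[u, ] * h) + p$bc[u]
    ci[u] <- sig(af) * c[u] + sig(ai) * tanh(ag)
    ao <- sum(p$Wxo[u, ] * x) + sum(p$Who[u, ] * h) + p$wco[u] * ci[u] + p$bo[u]
    hi[u] <- sig(ao) * tanh(ci[u])
  }
  list(h = hi, c = ci)
}

## valid 2-D convolution + ReLU + flatten by quadruple loops
oracle_conv <- function(X, kernels) {
  if (is.list(kernels))
    kernels <- array(unlist(kernels),
                     dim = c(nrow(kernels[[1]]), ncol(kernels[[1]]),
                             length(kernels)))
  k <- dim(kernels)[1]; nk <- dim(kernels)[3]
  Hout <- nrow(X) - k + 1; Wout <- ncol(X) - k + 1
  out <- numeric(0)
  for (kk in 1:nk) {
    O <- matrix(0, Hout, Wout)
    for (p in 1:Hout) for (q in 1:Wout) {
      s <- 0
      for (a in 1:k) for (b in 1:k)
        s <- s + kernels[a, b, kk] * X[p + a - 1, q + b - 1]
      O[p, q] <- max(s, 0)
    }
    out <- c(out, as.vector(O))
  }
  out
}

## AUC as the tie-corrected Mann-Whitney rank statistic
oracle_auc_rank <- function(labels, scores) {
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  r <- rank(scores)   # mean ranks for ties
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

## metrics recomputed from expanded label/prediction vectors; MCC doubles
## as the Pearson correlation of the two binary vectors
oracle_metrics <- function(TP, TN, FP, FN) {
  y <- c(rep(1, TP), rep(0, TN), rep(0, FP), rep(1, FN))
  p <- c(rep(1, TP), rep(0, TN), rep(1, FP), rep(0, FN))
  sdiv <- function(a, b) if (b == 0) 0 else a / b
  mcc <- suppressWarnings(stats::cor(y, p))
  list(acc = mean(y == p),
       sens = sdiv(sum(y == 1 & p == 1), sum(y == 1)),
       spec = sdiv(sum(y == 0 & p == 0), sum(y == 0)),
       prec = sdiv(sum(y == 1 & p == 1), sum(p == 1)),
       mcc = if (is.na(mcc)) 0 else mcc)
}

## random attention parameter set (from the current RNG stream)
random_attn_params <- function(h, d_w = 20L) {
  p <- attention_params(h = h, d_w = d_w)
  p
}

## small model config used across network tests; overrides win
tiny_config <- function(...) {
  defaults <- list(seq_kernels = 4L, struct_kernels = 3L, seq_lstm_units = 5L,
                   struct_lstm_units = 4L, dense_hidden = 6L, heads = 2L,
                   dropout = 0, val_fraction = 0, max_epochs = 3L,
                   batch_size = 8L, seed = 1L)
  do.call(model_config, utils::modifyList(defaults, list(...)))
}
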