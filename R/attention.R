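#' Initialise multi-head self-attention parameters
#'
#' Each of the `h` heads carries its own query/key/value projection of
#' shape `(d_w/h) x d_w`; a `d_w x d_w` output matrix mixes the
#' concatenated heads back to the model width. Initialisation is
#' Glorot-uniform from the current RNG stream, so each head starts from
#' different parameters.
#'
#' @param h Number of heads; must divide `d_w`. Default 2, the head count
#'   with the best accuracy/cost trade-off for this architecture.
#' @param d_w Model width; 20 for raw one-hot peptide input.
#' @param head_reg_weight Weight of the head-disagreement penalty added to
#'   the training loss (0 disables it).
#' @return Object of class `attention_params`.
#' @export
attention_params <- function(h = 2L, d_w = 20L, head_reg_weight = 0) {
  h <- as.integer(h); d_w <- as.integer(d_w)
  if (h < 1L || d_w %% h != 0L)
    pep_stop(sprintf("d_w (%d) must be divisible by the number of heads (%d)",
                     d_w, h),
             "pepattn_bad_shape")
  if (head_reg_weight < 0)
    pep_stop("head_reg_weight must be nonnegative", "pepattn_bad_config")
  dh <- d_w %/% h
  mk <- function() glorot(dh, d_w)
  hn <- paste0("h", seq_len(h))
  mkl <- function() stats::setNames(lapply(seq_len(h), function(i) mk()), hn)
  structure(list(h = h, d_w = d_w, head_reg_weight = head_reg_weight,
                 Wq = mkl(), Wk = mkl(), Wv = mkl(),
                 Wm = glorot(d_w, d_w)),
            class = "attention_params")
}

#' Scaled dot-product similarity scores
#'
#' `Score = Q K' / sqrt(d_w)`: every query position is compared with every
#' key position by inner product, scaled by the square root of the word
#' vector dimension to keep the softmax in a usable range.
#'
#' @param Q,K `n x d` matrices with equal column counts.
#' @param d_w Scaling dimension (the model width, not the per-head width).
#' @return `n x n` score matrix.
#' @export
scaled_scores <- function(Q, K, d_w) {
  if (ncol(Q) != ncol(K))
    pep_stop("Q and K must have the same number of columns", "pepattn_bad_shape")
  if (d_w <= 0) pep_stop("d_w must be positive", "pepattn_bad_shape")
  tcrossprod(Q, K) / sqrt(d_w)
}

#' Masked softmax attention weights
#'
#' Normalises each row of a score matrix into a probability distribution
#' over the *valid* key positions: masked keys receive an additive large
#' negative surrogate before the softmax, so their weight underflows to
#' exactly zero. Rows belonging to masked query positions are defined as
#' uniform over the valid keys (their outputs are zeroed downstream).
#'
#' @param scores `n x n` score matrix.
#' @param mask Optional length-`n` 0/1 validity vector (keys and queries).
#' @return Row-stochastic `n x n` matrix.
#' @export
attention_weights <- function(scores, mask = NULL) {
  n_k <- ncol(scores)
  if (is.null(mask)) mask <- rep(1, n_k)
  if (length(mask) != n_k)
    pep_stop("mask length must match the number of key positions",
             "pepattn_bad_shape")
  valid <- mask > 0
  if (!any(valid)) pep_stop("all positions masked", "pepattn_all_masked")
  s <- scores
  s[, !valid] <- -Inf
  m <- apply(s, 1L, max)
  e <- exp(s - m)            # rows of -Inf-only cannot occur: >=1 valid key
  w <- e / rowSums(e)
  ## self-attention (square scores): masked query rows become uniform over
  ## the valid keys; their outputs are zeroed downstream anyway
  if (nrow(scores) == n_k && any(!valid))
    w[!valid, ] <- rep(as.numeric(valid) / sum(valid), each = sum(!valid))
  w
}

#' Single attention head
#'
#' Projects the input into query/key/value subspaces, forms masked softmax
#' weights from the scaled scores, and returns the weighted value sums:
#' `head = softmax(S Wq' (S Wk')' / sqrt(d_w)) (S Wv')`.
#'
#' @param S `n x d_w` input matrix.
#' @param W_q,W_k,W_v `(d_w/h) x d_w` projection matrices.
#' @param mask Optional validity vector.
#' @param d_w Scaling width; defaults to `ncol(S)`.
#' @return `n x (d_w/h)` matrix.
#' @export
single_head <- function(S, W_q, W_k, W_v, mask = NULL, d_w = ncol(S)) {
  Q <- tcrossprod(S, W_q)
  K <- tcrossprod(S, W_k)
  V <- tcrossprod(S, W_v)
  attention_weights(scaled_scores(Q, K, d_w), mask) %*% V
}

#' Multi-head self-attention over a peptide representation
#'
#' Runs `h` parallel scaled dot-product attention heads on the same input
#' (query = key = value = S), concatenates their outputs along the feature
#' axis and mixes them with the output matrix, yielding an enhanced
#' representation `S'` of the same `n x d_w` shape. Rows at masked query
#' positions are zeroed; masked key positions receive no attention mass.
#'
#' @param S `n x d_w` input matrix (one-hot rows for peptides).
#' @param params An [attention_params()] object with matching `d_w`.
#' @param mask Optional length-`n` 0/1 validity vector.
#' @return List of class `attention_output` with elements `enhanced`
#'   (`n x d_w`), `weights` (list of `h` row-stochastic `n x n` matrices)
#'   and `heads` (list of `h` head output matrices).
#' @export
multi_head_self_attention <- function(S, params, mask = NULL) {
  if (ncol(S) != params$d_w)
    pep_stop(sprintf("input width %d != params d_w %d", ncol(S), params$d_w),
             "pepattn_bad_shape")
  fw <- attn_forward(S, mask, params)
  structure(list(enhanced = fw$Sprime, weights = fw$A, heads = fw$heads),
            class = "attention_output")
}

#' Disagreement penalty across attention heads
#'
#' Mean pairwise cosine similarity of the flattened head outputs: 1 when
#' all heads carry identical directions, 0 when they are mutually
#' orthogonal (or when fewer than two heads are present). Added to the
#' training loss scaled by `head_reg_weight` to push heads toward
#' different subspaces.
#'
#' @param head_outputs List of head output matrices.
#' @return Nonnegative scalar.
#' @export
head_disagreement_penalty <- function(head_outputs) {
  h <- length(head_outputs)
  if (h < 2L) return(0)
  u <- lapply(head_outputs, as.vector)
  nrm <- vapply(u, function(x) sqrt(sum(x^2)), numeric(1))
  tot <- 0
  for (i in seq_len(h - 1L)) for (j in (i + 1L):h) {
    if (nrm[i] > 0 && nrm[j] > 0)
      tot <- tot + sum(u[[i]] * u[[j]]) / (nrm[i] * nrm[j])
  }
  tot / (h * (h - 1) / 2)
}

## gradient of head_disagreement_penalty w.r.t. each head output
head_disagreement_grad <- function(head_outputs) {
  h <- length(head_outputs)
  grads <- lapply(head_outputs, function(m) array(0, dim = dim(m)))
  if (h < 2L) return(grads)
  u <- lapply(head_outputs, as.vector)
  nrm <- vapply(u, function(x) sqrt(sum(x^2)), numeric(1))
  np <- h * (h - 1) / 2
  for (i in seq_len(h - 1L)) for (j in (i + 1L):h) {
    if (nrm[i] > 0 && nrm[j] > 0) {
      cs <- sum(u[[i]] * u[[j]]) / (nrm[i] * nrm[j])
      gi <- (u[[j]] / (nrm[i] * nrm[j]) - cs * u[[i]] / nrm[i]^2) / np
      gj <- (u[[i]] / (nrm[i] * nrm[j]) - cs * u[[j]] / nrm[j]^2) / np
      grads[[i]] <- grads[[i]] + array(gi, dim = dim(head_outputs[[i]]))
      grads[[j]] <- grads[[j]] + array(gj, dim = dim(head_outputs[[j]]))
    }
  }
  grads
}

## ---- internal forward/backward used by the trainer ----

## forward pass for one peptide; returns everything the backward needs
attn_forward <- function(S, mask, params) {
  n <- nrow(S)
  if (is.null(mask)) mask <- rep(1, n)
  h <- params$h
  Q <- K <- V <- A <- heads <- vector("list", h)
  for (i in seq_len(h)) {
    Q[[i]] <- tcrossprod(S, params$Wq[[i]])
    K[[i]] <- tcrossprod(S, params$Wk[[i]])
    V[[i]] <- tcrossprod(S, params$Wv[[i]])
    A[[i]] <- attention_weights(scaled_scores(Q[[i]], K[[i]], params$d_w), mask)
    heads[[i]] <- A[[i]] %*% V[[i]]
  }
  H <- do.call(cbind, heads)
  Sprime <- tcrossprod(H, params$Wm)   # per-row application of the mixing matrix
  Sprime[mask == 0, ] <- 0
  list(S = S, mask = mask, Q = Q, K = K, V = V, A = A, heads = heads,
       H = H, Sprime = Sprime)
}

## backward pass for one peptide. dSprime: gradient at the enhanced output;
## dheads_extra: optional list of extra gradients applied directly to the
## head outputs (disagreement penalty). Returns parameter gradients and,
## when need_input_grad, the gradient at S.
attn_backward <- function(cache, dSprime, params, dheads_extra = NULL,
                          need_input_grad = FALSE) {
  mask <- cache$mask
  valid <- mask > 0
  dSprime[!valid, ] <- 0                   # masked rows contribute nothing
  h <- params$h
  dh <- params$d_w %/% h
  dWm <- crossprod(dSprime, cache$H)       # d_w x d_w
  dH <- dSprime %*% params$Wm              # n x d_w
  dWq <- dWk <- dWv <- vector("list", h)
  dS <- if (need_input_grad) matrix(0, nrow(cache$S), params$d_w) else NULL
  scl <- 1 / sqrt(params$d_w)
  for (i in seq_len(h)) {
    dhead <- dH[, ((i - 1L) * dh + 1L):(i * dh), drop = FALSE]
    if (!is.null(dheads_extra)) dhead <- dhead + dheads_extra[[i]]
    A <- cache$A[[i]]
    dA <- tcrossprod(dhead, cache$V[[i]])  # n x n
    dV <- crossprod(A, dhead)              # n x dh
    ## softmax backward, row-wise; masked-query rows carry no gradient
    ds <- A * (dA - rowSums(dA * A))
    ds[!valid, ] <- 0
    ds[, !valid] <- 0
    dQ <- (ds %*% cache$K[[i]]) * scl
    dK <- (crossprod(ds, cache$Q[[i]])) * scl
    dWq[[i]] <- crossprod(dQ, cache$S)
    dWk[[i]] <- crossprod(dK, cache$S)
    dWv[[i]] <- crossprod(dV, cache$S)
    if (need_input_grad)
      dS <- dS + dQ %*% params$Wq[[i]] + dK %*% params$Wk[[i]] +
        dV %*% params$Wv[[i]]
  }
  list(Wq = dWq, Wk = dWk, Wv = dWv, Wm = dWm, dS = dS)
}

#' Export attention weights as a tidy table
#'
#' Runs the attention encoder of a model over a batch and returns the
#' per-residue attention weights in long format, the per-residue
#' importance view used to inspect which residues the model attends to.
#' Weights over valid key positions sum to 1 for every (id, head,
#' query_position).
#'
#' @param model A `pep_model` with attention enabled.
#' @param batch A `pep_batch`.
#' @return Data frame with columns `id`, `head`, `query_position`,
#'   `key_position`, `weight` (valid positions only).
#' @export
attention_weight_table <- function(model, batch) {
  if (is.null(model$params$attn))
    pep_stop("model has no attention branch", "pepattn_bad_config")
  out <- vector("list", length(batch$ids))
  for (i in seq_along(batch$ids)) {
    L <- batch$lengths[i]
    S <- batch$seq[i, seq_len(L), , drop = TRUE]
    if (L == 1L) S <- matrix(S, 1L)
    ao <- multi_head_self_attention(S, model$params$attn)
    rows <- lapply(seq_along(ao$weights), function(hh) {
      w <- ao$weights[[hh]]
      data.frame(id = batch$ids[i], head = hh,
                 query_position = rep(seq_len(L), times = L),
                 key_position = rep(seq_len(L), each = L),
                 weight = as.vector(w))
    })
    out[[i]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}
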