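#' Initialise peephole LSTM parameters
#'
#' Gate equations (input gate i, forget gate f, output gate o, candidate
#' c~), with elementwise peephole connections from the cell state:
#' \deqn{i_t = \sigma(W_{xi} x_t + W_{hi} h_{t-1} + w_{ci} \odot c_{t-1} + b_i)}
#' \deqn{f_t = \sigma(W_{xf} x_t + W_{hf} h_{t-1} + w_{cf} \odot c_{t-1} + b_f)}
#' \deqn{c_t = f_t \odot c_{t-1} + i_t \odot \tanh(W_{xc} x_t + W_{hc} h_{t-1} + b_c)}
#' \deqn{o_t = \sigma(W_{xo} x_t + W_{ho} h_{t-1} + w_{co} \odot c_t + b_o)}
#' \deqn{h_t = o_t \odot \tanh(c_t)}
#' The input and forget gates peek at the previous cell state, the output
#' gate at the updated one. `peephole = FALSE` fixes the peephole vectors
#' at zero (untrained), giving the common library cell.
#'
#' @param input_dim Width of each timestep input vector.
#' @param units Number of memory units.
#' @param peephole Train the peephole weight vectors?
#' @return Object of class `lstm_params`.
#' @export
lstm_params <- function(input_dim, units, peephole = TRUE) {
  mkx <- function() glorot(units, input_dim)
  mkh <- function() glorot(units, units)
  p <- list(Wxi = mkx(), Whi = mkh(), wci = rep(0, units), bi = rep(0, units),
            Wxf = mkx(), Whf = mkh(), wcf = rep(0, units),
            bf = rep(1, units),      # forget-gate bias 1: remember by default
            Wxc = mkx(), Whc = mkh(), bc = rep(0, units),
            Wxo = mkx(), Who = mkh(), wco = rep(0, units), bo = rep(0, units))
  structure(c(p, list(units = units, input_dim = input_dim,
                      peephole = isTRUE(peephole))),
            class = "lstm_params")
}

#' One peephole LSTM step
#'
#' Advances the recurrence by one timestep for a single input vector.
#'
#' @param x_t Input vector (length `input_dim`).
#' @param h_prev,c_prev Previous hidden and cell state vectors (length
#'   `units`).
#' @param params An [lstm_params()] object.
#' @return List with elements `h` and `c`.
#' @export
lstm_step <- function(x_t, h_prev, c_prev, params) {
  i <- sigmoid(drop(params$Wxi %*% x_t) + drop(params$Whi %*% h_prev) +
                 params$wci * c_prev + params$bi)
  f <- sigmoid(drop(params$Wxf %*% x_t) + drop(params$Whf %*% h_prev) +
                 params$wcf * c_prev + params$bf)
  g <- tanh(drop(params$Wxc %*% x_t) + drop(params$Whc %*% h_prev) + params$bc)
  c_t <- f * c_prev + i * g
  o <- sigmoid(drop(params$Wxo %*% x_t) + drop(params$Who %*% h_prev) +
                 params$wco * c_t + params$bo)
  list(h = o * tanh(c_t), c = c_t)
}

#' Encode a padded sequence with an LSTM
#'
#' Scans the valid (mask = 1) timesteps left to right from a zero state
#' and returns the hidden state at the last valid position. Padded
#' timesteps are skipped entirely, so appending padding never changes the
#' result.
#'
#' @param X `Lmax x input_dim` matrix of per-timestep inputs.
#' @param mask Length-`Lmax` 0/1 validity vector (`NULL` = all valid).
#' @param params An [lstm_params()] object.
#' @return Hidden state vector of length `units`.
#' @export
lstm_encode <- function(X, mask = NULL, params) {
  if (is.null(mask)) mask <- rep(1, nrow(X))
  valid <- which(mask > 0)
  if (length(valid) == 0L)
    pep_stop("no valid timesteps", "pepattn_all_masked")
  h <- rep(0, params$units); c <- rep(0, params$units)
  for (t in valid) {
    st <- lstm_step(X[t, ], h, c, params)
    h <- st$h; c <- st$c
  }
  h
}

## ---- batched internals for the trainer ----

## Batched forward over an n x L x F array. Masked steps carry h/c through
## unchanged, so the final state is the state at each row's last valid
## position. Returns the final hidden states and a cache for BPTT.
lstm_forward_batch <- function(arr, mask, params) {
  n <- dim(arr)[1]; L <- dim(arr)[2]
  U <- params$units
  Wx <- cbind(t(params$Wxi), t(params$Wxf), t(params$Wxc), t(params$Wxo))
  Wh <- cbind(t(params$Whi), t(params$Whf), t(params$Whc), t(params$Who))
  b <- c(params$bi, params$bf, params$bc, params$bo)
  h <- matrix(0, n, U); cc <- matrix(0, n, U)
  steps <- vector("list", L)
  i1 <- 1:U; f1 <- (U + 1):(2 * U); g1 <- (2 * U + 1):(3 * U); o1 <- (3 * U + 1):(4 * U)
  for (t in seq_len(L)) {
    mt <- mask[, t]
    Xt <- matrix(arr[, t, ], n)
    A <- Xt %*% Wx + h %*% Wh
    A <- sweep(A, 2L, b, `+`)
    ig <- sigmoid(A[, i1, drop = FALSE] + cc * rep(params$wci, each = n))
    fg <- sigmoid(A[, f1, drop = FALSE] + cc * rep(params$wcf, each = n))
    g  <- tanh(A[, g1, drop = FALSE])
    c_new <- fg * cc + ig * g
    og <- sigmoid(A[, o1, drop = FALSE] + c_new * rep(params$wco, each = n))
    h_new <- og * tanh(c_new)
    steps[[t]] <- list(Xt = Xt, h_prev = h, c_prev = cc, i = ig, f = fg,
                       g = g, o = og, c_new = c_new, tanh_c = tanh(c_new),
                       mt = mt)
    h <- mt * h_new + (1 - mt) * h
    cc <- mt * c_new + (1 - mt) * cc
  }
  list(h_final = h, steps = steps, n = n, L = L)
}

## BPTT through the batched forward. dH: gradient at the final hidden
## states (n x U). Returns parameter gradients (same names as lstm_params)
## and, when requested, the gradient at the input array.
lstm_backward_batch <- function(cache, dH, params, need_input_grad = FALSE) {
  n <- cache$n; L <- cache$L; U <- params$units
  Fdim <- params$input_dim
  Wh_stack <- rbind(params$Whi, params$Whf, params$Whc, params$Who) # 4U x U? no
  ## rows of Wh_stack: we need dh_prev = da_i %*% Whi + ... ; stack along rows
  Wx_stack <- rbind(params$Wxi, params$Wxf, params$Wxc, params$Wxo)
  dWx <- matrix(0, 4 * U, Fdim)
  dWh <- matrix(0, 4 * U, U)
  db <- rep(0, 4 * U)
  dwci <- dwcf <- dwco <- rep(0, U)
  dC <- matrix(0, n, U)
  dX <- if (need_input_grad) array(0, dim = c(n, L, Fdim)) else NULL
  wci <- rep(params$wci, each = n); wcf <- rep(params$wcf, each = n)
  wco <- rep(params$wco, each = n)
  for (t in rev(seq_len(L))) {
    st <- cache$steps[[t]]
    mt <- st$mt
    dh_eff <- dH * mt
    dc_pass <- dC * (1 - mt)
    do_ <- dh_eff * st$tanh_c
    da_o <- do_ * st$o * (1 - st$o)
    dc_eff <- dC * mt + dh_eff * st$o * (1 - st$tanh_c^2) + da_o * wco
    di_ <- dc_eff * st$g
    da_i <- di_ * st$i * (1 - st$i)
    df_ <- dc_eff * st$c_prev
    da_f <- df_ * st$f * (1 - st$f)
    dg_ <- dc_eff * st$i
    da_g <- dg_ * (1 - st$g^2)
    DA <- cbind(da_i, da_f, da_g, da_o)               # n x 4U
    dWx <- dWx + crossprod(DA, st$Xt)
    dWh <- dWh + crossprod(DA, st$h_prev)
    db <- db + colSums(DA)
    if (params$peephole) {
      dwci <- dwci + colSums(da_i * st$c_prev)
      dwcf <- dwcf + colSums(da_f * st$c_prev)
      dwco <- dwco + colSums(da_o * st$c_new)
    }
    if (need_input_grad)
      dX[, t, ] <- DA %*% Wx_stack
    dH <- dH * (1 - mt) + DA %*% Wh_stack
    dC <- dc_pass + dc_eff * st$f + da_i * wci + da_f * wcf
  }
  i1 <- 1:U; f1 <- (U + 1):(2 * U); g1 <- (2 * U + 1):(3 * U); o1 <- (3 * U + 1):(4 * U)
  grads <- list(Wxi = dWx[i1, , drop = FALSE], Whi = dWh[i1, , drop = FALSE],
                wci = dwci, bi = db[i1],
                Wxf = dWx[f1, , drop = FALSE], Whf = dWh[f1, , drop = FALSE],
                wcf = dwcf, bf = db[f1],
                Wxc = dWx[g1, , drop = FALSE], Whc = dWh[g1, , drop = FALSE],
                bc = db[g1],
                Wxo = dWx[o1, , drop = FALSE], Who = dWh[o1, , drop = FALSE],
                wco = dwco, bo = db[o1])
  list(grads = grads, dX = dX)
}
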