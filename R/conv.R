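#' Convolutional feature branch over an encoded peptide plane
#'
#' Treats the `Lmax x F` encoded peptide (one-hot sequence plane, F = 20,
#' or structure plane, F = 3) as a single-channel image and applies every
#' `k x k` kernel in 'valid' 2-D convolution, followed by ReLU. No pooling
#' is applied — the per-window activations are kept intact — and the
#' activation maps are flattened into one feature vector of length
#' `n_k * (Lmax - k + 1) * (F - k + 1)` (window positions in column-major
#' order within each kernel, kernels concatenated).
#'
#' The layer carries no bias term, so windows lying entirely inside the
#' zero post-padding contribute exactly zero features.
#'
#' @param X `Lmax x F` numeric matrix.
#' @param kernels A `k x k x n_k` array, or a list of `k x k` matrices.
#' @return Numeric feature vector.
#' @export
#' @examples
#' X <- matrix(0, 6, 3); X[2, 2] <- 1
#' length(conv_branch(X, array(1, dim = c(3, 3, 2))))  # 2 * 4 * 1
conv_branch <- function(X, kernels) {
  if (is.list(kernels))
    kernels <- array(unlist(kernels),
                     dim = c(nrow(kernels[[1]]), ncol(kernels[[1]]),
                             length(kernels)))
  k <- dim(kernels)[1]
  if (dim(kernels)[2] != k)
    pep_stop("kernels must be square", "pepattn_bad_shape")
  if (nrow(X) < k || ncol(X) < k)
    pep_stop(sprintf("input %dx%d smaller than kernel %dx%d",
                     nrow(X), ncol(X), k, k),
             "pepattn_bad_shape")
  P <- im2col(X, k)                               # npos x k^2
  Kmat <- matrix(kernels, k * k, dim(kernels)[3]) # column-major per kernel
  as.vector(relu(P %*% Kmat))
}

## im2col for a single matrix: rows are output positions in column-major
## (Hout x Wout) order; columns are kernel offsets in column-major order
im2col <- function(X, k) {
  Hout <- nrow(X) - k + 1L
  Wout <- ncol(X) - k + 1L
  P <- matrix(0, Hout * Wout, k * k)
  cix <- 0L
  for (dj in 0:(k - 1L)) for (di in 0:(k - 1L)) {
    cix <- cix + 1L
    P[, cix] <- as.vector(X[(1L + di):(Hout + di), (1L + dj):(Wout + dj)])
  }
  P
}

## batched im2col over an N x L x F array. Row order: sample index fastest,
## then output position (column-major over the Hout x Wout grid), so row
## r = i + N * (pos - 1). This makes per-sample feature flattening a plain
## reshape with no transposition.
batch_im2col <- function(arr, k, sparse = FALSE) {
  N <- dim(arr)[1]; L <- dim(arr)[2]; F <- dim(arr)[3]
  Hout <- L - k + 1L
  Wout <- F - k + 1L
  if (Hout < 1L || Wout < 1L)
    pep_stop("input plane smaller than kernel", "pepattn_bad_shape")
  P <- matrix(0, N * Hout * Wout, k * k)
  cix <- 0L
  for (dj in 0:(k - 1L)) for (di in 0:(k - 1L)) {
    cix <- cix + 1L
    P[, cix] <- as.vector(arr[, (1L + di):(Hout + di), (1L + dj):(Wout + dj),
                              drop = FALSE])
  }
  if (sparse) P <- methods::as(P, "CsparseMatrix")
  list(P = P, N = N, npos = Hout * Wout, Hout = Hout, Wout = Wout)
}

## rows of the batched patch matrix belonging to samples `idx` (in order)
im2col_rows <- function(ic, idx) {
  as.vector(outer(idx, (seq_len(ic$npos) - 1L) * ic$N, `+`))
}

## scatter-add patch gradients back onto the input array (inverse of
## batch_im2col for a sample subset); dP has im2col row order for n samples
col2im_add <- function(dP, n, Hout, Wout, L, F, k) {
  dX <- array(0, dim = c(n, L, F))
  cix <- 0L
  for (dj in 0:(k - 1L)) for (di in 0:(k - 1L)) {
    cix <- cix + 1L
    dX[, (1L + di):(Hout + di), (1L + dj):(Wout + dj)] <-
      dX[, (1L + di):(Hout + di), (1L + dj):(Wout + dj), drop = FALSE] +
      array(dP[, cix], dim = c(n, Hout, Wout))
  }
  dX
}
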