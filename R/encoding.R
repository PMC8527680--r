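#' One-hot encode an amino-acid sequence
#'
#' Each residue becomes a length-20 indicator row (alphabetical column
#' order, see [pep_alphabet()]); a sequence of length L occupies the first
#' L rows of an `max_len x 20` matrix, with all-zero rows and mask 0 after
#' the sequence end (post-padding).
#'
#' @param sequence Amino-acid string.
#' @param max_len Number of rows of the padded matrix; must be >= the
#'   sequence length.
#' @param policy `"strict"` rejects residues outside the 20-letter
#'   alphabet; `"lenient"` maps them to an all-zero row (mask stays 1).
#' @return List with `onehot` (`max_len x 20` matrix) and `mask`
#'   (length-`max_len` 0/1 vector).
#' @export
#' @examples
#' enc <- one_hot_encode("AC", 4)
#' colSums(enc$onehot)[c("A", "C")]
one_hot_encode <- function(sequence, max_len, policy = c("strict", "lenient")) {
  policy <- match.arg(policy)
  chars <- strsplit(toupper(sequence), "")[[1]]
  L <- length(chars)
  if (L == 0L) pep_stop("empty sequence", "pepattn_empty_sequence")
  if (L > max_len)
    pep_stop(sprintf("sequence length %d exceeds max_len %d", L, max_len),
             "pepattn_overlong")
  idx <- match(chars, pep_alphabet())
  if (policy == "strict" && anyNA(idx))
    pep_stop(sprintf("invalid residue '%s' (strict mode)", chars[is.na(idx)][1]),
             "pepattn_invalid_residue")
  m <- matrix(0, max_len, 20, dimnames = list(NULL, pep_alphabet()))
  ok <- which(!is.na(idx))
  m[cbind(ok, idx[ok])] <- 1
  mask <- c(rep(1, L), rep(0, max_len - L))
  list(onehot = m, mask = mask)
}

#' Pad a secondary-structure profile to a fixed length
#'
#' @param profile `L x 3` matrix of per-residue (helix, strand, coil)
#'   probabilities.
#' @param max_len Target row count (>= L); padded rows are zero.
#' @return `max_len x 3` matrix.
#' @export
encode_structure <- function(profile, max_len) {
  L <- nrow(profile)
  if (L > max_len)
    pep_stop(sprintf("profile length %d exceeds max_len %d", L, max_len),
             "pepattn_overlong")
  out <- matrix(0, max_len, 3, dimnames = list(NULL, c("helix", "strand", "coil")))
  out[seq_len(L), ] <- as.matrix(profile)
  out
}

#' Encode a dataset into padded, masked tensors
#'
#' Produces the numeric batch consumed by the network: an
#' `N x Lmax x 20` one-hot sequence array, an `N x Lmax x 3` structure
#' array (all-zero when profiles are absent), an `N x Lmax` validity mask,
#' and aligned labels/lengths. Record order is preserved.
#'
#' @param dataset A `pep_dataset`.
#' @param max_len `"auto"` (the longest sequence in the dataset, capped at
#'   `cap`) or a positive integer. Sequences longer than the resolved
#'   maximum are rejected, never truncated.
#' @param policy Residue policy passed to [one_hot_encode()].
#' @param cap Upper bound applied when `max_len = "auto"`; anticancer
#'   peptides are at most ~50 residues, so the default cap is 50.
#' @return An object of class `pep_batch`.
#' @export
batch_encode <- function(dataset, max_len = "auto",
                         policy = c("strict", "lenient"), cap = 50L) {
  policy <- match.arg(policy)
  rec <- dataset$records
  n <- nrow(rec)
  if (n == 0L) pep_stop("empty dataset", "pepattn_empty_dataset")
  lens <- nchar(rec$sequence)
  if (identical(max_len, "auto")) {
    if (max(lens) > cap)
      pep_stop(sprintf("sequence length %d exceeds the %d-residue cap",
                       max(lens), cap),
               "pepattn_overlong")
    Lmax <- max(lens)
  } else {
    Lmax <- as.integer(max_len)
  }
  if (any(lens > Lmax))
    pep_stop(sprintf("sequence length %d exceeds max_len %d", max(lens), Lmax),
             "pepattn_overlong")

  with_prof <- rec$id %in% names(dataset$profiles)
  has_structure <- all(with_prof) && n > 0L
  if (any(with_prof) && !has_structure)
    pep_stop("some but not all records have structure profiles; use build_dataset(require_structure = TRUE) first",
             "pepattn_partial_structure")

  seq_arr <- array(0, dim = c(n, Lmax, 20))
  struct_arr <- array(0, dim = c(n, Lmax, 3))
  mask <- matrix(0, n, Lmax)
  for (i in seq_len(n)) {
    enc <- one_hot_encode(rec$sequence[i], Lmax, policy = policy)
    seq_arr[i, , ] <- enc$onehot
    mask[i, ] <- enc$mask
    if (has_structure)
      struct_arr[i, , ] <- encode_structure(dataset$profiles[[rec$id[i]]], Lmax)
  }
  structure(list(seq = seq_arr, struct = struct_arr, mask = mask,
                 labels = rec$label, lengths = lens, ids = rec$id,
                 max_len = Lmax, has_structure = has_structure),
            class = "pep_batch")
}

## subset a batch by record index (used by the CV harness and trainer)
batch_subset <- function(batch, idx) {
  structure(list(seq = batch$seq[idx, , , drop = FALSE],
                 struct = batch$struct[idx, , , drop = FALSE],
                 mask = batch$mask[idx, , drop = FALSE],
                 labels = batch$labels[idx],
                 lengths = batch$lengths[idx],
                 ids = batch$ids[idx],
                 max_len = batch$max_len,
                 has_structure = batch$has_structure),
            class = "pep_batch")
}

## extend padding of a batch to a larger Lmax (contents unchanged)
batch_repad <- function(batch, new_len) {
  if (new_len < batch$max_len)
    pep_stop("cannot shrink a batch below its current max_len",
             "pepattn_overlong")
  if (new_len == batch$max_len) return(batch)
  n <- dim(batch$seq)[1]
  seq_arr <- array(0, dim = c(n, new_len, 20))
  struct_arr <- array(0, dim = c(n, new_len, 3))
  mask <- matrix(0, n, new_len)
  seq_arr[, seq_len(batch$max_len), ] <- batch$seq
  struct_arr[, seq_len(batch$max_len), ] <- batch$struct
  mask[, seq_len(batch$max_len)] <- batch$mask
  batch$seq <- seq_arr; batch$struct <- struct_arr; batch$mask <- mask
  batch$max_len <- new_len
  batch
}

#' @export
print.pep_batch <- function(x, ...) {
  cat(sprintf("<pep_batch> %d peptides, max_len %d, structure %s\n",
              length(x$labels), x$max_len,
              if (x$has_structure) "present" else "absent"))
  invisible(x)
}
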