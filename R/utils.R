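#' The canonical amino-acid alphabet
#'
#' Fixed alphabetical ordering of the 20 canonical one-letter amino-acid
#' codes. This ordering defines the column layout of every one-hot encoding
#' produced by the package and is frozen for checkpoint compatibility.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' pep_alphabet()
pep_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

## classed errors so callers can distinguish failure modes
pep_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "pepattn_error", "error", "condition")))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

## Glorot/Xavier uniform initialisation; draws from the current RNG stream
glorot <- function(nrow, ncol, fan_in = ncol, fan_out = nrow) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## flatten a nested list of numeric arrays into a flat named list;
## names are dot-joined paths ("attn.Wq1", "dense.W1", ...)
flatten_params <- function(x, prefix = NULL) {
  skip <- c("units", "input_dim", "peephole", "h", "d_w", "head_reg_weight")
  out <- list()
  for (nm in names(x)) {
    if (nm %in% skip) next
    el <- x[[nm]]
    path <- if (is.null(prefix)) nm else paste0(prefix, ".", nm)
    if (is.list(el)) {
      out <- c(out, flatten_params(el, path))
    } else {
      out[[path]] <- el
    }
  }
  out
}

## write flat named values back into the nested structure
unflatten_params <- function(skeleton, flat) {
  for (nm in names(flat)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    skeleton[[parts]] <- flat[[nm]]
  }
  skeleton
}

n_params <- function(params) {
  sum(vapply(flatten_params(params), length, integer(1)))
}
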