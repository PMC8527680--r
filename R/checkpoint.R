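#' Save a model checkpoint
#'
#' Writes a version-stamped checkpoint (RDS archive of config, weights,
#' fitted length and training history) plus a human-readable plain-text
#' sidecar `<path>.config.txt` with one `key = value` line per
#' configuration field.
#'
#' @param model A `pep_model`.
#' @param path Output file path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(format = "pepattn-checkpoint-1", model = model), path)
  writeLines(config_lines(model$config,
                          extra = c(max_len = model$max_len,
                                    structure = model$structure)),
             paste0(path, ".config.txt"))
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Path written by [save_checkpoint()].
#' @return The stored `pep_model`.
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "pepattn-checkpoint-1"))
    pep_stop("not a recognised checkpoint file", "pepattn_bad_checkpoint")
  x$model
}

## key = value serialisation of a config (NULLs skipped)
config_lines <- function(config, extra = NULL) {
  vals <- c(unclass(config), as.list(extra))
  vals <- vals[!vapply(vals, is.null, logical(1))]
  paste(names(vals), unlist(lapply(vals, format)), sep = " = ")
}

#' Read a plain-text key = value configuration file
#'
#' Parses files of `key = value` lines (as written alongside checkpoints
#' and output directories) into a named list, coercing numeric and
#' logical values. Lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return Named list.
#' @export
read_config_file <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*(#|$)", ln) & grepl("=", ln, fixed = TRUE)]
  out <- list()
  for (line in ln) {
    key <- trimws(sub("=.*$", "", line))
    v <- trimws(sub("^[^=]*=", "", line))
    v2 <- suppressWarnings(as.numeric(v))
    out[[key]] <- if (!is.na(v2)) v2
    else if (v %in% c("TRUE", "FALSE")) as.logical(v)
    else v
  }
  out
}
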