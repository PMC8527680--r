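#' Read labelled peptide sequences from a FASTA file
#'
#' Reads a peptide FASTA file and returns one record per entry, order
#' preserved and sequences uppercased. Binary activity labels (1 =
#' anticancer/positive, 0 = negative) can be carried in the header or
#' supplied in a sidecar table.
#'
#' With `label_policy = "header_token"` the final `|`-delimited token of
#' each header must be `0` or `1` and the id is the header with that token
#' removed (the canonical format, e.g. `>AC_17|1`). With `"sidecar_table"`
#' labels are looked up in a two-column id/label table. With `"unlabeled"`
#' the full header (first whitespace-delimited word) is the id and labels
#' are `NA`.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped sequence lines).
#' @param label_policy One of `"header_token"`, `"sidecar_table"`,
#'   `"unlabeled"`.
#' @param sidecar For `"sidecar_table"`: a path to a tab-separated file with
#'   columns `id` and `label`, or an equivalent data frame.
#' @return A data frame with columns `id`, `sequence`, `label` (integer or
#'   `NA`), one row per FASTA entry.
#' @export
read_peptide_fasta <- function(path,
                               label_policy = c("header_token", "sidecar_table",
                                                "unlabeled"),
                               sidecar = NULL) {
  label_policy <- match.arg(label_policy)
  if (!file.exists(path))
    pep_stop(sprintf("FASTA file not found: %s", path), "pepattn_missing_file")
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) {
    warning("empty FASTA file: ", path)
    return(data.frame(id = character(), sequence = character(),
                      label = integer(), stringsAsFactors = FALSE))
  }
  headers <- names(seqs)
  sequences <- toupper(as.character(seqs))
  if (any(nchar(sequences) == 0L))
    pep_stop(sprintf("empty sequence for entry '%s'",
                     headers[which(nchar(sequences) == 0L)[1]]),
             "pepattn_empty_sequence")

  if (label_policy == "header_token") {
    has_bar <- grepl("|", headers, fixed = TRUE)
    token <- sub("^.*\\|", "", headers)
    bad <- !has_bar | !(token %in% c("0", "1"))
    if (any(bad))
      pep_stop(sprintf("header '%s' lacks a final |0 or |1 label token",
                       headers[which(bad)[1]]),
               "pepattn_bad_label")
    ids <- sub("\\|[^|]*$", "", headers)
    labels <- as.integer(token)
  } else {
    ids <- sub("\\s.*$", "", headers)
    if (label_policy == "sidecar_table") {
      tab <- if (is.data.frame(sidecar)) sidecar else {
        if (is.null(sidecar) || !file.exists(sidecar))
          pep_stop("sidecar label table not found", "pepattn_missing_file")
        utils::read.delim(sidecar, stringsAsFactors = FALSE)
      }
      if (!all(c("id", "label") %in% names(tab)))
        pep_stop("sidecar table must have columns 'id' and 'label'",
                 "pepattn_bad_label")
      m <- match(ids, tab$id)
      if (anyNA(m))
        pep_stop(sprintf("no label for id '%s' in sidecar table",
                         ids[which(is.na(m))[1]]),
                 "pepattn_bad_label")
      labels <- as.integer(tab$label[m])
      if (any(!labels %in% c(0L, 1L)))
        pep_stop("sidecar labels must be 0 or 1", "pepattn_bad_label")
    } else {
      labels <- rep(NA_integer_, length(ids))
    }
  }
  if (anyDuplicated(ids))
    pep_stop(sprintf("duplicate peptide id '%s'", ids[duplicated(ids)][1]),
             "pepattn_duplicate_id")
  data.frame(id = unname(ids), sequence = unname(sequences),
             label = unname(labels), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Write peptide records to FASTA
#'
#' Inverse of [read_peptide_fasta()] under the header-token convention:
#' labelled records get headers `id|label`, unlabelled records plain `id`.
#'
#' @param records Data frame with columns `id`, `sequence` and optionally
#'   `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_fasta <- function(records, path) {
  headers <- records$id
  if (!is.null(records$label) && !all(is.na(records$label)))
    headers <- paste0(records$id, "|", records$label)
  x <- Biostrings::BStringSet(records$sequence)
  names(x) <- headers
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read per-residue secondary-structure probability profiles
#'
#' Parses a tab-separated profile file with header columns
#' `id`, `residue_index`, `p_helix`, `p_strand`, `p_coil` — one row per
#' residue, `residue_index` 1-based and contiguous within each id — as
#' produced by post-processing an external secondary-structure predictor
#' (e.g. SPIDER3). Probabilities are clipped to `[0, 1]` and renormalised
#' per residue so each (helix, strand, coil) triple sums to exactly 1.
#'
#' @param path Path to the TSV file.
#' @return Named list of `L x 3` numeric matrices with columns
#'   `helix`, `strand`, `coil`, one per peptide id.
#' @export
read_structure_profiles <- function(path) {
  if (!file.exists(path))
    pep_stop(sprintf("profile file not found: %s", path), "pepattn_missing_file")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "residue_index", "p_helix", "p_strand", "p_coil")
  if (!all(need %in% names(tab)))
    pep_stop(paste("profile TSV must have columns:", paste(need, collapse = ", ")),
             "pepattn_bad_profile")
  if (nrow(tab) == 0L)
    pep_stop("profile file has no rows", "pepattn_bad_profile")
  out <- lapply(split(tab, factor(tab$id, levels = unique(tab$id))), function(d) {
    d <- d[order(d$residue_index), , drop = FALSE]
    if (!identical(as.integer(d$residue_index), seq_len(nrow(d))))
      pep_stop(sprintf("residue indices for id '%s' are not contiguous from 1",
                       d$id[1]),
               "pepattn_bad_profile")
    p <- as.matrix(d[, c("p_helix", "p_strand", "p_coil")])
    normalize_profile(p, d$id[1])
  })
  out
}

## clip to [0,1] and renormalise rows; tolerance 1e-3 on negative inputs
normalize_profile <- function(p, id = "?") {
  if (any(!is.finite(p)))
    pep_stop(sprintf("non-finite probability for id '%s'", id),
             "pepattn_bad_profile")
  if (any(p < -1e-3))
    pep_stop(sprintf("negative probability beyond tolerance for id '%s'", id),
             "pepattn_bad_profile")
  p[p < 0] <- 0
  p[p > 1] <- 1
  s <- rowSums(p)
  if (any(s <= 0))
    pep_stop(sprintf("all-zero probability row for id '%s'", id),
             "pepattn_bad_profile")
  p <- p / s
  dimnames(p) <- list(NULL, c("helix", "strand", "coil"))
  p
}

#' Pair peptide records with structure profiles into a dataset
#'
#' Validates that profiles match their records in length and assembles the
#' container consumed by [batch_encode()] and [cross_validate()]. With
#' `require_structure = TRUE`, records lacking a profile are dropped (the
#' number dropped is reported by a message), mirroring the removal of
#' peptides for which a structure predictor returns nothing.
#'
#' @param records Data frame from [read_peptide_fasta()] with non-missing
#'   labels.
#' @param profiles Named list of `L x 3` profile matrices (optional).
#' @param require_structure Drop records without a profile?
#' @return An object of class `pep_dataset`: list with elements `records`,
#'   `profiles`, `n_dropped`.
#' @export
build_dataset <- function(records, profiles = NULL, require_structure = FALSE) {
  if (nrow(records) == 0L)
    pep_stop("no records supplied", "pepattn_empty_dataset")
  if (anyNA(records$label))
    pep_stop("records must be labelled for dataset construction",
             "pepattn_unlabeled")
  if (anyDuplicated(records$id))
    pep_stop("duplicate peptide ids in records", "pepattn_duplicate_id")
  profiles <- profiles %||% list()
  orphan <- setdiff(names(profiles), records$id)
  if (length(orphan)) {
    warning(length(orphan), " profile(s) without a matching record dropped")
    profiles <- profiles[setdiff(names(profiles), orphan)]
  }
  for (id in names(profiles)) {
    L <- nchar(records$sequence[records$id == id])
    p <- profiles[[id]]
    if (nrow(p) != L)
      pep_stop(sprintf("profile length %d != sequence length %d for id '%s'",
                       nrow(p), L, id),
               "pepattn_length_mismatch")
    profiles[[id]] <- normalize_profile(p, id)
  }
  n_dropped <- 0L
  if (require_structure) {
    keep <- records$id %in% names(profiles)
    n_dropped <- sum(!keep)
    if (all(!keep))
      pep_stop("all records dropped: no structure profiles available",
               "pepattn_empty_dataset")
    if (n_dropped > 0L)
      message(n_dropped, " record(s) without structure profiles dropped")
    records <- records[keep, , drop = FALSE]
    rownames(records) <- NULL
  }
  structure(list(records = records,
                 profiles = profiles[intersect(records$id, names(profiles))],
                 n_dropped = n_dropped),
            class = "pep_dataset")
}

#' Subset a peptide dataset by record index
#'
#' @param dataset A `pep_dataset`.
#' @param idx Integer indices into the record table.
#' @return A `pep_dataset` containing the selected records (order of `idx`)
#'   and their profiles.
#' @export
dataset_subset <- function(dataset, idx) {
  rec <- dataset$records[idx, , drop = FALSE]
  rownames(rec) <- NULL
  structure(list(records = rec,
                 profiles = dataset$profiles[intersect(rec$id,
                                                       names(dataset$profiles))],
                 n_dropped = 0L),
            class = "pep_dataset")
}

#' @export
print.pep_dataset <- function(x, ...) {
  n <- nrow(x$records)
  npos <- sum(x$records$label == 1L)
  cat(sprintf("<pep_dataset> %d peptides (%d positive, %d negative), %d with structure profiles\n",
              n, npos, n - npos, length(x$profiles)))
  invisible(x)
}

#' @export
length.pep_dataset <- function(x) nrow(x$records)
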