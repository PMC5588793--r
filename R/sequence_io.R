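#' Construct a protein record table
#'
#' The central container of the package: a plain `data.frame` with one row
#' per protein and columns `id`, `sequence`, `label`. Labels use the
#' two-class vocabulary `"positive"` (ER-resident) / `"negative"`
#' (non-ER-resident); `NA` marks unlabelled query records.
#'
#' @param id character vector of identifiers (unique).
#' @param sequence character vector of amino-acid sequences (upper-case).
#' @param label optional character vector, `"positive"`, `"negative"` or `NA`.
#' @param desc optional description (FASTA header text after the first
#'   whitespace).
#' @return A `data.frame` with columns `id`, `sequence`, `label`, `desc`.
#' @export
protein_records <- function(id, sequence, label = NA_character_, desc = NA_character_) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence)) {
    input_error("'id' and 'sequence' must have the same length")
  }
  label <- rep_len(as.character(label), length(id))
  bad <- !is.na(label) & !label %in% c("positive", "negative")
  if (any(bad)) {
    input_error(sprintf("invalid label(s): %s (must be 'positive'/'negative'/NA)",
                        paste(unique(label[bad]), collapse = ", ")))
  }
  data.frame(id = id, sequence = sequence, label = label,
             desc = rep_len(as.character(desc), length(id)),
             stringsAsFactors = FALSE)
}

#' Read protein sequences from a FASTA file
#'
#' One record per FASTA entry, in file order. The header token up to the
#' first whitespace becomes the `id`; the remainder is kept as `desc`.
#' Sequences are upper-cased but not otherwise altered: run
#' [validate_records()] before feeding records to encoders or training.
#'
#' @param path path to a FASTA file.
#' @return A protein record `data.frame` (see [protein_records()]) with
#'   `label = NA`.
#' @seealso [write_fasta()], [validate_records()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    input_error(sprintf("FASTA file not found: %s", path))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) input_error(sprintf("cannot parse FASTA '%s': %s",
                                            path, conditionMessage(e))))
  if (length(set) == 0L) {
    input_error(sprintf("FASTA file '%s' contains no sequences", path))
  }
  headers <- names(set)
  empty <- Biostrings::width(set) == 0L
  if (any(empty)) {
    input_error(sprintf("FASTA entry with empty sequence: '%s'",
                        headers[which(empty)[1L]]))
  }
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers),
                 NA_character_)
  protein_records(id = ids, sequence = as.character(set), desc = desc)
}

#' Write protein records to a FASTA file
#'
#' @param records protein record `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  headers <- ifelse(is.na(records$desc), records$id,
                    paste(records$id, records$desc))
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Validate protein records for composition analysis
#'
#' Training and encoding assume sequences over the 20 standard amino acids
#' and longer than 50 residues (shorter SwissProt entries are mostly
#' fragments). Under `policy = "strict"` any sequence containing a
#' non-standard character (B, J, O, U, X, Z, gaps, ...) is rejected with
#' reason `bad_alphabet`; under `policy = "strip"` those characters are
#' removed and the length rule is re-checked. Sequences with fewer than
#' `min_length` residues are rejected with reason `too_short`.
#'
#' @param records protein record `data.frame`.
#' @param min_length minimum accepted sequence length (default 51, i.e.
#'   more than 50 residues).
#' @param policy `"strict"` or `"strip"` (see above).
#' @return A list with components `records` (the accepted rows, sequences
#'   possibly stripped) and `rejected` (`data.frame` with columns `id`,
#'   `reason`; reasons are `"too_short"` or `"bad_alphabet"`).
#' @export
validate_records <- function(records, min_length = 51L,
                             policy = c("strict", "strip")) {
  policy <- match.arg(policy)
  seqs <- toupper(records$sequence)
  valid_re <- sprintf("^[%s]*$", paste(AA20, collapse = ""))
  clean <- grepl(valid_re, seqs)
  reason <- rep(NA_character_, nrow(records))
  if (policy == "strict") {
    reason[!clean] <- "bad_alphabet"
  } else {
    seqs[!clean] <- gsub(sprintf("[^%s]", paste(AA20, collapse = "")), "",
                         seqs[!clean])
  }
  too_short <- is.na(reason) & nchar(seqs) < min_length
  reason[too_short] <- "too_short"
  keep <- is.na(reason)
  out <- records[keep, , drop = FALSE]
  out$sequence <- seqs[keep]
  rownames(out) <- NULL
  list(records = out,
       rejected = data.frame(id = records$id[!keep],
                             reason = reason[!keep],
                             stringsAsFactors = FALSE))
}

#' Write a validation-failure log as TSV
#'
#' @param rejected the `rejected` component of [validate_records()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rejected_tsv <- function(rejected, path) {
  utils::write.table(rejected, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
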