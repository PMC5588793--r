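#' The 20 standard amino acids, one-letter codes, alphabetical order
#'
#' All composition vectors produced by this package order their residue
#' components by this vector (A, C, D, ..., Y).
#'
#' @format Character vector of length 20.
#' @export
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# All 400 ordered dipeptides, lexicographic: AA, AC, ..., YY
aa_dipeptides <- function() {
  paste0(rep(AA20, each = 20L), rep(AA20, times = 20L))
}

# Split a sequence string into a character vector of residues
seq_chars <- function(seq) {
  strsplit(seq, "", fixed = TRUE)[[1L]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

input_error <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("erpred_input_error", "error")))
}

config_error <- function(msg) {
  stop(errorCondition(msg, class = c("erpred_config_error", "error")))
}
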