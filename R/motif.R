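#' Compile a PROSITE-syntax pattern
#'
#' Supports the pattern subset used for ER-retention signals and similar
#' short motifs: residue classes `[ABC]`, excluded classes `{ABC}`, the
#' wildcard `x`, repetition `(n)` and `(n,m)`, the N-terminal anchor `<`
#' and the C-terminal anchor `>`. Elements are separated by `-`; a trailing
#' `.` is accepted and ignored.
#'
#' @param pattern PROSITE pattern string, e.g. `"[KRHQSA]-[DENQ]-E-L>"`.
#' @param anchored_cterm override the C-terminal anchoring implied by the
#'   pattern string (`TRUE`/`FALSE`); `NULL` keeps the pattern's own `>`.
#' @return An object of class `motif_pattern`.
#' @export
compile_pattern <- function(pattern, anchored_cterm = NULL) {
  raw <- pattern
  pat <- gsub("\\s", "", pattern)
  pat <- sub("\\.$", "", pat)
  anchored_n <- startsWith(pat, "<")
  if (anchored_n) pat <- substring(pat, 2L)
  anchored_c <- endsWith(pat, ">")
  if (anchored_c) pat <- substring(pat, 1L, nchar(pat) - 1L)
  if (nchar(pat) == 0L) input_error("empty PROSITE pattern")

  elem_re <- "^(\\[[A-Za-z]+\\]|\\{[A-Za-z]+\\}|[A-Za-z])(\\((\\d+)(,(\\d+))?\\))?"
  elements <- list()
  pos <- 1L
  rest <- pat
  repeat {
    m <- regexec(elem_re, rest)[[1L]]
    if (m[1L] == -1L) {
      input_error(sprintf("PROSITE syntax error in '%s' at position %d", raw, pos))
    }
    groups <- regmatches(rest, regexec(elem_re, rest))[[1L]]
    core <- groups[2L]
    if (startsWith(core, "[")) {
      set <- toupper(seq_chars(substr(core, 2L, nchar(core) - 1L)))
      negated <- FALSE
    } else if (startsWith(core, "{")) {
      set <- toupper(seq_chars(substr(core, 2L, nchar(core) - 1L)))
      negated <- TRUE
    } else if (toupper(core) == "X") {
      set <- NULL
      negated <- FALSE
    } else {
      set <- toupper(core)
      negated <- FALSE
    }
    rep_min <- if (groups[4L] == "") 1L else as.integer(groups[4L])
    rep_max <- if (groups[6L] == "") rep_min else as.integer(groups[6L])
    if (rep_max < rep_min) {
      input_error(sprintf("PROSITE repetition (%d,%d) has max < min in '%s'",
                          rep_min, rep_max, raw))
    }
    elements[[length(elements) + 1L]] <-
      list(set = set, negated = negated, min = rep_min, max = rep_max)
    consumed <- attr(m, "match.length")[1L]
    pos <- pos + consumed
    rest <- substring(rest, consumed + 1L)
    if (rest == "") break
    if (!startsWith(rest, "-")) {
      input_error(sprintf("PROSITE syntax error in '%s' at position %d: expected '-'",
                          raw, pos))
    }
    rest <- substring(rest, 2L)
    pos <- pos + 1L
    if (rest == "") {
      input_error(sprintf("PROSITE syntax error in '%s': trailing '-'", raw))
    }
  }
  if (!is.null(anchored_cterm)) anchored_c <- isTRUE(anchored_cterm)
  structure(list(pattern = raw, elements = elements,
                 anchored_nterm = anchored_n, anchored_cterm = anchored_c),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif_pattern> %s (%d elements%s%s)\n", x$pattern,
              length(x$elements),
              if (x$anchored_nterm) ", N-anchored" else "",
              if (x$anchored_cterm) ", C-anchored" else ""))
  invisible(x)
}

# does residue ch satisfy one pattern element?
elem_matches <- function(elem, ch) {
  if (is.null(elem$set)) return(TRUE)           # wildcard x
  hit <- ch %in% elem$set
  if (elem$negated) !hit else hit
}

# Try to match the element list starting at position `start` (1-based).
# Returns the end position of the first (shortest) match, or NA. If
# `require_end` is a position, only matches ending exactly there count.
match_at <- function(chars, start, elements, require_end = NA_integer_) {
  L <- length(chars)
  recurse <- function(pos, ei) {
    if (ei > length(elements)) {
      end <- pos - 1L
      if (!is.na(require_end) && end != require_end) return(NA_integer_)
      return(end)
    }
    el <- elements[[ei]]
    # consume the mandatory minimum
    p <- pos
    for (k in seq_len(el$min)) {
      if (p > L || !elem_matches(el, chars[p])) return(NA_integer_)
      p <- p + 1L
    }
    # then try 0 .. (max - min) optional extras, shortest first
    for (extra in 0L:(el$max - el$min)) {
      if (extra > 0L) {
        q <- p + extra - 1L
        if (q > L || !elem_matches(el, chars[q])) return(NA_integer_)
      }
      res <- recurse(p + extra, ei + 1L)
      if (!is.na(res)) return(res)
    }
    NA_integer_
  }
  recurse(start, 1L)
}

#' Scan sequences for a motif
#'
#' Reports all matches, left to right, one per feasible start position
#' (after a match the scan restarts one position after the match start, so
#' overlapping occurrences are all reported). For a C-anchored pattern only
#' matches ending at the last residue are reported; for an N-anchored
#' pattern only matches starting at the first.
#'
#' @param records protein record `data.frame` (or a single sequence string).
#' @param pattern a `motif_pattern` from [compile_pattern()], or a PROSITE
#'   string (compiled on the fly).
#' @return `data.frame` with columns `id`, `start`, `end` (1-based,
#'   inclusive), `match`. Zero rows when nothing matches.
#' @export
scan_motif <- function(records, pattern) {
  if (is.character(pattern)) pattern <- compile_pattern(pattern)
  if (is.character(records)) {
    records <- protein_records(id = paste0("seq", seq_along(records)),
                               sequence = records)
  }
  out <- list()
  for (i in seq_len(nrow(records))) {
    chars <- seq_chars(records$sequence[i])
    L <- length(chars)
    starts <- if (pattern$anchored_nterm) 1L else seq_len(L)
    req_end <- if (pattern$anchored_cterm) L else NA_integer_
    for (s in starts) {
      e <- match_at(chars, s, pattern$elements, req_end)
      if (!is.na(e)) {
        out[[length(out) + 1L]] <- data.frame(
          id = records$id[i], start = s, end = e,
          match = paste(chars[s:e], collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(id = character(), start = integer(), end = integer(),
                      match = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Count records carrying a retention signal
#'
#' @param records protein record `data.frame`.
#' @param pattern a `motif_pattern` or PROSITE string (default: the
#'   KDEL-class ER-retention consensus, C-anchored).
#' @return A list with `count` (number of records with at least one hit)
#'   and `flags` (`data.frame` with columns `id`, `has_signal`, aligned
#'   with the input order).
#' @export
signal_census <- function(records, pattern = er_signal_patterns()[["kdel_class"]]) {
  if (is.character(pattern)) pattern <- compile_pattern(pattern)
  hits <- scan_motif(records, pattern)
  has <- records$id %in% hits$id
  list(count = sum(has),
       flags = data.frame(id = records$id, has_signal = has,
                          stringsAsFactors = FALSE))
}

#' Bundled ER-retrieval signal patterns
#'
#' The C-anchored KDEL-class luminal retention consensus and the dilysine /
#' arginine-lysine retrieval motif variants of membrane proteins.
#'
#' @return Named character vector of PROSITE patterns.
#' @export
er_signal_patterns <- function() {
  c(kdel_class     = "[KRHQSA]-[DENQ]-E-L>",
    dilysine_kkxx  = "K-K-x-x>",
    dilysine_kxkxx = "K-x-K-x-x>",
    dilysine_kxhxx = "K-x-H-x-x>",
    arg_lys_rkxx   = "R-K-x-x>")
}
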