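#' Pooled per-residue fractions of a record set
#'
#' All sequences are merged into one pool: the fraction of residue i is its
#' total count across all sequences divided by the total number of residues
#' (residue-weighted, not a per-sequence average). Fractions sum to 1.
#'
#' @param records protein record `data.frame`.
#' @return Named numeric vector of length 20.
#' @export
pooled_fraction <- function(records) {
  if (nrow(records) == 0L) input_error("pooled_fraction: empty record set")
  counts <- colSums(residue_count_matrix(records))
  counts / sum(counts)
}

# per-sequence residue count matrix (n x 20)
residue_count_matrix <- function(records) {
  m <- t(vapply(records$sequence, residue_counts, integer(20L)))
  dimnames(m) <- list(records$id, AA20)
  m
}

#' Compositional difference between a query and a background set
#'
#' For each residue, `D = (d1 - d2) / d2`, where `d1` is the pooled
#' fraction in the query set and `d2` in the background set. Positive D =
#' enriched in the query, negative = depleted; `D = -1` marks a residue
#' absent from the query. A residue with `d2 = 0` has no defined relative
#' difference and is reported as `NA` with `undefined = TRUE`.
#'
#' @param query,background protein record `data.frame`s.
#' @return `data.frame` with columns `residue`, `d1`, `d2`, `D`,
#'   `undefined`.
#' @export
compositional_difference <- function(query, background) {
  d1 <- pooled_fraction(query)
  d2 <- pooled_fraction(background)
  D <- ifelse(d2 > 0, (d1 - d2) / d2, NA_real_)
  data.frame(residue = AA20, d1 = unname(d1), d2 = unname(d2),
             D = unname(D), undefined = unname(d2 == 0),
             stringsAsFactors = FALSE)
}

#' Per-residue enrichment/depletion test
#'
#' Bootstrap test of the compositional difference of every residue between
#' a query set (e.g. ER-resident proteins) and a background set. Sequences
#' are resampled with replacement within each set; each iteration
#' recomputes the pooled fractions, and the two-sided p-value of residue i
#' is taken from the position of 0 in the bootstrap distribution of
#' `d1_i - d2_i` (add-one corrected so p is in (0, 1]).
#'
#' @param query,background protein record `data.frame`s.
#' @param iterations bootstrap iterations (default 10000, minimum 100).
#' @param seed optional integer seed for reproducible resampling.
#' @param alpha significance level for the `significant` flag
#'   (default 0.05).
#' @param bonferroni if `TRUE`, multiply p-values by 20 (capped at 1)
#'   before flagging; off by default, matching the convention of reporting
#'   raw per-residue p-values.
#' @return `data.frame` with columns `residue`, `d1`, `d2`, `D`,
#'   `p_value`, `significant`, `low_confidence` (set when either set has a
#'   single sequence, where sequence-level resampling is degenerate).
#' @export
enrichment_test <- function(query, background, iterations = 10000L,
                            seed = NULL, alpha = 0.05, bonferroni = FALSE) {
  iterations <- as.integer(iterations)
  if (iterations < 100L) config_error("enrichment_test: iterations must be >= 100")
  if (!is.null(seed)) set.seed(as.integer(seed))
  base <- compositional_difference(query, background)
  Q <- residue_count_matrix(query)
  B <- residue_count_matrix(background)
  nq <- nrow(Q); nb <- nrow(B)
  delta <- matrix(0, iterations, 20L)
  for (it in seq_len(iterations)) {
    qc <- colSums(Q[sample.int(nq, nq, replace = TRUE), , drop = FALSE])
    bc <- colSums(B[sample.int(nb, nb, replace = TRUE), , drop = FALSE])
    delta[it, ] <- qc / sum(qc) - bc / sum(bc)
  }
  p <- vapply(seq_len(20L), function(j) {
    lo <- (1 + sum(delta[, j] <= 0)) / (iterations + 1)
    hi <- (1 + sum(delta[, j] >= 0)) / (iterations + 1)
    min(1, 2 * min(lo, hi))
  }, numeric(1))
  if (bonferroni) p <- pmin(1, p * 20)
  base$p_value <- p
  base$significant <- !is.na(base$D) & p <= alpha
  base$low_confidence <- nq < 2L || nb < 2L
  base
}

#' Write an enrichment profile as TSV
#'
#' One row per residue: `residue, d1, d2, D, p_value, significant` —
#' sufficient to redraw an enrichment/depletion bar profile.
#'
#' @param profile output of [enrichment_test()] (or
#'   [compositional_difference()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
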