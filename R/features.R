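#' Feature encoding schemes
#'
#' The six fixed-length encodings of a variable-length protein sequence:
#'
#' * `AAC` — whole-sequence amino acid composition, 20 percentages.
#' * `DIPEP` — dipeptide composition over sliding windows of width 2,
#'   400 percentages.
#' * `PSEAAC` — type-1 pseudo amino acid composition, 20 + lambda values on
#'   the unit scale.
#' * `NTER_SAAC` — split composition: 25 N-terminal residues | remainder,
#'   40 percentages.
#' * `CTER_SAAC` — split composition: 25 C-terminal residues | remainder,
#'   40 percentages.
#' * `SAAC3` — three-part split composition: 25 N-terminal | 25 C-terminal |
#'   middle, 60 percentages.
#'
#' @format Character vector of the six scheme names.
#' @export
FEATURE_SCHEMES <- c("AAC", "DIPEP", "PSEAAC", "NTER_SAAC", "CTER_SAAC", "SAAC3")

#' Dimension of a feature scheme
#'
#' @param scheme one of [FEATURE_SCHEMES].
#' @param lambda sequence-order rank for `PSEAAC`.
#' @return Integer vector length.
#' @export
scheme_dimension <- function(scheme, lambda = 1L) {
  scheme <- match.arg(scheme, FEATURE_SCHEMES)
  switch(scheme,
         AAC = 20L, DIPEP = 400L, PSEAAC = 20L + as.integer(lambda),
         NTER_SAAC = 40L, CTER_SAAC = 40L, SAAC3 = 60L)
}

# Residue counts in AA20 order for one sequence string
residue_counts <- function(seq) {
  tabulate(factor(seq_chars(seq), levels = AA20), nbins = 20L)
}

#' Amino acid composition (percent)
#'
#' The fraction of each of the 20 standard amino acids in the sequence,
#' expressed as a percentage: `100 * count_i / length`. Components are in
#' alphabetical one-letter-code order ([AA20]) and sum to 100.
#'
#' @param seq a validated sequence string.
#' @return Named numeric vector of length 20.
#' @export
aac <- function(seq) {
  L <- nchar(seq)
  if (L == 0L) input_error("aac: empty sequence")
  counts <- residue_counts(seq)
  if (sum(counts) != L) {
    input_error("aac: sequence contains non-standard residues; validate first")
  }
  stats::setNames(100 * counts / L, AA20)
}

#' Dipeptide composition (percent)
#'
#' Percentages of the 400 ordered residue pairs counted in sliding windows
#' of width 2 and step 1, so the denominator is `length - 1`. Components in
#' lexicographic pair order (AA, AC, ..., YY); they sum to 100.
#'
#' @param seq a validated sequence string of length >= 2.
#' @return Named numeric vector of length 400.
#' @export
dipeptide <- function(seq) {
  L <- nchar(seq)
  if (L < 2L) input_error("dipeptide: sequence shorter than 2 residues")
  pairs <- paste0(substring(seq, 1:(L - 1L), 1:(L - 1L)),
                  substring(seq, 2:L, 2:L))
  counts <- tabulate(factor(pairs, levels = aa_dipeptides()), nbins = 400L)
  if (sum(counts) != L - 1L) {
    input_error("dipeptide: sequence contains non-standard residues; validate first")
  }
  stats::setNames(100 * counts / (L - 1L), aa_dipeptides())
}

# Amino-acid property scales for pseudo amino acid composition:
# hydrophobicity, hydrophilicity (Hopp-Woods) and side-chain mass, the three
# scales used by Chou's original type-1 formulation and by PseAAC-Builder's
# default mode. Values in AA20 order.
pseaac_properties <- function() {
  h1 <- c(A =  0.62, C =  0.29, D = -0.90, E = -0.74, F =  1.19,
          G =  0.48, H = -0.40, I =  1.38, K = -1.50, L =  1.06,
          M =  0.64, N = -0.78, P =  0.12, Q = -0.85, R = -2.53,
          S = -0.18, T = -0.05, V =  1.08, W =  0.81, Y =  0.26)
  h2 <- c(A = -0.5, C = -1.0, D =  3.0, E =  3.0, F = -2.5,
          G =  0.0, H = -0.5, I = -1.8, K =  3.0, L = -1.8,
          M = -1.3, N =  0.2, P =  0.0, Q =  0.2, R =  3.0,
          S =  0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3)
  m  <- c(A =  15, C =  47, D =  59, E =  73, F =  91,
          G =   1, H =  82, I =  57, K =  73, L =  57,
          M =  75, N =  58, P =  42, Q =  72, R = 101,
          S =  31, T =  45, V =  43, W = 130, Y = 107)
  # standardize each scale to zero mean, unit (population) SD over the 20
  # residues before use
  std <- function(x) (x - mean(x)) / sqrt(sum((x - mean(x))^2) / 20)
  rbind(hydrophobicity = std(h1[AA20]),
        hydrophilicity = std(h2[AA20]),
        sidechain_mass = std(m[AA20]))
}

#' Type-1 pseudo amino acid composition
#'
#' Chou's type-1 PseAAC: the 20 normalized residue frequencies augmented
#' with `lambda` sequence-order correlation factors. The correlation factor
#' of rank j is `tau_j = mean_i Theta(R_i, R_(i+j))`, where
#' `Theta(a, b)` is the mean of squared differences of standardized
#' hydrophobicity, hydrophilicity and side-chain mass between residues a
#' and b. Components are `p_u = f_u / (1 + w * sum(tau))` for the 20
#' frequency terms and `p_(20+j) = w * tau_j / (1 + w * sum(tau))`, so the
#' whole vector sums to 1. With `lambda = 0` the vector reduces to
#' `aac(seq) / 100`.
#'
#' @param seq a validated sequence string with `nchar(seq) > lambda`.
#' @param lambda sequence-order rank (default 1).
#' @param w weight factor for the correlation terms (default 0.05).
#' @return Named numeric vector of length `20 + lambda`.
#' @export
pseaac <- function(seq, lambda = 1L, w = 0.05) {
  lambda <- as.integer(lambda)
  if (lambda < 0L) config_error("pseaac: lambda must be >= 0")
  if (w <= 0) config_error("pseaac: weight factor must be > 0")
  L <- nchar(seq)
  if (L <= lambda) {
    input_error(sprintf("pseaac: sequence length %d must exceed lambda = %d",
                        L, lambda))
  }
  f <- aac(seq) / 100
  if (lambda == 0L) return(f)
  props <- pseaac_properties()
  idx <- match(seq_chars(seq), AA20)
  prop_seq <- props[, idx, drop = FALSE]  # 3 x L
  tau <- vapply(seq_len(lambda), function(j) {
    d <- prop_seq[, (1L + j):L, drop = FALSE] -
         prop_seq[, 1L:(L - j), drop = FALSE]
    mean(colMeans(d^2))
  }, numeric(1))
  denom <- 1 + w * sum(tau)
  stats::setNames(c(f, w * tau) / denom,
                  c(AA20, paste0("lambda", seq_len(lambda))))
}

#' Split a sequence into N-terminal, middle and C-terminal parts
#'
#' Exact non-overlapping partition: the first `n` residues, the last `n`
#' residues, and the (non-empty) interior. Requires `nchar(seq) >= 2n + 1`.
#'
#' @param seq a validated sequence string.
#' @param n terminal segment size (default 25).
#' @return A list with components `n_part`, `r_part` (middle), `c_part`, `n`.
#' @export
split_3 <- function(seq, n = 25L) {
  n <- as.integer(n)
  if (n < 1L) config_error("split_3: n must be >= 1")
  L <- nchar(seq)
  if (L < 2L * n + 1L) {
    input_error(sprintf(
      "split_3: sequence length %d < 2*%d + 1; cannot form three non-empty parts",
      L, n))
  }
  list(n_part = substr(seq, 1L, n),
       r_part = substr(seq, n + 1L, L - n),
       c_part = substr(seq, L - n + 1L, L),
       n = n)
}

#' Three-part split amino acid composition
#'
#' Per-part amino acid composition of the `n` N-terminal residues, the `n`
#' C-terminal residues and the middle of the sequence, concatenated in the
#' order N-terminal | C-terminal | middle. Each 20-component block is a
#' percentage composition summing to 100; the full vector has 60 components
#' at the default `n = 25`.
#'
#' @inheritParams split_3
#' @return Named numeric vector of length 60 (`Nterm_*`, `Cterm_*`, `Rem_*`).
#' @export
saac3 <- function(seq, n = 25L) {
  parts <- split_3(seq, n)
  v <- c(aac(parts$n_part), aac(parts$c_part), aac(parts$r_part))
  names(v) <- c(paste0("Nterm_", AA20), paste0("Cterm_", AA20),
                paste0("Rem_", AA20))
  v
}

#' Two-part split amino acid compositions
#'
#' `saac_nter()` concatenates the composition of the `n` N-terminal residues
#' with that of the remaining residues; `saac_cter()` does the same for the
#' `n` C-terminal residues. Each returns 40 values (two 20-blocks, each
#' summing to 100). Requires `nchar(seq) >= n + 1`.
#'
#' @inheritParams split_3
#' @return Named numeric vector of length 40.
#' @export
saac_nter <- function(seq, n = 25L) {
  n <- as.integer(n)
  L <- nchar(seq)
  if (L <= n) {
    input_error(sprintf("saac_nter: sequence length %d must exceed n = %d", L, n))
  }
  v <- c(aac(substr(seq, 1L, n)), aac(substr(seq, n + 1L, L)))
  names(v) <- c(paste0("Nterm_", AA20), paste0("Rest_", AA20))
  v
}

#' @rdname saac_nter
#' @export
saac_cter <- function(seq, n = 25L) {
  n <- as.integer(n)
  L <- nchar(seq)
  if (L <= n) {
    input_error(sprintf("saac_cter: sequence length %d must exceed n = %d", L, n))
  }
  v <- c(aac(substr(seq, L - n + 1L, L)), aac(substr(seq, 1L, L - n)))
  names(v) <- c(paste0("Cterm_", AA20), paste0("Rest_", AA20))
  v
}

#' Encode a batch of records under one scheme
#'
#' @param records protein record `data.frame` (validated).
#' @param scheme one of [FEATURE_SCHEMES].
#' @param n terminal segment size for the split schemes.
#' @param lambda,w pseudo amino acid composition parameters.
#' @return Numeric matrix, one row per record in input order, row names =
#'   record ids, column names = scheme-specific feature names.
#' @export
encode_batch <- function(records, scheme, n = 25L, lambda = 1L, w = 0.05) {
  scheme <- match.arg(scheme, FEATURE_SCHEMES)
  enc <- switch(scheme,
                AAC = function(s) aac(s),
                DIPEP = function(s) dipeptide(s),
                PSEAAC = function(s) pseaac(s, lambda = lambda, w = w),
                NTER_SAAC = function(s) saac_nter(s, n = n),
                CTER_SAAC = function(s) saac_cter(s, n = n),
                SAAC3 = function(s) saac3(s, n = n))
  dim <- scheme_dimension(scheme, lambda)
  if (nrow(records) == 0L) {
    return(matrix(numeric(0), nrow = 0L, ncol = dim))
  }
  rows <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    rows[[i]] <- tryCatch(enc(records$sequence[i]), error = function(e) {
      input_error(sprintf("encode_batch: record '%s' cannot be encoded under %s: %s",
                          records$id[i], scheme, conditionMessage(e)))
    })
  }
  X <- do.call(rbind, rows)
  rownames(X) <- records$id
  X
}

#' Write a feature matrix as TSV
#'
#' @param X matrix from [encode_batch()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features_tsv <- function(X, path) {
  df <- data.frame(id = rownames(X), X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
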