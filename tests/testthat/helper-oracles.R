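# Independent reference implementations used as oracles. These are written
# as plain character-counting loops and regex translations on purpose: they
# share no code with the package internals they check.

AAS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_seq <- function(len, alphabet = AAS) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

rand_records <- function(n, len_range = c(51, 200)) {
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  protein_records(id = sprintf("R%03d", seq_len(n)),
                  sequence = vapply(lens, rand_seq, character(1)))
}

# --- naive composition references -------------------------------------

naive_aac <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  out <- numeric(20)
  for (k in 1:20) out[k] <- 100 * sum(ch == AAS[k]) / length(ch)
  names(out) <- AAS
  out
}

naive_dipep <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  pairs <- as.vector(outer(AAS, AAS, function(a, b) paste0(a, b)))
  pairs <- sort(pairs)  # lexicographic
  out <- stats::setNames(numeric(400), pairs)
  for (i in 1:(L - 1)) {
    dp <- paste0(ch[i], ch[i + 1])
    out[dp] <- out[dp] + 1
  }
  100 * out / (L - 1)
}

naive_saac3 <- function(seq, n = 25) {
  L <- nchar(seq)
  c(naive_aac(substring(seq, 1, n)),
    naive_aac(substring(seq, L - n + 1, L)),
    naive_aac(substring(seq, n + 1, L - n)))
}

naive_nter <- function(seq, n = 25) {
  L <- nchar(seq)
  c(naive_aac(substring(seq, 1, n)), naive_aac(substring(seq, n + 1, L)))
}

naive_cter <- function(seq, n = 25) {
  L <- nchar(seq)
  c(naive_aac(substring(seq, L - n + 1, L)), naive_aac(substring(seq, 1, L - n)))
}

# Hand evaluation of the type-1 pseudo amino acid composition, looping over
# positions with the three standardized property scales written out inline.
naive_pseaac <- function(seq, lam = 1, w = 0.05) {
  hb <- c(A = 0.62, C = 0.29, D = -0.9, E = -0.74, F = 1.19, G = 0.48,
          H = -0.4, I = 1.38, K = -1.5, L = 1.06, M = 0.64, N = -0.78,
          P = 0.12, Q = -0.85, R = -2.53, S = -0.18, T = -0.05, V = 1.08,
          W = 0.81, Y = 0.26)
  hl <- c(A = -0.5, C = -1, D = 3, E = 3, F = -2.5, G = 0, H = -0.5,
          I = -1.8, K = 3, L = -1.8, M = -1.3, N = 0.2, P = 0, Q = 0.2,
          R = 3, S = 0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3)
  mm <- c(A = 15, C = 47, D = 59, E = 73, F = 91, G = 1, H = 82, I = 57,
          K = 73, L = 57, M = 75, N = 58, P = 42, Q = 72, R = 101, S = 31,
          T = 45, V = 43, W = 130, Y = 107)
  z <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  hb <- z(hb[AAS]); hl <- z(hl[AAS]); mm <- z(mm[AAS])
  theta <- function(a, b) {
    ((hb[b] - hb[a])^2 + (hl[b] - hl[a])^2 + (mm[b] - mm[a])^2) / 3
  }
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  f <- numeric(20)
  for (k in 1:20) f[k] <- sum(ch == AAS[k]) / L
  tau <- numeric(lam)
  for (j in seq_len(lam)) {
    s <- 0
    for (i in 1:(L - j)) s <- s + theta(ch[i], ch[i + j])
    tau[j] <- s / (L - j)
  }
  unname(c(f, w * tau) / (1 + w * sum(tau)))
}

# --- PROSITE -> regex oracle -------------------------------------------

prosite_regex <- function(pattern) {
  pat <- sub("\\.$", "", gsub("\\s", "", pattern))
  nanch <- grepl("^<", pat); pat <- sub("^<", "", pat)
  canch <- grepl(">$", pat); pat <- sub(">$", "", pat)
  parts <- strsplit(pat, "-", fixed = TRUE)[[1]]
  rx <- vapply(parts, function(el) {
    rep <- ""
    if (grepl("\\(", el)) {
      rep <- sub("^.*\\((\\d+(,\\d+)?)\\)$", "{\\1}", el)
      el <- sub("\\(.*$", "", el)
    }
    core <- if (el == "x") "." else if (grepl("^\\{", el)) {
      paste0("[^", substr(el, 2, nchar(el) - 1), "]")
    } else if (grepl("^\\[", el)) el else el
    paste0(core, rep)
  }, character(1))
  list(regex = paste0(rx, collapse = ""), nanch = nanch, canch = canch)
}

# all matches, one per start position, via the translated regex
regex_scan <- function(seq, pattern) {
  o <- prosite_regex(pattern)
  L <- nchar(seq)
  starts <- if (o$nanch) 1L else seq_len(L)
  hits <- list()
  for (s in starts) {
    tail <- substring(seq, s)
    rx <- if (o$canch) paste0("^(", o$regex, ")$") else paste0("^(", o$regex, ")")
    m <- regexpr(rx, tail, perl = TRUE)
    if (m[1] == 1) {
      hits[[length(hits) + 1]] <-
        c(start = s, end = s + attr(m, "match.length") - 1L)
    }
  }
  if (!length(hits)) return(matrix(integer(), 0, 2))
  do.call(rbind, hits)
}

# --- metric oracles ----------------------------------------------------

brute_metrics <- function(tp, tn, fp, fn) {
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  list(sens = if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn),
       spec = if (tn + fp == 0) NA_real_ else 100 * tn / (tn + fp),
       acc = 100 * (tp + tn) / (tp + tn + fp + fn),
       mcc = {
         d <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
         if (d == 0) 0 else (tp * tn - fp * fn) / sqrt(d)
       })
}

# AUC as the pairwise rank statistic, ties counted one half
rank_auc <- function(scores, labels) {
  sp <- scores[labels == "positive"]
  sn <- scores[labels == "negative"]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

write_temp_fasta <- function(records, dir = tempdir()) {
  f <- tempfile(tmpdir = dir, fileext = ".fasta")
  write_fasta(records, f)
  f
}

no_bias <- stats::setNames(numeric(0), character(0))
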