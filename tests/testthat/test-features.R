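test_that("amino acid composition matches worked examples and is order-invariant", {
  v <- aac("KDEL")
  expect_equal(unname(v[c("K", "D", "E", "L")]), rep(25, 4))
  expect_equal(sum(v), 100)
  expect_equal(unname(aac("AAAA")["A"]), 100)
  set.seed(1)
  s <- rand_seq(120)
  perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  expect_identical(aac(s), aac(perm))
  expect_error(aac(""), class = "erpred_input_error")
})

test_that("dipeptide composition counts overlapping windows", {
  v <- dipeptide("AAA")
  expect_equal(unname(v["AA"]), 100)
  v2 <- dipeptide("ACAC")
  expect_equal(unname(v2["AC"]), 100 * 2 / 3)
  expect_equal(unname(v2["CA"]), 100 * 1 / 3)
  expect_length(dipeptide(rand_seq(60)), 400L)
  expect_error(dipeptide("A"), class = "erpred_input_error")
})

test_that("three-part split partitions exactly and propagates errors", {
  set.seed(2)
  s <- rand_seq(60)
  p <- split_3(s)
  expect_equal(nchar(p$n_part), 25L)
  expect_equal(nchar(p$c_part), 25L)
  expect_equal(nchar(p$r_part), 10L)
  expect_equal(paste0(p$n_part, p$r_part, p$c_part), s)
  p51 <- split_3(rand_seq(51))
  expect_equal(nchar(p51$r_part), 1L)
  expect_error(split_3(rand_seq(50)), class = "erpred_input_error")
})

test_that("split compositions place each terminus in its declared block", {
  s <- paste0(strrep("A", 25), strrep("C", 10), strrep("D", 25))
  v <- saac3(s)
  expect_equal(unname(v["Nterm_A"]), 100)
  expect_equal(unname(v["Cterm_D"]), 100)
  expect_equal(unname(v["Rem_C"]), 100)
  expect_length(v, 60L)
  # every 20-block sums to 100
  expect_equal(as.vector(tapply(v, rep(1:3, each = 20), sum)), rep(100, 3),
               tolerance = 1e-12)

  n <- saac_nter(paste0(strrep("A", 25), strrep("C", 30)))
  expect_equal(unname(n[c("Nterm_A", "Rest_C")]), c(100, 100))
  c2 <- saac_cter(paste0(strrep("A", 30), strrep("C", 25)))
  expect_equal(unname(c2[c("Cterm_C", "Rest_A")]), c(100, 100))
  expect_length(n, 40L)
  expect_length(c2, 40L)

  # shuffling the middle part leaves the vector unchanged
  set.seed(3)
  s2 <- rand_seq(120)
  mid <- substring(s2, 26, 95)
  shuf <- paste0(substring(s2, 1, 25),
                 paste(sample(strsplit(mid, "")[[1]]), collapse = ""),
                 substring(s2, 96, 120))
  expect_identical(saac3(s2), saac3(shuf))
})

test_that("pseudo amino acid composition follows the type-1 formulation", {
  # dimension 20 + lambda, unit sum
  set.seed(4)
  s <- rand_seq(80)
  v <- pseaac(s, lambda = 1)
  expect_length(v, 21L)
  expect_equal(sum(v), 1, tolerance = 1e-12)
  v5 <- pseaac(s, lambda = 5)
  expect_length(v5, 25L)
  # homopolymer: identical residues have zero correlation
  h <- pseaac(strrep("A", 60), lambda = 1)
  expect_equal(unname(h["A"]), 1)
  expect_equal(unname(h["lambda1"]), 0)
  expect_equal(sum(h[setdiff(names(h), "A")]), 0)
  # lambda = 0 reduces to plain normalized composition
  expect_equal(unname(pseaac(s, lambda = 0)), unname(aac(s) / 100))
  expect_error(pseaac(rand_seq(3), lambda = 3), class = "erpred_input_error")
})

test_that("all six encoders agree with naive counting references", {
  set.seed(5)
  n_cases <- 1000
  lens <- sample(51:300, n_cases, replace = TRUE)
  max_err <- 0
  for (i in seq_len(n_cases)) {
    s <- rand_seq(lens[i])
    errs <- c(
      max(abs(aac(s) - naive_aac(s))),
      max(abs(dipeptide(s) - naive_dipep(s))),
      max(abs(unname(saac3(s)) - unname(naive_saac3(s)))),
      max(abs(unname(saac_nter(s)) - unname(naive_nter(s)))),
      max(abs(unname(saac_cter(s)) - unname(naive_cter(s)))))
    max_err <- max(max_err, errs)
  }
  expect_lt(max_err, 1e-9)
  # the pseudo-composition reference is slower; spot-check a subsample
  for (i in seq_len(200)) {
    s <- rand_seq(sample(51:150, 1))
    expect_equal(unname(pseaac(s, lambda = 3)), naive_pseaac(s, lam = 3),
                 tolerance = 1e-9)
  }
})

test_that("batch encoding preserves order and reports offending records", {
  set.seed(6)
  rec <- rand_records(3)
  X <- encode_batch(rec, "AAC")
  expect_equal(dim(X), c(3L, 20L))
  expect_equal(rownames(X), rec$id)
  expect_equal(X[2, ], aac(rec$sequence[2]))

  empty <- encode_batch(rec[0, ], "SAAC3")
  expect_equal(nrow(empty), 0L)
  expect_equal(ncol(empty), 60L)

  rec$sequence[2] <- rand_seq(50)
  expect_error(encode_batch(rec, "SAAC3"), rec$id[2],
               class = "erpred_input_error")
})

test_that("scheme dimensions are as declared", {
  expect_equal(scheme_dimension("AAC"), 20L)
  expect_equal(scheme_dimension("DIPEP"), 400L)
  expect_equal(scheme_dimension("PSEAAC", lambda = 4), 24L)
  expect_equal(scheme_dimension("NTER_SAAC"), 40L)
  expect_equal(scheme_dimension("CTER_SAAC"), 40L)
  expect_equal(scheme_dimension("SAAC3"), 60L)
})
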