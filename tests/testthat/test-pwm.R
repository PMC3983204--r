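test_that("raw frequencies are counted per offset from the C-terminus", {
  pwm <- toy_pwm(kappa = 0)
  # offset 0 (last residue): V x3, I x1
  expect_equal(unname(pwm$mat["0", c("V", "I")]), c(0.75, 0.25))
  expect_equal(sum(pwm$mat["0", setdiff(AA_ALPHABET, c("V", "I"))]), 0)
  # offset 2: T x3, S x1
  expect_equal(unname(pwm$mat["2", c("T", "S")]), c(0.75, 0.25))
  # offset 1 is invariant W
  expect_equal(unname(pwm$mat["1", "W"]), 1)
  # offsets beyond the longest peptide are uniform with zero information
  expect_equal(unname(pwm$mat["4", ]), rep(0.05, 20), ignore_attr = TRUE)
  expect_equal(unname(pwm$ic[c("4", "5", "6")]), rep(0, 3),
               ignore_attr = TRUE)
})

test_that("single-symbol columns are one-hot with maximal information", {
  pwm <- build_pwm(rep("AAAAAAA", 5), kappa = 0)
  for (n in as.character(0:6)) {
    expect_equal(unname(pwm$mat[n, "A"]), 1)
  }
  expect_equal(unname(pwm$ic), rep(log2(20), 7), tolerance = 1e-12)
})

test_that("information content matches direct entropy computation", {
  onehot <- c(1, rep(0, 19))
  expect_equal(position_information_content(onehot), log2(20))
  expect_equal(position_information_content(rep(0.05, 20)), 0)
  f <- c(0.75, 0.25, rep(0, 18))
  expect_equal(position_information_content(f),
               log2(20) - (-0.75 * log2(0.75) - 0.25 * log2(0.25)),
               tolerance = 1e-12)
  expect_equal(round(position_information_content(f), 4), 3.5106)
  expect_error(position_information_content(c(-0.1, 1.1, rep(0, 18))),
               "negative")
  expect_error(position_information_content(rep(0.1, 20)), "sum to 1")
})

test_that("degenerate alignments are rejected with informative errors", {
  expect_error(build_pwm(character(0)), "empty alignment")
  expect_error(build_pwm(c("ETWV", "")), "empty alignment")
  expect_error(build_pwm(c("ETWV", "ETXV")), "ETXV")
  expect_error(build_pwm("ETWVGETWV"), "longer")
})

test_that("rows are stochastic for all pseudocount settings", {
  for (mode in c("proportional", "inverse", "flat")) {
    for (kappa in c(0, 0.5, 1, 5, 100)) {
      pwm <- toy_pwm(kappa = kappa, mode = mode)
      expect_true(all(pwm$mat >= 0))
      expect_equal(unname(rowSums(pwm$mat)), rep(1, 7), tolerance = 1e-9)
    }
  }
})

test_that("pseudocount weight follows the selected mode", {
  # offset 1 of the toy alignment is one-hot (w = IC = log2 20 under
  # proportional); under flat the added mass is kappa/20 per residue
  kappa <- 2
  prop <- toy_pwm(kappa = kappa, mode = "proportional")
  flat <- toy_pwm(kappa = kappa, mode = "flat")
  inv <- toy_pwm(kappa = kappa, mode = "inverse")
  n_pep <- 4
  expect_equal(unname(prop$mat["1", "A"]),
               (kappa * log2(20) / 20) / (n_pep + kappa * log2(20)))
  expect_equal(unname(flat$mat["1", "A"]),
               (kappa / 20) / (n_pep + kappa))
  # an exactly one-hot column gets no inverse-mode smoothing
  expect_equal(unname(inv$mat["1", "W"]), 1)
})

test_that("scoring sums log10 probabilities anchored at the C-terminus", {
  pwm <- toy_pwm(kappa = 0)
  expect_equal(score_cterm(pwm, "ETWV"), 3 * log10(0.75))
  expect_equal(score_cterm(pwm, "ESWV"), 2 * log10(0.75) + log10(0.25))
  # uniform model scores any full-length 7-mer at 7*log10(0.05)
  uni <- build_pwm("A", kappa = 1e9, pseudocount_mode = "flat")
  expect_equal(score_cterm(uni, "GETWVAA"), 7 * log10(0.05),
               tolerance = 1e-6)
  # perfect consensus under a one-hot PWM scores 0
  expect_equal(score_cterm(onehot_pwm(), "GETWVAA"), 0)
  # short sequences use only their available offsets
  pwm4 <- toy_pwm(kappa = 0)
  expect_equal(score_cterm(pwm4, "WV"),
               log10(1) + log10(0.75))
  expect_error(score_cterm(pwm4, ""), "empty")
  expect_error(score_cterm(pwm4, "ETZV"), "invalid residue")
})

test_that("scores are never positive and zero only at probability-1 path", {
  set.seed(7)
  pwm <- build_pwm(simulate_peptides(simulate_pwm(seed = 3), 40, seed = 4),
                   kappa = 1)
  for (i in 1:25) {
    s <- paste(sample(AA_ALPHABET, 7, replace = TRUE), collapse = "")
    expect_lte(score_cterm(pwm, s), 0)
  }
  expect_lt(score_cterm(pwm, "AAAAAAA"), 0)
  expect_equal(score_cterm(onehot_pwm("GETWVAA"), "GETWVAA"), 0)
})

test_that("replacing a residue by a higher-probability one raises the score", {
  pwm <- toy_pwm(kappa = 1)
  # at offset 0, V (count 3) beats I (count 1) beats A (count 0)
  s_v <- score_cterm(pwm, "ETWV")
  s_i <- score_cterm(pwm, "ETWI")
  s_a <- score_cterm(pwm, "ETWA")
  expect_true(s_v > s_i && s_i > s_a)
})

test_that("consensus is the argmax with alphabetical tie-break", {
  expect_equal(pwm_consensus(onehot_pwm("GETWVAA")), "GETWVAA")
  # uniform rows tie; alphabetical order gives all-A
  uni <- build_pwm("A", kappa = 1e9, pseudocount_mode = "flat")
  expect_equal(pwm_consensus(uni), "AAAAAAA")
  pwm <- toy_pwm(kappa = 0)
  expect_equal(substr(pwm_consensus(pwm), 5, 7), "TWV")
})

test_that("consensus scores at least as high as any sequence (toy exhaustive)", {
  # two-letter alphabet: enumerate all 2^7 sequences over {A, C}
  pwm <- build_pwm(c("AACACAA", "ACCACAA", "AACCCAA", "AACACCA", "CACACAA"),
                   kappa = 1)
  cons <- pwm_consensus(pwm)
  s_cons <- score_cterm(pwm, cons)
  grid <- expand.grid(rep(list(c("A", "C")), 7), stringsAsFactors = FALSE)
  all_scores <- apply(grid, 1, function(ch) {
    score_cterm(pwm, paste(ch, collapse = ""))
  })
  expect_true(all(s_cons >= all_scores))
})

test_that("score_all covers the Cartesian product in input order", {
  pwms <- lapply(1:3, function(i) simulate_pwm(paste0("D", i), seed = i))
  ct <- tibble::tibble(
    protein_id = c("P1", "P2"), isoform_id = c("P1.1", "P2.1"),
    cterm = c("GETWVAA", "MKTLEDS")
  )
  sm <- score_all(pwms, ct)
  expect_equal(nrow(sm), 6)
  expect_equal(unique(sm$domain_id), c("D1", "D2", "D3"))
  expect_equal(sm$score[sm$domain_id == "D2" & sm$protein_id == "P1"],
               score_cterm(pwms[[2]], "GETWVAA"))
  # permuting the C-terminus input permutes rows within domains only
  sm2 <- score_all(pwms, ct[2:1, ])
  expect_equal(
    dplyr::arrange(sm, domain_id, protein_id),
    dplyr::arrange(sm2, domain_id, protein_id)
  )
  # singleton product equals score_cterm
  one <- score_all(pwms[[1]], "GETWVAA")
  expect_equal(nrow(one), 1)
  expect_equal(one$score, score_cterm(pwms[[1]], "GETWVAA"))
  expect_error(score_all(pwms, tibble::tibble(cterm = character())),
               "at least one")
})

test_that("JSON serialization round-trips a PWM", {
  pwm <- toy_pwm(kappa = 1.5, mode = "inverse")
  path <- withr::local_tempfile(fileext = ".json")
  write_pwm_json(pwm, path)
  back <- read_pwm_json(path)
  expect_equal(back$domain_id, pwm$domain_id)
  expect_equal(back$kappa, pwm$kappa)
  expect_equal(back$pseudocount_mode, pwm$pseudocount_mode)
  expect_equal(unname(back$mat), unname(pwm$mat), tolerance = 1e-12)
  expect_equal(score_cterm(back, "ETWV"), score_cterm(pwm, "ETWV"))
})

test_that("peptide files read as FASTA or plain lines", {
  plain <- withr::local_tempfile(fileext = ".txt")
  writeLines(toy_peptides, plain)
  p1 <- read_peptides(plain, domain_id = "toy")
  expect_equal(p1$peptide, toy_peptides)

  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(paste0(">pep", seq_along(toy_peptides), "\n", toy_peptides), fa)
  p2 <- read_peptides(fa, domain_id = "toy")
  expect_equal(p2$peptide, toy_peptides)

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("ETWV", "ET*V"), bad)
  expect_error(read_peptides(bad), "invalid residue")
})

test_that("tidy and autoplot work on a PWM", {
  pwm <- toy_pwm(kappa = 1)
  td <- tidy(pwm)
  expect_equal(nrow(td), 140)
  expect_equal(sum(td$prob), 7, tolerance = 1e-9)
  expect_s3_class(autoplot(pwm), "ggplot")
})
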