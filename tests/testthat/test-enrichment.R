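test_that("binomial enrichment matches brute-force pmf summation", {
  set.seed(21)
  for (i in 1:40) {
    region <- sample(10:2000, 1)
    total <- region + sample(100:8000, 1)
    n_tr <- sample(50:total, 1)
    k <- rbinom(1, region, n_tr / total)
    for (side in c("greater", "less", "two")) {
      got <- binomial_enrichment(k, n_tr, region, total, sidedness = side)
      want <- oracle_binom(k, region, n_tr / total, side)
      expect_equal(got$p_value, want, tolerance = 1e-3,
                   label = sprintf("k=%d region=%d side=%s", k, region, side))
      expect_equal(got$expected, region * n_tr / total)
    }
  }
})

test_that("binomial edge cases behave exactly", {
  # zero observed, greater tail: p = 1 exactly
  expect_equal(binomial_enrichment(0, 1, 1, 2, "greater")$p_value, 1)
  expect_error(binomial_enrichment(5, 10, 3, 0), "total_aa")
  expect_error(binomial_enrichment(0, 10, 1, 2), "density")
  expect_error(binomial_enrichment(5, 10, 30, 20), "region_aa")
  expect_error(binomial_enrichment(11, 10, 3, 20), "k_observed")
})

test_that("fisher overlap equals the hypergeometric tail", {
  # exhaustively enumerable case: universe 10, 5 hits, sample 2, both hits
  got <- fisher_overlap(10, 5, 2, 2)
  expect_equal(got$p_value, choose(5, 2) / choose(10, 2), tolerance = 1e-9)
  expect_equal(round(got$p_value, 4), 0.2222)

  set.seed(22)
  for (i in 1:1000) {
    u <- sample(10:400, 1)
    uh <- sample(0:u, 1)
    s <- sample(1:min(u, 50), 1)
    sh_range <- max(0, s + uh - u):min(s, uh)
    sh <- sh_range[sample.int(length(sh_range), 1)]
    got <- fisher_overlap(u, uh, s, sh)$p_value
    want <- oracle_hyper_upper(sh, u, uh, s)
    expect_equal(got, want, tolerance = 1e-6,
                 label = sprintf("u=%d uh=%d s=%d sh=%d", u, uh, s, sh))
  }

  expect_error(fisher_overlap(10, 5, 2, 3), "negative cell")
})

test_that("threshold sweep counts a hand-countable fixture", {
  # 10 C-termini; scores chosen so exactly 2 exceed t = -5
  pro <- tibble::tibble(
    protein_id = sprintf("P%02d", 1:10),
    isoform_id = sprintf("P%02d.1", 1:10),
    sequence = replicate(10, paste(
      sample(AA_ALPHABET, 20, replace = TRUE), collapse = ""
    ))
  )
  ct <- extract_ctermini(pro)
  scores <- tibble::tibble(
    domain_id = "d1",
    isoform_id = ct$isoform_id,
    cterm = ct$cterm,
    score = c(-4, -4.5, rep(-9, 8))
  )
  # 12 distinct C-terminal variants, 3 of them in the two qualifying windows
  variants <- tibble::tibble(
    variant_id = sprintf("v%02d", 1:12),
    isoform_id = c("P01.1", "P01.1", "P02.1",
                   sprintf("P%02d.1", c(3:10, 3)))
  )
  sw <- sweep_motif_thresholds(scores, ct, variants, thresholds = c(-5, -20, 0))
  row <- sw[sw$threshold == -5, ]
  expect_equal(row$n_ctermini, 2L)
  expect_equal(row$n_variants, 3L)
  expect_equal(row$n_aa, 14L)
  expect_equal(row$ratio, 3 / 14, tolerance = 1e-12)
  expect_equal(row$p_value, pbinom(3, 14, 12 / 70), tolerance = 1e-12)

  # threshold below every score: everything qualifies, density = background
  low <- sw[sw$threshold == -20, ]
  expect_equal(low$n_ctermini, 10L)
  expect_equal(low$n_variants, 12L)
  expect_equal(low$ratio, 12 / 70)
  expect_gt(low$p_value, 0.4)   # at the expectation: no depletion signal

  # threshold above every score: no motifs, ratio and p undefined
  high <- sw[sw$threshold == 0, ]
  expect_equal(high$n_variants, 0L)
  expect_true(is.na(high$ratio))
  expect_true(is.na(high$p_value))

  # monotonicity over a fine grid
  sw2 <- sweep_motif_thresholds(scores, ct, variants,
                                thresholds = seq(-12, -4, by = 0.1))
  expect_true(all(diff(sw2$n_variants) >= 0))   # descending threshold order
  expect_true(all(diff(sw2$n_aa) >= 0))

  expect_error(
    sweep_motif_thresholds(scores, ct, variants, thresholds = numeric()),
    "empty threshold grid"
  )
})

test_that("randomization null matches exhaustive substitution enumeration", {
  # single variant, one informative position: the exact null disruption
  # probability is (# of the 19 substitutions crossing both thresholds)/19
  pwm <- onehot_pwm("GETWVAA")
  pro <- tibble::tibble(
    protein_id = "M1", isoform_id = "M1.1",
    sequence = paste0(strrep("K", 13), "GETWVAA")
  )
  v <- tibble::tibble(
    variant_id = "v1", protein_id = "M1", isoform_id = "M1.1",
    position = 17L, ref_aa = "W", alt_aa = "C", kind = "missense"
  )
  rd <- randomized_disruption_fraction(
    v, pro, pwm, s_min = -8.3, s_max_grid = c(-6.4, -5),
    n_reps = 400, seed = 99L
  )
  # every one of the 19 substitutions sends the score to -Inf: null mean 1
  expect_equal(rd$observed_fraction, c(1, 1))
  expect_equal(rd$null_mean, c(1, 1))
  expect_equal(rd$null_sd, c(0, 0))

  # a kappa-smoothed PWM where only some substitutions cross s_min
  pwm2 <- build_pwm(
    c("GETWVAA", "GETWVAA", "GETWVAA", "GETWVAC", "GETWVAD", "GETWVAE",
      "GETWVAF", "GETWVAG", "GETWVAH", "GETWVAI"),
    domain_id = "soft", kappa = 0
  )
  # offset 0 probabilities: A 0.3, each of C,D,E,F,G,H,I 0.1, rest 0
  base <- score_cterm(pwm2, "GETWVA")  # offsets 1..6 of GETWVAA
  v2 <- v
  v2$position <- 20L; v2$ref_aa <- "A"; v2$alt_aa <- "C"
  s_min <- -3; s_max <- -1
  wt <- score_cterm(pwm2, "GETWVAA")
  subs <- setdiff(AA_ALPHABET, "A")
  cross <- vapply(subs, function(a) {
    m <- score_cterm(pwm2, paste0("GETWVA", a))
    wt > s_max && m < s_min
  }, logical(1))
  exact <- mean(cross)
  rd2 <- randomized_disruption_fraction(
    v2, pro, pwm2, s_min = s_min, s_max_grid = s_max,
    n_reps = 1000, seed = 5L
  )
  se <- sqrt(exact * (1 - exact) / 1000)
  expect_lt(abs(rd2$null_mean - exact), 3 * se + 1e-9)

  # determinism: identical seed, identical summary
  rd3 <- randomized_disruption_fraction(
    v2, pro, pwm2, s_min = s_min, s_max_grid = s_max,
    n_reps = 1000, seed = 5L
  )
  expect_identical(rd2, rd3)

  # zero variants: zero fractions, zero sd, no error
  rd0 <- randomized_disruption_fraction(
    v[0, ], pro, pwm, n_reps = 10, seed = 1L
  )
  expect_equal(rd0$observed_fraction, rep(0, nrow(rd0)))
  expect_equal(rd0$null_sd, rep(0, nrow(rd0)))
})

test_that("observed curve is calibrated against its own null", {
  # alt residues drawn from the same null the randomizer uses: the observed
  # curve must sit within 3 standard errors of the null mean
  bundle <- default_bundle(seed = 3L)
  pro <- bundle$proteome
  pwms <- bundle$truth$pwms
  mis <- bundle$variants[bundle$variants$kind == "missense", ]
  mis <- variant_in_cterm(mis, pro)
  mis <- mis[mis$in_cterm, ]
  # redraw alt residues uniformly from the 19 non-reference residues
  set.seed(77)
  mis$alt_aa <- vapply(mis$ref_aa, function(r) {
    sample(setdiff(AA_ALPHABET, r), 1)
  }, character(1))
  mis <- mis[, c("variant_id", "protein_id", "isoform_id", "position",
                 "ref_aa", "alt_aa", "kind")]
  n_reps <- 300
  rd <- randomized_disruption_fraction(
    mis, pro, pwms, s_max_grid = c(-6.4, -5.5), n_reps = n_reps, seed = 8L
  )
  for (i in seq_len(nrow(rd))) {
    se <- rd$null_sd[i] / sqrt(n_reps)
    # per-variant binomial spread of the observed fraction dominates
    spread <- sqrt(rd$null_mean[i] * (1 - rd$null_mean[i]) / rd$n_variants[i])
    expect_lt(abs(rd$observed_fraction[i] - rd$null_mean[i]),
              3 * (spread + se) + 1e-9)
  }
})

test_that("sweep and randomization plots build", {
  bundle <- default_bundle(seed = 5L)
  pro <- bundle$proteome
  ct <- extract_ctermini(pro)
  scores <- score_all(bundle$truth$pwms, ct)
  sw <- sweep_motif_thresholds(scores, ct, bundle$variants,
                               thresholds = seq(-12, -4, 0.5),
                               proteome = pro)
  expect_s3_class(autoplot(sw), "ggplot")
  rd <- randomized_disruption_fraction(
    bundle$variants, pro, bundle$truth$pwms,
    s_max_grid = c(-6.4, -5), n_reps = 20, seed = 2L
  )
  expect_s3_class(autoplot(rd), "ggplot")
})
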