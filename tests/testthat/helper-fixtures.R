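# Shared fixtures, all built in code.

# the four-peptide alignment used across PWM tests
toy_peptides <- c("ETWV", "ESWV", "ETWI", "QTWV")

toy_pwm <- function(kappa = 0, mode = "proportional") {
  build_pwm(toy_peptides, domain_id = "toy", kappa = kappa,
            pseudocount_mode = mode)
}

# a PWM whose every consensus entry is 1 (one-hot over 7 positions)
onehot_pwm <- function(pep = "GETWVAA") {
  build_pwm(rep(pep, 5), domain_id = "onehot", kappa = 0)
}

# tiny proteome: two proteins, one with two isoforms
tiny_proteome <- function() {
  tibble::tibble(
    protein_id = c("PA", "PA", "PB"),
    isoform_id = c("PA.1", "PA.2", "PB.1"),
    sequence = c(
      paste0(strrep("A", 13), "GETWVAA"),  # 20 aa
      paste0(strrep("A", 3), "GETWV"),     # 8 aa, different suffix
      "MKT"                                # shorter than the window
    )
  )
}

# brute-force binomial upper/lower/two-sided tails by pmf summation
oracle_binom <- function(k, n, p, sidedness) {
  pmf <- stats::dbinom(0:n, n, p)
  switch(sidedness,
    greater = sum(pmf[(k + 1):(n + 1)]),
    less = sum(pmf[1:(k + 1)]),
    two = sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)])
  )
}

# brute-force hypergeometric upper tail: P(X >= k) for k hits in a sample
# of size s from a universe with uh hits among u
oracle_hyper_upper <- function(k, u, uh, s) {
  kk <- k:min(uh, s)
  sum(choose(uh, kk) * choose(u - uh, s - kk)) / choose(u, s)
}

# deterministic synthetic bundle at the default study conditions:
# 100 proteins, 5 ground-truth PWMs, 20 disrupt / 10 create / 50 neutral /
# 10 stop-gain planted variants, margin 1.0
default_bundle <- function(seed = 42L) {
  pwms <- lapply(1:5, function(i) {
    simulate_pwm(paste0("DOM", i), seed = seed + i)
  })
  sim <- simulate_proteome(
    n_proteins = 100, length_range = c(50, 200), motif_fraction = 0.2,
    pwms = pwms, isoform_rate = 0.1, go_fraction = 0.1, margin = 1,
    seed = seed
  )
  simulate_variants(sim, n_disrupt = 20, n_create = 10, n_neutral = 50,
                    n_stopgain = 10, margin = 1, seed = seed + 1L)
}
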