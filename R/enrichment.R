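#' Exact binomial test for variant density in a sequence region
#'
#' Tests whether the number of variants observed in a region (e.g. all
#' C-terminal windows) departs from what the genome-wide per-position variant
#' density predicts. The count is modelled as
#' \deqn{k \sim \mathrm{Binom}(\mathrm{region\_aa},\; n_{trials}/\mathrm{total\_aa})}
#' i.e. every region position draws variants at the overall density
#' `n_trials / total_aa`; a binomial (rather than hypergeometric) model is
#' appropriate because several variants can hit the same residue. The
#' expected count is `region_aa * n_trials / total_aa`. The p-value is the
#' exact binomial tail (two-sided by the minimum-likelihood method of
#' [stats::binom.test()], or a one-sided tail sum); no normal approximation
#' is ever used.
#'
#' @param k_observed Number of variants observed in the region.
#' @param n_trials Total number of variants genome-wide.
#' @param region_aa Number of amino-acid positions in the region.
#' @param total_aa Total number of amino-acid positions.
#' @param sidedness `"two"` (default), `"greater"` or `"less"`.
#' @return A one-row tibble: `test`, `observed`, `expected`, `p_value`,
#'   `sidedness`, `region_aa`, `total_aa`, `n_trials`, `rate`.
#' @examples
#' binomial_enrichment(15004, 1026979, 151571, 11269376)
#' @export
binomial_enrichment <- function(k_observed, n_trials, region_aa, total_aa,
                                sidedness = c("two", "greater", "less")) {
  sidedness <- match.arg(sidedness)
  if (total_aa <= 0) stop("total_aa must be positive", call. = FALSE)
  if (region_aa > total_aa) stop("region_aa exceeds total_aa", call. = FALSE)
  if (k_observed > n_trials) stop("k_observed exceeds n_trials", call. = FALSE)
  stopifnot(k_observed >= 0, region_aa >= 0)
  if (n_trials > total_aa) {
    stop("overall variant density exceeds one per position; ",
         "the binomial rate is undefined", call. = FALSE)
  }
  rate <- n_trials / total_aa
  expected <- region_aa * rate
  p_value <- switch(sidedness,
    two = stats::binom.test(k_observed, region_aa, rate)$p.value,
    greater = stats::pbinom(k_observed - 1, region_aa, rate,
                            lower.tail = FALSE),
    less = stats::pbinom(k_observed, region_aa, rate)
  )
  tibble::tibble(
    test = "binomial",
    observed = k_observed,
    expected = expected,
    p_value = p_value,
    sidedness = sidedness,
    region_aa = region_aa,
    total_aa = total_aa,
    n_trials = n_trials,
    rate = rate
  )
}

#' Fisher's exact test for overlap with a gold-standard set
#'
#' One-sided Fisher's exact test that "hits" (e.g. domain–protein pairs
#' scoring above a threshold) are enriched in a sample (e.g. curated known
#' interactions) drawn from a universe of pairs. The 2x2 table is
#' `[[sample_hits, sample - sample_hits], [universe_hits - sample_hits,
#' universe - sample - universe_hits + sample_hits]]`; the one-sided
#' `greater` p-value equals the hypergeometric upper tail.
#'
#' @param universe Total number of pairs in the universe (sample included).
#' @param universe_hits Number of hits in the universe.
#' @param sample Size of the gold-standard sample.
#' @param sample_hits Number of hits within the sample.
#' @param sidedness `"greater"` (default), `"less"` or `"two"`.
#' @return A one-row tibble: `test`, `observed`, `expected`, `p_value`,
#'   `sidedness`, plus the echoed table margins.
#' @examples
#' fisher_overlap(296265, 2818, 36, 23)
#' @export
fisher_overlap <- function(universe, universe_hits, sample, sample_hits,
                           sidedness = c("greater", "less", "two")) {
  sidedness <- match.arg(sidedness)
  tab <- matrix(
    c(
      sample_hits, sample - sample_hits,
      universe_hits - sample_hits,
      universe - sample - universe_hits + sample_hits
    ),
    nrow = 2, byrow = TRUE
  )
  if (any(tab < 0)) {
    stop("inconsistent counts: negative cell in the 2x2 table", call. = FALSE)
  }
  alt <- switch(sidedness, greater = "greater", less = "less", two = "two.sided")
  p_value <- stats::fisher.test(tab, alternative = alt)$p.value
  tibble::tibble(
    test = "fisher",
    observed = sample_hits,
    expected = sample * universe_hits / universe,
    p_value = p_value,
    sidedness = sidedness,
    universe = universe,
    universe_hits = universe_hits,
    sample = sample
  )
}

#' Sweep the motif-defining threshold and count variants inside motifs
#'
#' For each threshold `t` in a descending grid, a C-terminus is *motif-
#' containing* if its best score over all domains exceeds `t`. The sweep
#' reports, per threshold: the number of distinct C-terminal variants falling
#' in motif-containing C-termini, the number of amino acids those C-termini
#' span, their ratio (the variant density inside motifs), and a one-sided
#' `"less"` exact binomial p-value of the variant count against the global
#' C-terminal variant density — probing whether motif positions carry
#' *fewer* variants than C-termini at large.
#'
#' @param scores Long score table from [score_all()] (needs `isoform_id`
#'   and `score`).
#' @param ctermini C-terminus table from [extract_ctermini()].
#' @param variants Variant table restricted to C-terminal missense records,
#'   or any variant table plus `proteome` to derive that restriction.
#' @param thresholds Numeric score grid; default `seq(-12, -4, by = 0.1)`,
#'   swept in descending order.
#' @param background_rate Global fraction of C-terminal positions carrying
#'   variants. Default `NULL` computes distinct C-terminal variants divided
#'   by total C-terminal amino acids from the inputs.
#' @param proteome Optional proteome tibble used to flag C-terminal variants
#'   when `variants` has not been pre-filtered.
#' @return A `pdz_sweep` tibble: `threshold`, `n_ctermini`, `n_variants`,
#'   `n_aa`, `ratio` (NA when no C-terminus qualifies), `p_value`.
#' @export
sweep_motif_thresholds <- function(scores, ctermini, variants,
                                   thresholds = seq(-12, -4, by = 0.1),
                                   background_rate = NULL,
                                   proteome = NULL) {
  if (length(thresholds) == 0) stop("empty threshold grid", call. = FALSE)
  stopifnot(all(is.finite(thresholds)))
  thresholds <- sort(thresholds, decreasing = TRUE)

  if (!is.null(proteome)) {
    variants <- variant_in_cterm(variants, proteome)
    variants <- variants[variants$kind == "missense" & variants$in_cterm, ]
  }
  # best score per isoform over all domains
  best <- dplyr::summarise(
    dplyr::group_by(scores, .data$isoform_id),
    best_score = max(.data$score),
    .groups = "drop"
  )
  ct <- dplyr::left_join(ctermini, best, by = "isoform_id")
  if (anyNA(ct$best_score)) {
    stop("ctermini present that were never scored", call. = FALSE)
  }
  total_aa <- sum(ct$cterm_length)
  n_var_total <- length(unique(variants$variant_id))
  if (is.null(background_rate)) {
    background_rate <- n_var_total / total_aa
  }

  iso_var <- unique(variants[, c("variant_id", "isoform_id")])
  per_t <- lapply(thresholds, function(t) {
    qual <- ct[ct$best_score > t, ]
    n_aa <- sum(qual$cterm_length)
    n_variants <- length(unique(
      iso_var$variant_id[iso_var$isoform_id %in% qual$isoform_id]
    ))
    tibble::tibble(
      threshold = t,
      n_ctermini = nrow(qual),
      n_variants = n_variants,
      n_aa = n_aa,
      ratio = if (n_aa > 0) n_variants / n_aa else NA_real_,
      p_value = if (n_aa > 0) {
        stats::pbinom(n_variants, n_aa, background_rate)
      } else {
        NA_real_
      }
    )
  })
  out <- dplyr::bind_rows(per_t)
  attr(out, "background_rate") <- background_rate
  class(out) <- c("pdz_sweep", class(out))
  out
}

#' Observed vs null fraction of motif-disrupting variants across s_max
#'
#' The observed curve is the fraction of C-terminal missense variants
#' classified as disrupting for each value of the upper threshold `s_max`
#' (with `s_min` held fixed). The null replaces every variant's alternate
#' residue by a uniform draw from the 19 non-identical residues at the same
#' position — random amino-acid modifications excluding synonymous ones —
#' reclassifies, and repeats `n_reps` times; the per-threshold null mean and
#' population standard deviation summarise the randomizations.
#'
#' A variant counts as disrupting if, on any isoform it maps to and for any
#' domain, the wild-type score exceeds `s_max` and the mutant score falls
#' below `s_min`.
#'
#' @param variants Variant tibble; only missense records falling in a
#'   C-terminal window enter the curves.
#' @param proteome Proteome tibble.
#' @param pwms A `pdz_pwm` or list of them.
#' @param s_min Fixed lower threshold (default -8.3).
#' @param s_max_grid Grid of upper thresholds (default
#'   `seq(-8.2, -4, by = 0.2)`); all values must exceed `s_min`.
#' @param n_reps Number of randomizations (default 1000).
#' @param seed Integer seed; the run is a pure function of inputs and seed.
#' @param window C-terminal window length.
#' @return A `pdz_randomization` tibble: `s_max`, `observed_fraction`,
#'   `null_mean`, `null_sd`, `n_variants`, with `n_reps` and `seed` as
#'   attributes.
#' @export
randomized_disruption_fraction <- function(variants, proteome, pwms,
                                           s_min = -8.3,
                                           s_max_grid = seq(-8.2, -4, by = 0.2),
                                           n_reps = 1000, seed = 1L,
                                           window = 7L) {
  stopifnot(n_reps >= 1, all(s_max_grid > s_min))
  pwms <- as_pwm_list(pwms)
  s_max_grid <- sort(s_max_grid)

  empty <- tibble::tibble(
    s_max = s_max_grid,
    observed_fraction = 0, null_mean = 0, null_sd = 0, n_variants = 0L
  )
  mk <- function(tb) {
    attr(tb, "n_reps") <- n_reps
    attr(tb, "seed") <- seed
    class(tb) <- c("pdz_randomization", class(tb))
    tb
  }

  mis <- variants[variants$kind == "missense", , drop = FALSE]
  if (nrow(mis) == 0) return(mk(empty))
  mis <- variant_in_cterm(mis, proteome, window = window)
  mis <- mis[mis$in_cterm, , drop = FALSE]
  if (nrow(mis) == 0) return(mk(empty))

  # Precompute, per (variant-isoform, domain): the wild-type score with the
  # mutated offset left out (s_base) and the PWM log-prob row at that offset.
  # Then s_wt = s_base + lp[ref] and s_mut(a) = s_base + lp[a] for any
  # alternate residue a, making each randomization a table lookup.
  iso_key <- paste(proteome$protein_id, proteome$isoform_id, sep = "\r")
  seq_of <- stats::setNames(proteome$sequence, iso_key)
  n_dom <- length(pwms)
  blocks <- vector("list", nrow(mis))
  for (r in seq_len(nrow(mis))) {
    v <- mis[r, ]
    seq <- seq_of[[paste(v$protein_id, v$isoform_id, sep = "\r")]]
    len <- nchar(seq)
    start <- max(1L, len - as.integer(window) + 1L)
    ct <- substr(seq, start, len)
    res <- cterm_residues(ct)                 # offset order
    off <- len - v$position                   # 0-based offset of the variant
    idx <- match(res, AA_ALPHABET)
    s_base <- numeric(n_dom)
    lp_row <- matrix(0, nrow = n_dom, ncol = 20)
    for (d in seq_len(n_dom)) {
      lp <- log10(pwms[[d]]$mat)
      full <- lp[cbind(seq_along(res), idx)]
      s_base[d] <- sum(full[-(off + 1L)])
      lp_row[d, ] <- lp[off + 1L, ]
    }
    blocks[[r]] <- list(
      variant_id = v$variant_id,
      ref_idx = match(v$ref_aa, AA_ALPHABET),
      alt_idx = match(v$alt_aa, AA_ALPHABET),
      s_wt = s_base + lp_row[, match(v$ref_aa, AA_ALPHABET)],
      s_mut_by_alt = s_base + lp_row    # n_dom x 20
    )
  }

  var_ids <- unique(vapply(blocks, `[[`, character(1), "variant_id"))
  n_var <- length(var_ids)
  # flatten to row-per-(variant-isoform, domain)
  row_var <- rep(match(vapply(blocks, `[[`, character(1), "variant_id"),
                       var_ids), each = n_dom)
  s_wt_rows <- unlist(lapply(blocks, `[[`, "s_wt"))
  mut_mat <- do.call(rbind, lapply(blocks, `[[`, "s_mut_by_alt"))
  below <- mut_mat < s_min                       # rows x 20
  # per variant: its reference residue (same across isoform rows by contract)
  ref_of_var <- vapply(var_ids, function(id) {
    blocks[[which(vapply(blocks, `[[`, character(1), "variant_id") == id)[1]]]$ref_idx
  }, integer(1))
  alt_of_var <- vapply(var_ids, function(id) {
    blocks[[which(vapply(blocks, `[[`, character(1), "variant_id") == id)[1]]]$alt_idx
  }, integer(1))

  frac_disrupt <- function(alt_idx_per_var) {
    hit <- below[cbind(seq_len(nrow(below)), alt_idx_per_var[row_var])]
    vapply(s_max_grid, function(t) {
      sup <- hit & (s_wt_rows > t)
      sum(tabulate(row_var[sup], nbins = n_var) > 0) / n_var
    }, numeric(1))
  }

  observed <- frac_disrupt(alt_of_var)

  old <- .Random.seed_exists()
  set.seed(seed)
  null_mat <- matrix(0, nrow = n_reps, ncol = length(s_max_grid))
  for (rep_i in seq_len(n_reps)) {
    # uniform over the 19 residues differing from the reference
    draw <- (ref_of_var + sample.int(19, n_var, replace = TRUE) - 1L) %% 20L + 1L
    null_mat[rep_i, ] <- frac_disrupt(draw)
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

  out <- tibble::tibble(
    s_max = s_max_grid,
    observed_fraction = observed,
    null_mean = colMeans(null_mat),
    null_sd = apply(null_mat, 2, function(x) sqrt(mean((x - mean(x))^2))),
    n_variants = n_var
  )
  mk(out)
}

#' @noRd
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

#' Plot a threshold sweep
#'
#' Three stacked panels over the score threshold: variant count inside
#' motif-containing C-termini, variant density (with the global background
#' density dashed), and the one-sided binomial p-value (log scale).
#'
#' @param object A `pdz_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pdz_sweep
#' @export
autoplot.pdz_sweep <- function(object, ...) {
  bg <- attr(object, "background_rate")
  d <- tidyr::pivot_longer(
    dplyr::transmute(
      tibble::as_tibble(object),
      threshold = .data$threshold,
      `nsSNPs in motifs` = .data$n_variants,
      `nsSNP density` = .data$ratio,
      `binomial p` = .data$p_value
    ),
    -"threshold", names_to = "panel", values_to = "value"
  )
  d$panel <- factor(d$panel,
                    levels = c("nsSNPs in motifs", "nsSNP density", "binomial p"))
  ref <- tibble::tibble(panel = factor("nsSNP density", levels = levels(d$panel)),
                        yintercept = bg)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$threshold, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(data = ref,
                        ggplot2::aes(yintercept = .data$yintercept),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "PWM score threshold", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot observed vs randomized disruption fractions
#'
#' Observed fraction of disrupting variants (solid) against the
#' randomization null (mean with +/- 1 sd error bars) across `s_max`.
#'
#' @param object A `pdz_randomization`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pdz_randomization
#' @export
autoplot.pdz_randomization <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$s_max)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$null_mean - .data$null_sd,
                   ymax = .data$null_mean + .data$null_sd),
      width = 0.05, colour = "grey40"
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$null_mean), colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed_fraction),
                       colour = "red") +
    ggplot2::labs(
      x = expression(S[max]),
      y = "fraction of nsSNPs disrupting a motif"
    ) +
    ggplot2::theme_minimal()
}
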