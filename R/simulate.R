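#' Simulate a ground-truth PDZ specificity PWM
#'
#' Draws a sparse specificity model: each of the 7 positions allows a small
#' random support of residues (the first drawn residue taking most of the
#' mass), all other residues having probability exactly zero. Sparse support
#' mirrors phage-display-derived specificities, where most residues are never
#' selected at a given position, and is what makes single-residue variants
#' able to cross the classification band: a substitution to an unsupported
#' residue sends the score to `-Inf`.
#'
#' @param domain_id Label for the simulated domain.
#' @param n_support Number of residues allowed per position (default 3).
#' @param top_prob Probability of the preferred residue (default 0.75); the
#'   remainder is spread evenly over the other supported residues.
#' @param seed Integer seed.
#' @return A `pdz_pwm` with `kappa = 0`.
#' @export
simulate_pwm <- function(domain_id = "sim", n_support = 3, top_prob = 0.75,
                         seed = 1L) {
  stopifnot(n_support >= 1, n_support <= 20, top_prob > 0, top_prob <= 1)
  if (n_support == 1) top_prob <- 1
  set.seed(seed)
  mat <- matrix(
    0, nrow = PDZ_WINDOW, ncol = 20,
    dimnames = list(offset = as.character(0:(PDZ_WINDOW - 1)),
                    residue = AA_ALPHABET)
  )
  for (n in seq_len(PDZ_WINDOW)) {
    sup <- sample.int(20, n_support)
    mat[n, sup[1]] <- top_prob
    if (n_support > 1) {
      mat[n, sup[-1]] <- (1 - top_prob) / (n_support - 1)
    }
  }
  ic <- apply(mat, 1, position_information_content)
  structure(
    list(domain_id = domain_id, mat = mat, ic = unname(ic),
         kappa = 0, pseudocount_mode = "proportional",
         n_peptides = 0L),
    class = "pdz_pwm"
  )
}

#' Sample peptides from a PWM
#'
#' Draws `n` 7-mers position-independently from the PWM rows — the
#' generative model under which [build_pwm()] with `kappa = 0` is the
#' maximum-likelihood estimator, so a PWM rebuilt from a large sample
#' recovers the truth entrywise.
#'
#' @param pwm A `pdz_pwm` (the ground truth).
#' @param n Number of peptides.
#' @param seed Integer seed.
#' @return Character vector of `n` peptides (length 7 each).
#' @export
simulate_peptides <- function(pwm, n, seed = 1L) {
  stopifnot(inherits(pwm, "pdz_pwm"), n >= 1)
  set.seed(seed)
  cols <- vapply(seq_len(PDZ_WINDOW), function(pos) {
    sample(AA_ALPHABET, n, replace = TRUE, prob = pwm$mat[pos, ])
  }, character(n))
  if (n == 1) cols <- matrix(cols, nrow = 1)
  # columns are offsets 0..6; peptides read N- to C-terminal
  apply(cols[, PDZ_WINDOW:1, drop = FALSE], 1, paste, collapse = "")
}

#' @noRd
sample_motif_suffix <- function(pwm, min_score, seed_state_ok = TRUE,
                                max_tries = 200) {
  for (i in seq_len(max_tries)) {
    s <- simulate_peptides_raw(pwm, 1)
    if (score_cterm(pwm, s) > min_score) return(s)
  }
  pwm_consensus(pwm)
}

# sampling without touching the seed (caller manages RNG state)
#' @noRd
simulate_peptides_raw <- function(pwm, n) {
  cols <- vapply(seq_len(PDZ_WINDOW), function(pos) {
    sample(AA_ALPHABET, n, replace = TRUE, prob = pwm$mat[pos, ])
  }, character(n))
  if (n == 1) cols <- matrix(cols, nrow = 1)
  apply(cols[, PDZ_WINDOW:1, drop = FALSE], 1, paste, collapse = "")
}

#' @noRd
random_protein <- function(len) {
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

#' Simulate a proteome with planted PDZ-binding motifs
#'
#' Generates `n_proteins` random-background proteins (residues uniform over
#' the 20-letter alphabet, so an uninformative PWM scores every C-terminus at
#' exactly `7 * log10(0.05)`). A `motif_fraction` subset has its 7-residue
#' suffix replaced by a draw from a randomly assigned ground-truth PWM,
#' rejection-sampled until its score under that PWM exceeds
#' `s_max + margin`. An `isoform_rate` fraction of proteins gains a second
#' isoform with a re-randomised suffix. A `go_fraction` of the *non-motif*
#' proteins receives compartment annotations (extracellular, mitochondrial,
#' or extracellular-with-rescue, in rotation) to exercise the compartment
#' filter without removing planted truth.
#'
#' @param n_proteins Number of proteins (default 100).
#' @param length_range Protein length range, inclusive (default c(50, 200)).
#' @param motif_fraction Fraction of proteins carrying a planted motif.
#' @param pwms List of ground-truth `pdz_pwm`s (e.g. [simulate_pwm()]).
#' @param isoform_rate Fraction of proteins with a second isoform.
#' @param go_fraction Fraction of non-motif proteins annotated to a filtered
#'   compartment (default 0.1).
#' @param s_max Upper classification threshold used for planting.
#' @param margin Score margin above `s_max` required of planted motifs.
#' @param seed Integer seed.
#' @return A list with `proteome` (tibble), `annotations` (tibble) and
#'   `truth` — a list holding the ground-truth `pwms`, the planted
#'   `motif_proteins` tibble (`protein_id`, `isoform_id`, `domain_id`,
#'   `suffix`, `score`), the generator `params` and `seed`.
#' @export
simulate_proteome <- function(n_proteins = 100, length_range = c(50, 200),
                              motif_fraction = 0.2, pwms,
                              isoform_rate = 0.1, go_fraction = 0.1,
                              s_max = -6.4, margin = 1, seed = 1L) {
  stopifnot(motif_fraction >= 0, motif_fraction <= 1,
            isoform_rate >= 0, isoform_rate <= 1,
            length_range[1] >= 20, length_range[2] >= length_range[1])
  pwms <- as_pwm_list(pwms)
  set.seed(seed)

  n_motif <- round(n_proteins * motif_fraction)
  protein_id <- sprintf("P%04d", seq_len(n_proteins))
  lens <- sample(length_range[1]:length_range[2], n_proteins, replace = TRUE)
  seqs <- vapply(lens, random_protein, character(1))

  motif_idx <- if (n_motif > 0) seq_len(n_motif) else integer(0)
  motif_rows <- vector("list", length(motif_idx))
  for (k in seq_along(motif_idx)) {
    i <- motif_idx[k]
    d <- sample(seq_along(pwms), 1)
    suf <- sample_motif_suffix(pwms[[d]], s_max + margin)
    substr(seqs[i], lens[i] - PDZ_WINDOW + 1L, lens[i]) <- suf
    pid <- protein_id[i]
    motif_rows[[k]] <- tibble::tibble(
      protein_id = pid,
      isoform_id = paste0(pid, ".1"),
      domain_id = pwms[[d]]$domain_id,
      suffix = suf,
      score = score_cterm(pwms[[d]], suf)
    )
  }

  proteome <- tibble::tibble(
    protein_id = protein_id,
    isoform_id = paste0(protein_id, ".1"),
    sequence = seqs
  )

  n_iso <- round(n_proteins * isoform_rate)
  if (n_iso > 0) {
    iso_idx <- sample.int(n_proteins, n_iso)
    extra <- proteome[iso_idx, ]
    extra$isoform_id <- paste0(extra$protein_id, ".2")
    extra$sequence <- vapply(extra$sequence, function(s) {
      l <- nchar(s)
      substr(s, l - PDZ_WINDOW + 1L, l) <- random_protein(PDZ_WINDOW)
      s
    }, character(1), USE.NAMES = FALSE)
    proteome <- dplyr::bind_rows(proteome, extra)
  }

  non_motif <- setdiff(seq_len(n_proteins), motif_idx)
  n_go <- round(length(non_motif) * go_fraction)
  annotations <- tibble::tibble(protein_id = character(), go_term = character())
  if (n_go > 0) {
    chosen <- sample(non_motif, n_go)
    kinds <- rep(c("extracellular", "mito", "rescued"), length.out = n_go)
    ann <- lapply(seq_len(n_go), function(j) {
      p <- protein_id[chosen[j]]
      switch(kinds[j],
        extracellular = tibble::tibble(protein_id = p, go_term = "GO:0005615"),
        mito = tibble::tibble(protein_id = p, go_term = "GO:0044429"),
        rescued = tibble::tibble(protein_id = p,
                                 go_term = c("GO:0005615", "GO:0044459"))
      )
    })
    annotations <- dplyr::bind_rows(ann)
  }

  truth <- list(
    pwms = pwms,
    motif_proteins = if (length(motif_rows)) dplyr::bind_rows(motif_rows)
                     else tibble::tibble(protein_id = character(),
                                         isoform_id = character(),
                                         domain_id = character(),
                                         suffix = character(),
                                         score = numeric()),
    params = list(
      n_proteins = n_proteins, length_range = length_range,
      motif_fraction = motif_fraction, isoform_rate = isoform_rate,
      go_fraction = go_fraction, s_max = s_max, margin = margin
    ),
    seed = seed
  )
  list(proteome = proteome, annotations = annotations, truth = truth)
}

#' Plant variants with known verdicts in a simulated proteome
#'
#' Builds a variant table whose intended classifications are guaranteed by
#' construction and recorded in the returned truth:
#' \describe{
#'   \item{disrupt}{a missense in the suffix of a planted motif protein,
#'     substituting a residue the matched PWM assigns probability zero, so
#'     the mutant score is `-Inf < s_min` while the wild type stays above
#'     `s_max + margin`.}
#'   \item{create}{the suffix of a non-motif, unannotated protein is first
#'     overwritten with a high-scoring draw corrupted at one position by a
#'     zero-probability residue (wild-type score `-Inf`); the variant
#'     restores the high-scoring residue.}
#'   \item{neutral}{alternating between substitutions outside every
#'     C-terminal window and in-window substitutions verified to leave all
#'     domain scores below `s_max`.}
#'   \item{stop_gain}{half truncate planted motif proteins (disrupting when
#'     the new C-terminus scores below `s_min` for the matched domain),
#'     half truncate background proteins (neutral); placements are verified
#'     against the ground-truth PWMs and the intended verdict recorded.}
#' }
#' Every planted verdict is re-checked against *all* ground-truth PWMs
#' (rejection-sampling placements) so the recorded truth holds under the
#' full classification rule, not just the matched domain.
#'
#' @param sim Output of [simulate_proteome()] (list with `proteome`,
#'   `annotations`, `truth`).
#' @param n_disrupt,n_create,n_neutral,n_stopgain Requested counts.
#' @param s_min,s_max Classification thresholds the planting targets.
#' @param margin Required score margin beyond each crossed threshold.
#' @param seed Integer seed.
#' @return A list: `variants` (tibble ready for [screen_variants()]),
#'   `proteome` (updated: create-variant suffixes are rewritten),
#'   `annotations`, and `truth` augmented with a `variants` tibble carrying
#'   `intended_verdict`.
#' @export
simulate_variants <- function(sim, n_disrupt = 20, n_create = 10,
                              n_neutral = 50, n_stopgain = 10,
                              s_min = -8.3, s_max = -6.4, margin = 1,
                              seed = 1L) {
  proteome <- sim$proteome
  truth <- sim$truth
  pwms <- truth$pwms
  set.seed(seed)

  motif <- truth$motif_proteins
  used_disrupt <- character(0)
  score_all_domains <- function(ct) vapply(pwms, score_cterm, numeric(1), cterm = ct)
  seq_lookup <- function(pid, iid) {
    proteome$sequence[proteome$protein_id == pid & proteome$isoform_id == iid][1]
  }
  set_seq <- function(pid, iid, s) {
    proteome$sequence[proteome$protein_id == pid &
                        proteome$isoform_id == iid] <<- s
  }

  variants <- list()
  truth_rows <- list()
  vn <- 0L
  add_variant <- function(pid, iid, pos, ref, alt, kind, intended) {
    vn <<- vn + 1L
    id <- sprintf("rs%05d", vn)
    variants[[vn]] <<- tibble::tibble(
      variant_id = id, protein_id = pid, isoform_id = iid,
      position = as.integer(pos), ref_aa = ref, alt_aa = alt, kind = kind
    )
    truth_rows[[vn]] <<- tibble::tibble(
      variant_id = id, intended_verdict = intended
    )
  }

  ## --- disrupt: zero-probability substitution in a planted motif suffix ---
  if (n_disrupt > nrow(motif)) {
    stop("infeasible request: ", n_disrupt, " disrupt variants but only ",
         nrow(motif), " planted motif proteins", call. = FALSE)
  }
  if (n_disrupt > 0) {
    rows <- sample.int(nrow(motif), n_disrupt)
    for (r in rows) {
      m <- motif[r, ]
      pwm <- pwms[[m$domain_id]]
      seq <- seq_lookup(m$protein_id, m$isoform_id)
      len <- nchar(seq)
      placed <- FALSE
      for (off in sample(0:(PDZ_WINDOW - 1))) {
        zero_res <- AA_ALPHABET[pwm$mat[off + 1L, ] == 0]
        if (length(zero_res) == 0) next
        pos <- len - off
        ref <- substr(seq, pos, pos)
        alt <- sample(zero_res, 1)
        ct <- substr(seq, len - PDZ_WINDOW + 1L, len)
        mut <- mutate_cterm(ct, pos, ref, alt,
                            start_position = len - PDZ_WINDOW + 1L)
        ms <- score_all_domains(mut)
        # must not accidentally create a motif for another domain
        if (all(ms < s_max) && ms[m$domain_id] < s_min) {
          add_variant(m$protein_id, m$isoform_id, pos, ref, alt,
                      "missense", "disrupts")
          used_disrupt <- c(used_disrupt, m$protein_id)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("infeasible request: could not place a disrupt variant on ",
             m$protein_id, call. = FALSE)
      }
    }
  }

  ## --- create: corrupted motif planted, variant restores it ---
  annotated <- unique(sim$annotations$protein_id)
  pool <- setdiff(unique(proteome$protein_id),
                  c(motif$protein_id, annotated))
  if (n_create > length(pool)) {
    stop("infeasible request: ", n_create, " create variants but only ",
         length(pool), " eligible background proteins", call. = FALSE)
  }
  if (n_create > 0) {
    chosen <- sample(pool, n_create)
    for (pid in chosen) {
      iid <- paste0(pid, ".1")
      seq <- seq_lookup(pid, iid)
      len <- nchar(seq)
      placed <- FALSE
      for (try in 1:100) {
        d <- sample(seq_along(pwms), 1)
        pwm <- pwms[[d]]
        good <- sample_motif_suffix(pwm, s_max + margin)
        off <- sample(0:(PDZ_WINDOW - 1), 1)
        zero_res <- AA_ALPHABET[pwm$mat[off + 1L, ] == 0]
        if (length(zero_res) == 0) next
        good_res <- substr(good, PDZ_WINDOW - off, PDZ_WINDOW - off)
        bad <- good
        substr(bad, PDZ_WINDOW - off, PDZ_WINDOW - off) <- sample(zero_res, 1)
        ws <- score_all_domains(bad)
        ms <- score_all_domains(good)
        # wild type must bind nothing; mutant must not disrupt elsewhere
        if (all(ws < s_min) && all(ms[-d] < s_max | ws[-d] > s_min)) {
          new_seq <- seq
          substr(new_seq, len - PDZ_WINDOW + 1L, len) <- bad
          set_seq(pid, iid, new_seq)
          pos <- len - off
          add_variant(pid, iid, pos, substr(bad, PDZ_WINDOW - off,
                                            PDZ_WINDOW - off),
                      good_res, "missense", "creates")
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("infeasible request: could not plant a create variant on ",
             pid, call. = FALSE)
      }
    }
  }

  ## --- neutral: outside windows, or in-window without crossing s_max ---
  neutral_pool <- setdiff(pool, vapply(variants, function(v) v$protein_id[1],
                                       character(1)))
  if (n_neutral > 0) {
    if (n_neutral > length(neutral_pool)) {
      stop("infeasible request: ", n_neutral, " neutral variants but only ",
           length(neutral_pool), " unused background proteins", call. = FALSE)
    }
    chosen <- sample(neutral_pool, n_neutral)
    for (j in seq_len(n_neutral)) {
      pid <- chosen[j]
      iid <- paste0(pid, ".1")
      seq <- seq_lookup(pid, iid)
      len <- nchar(seq)
      if (j %% 2 == 0) {
        # outside every C-terminal window
        pos <- sample.int(len - PDZ_WINDOW, 1)
        ref <- substr(seq, pos, pos)
        alt <- sample(setdiff(AA_ALPHABET, ref), 1)
        add_variant(pid, iid, pos, ref, alt, "missense", "neutral")
      } else {
        placed <- FALSE
        for (try in 1:100) {
          pos <- len - sample(0:(PDZ_WINDOW - 1), 1)
          ref <- substr(seq, pos, pos)
          alt <- sample(setdiff(AA_ALPHABET, ref), 1)
          ct <- substr(seq, len - PDZ_WINDOW + 1L, len)
          mut <- mutate_cterm(ct, pos, ref, alt,
                              start_position = len - PDZ_WINDOW + 1L)
          ws <- score_all_domains(ct)
          ms <- score_all_domains(mut)
          no_disrupt <- all(!(ws > s_max & ms < s_min))
          no_create <- all(!(ws < s_min & ms > s_max))
          if (no_disrupt && no_create) {
            add_variant(pid, iid, pos, ref, alt, "missense", "neutral")
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop("infeasible request: could not place a neutral variant on ",
               pid, call. = FALSE)
        }
      }
    }
  }

  ## --- stop-gains: half disrupt motif proteins, half neutral ---
  if (n_stopgain > 0) {
    n_sg_disrupt <- ceiling(n_stopgain / 2)
    sg_motif_pool <- setdiff(motif$protein_id, character(0))
    if (n_sg_disrupt > length(sg_motif_pool)) {
      stop("infeasible request: ", n_sg_disrupt,
           " disrupting stop-gains but only ", length(sg_motif_pool),
           " motif proteins", call. = FALSE)
    }
    sg_neutral_pool <- setdiff(neutral_pool,
                               vapply(variants, function(v) v$protein_id[1],
                                      character(1)))
    n_sg_neutral <- n_stopgain - n_sg_disrupt
    if (n_sg_neutral > length(sg_neutral_pool)) {
      stop("infeasible request: ", n_sg_neutral,
           " neutral stop-gains but only ", length(sg_neutral_pool),
           " background proteins", call. = FALSE)
    }
    place_stop <- function(pid, iid, want_disrupt) {
      seq <- seq_lookup(pid, iid)
      len <- nchar(seq)
      ct <- substr(seq, len - PDZ_WINDOW + 1L, len)
      ws <- score_all_domains(ct)
      for (try in 1:100) {
        pos <- sample(seq(PDZ_WINDOW + 2L, len - PDZ_WINDOW), 1)
        tr <- truncate_at_stop(seq, pos)
        ms <- score_all_domains(tr$cterm)
        disrupts <- any(ws > s_max & ms < s_min)
        creates <- any(ws < s_min & ms > s_max)
        if (want_disrupt && disrupts && !creates) {
          add_variant(pid, iid, pos, substr(seq, pos, pos), "",
                      "stop_gain", "disrupts")
          return(TRUE)
        }
        if (!want_disrupt && !disrupts && !creates) {
          add_variant(pid, iid, pos, substr(seq, pos, pos), "",
                      "stop_gain", "neutral")
          return(TRUE)
        }
      }
      FALSE
    }
    for (pid in sample(sg_motif_pool, n_sg_disrupt)) {
      if (!place_stop(pid, paste0(pid, ".1"), TRUE)) {
        stop("infeasible request: could not place a disrupting stop-gain on ",
             pid, call. = FALSE)
      }
    }
    if (n_sg_neutral > 0) {
      for (pid in sample(sg_neutral_pool, n_sg_neutral)) {
        if (!place_stop(pid, paste0(pid, ".1"), FALSE)) {
          stop("infeasible request: could not place a neutral stop-gain on ",
               pid, call. = FALSE)
        }
      }
    }
  }

  variants <- if (vn > 0) dplyr::bind_rows(variants) else tibble::tibble(
    variant_id = character(), protein_id = character(),
    isoform_id = character(), position = integer(),
    ref_aa = character(), alt_aa = character(), kind = character()
  )
  truth$variants <- if (vn > 0) {
    dplyr::left_join(dplyr::bind_rows(truth_rows),
                     variants[, c("variant_id", "protein_id", "kind")],
                     by = "variant_id")
  } else {
    tibble::tibble(variant_id = character(), intended_verdict = character(),
                   protein_id = character(), kind = character())
  }
  truth$variant_seed <- seed

  list(
    variants = variants,
    proteome = proteome,
    annotations = sim$annotations,
    truth = truth
  )
}

#' Write a synthetic bundle to disk in the pipeline's input dialects
#'
#' Emits `proteome.fasta` (headers `protein_id|isoform_id`),
#' `variants.tsv`, `annotations.tsv`, one `peptides/<domain>.txt` per
#' ground-truth PWM (peptides sampled from it) and `truth.json`.
#'
#' @param bundle Output of [simulate_variants()].
#' @param dir Output directory (created if missing).
#' @param n_peptides Peptides sampled per domain for the PWM inputs.
#' @param seed Seed for peptide sampling.
#' @return `dir`, invisibly.
#' @export
write_synthetic_bundle <- function(bundle, dir, n_peptides = 2000, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "peptides"), showWarnings = FALSE)

  fa <- file.path(dir, "proteome.fasta")
  writeLines(
    paste0(">", bundle$proteome$protein_id, "|", bundle$proteome$isoform_id,
           "\n", bundle$proteome$sequence),
    fa
  )
  utils::write.table(bundle$variants, file.path(dir, "variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$annotations, file.path(dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  for (i in seq_along(bundle$truth$pwms)) {
    pwm <- bundle$truth$pwms[[i]]
    peps <- simulate_peptides(pwm, n_peptides, seed = seed + i)
    writeLines(peps, file.path(dir, "peptides",
                               paste0(pwm$domain_id, ".txt")))
  }
  jsonlite::write_json(
    list(
      params = bundle$truth$params,
      seed = bundle$truth$seed,
      variant_seed = bundle$truth$variant_seed,
      motif_proteins = bundle$truth$motif_proteins,
      variants = bundle$truth$variants
    ),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
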