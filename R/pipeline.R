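#' Configuration for an end-to-end screen
#'
#' Bundles all input paths and numeric settings with the screen's canonical
#' defaults: 7-residue C-terminal window, classification thresholds
#' `s_min = -8.3` / `s_max = -6.4`, pseudocount `kappa = 1` (proportional
#' mode), sweep grid -12..-4 by 0.1, and 1000 randomizations.
#'
#' @param peptides Directory of per-domain peptide files (filename = domain
#'   id), or a character vector of files.
#' @param proteome FASTA path (headers `protein_id|isoform_id`).
#' @param variants Variant TSV path (see [read_variants()]).
#' @param annotations Optional GO annotation TSV path (`NULL` skips the
#'   compartment filter).
#' @param gold_standard Optional TSV of known (domain_id, protein_id)
#'   interaction pairs for the Fisher overlap test.
#' @param out_dir Output directory.
#' @param kappa,pseudocount_mode PWM smoothing (see [build_pwm()]).
#' @param window C-terminal window length.
#' @param s_min,s_max Classification thresholds; must satisfy
#'   `s_min < s_max`.
#' @param threshold_grid Sweep grid.
#' @param s_max_grid Randomization grid of upper thresholds.
#' @param n_reps Randomizations for the null curve.
#' @param seed Integer seed for all randomness in the run.
#' @return A `pdz_run_config` list.
#' @export
run_config <- function(peptides, proteome, variants,
                       annotations = NULL, gold_standard = NULL,
                       out_dir = "pdzsnp_out",
                       kappa = 1, pseudocount_mode = "proportional",
                       window = 7L, s_min = -8.3, s_max = -6.4,
                       threshold_grid = seq(-12, -4, by = 0.1),
                       s_max_grid = seq(-8.2, -4, by = 0.2),
                       n_reps = 1000, seed = 1L) {
  if (s_min >= s_max) {
    stop("invalid configuration: s_min (", s_min,
         ") must be below s_max (", s_max, ")", call. = FALSE)
  }
  if (window < 1) stop("invalid configuration: window must be >= 1",
                       call. = FALSE)
  structure(
    list(
      peptides = peptides, proteome = proteome, variants = variants,
      annotations = annotations, gold_standard = gold_standard,
      out_dir = out_dir, kappa = kappa,
      pseudocount_mode = pseudocount_mode, window = as.integer(window),
      s_min = s_min, s_max = s_max, threshold_grid = threshold_grid,
      s_max_grid = s_max_grid, n_reps = n_reps, seed = as.integer(seed)
    ),
    class = "pdz_run_config"
  )
}

#' Run the full PDZ-binding-motif variant screen
#'
#' Executes the whole pipeline: build PWMs from the peptide sets, read and
#' compartment-filter the proteome, extract C-termini, score all of them
#' against all domains, classify every variant, and compute the enrichment
#' statistics (C-terminal binomial enrichment, threshold sweep,
#' randomization null, and — when a gold standard is supplied — the Fisher
#' overlap test of known interactions against pairs scoring above `s_min`).
#'
#' Outputs written under `config$out_dir`: `classification.tsv`,
#' `summary.json`, `enrichment.json`, `sweep.tsv`, `randomization.tsv`, and
#' `manifest.json` (configuration, seed, and MD5 checksums of the inputs).
#' Reruns with an identical configuration and seed produce byte-identical
#' tables. On failure all partial outputs are removed.
#'
#' @param config A `pdz_run_config` from [run_config()].
#' @return Invisibly, a run report list: `pwms`, `proteome`, `ctermini`,
#'   `scores`, `screen` (a `pdz_screen`), `enrichment`, `sweep`,
#'   `randomization`, `fisher` (or `NULL`), `summary`.
#' @export
run_screen <- function(config) {
  stopifnot(inherits(config, "pdz_run_config"))
  inputs <- c(config$proteome, config$variants, config$annotations,
              config$gold_standard)
  pep_files <- config$peptides
  if (length(pep_files) == 1 && dir.exists(pep_files)) {
    pep_files <- list.files(pep_files, full.names = TRUE)
  }
  inputs <- c(inputs, pep_files)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) {
    stop("unreadable input file: ", missing[1], call. = FALSE)
  }

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- file.path(config$out_dir,
                       c("classification.tsv", "summary.json",
                         "enrichment.json", "sweep.tsv",
                         "randomization.tsv", "manifest.json"))
  on_fail <- function(e) {
    unlink(outputs)
    stop(e)
  }

  tryCatch({
    pwms <- lapply(pep_files, function(f) {
      peps <- read_peptides(f)
      build_pwm(peps$peptide, domain_id = peps$domain_id[1],
                kappa = config$kappa,
                pseudocount_mode = config$pseudocount_mode)
    })
    pwms <- as_pwm_list(pwms)

    proteome <- read_proteome(config$proteome)
    if (!is.null(config$annotations)) {
      ann <- read_go_annotations(config$annotations)
      proteome <- filter_compartments(proteome, ann)
    }
    ctermini <- extract_ctermini(proteome, window = config$window)
    scores <- score_all(pwms, ctermini)

    variants <- read_variants(config$variants)
    variants <- variants[variants$protein_id %in% proteome$protein_id, ]
    screen <- screen_variants(proteome, variants, pwms,
                              s_min = config$s_min, s_max = config$s_max,
                              window = config$window)

    # C-terminal enrichment over the filtered isoform set
    total_aa <- sum(nchar(proteome$sequence))
    cterm_aa <- sum(ctermini$cterm_length)
    mis <- variants[variants$kind == "missense", , drop = FALSE]
    enrichment <- NULL
    flags <- NULL
    if (nrow(mis) > 0) {
      flags <- variant_in_cterm(mis, proteome, window = config$window)
      k_cterm <- length(unique(flags$variant_id[flags$in_cterm_any]))
      enrichment <- binomial_enrichment(
        k_observed = k_cterm,
        n_trials = length(unique(mis$variant_id)),
        region_aa = cterm_aa,
        total_aa = total_aa
      )
    }

    sweep <- NULL
    randomization <- NULL
    if (!is.null(flags)) {
      ct_mis <- flags[flags$in_cterm, , drop = FALSE]
      sweep <- sweep_motif_thresholds(scores, ctermini, ct_mis,
                                      thresholds = config$threshold_grid)
      randomization <- randomized_disruption_fraction(
        mis, proteome, pwms,
        s_min = config$s_min, s_max_grid = config$s_max_grid,
        n_reps = config$n_reps, seed = config$seed,
        window = config$window
      )
    }

    fisher <- NULL
    if (!is.null(config$gold_standard)) {
      gold <- utils::read.delim(config$gold_standard,
                                colClasses = "character")
      fisher <- fisher_gold_standard(scores, gold, s_min = config$s_min)
    }

    ## ---- write outputs ----
    write_screen_tsv(screen, outputs[1])
    jsonlite::write_json(as.list(screen$summary), outputs[2],
                         auto_unbox = TRUE, digits = NA)
    enr <- list(
      cterm_binomial = if (is.null(enrichment)) NULL else as.list(enrichment),
      gold_standard_fisher = if (is.null(fisher)) NULL else as.list(fisher)
    )
    jsonlite::write_json(enr, outputs[3], auto_unbox = TRUE, digits = NA)
    if (!is.null(sweep)) {
      utils::write.table(as.data.frame(sweep), outputs[4], sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    if (!is.null(randomization)) {
      utils::write.table(as.data.frame(randomization), outputs[5], sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    manifest <- list(
      config = config[setdiff(names(config), "out_dir")],
      input_md5 = as.list(tools::md5sum(inputs))
    )
    jsonlite::write_json(manifest, outputs[6], auto_unbox = TRUE, digits = NA)

    invisible(list(
      pwms = pwms, proteome = proteome, ctermini = ctermini,
      scores = scores, screen = screen, enrichment = enrichment,
      sweep = sweep, randomization = randomization, fisher = fisher,
      summary = screen$summary
    ))
  }, error = on_fail)
}

#' Fisher overlap of a gold-standard interaction list with high-scoring pairs
#'
#' The universe is every scored (domain, protein) pair; a pair is a *hit*
#' when its best isoform score exceeds `s_min`. Tests whether gold-standard
#' interactions are enriched among hits (equivalently, whether known
#' interactions scoring below `s_min` are underrepresented).
#'
#' @param scores Long score table from [score_all()].
#' @param gold Data frame of known interactions with `domain_id`,
#'   `protein_id`.
#' @param s_min Score threshold defining a hit (default -8.3).
#' @return A one-row tibble as in [fisher_overlap()].
#' @export
fisher_gold_standard <- function(scores, gold, s_min = -8.3) {
  stopifnot(all(c("domain_id", "protein_id") %in% names(gold)))
  pairs <- dplyr::summarise(
    dplyr::group_by(scores, .data$domain_id, .data$protein_id),
    best = max(.data$score),
    .groups = "drop"
  )
  key <- paste(pairs$domain_id, pairs$protein_id, sep = "\r")
  gkey <- unique(paste(gold$domain_id, gold$protein_id, sep = "\r"))
  gkey <- gkey[gkey %in% key]   # pairs outside the scored universe dropped
  in_gold <- key %in% gkey
  hit <- pairs$best > s_min
  fisher_overlap(
    universe = nrow(pairs),
    universe_hits = sum(hit),
    sample = sum(in_gold),
    sample_hits = sum(hit & in_gold)
  )
}
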