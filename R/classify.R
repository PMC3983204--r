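#' Apply a missense variant to a C-terminal window
#'
#' @param cterm The wild-type C-terminal sequence (the window itself).
#' @param position 1-based protein coordinate of the substituted residue.
#' @param ref_aa,alt_aa Wild-type and variant residues.
#' @param start_position 1-based protein coordinate of the window's first
#'   residue (default 1, i.e. `position` indexes into `cterm` directly).
#' @return The mutated C-terminal sequence.
#' @examples
#' mutate_cterm("GETWV", 5, "V", "R") # "GETWR"
#' @export
mutate_cterm <- function(cterm, position, ref_aa, alt_aa, start_position = 1L) {
  at <- position - start_position + 1L
  if (at < 1 || at > nchar(cterm)) {
    stop("not a C-terminal variant: position ", position,
         " outside window starting at ", start_position, call. = FALSE)
  }
  have <- substr(cterm, at, at)
  if (have != ref_aa) {
    stop("reference residue mismatch at position ", position,
         ": expected '", ref_aa, "', window has '", have, "'", call. = FALSE)
  }
  check_aa(alt_aa, what = "alternate residue")
  substr(cterm, at, at) <- alt_aa
  cterm
}

#' New C-terminus created by a stop-gain variant
#'
#' A premature stop at `position` truncates the protein to residues
#' `1 .. position - 1`; the new C-terminus is the trailing
#' `min(window, position - 1)` residues of the truncated product.
#'
#' @param sequence Full isoform sequence.
#' @param position 1-based position of the gained stop codon (>= 2).
#' @param window C-terminal window length (default 7).
#' @return A list with `cterm`, `start_position` (on the original protein
#'   coordinates) and `truncated_length`.
#' @examples
#' truncate_at_stop(paste0(strrep("A", 13), "WETWVAA"), 15)$cterm
#' @export
truncate_at_stop <- function(sequence, position, window = 7L) {
  if (position < 2) stop("empty protein after truncation", call. = FALSE)
  if (position > nchar(sequence)) {
    stop("stop position ", position, " beyond protein length ",
         nchar(sequence), call. = FALSE)
  }
  trunc_len <- position - 1L
  start <- max(1L, trunc_len - as.integer(window) + 1L)
  list(
    cterm = substr(sequence, start, trunc_len),
    start_position = start,
    truncated_length = trunc_len
  )
}

#' Classify a variant from wild-type and mutant per-domain scores
#'
#' The two-threshold rule: domain *i* supports **disrupts** iff the
#' wild-type score exceeds `s_max` *and* the mutant score falls below
#' `s_min` (both strict); it supports **creates** under the mirrored
#' condition. Scores inside the indeterminate band `[s_min, s_max]` never
#' support a call, which guarantees a domain cannot support both verdicts.
#' The verdict is `disrupts` if any domain supports it, else `creates` if
#' any domain does, else `neutral`.
#'
#' @param wt_scores,mut_scores Named numeric vectors of per-domain scores for
#'   the wild-type and mutant C-terminus; the domain sets must be identical.
#' @param s_min,s_max Score thresholds (defaults -8.3 and -6.4); `s_min`
#'   must be below `s_max`.
#' @return A list with `verdict` (`"disrupts"`, `"creates"` or `"neutral"`),
#'   `disrupt_domains`, `create_domains`, and a `domains` tibble of the
#'   per-domain score pairs.
#' @export
classify_variant <- function(wt_scores, mut_scores, s_min = -8.3, s_max = -6.4) {
  if (s_min >= s_max) stop("s_min must be < s_max", call. = FALSE)
  if (is.null(names(wt_scores)) || is.null(names(mut_scores)) ||
      !setequal(names(wt_scores), names(mut_scores)) ||
      length(wt_scores) != length(mut_scores)) {
    stop("mismatched domain sets between wild-type and mutant scores",
         call. = FALSE)
  }
  mut_scores <- mut_scores[names(wt_scores)]
  disrupt <- names(wt_scores)[wt_scores > s_max & mut_scores < s_min]
  create <- names(wt_scores)[wt_scores < s_min & mut_scores > s_max]
  verdict <- if (length(disrupt)) "disrupts"
             else if (length(create)) "creates"
             else "neutral"
  list(
    verdict = verdict,
    disrupt_domains = disrupt,
    create_domains = create,
    domains = tibble::tibble(
      domain_id = names(wt_scores),
      s_wt = unname(wt_scores),
      s_mut = unname(mut_scores)
    )
  )
}

#' Screen a variant table against PDZ specificity models
#'
#' The core screen: for every missense variant that falls in the C-terminal
#' window of an isoform, and for every stop-gain, the wild-type and mutant
#' (substituted or truncated) C-termini are scored against all PWMs and
#' classified with the two-threshold rule of [classify_variant()]. A variant
#' observed on several isoforms is classified per isoform; its rolled-up
#' verdict is `disrupts` if any (isoform, domain) pair supports disruption,
#' else `creates` if any supports creation, else `neutral`. Missense
#' variants outside every C-terminal window are reported `neutral` with
#' status `not_cterm` and are never scored. Per-variant failures (e.g. a
#' reference mismatch) are logged, marked `skipped`, and never abort the
#' screen.
#'
#' For stop-gain bookkeeping, a *predicted PDZ-mediated interaction* is a
#' (domain, protein) pair whose wild-type C-terminus scores above `s_max`;
#' `interactions_affected` counts the distinct pairs disrupted by at least
#' one stop-gain (one pair may be hit by several stops).
#'
#' @param proteome Proteome tibble (already compartment-filtered if wanted).
#' @param variants Variant tibble (see [read_variants()]).
#' @param pwms A `pdz_pwm` or list of them.
#' @param s_min,s_max Classification thresholds (defaults -8.3 / -6.4).
#' @param window C-terminal window length (default 7).
#' @return A `pdz_screen` object; use [tidy()] for the per-(variant, isoform)
#'   table and [glance()] for the summary counts. Fields: `results`
#'   (per variant-isoform: wild-type/mutant windows, best supporting domain
#'   and its score pair, verdict, status), `variant_verdicts` (rolled up per
#'   variant), `summary` (n_disrupt / n_create / n_neutral / n_skipped over
#'   screened variants, plus `interactions_affected`), and
#'   `affected_interactions` (the disrupted (domain, protein) pairs).
#' @export
screen_variants <- function(proteome, variants, pwms,
                            s_min = -8.3, s_max = -6.4, window = 7L) {
  if (s_min >= s_max) stop("s_min must be < s_max", call. = FALSE)
  pwms <- as_pwm_list(pwms)
  empty_results <- tibble::tibble(
    variant_id = character(), protein_id = character(),
    isoform_id = character(), kind = character(),
    wt_cterm = character(), mut_cterm = character(),
    best_domain = character(), s_wt = numeric(), s_mut = numeric(),
    verdict = character(), status = character(),
    disrupt_domains = list(), create_domains = list()
  )
  if (nrow(variants) == 0) {
    return(new_pdz_screen(empty_results, pwms, s_min, s_max,
                          affected = empty_interactions()))
  }

  score_vec <- function(ct) {
    vapply(pwms, score_cterm, numeric(1), cterm = ct)
  }

  rows <- vector("list", nrow(variants))
  affected <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    rows[[i]] <- tryCatch({
      iso <- proteome[proteome$protein_id == v$protein_id &
                        proteome$isoform_id == v$isoform_id, ]
      if (nrow(iso) == 0) {
        stop("unknown isoform '", v$isoform_id, "'", call. = FALSE)
      }
      seq <- iso$sequence[1]
      len <- nchar(seq)
      if (v$position < 1 || v$position > len) {
        stop("position out of range", call. = FALSE)
      }
      wt_start <- max(1L, len - as.integer(window) + 1L)
      wt_ct <- substr(seq, wt_start, len)

      if (v$kind == "missense") {
        if (v$position < wt_start) {
          # outside the C-terminal window of this isoform: not screened
          return_row <- tibble::tibble(
            variant_id = v$variant_id, protein_id = v$protein_id,
            isoform_id = v$isoform_id, kind = v$kind,
            wt_cterm = wt_ct, mut_cterm = NA_character_,
            best_domain = NA_character_, s_wt = NA_real_, s_mut = NA_real_,
            verdict = "neutral", status = "not_cterm",
            disrupt_domains = list(character()),
            create_domains = list(character())
          )
          return_row
        } else {
          mut_ct <- mutate_cterm(wt_ct, v$position, v$ref_aa, v$alt_aa,
                                 start_position = wt_start)
          cl <- classify_variant(score_vec(wt_ct), score_vec(mut_ct),
                                 s_min = s_min, s_max = s_max)
          result_row(v, wt_ct, mut_ct, cl)
        }
      } else { # stop_gain
        ref_here <- substr(seq, v$position, v$position)
        if (nzchar(v$ref_aa) && ref_here != v$ref_aa) {
          stop("reference residue mismatch", call. = FALSE)
        }
        tr <- truncate_at_stop(seq, v$position, window = window)
        wt_s <- score_vec(wt_ct)
        cl <- classify_variant(wt_s, score_vec(tr$cterm),
                               s_min = s_min, s_max = s_max)
        if (length(cl$disrupt_domains)) {
          affected[[length(affected) + 1]] <- tibble::tibble(
            domain_id = cl$disrupt_domains,
            protein_id = v$protein_id
          )
        }
        result_row(v, wt_ct, tr$cterm, cl)
      }
    }, error = function(e) {
      message("variant '", v$variant_id, "' skipped: ", conditionMessage(e))
      tibble::tibble(
        variant_id = v$variant_id, protein_id = v$protein_id,
        isoform_id = v$isoform_id, kind = v$kind,
        wt_cterm = NA_character_, mut_cterm = NA_character_,
        best_domain = NA_character_, s_wt = NA_real_, s_mut = NA_real_,
        verdict = NA_character_, status = "skipped",
        disrupt_domains = list(character()), create_domains = list(character())
      )
    })
  }

  results <- dplyr::bind_rows(rows)
  affected <- if (length(affected)) {
    dplyr::distinct(dplyr::bind_rows(affected))
  } else {
    empty_interactions()
  }
  new_pdz_screen(results, pwms, s_min, s_max, affected)
}

#' @noRd
empty_interactions <- function() {
  tibble::tibble(domain_id = character(), protein_id = character())
}

#' @noRd
result_row <- function(v, wt_ct, mut_ct, cl) {
  sup <- switch(cl$verdict,
    disrupts = cl$disrupt_domains,
    creates = cl$create_domains,
    character(0)
  )
  if (length(sup)) {
    d <- cl$domains[cl$domains$domain_id %in% sup, ]
    # most extreme wild-type score among supporting domains
    best <- d$domain_id[which.max(if (cl$verdict == "disrupts") d$s_wt else d$s_mut)]
  } else {
    best <- cl$domains$domain_id[which.max(cl$domains$s_wt)]
  }
  bi <- match(best, cl$domains$domain_id)
  tibble::tibble(
    variant_id = v$variant_id, protein_id = v$protein_id,
    isoform_id = v$isoform_id, kind = v$kind,
    wt_cterm = wt_ct, mut_cterm = mut_ct,
    best_domain = best,
    s_wt = cl$domains$s_wt[bi], s_mut = cl$domains$s_mut[bi],
    verdict = cl$verdict, status = "ok",
    disrupt_domains = list(cl$disrupt_domains),
    create_domains = list(cl$create_domains)
  )
}

#' @noRd
new_pdz_screen <- function(results, pwms, s_min, s_max, affected) {
  ok <- results[!is.na(results$verdict), ]
  verdicts <- dplyr::summarise(
    dplyr::group_by(ok, .data$variant_id),
    protein_id = .data$protein_id[1],
    kind = .data$kind[1],
    verdict = if (any(.data$verdict == "disrupts")) "disrupts"
              else if (any(.data$verdict == "creates")) "creates"
              else "neutral",
    screened = any(.data$status == "ok"),
    .groups = "drop"
  )
  screened <- verdicts[verdicts$screened, ]
  summary <- tibble::tibble(
    n_variants = length(unique(results$variant_id)),
    n_screened = nrow(screened),
    n_disrupt = sum(screened$verdict == "disrupts"),
    n_create = sum(screened$verdict == "creates"),
    n_neutral = sum(screened$verdict == "neutral"),
    n_skipped = length(unique(results$variant_id[results$status == "skipped"])),
    n_stopgain_screened = sum(screened$kind == "stop_gain"),
    interactions_affected = nrow(affected)
  )
  structure(
    list(
      results = results,
      variant_verdicts = verdicts,
      summary = summary,
      affected_interactions = affected,
      s_min = s_min, s_max = s_max,
      domain_ids = names(pwms)
    ),
    class = "pdz_screen"
  )
}

#' @export
print.pdz_screen <- function(x, ...) {
  s <- x$summary
  cat("<pdz_screen>", s$n_variants, "variants against",
      length(x$domain_ids), "PDZ domains",
      sprintf("(s_min = %.2f, s_max = %.2f)\n", x$s_min, x$s_max))
  cat("  screened:", s$n_screened,
      "| disrupts:", s$n_disrupt,
      "| creates:", s$n_create,
      "| neutral:", s$n_neutral,
      "| skipped:", s$n_skipped, "\n")
  if (s$n_stopgain_screened > 0) {
    cat("  stop-gains screened:", s$n_stopgain_screened,
        "| predicted interactions affected:", s$interactions_affected, "\n")
  }
  invisible(x)
}

#' Per-row and summary views of a screen
#'
#' `tidy()` returns the per-(variant, isoform) classification table (list
#' columns of supporting domains included); `glance()` the one-row summary
#' counts.
#'
#' @param x A `pdz_screen`.
#' @param ... Unused.
#' @method tidy pdz_screen
#' @export
tidy.pdz_screen <- function(x, ...) x$results

#' @rdname tidy.pdz_screen
#' @method glance pdz_screen
#' @export
glance.pdz_screen <- function(x, ...) x$summary

#' Write the flat classification table of a screen
#'
#' Column-stable TSV: `variant_id`, `protein_id`, `isoform_id`, `kind`,
#' `wt_cterm`, `mut_cterm`, `best_domain`, `s_wt`, `s_mut`, `verdict`,
#' `status`.
#'
#' @param screen A `pdz_screen`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen_tsv <- function(screen, path) {
  stopifnot(inherits(screen, "pdz_screen"))
  flat <- dplyr::select(
    screen$results,
    "variant_id", "protein_id", "isoform_id", "kind", "wt_cterm",
    "mut_cterm", "best_domain", "s_wt", "s_mut", "verdict", "status"
  )
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
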