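#' Build a PDZ specificity position weight matrix from aligned peptides
#'
#' Peptides selected against a PDZ domain (e.g. by phage display) are aligned
#' at their C-terminal residue and per-position residue frequencies become the
#' PWM. Positions are indexed by *offset from the C-terminus*: offset 0 is the
#' last residue, offset 6 the seventh-from-last. A PWM always spans 7
#' positions, the canonical maximum length of a C-terminal PDZ-binding site;
#' positions beyond the longest peptide get the uniform row 1/20.
#'
#' Construction is two-pass. Raw counts give raw frequencies, from which the
#' per-position information content
#' \deqn{IC_n = \log_2 20 - H_n} (Shannon entropy \eqn{H_n} in bits) is
#' computed. A pseudocount is then spread evenly over the 20 residues before
#' renormalising: smoothed count = raw count + \eqn{\kappa w(IC_n)/20}, where
#' the weight \eqn{w} depends on `pseudocount_mode`:
#' \describe{
#'   \item{`"proportional"`}{\eqn{w = IC_n} — a random count proportional to
#'     the information content of the column (the default used to account for
#'     under-sampled residues at specific positions).}
#'   \item{`"inverse"`}{\eqn{w = \log_2 20 - IC_n} — stronger smoothing at
#'     degenerate positions (the conventional direction).}
#'   \item{`"flat"`}{\eqn{w = 1} at every position.}
#' }
#' With `kappa = 0` the PWM holds the raw frequencies and unobserved residues
#' have probability exactly 0.
#'
#' @param peptides Character vector of peptides, each a string over the
#'   20-letter amino-acid alphabet, length at most 7. May also be a data frame
#'   with a `peptide` column (e.g. from [read_peptides()]).
#' @param domain_id Label for the PDZ domain the peptides were selected
#'   against. Proteins with several PDZ domains conventionally use a `#k`
#'   suffix (e.g. `"MPDZ#2"`).
#' @param kappa Nonnegative pseudocount weight \eqn{\kappa}. Default 1.
#' @param pseudocount_mode One of `"proportional"` (default), `"inverse"`,
#'   `"flat"`.
#' @return A `pdz_pwm` object: list with `domain_id`, `mat` (7 x 20 row-
#'   stochastic probability matrix, rows = offsets 0..6, columns =
#'   [AA_ALPHABET]), `ic` (per-offset information content, bits), `kappa`,
#'   `pseudocount_mode`, `n_peptides`.
#' @examples
#' pwm <- build_pwm(c("ETWV", "ESWV", "ETWI", "QTWV"), "toy", kappa = 0)
#' pwm$mat["0", c("V", "I")] # 0.75 0.25
#' pwm_consensus(pwm)
#' @seealso [score_cterm()], [pwm_consensus()], [simulate_peptides()]
#' @export
build_pwm <- function(peptides, domain_id = "domain", kappa = 1,
                      pseudocount_mode = c("proportional", "inverse", "flat")) {
  pseudocount_mode <- match.arg(pseudocount_mode)
  if (is.data.frame(peptides)) peptides <- peptides$peptide
  peptides <- as.character(peptides)
  if (length(peptides) == 0) stop("empty alignment", call. = FALSE)
  if (any(!nzchar(peptides))) stop("empty alignment", call. = FALSE)
  if (any(nchar(peptides) > PDZ_WINDOW)) {
    stop("peptides longer than ", PDZ_WINDOW, " residues: '",
         peptides[which(nchar(peptides) > PDZ_WINDOW)[1]], "'", call. = FALSE)
  }
  check_aa(peptides, what = "peptide")
  stopifnot(is.numeric(kappa), length(kappa) == 1, kappa >= 0)

  counts <- matrix(
    0, nrow = PDZ_WINDOW, ncol = 20,
    dimnames = list(offset = as.character(0:(PDZ_WINDOW - 1)),
                    residue = AA_ALPHABET)
  )
  for (pep in peptides) {
    res <- cterm_residues(pep)
    for (n in seq_along(res)) {
      counts[n, res[n]] <- counts[n, res[n]] + 1
    }
  }

  totals <- rowSums(counts)
  mat <- matrix(1 / 20, nrow = PDZ_WINDOW, ncol = 20,
                dimnames = dimnames(counts))
  ic <- numeric(PDZ_WINDOW)
  names(ic) <- rownames(counts)
  for (n in seq_len(PDZ_WINDOW)) {
    if (totals[n] == 0) next   # undefined position: uniform row, IC 0
    f <- counts[n, ] / totals[n]
    ic[n] <- position_information_content(f)
    w <- switch(pseudocount_mode,
      proportional = ic[n],
      inverse      = log2(20) - ic[n],
      flat         = 1
    )
    sm <- counts[n, ] + kappa * w / 20
    if (sum(sm) == 0) sm <- f else sm <- sm / sum(sm)
    mat[n, ] <- sm
  }

  structure(
    list(
      domain_id = domain_id,
      mat = mat,
      ic = ic,
      kappa = kappa,
      pseudocount_mode = pseudocount_mode,
      n_peptides = length(peptides)
    ),
    class = "pdz_pwm"
  )
}

#' Information content of a residue frequency vector
#'
#' \eqn{IC = \log_2 20 - H(f)} with \eqn{H} the Shannon entropy in bits
#' (\eqn{0 \log 0 = 0}). Ranges from 0 bits (uniform) to
#' \eqn{\log_2 20 \approx 4.32} bits (single residue).
#'
#' @param frequencies Numeric vector of 20 nonnegative frequencies summing
#'   to 1 (within 1e-9).
#' @return Information content in bits.
#' @examples
#' position_information_content(c(1, rep(0, 19))) # log2(20)
#' @export
position_information_content <- function(frequencies) {
  if (any(frequencies < 0)) {
    stop("negative frequency", call. = FALSE)
  }
  if (abs(sum(frequencies) - 1) > 1e-9) {
    stop("frequencies must sum to 1", call. = FALSE)
  }
  nz <- frequencies[frequencies > 0]
  h <- -sum(nz * log2(nz))
  log2(20) - h
}

#' Score a C-terminal sequence against a PDZ specificity PWM
#'
#' The binding score between domain *i* and C-terminus *j* is the summed
#' log10 probability
#' \deqn{S_{ij} = \sum_n \log_{10} p_i[n, j(n)]}
#' where \eqn{j(n)} is the residue of the C-terminus at offset *n* from its
#' last residue. The higher the score, the more similar the sequence is to
#' the domain's binding specificity; \eqn{S_{ij} \le 0} always. A sequence
#' shorter than 7 residues is scored over its available offsets only
#' (C-terminally anchored). `-Inf` can occur only for a PWM built with
#' `kappa = 0`.
#'
#' @param pwm A `pdz_pwm` object.
#' @param cterm A non-empty amino-acid string of length at most 7 (longer
#'   strings are scored on their last 7 residues).
#' @return A single numeric score.
#' @examples
#' pwm <- build_pwm(c("ETWV", "ESWV", "ETWI", "QTWV"), kappa = 0)
#' score_cterm(pwm, "ETWV")
#' @export
score_cterm <- function(pwm, cterm) {
  stopifnot(inherits(pwm, "pdz_pwm"))
  if (length(cterm) != 1 || is.na(cterm) || !nzchar(cterm)) {
    stop("empty C-terminal sequence", call. = FALSE)
  }
  check_aa(cterm, what = "C-terminus")
  res <- cterm_residues(cterm)
  if (length(res) > PDZ_WINDOW) res <- res[seq_len(PDZ_WINDOW)]
  idx <- match(res, AA_ALPHABET)
  sum(log10(pwm$mat[cbind(seq_along(res), idx)]))
}

#' Score every C-terminus against every PDZ PWM
#'
#' Computes the full score table over the Cartesian product of domains and
#' C-termini, in input order (permuting the C-terminus input permutes rows of
#' the output within each domain, nothing else).
#'
#' @param pwms A `pdz_pwm` or a list of them.
#' @param ctermini A data frame with a `cterm` column (e.g. from
#'   [extract_ctermini()]; `protein_id`/`isoform_id` columns are carried
#'   through), or a character vector of sequences.
#' @return A tibble with one row per (domain, C-terminus): `domain_id`,
#'   any identifier columns of the input, `cterm`, `score`.
#' @examples
#' pwm <- build_pwm(c("ETWV", "ESWV"), "toy", kappa = 1)
#' score_all(pwm, c("GETWV", "AAAAAAA"))
#' @export
score_all <- function(pwms, ctermini) {
  pwms <- as_pwm_list(pwms)
  if (is.character(ctermini)) {
    ctermini <- tibble::tibble(cterm = ctermini)
  }
  stopifnot(is.data.frame(ctermini), "cterm" %in% names(ctermini))
  if (length(pwms) == 0 || nrow(ctermini) == 0) {
    stop("score_all needs at least one PWM and one C-terminus", call. = FALSE)
  }
  keep <- intersect(c("protein_id", "isoform_id", "cterm"), names(ctermini))
  ct <- ctermini[keep]
  scores_for <- function(pwm) {
    s <- vapply(ct$cterm, function(x) {
      tryCatch(score_cterm(pwm, x), error = function(e) {
        stop("scoring domain '", pwm$domain_id, "' vs C-terminus '", x,
             "': ", conditionMessage(e), call. = FALSE)
      })
    }, numeric(1), USE.NAMES = FALSE)
    dplyr::mutate(ct, domain_id = pwm$domain_id, score = s, .before = 1)
  }
  dplyr::bind_rows(lapply(pwms, scores_for))
}

#' @noRd
as_pwm_list <- function(pwms) {
  if (inherits(pwms, "pdz_pwm")) pwms <- list(pwms)
  stopifnot(all(vapply(pwms, inherits, logical(1), "pdz_pwm")))
  names(pwms) <- vapply(pwms, `[[`, character(1), "domain_id")
  pwms
}

#' Consensus sequence of a PWM
#'
#' Per-position argmax residue over all 7 offsets, ties broken alphabetically.
#' Used for logo labelling and as the seed sequence for planted synthetic
#' motifs.
#'
#' @param pwm A `pdz_pwm`.
#' @return A 7-character string, N- to C-terminal order.
#' @export
pwm_consensus <- function(pwm) {
  stopifnot(inherits(pwm, "pdz_pwm"))
  best <- AA_ALPHABET[apply(pwm$mat, 1, which.max)]
  paste(rev(best), collapse = "")
}

#' Read a peptide set for one PDZ domain
#'
#' Accepts FASTA or plain one-peptide-per-line text; the domain is named
#' after the file (without extension) unless `domain_id` is given.
#'
#' @param path File path.
#' @param domain_id Optional domain label overriding the filename.
#' @return A tibble with columns `domain_id`, `peptide`.
#' @export
read_peptides <- function(path, domain_id = NULL) {
  if (is.null(domain_id)) {
    domain_id <- tools::file_path_sans_ext(basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty alignment", call. = FALSE)
  if (startsWith(lines[1], ">")) {
    peps <- as.character(Biostrings::readAAStringSet(path))
  } else {
    peps <- lines
  }
  check_aa(peps, what = paste0("peptide file '", basename(path), "'"))
  tibble::tibble(domain_id = domain_id, peptide = unname(peps))
}

#' Serialize / read a PWM as JSON
#'
#' The JSON carries `domain_id`, `kappa`, `pseudocount_mode` and the 7 x 20
#' probability matrix keyed by offset then residue, so models can be stored
#' and exchanged without the underlying peptides.
#'
#' @param pwm A `pdz_pwm`.
#' @param path Output / input file path.
#' @return `write_pwm_json()` returns `path` invisibly; `read_pwm_json()`
#'   returns a `pdz_pwm`.
#' @export
write_pwm_json <- function(pwm, path) {
  stopifnot(inherits(pwm, "pdz_pwm"))
  entries <- lapply(seq_len(nrow(pwm$mat)), function(n) as.list(pwm$mat[n, ]))
  names(entries) <- rownames(pwm$mat)
  obj <- list(
    domain_id = pwm$domain_id,
    kappa = pwm$kappa,
    pseudocount_mode = pwm$pseudocount_mode,
    n_peptides = pwm$n_peptides,
    ic = as.list(stats::setNames(pwm$ic, rownames(pwm$mat))),
    matrix = entries
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pwm_json
#' @export
read_pwm_json <- function(path) {
  obj <- jsonlite::read_json(path)
  mat <- matrix(
    0, nrow = PDZ_WINDOW, ncol = 20,
    dimnames = list(offset = as.character(0:(PDZ_WINDOW - 1)),
                    residue = AA_ALPHABET)
  )
  for (n in names(obj$matrix)) {
    mat[n, ] <- unlist(obj$matrix[[n]])[AA_ALPHABET]
  }
  structure(
    list(
      domain_id = obj$domain_id,
      mat = mat,
      ic = unlist(obj$ic),
      kappa = obj$kappa,
      pseudocount_mode = obj$pseudocount_mode,
      n_peptides = obj$n_peptides
    ),
    class = "pdz_pwm"
  )
}

#' @export
print.pdz_pwm <- function(x, ...) {
  cat("<pdz_pwm> domain", x$domain_id,
      "| built from", x$n_peptides, "peptides",
      "| kappa =", x$kappa, paste0("(", x$pseudocount_mode, ")"), "\n")
  cat("consensus:", pwm_consensus(x),
      "| total IC:", round(sum(x$ic), 2), "bits\n")
  invisible(x)
}

#' Tidy a PWM into a long tibble
#'
#' @param x A `pdz_pwm`.
#' @param ... Unused.
#' @return A tibble with `domain_id`, `offset` (0 = C-terminal residue),
#'   `residue`, `prob`, `ic`.
#' @method tidy pdz_pwm
#' @export
tidy.pdz_pwm <- function(x, ...) {
  tibble::tibble(
    domain_id = x$domain_id,
    offset = rep(0:(PDZ_WINDOW - 1), each = 20),
    residue = rep(AA_ALPHABET, PDZ_WINDOW),
    prob = as.vector(t(x$mat)),
    ic = rep(unname(x$ic), each = 20)
  )
}

#' Information-scaled logo plot of a PWM
#'
#' Stacked bars per position (x axis runs N- to C-terminal, labelled by
#' offset from the C-terminus), residue heights `prob * ic` so bar height is
#' the position's information content in bits.
#'
#' @param object A `pdz_pwm`.
#' @param min_prob Residues below this probability are dropped from the
#'   stack for legibility.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pdz_pwm
#' @export
autoplot.pdz_pwm <- function(object, min_prob = 0.02, ...) {
  d <- tidy.pdz_pwm(object)
  d <- dplyr::filter(d, .data$prob >= min_prob)
  d$position <- factor(-d$offset, levels = sort(unique(-d$offset)),
                       labels = paste0("P", sort(unique(-d$offset))))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position,
                                  y = .data$prob * .data$ic,
                                  fill = .data$residue,
                                  label = .data$residue)) +
    ggplot2::geom_col(colour = "grey30", linewidth = 0.2) +
    ggplot2::geom_text(position = ggplot2::position_stack(vjust = 0.5),
                       size = 3) +
    ggplot2::labs(
      x = "position (0 = C-terminal residue)",
      y = "information (bits)",
      title = paste("PDZ specificity:", object$domain_id)
    ) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
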