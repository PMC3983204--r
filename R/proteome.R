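#' Read a proteome of protein isoforms from FASTA
#'
#' Headers follow `protein_id|isoform_id`; a header without `|` uses the
#' whole header as both ids. Records with characters outside the 20-letter
#' alphabet (e.g. `X`, `U`, `*`) or empty sequences are skipped with a
#' warning rather than aborting the run.
#'
#' @param path FASTA file of amino-acid sequences.
#' @return A tibble with `protein_id`, `isoform_id`, `sequence`.
#' @export
read_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  hdr <- names(aa)
  seqs <- as.character(aa)
  protein_id <- sub("\\|.*$", "", hdr)
  isoform_id <- ifelse(grepl("|", hdr, fixed = TRUE),
                       sub("^[^|]*\\|", "", hdr), hdr)
  ok <- nzchar(seqs) &
    vapply(strsplit(seqs, "", fixed = TRUE),
           function(ch) all(ch %in% AA_ALPHABET), logical(1))
  if (any(!ok)) {
    warning(sum(!ok), " unparseable FASTA record(s) skipped (empty or ",
            "non-standard residues), e.g. '", hdr[which(!ok)[1]], "'",
            call. = FALSE)
  }
  tibble::tibble(
    protein_id = protein_id[ok],
    isoform_id = isoform_id[ok],
    sequence = unname(seqs[ok])
  )
}

#' Read protein-level GO annotations
#'
#' Two-column TSV (`protein_id`, `go_term`), one pair per line, no header
#' required (a header line starting with `protein_id` is tolerated).
#'
#' @param path TSV path.
#' @return A tibble with `protein_id`, `go_term`.
#' @export
read_go_annotations <- function(path) {
  d <- utils::read.delim(path, header = FALSE, col.names = c("protein_id", "go_term"),
                         colClasses = "character")
  if (nrow(d) > 0 && d$protein_id[1] == "protein_id") d <- d[-1, , drop = FALSE]
  check_go(d$go_term)
  tibble::as_tibble(d)
}

#' @noRd
check_go <- function(terms) {
  bad <- !grepl("^GO:\\d{7}$", terms)
  if (any(bad)) {
    stop("malformed GO ID: '", terms[which(bad)[1]], "'", call. = FALSE)
  }
  invisible(terms)
}

#' Remove extracellular and mitochondrial proteins
#'
#' PDZ domains act primarily in the cytoplasm, so proteins annotated to
#' extracellular compartments (extracellular matrix GO:0031012 or
#' extracellular space GO:0005615) are removed — unless they also carry the
#' plasma-membrane-part rescue term GO:0044459, since many plasma membrane
#' proteins are co-annotated extracellular. Proteins annotated with the
#' mitochondrial-part term GO:0044429 are removed unconditionally.
#' Membership is by the literal term sets supplied: no GO-graph ancestor
#' propagation is performed. Unannotated proteins are retained.
#'
#' @param proteome Tibble from [read_proteome()] (any tibble with a
#'   `protein_id` column works; all isoform rows of a removed protein go).
#' @param annotations Tibble with `protein_id`, `go_term`
#'   ([read_go_annotations()]).
#' @param extracellular_terms,rescue_term,mito_term GO term sets defining
#'   the filter.
#' @return The filtered proteome tibble, with a `filter_report` attribute:
#'   a tibble (`protein_id`, `reason`) of removed proteins. Retrieve it with
#'   [compartment_filter_report()].
#' @export
filter_compartments <- function(proteome, annotations,
                                extracellular_terms = c("GO:0031012", "GO:0005615"),
                                rescue_term = "GO:0044459",
                                mito_term = "GO:0044429") {
  stopifnot(is.data.frame(proteome), "protein_id" %in% names(proteome))
  stopifnot(is.data.frame(annotations),
            all(c("protein_id", "go_term") %in% names(annotations)))
  check_go(annotations$go_term)
  check_go(c(extracellular_terms, rescue_term, mito_term))

  go_sets <- split(annotations$go_term, annotations$protein_id)
  classify_protein <- function(p) {
    g <- go_sets[[p]]
    if (is.null(g)) return(NA_character_)
    if (mito_term %in% g) return("mitochondrial")
    if (any(extracellular_terms %in% g) && !(rescue_term %in% g)) {
      return("extracellular")
    }
    NA_character_
  }
  prot <- unique(proteome$protein_id)
  reason <- unname(vapply(prot, classify_protein, character(1)))
  removed <- tibble::tibble(protein_id = prot, reason = reason)
  removed <- removed[!is.na(removed$reason), , drop = FALSE]

  out <- dplyr::filter(proteome, !(.data$protein_id %in% removed$protein_id))
  attr(out, "filter_report") <- removed
  out
}

#' @rdname filter_compartments
#' @param filtered A proteome returned by [filter_compartments()].
#' @export
compartment_filter_report <- function(filtered) {
  rep <- attr(filtered, "filter_report")
  if (is.null(rep)) {
    tibble::tibble(protein_id = character(), reason = character())
  } else {
    rep
  }
}

#' Extract the C-terminal window of every isoform
#'
#' One record per isoform — identical suffixes shared by several isoforms
#' are *not* deduplicated, because variant and amino-acid counting is
#' per isoform. Proteins shorter than the window yield their whole sequence.
#'
#' @param proteome Tibble with `protein_id`, `isoform_id`, `sequence`.
#' @param window Window length; 7 is the canonical maximum span of a
#'   C-terminal PDZ-binding site.
#' @return A tibble with `protein_id`, `isoform_id`, `cterm`,
#'   `start_position` (1-based position of the window's first residue) and
#'   `cterm_length`.
#' @export
extract_ctermini <- function(proteome, window = 7L) {
  stopifnot(window >= 1)
  stopifnot(all(c("protein_id", "isoform_id", "sequence") %in% names(proteome)))
  len <- nchar(proteome$sequence)
  start <- pmax(1L, len - as.integer(window) + 1L)
  tibble::tibble(
    protein_id = proteome$protein_id,
    isoform_id = proteome$isoform_id,
    cterm = substr(proteome$sequence, start, len),
    start_position = start,
    cterm_length = len - start + 1L
  )
}

#' Read a protein-level variant table
#'
#' TSV with columns `variant_id`, `protein_id`, `isoform_id`, `position`
#' (1-based), `ref_aa`, `alt_aa` (empty for stop-gains), `kind`
#' (`missense` or `stop_gain`).
#'
#' @param path TSV path.
#' @return A tibble of variants.
#' @export
read_variants <- function(path) {
  v <- readr::read_tsv(
    path,
    col_types = readr::cols(
      variant_id = readr::col_character(),
      protein_id = readr::col_character(),
      isoform_id = readr::col_character(),
      position = readr::col_integer(),
      ref_aa = readr::col_character(),
      alt_aa = readr::col_character(),
      kind = readr::col_character()
    ),
    progress = FALSE
  )
  v$alt_aa[is.na(v$alt_aa)] <- ""
  bad <- !v$kind %in% c("missense", "stop_gain")
  if (any(bad)) {
    stop("unknown variant kind '", v$kind[which(bad)[1]], "'", call. = FALSE)
  }
  v
}

#' Does a variant fall in the C-terminus of any splice variant?
#'
#' A variant affects the C-terminal sequence of a protein if it falls within
#' the last `window` residues of *any* isoform carrying it. Each
#' (variant, isoform) row is assessed separately and the per-variant flag is
#' the OR over isoforms.
#'
#' @param variants Variant tibble (see [read_variants()]).
#' @param proteome Proteome tibble.
#' @param window C-terminal window length (default 7).
#' @return The variants tibble augmented with `isoform_length`, `in_cterm`
#'   (this isoform) and `in_cterm_any` (OR over all isoform rows sharing the
#'   `variant_id`).
#' @export
variant_in_cterm <- function(variants, proteome, window = 7L) {
  key <- paste(proteome$protein_id, proteome$isoform_id, sep = "\r")
  len <- stats::setNames(nchar(proteome$sequence), key)
  seqs <- stats::setNames(proteome$sequence, key)
  vkey <- paste(variants$protein_id, variants$isoform_id, sep = "\r")
  missing <- !(vkey %in% key)
  if (any(missing)) {
    stop("unknown isoform '", variants$isoform_id[which(missing)[1]],
         "' for variant '", variants$variant_id[which(missing)[1]], "'",
         call. = FALSE)
  }
  vlen <- unname(len[vkey])
  if (any(variants$position < 1 | variants$position > vlen)) {
    i <- which(variants$position < 1 | variants$position > vlen)[1]
    stop("position out of range for variant '", variants$variant_id[i],
         "' (position ", variants$position[i], ", isoform length ",
         vlen[i], ")", call. = FALSE)
  }
  ref_here <- substr(seqs[vkey], variants$position, variants$position)
  mism <- ref_here != variants$ref_aa
  if (any(mism)) {
    i <- which(mism)[1]
    stop("reference residue mismatch for variant '", variants$variant_id[i],
         "' at ", variants$protein_id[i], ":", variants$isoform_id[i],
         " position ", variants$position[i], ": table says '",
         variants$ref_aa[i], "', sequence has '", ref_here[i], "'",
         call. = FALSE)
  }
  out <- dplyr::mutate(
    variants,
    isoform_length = vlen,
    in_cterm = .data$position >= .data$isoform_length - (window - 1L)
  )
  dplyr::mutate(
    dplyr::group_by(out, .data$variant_id),
    in_cterm_any = any(.data$in_cterm)
  ) |>
    dplyr::ungroup()
}
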