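#' The 20 standard amino acids
#'
#' One-letter codes in alphabetical order. This ordering is the tie-break
#' order everywhere a tie can occur (e.g. [pwm_consensus()]).
#'
#' @format A length-20 character vector.
#' @export
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# number of positions in a canonical C-terminal PDZ-binding site
PDZ_WINDOW <- 7L

#' @keywords internal
#' @noRd
check_aa <- function(x, what = "sequence") {
  bad <- !vapply(
    strsplit(x, "", fixed = TRUE),
    function(ch) all(ch %in% AA_ALPHABET),
    logical(1)
  )
  if (any(bad)) {
    stop(
      "invalid residue (outside the 20-letter amino-acid alphabet) in ",
      what, ": '", x[which(bad)[1]], "'",
      call. = FALSE
    )
  }
  invisible(x)
}

# split a sequence into residues ordered by offset from the C-terminus:
# element 1 = last residue (offset 0), element 2 = second-to-last, ...
#' @noRd
cterm_residues <- function(seq) {
  rev(strsplit(seq, "", fixed = TRUE)[[1]])
}
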