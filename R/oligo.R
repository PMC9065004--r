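#' Terminus mass adjustments
#'
#' The internal-residue convention makes a 5'-OH / 3'-linear-phosphate chain
#' the neutral reference (sum of residues + H2O). Other terminal chemistries
#' are additive adjustments relative to it: a 5'-phosphate adds HPO3; a 3'-OH
#' removes HPO3; a 2',3'-cyclic phosphate (cP) is one water lighter than the
#' linear phosphate.
#'
#' @param five_prime One of `"OH"`, `"P"`.
#' @param three_prime One of `"OH"`, `"P"`, `"cP"`.
#' @return Mass adjustment in Da to add to the 5'-OH/3'-P chain mass.
#' @export
terminus_adjustment <- function(five_prime = c("OH", "P"),
                                three_prime = c("P", "OH", "cP")) {
  five_prime <- match.arg(five_prime)
  three_prime <- match.arg(three_prime)
  d5 <- switch(five_prime, OH = 0, P = .const$hpo3)
  d3 <- switch(three_prime, P = 0, OH = -.const$hpo3, cP = -.const$h2o)
  d5 + d3
}

#' Construct an oligonucleotide
#'
#' An `oligo` is a nucleolytic fragment: residue codes, terminal chemistry,
#' labeling scheme, and (optionally) its coordinates on the parent sequence.
#'
#' @param seq Sequence string of single-character residue codes.
#' @param five_prime 5' chemistry, `"OH"` or `"P"`.
#' @param three_prime 3' chemistry, `"P"`, `"OH"` or `"cP"`.
#' @param scheme A [labeling_scheme()].
#' @param alphabet Residue alphabet.
#' @param parent_id,start,end Provenance on the parent sequence (1-based,
#'   inclusive).
#' @param missed Number of missed cleavage sites retained.
#' @return An object of class `oligo`.
#' @export
#' @examples
#' oligo("ACG")                    # 5'-OH / 3'-P by default
#' oligo("ACG", three_prime = "cP")
oligo <- function(seq, five_prime = "OH", three_prime = "P",
                  scheme = scheme_identity(), alphabet = default_alphabet(),
                  parent_id = NA_character_, start = NA_integer_,
                  end = NA_integer_, missed = 0L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) stop("empty sequence", call. = FALSE)
  codes <- strsplit(seq, "")[[1]]
  .alphabet_row(alphabet, codes)  # validates codes
  structure(
    list(seq = seq, codes = codes, five_prime = five_prime,
         three_prime = three_prime, scheme = scheme, alphabet = alphabet,
         parent_id = parent_id, start = start, end = end,
         missed = as.integer(missed)),
    class = "oligo"
  )
}

#' @export
print.oligo <- function(x, ...) {
  cat(sprintf("<oligo> 5'-%s/%s/3'-%s [%s, %s]", x$five_prime, x$seq,
              x$three_prime, x$scheme$name, x$scheme$channel),
      if (!is.na(x$start)) sprintf(" %s:%d-%d", x$parent_id, x$start, x$end),
      "\n", sep = "")
  invisible(x)
}

#' Neutral monoisotopic mass of an oligonucleotide
#'
#' Sum of internal-residue masses plus one water, plus terminal adjustments,
#' under the oligo's labeling scheme.
#'
#' @param x An [oligo()].
#' @return Neutral monoisotopic mass in Da.
#' @export
#' @examples
#' oligo_neutral_mass(oligo("ACG"))  # 997.1518
oligo_neutral_mass <- function(x) {
  stopifnot(inherits(x, "oligo"))
  sum(residue_mass(x$codes, x$alphabet, x$scheme)) + .const$h2o +
    terminus_adjustment(x$five_prime, x$three_prime)
}

#' m/z of a deprotonated ion (negative ESI)
#'
#' RNA is analyzed in negative ionization; an ion of charge z has lost z
#' protons: m/z = (M - z * 1.007276) / z.
#'
#' @param neutral_mass Neutral monoisotopic mass in Da.
#' @param charge Charge-state magnitude (positive integer).
#' @return m/z value(s).
#' @export
#' @examples
#' mz_from_mass(997.1518, 1)
#' mz_from_mass(997.1518, 2)
mz_from_mass <- function(neutral_mass, charge) {
  if (any(charge < 1) || any(charge != as.integer(charge))) {
    stop("charge must be a positive integer", call. = FALSE)
  }
  (neutral_mass - charge * .const$proton) / charge
}

#' Neutral mass back from an m/z value
#'
#' Inverse of [mz_from_mass()] for deprotonated ions.
#'
#' @param mz Observed m/z.
#' @param charge Charge-state magnitude.
#' @return Neutral mass in Da.
#' @export
mass_from_mz <- function(mz, charge) {
  mz * charge + charge * .const$proton
}

# signed ppm difference of observed vs theoretical m/z
.ppm <- function(observed, theoretical) {
  (observed - theoretical) / theoretical * 1e6
}
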