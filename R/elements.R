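#' Monoisotopic element masses
#'
#' Monoisotopic atomic masses (Da) for the elements occurring in RNA plus the
#' stable heavy isotopes used in metabolic labeling. Values are CODATA/NIST
#' monoisotopic masses, hard-coded so that mass arithmetic is bit-stable.
#'
#' @return Named numeric vector of monoisotopic masses in Da. Heavy isotopes
#'   are keyed `"2H"`, `"13C"`, `"15N"`, `"18O"`.
#' @export
#' @examples
#' element_masses()[["15N"]] - element_masses()[["N"]]  # ~0.99703 Da
element_masses <- function() {
  c(
    H = 1.00782503207,
    C = 12.0,
    N = 14.0030740048,
    O = 15.9949146196,
    P = 30.97376163,
    S = 31.97207100,
    `2H`  = 2.01410177785,
    `13C` = 13.00335483507,
    `15N` = 15.00010889890,
    `18O` = 17.99916103200
  )
}

# physical constants used across the package
.const <- list(
  proton  = 1.00727646688,  # mass of H+ (Da); deprotonation in negative ESI
  h2o     = 18.0105646863,
  hpo3    = 79.96633088860, # H + P + 3*O
  neutron = 1.00335         # isotopologue spacing used for M+1/M-1 matching
)

#' Parse a molecular formula string
#'
#' Hill-style formulas such as `"C9H12N3O7P"`. Element symbols are one
#' uppercase letter optionally followed by one lowercase letter; counts
#' default to 1.
#'
#' @param formula Single formula string.
#' @return Named integer vector of atom counts.
#' @export
#' @examples
#' parse_formula("C9H12N3O7P")
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  if (formula == "" || formula == "0") {
    return(stats::setNames(integer(0), character(0)))
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(toks)) != nchar(formula)) {
    stop("malformed formula: '", formula, "'", call. = FALSE)
  }
  sym <- sub("[0-9]*$", "", toks)
  cnt <- as.integer(ifelse(grepl("[0-9]+$", toks),
                           sub("^[A-Za-z]+", "", toks), "1"))
  out <- tapply(cnt, sym, sum)
  stats::setNames(as.integer(out), names(out))
}

#' Monoisotopic mass of a molecular formula
#'
#' @param formula Formula string or named count vector from [parse_formula()].
#' @return Mass in Da.
#' @export
#' @examples
#' formula_mass("H2O")  # 18.010565
formula_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  if (length(counts) == 0L) return(0)
  em <- element_masses()
  unknown <- setdiff(names(counts), names(em))
  if (length(unknown) > 0L) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  sum(em[names(counts)] * counts)
}
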