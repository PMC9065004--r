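#' Default residue alphabet
#'
#' Single-character residue codes for the four canonical ribonucleotides plus
#' a starter set of post-transcriptional modifications. Each internal residue
#' is defined as the nucleoside-3'-monophosphate minus one water, so a
#' 5'-OH/3'-P chain is simply the sum of its residues plus H2O. The base
#' formula is the neutral nucleobase (BH) lost in a-B ions and precursor base
#' losses.
#'
#' Codes are case- and digit-sensitive single characters, so well over 50
#' distinct modifications can be carried in one alphabet; add rows with
#' [add_residue()] or load a custom table with [read_alphabet()].
#'
#' @return A data.frame with columns `code`, `name`, `formula`,
#'   `base_formula`.
#' @export
#' @examples
#' alf <- default_alphabet()
#' alf[alf$code == "Y", ]  # pseudouridine
default_alphabet <- function() {
  df <- data.frame(
    code = c("A", "C", "G", "U", "Y", "1", "5", "7", "3", "6", "4", "D"),
    name = c("A", "C", "G", "U", "Y", "m1Y", "m5C", "m7G", "m3U",
             "m62A", "m4Cm", "D"),
    formula = c(
      "C10H12N5O6P",  # A
      "C9H12N3O7P",   # C
      "C10H12N5O7P",  # G
      "C9H11N2O8P",   # U
      "C9H11N2O8P",   # Y = pseudouridine (C-glycoside isomer of U)
      "C10H13N2O8P",  # m1Y = N1-methylpseudouridine
      "C10H14N3O7P",  # m5C
      "C11H14N5O7P",  # m7G
      "C10H13N2O8P",  # m3U
      "C12H16N5O6P",  # m62A = N6,N6-dimethyladenosine
      "C11H16N3O7P",  # m4Cm = N4,2'-O-dimethylcytidine
      "C9H13N2O8P"    # D = dihydrouridine
    ),
    base_formula = c(
      "C5H5N5",    # adenine
      "C4H5N3O",   # cytosine
      "C5H5N5O",   # guanine
      "C4H4N2O2",  # uracil
      "C4H4N2O2",  # uracil (pseudouridine)
      "C5H6N2O2",  # 1-methylpseudouracil
      "C5H7N3O",   # 5-methylcytosine
      "C6H7N5O",   # 7-methylguanine
      "C5H6N2O2",  # 3-methyluracil
      "C7H9N5",    # N6,N6-dimethyladenine
      "C5H7N3O",   # N4-methylcytosine (2'-O-methyl stays on the sugar)
      "C4H6N2O2"   # dihydrouracil
    ),
    stringsAsFactors = FALSE
  )
  class(df) <- c("residue_alphabet", "data.frame")
  df
}

#' Add or replace a residue definition
#'
#' @param alphabet A residue alphabet data.frame.
#' @param code Single-character residue code (case-sensitive letter or digit).
#' @param name Display name (e.g. `"m5C"`).
#' @param formula Elemental formula of the internal residue
#'   (nucleoside-3'-monophosphate minus water).
#' @param base_formula Elemental formula of the neutral nucleobase.
#' @return The updated alphabet.
#' @export
add_residue <- function(alphabet, code, name, formula, base_formula) {
  stopifnot(nchar(code) == 1L)
  counts <- parse_formula(formula)            # validates
  if (any(counts < 0)) stop("negative element counts", call. = FALSE)
  parse_formula(base_formula)
  alphabet <- alphabet[alphabet$code != code, , drop = FALSE]
  row <- data.frame(code = code, name = name, formula = formula,
                    base_formula = base_formula, stringsAsFactors = FALSE)
  out <- rbind(alphabet, row)
  rownames(out) <- NULL
  class(out) <- c("residue_alphabet", "data.frame")
  out
}

.alphabet_row <- function(alphabet, code) {
  i <- match(code, alphabet$code)
  if (any(is.na(i))) {
    stop("unknown residue code(s): ",
         paste(unique(code[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  alphabet[i, , drop = FALSE]
}

#' Construct an isotope-labeling scheme
#'
#' A scheme is applied on top of the natural-abundance elemental formulas:
#' `element_swap` replaces every atom of an element by a heavy isotope
#' (e.g. all N by 15N for metabolic 15N labeling), and `residue_h` gives, per
#' residue code, how many hydrogens are exchanged for deuterium (e.g. 2 for C
#' and U, 1 for pseudouridine under 5,6-2H-uracil feeding; the exchanged
#' positions sit on the pyrimidine base, so base-loss masses shift too).
#'
#' @param name Scheme name.
#' @param channel `"light"` or `"heavy"`; tag carried into library entries.
#' @param element_swap Named character vector, element -> isotope key of
#'   [element_masses()], e.g. `c(N = "15N")`.
#' @param residue_h Named numeric vector, residue code -> number of 2H
#'   substitutions.
#' @return An object of class `labeling_scheme`.
#' @export
#' @examples
#' scheme_15n()
#' labeling_scheme("13C", "heavy", element_swap = c(C = "13C"))
labeling_scheme <- function(name, channel = c("light", "heavy"),
                            element_swap = NULL, residue_h = NULL) {
  channel <- match.arg(channel)
  em <- element_masses()
  if (!is.null(element_swap)) {
    bad <- setdiff(c(names(element_swap), unname(element_swap)), names(em))
    if (length(bad) > 0L) {
      stop("scheme references unknown element/isotope: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(name = name, channel = channel,
                 element_swap = element_swap, residue_h = residue_h),
            class = "labeling_scheme")
}

#' @rdname labeling_scheme
#' @export
scheme_identity <- function() labeling_scheme("unlabeled", "light")

#' @rdname labeling_scheme
#' @export
scheme_15n <- function() {
  labeling_scheme("15N", "heavy", element_swap = c(N = "15N"))
}

#' @rdname labeling_scheme
#' @export
scheme_13c <- function() {
  labeling_scheme("13C", "heavy", element_swap = c(C = "13C"))
}

#' Metabolic 5,6-2H-uracil labeling
#'
#' Pyrimidines synthesized from 5,6-2H-uracil carry two deuteriums (U, C and
#' their base-methylated derivatives keep H5/H6 or the methylated analogue),
#' while pseudouridine retains only one because its C5 is bonded to the
#' ribose. Purines are not labeled under this scheme.
#'
#' @return A `labeling_scheme`.
#' @export
scheme_2h_pyrimidine <- function() {
  labeling_scheme(
    "5,6-2H-uracil", "light",
    residue_h = c(C = 2, U = 2, Y = 1, `5` = 1, `3` = 2, `1` = 1, `4` = 1)
  )
}

# mass delta contributed by a scheme to a formula; residue code optional
.scheme_delta <- function(scheme, counts, code = NULL) {
  em <- element_masses()
  d <- 0
  if (!is.null(scheme$element_swap)) {
    for (el in names(scheme$element_swap)) {
      n <- counts[el]
      if (!is.na(n) && n > 0) {
        d <- d + n * (em[[scheme$element_swap[[el]]]] - em[[el]])
      }
    }
  }
  if (!is.null(code) && !is.null(scheme$residue_h) &&
      code %in% names(scheme$residue_h)) {
    k <- scheme$residue_h[[code]]
    nh <- counts["H"]
    if (is.na(nh) || nh < k) {
      stop("scheme substitutes ", k, " H in residue '", code,
           "' but formula has ", ifelse(is.na(nh), 0, nh), call. = FALSE)
    }
    d <- d + k * (em[["2H"]] - em[["H"]])
  }
  unname(d)
}

#' Monoisotopic mass of one internal residue
#'
#' Mass of the internal residue (nucleoside-3'-monophosphate minus water)
#' under a labeling scheme.
#'
#' @param code Residue code (vectorized).
#' @param alphabet Residue alphabet; default [default_alphabet()].
#' @param scheme A [labeling_scheme()]; default unlabeled.
#' @return Numeric vector of masses in Da.
#' @export
#' @examples
#' residue_mass("C")                       # 305.0413
#' residue_mass("U") - residue_mass("C")   # 0.984
residue_mass <- function(code, alphabet = default_alphabet(),
                         scheme = scheme_identity()) {
  rows <- .alphabet_row(alphabet, code)
  vapply(seq_len(nrow(rows)), function(i) {
    counts <- parse_formula(rows$formula[i])
    formula_mass(counts) + .scheme_delta(scheme, counts, rows$code[i])
  }, numeric(1))
}

#' Monoisotopic mass of a residue's neutral nucleobase
#'
#' The base lost in a-B fragment ions and precursor base-loss ions, under the
#' same labeling scheme as the residue (deuterium substitutions sit on the
#' base).
#'
#' @inheritParams residue_mass
#' @return Numeric vector of masses in Da.
#' @export
#' @examples
#' base_mass("A")  # adenine, 135.0545
base_mass <- function(code, alphabet = default_alphabet(),
                      scheme = scheme_identity()) {
  rows <- .alphabet_row(alphabet, code)
  vapply(seq_len(nrow(rows)), function(i) {
    counts <- parse_formula(rows$base_formula[i])
    formula_mass(counts) + .scheme_delta(scheme, counts, rows$code[i])
  }, numeric(1))
}

#' Read / write a residue alphabet
#'
#' Tab-separated, four columns: `code`, `name`, `formula`, `base_formula`.
#'
#' @param path File path.
#' @param alphabet Alphabet to write.
#' @return `read_alphabet()` returns a residue alphabet data.frame.
#' @export
read_alphabet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("code", "name", "formula", "base_formula")
  if (!all(need %in% names(df))) {
    stop("alphabet file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$code)) stop("duplicate residue codes", call. = FALSE)
  for (f in df$formula) parse_formula(f)
  for (f in df$base_formula) parse_formula(f)
  df <- df[, need]
  class(df) <- c("residue_alphabet", "data.frame")
  df
}

#' @rdname read_alphabet
#' @export
write_alphabet <- function(alphabet, path) {
  utils::write.table(as.data.frame(alphabet), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a labeling scheme
#'
#' Tab-separated key/value rows: `name` and `channel` rows, one
#' `element <from> <iso>` row per element swap, one `residue <code> <k>` row
#' per deuterium substitution count.
#'
#' @param path File path.
#' @param scheme A `labeling_scheme`.
#' @return `read_scheme()` returns a `labeling_scheme`.
#' @export
write_scheme <- function(scheme, path) {
  rows <- data.frame(field = "name", key = scheme$name, value = "",
                     stringsAsFactors = FALSE)
  rows <- rbind(rows, data.frame(field = "channel", key = scheme$channel,
                                 value = ""))
  if (!is.null(scheme$element_swap)) {
    rows <- rbind(rows, data.frame(field = "element",
                                   key = names(scheme$element_swap),
                                   value = unname(scheme$element_swap)))
  }
  if (!is.null(scheme$residue_h)) {
    rows <- rbind(rows, data.frame(field = "residue",
                                   key = names(scheme$residue_h),
                                   value = as.character(scheme$residue_h)))
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  nm <- df$key[df$field == "name"]
  ch <- df$key[df$field == "channel"]
  el <- df[df$field == "element", , drop = FALSE]
  rh <- df[df$field == "residue", , drop = FALSE]
  labeling_scheme(
    name = nm, channel = ch,
    element_swap = if (nrow(el)) stats::setNames(el$value, el$key),
    residue_h = if (nrow(rh)) stats::setNames(as.numeric(rh$value), rh$key)
  )
}
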