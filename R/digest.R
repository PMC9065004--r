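#' Endonuclease specificities
#'
#' Built-in cleavage rules as sets of residue codes after which the backbone
#' is cut (3' side of the named residue). RNase T1 cuts after G; RNase A
#' after pyrimidines (C, U, pseudouridine, and N1-methylpseudouridine in
#' fully substituted mRNA). Cusativin, MC1 and MAZ specificities are shipped
#' as editable defaults taken from the nuclease literature, not asserted
#' constants — override via `enzyme_spec()`. `"nonspecific"` cuts after every
#' residue; `"none"` never cuts.
#'
#' @param name Enzyme name or `"nonspecific"` / `"none"`.
#' @param cut_after For a custom enzyme, character vector of residue codes.
#' @return An object of class `enzyme_spec`.
#' @export
#' @examples
#' enzyme_spec("T1")
#' enzyme_spec("custom", cut_after = c("A", "G"))
enzyme_spec <- function(name, cut_after = NULL) {
  builtin <- list(
    T1 = "G",
    A = c("C", "U", "Y", "1", "5", "3"),
    cusativin = "C",
    MC1 = "U",
    MAZ = "A",
    nonspecific = NA,
    none = character(0)
  )
  if (is.null(cut_after)) {
    if (!name %in% names(builtin)) {
      stop("unknown enzyme '", name, "'; built-ins: ",
           paste(names(builtin), collapse = ", "), call. = FALSE)
    }
    cut_after <- builtin[[name]]
  } else {
    if (length(cut_after) == 0L && name != "none") {
      stop("cleavage rule must be a non-empty residue set", call. = FALSE)
    }
  }
  structure(list(name = name, cut_after = cut_after), class = "enzyme_spec")
}

.cut_sites <- function(codes, enzyme) {
  n <- length(codes)
  if (n <= 1L) return(integer(0))
  idx <- seq_len(n - 1L)  # potential cut after position i
  if (identical(enzyme$name, "nonspecific") ||
      (length(enzyme$cut_after) == 1L && is.na(enzyme$cut_after[1L]))) {
    return(idx)
  }
  idx[codes[idx] %in% enzyme$cut_after]
}

#' In silico endonuclease digestion
#'
#' Cleaves a (modified) sequence according to an enzyme's base specificity
#' and enumerates every fragment with up to `max_missed` retained internal
#' cleavage sites. Coordinates are 1-based inclusive on the parent.
#'
#' @param seq Sequence string (modification codes already substituted; see
#'   [apply_modifications()]).
#' @param enzyme An [enzyme_spec()] or enzyme name.
#' @param max_missed Maximum number of missed cleavages (>= 0).
#' @param parent_id Identifier recorded on each fragment.
#' @param min_length,max_length Product length bounds; mainly to keep
#'   nonspecific digests finite. Defaults keep everything.
#' @return A data.frame with columns `parent_id`, `start`, `end`, `seq`,
#'   `missed`, `is_parent_3p` (fragment ends at the parent 3' terminus).
#' @export
#' @examples
#' digest("AUCGGAUG", "T1")                 # AUCG | G | AUG
#' digest("AUCGGAUG", "T1", max_missed = 1)
digest <- function(seq, enzyme = "T1", max_missed = 0L,
                   parent_id = "seq1", min_length = 1L, max_length = Inf) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) > 0L,
            max_missed >= 0L)
  if (!inherits(enzyme, "enzyme_spec")) enzyme <- enzyme_spec(enzyme)
  codes <- strsplit(seq, "")[[1]]
  n <- length(codes)
  sites <- .cut_sites(codes, enzyme)
  bounds <- c(0L, sites, n)  # fragment k spans (bounds[k]+1) .. bounds[k+1]
  m <- length(bounds) - 1L
  out <- vector("list", 0L)
  for (i in seq_len(m)) {
    for (k in 0:min(max_missed, m - i)) {
      start <- bounds[i] + 1L
      end <- bounds[i + k + 1L]
      len <- end - start + 1L
      if (len < min_length || len > max_length) next
      out[[length(out) + 1L]] <- data.frame(
        parent_id = parent_id, start = start, end = end,
        seq = paste(codes[start:end], collapse = ""),
        missed = k, is_parent_3p = (end == n),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(parent_id = character(0), start = integer(0),
                      end = integer(0), seq = character(0),
                      missed = integer(0), is_parent_3p = logical(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$end), , drop = FALSE]
}

#' Place modifications on a parent sequence
#'
#' Substitutes modification codes at 1-based positions. Substitution is
#' idempotent: re-applying the same table is a no-op.
#'
#' @param seq Parent sequence string (canonical codes).
#' @param mod_table data.frame with columns `position` (1-based) and `code`
#'   (single-character modification code). An empty table returns the input.
#' @return Modified sequence string.
#' @export
#' @examples
#' apply_modifications("AAACGAA", data.frame(position = 3, code = "5"))
apply_modifications <- function(seq, mod_table) {
  if (is.null(mod_table) || nrow(mod_table) == 0L) return(seq)
  stopifnot(all(c("position", "code") %in% names(mod_table)))
  codes <- strsplit(seq, "")[[1]]
  pos <- as.integer(mod_table$position)
  if (any(pos < 1L | pos > length(codes))) {
    stop("modification position out of range (sequence length ",
         length(codes), ")", call. = FALSE)
  }
  if (any(nchar(mod_table$code) != 1L)) {
    stop("modification codes must be single characters", call. = FALSE)
  }
  codes[pos] <- mod_table$code
  paste(codes, collapse = "")
}

#' Substitute every occurrence of one residue
#'
#' Uniform substitution across the whole sequence, e.g. replacing all U with
#' N1-methylpseudouridine in a synthetic mRNA.
#'
#' @param seq Sequence string.
#' @param from,to Single-character residue codes.
#' @return Modified sequence string.
#' @export
substitute_residue <- function(seq, from, to) {
  stopifnot(nchar(from) == 1L, nchar(to) == 1L)
  gsub(from, to, seq, fixed = TRUE)
}

#' Expand fragments into terminus / labeling variants
#'
#' Cartesian expansion of digestion products over terminal chemistries and
#' labeling schemes. Cleaved fragments default to 5'-OH / 3'-P (the nuclease
#' leaves a linear phosphate); the fragment containing the parent 3' end
#' keeps the parent's terminal chemistry instead of the enzymatic 3'
#' variants.
#'
#' @param fragments data.frame from [digest()].
#' @param three_prime Character vector of 3' chemistries for cleaved
#'   fragments (subset of `"P"`, `"cP"`, `"OH"`).
#' @param schemes List of [labeling_scheme()] objects.
#' @param five_prime 5' chemistry for all fragments.
#' @param parent_three_prime 3' chemistry of the parent molecule, applied to
#'   3'-terminal fragments.
#' @param alphabet Residue alphabet.
#' @return List of [oligo()] objects; length = rows x |termini| x |schemes|
#'   (3'-terminal fragments contribute one terminus each).
#' @export
enumerate_variants <- function(fragments, three_prime = "P",
                               schemes = list(scheme_identity()),
                               five_prime = "OH", parent_three_prime = "OH",
                               alphabet = default_alphabet()) {
  stopifnot(length(three_prime) > 0L, length(schemes) > 0L)
  out <- list()
  for (i in seq_len(nrow(fragments))) {
    t3set <- if (fragments$is_parent_3p[i]) parent_three_prime else three_prime
    for (t3 in t3set) {
      for (sc in schemes) {
        out[[length(out) + 1L]] <- oligo(
          fragments$seq[i], five_prime = five_prime, three_prime = t3,
          scheme = sc, alphabet = alphabet,
          parent_id = fragments$parent_id[i], start = fragments$start[i],
          end = fragments$end[i], missed = fragments$missed[i]
        )
      }
    }
  }
  out
}

#' Read a multi-record FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences (T converted to U).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  gsub("T", "U", toupper(seqs))
}

#' Read a modification placement table
#'
#' Tab-separated with columns `seq_id`, `position` (1-based), `code`.
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_mod_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "character"))
  need <- c("seq_id", "position", "code")
  if (!all(need %in% names(df))) {
    stop("modification table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  df
}
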