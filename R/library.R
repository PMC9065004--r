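#' Default precursor / fragment charge tables
#'
#' Charge states observed in negative ESI are an empirical, per-platform
#' property; they are supplied as length-keyed tables. Defaults: precursor
#' charge 1 for very short oligos rising to 1-3 for long ones; fragment
#' charges 1 (short oligos) or 1-2.
#'
#' @return A list with data.frames `precursor` and `fragment`, columns
#'   `min_len`, `max_len`, `charges` (comma-separated).
#' @export
default_charge_tables <- function() {
  list(
    precursor = data.frame(
      min_len = c(1L, 4L, 8L), max_len = c(3L, 7L, .Machine$integer.max),
      charges = c("1", "1,2", "1,2,3"), stringsAsFactors = FALSE
    ),
    fragment = data.frame(
      min_len = c(1L, 5L), max_len = c(4L, .Machine$integer.max),
      charges = c("1", "1,2"), stringsAsFactors = FALSE
    )
  )
}

#' Look up allowed charges for an oligo length
#'
#' @param length Oligo length (nt).
#' @param table One element of [default_charge_tables()].
#' @return Integer vector of charge magnitudes.
#' @export
charges_for_length <- function(length, table) {
  hit <- which(table$min_len <= length & length <= table$max_len)
  if (length(hit) == 0L) {
    stop("no charge rule for length ", length, call. = FALSE)
  }
  z <- as.integer(strsplit(table$charges[hit[1L]], ",")[[1]])
  if (any(z < 1L)) stop("charges must be >= 1", call. = FALSE)
  z
}

#' Read / write a charge table
#'
#' Tab-separated columns `min_len`, `max_len`, `charges`.
#' @param path File path.
#' @param table Charge table data.frame.
#' @return `read_charge_table()` returns the data.frame.
#' @export
read_charge_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("min_len", "max_len", "charges") %in% names(df)))
  df$charges <- as.character(df$charges)
  df
}

#' @rdname read_charge_table
#' @export
write_charge_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Default CID ion series for a 3' terminus
#'
#' Eleven series (a, a-B, b, c, d, w, x, y, z, y-P, z-P) for oligos ending in
#' a linear 3'-phosphate; the two phosphate-loss series do not apply to 3'-OH
#' or 2',3'-cyclic phosphate ends, leaving the nine McLuckey series.
#'
#' @param three_prime 3' chemistry (`"P"`, `"OH"`, `"cP"`).
#' @return Character vector of series names.
#' @export
default_series <- function(three_prime) {
  base <- c("a", "a-B", "b", "c", "d", "w", "x", "y", "z")
  if (identical(three_prime, "P")) c(base, "y-P", "z-P") else base
}

#' Theoretical sequence-defining fragment ions
#'
#' Enumerates CID fragment ions for an oligo of length n at indices
#' i = 1..n-1, counted from each series' own terminus. Neutral masses of the
#' 5' series are built from prefix sums (d_i = prefix + H2O + 5'-terminus;
#' c = d - H2O; b = d - HPO3; a = b - H2O; a-B = a - base_i) and the 3'
#' series follow by complementarity with the precursor:
#' a_i + w_(n-i) = b_i + x_(n-i) = c_i + y_(n-i) = d_i + z_(n-i) = M + H2O.
#'
#' @param x An [oligo()] with length >= 2.
#' @param series Series names; default [default_series()] for the oligo's 3'
#'   end. y-P/z-P requested for a non-3'-P oligo are skipped with a warning.
#' @param charges Integer vector of fragment charge magnitudes, or a
#'   fragment charge table (see [default_charge_tables()]).
#' @return data.frame with columns `series`, `index`, `charge`,
#'   `neutral_mass`, `mz`.
#' @export
#' @examples
#' nrow(fragment_series(oligo("ACGUA"), charges = 1))  # 11 * 4 = 44
fragment_series <- function(x, series = default_series(x$three_prime),
                            charges = default_charge_tables()$fragment) {
  stopifnot(inherits(x, "oligo"))
  n <- length(x$codes)
  if (n < 2L) {
    return(data.frame(series = character(0), index = integer(0),
                      charge = integer(0), neutral_mass = numeric(0),
                      mz = numeric(0)))
  }
  if (is.data.frame(charges)) charges <- charges_for_length(n, charges)
  if (!identical(x$three_prime, "P") && any(series %in% c("y-P", "z-P"))) {
    warning("y-P/z-P series skipped for 3'-", x$three_prime, " oligo")
    series <- setdiff(series, c("y-P", "z-P"))
  }
  res <- residue_mass(x$codes, x$alphabet, x$scheme)
  bases <- base_mass(x$codes, x$alphabet, x$scheme)
  t5 <- terminus_adjustment(x$five_prime, "P")  # 5' contribution only
  m_h2o <- oligo_neutral_mass(x) + .const$h2o
  i <- seq_len(n - 1L)
  d <- cumsum(res)[i] + .const$h2o + t5
  five <- list(
    "d" = d, "c" = d - .const$h2o, "b" = d - .const$hpo3,
    "a" = d - .const$hpo3 - .const$h2o,
    "a-B" = d - .const$hpo3 - .const$h2o - bases[i]
  )
  three <- list(
    "w" = m_h2o - rev(five[["a"]]), "x" = m_h2o - rev(five[["b"]]),
    "y" = m_h2o - rev(five[["c"]]), "z" = m_h2o - rev(five[["d"]])
  )
  three[["y-P"]] <- three[["y"]] - .const$hpo3
  three[["z-P"]] <- three[["z"]] - .const$hpo3
  all_series <- c(five, three)
  rows <- lapply(intersect(series, names(all_series)), function(s) {
    data.frame(series = s, index = i, neutral_mass = all_series[[s]],
               stringsAsFactors = FALSE)
  })
  ions <- do.call(rbind, rows)
  ions <- ions[rep(seq_len(nrow(ions)), each = length(charges)), ]
  ions$charge <- rep(as.integer(charges), length.out = nrow(ions))
  ions$mz <- mz_from_mass(ions$neutral_mass, ions$charge)
  rownames(ions) <- NULL
  ions[, c("series", "index", "charge", "neutral_mass", "mz")]
}

#' Precursor loss ions
#'
#' The intact precursor (M) and its neutral losses of water, phosphate
#' (HPO3), and each distinct nucleobase present in the oligo. These ions are
#' used for peak exclusion and annotation only — they are never counted among
#' the sequence-defining candidates (n, L).
#'
#' @param x An [oligo()].
#' @param charges Integer vector of charge magnitudes (defaults to the
#'   precursor charges for the oligo length).
#' @return data.frame with columns `type`, `charge`, `neutral_mass`, `mz`.
#' @export
#' @examples
#' precursor_losses(oligo("AUG"), charges = 1)
precursor_losses <- function(x, charges = NULL) {
  stopifnot(inherits(x, "oligo"))
  if (is.null(charges)) {
    charges <- charges_for_length(length(x$codes),
                                  default_charge_tables()$precursor)
  }
  m <- oligo_neutral_mass(x)
  ub <- !duplicated(x$codes)
  losses <- c(M = m, `M-H2O` = m - .const$h2o, `M-HPO3` = m - .const$hpo3,
              stats::setNames(m - base_mass(x$codes[ub], x$alphabet,
                                            x$scheme),
                              paste0("M-base(", x$codes[ub], ")")))
  out <- data.frame(
    type = rep(names(losses), each = length(charges)),
    charge = rep(as.integer(charges), times = length(losses)),
    neutral_mass = rep(unname(losses), each = length(charges)),
    stringsAsFactors = FALSE
  )
  out$mz <- mz_from_mass(out$neutral_mass, out$charge)
  out
}

#' Shuffled decoy sequence
#'
#' A decoy is a random permutation of the target's residues that keeps the
#' 3'-terminal residue fixed (it carries the nuclease specificity) and must
#' differ from the target. Returns `NULL` when no distinct permutation
#' exists (e.g. homopolymers). Draws from R's RNG, so results are
#' reproducible under `set.seed()`.
#'
#' @param x Target [oligo()], length >= 2.
#' @return A decoy `oligo` (same termini, scheme, provenance) or `NULL`.
#' @export
generate_decoy <- function(x) {
  stopifnot(inherits(x, "oligo"))
  n <- length(x$codes)
  if (n < 2L) return(NULL)
  head <- x$codes[seq_len(n - 1L)]
  if (length(unique(head)) == 1L) return(NULL)
  repeat {
    perm <- sample(head)
    if (!identical(perm, head)) break
  }
  dec <- x
  dec$codes <- c(perm, x$codes[n])
  dec$seq <- paste(dec$codes, collapse = "")
  dec
}

.entry_id <- function(seq, x, is_decoy) {
  paste0(ifelse(is_decoy, "DECOY_", ""), seq, "|", x$five_prime, "/",
         x$three_prime, "|", x$scheme$name, "|",
         ifelse(is.na(x$start), "", paste0(x$parent_id, ":", x$start)))
}

#' Expand one oligo into a library entry
#'
#' Attaches per-charge precursor m/z values and the theoretical fragment-ion
#' list (the L sequence-defining candidates).
#'
#' @param x An [oligo()].
#' @param charge_tables List with `precursor` and `fragment` tables.
#' @param series Ion series; default per the oligo's 3' terminus.
#' @param is_decoy Logical flag.
#' @param decoy_of Entry id of the target a decoy was shuffled from.
#' @return A `library_entry` list.
#' @export
library_entry <- function(x, charge_tables = default_charge_tables(),
                          series = default_series(x$three_prime),
                          is_decoy = FALSE, decoy_of = NA_character_) {
  m <- oligo_neutral_mass(x)
  zs <- charges_for_length(length(x$codes), charge_tables$precursor)
  prec <- data.frame(charge = zs, mz = mz_from_mass(m, zs))
  frags <- fragment_series(x, series = series,
                           charges = charge_tables$fragment)
  structure(
    list(id = .entry_id(x$seq, x, is_decoy), oligo = x, seq = x$seq,
         channel = x$scheme$channel, scheme = x$scheme$name,
         is_decoy = is_decoy, decoy_of = decoy_of, neutral_mass = m,
         precursors = prec, fragments = frags,
         display = x$seq, members = x$seq),
    class = "library_entry"
  )
}

#' SeqX consolidation of indistinguishable entries
#'
#' Entries of equal length and identical termini whose precursor masses
#' agree within `ms1_ppm` and whose fragment ions agree pairwise (matched by
#' series/index/charge) within `ms2_ppm` cannot be told apart at instrument
#' accuracy. Such groups — closed transitively with union-find, so the result
#' is order-independent — are renamed with an X at every position where
#' members differ, listing all members (self first), e.g.
#' `"AXG: ACG|AYG"`. Decoys falling in a group with at least one target are
#' removed. Idempotent.
#'
#' @param entries List of `library_entry` objects.
#' @param ms1_ppm,ms2_ppm Consolidation tolerances in ppm (> 0).
#' @return Consolidated list of entries.
#' @export
seqx_consolidate <- function(entries, ms1_ppm, ms2_ppm) {
  stopifnot(ms1_ppm > 0, ms2_ppm > 0)
  n <- length(entries)
  if (n < 2L) return(entries)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  key <- vapply(entries, function(e) {
    paste(nchar(e$seq), e$oligo$five_prime, e$oligo$three_prime)
  }, character(1))
  indist <- function(e1, e2) {
    if (abs(.ppm(e1$neutral_mass, e2$neutral_mass)) > ms1_ppm) return(FALSE)
    f1 <- e1$fragments; f2 <- e2$fragments
    if (nrow(f1) != nrow(f2)) return(FALSE)
    k1 <- paste(f1$series, f1$index, f1$charge)
    k2 <- paste(f2$series, f2$index, f2$charge)
    o2 <- match(k1, k2)
    if (any(is.na(o2))) return(FALSE)
    all(abs(.ppm(f1$mz, f2$mz[o2])) <= ms2_ppm)
  }
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      if (key[i] != key[j]) next
      ri <- find(i); rj <- find(j)
      if (ri == rj) next
      if (indist(entries[[i]], entries[[j]])) parent[rj] <- ri
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  drop <- logical(n)
  for (r in unique(root)) {
    grp <- which(root == r)
    if (length(grp) < 2L) next
    seqs <- vapply(entries[grp], function(e) e$seq, character(1))
    mat <- do.call(rbind, strsplit(seqs, ""))
    cons <- apply(mat, 2, function(col) {
      if (length(unique(col)) == 1L) col[1L] else "X"
    })
    cons <- paste(cons, collapse = "")
    has_target <- any(!vapply(entries[grp], `[[`, logical(1), "is_decoy"))
    for (g in grp) {
      if (entries[[g]]$is_decoy && has_target) {
        drop[g] <- TRUE
        next
      }
      others <- setdiff(unique(seqs), entries[[g]]$seq)
      entries[[g]]$members <- c(entries[[g]]$seq, others)
      entries[[g]]$display <- paste0(
        cons, ": ", paste(entries[[g]]$members, collapse = "|"))
    }
  }
  entries[!drop]
}

#' Build a target-decoy theoretical library
#'
#' Orchestrates the in silico pipeline: place modifications, digest each
#' sequence, expand terminus/labeling variants, compute precursor and
#' fragment ions, append one shuffled decoy per target, and (optionally)
#' SeqX-consolidate. Deterministic for a fixed `seed`.
#'
#' @param sequences Named character vector of parent sequences (canonical
#'   codes; see [read_fasta()]).
#' @param mod_table Optional data.frame `seq_id`, `position`, `code`.
#' @param enzyme Enzyme name or [enzyme_spec()].
#' @param max_missed Missed cleavages allowed.
#' @param three_prime 3' chemistries for cleaved fragments.
#' @param schemes List of labeling schemes (light and/or heavy channels).
#' @param charge_tables See [default_charge_tables()].
#' @param decoys Append shuffled decoys?
#' @param seqx `NULL`, or `list(ms1_ppm =, ms2_ppm =)` to consolidate.
#' @param min_length Minimum product length kept (default 2: shorter
#'   products have no sequence-defining ions).
#' @param max_length Maximum product length kept.
#' @param seed Integer seed for decoy shuffling.
#' @param alphabet Residue alphabet.
#' @param five_prime,parent_three_prime Terminal chemistry conventions; see
#'   [enumerate_variants()].
#' @return A `theoretical_library`: list with `entries` and the build
#'   parameters.
#' @export
build_library <- function(sequences, mod_table = NULL, enzyme = "T1",
                          max_missed = 0L, three_prime = "P",
                          schemes = list(scheme_identity()),
                          charge_tables = default_charge_tables(),
                          decoys = TRUE, seqx = NULL, min_length = 2L,
                          max_length = Inf, seed = NULL,
                          alphabet = default_alphabet(), five_prime = "OH",
                          parent_three_prime = "OH") {
  if (length(sequences) == 0L) {
    warning("empty input: returning empty library")
    return(structure(list(entries = list(), alphabet = alphabet),
                     class = "theoretical_library"))
  }
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  if (!is.null(seed)) set.seed(seed)
  oligos <- list()
  for (id in names(sequences)) {
    s <- sequences[[id]]
    if (!is.null(mod_table)) {
      mt <- mod_table[mod_table$seq_id == id, , drop = FALSE]
      s <- apply_modifications(s, mt)
    }
    frags <- digest(s, enzyme = enzyme, max_missed = max_missed,
                    parent_id = id, min_length = min_length,
                    max_length = max_length)
    oligos <- c(oligos, enumerate_variants(
      frags, three_prime = three_prime, schemes = schemes,
      five_prime = five_prime, parent_three_prime = parent_three_prime,
      alphabet = alphabet))
  }
  entries <- lapply(oligos, library_entry, charge_tables = charge_tables)
  # one entry per distinct (sequence, termini, scheme); duplicated digestion
  # products (e.g. the same fragment at two loci) keep their first provenance
  ids <- vapply(entries, function(e) sub("\\|[^|]*$", "", e$id), character(1))
  entries <- entries[!duplicated(ids)]
  if (decoys) {
    seen <- vapply(entries, function(e) paste(e$seq, e$channel),
                   character(1))
    dec <- list()
    for (e in entries) {
      d <- generate_decoy(e$oligo)
      if (is.null(d)) next
      k <- paste(d$seq, e$channel)
      if (k %in% seen) next  # only unique decoy sequences are retained
      seen <- c(seen, k)
      dec[[length(dec) + 1L]] <- library_entry(
        d, charge_tables = charge_tables, is_decoy = TRUE, decoy_of = e$id)
    }
    entries <- c(entries, dec)
  }
  if (!is.null(seqx)) {
    entries <- seqx_consolidate(entries, seqx$ms1_ppm, seqx$ms2_ppm)
  }
  structure(list(entries = entries, alphabet = alphabet,
                 charge_tables = charge_tables),
            class = "theoretical_library")
}

#' @export
print.theoretical_library <- function(x, ...) {
  dec <- sum(vapply(x$entries, `[[`, logical(1), "is_decoy"))
  cat(sprintf("<theoretical_library> %d entries (%d targets, %d decoys)\n",
              length(x$entries), length(x$entries) - dec, dec))
  invisible(x)
}

#' Serialize / load a theoretical library
#'
#' Writes one TSV row per fragment ion plus a JSON sidecar
#' (`<path>.json`) holding entry metadata (precursor charges/m-z, termini,
#' scheme, decoy provenance, SeqX names) and the residue alphabet; the pair
#' round-trips through `read_library()`.
#'
#' @param library A `theoretical_library`.
#' @param path TSV path; the sidecar is written next to it.
#' @return `read_library()` returns the `theoretical_library`.
#' @export
write_library <- function(library, path) {
  ent <- library$entries
  frag_rows <- lapply(seq_along(ent), function(i) {
    f <- ent[[i]]$fragments
    if (nrow(f) == 0L) return(NULL)
    cbind(entry = i, id = ent[[i]]$id, seq = ent[[i]]$seq, f)
  })
  frags <- do.call(rbind, frag_rows)
  utils::write.table(frags, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- lapply(ent, function(e) {
    o <- e$oligo
    list(id = e$id, seq = e$seq, display = e$display, members = e$members,
         channel = e$channel, scheme_name = o$scheme$name,
         element_swap = as.list(o$scheme$element_swap),
         residue_h = as.list(o$scheme$residue_h),
         five_prime = o$five_prime, three_prime = o$three_prime,
         parent_id = o$parent_id, start = o$start, end = o$end,
         missed = o$missed, is_decoy = e$is_decoy, decoy_of = e$decoy_of,
         neutral_mass = e$neutral_mass,
         prec_charge = e$precursors$charge, prec_mz = e$precursors$mz)
  })
  jsonlite::write_json(
    list(alphabet = as.list(as.data.frame(library$alphabet)), entries = meta),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  frags <- utils::read.delim(path, stringsAsFactors = FALSE)
  side <- jsonlite::fromJSON(paste0(path, ".json"), simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  alphabet <- as.data.frame(side$alphabet, stringsAsFactors = FALSE)
  class(alphabet) <- c("residue_alphabet", "data.frame")
  meta <- side$entries
  entries <- lapply(meta, function(m) {
    swap <- unlist(m$element_swap)
    rh <- unlist(m$residue_h)
    sc <- labeling_scheme(m$scheme_name, m$channel,
                          element_swap = if (length(swap)) swap,
                          residue_h = if (length(rh)) rh)
    o <- oligo(m$seq, five_prime = m$five_prime, three_prime = m$three_prime,
               scheme = sc, alphabet = alphabet,
               parent_id = if (is.null(m$parent_id)) NA_character_ else m$parent_id,
               start = if (is.null(m$start)) NA_integer_ else m$start,
               end = if (is.null(m$end)) NA_integer_ else m$end,
               missed = if (is.null(m$missed)) 0L else m$missed)
    f <- frags[frags$id == m$id,
               c("series", "index", "charge", "neutral_mass", "mz")]
    rownames(f) <- NULL
    structure(
      list(id = m$id, oligo = o, seq = m$seq, channel = m$channel,
           scheme = m$scheme_name, is_decoy = m$is_decoy,
           decoy_of = if (is.null(m$decoy_of)) NA_character_ else m$decoy_of,
           neutral_mass = m$neutral_mass,
           precursors = data.frame(charge = m$prec_charge, mz = m$prec_mz),
           fragments = f, display = m$display, members = m$members),
      class = "library_entry")
  })
  structure(list(entries = entries, alphabet = alphabet,
                 charge_tables = NULL),
            class = "theoretical_library")
}
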