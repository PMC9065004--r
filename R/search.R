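#' Scoring and matching parameters
#'
#' @param ms1_ppm,ms2_ppm Precursor / fragment matching tolerances (ppm).
#' @param beta Base reward per consecutively matched ion pair (default
#'   0.025).
#' @param alpha Amplification factor for consecutive matches (default 2).
#' @param exclusion_window Half-width (m/z) of the window excluded around
#'   the assigned precursor and precursor-loss peaks; wide enough to cover
#'   their isotope envelopes.
#' @param isotopologues Also accept precursor matches at the M+1 / M-1
#'   isotopologue m/z (+- 1.00335/z)?
#' @param ms1_offset_ppm,ms2_offset_ppm Global systematic-offset
#'   corrections subtracted from observed ppm errors (see
#'   [ppm_offset_stats()]).
#' @return A `score_params` list.
#' @export
score_params <- function(ms1_ppm = 20, ms2_ppm = 40, beta = 0.025,
                         alpha = 2, exclusion_window = 1.5,
                         isotopologues = FALSE, ms1_offset_ppm = 0,
                         ms2_offset_ppm = 0) {
  stopifnot(ms1_ppm > 0, ms2_ppm > 0, beta >= 0, alpha >= 1,
            exclusion_window >= 0)
  structure(list(ms1_ppm = ms1_ppm, ms2_ppm = ms2_ppm, beta = beta,
                 alpha = alpha, exclusion_window = exclusion_window,
                 isotopologues = isotopologues,
                 ms1_offset_ppm = ms1_offset_ppm,
                 ms2_offset_ppm = ms2_offset_ppm),
            class = "score_params")
}

#' Precursor-level candidate lookup
#'
#' Returns the indices of library entries whose precursor m/z at the
#' spectrum's charge lies within the MS1 tolerance of the observed value
#' (after global offset correction). With `isotopologues` enabled, matches
#' displaced by +-1.00335/z are accepted too.
#'
#' @param spectrum A `spectrum`.
#' @param library A `theoretical_library`.
#' @param params [score_params()].
#' @return Integer vector of entry indices (possibly empty) with attribute
#'   `ppm` holding the signed precursor matching offsets.
#' @export
match_precursor <- function(spectrum, library, params = score_params()) {
  stopifnot(length(library$entries) > 0L)
  hits <- integer(0)
  ppms <- numeric(0)
  shifts <- 0
  if (isTRUE(params$isotopologues) && !is.na(spectrum$charge)) {
    shifts <- c(0, .const$neutron / spectrum$charge,
                -.const$neutron / spectrum$charge)
  }
  for (i in seq_along(library$entries)) {
    prec <- library$entries[[i]]$precursors
    row <- prec[prec$charge == spectrum$charge, , drop = FALSE]
    if (nrow(row) == 0L) next
    for (sh in shifts) {
      off <- .ppm(spectrum$pepmass, row$mz[1L] + sh) - params$ms1_offset_ppm
      if (abs(off) <= params$ms1_ppm) {
        hits <- c(hits, i)
        ppms <- c(ppms, off)
        break
      }
    }
  }
  attr(hits, "ppm") <- ppms
  hits
}

# greedy one-to-one assignment of theoretical ions to peaks by ascending
# |ppm error|; ties broken by higher peak intensity, then lower peak m/z
.assign_peaks <- function(theo_mz, peak_mz, peak_int, tol_ppm, offset_ppm) {
  pairs <- NULL
  for (t in seq_along(theo_mz)) {
    err <- .ppm(peak_mz, theo_mz[t]) - offset_ppm
    ok <- which(abs(err) <= tol_ppm)
    if (length(ok)) {
      pairs <- rbind(pairs, cbind(ion = t, peak = ok, ppm = err[ok]))
    }
  }
  assign_ion <- rep(NA_integer_, length(theo_mz))
  assign_ppm <- rep(NA_real_, length(theo_mz))
  if (is.null(pairs)) return(list(peak = assign_ion, ppm = assign_ppm))
  ord <- order(abs(pairs[, "ppm"]), -peak_int[pairs[, "peak"]],
               peak_mz[pairs[, "peak"]], pairs[, "ion"])
  pairs <- pairs[ord, , drop = FALSE]
  used_peak <- logical(length(peak_mz))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, "ion"]; p <- pairs[r, "peak"]
    if (!is.na(assign_ion[i]) || used_peak[p]) next
    assign_ion[i] <- p
    assign_ppm[i] <- pairs[r, "ppm"]
    used_peak[p] <- TRUE
  }
  list(peak = assign_ion, ppm = assign_ppm)
}

#' Fragment-level matching of one candidate against one spectrum
#'
#' First the precursor peak (M) and its loss peaks are located within the
#' MS2 tolerance and excluded — together with their +-`exclusion_window`
#' neighborhoods — from the spectrum. Remaining peak intensities are
#' normalized to the most intense remaining peak. Theoretical
#' sequence-defining ions are then assigned greedily (each ion and each peak
#' at most once, ascending |ppm error|, ties to the more intense then
#' lower-m/z peak).
#'
#' @param spectrum A `spectrum`.
#' @param entry A `library_entry`.
#' @param params [score_params()].
#' @return A list: `assignments` (fragment table plus `peak_mz`,
#'   `peak_intensity` (normalized), `ppm`, `matched`), `n`, `L`,
#'   `sum_I_match`, `sum_I_all`, `excluded` (loss-peak annotation table).
#' @export
match_fragments <- function(spectrum, entry, params = score_params()) {
  frag <- entry$fragments
  L <- nrow(frag)
  peaks <- spectrum$peaks
  losses <- precursor_losses(entry$oligo,
                             charges = unique(entry$precursors$charge))
  excl <- rep(FALSE, nrow(peaks))
  loss_hits <- numeric(0)
  for (lm in losses$mz) {
    err <- .ppm(peaks[, "mz"], lm) - params$ms2_offset_ppm
    hit <- which(abs(err) <= params$ms2_ppm)
    if (length(hit)) {
      centers <- peaks[hit, "mz"]
      loss_hits <- c(loss_hits, centers)
      for (cmz in centers) {
        excl <- excl | abs(peaks[, "mz"] - cmz) <= params$exclusion_window
      }
    }
  }
  keep <- which(!excl)
  if (length(keep) == 0L || L == 0L) {
    return(list(
      assignments = cbind(frag, peak_mz = NA_real_,
                          peak_intensity = NA_real_, ppm = NA_real_,
                          matched = logical(L))[seq_len(L), , drop = FALSE],
      n = 0L, L = L, sum_I_match = 0, sum_I_all = 0, excluded = losses))
  }
  norm <- max(peaks[keep, "intensity"])
  rel <- peaks[, "intensity"] / norm
  asg <- .assign_peaks(frag$mz, peaks[keep, "mz"], peaks[keep, "intensity"],
                       params$ms2_ppm, params$ms2_offset_ppm)
  peak_idx <- keep[asg$peak]
  matched <- !is.na(asg$peak)
  assignments <- cbind(
    frag,
    peak_mz = ifelse(matched, peaks[peak_idx, "mz"], NA_real_),
    peak_intensity = ifelse(matched, rel[peak_idx], NA_real_),
    ppm = asg$ppm, matched = matched)
  list(assignments = assignments, n = sum(matched), L = L,
       sum_I_match = sum(rel[peak_idx[matched]]),
       sum_I_all = sum(rel[keep]), excluded = losses)
}

#' Consecutive-match reward
#'
#' The reward term of the score: for each ion-series track s (one series at
#' one charge), B_s = beta * alpha * k_s where k_s counts adjacent matched
#' index pairs (i, i+1) within the track. This linear-in-consecutive-pairs
#' form follows the SEQUEST lineage of rewarding uninterrupted ion ladders;
#' it is isolated here so alternative reward shapes can be swapped in.
#'
#' @param assignments Assignment table from [match_fragments()].
#' @param params [score_params()].
#' @return Sum over series tracks of B_s.
#' @export
consecutive_reward <- function(assignments, params = score_params()) {
  m <- assignments[assignments$matched, , drop = FALSE]
  if (nrow(m) == 0L) return(0)
  total <- 0
  for (key in unique(paste(m$series, m$charge))) {
    idx <- sort(m$index[paste(m$series, m$charge) == key])
    k <- sum(diff(idx) == 1L)
    total <- total + params$beta * params$alpha * k
  }
  total
}

#' Empirical match score S_p
#'
#' S_p = (sum I_match / sum I_all) * (n / L) * (1 + sum_s B_s): the fraction
#' of retained spectral intensity explained, times the fraction of the
#' theoretical ladder observed, amplified by the consecutive-match reward.
#' Defined as 0 when nothing matches or the retained spectrum is empty.
#'
#' @param match Result of [match_fragments()].
#' @param params [score_params()].
#' @return Numeric score >= 0.
#' @export
score_sp <- function(match, params = score_params()) {
  if (match$n == 0L || match$L == 0L || match$sum_I_all <= 0) return(0)
  (match$sum_I_match / match$sum_I_all) * (match$n / match$L) *
    (1 + consecutive_reward(match$assignments, params))
}

#' Rank competing OSMs and compute delta scores
#'
#' Sorts the oligonucleotide-spectrum matches for one spectrum by descending
#' S_p (ties: larger n, then targets before decoys, then lexicographic
#' sequence) and attaches dSp = (Sp_top - Sp)/Sp_top per OSM, plus two
#' specificity measures attributed to every row: `dSp2`, the dSp of the
#' second-best target, and `dSpD`, the dSp of the highest-scoring competing
#' decoy. When the top score is 0 all deltas are 0 and `degenerate` is set.
#'
#' @param osms data.frame with at least `Sp`, `n`, `is_decoy`, `seq`.
#' @return The data.frame sorted with columns `rank`, `dSp`, `dSp2`, `dSpD`,
#'   `degenerate` added.
#' @export
rank_and_delta <- function(osms) {
  stopifnot(nrow(osms) >= 1L)
  ord <- order(-osms$Sp, -osms$n, osms$is_decoy, osms$seq)
  osms <- osms[ord, , drop = FALSE]
  osms$rank <- seq_len(nrow(osms))
  top <- osms$Sp[1L]
  degenerate <- top <= 0
  osms$dSp <- if (degenerate) 0 else (top - osms$Sp) / top
  tg <- which(!osms$is_decoy)
  osms$dSp2 <- if (length(tg) >= 2L && !degenerate) osms$dSp[tg[2L]] else NA_real_
  dc <- which(osms$is_decoy)
  osms$dSpD <- if (length(dc) >= 1L && !degenerate) osms$dSp[dc[1L]] else NA_real_
  osms$degenerate <- degenerate
  rownames(osms) <- NULL
  osms
}

#' Score one candidate against one spectrum
#'
#' @param spectrum A `spectrum`.
#' @param entry A `library_entry`.
#' @param params [score_params()].
#' @param precursor_ppm Optional precomputed precursor offset.
#' @return One-row data.frame (an unranked OSM); the full assignment table
#'   is attached as attribute `"assignments"`.
#' @export
score_osm <- function(spectrum, entry, params = score_params(),
                      precursor_ppm = NA_real_) {
  m <- match_fragments(spectrum, entry, params)
  row <- data.frame(
    scan = spectrum$scan, seq = entry$seq, display = entry$display,
    channel = entry$channel, is_decoy = entry$is_decoy,
    entry_id = entry$id, parent_id = entry$oligo$parent_id,
    start = entry$oligo$start, end = entry$oligo$end,
    n = m$n, L = m$L, sum_I_match = m$sum_I_match,
    sum_I_all = m$sum_I_all, Sp = score_sp(m, params),
    precursor_ppm = precursor_ppm, stringsAsFactors = FALSE)
  attr(row, "assignments") <- m$assignments
  row
}

#' Search spectra against a theoretical library
#'
#' The full matching pipeline: precursor lookup within the MS1 tolerance,
#' fragment matching and S_p scoring of every candidate, and per-spectrum
#' ranking with delta scores.
#'
#' @param spectra List of `spectrum` objects (see [read_mgf()]).
#' @param library A `theoretical_library`.
#' @param params [score_params()].
#' @return OSM table: one row per (spectrum, candidate), ranked within each
#'   spectrum. Spectra without candidates contribute no rows.
#' @export
search_spectra <- function(spectra, library, params = score_params()) {
  out <- list()
  for (sp in spectra) {
    cand <- match_precursor(sp, library, params)
    if (length(cand) == 0L) next
    ppm <- attr(cand, "ppm")
    rows <- lapply(seq_along(cand), function(k) {
      score_osm(sp, library$entries[[cand[k]]], params,
                precursor_ppm = ppm[k])
    })
    out[[length(out) + 1L]] <- rank_and_delta(do.call(rbind, rows))
  }
  if (length(out) == 0L) {
    warning("no spectra matched any library precursor")
    return(data.frame())
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write an OSM table
#'
#' @param osms OSM data.frame from [search_spectra()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_osm_table <- function(osms, path) {
  num <- vapply(osms, is.numeric, logical(1)) &
    !vapply(osms, is.integer, logical(1))
  osms[num] <- lapply(osms[num], function(x) {
    formatC(x, format = "g", digits = 10)
  })
  utils::write.table(osms, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
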