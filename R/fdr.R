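#' Simple target-decoy FDR at a score cutoff
#'
#' Following the concatenated target-decoy convention, the false discovery
#' rate at cutoff s is the ratio of rank-1 decoys to rank-1 targets scoring
#' at or above s: FDR(s) = D(s)/T(s). Returns `NA` (not applicable) when no
#' target reaches the cutoff.
#'
#' @param rank1 data.frame of rank-1 OSMs with columns `Sp`, `is_decoy`.
#' @param sp_cutoff Score cutoff.
#' @return FDR value (0 when no decoy passes), or `NA` when T = 0.
#' @export
#' @examples
#' r1 <- data.frame(Sp = c(1, .8, .5, .3), is_decoy = c(F, F, T, F))
#' simple_fdr(r1, 0.4)
simple_fdr <- function(rank1, sp_cutoff) {
  pass <- rank1$Sp >= sp_cutoff
  t <- sum(pass & !rank1$is_decoy)
  d <- sum(pass & rank1$is_decoy)
  if (t == 0L) return(NA_real_)
  d / t
}

#' Restrict to targets with at least one competing decoy
#'
#' RNA's four-letter alphabet makes decoy sampling sparse for short targets;
#' the default statistical analysis therefore considers only rank-1 targets
#' that had at least one competing decoy in their candidate list (plus all
#' rank-1 decoys). Pass the full OSM table.
#'
#' @param osms Ranked OSM table from [search_spectra()].
#' @param require_decoy Apply the restriction? Default TRUE.
#' @return Rank-1 subset of `osms`.
#' @export
rank1_for_stats <- function(osms, require_decoy = TRUE) {
  r1 <- osms[osms$rank == 1L, , drop = FALSE]
  if (!require_decoy) return(r1)
  has_decoy <- tapply(osms$is_decoy, osms$scan, any)
  keep <- r1$is_decoy | has_decoy[as.character(r1$scan)]
  r1[keep, , drop = FALSE]
}

#' S_p cutoff achieving a desired FDR
#'
#' Scans the observed rank-1 scores and returns the minimal cutoff s with
#' FDR(s) <= `target_fdr`; the same uniform cutoff applies to every sequence
#' length. `Inf` (with a warning) when no cutoff reaches the requested
#' level.
#'
#' @param rank1 Rank-1 OSM data.frame (`Sp`, `is_decoy`).
#' @param target_fdr Desired FDR in (0, 1].
#' @return S_p cutoff.
#' @export
sp_cutoff_for_fdr <- function(rank1, target_fdr) {
  stopifnot(target_fdr > 0, target_fdr <= 1)
  cand <- sort(unique(rank1$Sp))
  for (s in cand) {
    f <- simple_fdr(rank1, s)
    if (!is.na(f) && f <= target_fdr) return(s)
  }
  warning("requested FDR unreachable; returning Inf")
  Inf
}

#' FDR table over all candidate cutoffs
#'
#' @param rank1 Rank-1 OSM data.frame.
#' @return data.frame with one row per distinct score: `cutoff`, `targets`,
#'   `decoys`, `fdr`.
#' @export
fdr_table <- function(rank1) {
  cand <- sort(unique(rank1$Sp))
  do.call(rbind, lapply(cand, function(s) {
    pass <- rank1$Sp >= s
    data.frame(cutoff = s, targets = sum(pass & !rank1$is_decoy),
               decoys = sum(pass & rank1$is_decoy),
               fdr = simple_fdr(rank1, s))
  }))
}

#' m/z matching-offset statistics
#'
#' Mean, standard deviation and histogram counts of the signed ppm matching
#' offsets, used to diagnose systematic mass-measurement bias; the returned
#' mean is the global offset correction that re-centers the distribution at
#' zero, and 2*sigma is the usual basis for choosing matching tolerances.
#'
#' @param ppm Numeric vector of signed ppm offsets (MS1 or MS2 level).
#' @param robust Use median/MAD instead of mean/sd.
#' @param breaks Passed to [graphics::hist()] (computation only).
#' @return List: `mean`, `sigma`, `n`, `histogram` (data.frame `mid`,
#'   `count`).
#' @export
ppm_offset_stats <- function(ppm, robust = FALSE, breaks = "Sturges") {
  ppm <- ppm[!is.na(ppm)]
  if (length(ppm) == 0L) stop("no matched ions: no offsets to summarize",
                              call. = FALSE)
  h <- graphics::hist(ppm, breaks = breaks, plot = FALSE)
  list(
    mean = if (robust) stats::median(ppm) else mean(ppm),
    sigma = if (robust) stats::mad(ppm) else stats::sd(ppm),
    n = length(ppm),
    histogram = data.frame(mid = h$mids, count = h$counts)
  )
}
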