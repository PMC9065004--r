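#' Simulation parameters for synthetic spectra
#'
#' Controls the generative model used to synthesize ground-truth MS/MS data
#' from a theoretical library: each theoretical fragment ion is detected
#' independently with probability `p_detect` at a log-normally distributed
#' intensity and an m/z jittered by Gaussian ppm noise; uniform-m/z noise
#' peaks with (lower) log-normal intensities are added; the precursor peak
#' is always present.
#'
#' @param p_detect Per-fragment detection probability in [0, 1].
#' @param int_meanlog,int_sdlog Log-normal intensity model for fragment
#'   peaks.
#' @param noise_n Number of noise peaks per spectrum.
#' @param noise_meanlog,noise_sdlog Log-normal intensity model for noise.
#' @param noise_range m/z range for noise peaks (`NULL`: span of the
#'   theoretical ions).
#' @param ms1_jitter_ppm,ms2_jitter_ppm Gaussian m/z jitter (sigma, ppm).
#' @param isotopologue_prob Probability that the recorded precursor m/z is
#'   displaced to the M+1 or M-1 isotopologue.
#' @return A `sim_params` list.
#' @export
sim_params <- function(p_detect = 0.9, int_meanlog = 9, int_sdlog = 1,
                       noise_n = 5, noise_meanlog = 6.5, noise_sdlog = 1,
                       noise_range = NULL, ms1_jitter_ppm = 2,
                       ms2_jitter_ppm = 3, isotopologue_prob = 0) {
  stopifnot(p_detect >= 0, p_detect <= 1, noise_n >= 0,
            ms1_jitter_ppm >= 0, ms2_jitter_ppm >= 0,
            isotopologue_prob >= 0, isotopologue_prob <= 1)
  structure(as.list(environment()), class = "sim_params")
}

#' Synthesize one spectrum from a library entry
#'
#' Uses R's RNG; wrap in `set.seed()` for reproducibility.
#'
#' @param entry A `library_entry` with fragments.
#' @param params [sim_params()].
#' @param scan Scan identifier.
#' @param charge Precursor charge to record (default: the entry's lowest).
#' @return A `spectrum` whose truth is the entry's sequence.
#' @export
synthesize_spectrum <- function(entry, params = sim_params(),
                                scan = "sim_1", charge = NULL) {
  frag <- entry$fragments
  stopifnot(nrow(frag) > 0L)
  if (is.null(charge)) charge <- min(entry$precursors$charge)
  prec_mz <- entry$precursors$mz[entry$precursors$charge == charge][1L]
  jit <- function(mz, sigma) mz * (1 + stats::rnorm(length(mz), 0, sigma) * 1e-6)
  det <- stats::runif(nrow(frag)) < params$p_detect
  mz <- jit(frag$mz[det], params$ms2_jitter_ppm)
  int <- stats::rlnorm(sum(det), params$int_meanlog, params$int_sdlog)
  # precursor peak, always present and intense
  mz <- c(mz, jit(prec_mz, params$ms2_jitter_ppm))
  int <- c(int, stats::rlnorm(1, params$int_meanlog + 1, params$int_sdlog))
  if (params$noise_n > 0L) {
    rng <- params$noise_range
    if (is.null(rng)) rng <- range(frag$mz)
    mz <- c(mz, stats::runif(params$noise_n, rng[1], rng[2]))
    int <- c(int, stats::rlnorm(params$noise_n, params$noise_meanlog,
                                params$noise_sdlog))
  }
  pep <- jit(prec_mz, params$ms1_jitter_ppm)
  if (params$isotopologue_prob > 0 &&
      stats::runif(1) < params$isotopologue_prob) {
    pep <- pep + sample(c(-1, 1), 1) * 1.00335 / charge
  }
  o <- order(mz)
  structure(list(scan = scan, pepmass = pep, charge = charge,
                 polarity = "-", rt = NA_real_,
                 peaks = cbind(mz = mz[o], intensity = int[o])),
            class = "spectrum")
}

#' Synthesize a ground-truth dataset from a library
#'
#' Draws `n_spectra` target entries (never decoys, uniformly with
#' replacement), synthesizes one spectrum per draw, and records the truth.
#' Deterministic for a fixed `seed` — the written mgf is byte-identical
#' across runs.
#'
#' @param library A `theoretical_library`.
#' @param n_spectra Number of spectra.
#' @param params [sim_params()].
#' @param seed Integer seed.
#' @param mgf_path Optional path: also write the spectra as mgf.
#' @param truth_path Optional path: also write the truth table as TSV.
#' @return List: `spectra`, `truth` (data.frame `scan`, `seq`, `entry_id`,
#'   `channel`).
#' @export
synthesize_dataset <- function(library, n_spectra, params = sim_params(),
                               seed = NULL, mgf_path = NULL,
                               truth_path = NULL) {
  ent <- library$entries
  ok <- vapply(ent, function(e) !e$is_decoy && nrow(e$fragments) > 0L,
               logical(1))
  pool <- which(ok)
  stopifnot(length(pool) > 0L)
  if (!is.null(seed)) set.seed(seed)
  draw <- sample(pool, n_spectra, replace = TRUE)
  spectra <- vector("list", n_spectra)
  truth <- data.frame(scan = paste0("sim_", seq_len(n_spectra)),
                      seq = NA_character_, entry_id = NA_character_,
                      channel = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(n_spectra)) {
    e <- ent[[draw[i]]]
    spectra[[i]] <- synthesize_spectrum(e, params, scan = truth$scan[i])
    truth$seq[i] <- e$seq
    truth$entry_id[i] <- e$id
    truth$channel[i] <- e$channel
  }
  if (!is.null(mgf_path)) write_mgf(spectra, mgf_path)
  if (!is.null(truth_path)) {
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(spectra = spectra, truth = truth)
}
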