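# build a spectrum containing exactly the theoretical peaks of an entry
exact_spectrum <- function(entry, intensity = 100, charge = NULL,
                           extra_mz = numeric(0), extra_int = numeric(0)) {
  if (is.null(charge)) charge <- min(entry$precursors$charge)
  mz <- c(entry$fragments$mz, extra_mz)
  int <- c(rep(intensity, nrow(entry$fragments)), extra_int)
  o <- order(mz)
  structure(list(scan = "fx", pepmass = entry$precursors$mz[
    entry$precursors$charge == charge][1],
    charge = charge, polarity = "-", rt = NA_real_,
    peaks = cbind(mz = mz[o], intensity = int[o])),
    class = "spectrum")
}

test_that("precursor matching respects tolerance, charge and isotopologues", {
  lib <- toy_library(seed = 29, len = 100)
  e <- lib$entries[[1]]
  z <- e$precursors$charge[1]
  mkspec <- function(mz) structure(
    list(scan = "s", pepmass = mz, charge = z, polarity = "-",
         rt = NA_real_, peaks = cbind(mz = 100, intensity = 1)),
    class = "spectrum")
  p <- score_params(ms1_ppm = 20)
  hit <- match_precursor(mkspec(e$precursors$mz[1]), lib, p)
  expect_true(1 %in% hit)
  # 50 ppm off at 20 ppm tolerance: no hit for this entry
  off <- e$precursors$mz[1] * (1 + 50e-6)
  expect_false(1 %in% match_precursor(mkspec(off), lib, p))
  # M+1 isotopologue accepted only with the flag
  iso <- e$precursors$mz[1] + 1.00335 / z
  expect_false(1 %in% match_precursor(mkspec(iso), lib, p))
  p2 <- score_params(ms1_ppm = 20, isotopologues = TRUE)
  expect_true(1 %in% match_precursor(mkspec(iso), lib, p2))
  expect_true(1 %in% match_precursor(
    mkspec(e$precursors$mz[1] - 1.00335 / z), lib, p2))
})

test_that("a perfect spectrum matches everything; beta = 0 gives S_p = 1", {
  e <- library_entry(oligo("AUCGG"))
  sp <- exact_spectrum(e)
  m <- match_fragments(sp, e, score_params())
  expect_equal(m$n, m$L)
  expect_equal(m$sum_I_match, m$sum_I_all)
  expect_equal(score_sp(m, score_params(beta = 0)), 1)
  # with the default reward the score exceeds 1 (full consecutive ladders)
  expect_gt(score_sp(m, score_params()), 1)
})

test_that("degenerate spectra score zero", {
  e <- library_entry(oligo("AUCGG"))
  # spectrum made of only precursor-loss peaks: everything excluded
  pl <- precursor_losses(e$oligo, charges = e$precursors$charge)
  sp <- structure(list(scan = "loss", pepmass = e$precursors$mz[1],
                       charge = e$precursors$charge[1], polarity = "-",
                       rt = NA_real_,
                       peaks = cbind(mz = sort(pl$mz),
                                     intensity = rep(50, nrow(pl)))),
                  class = "spectrum")
  m <- match_fragments(sp, e, score_params())
  expect_equal(m$n, 0L)
  expect_equal(m$sum_I_all, 0)
  expect_equal(score_sp(m, score_params()), 0)
})

test_that("the hand-computed score example reproduces", {
  # sumI fraction 0.8, n/L = 10/44, three adjacent pairs in one series:
  # S_p = 0.8 * (10/44) * (1 + 0.025*2*3) = 0.2091
  asg <- data.frame(
    series = c(rep("w", 4), rep("a", 3), rep("c", 3)),
    index = c(1, 2, 3, 4, 1, 3, 5, 1, 3, 5),
    charge = 1, matched = TRUE)
  m <- list(n = 10L, L = 44L, sum_I_match = 0.8, sum_I_all = 1,
            assignments = asg)
  expect_equal(score_sp(m, score_params(beta = 0.025, alpha = 2)),
               0.2091, tolerance = 1e-4)
  # reward counts pairs per series track: w has 3, a and c none
  expect_equal(consecutive_reward(asg, score_params()), 0.15)
})

test_that("score is invariant to uniform intensity rescaling", {
  lib <- toy_library(seed = 37, len = 120)
  set.seed(8)
  sim <- synthesize_dataset(lib, 4, sim_params(), seed = 41)
  for (sp in sim$spectra) {
    cand <- match_precursor(sp, lib, score_params())
    if (length(cand) == 0) next
    e <- lib$entries[[cand[1]]]
    s1 <- score_sp(match_fragments(sp, e, score_params()), score_params())
    sp2 <- sp
    sp2$peaks[, "intensity"] <- sp2$peaks[, "intensity"] * 1234.5
    s2 <- score_sp(match_fragments(sp2, e, score_params()), score_params())
    expect_equal(s1, s2, tolerance = 1e-12)
  }
})

test_that("adding correct peaks never lowers the score", {
  e <- library_entry(oligo("AUCGGA"))
  base_noise <- c(123.456, 234.567)  # unmatched noise peaks
  scores <- vapply(seq(2, nrow(e$fragments), by = 7), function(k) {
    sp <- structure(list(
      scan = "inc", pepmass = e$precursors$mz[1],
      charge = e$precursors$charge[1], polarity = "-", rt = NA_real_,
      peaks = {
        mz <- c(e$fragments$mz[seq_len(k)], base_noise)
        cbind(mz = sort(mz), intensity = rep(10, length(mz)))
      }), class = "spectrum")
    score_sp(match_fragments(sp, e, score_params()), score_params())
  }, numeric(1))
  expect_true(all(diff(scores) >= -1e-12))
})

test_that("peak assignment is deterministic under constructed ties", {
  e <- library_entry(oligo("ACGU"))
  f <- e$fragments
  # two peaks equidistant in ppm from one theoretical ion: the more
  # intense, then lower-m/z peak wins; repeated runs identical
  t1 <- f$mz[1]
  sp <- structure(list(
    scan = "tie", pepmass = e$precursors$mz[1],
    charge = e$precursors$charge[1], polarity = "-", rt = NA_real_,
    peaks = cbind(mz = c(t1 * (1 - 5e-6), t1 * (1 + 5e-6)),
                  intensity = c(10, 90))),
    class = "spectrum")
  m1 <- match_fragments(sp, e, score_params(ms2_ppm = 20))
  m2 <- match_fragments(sp, e, score_params(ms2_ppm = 20))
  expect_identical(m1$assignments, m2$assignments)
  won <- m1$assignments$peak_mz[!is.na(m1$assignments$peak_mz)][1]
  expect_equal(won, t1 * (1 + 5e-6))  # higher intensity wins the tie
})

test_that("matching and scoring agree with the exhaustive oracle", {
  set.seed(501)
  p <- score_params(ms2_ppm = 25)
  for (k in 1:30) {
    o <- random_oligo(len = sample(3:4, 1), three_prime = "P")
    e <- library_entry(o)
    # <= 6 peaks: a few true ions (jittered), some noise
    f <- e$fragments
    n_true <- sample(0:4, 1)
    idx <- sample(nrow(f), n_true)
    mz <- c(f$mz[idx] * (1 + runif(n_true, -15e-6, 15e-6)),
            runif(6 - n_true, 150, 1500))
    int <- runif(6, 1, 100)
    ord <- order(mz)
    sp <- structure(list(scan = "or", pepmass = e$precursors$mz[1],
                         charge = e$precursors$charge[1], polarity = "-",
                         rt = NA_real_,
                         peaks = cbind(mz = mz[ord], intensity = int[ord])),
                    class = "spectrum")
    got <- match_fragments(sp, e, p)
    want <- oracle_match_score(sp, e, p)
    expect_equal(got$n, want$n)
    expect_equal(got$sum_I_match, want$sum_I_match, tolerance = 1e-12)
    expect_equal(got$sum_I_all, want$sum_I_all, tolerance = 1e-12)
    expect_equal(score_sp(got, p), want$Sp, tolerance = 1e-12)
  }
})

test_that("ranking and delta scores follow the definitions", {
  osms <- data.frame(
    scan = "s1", seq = c("AAAG", "AACG", "ACAG", "GCAG"),
    Sp = c(1.0, 0.8, 0.25, 0.6), n = c(10, 8, 3, 6),
    is_decoy = c(FALSE, FALSE, TRUE, FALSE), stringsAsFactors = FALSE)
  r <- rank_and_delta(osms)
  expect_equal(r$seq[1], "AAAG")
  expect_equal(r$dSp[1], 0)
  expect_equal(r$dSp, c(0, 0.2, 0.4, 0.75))
  expect_equal(unique(r$dSp2), 0.2)    # second-best target
  expect_equal(unique(r$dSpD), 0.75)   # best competing decoy
  # equal scores: tie broken by n, then target over decoy; dSp2 = 0
  tie <- data.frame(scan = "s2", seq = c("A", "B", "C"),
                    Sp = c(0.5, 0.5, 0.5), n = c(5, 5, 7),
                    is_decoy = c(TRUE, FALSE, FALSE))
  rt <- rank_and_delta(tie)
  expect_equal(rt$seq, c("C", "B", "A"))
  expect_equal(rt$dSp2[1], 0)
  # top score zero: deltas zeroed and flagged
  z <- rank_and_delta(data.frame(scan = "s3", seq = c("A", "B"),
                                 Sp = c(0, 0), n = c(0, 0),
                                 is_decoy = c(FALSE, TRUE)))
  expect_true(all(z$dSp == 0))
  expect_true(all(z$degenerate))
})

test_that("OSM tables are identical across repeated searches", {
  lib <- toy_library(seed = 43, len = 150)
  sim <- synthesize_dataset(lib, 10, sim_params(), seed = 47)
  t1 <- withr::local_tempfile(); t2 <- withr::local_tempfile()
  write_osm_table(search_spectra(sim$spectra, lib, score_params()), t1)
  write_osm_table(search_spectra(sim$spectra, lib, score_params()), t2)
  expect_identical(readLines(t1), readLines(t2))
})
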