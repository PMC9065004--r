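# Independent oracles used across the suite. These deliberately re-derive
# masses and scores from first principles along a different code path than
# the package (their own atomic-mass table, their own formula expansion),
# so agreement is meaningful.

# independently typed NIST monoisotopic masses
ORACLE_MASS <- c(
  H = 1.007825032, C = 12, N = 14.003074005, O = 15.994914620,
  P = 30.973761630, D = 2.014101778, C13 = 13.003354835, N15 = 15.000108899
)

# expand a formula string atom by atom (character walk, no regex groups)
oracle_formula_mass <- function(formula) {
  chars <- strsplit(formula, "")[[1]]
  total <- 0
  i <- 1
  while (i <= length(chars)) {
    sym <- chars[i]; i <- i + 1
    if (i <= length(chars) && grepl("[a-z]", chars[i])) {
      sym <- paste0(sym, chars[i]); i <- i + 1
    }
    digits <- ""
    while (i <= length(chars) && grepl("[0-9]", chars[i])) {
      digits <- paste0(digits, chars[i]); i <- i + 1
    }
    count <- if (digits == "") 1 else as.integer(digits)
    total <- total + ORACLE_MASS[[sym]] * count
  }
  total
}

ORACLE_H2O <- 2 * ORACLE_MASS[["H"]] + ORACLE_MASS[["O"]]
ORACLE_HPO3 <- ORACLE_MASS[["H"]] + ORACLE_MASS[["P"]] + 3 * ORACLE_MASS[["O"]]

# neutral mass of an oligo from its literal elemental composition
oracle_oligo_mass <- function(seq, five_prime = "OH", three_prime = "P",
                              n15 = FALSE, h2 = NULL) {
  alf <- default_alphabet()
  codes <- strsplit(seq, "")[[1]]
  total <- ORACLE_H2O
  for (cd in codes) {
    f <- alf$formula[alf$code == cd]
    total <- total + oracle_formula_mass(f)
    if (n15) {
      nN <- sum(parse_formula(f)[["N"]])
      total <- total + nN * (ORACLE_MASS[["N15"]] - ORACLE_MASS[["N"]])
    }
    if (!is.null(h2) && cd %in% names(h2)) {
      total <- total + h2[[cd]] * (ORACLE_MASS[["D"]] - ORACLE_MASS[["H"]])
    }
  }
  if (five_prime == "P") total <- total + ORACLE_HPO3
  if (three_prime == "OH") total <- total - ORACLE_HPO3
  if (three_prime == "cP") total <- total - ORACLE_H2O
  total
}

# random oligo for property tests; modified codes included with prob mod_p
random_oligo <- function(len = sample(3:8, 1), mod_p = 0.2,
                         three_prime = sample(c("P", "OH", "cP"), 1),
                         scheme = scheme_identity()) {
  canon <- c("A", "C", "G", "U")
  mods <- c("Y", "5", "7", "3", "6")
  codes <- sample(canon, len, replace = TRUE)
  swap <- runif(len) < mod_p
  codes[swap] <- sample(mods, sum(swap), replace = TRUE)
  oligo(paste(codes, collapse = ""), three_prime = three_prime,
        scheme = scheme)
}

# exhaustive re-derivation of the fragment assignment and score:
# iteratively pick the globally closest (ion, peak) pair within tolerance
# (ties: higher intensity, then lower m/z), then recompute n, the intensity
# sums and S_p straight from the definitions.
oracle_match_score <- function(spectrum, entry, params) {
  peaks <- spectrum$peaks
  # exclusion of precursor and loss peaks
  losses <- precursor_losses(entry$oligo,
                             charges = unique(entry$precursors$charge))
  excluded <- rep(FALSE, nrow(peaks))
  for (lm in losses$mz) {
    hit <- abs((peaks[, "mz"] - lm) / lm * 1e6) <= params$ms2_ppm
    for (cmz in peaks[hit, "mz"]) {
      excluded <- excluded |
        abs(peaks[, "mz"] - cmz) <= params$exclusion_window
    }
  }
  pk <- peaks[!excluded, , drop = FALSE]
  L <- nrow(entry$fragments)
  if (nrow(pk) == 0 || L == 0) {
    return(list(n = 0L, sum_I_match = 0, sum_I_all = 0, Sp = 0))
  }
  rel <- pk[, "intensity"] / max(pk[, "intensity"])
  frag <- entry$fragments
  avail_ion <- rep(TRUE, L)
  avail_peak <- rep(TRUE, nrow(pk))
  matched <- integer(0)          # ion indices matched
  repeat {
    best <- NULL
    for (t in which(avail_ion)) {
      for (p in which(avail_peak)) {
        err <- (pk[p, "mz"] - frag$mz[t]) / frag$mz[t] * 1e6
        if (abs(err) > params$ms2_ppm) next
        cand <- c(abs(err), -pk[p, "intensity"], pk[p, "mz"], t, p)
        if (is.null(best) ||
            isTRUE(cand[1] < best[1]) ||
            (cand[1] == best[1] && cand[2] < best[2]) ||
            (cand[1] == best[1] && cand[2] == best[2] &&
             cand[3] < best[3])) {
          best <- cand
        }
      }
    }
    if (is.null(best)) break
    avail_ion[best[4]] <- FALSE
    avail_peak[best[5]] <- FALSE
    matched <- c(matched, best[4])
    names(matched)[length(matched)] <- best[5]
  }
  n <- length(matched)
  sum_match <- sum(rel[as.integer(names(matched))])
  sum_all <- sum(rel)
  if (n == 0) return(list(n = 0L, sum_I_match = 0, sum_I_all = sum_all,
                          Sp = 0))
  # consecutive reward from the definition
  B <- 0
  mf <- frag[matched, ]
  for (key in unique(paste(mf$series, mf$charge))) {
    idx <- sort(mf$index[paste(mf$series, mf$charge) == key])
    B <- B + params$beta * params$alpha * sum(diff(idx) == 1)
  }
  list(n = n, sum_I_match = sum_match, sum_I_all = sum_all,
       Sp = (sum_match / sum_all) * (n / L) * (1 + B))
}

# small T1 library over a fixed random parent, reused by several files
toy_library <- function(seed = 11, len = 200, max_missed = 1,
                        schemes = list(scheme_identity())) {
  set.seed(seed)
  seqs <- c(ref1 = paste(sample(c("A", "C", "G", "U"), len, TRUE),
                         collapse = ""))
  build_library(seqs, enzyme = "T1", max_missed = max_missed,
                schemes = schemes, seed = seed + 1)
}
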