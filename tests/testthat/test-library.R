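test_that("default series counts depend on the 3' chemistry", {
  expect_length(default_series("P"), 11)
  expect_length(default_series("OH"), 9)
  expect_length(default_series("cP"), 9)
  expect_equal(nrow(fragment_series(oligo("ACGUA"), charges = 1)), 44)
  expect_equal(nrow(fragment_series(oligo("ACGUA", three_prime = "OH"),
                                    charges = 1)), 36)
  # y-P/z-P on a 3'-OH oligo are skipped with a warning
  expect_warning(
    f <- fragment_series(oligo("ACG", three_prime = "OH"),
                         series = c("y", "y-P"), charges = 1),
    "skipped")
  expect_equal(unique(f$series), "y")
})

test_that("complementary fragment pairs reconstruct the precursor mass", {
  set.seed(401)
  for (k in 1:100) {
    o <- random_oligo(len = sample(3:9, 1),
                      scheme = if (k %% 3 == 0) scheme_15n()
                               else scheme_identity())
    f <- fragment_series(o, series = default_series(o$three_prime),
                         charges = 1)
    target <- oligo_neutral_mass(o) + 18.0105647
    n <- length(o$codes)
    for (pair in list(c("a", "w"), c("b", "x"), c("c", "y"),
                      c("d", "z"))) {
      for (i in seq_len(n - 1)) {
        m5 <- f$neutral_mass[f$series == pair[1] & f$index == i]
        m3 <- f$neutral_mass[f$series == pair[2] & f$index == n - i]
        expect_equal(m5 + m3, target, tolerance = 1e-4)
      }
    }
  }
})

test_that("fragment masses reproduce from literal elemental composition", {
  set.seed(402)
  alf <- default_alphabet()
  for (k in 1:25) {
    o <- random_oligo(len = sample(3:7, 1), three_prime = "P")
    f <- fragment_series(o, charges = 1)
    n <- length(o$codes)
    M <- oracle_oligo_mass(o$seq, o$five_prime, o$three_prime)
    for (i in seq_len(n - 1)) {
      prefix <- substr(o$seq, 1, i)
      d_i <- oracle_oligo_mass(prefix, o$five_prime, "P")
      expect_equal(f$neutral_mass[f$series == "d" & f$index == i], d_i,
                   tolerance = 1e-4)
      expect_equal(f$neutral_mass[f$series == "c" & f$index == i],
                   d_i - ORACLE_H2O, tolerance = 1e-4)
      expect_equal(f$neutral_mass[f$series == "b" & f$index == i],
                   d_i - ORACLE_HPO3, tolerance = 1e-4)
      a_i <- d_i - ORACLE_HPO3 - ORACLE_H2O
      expect_equal(f$neutral_mass[f$series == "a" & f$index == i], a_i,
                   tolerance = 1e-4)
      base_i <- oracle_formula_mass(
        alf$base_formula[alf$code == substr(o$seq, i, i)])
      expect_equal(f$neutral_mass[f$series == "a-B" & f$index == i],
                   a_i - base_i, tolerance = 1e-4)
      # one 3' series checked independently: under the hydrolytic
      # complementarity bookkeeping (a + w = M + H2O) the w ion is the
      # 5'-phosphorylated suffix plus one water
      suffix <- substr(o$seq, i + 1, n)
      expect_equal(f$neutral_mass[f$series == "w" & f$index == n - i],
                   oracle_oligo_mass(suffix, "P", o$three_prime) +
                     ORACLE_H2O,
                   tolerance = 1e-4)
    }
    # m/z consistency across all rows
    f2 <- fragment_series(o, charges = c(1, 2))
    expect_equal(f2$mz, mz_from_mass(f2$neutral_mass, f2$charge))
  }
})

test_that("precursor losses cover water, phosphate and each distinct base", {
  pl <- precursor_losses(oligo("AUG"), charges = 1)
  M <- oligo_neutral_mass(oligo("AUG"))
  get <- function(t) pl$neutral_mass[pl$type == t]
  expect_equal(M - get("M-base(A)"), 135.0545, tolerance = 1e-4)
  expect_equal(M - get("M-base(U)"), 112.0273, tolerance = 1e-4)
  expect_equal(M - get("M-base(G)"), 151.0494, tolerance = 1e-4)
  expect_equal(get("M-H2O"), M - 18.010565, tolerance = 1e-4)
  expect_true(all(pl$neutral_mass > 0 & pl$neutral_mass <= M))
  # homopolymer: exactly one distinct base loss
  pg <- precursor_losses(oligo("GGG"), charges = 1)
  expect_equal(sum(grepl("base", pg$type)), 1)
})

test_that("decoys shuffle all but the 3' residue and are reproducible", {
  o <- oligo("UACG")
  set.seed(403)
  seen <- character(0)
  for (k in 1:25) {
    d <- generate_decoy(o)
    expect_equal(substr(d$seq, 4, 4), "G")          # 3' residue fixed
    expect_false(d$seq == o$seq)                    # must differ
    expect_equal(sort(d$codes), sort(o$codes))      # a permutation
    seen <- c(seen, d$seq)
  }
  expect_gt(length(unique(seen)), 1)
  expect_null(generate_decoy(oligo("GGGG")))        # homopolymer: none
  expect_null(generate_decoy(oligo("AAG")))         # unique head: none
  set.seed(99); a <- replicate(10, generate_decoy(o)$seq)
  set.seed(99); b <- replicate(10, generate_decoy(o)$seq)
  expect_identical(a, b)                            # determinism
})

test_that("library construction matches hand enumeration on a toy FASTA", {
  seqs <- c(toy = "AUCGGAUGCCGAUAAGGCUA")  # 20 nt
  lib <- build_library(seqs, enzyme = "T1", max_missed = 0, decoys = FALSE)
  # T1 products: AUCG|G|AUG|CCG|AUAAG|G|CUA; min_length 2 drops the two G;
  # duplicates collapse; expect AUCG, AUG, CCG, AUAAG, CUA
  expect_setequal(vapply(lib$entries, `[[`, character(1), "seq"),
                  c("AUCG", "AUG", "CCG", "AUAAG", "CUA"))
  # terminal fragment keeps the parent 3'-OH; others carry 3'-P
  t3 <- vapply(lib$entries, function(e) e$oligo$three_prime, character(1))
  sq <- vapply(lib$entries, `[[`, character(1), "seq")
  expect_equal(t3[sq == "CUA"], "OH")
  expect_true(all(t3[sq != "CUA"] == "P"))
  # decoy:target ratio is at most one
  lib2 <- build_library(seqs, enzyme = "T1", decoys = TRUE, seed = 5)
  dec <- sum(vapply(lib2$entries, `[[`, logical(1), "is_decoy"))
  expect_lte(dec, length(lib2$entries) - dec)
  expect_warning(empty <- build_library(character(0)), "empty")
  expect_length(empty$entries, 0)
})

test_that("library decoy sets are byte-identical across equal seeds", {
  seqs <- c(toy = "AUCGGAUGCCGAUAAGGCUAACCGGAUUACG")
  ids <- function(seed) {
    lib <- build_library(seqs, enzyme = "T1", max_missed = 1, seed = seed)
    vapply(lib$entries, `[[`, character(1), "id")
  }
  expect_identical(ids(7), ids(7))
  expect_false(identical(ids(7), ids(8)))
})

test_that("SeqX consolidates the 2H-scheme ACG/AYG ambiguity", {
  d <- scheme_2h_pyrimidine()
  e1 <- library_entry(oligo("ACG", scheme = d))
  e2 <- library_entry(oligo("AYG", scheme = d))
  # the pair differs by ~22 ppm at MS1 and up to ~50 ppm across fragments
  # (the a-B ion is the lightest ion carrying the C/Y difference), so it
  # merges once the tolerances exceed the ambiguity ...
  out <- seqx_consolidate(list(e1, e2), ms1_ppm = 25, ms2_ppm = 55)
  expect_length(out, 2)
  expect_equal(out[[1]]$display, "AXG: ACG|AYG")
  expect_equal(out[[2]]$display, "AXG: AYG|ACG")
  # ... and stays resolvable at tolerances below it
  keep <- seqx_consolidate(list(e1, e2), ms1_ppm = 16, ms2_ppm = 40)
  expect_equal(keep[[1]]$display, "ACG")
  # idempotent
  out2 <- seqx_consolidate(out, ms1_ppm = 25, ms2_ppm = 55)
  expect_identical(lapply(out2, `[[`, "display"),
                   lapply(out, `[[`, "display"))
  # far-apart sequences stay separate
  f1 <- library_entry(oligo("ACG"))
  f2 <- library_entry(oligo("AGG"))
  out3 <- seqx_consolidate(list(f1, f2), ms1_ppm = 16, ms2_ppm = 40)
  expect_equal(out3[[1]]$display, "ACG")
  expect_equal(out3[[2]]$display, "AGG")
  # a decoy indistinguishable from a target is removed
  dec <- library_entry(oligo("AYG", scheme = d), is_decoy = TRUE,
                       decoy_of = e1$id)
  out4 <- seqx_consolidate(list(e1, dec), ms1_ppm = 25, ms2_ppm = 55)
  expect_length(out4, 1)
  expect_false(out4[[1]]$is_decoy)
})

test_that("charge tables resolve by length and round-trip as TSV", {
  ct <- default_charge_tables()
  expect_equal(charges_for_length(3, ct$precursor), 1L)
  expect_equal(charges_for_length(5, ct$precursor), c(1L, 2L))
  expect_equal(charges_for_length(12, ct$precursor), c(1L, 2L, 3L))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_charge_table(ct$precursor, tf)
  expect_equal(read_charge_table(tf), ct$precursor)
})

test_that("a library round-trips through TSV + JSON sidecar", {
  lib <- toy_library(seed = 17, len = 60)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_library(lib, tf)
  back <- read_library(tf)
  expect_length(back$entries, length(lib$entries))
  for (i in seq_along(lib$entries)) {
    a <- lib$entries[[i]]; b <- back$entries[[i]]
    expect_equal(b$id, a$id)
    expect_equal(b$seq, a$seq)
    expect_equal(b$is_decoy, a$is_decoy)
    expect_equal(b$neutral_mass, a$neutral_mass, tolerance = 1e-9)
    expect_equal(b$precursors$mz, a$precursors$mz, tolerance = 1e-9)
    expect_equal(b$fragments$mz, a$fragments$mz, tolerance = 1e-6)
    expect_equal(b$fragments$series, a$fragments$series)
  }
})
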