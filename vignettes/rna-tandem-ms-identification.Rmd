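---
title: "Identifying modified RNA oligonucleotides from tandem MS data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying modified RNA oligonucleotides from tandem MS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligoms)
```

## The identification problem

Bottom-up RNA mass spectrometry digests an RNA with a base-specific
endonuclease, separates the short oligonucleotide products by LC, and
fragments them by CID in negative-ion mode. Each MS/MS scan must then be
assigned to the nucleolytic fragment — with its modifications, terminal
chemistry and isotope-label channel — that produced it. `oligoms` solves
this as a database search: an exhaustive theoretical library of candidate
precursors and their predicted fragment ions is built in silico, each scan
is matched against the candidates that fit its precursor m/z and charge,
and the quality of each oligonucleotide-spectrum match (OSM) is summarized
by an empirical score whose null behaviour is calibrated by shuffled decoy
sequences.

## Mass model

Monoisotopic atomic masses are hard-coded (CODATA/NIST values) so that all
mass arithmetic is bit-stable. An internal residue is defined as the
nucleoside-3′-monophosphate minus one water; a 5′-OH/3′-linear-phosphate
chain is then simply the sum of its residues plus H₂O, and other terminal
chemistries are additive adjustments (5′-P: +HPO₃; 3′-OH: −HPO₃;
2′,3′-cyclic phosphate: −H₂O). This convention mirrors the behaviour of
the common endonucleases, which leave 5′-OH/3′-P products, so enzymatic
fragments need no adjustment at all. Negative-mode ions are deprotonated:
m/z = (M − z·1.007276)/z.

Every residue is a single case- and digit-sensitive character backed by an
elemental formula and a base formula in an editable alphabet, so dozens of
modifications can coexist in one digest. Labeling schemes act on top of the
formulas: "all N → ¹⁵N"-style element swaps scale with the nitrogen count
of whatever formula they touch, while per-residue deuterium counts encode
metabolic 5,6-²H-uracil feeding (two ²H on C and U, one on Ψ because its
C5 is bonded to the ribose). The deuterium positions sit on the pyrimidine
base, so base-loss ions shift accordingly. Purines are left unlabeled under
this scheme; the label enters pyrimidine biosynthesis only. This mass model
reproduces the characteristic diagnostics of the labeling strategies: the
0.984 Da natural U/C gap, its collapse to 0.013 Da under uniform ¹⁵N, and
the 0.022 Da Ψ/C shift under ²H feeding.

## Fragment-ion model

CID of the phosphodiester backbone yields four bond cleavages and hence
eight sequence-defining series (a/b/c/d from the 5′ side, w/x/y/z from the
3′ side), plus the a-B series (a ions that have lost their 3′-terminal
nucleobase) and, for 3′-phosphate oligos, the frequent phosphate-loss
variants y-P and z-P — 11 series for 3′-P, 9 for 3′-OH/cP. Each series runs
over indices 1…n−1 from its own terminus (a-B included, a symmetric choice
the data formats leave open).

Neutral masses are generated from a prefix-sum offset table
(d_i = Σ residues + H₂O + 5′ adjustment; c = d − H₂O; b = d − HPO₃;
a = b − H₂O; a-B = a − base) and the 3′ series follow by hydrolytic
complementarity:

a_i + w_{n−i} = b_i + x_{n−i} = c_i + y_{n−i} = d_i + z_{n−i} = M + H₂O.

That identity — each complementary pair reassembles the precursor plus the
water formally consumed by cleaving the bond — is the primary correctness
oracle for the table and is asserted to < 10⁻⁴ Da on random oligos in the
test suite, together with an independent elemental-composition derivation
of every 5′ ion and of w.

Precursor losses (M, M−H₂O, M−HPO₃, M−base for each distinct base) are
generated at the precursor charge states only. They are annotation and
exclusion ions: they are never counted in n or L.

Charge states are empirical, per-platform inputs; they ship as editable
length-keyed tables (precursor z = 1…3 rising with length, fragment
z = 1–2) rather than asserted constants.

## Scoring

For a candidate with L theoretical sequence-defining ions of which n match
spectrum peaks:

S_p = (ΣI_match / ΣI_all) · (n/L) · (1 + Σ_s B_s)

* Intensities are normalized to the most intense peak remaining after the
  precursor and its loss peaks have been assigned and excluded together
  with a ±1.5 m/z window around each (wide enough to cover their isotope
  envelopes; configurable). ΣI_all keeps unmatched noise peaks — that is
  what penalizes wrong candidates — so the score is invariant to uniform
  intensity rescaling but not to spectral contamination.
* L counts all generated candidate ions for the entry, across its fragment
  charge states; restricting the series/charge tables is the intended way
  to keep L (and with it the n/L penalty) realistic for a given platform.
* B_s = β·α·k_s, where k_s is the number of adjacent matched index pairs
  (i, i+1) within one series-at-one-charge track, with defaults β = 0.025
  and α = 2. The linear-in-consecutive-pairs form follows the SEQUEST
  lineage of rewarding uninterrupted ion ladders; the exact published
  reward shape for RNA is not fully specified, so this form is isolated in
  one pure function (`consecutive_reward()`) and is the one deliberately
  replaceable component of the score.
* Peak assignment is greedy by ascending |ppm error|, each peak and each
  ion used at most once; ties go to the higher-intensity, then lower-m/z
  peak. This is deterministic and order-independent, and agrees exactly
  with an exhaustive re-derivation on small spectra (tested).

Competing OSMs for a spectrum are ranked by S_p (ties: larger n, then
target before decoy, then lexicographic sequence — purely to make reports
reproducible) and annotated with ΔS_p = (S_p^top − S_p)/S_p^top, the
runner-up-target ΔS_p2 and best-decoy ΔS_pD; when the top score is 0 the
deltas are defined as 0 and flagged. S_p is 0 whenever n = 0 or the
retained spectrum is empty.

## Decoys, FDR and diagnostics

Each target contributes at most one decoy: a random permutation of its
residues with the 3′-terminal residue fixed (it carries the cleavage
specificity), required to differ from the target; homopolymers yield none,
and only decoy sequences unique within the library (and distinct from all
targets) are retained. Simple FDR at cutoff s is D(s)/T(s) over rank-1
OSMs — D/T rather than (D+1)/T, matching the cited proteomics convention —
and the cutoff for a requested FDR is the minimal observed score achieving
it, applied uniformly across sequence lengths. Because RNA's four-letter
alphabet starves short targets of decoys, the default statistical analysis
restricts to targets that had at least one competing decoy (toggleable).
Matching-offset distributions (mean, σ, histogram) diagnose systematic
drifts; the mean is exactly the global MS1/MS2 offset correction that
re-centers them, and 2σ is the usual basis for choosing tolerances.

## SeqX consolidation

Isotope labeling can make distinct sequences indistinguishable (the ²H
scheme leaves ACG and AΨG 0.022 Da ≈ 22 ppm apart at the precursor level,
and ~35–50 ppm at the fragment level, the lightest discriminating ion —
a-B — being the most sensitive). Entries of equal length and termini whose
precursor masses agree within the MS1 tolerance and whose fragment sets
agree pairwise within the MS2 tolerance are therefore merged under an
X-placeholder name listing all members (`AXG: ACG|AYG`), and decoys that
fall into a group containing a target are removed. The pairwise relation is
closed transitively with union-find so the result is order-independent,
and the operation is idempotent. Consequently a pair merges only when the
stated tolerances actually exceed its ambiguity — at 16/40 ppm the ACG/AΨG
pair is still resolvable, at 25/55 ppm it merges.

## The spectrum simulator

`synthesize_spectrum()` emulates the features of a centroided CID scan
that the search and score actually consume: per-fragment Bernoulli
detection (default p = 0.9), log-normal peak intensities, Gaussian ppm
jitter (2 ppm MS1, 3 ppm MS2 — modern Q-TOF territory), uniform-m/z noise
peaks with lower log-normal intensities (default 5 per scan, the simplest
null that exercises the ΣI_all penalty), an always-present precursor peak,
and optional isotopologue displacement of the recorded precursor. It does
not emulate chromatography, isotope envelopes, series-dependent intensity
structure, or co-isolation chimeras; passing tests therefore demonstrate
correctness of the matching/scoring/FDR machinery, not instrument-level
realism. Truths are always drawn from targets.

## Validation scales and numerical choices

The test suite validates mass arithmetic on 100 random oligos against an
independently coded elemental-summation oracle (< 10⁻⁴ Da), scoring against
exhaustive assignment enumeration on ≤ 6-peak spectra (exact), FDR against
a brute-force cutoff scan on 1,000 synthetic rank-1 scores (identical), and
the full pipeline on 200 simulated spectra from a T1 digest of a random
400-nt RNA with one missed cleavage (≥ 95% rank-1 recovery; estimated FDR
at the 1% cutoff consistent with the true false-positive proportion within
the 95% binomial interval). Determinism is byte-level: equal seeds give
identical decoy sets, mgf files and OSM tables. These sizes keep the whole
suite under a minute while leaving every code path exercised.

Degenerate inputs are defined, not special-cased: empty digests warn and
return empty libraries; length-1 oligos carry no fragments and score 0;
spectra consisting solely of precursor-loss peaks score 0; an unreachable
FDR returns +∞ with a warning.

## Limitations

Average (non-monoisotopic) masses, positive-ion mode, adducts, internal
fragments, intensity prediction and isotope-ratio quantitation are out of
scope. Cleavage rules for cusativin/MC1/MAZ are editable defaults from the
nuclease literature, not asserted constants; cleavage is all-or-none (no
partial-efficiency model). The consecutive-match reward is one defensible
member of a family the published material does not pin down; conclusions
that hinge on its exact shape should be checked against alternatives via
`consecutive_reward()`.
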