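---
title: "Targeted detection of tetra-sialylated EPO glycopeptides: methods and design"
author: "episial authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted detection of tetra-sialylated EPO glycopeptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episial)
```

## The problem

Recombinant erythropoietin (rEPO) is misused as a doping agent. Endogenous
urinary EPO carries mono- to tri-sialylated N-glycans; glycans terminating
in **four** sialic acid (NeuAc) residues occur on recombinant products but
not on the endogenous hormone, so a tetra-sialylated N-glycopeptide is an
*exogenous* marker: observing it in urine implies an administered drug.

`episial` implements the computational side of a targeted LC–HRMS assay for
such glycopeptides: in-silico multi-enzyme digestion of the EPO sequence,
exact monoisotopic mass and m/z arithmetic for intact glycopeptides,
diagnostic fragment generation, targeted detection in centroided runs, and
the bioanalytical validation battery — plus a synthetic-run generator with
known ground truth so the whole pipeline is testable without instrument
data.

## Mass model

All arithmetic is monoisotopic. A peptide's neutral mass is the sum of its
residue masses plus one water, plus fixed modifications (default:
carbamidomethyl on Cys, +57.021464 Da, from chloroacetamide alkylation
during sample preparation; variable modifications are out of scope). An
attached N-glycan contributes the sum of its dehydrated monomer (residue)
masses with **no** extra water — the reducing end is engaged in the bond to
Asn. Glycan compositions are vectors of counts over the residue classes

| class | residue mass (Da) |
|-------|------------------:|
| HexNAc | 203.079373 |
| Hex | 162.052824 |
| Fuc | 146.057909 |
| NeuAc | 291.095417 |
| Acetyl | 42.010565 |

and are read and written in two notations: `HexNAc(6)Hex(7)Fuc(1)NeuAc(4)`
and the compact glycopeptide-name suffix `_6_7_1_4`. **Digit order in the
suffix notation is (HexNAc, Hex, Fuc, NeuAc).** Some published figure
captions list hexose before HexNAc for this nomenclature; only the
HexNAc-first reading is consistent with the composition tables and with the
published precursor m/z for the target (see below), so the package adopts
it and treats the caption ordering as a transcription slip.

The ion m/z at charge $z$ monitoring the $k$-th ^13^C isotopologue is

$$ m/z = \frac{M + k\,\Delta_{13C} + z\,m_p}{z}, \qquad
   \Delta_{13C} = 1.003355,\ m_p = 1.007276 . $$

### Why the monitored isotopologue defaults to 2

For the assay target — `HCSLNENITVPDTK` (EPO Asn38 tramline, mature-chain
residues 32–45) carrying `HexNAc(6)Hex(7)Fuc(1)NeuAc(4)` — the neutral
monoisotopic mass is 5290.0528 Da, so the monoisotopic [M+4H]^4+^ is
1323.5205. Published transition tables for this assay list the precursor as
1324.02, which is the **M+2 isotopologue** (1323.5205 + 2·1.003355/4 =
1324.0221): a ~5.3 kDa analyte has its isotope-envelope maximum near M+2
(the binomial ^13^C model in `isotope_cluster()` puts the mode at index 2
for this mass), and a narrow SIM window is sensibly centred there.
`transition_entry()` therefore carries an explicit `isotopologue` index,
default 2.

## Digestion

Cleavage is C-terminal to a residue set: trypsin K/R, Glu-C E/D, and the
combined multi-enzyme digest E/D/R/K. The proline rule (no cleavage before
P) is on by default for all presets and can be disabled — search engines
differ on whether combined-specificity settings apply it, so both behaviours
are supported. `digest()` emits every fully specific peptide with 0 to
`max_missed` (default 2) internal missed cleavages; the 0-missed set
partitions the protein. Glycosylated Asn does not alter cleavage.

On the packaged 165-residue mature EPO chain (signal peptide and C-terminal
Arg removed; N-sites number 24/38/83 on this chain), the combined rule at
≤2 missed cleavages yields the three glycopeptide backbones covering the
sites: `AENITTGCAE` (Asn24), `HCSLNENITVPDTK` (Asn38, 2 missed cleavages:
internal E and D), `GQALLVNSSQPWEPLQLHVDK` (Asn83). Sequon discovery
(`find_sequons()`) reports every N-X-[S/T] with X ≠ P.

## Fragments and transitions

`oxonium_ions()` emits the low-mass diagnostics at charge 1: one ion per
monosaccharide class present, the NeuAc water-loss ion, and the
HexNAc+Hex and HexNAc+Hex+NeuAc combinations when counts allow. For the
target these are 204.087, 274.092, 292.103, 366.139 and 657.235 — matching
the published transition set to its printed precision (±0.01). Ions are
**labelled by computed composition**, never by table labels: 204.087 is the
HexNAc oxonium (the hexose oxonium is 163.060), even though some published
tables annotate 204.08 as "hexose".

One published product entry, 658.23 annotated "y6", does not match the
computed y6 of the target backbone (TVPDTK, 660.356); it does match the
first ^13^C isotopologue of the 657.235 oxonium to 0.01. The package does
not assert an identity: `target_transition(extra_product_mz = 658.23)`
carries it verbatim as an `"extra"` product that never counts toward the
detection policy's product requirement. This ambiguity is also why the
default policy requires 4 of the 5 composition-derived products rather
than a strict 5.

Backbone `b`/`y` ladders use the glycan-free backbone convention (under
stepped-energy HCD the glycan is typically lost before backbone cleavage);
`y_ladder()` builds the peptide+partial-glycan Y series attaching residues
core-first (HexNAc, Hex, Fuc, NeuAc last — i.e. NeuAc trimmed first). The
trimming order is a labelling convention only; detection uses set
membership.

## Detection

`detect_target()` implements the targeted call:

1. **XIC**: per-scan summed intensity within ±10 ppm (the assay's precursor
   tolerance) of the transition precursor, inside its retention-time
   window.
2. **Peak and S/N**: apex of the XIC; peak region = apex ± 3 scan widths;
   S/N = apex / (median + 1.4826·MAD of the region-exterior points). The
   robust noise estimator tolerates sparse spikes; an all-zero background
   is reported as infinite S/N with a flag rather than silently.
3. **MS2 confirmation**: product ions matched one-to-one (closest absolute
   error first, ties to the lower expected m/z) within ±0.01 m/z in MS2
   scans whose isolation window covers the precursor.
4. **Call**: detected iff S/N > 3 **and** ≥ 4 non-extra products matched.
   The stricter reference S/N (5) is reported alongside. Absent MS2
   coverage is a diagnosed negative, never an error.

Quantification uses `measure_peak_area()`: the median XIC intensity of the
window — the chemical background at the target mass — is subtracted before
trapezoidal integration. Without this baseline correction the calibration
intercept absorbs the background, which in turn destabilises
back-calculation at concentrations whose signal is comparable to the
background.

## Validation battery

All thresholds follow the assay's stated acceptance rules and are strict
inequalities: carryover passes iff mean(blank)/mean(high) × 100 < 5%;
intraday precision passes iff %CV of back-calculated concentrations < 15%
per level; detection requires S/N > 3 (reference > 5). The LOD is the
lowest ladder concentration at which **all** replicates exceed S/N 3
(`mode = "all"`, the conservative reading; a replicate-mean mode is also
implemented since assays differ and the convention is rarely stated).

Linearity is ordinary least squares of per-level mean area against
concentration, unweighted by default for the *reported* slope/r².
**Back-calculation**, however, defaults to a 1/x²-weighted fit: with
proportional (constant-CV) error over a 0–800 ng/mL range, the unweighted
fit is dominated by the high levels and leaves the intercept orders of
magnitude too uncertain to invert areas at 0.5 ng/mL; 1/x² weighting is
the standard bioanalytical remedy. Both choices are arguments of
`validate_study()`.

## The synthetic-run generator

`simulate_run()` emulates the assay's signal structure, not urine
chemistry:

* **MS1 (t-SIM)**: the precursor isotopologue cluster (binomial ^13^C
  model) eluting as a Gaussian peak — apex 15 min inside a 35-min-gradient
  style acquisition, FWHM 0.2 min, one scan per 0.03 min over a 2-min
  window — on a chemical background at the target mass (baseline 20
  counts, Gaussian sd 4, sparse exponential spikes, 2 ppm mass jitter).
* **MS2**: product ions scaled to the elution profile plus diffuse random
  background peaks, one scan after every third MS1 scan, 2 m/z isolation.
* **Calibration convention**: the full-window XIC area of the monitored
  isotopologue equals concentration × response factor (default 100 area
  units per ng/mL), which makes every injected parameter recoverable in
  closed form.

Under these defaults blank runs sit well below the S/N-3 threshold and
produce essentially no MS2 product matches, so the false-positive rate on
seeded blanks is zero. (Blank S/N cannot be driven much below ~1 by
parameter choice alone: the apex is a maximum over the peak region and the
noise level is a median-based statistic of the same distribution, so their
ratio concentrates near 1–2 for pure noise.)

`simulate_validation_study()` generates the full battery with the assay's
published design — 8 calibration levels (0–800 ng/mL) × 7 replicates,
5 × 1000 ng/mL carryover pairs, 3 precision levels (0.5/50/200 ng/mL) × 5
replicates, 5 spiked (10 ng/mL)/negative pairs, 5 urine/neat matrix pairs
(101 runs) — with injected truths: 5% proportional response noise on the
calibration arms, 8% on the precision arm, a 2% carryover fraction, and a
0.9 urine suppression factor. The precision arm models a single day
(3 × 5 runs); multi-day reproducibility is out of scope.

What the generator does **not** emulate: real urine background libraries,
co-eluting glycoforms, retention-time drift, detector saturation, and
ionisation-efficiency differences between glycoforms. Passing recovery
tests therefore demonstrates that the estimators are correct and unbiased
under the stated signal model — not that the assay achieves any particular
performance on real samples. The assay's published instrument results
(r² 0.988, LOD 0.5 ng/mL, %CV 1.94–11.29) are instrument-dependent and are
deliberately not targets of the synthetic study.

## Numerical choices and degenerate inputs

* m/z comparisons against two-decimal published values use ±0.01 (printed
  precision); internal recomputation checks use 1e-4 Da.
* Mass tables are validated against an independent elemental-composition
  oracle (CODATA isotope masses) to 1e-4 Da in the test suite.
* Empty peptide, zero/negative charge, negative counts, malformed
  composition strings, empty candidate or glycan lists, single-level
  calibration, sub-2-replicate precision levels: all rejected with
  explicit messages. Zero means (carryover high, neat matrix, precision
  level) yield flagged `NA`s, never silent zeros.
* Tie-breaks: product matching assigns closest-first with exact ties going
  to the lower expected m/z; duplicate transitions are collapsed with a
  warning.
* Determinism: every stochastic routine takes an explicit seed, restores
  the caller's RNG state, and derives sub-seeds below 2^31.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script simulations use the study design
above at its natural size (101 runs per study; 5 study seeds for recovery
means), 50 seeded blanks for the false-positive rate, 100 runs for S/N
recovery, a 6-level × 5-replicate LOD ladder, and 100 random sequences
(length ≤ 50) for the digestion oracle — sizes at which each property's
sampling error is comfortably inside its stated tolerance.

## Known limitations

* Only proton adducts and monoisotopic masses; no isotope fine structure
  or average masses.
* Semi-/non-specific digestion and enzyme kinetics are not modelled.
* Quantification is XIC peak area only; no cross-run alignment or
  co-elution deconvolution.
* O-glycosylation (EPO Ser126) and hyperglycosylated analogues
  (darbepoetin) are out of scope.
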