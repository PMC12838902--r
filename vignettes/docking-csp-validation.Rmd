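---
title: "Validating docked protein–ligand poses against NMR chemical shift perturbations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating docked protein–ligand poses against NMR chemical shift perturbations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dockcsp)
```

## The problem

Polysialylation of the neural cell adhesion molecule is catalysed by the
polysialyltransferases ST8Sia2/ST8Sia4 and is a drug target in metastatic
cancer. The catalytically crucial polysialyltransferase domain (PSTD,
residues 246–277 of ST8Sia4) binds the donor substrate CMP-Sia, and three
inhibitor candidates — CMP, low molecular weight heparin (LMWH) and the
11-residue lactoferricin peptide LFcinB11 — compete for the same site. No
experimental 3D structure of ST8Sia4 exists, so predicted structures
(AlphaFold) and docked poses (DiffDock/AlphaFold 3) are the only atomic
models, and their binding maps need independent validation.

`dockcsp` implements that validation as a reusable pipeline:

1. **Contact profiling** — classify receptor–ligand heavy-atom distances
   into three interaction classes and aggregate per-residue binding-site
   profiles, binding ranges, mean contact distances and hotspot residues.
2. **CSP analysis** — compute per-residue combined amide chemical shift
   perturbations from free/bound ¹H–¹⁵N HSQC shift tables, locate the peak
   residue and the significant perturbation range, and rank ligands.
3. **Consistency reporting** — quantify the agreement between the
   docking-derived binding map and the NMR perturbation map.

The published reference data for the three PSTD ligand systems never
deposited pose coordinates; their printed per-residue distance lists are
the only coordinates-free record of the docking models. The package ships
those lists as transcribed fixtures (`reference_fixtures()`), and
`profile_from_distance_table()` reproduces the published summaries from
them directly, bypassing 3D geometry.

## Distance classes

Contacts are classified purely by heavy-atom distance \(d\):

| class | default bin (Å) | interpretation |
|---|---|---|
| `moderate_hbond` | \(0 < d \le 3.3\) | moderate hydrogen bond |
| `weak_hbond_vdw` | \(3.3 < d \le 4.0\) | weak H-bond / optimal van der Waals |
| `hydrophobic` | \(4.0 < d \le 7.0\) | hydrophobic contact |

The source data describe the bins inconsistently: the prose gives
2.5–3.5 / 3.5–4.0 / 4.0–6.9 Å, the table headers 2.7–3.3 / 3.3–4.0 /
4–10 Å, and the lists themselves contain a 2.4 Å "moderate" entry and a
3.3 Å "moderate" entry. The default scheme `(0, 3.3] / (3.3, 4.0] /
(4.0, 7.0]` is the unique contiguous upper-edge-inclusive partition that
reproduces *every* listed per-distance class assignment; both published
variants remain available as `bin_preset("text")` and
`bin_preset("table")`.

Distance is the operative criterion in the source data, so the
donor–acceptor **chemistry gate** is off by default. With
`bin_scheme(chemistry_gate = TRUE)`, a pair in the moderate bin whose
atoms cannot form a donor–acceptor pair (per a packaged residue-chemistry
table; ligand N/O atoms are over-approximated as both donor and acceptor
when no hydrogens are present) is demoted to the weak class rather than
dropped — the geometric contact still exists, it just cannot be a
hydrogen bond.

## What one "binding site" is

The source lists count a residue several times (R252 contributes 4–7
entries per ligand) but never define the pairing rule. The package's
default reduction keeps, for each (receptor residue, ligand heavy atom)
pair, only the closest receptor atom: a residue can bind several ligand
atoms, but one ligand atom is never counted twice against the same
residue. `reduction = "all"` and `"closest_per_residue"` are available for
sensitivity analysis. Candidate pairs are found with a uniform cell-list
spatial index (cell edge = outer bin bound); the test suite proves it
equivalent to a brute-force all-pairs scan on randomized structures.

Hotspot ties break to the lowest sequence number, with all tied residues
retained in machine-readable output. Distances are reported to 0.1 Å in
human-readable output (matching the source convention) but kept at full
precision internally; means are displayed at 2 decimals.

```{r}
cmp <- profile_from_distance_table(read_distance_fixture("cmp"),
                                   ligand_id = "CMP")
glance(cmp)
```

## Combined CSP

The source data quantify binding by amide chemical shift perturbation but
never print the combination formula. The package uses the standard
Euclidean amide form
\[
\mathrm{CSP} = \sqrt{\Delta\delta_H^2 + (\Delta\delta_N/\alpha)^2},
\qquad \alpha = 5 \text{ by default},
\]
with \(\alpha\) configurable (the other widespread convention, a 0.14
nitrogen weight, corresponds to \(\alpha \approx 7.14\)). This is a
deliberate, prominently flagged gap-filling choice: peak *locations* and
range calls are insensitive to \(\alpha\), absolute ppm values are not.

The **significant range** is the maximal contiguous run of residues with
CSP at least `fraction_of_max` (default 0.5) of the peak that contains the
peak residue. The default reproduces a contiguous 9-residue
plateau (the N247–Y255 pattern) on plateau-shaped fixtures; raising the
threshold can only shrink the range.

Ligand **ranking** is by descending peak CSP; exact ties break toward the
lower ligand concentration (a larger perturbation at lower concentration
implies tighter binding under fast exchange), then alphabetically, with a
`tie_flag` marking ties that concentration could not cleanly resolve.
Concentration is metadata only — no \(K_d\) fitting is attempted.

## Docking-vs-NMR consistency

`compare_docking_csp()` compares residue *sets* (contact-bearing residues
vs significant-range residues) with the Jaccard index, so interior gaps in
either map reduce the score; `mode = "interval"` reproduces the looser
min–max-interval reading. The verdict thresholds (0.4 partial / 0.8
consistent, plus a hotspot-identity requirement for "consistent") are
package-defined stand-ins: the source data offer only qualitative language
("almost consistent"), so the thresholds are explicit and logged rather
than implied.

```{r}
fx <- make_csp_fixture(peak_value = 0.151, noise_sd = 0)
prof <- csp_profile(fx$free, fx$bound, ligand_id = "CMP", concentration = "1mM")
compare_docking_csp(profile_from_distance_table(
  read_distance_fixture("cmp"), ligand_id = "CMP"), prof)
```

## Structure input and pLDDT

PDB input goes through `bio3d`; mmCIF through a minimal `atom_site`
reader that prefers author (`auth_`) numbering so residue labels match the
published residue names (N247, R252). Altloc handling keeps the
highest-occupancy conformer (ties to the first encountered) — a
single-pose analysis needs one conformer per atom. Hydrogens are parsed
and flagged but excluded from every distance computation: the reference
distances are heavy-atom scale. Residue numbering is author numbering,
verbatim, with insertion codes honoured.

AlphaFold-style files carry per-residue pLDDT in the B-factor column.
`plddt_confidence()` summarises a residue range into the four standard
bands; the source names only the outer bounds (very low < 50, very high
> 90), so the 70 split between "low" and "high" follows the AlphaFold
convention, and the edges are implemented literally: 50 is "low", 70 and
90 are "high", anything above 90 "very high". Only per-residue and
per-region summaries are exposed — how a whole-model docking confidence
would derive from per-residue pLDDT is not defined in the source data, so
the package does not invent one. Values above 100 trigger a warning (they
cannot be pLDDT) but are not rejected.

## Synthetic data: what it emulates and what it does not

`make_toy_complex()` builds poly-alanine-like scaffolds (five idealised
heavy atoms per residue, strung along an axis at 10 Å spacing, PSTD
residue identities at positions 246–255) and places ligand atoms at
prescribed distances. The design guarantees analytic ground truth: all
scaffold z-offsets are ≤ 0 and default placement directions sit in a
narrow cone around +z, so a placed atom is within classification range of
*only* its target residue; coordinates snap to the 0.001 Å PDB grid at
generation so the emitted file, the collision check (no placed atom may
come within 2 Å of a non-target atom) and the truth table describe
identical geometry. The truth table's nearest-residue assignments come
from an exhaustive scan, independent of the cell-list search it is used
to test.

`make_csp_fixture()` emulates the canonical binding-site CSP curve: flat
background, contiguous plateau (default 0.6 × peak over residues
247–255), single peak (default 0.151 ppm at R252). Prescribed CSPs are
split into shift changes as \(\Delta\delta_H = 0.6c\),
\(\Delta\delta_N = 0.8\alpha c\) (a 3-4-5 split), so the combined CSP
recovers the prescription exactly. Noise is truncated Gaussian (clipped
at ±2 sd) and the generator enforces sd < (peak − plateau)/4; together
these make peak recovery certain, not merely probable. Note that
*range* recovery at the 0.5 threshold needs the stricter
sd ≲ (plateau − 0.5·peak)/3 (≈ 0.005 ppm at the defaults); the package's
property tests run at 0.004 ppm, satisfying both.

These generators test geometry and bookkeeping, not chemistry: toy
scaffolds have no realistic stereochemistry, torsions or packing, and CSP
fixtures have no exchange-regime effects, peak overlap or assignment
ambiguity. Passing tests therefore demonstrate correctness of
classification, aggregation and recovery logic — not docking accuracy on
real complexes.

## Transcribed fixtures and known source inconsistencies

`reference_fixtures()` ships the three distance lists and the binding
summary with discrepancy annotations:

* the LMWH list holds 22 distances, but the printed totals say 21 (table)
  and 20 (text, with 14 vs 15 hydrophobic); its printed hotspot count (6)
  disagrees with its own list (7 entries for R252);
* the printed mean distances 4.33 (LMWH) and 4.23 (LFcinB11) do not equal
  the means of the corresponding lists (≈ 4.31 / 4.29); only the CMP mean
  (4.55) is arithmetically consistent;
* the LFcinB11 ligand concentration is reported as both 80 µM and 60 µM
  in different places; the fixtures carry 60 µM and note the alternative.

The package reproduces the self-consistent quantities (CMP counts and
mean; LFcinB11 class counts and hotspot; peak CSPs and ligand ordering)
and asserts — rather than hides — the inconsistent ones: the test suite
checks that the recomputed LMWH mean falls in a 4.25–4.35 sanity band and
*differs* from the printed 4.33.

## Problem sizes and numerical choices

Randomized equivalence tests run 100 structure pairs of up to ~500
atoms; generator-recovery properties run 100 seeds; both complete in
seconds. Bin edges are upper-inclusive half-open intervals, so every
distance in (0, 7] receives exactly one class; `classify_distance()`
rejects non-positive distances rather than silently dropping them. The
Jaccard of two empty residue sets is defined as 0. Zero-contact docking
summaries carry an explicit `empty` flag and compare as "inconsistent"
with a reason code instead of erroring.
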