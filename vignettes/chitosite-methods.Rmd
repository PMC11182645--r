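---
title: "Methods: subsite occupancy, triad conformers, and the two-mechanism pH model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subsite occupancy, triad conformers, and the two-mechanism pH model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chitosite)
```

# The system and the questions

GH18 chitinases hydrolyse the β-1,4 linkages of chitin by substrate-assisted
catalysis: the catalytic glutamate of the DxDxE motif protonates the
glycosidic oxygen bridging the −1 and +1 sugars, the −1 sugar's own
N-acetyl carbonyl attacks the anomeric carbon to form an oxazolinium
intermediate, and water resolves it. The mouse acidic mammalian chitinase
does this efficiently at two very different pH values, which raises two
linked questions this package is built to answer quantitatively:

1. How are oligosaccharide ligands distributed over the cleft's
   sugar-binding subsites, when the crystallographic evidence is a set of
   overlapping alternative conformations with fractional occupancies?
2. How does the protonation machinery of the triad support catalysis both
   when protons are abundant (acid) and scarce (neutral pH)?

# Subsite register and occupancy accounting

Subsites are labelled −n…+n from the non-reducing end, with no 0 site:
−1 and +1 are adjacent across the cleavage point. Two non-canonical
registers are first-class labels: half-integer sites (−3.5, −2.5, −1.5)
midway between canonical sites, occupied by translocation-intermediate
poses, and +1′, a product-binding position displaced above +1 (not a
half-integer: it sits off the cleft axis).

**Frame calibration** (`calibrate_frame`) turns a labelled example model
into a reference frame: integer-site centroids are arithmetic means of the
labelled ring centroids; half-integer centroids missing from the labelling
are synthesised as flanking midpoints (only where both flanks exist, which
is why a frame calibrated from −4…+2 carries three half-integer sites);
+1′ is included only on explicit evidence. Validity checks warn when
consecutive integer centroids are not 4–6 Å apart (the canonical pyranose
step is ~5 Å) or when a half-integer centroid strays more than 1.5 Å from
its flanking midpoint.

**Assignment** (`assign_subsites`) is nearest-centroid with an acceptance
radius `r_max` (default 2.0 Å). The original assignments in this kind of
work are made by eye from difference density; an automated rule needs two
explicit choices the manual procedure never had to state:

* *the radius*: 2.0 Å is half the inter-register spacing (half-integer
  sites are 2.5 Å from their neighbours), so radii cannot overlap
  ambiguously, yet it comfortably absorbs the sub-0.5 Å centroid scatter of
  real refined conformers;
* *the tie rule*: when two centroids are within 0.05 Å in distance, the
  more negative label wins. Any deterministic rule would do; this one keeps
  assignments stable under atom-order and floating-point permutations.

Ring centroids are means of the six pyranose ring atoms. Rings of one
conformer must occupy consecutive registers (a soft check: violations warn,
because partially disordered ligands legitimately skip density).

**Occupancy** (`subsite_occupancy`) is the sum of conformer occupancies
assigned to a subsite. Sums may slightly exceed 1 because overlapping
conformers are refined independently; the flagging tolerance is 0.05, while
the per-residue audit (`occupancy_audit`) uses 1e-6 for hard violations and
1e-3 for within-group occupancy equality, matching the 2-decimal rounding
of deposited models.

# Triad conformers

The central aspartate (D2, Asp138 in mAMCase numbering) toggles between an
*inactive* rotamer hydrogen-bonded to D1 (Asp136) and an *active* rotamer
hydrogen-bonded to E (Glu140). `classify_D2` decides the state per
conformer by carboxylate proximity — the minimum O···O distance to E's
carboxylate versus D1's — rather than by a χ1 cutoff. The orientation *is*
the definition of the state, and a distance criterion transfers unchanged
across chains with slightly different backbones, where a χ1 threshold would
need re-tuning. χ1 (IUPAC sign convention, N–CA–CB–CG) is reported
alongside. Conformers equidistant within 0.05 Å are `ambiguous`, excluded
from the aggregate active occupancy, and warned about.

The torsion–density scan (`torsion_density_scan`) rotates only the CG atom
about the CA–CB axis and interpolates the map trilinearly at each rotated
position (10° steps by default; peaks are circular local maxima above
0.3 σ). Scanning a single atom is a deliberate simplification of the full
published torsion-scan method — it is "Ringer-style", sufficient to detect
rotamer pairs in the synthetic Gaussian maps and in well-resolved
experimental density, but it does not reproduce the original tool's
side-chain-aware sampling.

Cross-chain correlation (`correlate_subsites`) uses OLS slope plus Pearson
r per subsite, a two-sided permutation test on the active-occupancy column
(exhaustive enumeration up to 8 chains, seeded sampling above), and
Benjamini–Hochberg adjustment across the ~10 subsites tested jointly. The
published analysis reports correlation directions without naming a test;
fixing OLS + permutation makes the directions reproducible and exposes the
choices (`n_perm`, seed) explicitly.

# The two-mechanism pH-activity model

The model encodes the verbal mechanism — direct protonation of E from
solution at acidic pH, proton shuttling D1→D2→E near neutral pH — with
Henderson–Hasselbalch fractions `f(pKa, pH) = 1/(1+10^(pH−pKa))`:

* `w_low = f(pKa_E) · f(pKa_D1)` — both E and D1 protonated;
* `w_high = f(pKa_E) · (1 − f(pKa_D1))` — E protonated, D1 deprotonated.

For one pKa pair these weights conserve `w_low + w_high = f(pKa_E)` (the
package computes `w_high` as the complement so the identity holds to
machine precision) and `w_high` is unimodal with its maximum at
`(pKa_D1 + pKa_E)/2`.

**Why the two routes carry separate pKa pairs.** A natural first design
evaluates both weights with a single shared pair and writes
`total = A_low·w_low + A_high·w_high`. That family cannot be bimodal. With
a shared pair, `total = f_E · (A_high + (A_low − A_high)·f_D1)`: when
`A_low ≥ A_high` it is a product of two non-increasing factors, hence
monotone; when `A_high > A_low` an interior bump is possible in principle,
but the rise of the bracket is bounded by `ln10·f_D1(1−f_D1)(ρ−1)/(f_D1+ρ(1−f_D1))`
while the fall of `f_E` at the same pH is `ln10·(1−f_E)`, and the
constraints "global maximum at the acidic boundary" plus "several-fold drop
to the neutral end" force these bounds to cross the wrong way at every
candidate peak. A numerical sweep over the full parameter box (pKas 0–16,
amplitude ratio 10⁻³–10⁴) confirms it: no member has a secondary interior
maximum together with a global acidic one. The resolution is already in
the structural biology: the empirical pKa predictor assigns *different*
triad pKas depending on the D2 conformation (inactive split: Asp136 2.0,
Asp138 13.0, Glu140 7.7; active split: 3.4, 12.4, 6.4), i.e. each
mechanism operates in its own conformational regime with its own effective
constants. `MechanismParams` therefore carries a low-pH pair and a high-pH
pair; `w_low` is evaluated with the former, `w_high` with the latter, and
`total = A_low·w_low + A_high·w_high` pointwise as before.

Default pairs: the low-pH pair uses pKa_D1 = 3.4 (the active-conformation
Asp136 value, which places the acid limb's decay where the direct route
fades) and pKa_E = 7.7; the high-pH pair (5.8, 7.2) is a calibration
choice — the shuttle's *effective* transition constants — set once so the
calibrated profile peaks at pH 6.5, the observed secondary optimum. D2's
own pKa (12.4–13.0) never titrates between pH 2 and 7.4 and does not enter
the weights.

`calibrate_mechanism` solves the 2×2 linear system for the amplitudes given
a fold change (default `total(2.0)/total(7.4) = 6.3`) and a reference
activity. `fit_mechanism` fits five parameters (both amplitudes, both D1
pKas, the high-pair E pKa) by Levenberg–Marquardt with a seeded 5-start
multistart; the low-pair E pKa is held at its initial value because it
multiplies a term that is already negligible wherever it titrates —
freeing it would add an unidentifiable direction to the fit. Optima are
grid local maxima on [2.0, 7.4] at 0.1 steps with boundary points eligible,
since the acidic optimum sits at the boundary of the measurable range.

# Endpoint kinetics

The 4MU-chitobioside assay is an endpoint design: reactions at each pH are
quenched with alkaline glycine at 0/15/30/45/60/90 s, and fluorescence is
read at the quench pH so the fluorophore's pH-dependence cancels. The
pipeline mirrors that arithmetic exactly:

* standard curves are through-origin regressions (slope = Σxy/Σx²) of RFU
  on post-quench 4MU concentration (50…3.125 µM plus blank), one per pH;
* initial rates are through-origin slopes of product vs time per replicate,
  averaged over n = 4;
* Michaelis–Menten fits are unweighted nonlinear least squares without a
  substrate-inhibition term; kcat = Vmax/[E] with [E] = 0.1 µM, and
  catalytic efficiency is kcat/KM (the ratio in this orientation — an
  efficiency must rise with kcat; the occasional inverted formula seen in
  methods sections is treated as a typographical slip);
* wells above a configurable ceiling (default 80 µM) can be excluded via
  `exclude_above_uM` to guard against the product-inhibition regime;
  the default fits everything and instead reports a high-substrate
  residual-trend diagnostic, positive when observed rates fall below the
  hyperbola.

Units are fixed throughout: [S] and KM in µM, rates in µM/s, kcat in 1/s.

# What the generators emulate — and what they do not

Every generator is a pure function of (spec, seed); its manifest records
the exact ground truth, and the repository's core property is that each
pipeline stage recovers its manifest within documented tolerance.

**Structures.** A straight cleft with 5 Å subsite spacing; flat-chair
pyranose templates (hexagon radius 1.45 Å, ±0.25 Å pucker) whose bridging
oxygens close both glycosidic bonds under 1.8 Å; a D2 residue built by
internal-coordinate placement so each rotamer's χ1 is exact; D1/E
carboxylates placed at 2.6 Å from the matching rotamer (6.0 Å when a state
has no conformer). Multi-chain specs replicate the same local geometry per
chain, as NCS-related chains do. Not emulated: real sugar stereochemistry
beyond the anomeric substituent, solvent, crystallographic symmetry, or
refinement noise — so passing tests validate the *accounting*, not a
refinement program.

**Maps.** Sums of per-atom isotropic Gaussians, width σ² = B/(8π²),
amplitude ∝ occupancy × atomic number, σ-scaled. No Fourier truncation
ripples, no solvent flattening; peak detection thresholds tuned on these
maps transfer to experimental maps only qualitatively.

**Trajectories.** A two-state Markov chain on χ1 (default modes −65°/175°,
8° Gaussian jitter, transition probabilities 0.03/0.07 per 10 ps frame)
plus a reflected random walk for the probe distance (bounds 1.5–2.3 Å).
These reproduce dwell statistics and bounded fluctuation, not dynamics.

**Plates.** Product accumulates linearly at the true Michaelis–Menten rate;
RFU noise is multiplicative Gaussian (default 3%). The linear-regime
assumption is audited: the generator warns when implied substrate depletion
exceeds 10% over the 90 s window. The kcat scale (0.1 /s at pH 7.4, hence
0.63 /s at pH 2.0) is a deliberate choice in the plausible range for
fluorogenic chitinase assays, set so worst-case depletion stays at ~7.6%
(pH 2.0, lowest substrate) and the endpoint design remains self-consistent;
KM is log-linear in pH from 30 µM at pH 7.4 to 2.5× that at pH 2.0. The pH
panel is 2.0–7.0 in 0.5 steps plus 7.4. Optional product inhibition
linearly attenuates rates above 80 µM.

# Numerical choices and degenerate inputs

* Dihedrals use the atan2 formulation (stable near 0/180°); the anomer rule
  calls the C1→O1 bond axial when within 45° of the SVD ring normal.
* Map interpolation is trilinear; points outside the grid are hard errors
  rather than extrapolations.
* CCP4/MRC I/O is mode 2 (float32), axis-aligned orthogonal cells only —
  the subset the generators produce.
* Two-state trajectory thresholds default to the minimum-density angle
  between the two dominant 10°-histogram modes, computed per series.
* Michaelis–Menten and mechanism fits run Levenberg–Marquardt with tight
  (1e-14) convergence tolerances so noiseless recovery is exact to 1e-6
  relative; non-convergence is flagged on the result, never thrown.
* Degenerate inputs: a single-conformer D2 duplicates into its matching
  split slot (other slot empty, with a warning); an all-zero kinetic
  profile fits to zero amplitudes; an empty assignment yields an empty
  occupancy table; KM fitted beyond 10× the sampled range is flagged
  poorly determined.

# Problem sizes

The shipped tests and the acceptance script use: 12 pH points × 8 substrate
concentrations × 6 timepoints × 4 replicates per plate cohort; 1000-frame
trajectories at 10 ps spacing; 36-point torsion scans on ~0.4 Å grids;
cohorts of 6–20 chains for the correlation analyses (≤ 8 chains exercises
the exhaustive permutation path, 720–40320 permutations). These sizes make
every stochastic recovery criterion sharp at its stated tolerance while a
full run stays interactive.

# Known limitations

* The pKa predictor is consumed through its `.pka` summary files; the
  package never recomputes electrostatics, and the shipped `.pka` fixtures
  are synthetic stand-ins in the predictor's dialect (labelled as such).
* Sugar recognition is limited to GlcNAc (NAG) and linear β-1,4 chains;
  branched ligands are out of scope.
* The two-mechanism model is a minimal phenomenological encoding of the
  protonation logic: its high-pH pKa pair is an effective calibration, not
  a prediction, and the model says nothing about transglycosylation or the
  oxazolinium chemistry itself (the catalytic cycle enters only through
  protonation-state populations).
* Assignments assume the model and frame share one coordinate system;
  symmetry expansion and cross-crystal superposition are the caller's
  responsibility.
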