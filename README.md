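# chitosite

Analysis toolkit for the structural enzymology of family-18 glycoside
hydrolases (GH18), built around the mouse acidic mammalian chitinase
(mAMCase) catalytic domain. mAMCase is unusual among enzymes: it degrades
chitin efficiently both in the stomach (pH ~2) and in the lung (pH ~7),
with two distinct activity optima rather than one broad one. Understanding
that behaviour requires joining three kinds of evidence that rarely live in
one codebase:

* **multi-conformer crystallography** — oligomeric GlcNAc ligands modelled
  as overlapping alternative conformations with fractional occupancies
  across the sugar-binding subsites of the cleft;
* **catalytic-triad conformational analysis** — the central aspartate of the
  DxDxE motif (Asp136-x-Asp138-x-Glu140) toggles between an *inactive*
  rotamer (toward Asp136) and an *active* rotamer (toward Glu140);
* **pH-dependent enzyme kinetics** — endpoint fluorogenic
  (4MU-chitobioside) plate assays fitted to Michaelis–Menten kinetics at
  each pH.

The package is aimed at structural biologists and enzymologists who want a
tested, scriptable version of this analysis for their own GH18 (or
GH18-like) systems.

## What it computes

**Subsite occupancy accounting.** Sugar-binding positions are labelled
−n…+n (non-reducing → reducing; cleavage between −1 and +1), with
half-integer registers (−3.5, −2.5, −1.5) for translocation-intermediate
poses and a displaced product site +1′ above +1. Rings of each ligand
conformer are assigned to the nearest subsite centroid, and subsite
occupancy is the sum of the occupancies of all conformers assigned there.

**Triad conformer analysis.** Per Asp138 conformer the package reports χ1
(N–CA–CB–CG) and classifies the rotamer *active*/*inactive* by carboxylate
proximity (min O···O distance to Glu140 vs Asp136). A torsion–density scan
samples electron density along the χ1 circle to confirm rotamer pairs, and
cross-chain correlation relates per-subsite occupancy to the active-rotamer
occupancy (OLS slope, Pearson r, exhaustive/seeded permutation p,
Benjamini–Hochberg across subsites).

**Two-mechanism pH-activity model.** The catalytic glutamate must be
protonated to attack the glycosidic oxygen; the proton arrives either
directly from solution (dominant at acidic pH) or by shuttling across the
triad (dominant near neutral pH). With Henderson–Hasselbalch fractions
f(pKa, pH) = 1/(1+10^(pH−pKa)), each route is weighted by its own
conformation-specific pKa pair,

    w_low(pH)  = f(pKa_E_low)  · f(pKa_D1_low)         (direct route)
    w_high(pH) = f(pKa_E_high) · (1 − f(pKa_D1_high))   (shuttle route)
    total(pH)  = A_low · w_low + A_high · w_high

and the fitted total reproduces a bimodal profile: global optimum at
pH 2.0, secondary optimum at pH 6.5. (A single shared pKa pair provably
cannot produce two optima — see the methods vignette.)

**Endpoint kinetics pipeline.** Through-origin standard curves (RFU per µM
4MU), fluorescence→product conversion, through-origin initial rates per
replicate, unweighted Michaelis–Menten fits per pH
(v = Vmax·[S]/(KM+[S]); kcat = Vmax/[E], [E] = 0.1 µM), catalytic
efficiency kcat/KM, and fold changes across pH.

**Synthetic data.** Seeded generators emit every input class with a
ground-truth manifest: multi-conformer mmCIF/PDB active sites, Gaussian-atom
density maps (CCP4/MRC), two-state χ1 jump trajectories (multi-model PDB),
and endpoint plate CSVs whose underlying kcat(pH)/KM(pH) encode the
6.3-fold kcat increase and 2.5-fold KM worsening between pH 7.4 and 2.0.

## Worked example

```r
library(chitosite)

# endpoint plate cohort at the study's assay conditions (pH 2.0-7.4,
# substrate to 117 uM, timepoints 0-90 s, 4 replicates, 3% RFU noise)
cohort <- gen_kinetics_plate(seed = 1)
fits <- fit_plate_kinetics(cohort$plate)
profile <- ph_profile_and_folds(fits)
print(profile)
#> PHKineticProfile: 12 pH points, kcat optimum at pH 2.00
#>  parameter pH_a pH_b    ratio
#>       kcat    2  7.4 6.281769
#>         KM    2  7.4 2.486891
#>         CE    2  7.4 2.525953
print(fits[["2.00"]])
#> MMFit pH 2.00: kcat 0.6324 /s, KM 75.49 uM, kcat/KM 0.008377 /(uM s)

# two-mechanism model fitted to the recovered kcat(pH)
mech <- fit_mechanism(profile$table$pH, profile$table$kcat, seed = 2)
activity_profile(mech$params)$optima
#>    pH     value global
#> 1 2.0 0.6335031   TRUE
#> 2 6.5 0.1867694  FALSE
```

The kcat fold change (6.28 vs the injected 6.3), KM fold (2.49 vs 2.5) and
the two profile optima (pH 2.0 global, pH 6.5 secondary) are recovered from
the raw fluorescence wells.

Structural side, on a synthetic multi-conformer active site:

```r
g <- gen_structure_fixture(seed = 1, dir = NULL)
subsite_occupancy(assign_subsites(g$model, default_subsite_geometry()))
#>   chain subsite occupancy n_conformers  flag
#> 1     A      -3      0.40            1 FALSE
#> 2     A      -2      0.70            2 FALSE
#> 3     A      -1      0.55            2 FALSE
#> 4     A      +1      0.25            1 FALSE
classify_D2(g$model)
#> TriadState (chain A, D2=138): active occupancy 0.550, inactive 0.450
#>  alt chi1   d_to_E  d_to_D1    state occupancy
#>    A  -65 2.600000 6.396872   active      0.55
#>    B  175 5.862903 2.600000 inactive      0.45
```

Two conformers overlap at subsite −2 (0.4 + 0.3 = 0.7), and the Asp138-like
residue splits 0.55/0.45 between its active and inactive rotamers — both
exactly as the generator's manifest prescribes.

A command-line wrapper is installed with the package
(`inst/cli/chitosite.R`): `Rscript $(Rscript -e
'cat(system.file("cli/chitosite.R", package="chitosite"))') --help`.

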