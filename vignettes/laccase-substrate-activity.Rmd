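---
title: "Modelling laccase substrate activity: poses, descriptors and QSAR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling laccase substrate activity: poses, descriptors and QSAR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lacqsar)
```

## The scientific problem

Fungal laccases (EC 1.10.3.2) oxidize a remarkably broad range of phenolic
and related substrates by single-electron transfer at a surface-exposed
mononuclear copper centre, the T1 site. Two questions drive this package:

1. **Which docked substrate conformation is the catalytically relevant
   one?** Electron-transfer rates fall off exponentially with the distance
   between the donor orbital of the substrate and the acceptor orbitals
   around the T1 copper, so only poses that place the expected donor atom
   close to the catalytic histidine (His-458 in *Trametes versicolor*
   laccase numbering, His-454 in the *Cerrena unicolor* enzyme) can account
   for observed turnover.
2. **Which physicochemical properties of a substrate predict its Michaelis
   constant or relative activity?** Small multiple-linear-regression (MLR)
   QSAR models on a handful of interpretable descriptors — ionization
   potential, shape, hydrophobic/hydrophilic surface balance — turn out to
   carry most of the signal.

The package implements the full desk-scale analysis: pose triage by
electron-transfer distance and interaction fingerprints, descriptor
computation, MLR model building with leave-one-out validation, correlation
of activities against externally computed binding-energy tables, and
sequence-level comparison of the two enzymes.

## The active-conformation rule

A pose is called *active* when its designated electron-donor atom lies
**strictly within 5 Å** of the catalytic histidine's Nε hydrogen. Donor
designation is rule-based:

* phenolic substrates donate from the hydroxyl oxygen; when several O–H
  groups exist, the one closest to the histidine is taken;
* amines donate from the primary amine nitrogen;
* for substrates with neither (delocalized donors such as ABTS), the ligand
  heavy atom closest to the histidine is used. This is a deterministic
  surrogate for the visual inspection such substrates otherwise require,
  and it is flagged as class `nearest_heavy` in every output.

The 5 Å threshold is the one substantive geometric parameter; the boundary
is exclusive (a distance of exactly 5.0 Å is inactive), and the
classification is monotone in distance by construction. The remaining
interaction thresholds are declared package conventions, exposed as
arguments with these defaults:

| rule | threshold | note |
|---|---|---|
| hydrogen bond | donor–acceptor ≤ 3.5 Å and D–H···A ≥ 120° | angle applied only when the donor H is present |
| salt bridge | carboxylate O ··· ammonium N ≤ 4.0 Å | N must carry ≥ 3 H or charge > +0.5 e |
| π–π stacking | ring centroids ≤ 5.5 Å | interplanar ≤ 30° = face, 60–90° = edge; 30–60° reported as no contact |
| active pose | donor to Nε-H < 5.0 Å | strict inequality |

When hydrogens are absent from an input structure, H-dependent criteria
degrade gracefully: distances are referenced to Nε itself (flagged in the
output), and hydrogen bonds fall back to the distance criterion alone.
Protonation is never inferred.

```{r pose}
cx <- gen_synthetic_pose(4.2, hbond_geometry = list(distance = 2.8, angle = 165))
fp <- build_fingerprint(cx)
fp
attr(fp, "active_call")
```

## Descriptors

**Surface and shape.** Solvent-accessible surface area uses the
Shrake–Rupley construction on a deterministic Fibonacci point set (default
960 points/atom, probe 1.4 Å, Bondi radii); determinism means every surface
quantity is exactly reproducible without a seed, and doubling the point
count changes the total by well under the declared 0.5 % convergence
tolerance. van der Waals volume is obtained by grid counting (default
0.2 Å spacing; 0.15 Å when sub-0.5 % accuracy is needed). Globularity is
`4πr_eq²/SASA` with `r_eq` the radius of the sphere having the molecular
volume — 1 for a probe-0 sphere, decreasing with elongation — and
`Vol/SASA` is its companion. The hydrophilic component FISA sums the SASA
of N, O and their hydrogens; the π component PISA sums aromatic carbons
and their attached hydrogens (the two atom sets are disjoint, so
FISA + PISA ≤ SASA always).

**Solubility and partitioning.** The logP analogue is an additive
atom-contribution scheme with ten atom types resolvable from elements,
bonds and aromatic flags alone (`lacqsar.clogp.v1`, table documented in
the source); the logS analogue is the published ESOL regression on logP,
molecular weight, rotatable bonds and aromatic proportion. Both are
analogues of the commercial QPlogPo/w and QPlogS descriptors, not
re-implementations; exact agreement with those tools is explicitly not
promised, and each value carries its scheme tag.

**Electrostatics.** ESP extrema are the Coulomb potential of the atomic
point charges evaluated at every accessible surface point (conversion
332.0636 kcal·Å/(mol·e²)). Charges are an *input*: any charge model can be
supplied; `assign_simple_charges()` provides a deliberately crude fixture
model for tests and demos only.

**Electronic structure.** From orbital energies the package applies the
Koopmans approximation — IP = −E(HOMO), EA = −E(LUMO), electronegativity
χ = (IP+EA)/2, hardness η = (IP−EA)/2, chemical potential µ = −χ, gap =
IP − EA — with the hartree→eV constant fixed at 27.2114. A total-energy
(ΔE) route exists for species whose orbital energies are unreliable
(anions); the two routes agree exactly on Koopmans-consistent fixtures.
No quantum chemistry is ever run: energies, like binding free energies
(MMGBSA), solvation energies and experimental oxidation potentials, are
consumed as input columns.

## QSAR methodology

K_m values in µM are converted to molar and expressed as pK_m =
−log₁₀(K_m·10⁻⁶); relative activities are log₁₀-transformed. Descriptors
are z-scored; the training mean/sd pair is stored so external compounds
are always transformed with the *training* population. Models are ordinary
least squares with at most three descriptors — larger models are
deliberately out of reach of these dataset sizes (11–23 compounds).
Leave-one-out Q² = 1 − PRESS/SS_tot is computed exhaustively (via the hat
matrix identity, verified in the tests against a literal n-refit loop);
for leave-one-out, a randomized-complete and an exhaustive scheme
coincide, which is why the package implements the published procedure as
plain exhaustive LOO. `subset_search()` enumerates every subset up to size
3 (≤ 2 625 fits at the 25-descriptor cap) and ranks by Q² or R², breaking
ties toward fewer descriptors, then lexicographic names.

Outlier handling mirrors the published practice but is **never
automatic**: exclusions (an amine in a phenol series, a phosphate with an
extreme K_m) are explicit user flags recorded in model provenance.
`outlier_sensitivity()` quantifies per-point leverage as the change in R²
on removal, flagging |ΔR²| > 0.15 by default.

The seven published models are shipped verbatim as fixed predictors
(`published_model(1:7)`): four log(activity) models for the phenol series
and three pK_m models, including the single-descriptor model
pK_m = 4.43 − 2.93·IP(eV). Their normalization parameters were never
printed, so the package requires a user-declared reference population at
prediction time and labels outputs trend-level, not absolute — absolute
prediction against unpublished internal tables cannot be certified, and
the package does not pretend otherwise.

```{r qsar}
m5 <- published_model(5)
tidy(m5)
glance(m5)
```

## Correlation analysis

`corr_with_p()` reports Pearson R² with a two-sided t-test p-value,
t = r·√((n−2)/(1−r²)) on n−2 degrees of freedom — equivalent to the
simple-regression F-test, which is why the choice between the two is
immaterial and documented as such. The convention is checkable without
raw data: `p_from_r2(0.10, 11)` gives 0.34, `p_from_r2(0.33, 23)` gives
0.004 and `p_from_r2(0.29, 16)` gives 0.03, reproducing the printed
(R², n, p) triples of the reference analysis — that agreement is the
evidence for the convention. `correlation_scan()` applies this per score
column (docking score; binding energies at protein flexibility radii 0–20
Å), dropping unmatched substrates pairwise with a logged count and
flagging the best cell. No multiple-testing correction is applied across
the scan, matching the source methodology.

## Sequence comparison

Global alignment is Needleman–Wunsch with affine gaps via Biostrings
(BLOSUM62, gap open 10 / extend 0.5 — CLUSTALW-like defaults, since the
exact alignment settings behind the reported identity are unknown). Percent
identity divides identities by aligned columns containing at least one
residue; alternative denominators are selectable because the convention
behind the reported 68.3 % TvL/CuL identity is not stated. Hydropathy
profiles are unweighted sliding means of the Kyte–Doolittle scale (window
9, the ProtScale default, configurable); difference regions are maximal
runs where profiles differ by more than 1.0, never merged across
sub-threshold positions.

The package ships a *synthetic* laccase-like sequence pair
(`inst/extdata/synthetic_laccase_pair.fasta`, ~70 % identity by
construction: 30 % substitutions plus short indels) to exercise this
machinery offline; it is a labelled stand-in, not the real TvL/CuL pair,
and conclusions about the real enzymes require the real accessions.

## The synthetic-data generators

Every pipeline input can be simulated, each generator seeded and
deterministic, with the seed recorded in the output attributes:

* `gen_linear_dataset()` plants a ≤ 3-term linear structure (standard-normal
  descriptors, Gaussian noise, independent standard-normal decoys) — the
  statistical skeleton of the published models, used for coefficient
  recovery and subset-search checks.
* `gen_toy_molecule()` builds spheres, pairs, chains, rings and a
  phenol-like molecule, attaching analytic SASA/volume references where
  closed forms exist.
* `gen_synthetic_pose()` constructs a minimal binding site (idealized
  internal coordinates: imidazole with its Nε-H, a carboxylate, a Cu
  marker, optionally a stacking ring) around a phenol-like ligand with the
  donor distance exact to 0.01 Å and the hydrogen-bond geometry exact by
  construction — only relative geometry matters for the detectors.
* `gen_activity_table()` emulates the three study dataset shapes: 11
  diverse TvL substrates with K_m at pH 4.5, 16 TvL substrates (15
  congeneric phenols + 1 amine) with relative activity at pH 9.0, and 23
  diverse CuL substrates with K_m. K_m values are lognormal (meanlog
  log 150 µM, sdlog 1.6, truncated to 1–10 000 µM) — a realistic spread
  for laccase substrate panels, chosen once; no distributional claim about
  the real tables is implied.
* `gen_orbital_table()` emits orbital/total-energy fixtures with
  E(HOMO) < E(LUMO) in every row and totals constructed
  Koopmans-consistently, so the two electronic routes can be
  cross-checked.

What the generators deliberately do **not** emulate: real conformational
ensembles, force-field energetics, realistic protein structure, or any
correlation between a substrate's descriptors and its simulated activity.
Green tests therefore certify the *machinery* — geometry, statistics,
transforms, determinism — not chemical accuracy on real laccase data,
which additionally depends on the external docking/MMGBSA/QM inputs this
package consumes but does not compute.

## Numerical choices and degenerate inputs

* Surface quadrature 960 points/atom (≤ 0.5 % convergence); volume grid
  0.2 Å default, 0.15 Å where 0.5 % accuracy is required; both
  deterministic.
* Leverage-one points in LOO (hat value ≈ 1) are guarded with an ε of
  1e-12 in the PRESS denominator, so degenerate folds yield a very
  negative Q² rather than NaN.
* Constant descriptor columns are a named error in normalization;
  rank-deficient designs are a collinearity error in fitting; subsets that
  fail to fit are dropped from the search rather than poisoning the
  ranking.
* Alternate-location PDB records keep the highest-occupancy conformer
  (ties: first altLoc code), with a message.
* Demo pipeline molecules are schematic (phenol-like cores and toy
  chains/rings with per-substrate size scaling); their descriptor table
  exercises the machinery end-to-end but encodes no real chemistry, and
  its QSAR leaderboard should be read accordingly.
* Problem sizes used by the shipped checks — 200 observations for
  coefficient recovery, 1 000 orbital fixtures, 1 000 random rigid
  transforms, 960-point surfaces — were chosen as comfortably sufficient
  for the tolerances stated above.

## Known limitations

* Docking, MMGBSA, LigPrep protonation enumeration, quantum-chemistry
  engines, homology modelling and molecular dynamics are out of scope by
  design; their outputs are inputs here.
* The logP/logS analogues use a condensed typing scheme; they track the
  commercial descriptors' trends, not their values.
* The exact atom sets behind the commercial FISA/PISA definitions and the
  surface used for the commercial ESP extrema are not public; the
  definitions above are declared conventions.
* For delocalized donors the nearest-heavy-atom rule is a deterministic
  stand-in for expert inspection.
* Absolute predictions from the published models depend on unpublished
  normalization parameters; only trends are supported.
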