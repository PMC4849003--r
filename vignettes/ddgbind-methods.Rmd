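---
title: "Methods: an MM/PBSA-style predictor of binding free energy changes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an MM/PBSA-style predictor of binding free energy changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddgbind)
```

## The problem

A missense mutation at or near a protein–protein interface can strengthen or
weaken the complex. The quantity of interest is the change in binding free
energy,

$$\Delta\Delta G \;=\; \Delta G_\mathrm{bind}(\mathrm{MT}) -
\Delta G_\mathrm{bind}(\mathrm{WT}),$$

in kcal/mol. Our sign convention is fixed and documented rather than
inferred: **positive values mean the mutation weakens binding**. Predicted
changes are useful both for protein engineering and for asking whether a
clinical variant plausibly acts through disrupted binding: variants whose
predicted |ΔΔG| is large are candidates for a binding-mediated disease
mechanism.

## The energy model

`ddgbind` follows the MM/PBSA family of end-point methods. The binding free
energy of a complex AB is decomposed per structure as

$$G \;=\; E_{\mathrm{vdW}} + E_{\mathrm{elec}} + G_{\mathrm{polar}} +
G_{\mathrm{nonpolar}},$$

and the binding value is the difference
$\Delta G_\mathrm{bind} = G(AB) - G(A) - G(B)$ with both partners evaluated
at their bound-state coordinates (the *single-trajectory* convention). With
that convention every intramolecular molecular-mechanics term cancels in the
difference, so the MM part of binding reduces exactly to inter-partner
interactions — a property the test suite asserts against a brute-force
inter-chain pair sum.

The components, all heavy-atom (hydrogens are not modelled; their charge is
absorbed into the bonded heavy atom, united-atom style):

* **van der Waals**: Lennard-Jones 12-6,
  $E = \varepsilon_{ij}[(R_{min,ij}/r)^{12} - 2 (R_{min,ij}/r)^{6}]$, with
  per-element well depths and radii combined by the Lorentz–Berthelot rules.
  Pairs separated by one or two covalent bonds are excluded; 1-4 pairs are
  scaled by 0.5, the common force-field convention.
* **electrostatics**: Coulomb with a distance-dependent dielectric
  $\epsilon(r) = 4r$, i.e. $E = 332.06\, q_i q_j / (4 r^2)$ kcal/mol. The
  growing dielectric stands in for the polarization and solvent screening
  that an explicit-hydrogen, explicit-solvent model would provide.
* **polar solvation**: a Still-style pairwise Generalized Born model,
  $$\Delta G_{pol} = -\tfrac{1}{2}\,332.06\,(1 - 1/80)
  \sum_{i,j} \frac{q_i q_j}{f_{GB}(r_{ij}, a_i, a_j)},\qquad
  f_{GB} = \sqrt{r^2 + a_i a_j e^{-r^2/4a_i a_j}},$$
  with intrinsic Born radii equal to the van der Waals radii. For a single
  ion this is exactly the Born formula, which the tests check to 0.1%.
  A numerical Poisson–Boltzmann solver would be the more rigorous choice
  for the polar term; the component interface is solver-agnostic
  so a PB backend can replace the GB routine without touching anything
  downstream, and GB keeps the package dependency-free and fast at desk
  scale.
* **nonpolar solvation**: $\gamma \cdot SASA + b$ with
  $\gamma = 0.005$ kcal/mol/Å² and $b = 0$ by default, over the heavy-atom
  solvent-accessible surface area.

The prediction is a weighted linear combination of component changes,

$$\Delta\Delta G = \sum_k w_k\,\bigl(\Delta G_{\mathrm{bind},k}^{MT} -
\Delta G_{\mathrm{bind},k}^{WT}\bigr) + w_0 .$$

The default weight vector is **unit weights, zero intercept** — the raw
physics with no empirical calibration. Fitting the weights to an
experimental mutation database is a modelling exercise outside this
package's scope; `weight_vector()` and `read_weights()` accept any fitted
coefficient set, and `register_ddg_feature()` lets auxiliary per-mutation
descriptors (a site-category indicator, a hydrophobicity change, …) enter
the combination, with weight 0 unless a coefficient is supplied. Because
the defaults are uncalibrated, absolute ΔΔG magnitudes from the bundled
physics should be read as rankings, not as quantitative reproductions of
any published predictor's output.

## SASA and interface location

SASA is computed by the Shrake–Rupley method: each atom inflated by a probe
of 1.4 Å (a water molecule) and sampled with a deterministic golden-section
spiral of 960 points by default. 960 points keep the per-residue error well
inside the 2% envelope of a 10,000-point random oracle while staying fast;
the count is a parameter everywhere it matters.

Relative SASA (rSASA) divides a residue's SASA by its fully-exposed
reference value (the theoretical Gly-X-Gly maxima of Tien *et al.* 2013).
The ratio is deliberately not clamped: extended conformers can slightly
exceed 1.

A mutation site is classified from rSASA in the isolated monomer
(rSASA~m~), in the complex (rSASA~c~), and their difference ΔrSASA:

| category | interface | ΔrSASA | rSASA~m~ | rSASA~c~ |
|----------|-----------|--------|----------|----------|
| COR (core) | yes | > 0 | > 25% | < 25% |
| SUP (support) | yes | > 0 | < 25% | < 25% |
| RIM (rim) | yes | > 0 | any | > 25% |
| INT (interior) | no | = 0 | any | < 25% |
| SUR (surface) | no | = 0 | any | > 25% |

Two numerical choices close gaps the tabulated rules leave open. First, the
"ΔrSASA = 0" condition cannot hold exactly in floating point; a tolerance of
ε = 0.005 (half a percent of relative exposure) separates "no burial" from
"buried". Second, a value exactly at the 25% boundary goes to the "< 25%"
branch, a deterministic tie-break. With both rules every admissible
(rSASA~m~, rSASA~c~) pair maps to exactly one category; the suite sweeps a
dense grid over [0,1]² to confirm the partition.

## Mutagenesis and minimization

A point substitution keeps the backbone (N, CA, C, O) fixed and rebuilds the
side chain from ideal internal-coordinate geometry: CB from the tetrahedral
backbone construction, then each heavy atom by bond length / bond angle /
dihedral placement. Candidate conformers come from a small discrete rotamer
library (gauche−/trans/gauche+ for aliphatic χ angles, ±90°-type sets for
aromatics and amides; 1–27 rotamers per residue type) and are scored by soft
steric overlap against the rest of the structure; the lowest-clash rotamer
wins, ties broken by library order so the result is deterministic. A
self-mutation on a complete residue is the identity; residues with missing
heavy side-chain atoms are rebuilt by the same machinery, while a missing
backbone atom is a hard error because minimization needs a complete
backbone.

Minimization is steepest descent with an Armijo backtracking line search on
the nonbonded potential plus harmonic bond restraints (detected covalent
bonds held at their observed lengths, k = 300 kcal/mol/Å²). Backbone atoms
are positionally restrained by default (k = 10 kcal/mol/Å²) so wild type
and mutant relax in comparable frames instead of drifting apart
conformationally — without the restraint the ΔΔG difference would be
dominated by independent backbone drift rather than by the substitution.
Every accepted step strictly lowers the energy, so the returned trace is
monotone non-increasing by construction; defaults are 500 iterations and a
force tolerance of 0.1 kcal/mol/Å. The minimizer is deterministic, so a
fixed input yields byte-identical reports. Note the positional restraints
re-anchor at each call's starting coordinates: re-minimizing a relaxed
structure under the default scheme is *not* a strict fixed point (the
unrestrained scheme is, and the test suite checks it there).

## Benchmarking layer

Calculated (A) vs experimental (B) changes are compared through confusion
counts under five threshold scenarios with cut-offs x ≤ y ≤ z, applied to
the magnitudes a = |A|, b = |B|:

| | tp | tn | fp | fn |
|---|----|----|----|----|
| 1 (x) | a≥x, b≥x | a<x, b<x | a≥x, b<x | a<x, b≥x |
| 2 (x,y) | a≥y, b≥y | a<x, b<x | a≥y, b<x | a<x, b≥y |
| 3 (x,y) | a≥x, b≥y | a<y, b<x | a≥y, b<x | a<x, b≥y |
| 4 (x,y,z) | a≥x, b≥y | a<z, b<y | a≥x, b<y | a<z, b≥y |
| 5 (x,y,z) | a≥y, b≥x | a<y, b<z | a≥y, b<z | a<y, b≥x |

Magnitudes are compared because the case-study protocol explicitly uses an
absolute-value cut-off, and because signed thresholds would make a large
negative experimental change unclassifiable. A true positive additionally
requires sign agreement; a pair whose magnitudes satisfy the tp conditions
with *disagreeing* signs is counted as a false positive (a confident call
in the wrong direction). Predicates are evaluated in the order tp, fp, fn,
tn with first match winning, which resolves the overlapping bottom-limit
regions of scenarios 4 and 5 deterministically. Pairs matching no predicate
form the gray zone: they stay in the database size (the coverage
denominator) but not in the counts — forced by the coverage definition
(tp+tn+fp+fn over all cases). `sign(0)` is treated as positive; this only
affects exact-zero predictions, which fall below every positive cut-off
anyway.

Nine statistics follow: TPR, FNR, TNR, PPV, NPV, accuracy, F1, MCC and
coverage. FNR is computed as fn/(fn+tp), the standard complement of
sensitivity. Zero-denominator statistics return 0 with a flag instead of
raising, so cut-off sweeps over sparse corners never abort.

Regression summaries (`regression_summary()`) report the Pearson R,
intercept and slope of experimental on calculated values, optionally
refitted after removing pairs whose residual exceeds k standard deviations
(the conventional "within 2 SD" variant).

## Case-study protocols

Two clinical variant tables ship with the package: 14 angiogenin variants
mapped on the ribonuclease inhibitor–angiogenin heterocomplex and 18
variants of the homodimeric human liver aldolase, each annotated Disease /
Polymorphism / Unclassified. The discrimination protocol classifies a
variant as large-effect when |ΔΔG| ≥ 1 kcal/mol. The cut-off is inclusive
(≥): the published five-of-twelve disease count for angiogenin includes a
variant at exactly 1.04, and an exclusive reading at a 1.04-adjacent
boundary would be fragile; ≥ is the deterministic choice consistent with
the published counts.

For a homodimer the substitution exists on both chains but the predictor
models single mutations, so the protocol predicts the mutation separately
on chain A and chain B and sums the effects (`sum_chain_effects()`). The
bundled table's printed sums are rounded from unrounded per-chain values;
recomputing the sums from the printed per-chain columns therefore matches
the printed totals only within 0.01 kcal/mol (e.g. printed 1.27 vs
recomputed 1.26 for A150P), which is the tolerance the tests use. The
published validation of the summation against simultaneous double mutants
(RMSD ≈ 0.3 kcal/mol) cannot be recomputed here — it requires the original
fitted predictor — and is recorded as documentation only.

## The synthetic-data generator

`make_synthetic_complex()` builds two ideal α-helices (φ = −57°, ψ = −47°,
ω = 180°) with side chains from the rotamer machinery, aligns each with the
z axis and places the second chain at a chosen perpendicular axis-to-axis
separation, rotated half a turn so the faces meet. The helical template is
the simplest generator with a tunable buried surface: at ≤ 8 Å separation
residues bury and classify as interface, at ≥ 50 Å nothing does.
`make_prediction_pairs()` draws calculated values from a centred normal
(SD 1.5 kcal/mol, a typical spread for mutation effect sizes) and adds
Gaussian noise scaled as $\sigma\sqrt{1/r^2 - 1}$ to hit a target
correlation; the default target of 0.62 mirrors the performance level a
calibrated structure-based predictor reaches on large mutation benchmarks.
Both generators are deterministic per seed, and the pair generator restores
the caller's RNG state.

What the synthetic data does *not* emulate: real interface packing and
shape complementarity, loops and β-structure, buried waters, ions and
cofactors, experimental coordinate error, and any correlation structure
between mutation site and effect size. Passing tests on synthetic
complexes therefore validate the machinery (geometry, energies,
classification, bookkeeping), not predictive accuracy on real complexes —
the latter would require the external benchmark sets and a calibrated
weight vector, both out of scope.

## Problem sizes and other choices

The test suite and the acceptance script run on complexes of 6–20 residues
(40–160 heavy atoms), 150–4000 minimizer iterations, 240–960 sphere points
and 10³ synthetic pairs; at these sizes the whole suite completes in well
under a minute. These scales were chosen as the smallest at which every
asserted property is non-trivially exercised (e.g. an actual buried
interface exists at 6 Å separation).

Other conventions: PDB input keeps author chain IDs, residue numbers and
insertion codes; alternate locations resolve to the highest occupancy (ties
by altloc letter); HETATM records and waters are excluded from the energy
model but retained in a side store; selenomethionine maps to MET; only the
first NMR model is read. Parsing and column-exact writing are delegated to
`bio3d`, with this package's policy layered on top.

## Known limitations

* The default unit-weight ΔΔG is an uncalibrated physics score; its
  absolute scale is not comparable to regression-trained predictors.
* Generalized Born with intrinsic (non-integrated) Born radii
  underestimates descreening in deeply buried environments; a PB solver
  would refine the polar term.
* The rotamer library is coarse (no backbone-dependence, no off-rotamer
  minimization), so tightly packed mutation sites can receive a strained
  conformer that minimization must relax.
* Steepest descent converges slowly near flat minima; the backbone
  restraints keep this from affecting WT/MT comparability, but unrestrained
  minimization to tight tolerances is expensive.
* Single point mutations only; multi-site effects are handled only through
  the additive homodimer protocol, which assumes no coupling between sites.
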