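---
title: "Designing and analyzing metal-responsive enzyme switches"
author: "bpyswitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and analyzing metal-responsive enzyme switches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpyswitch)
```

## The problem

A conformational enzyme switch is built by genetically encoding a pair of
bipyridinylalanine (BpyAla) residues at positions chosen so that a
divalent metal ion can bridge the two bipyridine side chains —
an M(BpyAla)₂ bis-bidentate complex — and thereby staple together two
domains that must move apart during catalysis. With the metal bound, the
enzyme is trapped in one conformation and inactive (or, at some sites,
activated); adding a stronger chelator such as EDTA strips the metal and
restores activity. Two computational tasks surround the wet-lab work, and
this package implements both: choosing where to put the BpyAla pair, and
analyzing the high-throughput kinetic screens and steady-state assays
that characterize the resulting variants.

## Site-pair design

### Geometric reference and distance window

The Cβ atom is the anchor point of the side chain, so candidate pairs are
screened on Cβ–Cβ distances. Analysis of a Zn(Bpy)₂ crystal structure
places the two ligand attachment points 10.5 ± 0.5 Å apart when the
complex is formed; the screen itself uses a wider 9.5–11.5 Å window to
allow for side-chain flexibility. `design_config()` expresses both as
`distance_center` ± `distance_halfwidth` and defaults to the screening
window (halfwidth 1.0 Å); the tighter crystallographic constraint is one
argument away (`distance_halfwidth = 0.5`).

### The four selection criteria

`select_pairs()` keeps a pair when, and only when:

1. its closed-state Cβ–Cβ distance lies inside the window (the complex
   must be able to form in the state being trapped);
2. both residues are solvent exposed — relative SASA at least
   `min_relative_sasa` (default 0.20, a common surface-residue
   convention) in the closed state, since buried side chains cannot
   chelate;
3. the distance changes by at least `min_delta_distance` (default
   2.0 Å) between states, so the cross-link cannot form in the open
   state; and
4. the two residues sit on different user-declared domains, so the
   staple spans the functional hinge.

Survivors are ranked by descending |d_open − d_closed|; ties are broken
lexicographically by residue identifier so the output is deterministic.
The signed change d_open − d_closed is reported alongside, because the
literature does not fix whether "change in distance" is signed; the
absolute value is used for ranking here, which also admits pairs that
close upon opening.

Several design points were genuinely open and were resolved as follows.
Exposure is assessed in the closed state only (the state in which the
complex must form); requiring both states is available via
`sasa_both_states`. When a state label carries several frames (snapshots
standing in for an MD trajectory), frame-averaged distance matrices are
used — single representative structures and frame averages are both
supported because published screens do not always say which was used.
No exposure metric or cutoff is standard in this setting; Shrake–Rupley
with a 1.4 Å probe and a 0.20 relative-SASA floor are explicit,
configurable defaults rather than claims about any particular published
pair list.

### Solvent accessibility

`shrake_rupley_sasa()` implements the classic rolling-probe point count:
each heavy atom is inflated by the probe radius, `n_points` (default
960) quasi-uniform points are placed on the inflated sphere with a
Fibonacci lattice, and the accessible fraction scales the sphere area.
Bondi van der Waals radii are used; hydrogens are ignored. The estimator
is exact for isolated atoms at any sampling density (every point is
accessible) and converges as 1/√n for occluded geometries; at 960 points
two-sphere test cases agree with the analytic spherical-cap area to
better than 2%. Relative SASA divides by the residue type's maximum
exposure in a Gly-X-Gly tripeptide (theoretical values of Tien et al.
2013); values above 1 can occur for distorted geometry and are reported
as-is.

### C-beta bookkeeping

Glycine has no Cβ; a virtual Cβ is reconstructed from N/CA/C with ideal
tetrahedral geometry (1.522 Å bond, 109.5° angles, L-chirality) so that
every position stays eligible for design. Residues missing backbone
atoms fall back to CA; residues with neither CA nor CB are dropped with
a warning. Alternate locations keep the highest-occupancy conformer
(ties: first encountered); insertion codes are rejected rather than
silently renumbered, because downstream outputs use author numbering
verbatim.

## Plate-screen analysis

The screen reads two CSVs: a raw table (`time_s` plus one column per
well) and a descriptor annotating each well (variant, metal,
concentration in µM, EDTA flag, replicate, blank flag). Rates are
extracted exactly as a screening script would: an ordinary
least-squares line over every contiguous window of five timepoints, with
the maximum slope (earliest window on ties) taken as the reaction rate.
Regression uses the actual time values, so uneven sampling is handled
correctly. Saturated trailing points (default ceiling 3.5 AU) are
trimmed first, since slopes on a detector plateau are meaningless, and
non-finite points are dropped pairwise. Slopes are stored per second and
reported per minute.

Replicates are summarized by mean and sample standard deviation (n−1;
zero for singletons). Dose–response classification is deliberately
simple and mirrors screening practice: a variant is **inactive** when
its apo (0 metal) rate falls below an activity floor (5% of a supplied
wild-type reference, or an absolute floor when no reference exists —
the floor is configurable because "displayed activity" is a qualitative
call); otherwise **inhibited** when the rate at the highest metal
concentration drops below 50% of the apo rate, **activated** when it
exceeds 150%, and **unresponsive** in between. Classification is
invariant to uniform rescaling of a variant's rates. Reversibility is
the fractional recovery (rate_after_EDTA − rate_metal) / (rate_apo −
rate_metal): 1 for full reversal, 0 for Fe(II)-like irreversibility,
undefined (flagged) for non-responders where the denominator vanishes.
Optional per-plate blank correction subtracts the mean blank-well slope;
it is off by default but recommended whenever blank wells are present,
because the maximum-over-windows estimator has a small positive bias
under noise that blanks share and therefore cancel.

## Steady-state kinetics

Absorbance slopes convert to molar rates through Beer–Lambert with the
p-nitroaniline extinction coefficient ε₄₁₀ = 7,126 M⁻¹cm⁻¹ (default,
overridable) and the cuvette path length.

`fit_michaelis_menten()` fits v = V·S/(K_M + S) by Levenberg–Marquardt
(`minpack.lm::nls.lm`) with deterministic multi-start initialization:
V starts at the maximal observed rate, K_M at the interpolated
half-saturation concentration, perturbed over a log-spaced factor grid
{0.1, 0.3, 1, 3, 10}; the lowest weighted RSS wins. Standard errors come
from the converged Jacobian, σ²(JᵀJ)⁻¹; a parameter pinned at a box
bound gets NA because the Wald approximation is invalid there. k_cat =
V/[E] is reported when the enzyme concentration is given. K_M is flagged
indeterminate when the fit runs past 10× the highest tested substrate
concentration or its confidence interval spans more than two orders of
magnitude — the honest report when saturation lies beyond the substrate
solubility limit.

`fit_substrate_inhibition()` uses the canonical uncompetitive form
v = V·S/(K_M + S(1 + S/K_i)), chosen because it nests Michaelis–Menten
(K_i → ∞), is standard, and has the closed-form optimum S* = √(K_M·K_i)
that doubles as an independent test oracle. Both models are fitted and
compared by corrected AIC (k counts the error variance). Weighting
options are none (OLS), 1/sd², or `relative` (1/rate², the constant-CV
error model of optical assays). The relative scheme matters for model
comparison: under multiplicative noise, unweighted RSS is dominated by
the plateau points, and a chance downward tilt among them lets the
inhibition term "improve" the fit spuriously in roughly one trial in
ten; with correct weights AICc keeps the simpler model in ≥ 95% of
trials. Weights are folded into the residuals (√w·(v − f)) rather than
passed to the optimizer's weights argument, which is numerically
fragile at RLU scales.

Switching series (alternating metal/chelator rounds) are normalized so
the highest relative rate is 1; the dynamic range is the mean of on-round
relative rates over the mean of off-round ones (arithmetic means of
normalized rates; a geometric-mean variant would weight rounds
multiplicatively and is not the convention followed here), with an
infinite-range flag when all off rounds are zero, and an OLS trend slope
of on-round rates versus round index as a degradation check.

## Synthetic data: what it emulates, and what it does not

The generators define the test conditions for the whole package.

**Hinge toys** (`make_hinge_toy()`) build two rigid poly-alanine
pseudo-domains of packed, well-separated residues (explicit CB atoms, so
no virtual-Cβ logic is exercised unless requested). Domain B is related
between states by a rotation about a distant hinge axis
(`hinge_radius`, default 60 Å), which approximates a translation and
guarantees that the planted cross-domain pairs — constructed at exact
closed-state target distances along the inter-domain axis — move apart
on opening. The generator emits a ground-truth table of every pairwise
distance in both states, computed from in-memory coordinates before PDB
serialization (which rounds to 3 decimals, hence "printed precision"
≈ 2×10⁻³ Å on distances). Equal open and closed hinge angles give the
degenerate no-motion control.

**Plates** (`simulate_plate()`) give each variant a phenotype and drive
its rate with a Hill occupancy θ = c^h/(EC50^h + c^h); h defaults to 2,
motivated by the 2:1 bipyridine:metal stoichiometry of the intended
cross-link. Inhibited variants fall to a residual fraction (default
0.05) at saturating metal, activated ones gain a configurable fraction,
inactive ones have rate exactly 0 (dead protein), and EDTA wells revert
to the apo rate unless the binding is declared irreversible. Signals are
linear absorbance ramps, baseline 0.05 AU, apo rate 0.02 AU/min, with
7 reads 600 s apart — long-interval reads appropriate for a slow,
thermostable enzyme followed over an hour, and deliberately few: with a
five-point regression window, slope information per window scales with
the read spacing, so sparse sampling is what makes rates resolvable at
the noise levels the tests probe (Gaussian noise up to 5% of the total
signal rise). Within those conditions the pipeline recovers planted
phenotypes exactly without noise and ≥95% of labels at 5% noise across
50 seeds.

What the simulations do **not** emulate: real MD conformational
ensembles (rigid-body hinges only — consequently the package cannot and
does not reproduce any published pair list for a real protein), lysate
matrix effects, pipetting errors, flash-glow luminescence kinetics,
temperature dependence, or metal-buffer thermodynamics. Passing tests
demonstrate that the algorithms are implemented correctly under
controlled conditions, not that any particular biological screen will
behave as cleanly.

## Numerical choices and limitations

* Distances are Å throughout; no unit options.
* All generators are bit-reproducible given a seed; every stochastic
  test fixes one.
* Fit tolerances are tight (ftol = ptol = 10⁻¹⁵) so noiseless
  round-trips recover generating parameters to ~10⁻⁶ relative; this is
  a regression guard on the optimizer plumbing, not a claim about
  experimental precision.
* Problem sizes in the test suite (hinge toys of ~40–200 residues,
  27-variant plates, 50–100 seeded replicates per property) were chosen
  as the smallest sizes at which the statistical properties under test
  are meaningful.
* The exhaustive O(n²) pair filter is fine for single proteins
  (a 616-residue protein has 189,420 pairs); no spatial indexing is
  attempted.
* mmCIF and trajectory formats are out of scope: convert frames to
  multi-model PDB first. Insertion codes are rejected.
* The SASA implementation is plain R; ~2 s for a 1,000-atom structure
  at 960 points. Reduce `sasa_points` for quick scans.
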