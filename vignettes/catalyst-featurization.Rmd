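---
title: "Precatalyst featurization and domain-transfer benchmarking: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Precatalyst featurization and domain-transfer benchmarking: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chiralcat)
```

This vignette is the package's own account of its science: the models and
conventions behind each stage, the tunable parameters and why their
defaults are what they are, what the synthetic-data generators do and do
not emulate, and the numerical choices a maintainer would want written
down. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The system and the pipeline

The species featurized is the cationic square-planar precatalyst
`[Rh(L)(NBD)]+`: a chiral, usually bidentate P/N-donor ligand L and the
rigid norbornadiene (NBD) diene occupying the remaining two coordination
sites. The pipeline is

1. read the optimized geometry (XYZ) and the electronic *sidecars* (JSON
   files with the HOMO-LUMO gap, NBO charges and donor lone-pair
   occupancies, for the complex and for the free ligand) — the package
   ingests electronic-structure results, it never runs quantum chemistry;
2. perceive bonds, partition the complex into metal / ligand / auxiliary
   diene, label the donors;
3. compute the fixed 34-descriptor vector and, for substrates, the
   18-feature olefin fingerprint;
4. feed descriptor tables into the random-forest benchmark or the PCA
   chemical-space maps.

**Indexing convention.** Atom indices are 1-based everywhere, including
sidecar keys. A cross-language serialization might prefer 0-based; in an
R package a mixed convention would be a permanent source of off-by-one
errors, so the package uses R's native indexing and validates it at every
boundary.

**XYZ dialect.** Standard XYZ with one extension: the comment line may
carry `charge=<int>` (so `+1` survives a round trip while the file stays
readable by any other tool). Coordinates are written with 8 decimals;
round trips are exact to well below 1e-6 Å.

## 2. Bond perception and partitioning

Atoms i, j are bonded iff `d(i,j) <= 1.20 * (r_cov(i) + r_cov(j))`, with
single-bond covalent radii shipped as a CSV (`element_radii()`). The 1.20
multiplier is the common tolerance for optimized geometries; it accepts
Rh-P (~2.3 Å vs. cutoff 2.99 Å) and Rh-olefin contacts while rejecting
second-sphere distances.

After deleting the metal, every connected component bonded to the metal is
classified: components carrying a P or N atom within the metal-donor
cutoff (2.8 Å, generous for Rh-P/Rh-N) are ligand; the component whose
heavy atoms are all carbon is the auxiliary diene; anything else is an
error — the package fails loudly on unexpected topologies rather than
guessing. If the ligand fragments into several donor components (two
monophosphines), their union is taken and a message is emitted.

Donor labels follow partial charge: `max_donor` is the most positively
charged donor by complex-context NBO charge, `min_donor` the least; exact
ties resolve to the smaller atom index (deterministic, permutation-stable
up to that documented rule). A monodentate ligand fills both roles with
its single donor, with a message.

## 3. Steric descriptors

One radii convention serves all steric code: Bondi-type van der Waals
radii scaled by **1.17**, the dominant community convention for percent
buried volume; hydrogens are included by default.

**Percent buried volume.** `%Vbur = 100 * V(sphere ∩ ∪ atom spheres) /
V(sphere)`, computed on a cubic voxel grid of default spacing **0.05 Å**
over probe spheres of **3.5 / 4.5 / 6.0 Å**. The grid is half-offset so no
voxel centre lies exactly on a frame plane; this makes quadrant sums exact
under reflection and avoids boundary double-counting. Oracles: the
closed-form single-sphere ratio `100 (r/R)^3` and a 1e6-point Monte-Carlo
rejection sampler agree within 0.5%; rotation of the whole structure
moves values by at most ~0.3 (grid jitter).

**Quadrant resolution.** The frame is anchored on the complex: +z from the
metal toward the donor midpoint, the xz half-plane through the max donor.
The mean of the four quadrant percentages equals the total within grid
tolerance (a conservation check in the tests). Because the frame is
handed, a mirror-image complex *permutes* the quadrants (x+y+ ↔ x+y-,
x-y+ ↔ x-y-) rather than fixing them — the covariant behaviour asserted
in the tests; all unhanded descriptors are reflection-invariant and only
the signed dihedral G3 changes sign.

**Exact cone angle.** The minimal apex angle of a cone at the metal
containing every scaled van der Waals sphere: for axis u the required
half-angle is `max_i [ angle(u, v_i) + asin(r_i / d_i) ]`, minimized over
axis directions by a 4096-point Fibonacci-sphere scan (plus the atom
directions themselves) followed by Nelder-Mead refinement from the five
best starts. The optimizer reproduces the one-atom closed form
`2 asin(r/d)` and a 1e6-direction brute-force scan to well under 0.1°. An
atom sphere engulfing the apex is an error ("cone undefined").

**Sterimol.** All lengths are measured from the attachment atom along the
axis attach→first, with the same scaled radii: L is the maximal axial
extent (projection + radius), B5 the maximal perpendicular extent, B1 the
minimal supporting-half-plane width over a 0.1° rotational scan (3600
directions). A 36000-direction brute force agrees within 0.01 Å.

**Donor-centred spheres.** For spheres centred *on an atom* (S12-S15 and
the substrate fingerprint) the centre atom itself is excluded from the
occupying set, so the value measures the crowding of the *environment*
around that position rather than the trivially present central sphere.

## 4. The 34-descriptor schema

The schema (S1-S15 / G1-G8 / E1-E11, `catalyst_schema()`) is frozen as a
registry so feature matrices are reproducible. The category counts
(15 steric, 8 geometric, 11 electronic) and five anchored members are
fixed points of the design: S15 = min-donor-centred buried volume,
G4 = metal-min-donor distance, E5 = metal NBO charge, E7 = free-ligand
min-donor lone-pair occupancy, E10 = free-ligand max-donor NBO charge.
Around those anchors the steric block is a centre x radius design
(metal / donor midpoint / max donor at 3.5, 4.5, 6.0 Å, four quadrants,
one H-excluded value), the geometric block the bite angle, cone angle,
diene dihedral and five framework distances, and the electronic block the
six complex-context and five free-ligand values. The package does **not**
re-run the historical redundancy pruning that produced a 34-descriptor
set from a larger pool: that pruning mixed dataset correlations with
expert judgment and cannot be mechanized faithfully; a frozen documented
schema is what reproducibility requires.

The diene dihedral (G3) is the signed four-point dihedral
min-donor — metal — midpoint1 — midpoint2, the midpoints being the two
auxiliary C-C bonded pairs nearest the metal (the metal-facing olefins),
with the standard praxeolitic sign convention; it is the only
chirality-sensitive scalar in the schema.

## 5. Substrate fingerprints

`locate_olefin()` finds the reactive C=C geometrically: bonded carbon
pairs with length ≤ 1.42 Å, at most three neighbours per carbon, and the
bond not inside a ring (which excludes aromatic bonds but also means
ring-internal olefins need the explicit `hint`). Structures embedded from
SMILES carry the perceived double bond as an attribute, which serves as
the hint automatically. Substituent anchors are ordered canonically per
carbon — descending atomic number, ties by ascending index; hydrogens
count as substituents.

The 18 features are six buried volumes (3.5 Å spheres on C1, C2, R1-R4;
whole molecule minus the centre atom) and sterimol B1/B5/L for the four
C-R pairings, the sterimol subset being the branch reachable from R
without crossing its olefin carbon — which isolates exactly the
substituent the pairing names.

`embed_from_smiles()` produces one deterministic conformer per seed
(ETKDG distance geometry + MMFF relaxation via the bundled rdkit helper).
Descriptor values from an embedded conformer deliberately differ from
those of a quantum-chemistry geometry of the same molecule; the two are
distinct substrate representations (`dft_fp` vs. `smiles_fp`) in the
benchmark.

## 6. Synthetic data: what it emulates, and what it does not

The generators exist so the whole pipeline is buildable and testable
without DFT or a proprietary screen. Their defaults *are* the study
conditions.

**Geometries.** `generate_complex_fixture()` builds toy complexes — Rh at
the origin, donors at 2.30 Å realizing the requested bite angle
(feasible range 60-140°), an ethylene backbone and alkyl arms with
element-appropriate bond lengths, and a rigid C7H8 cage bonded trans to
the donors with both olefin midpoints facing the metal. Bookkeeping
records the true atom roles, so partitioning has a known ground truth.
Chemical realism is explicitly not a goal; geometric validity for the
descriptor code is.

**Descriptor tables.** `generate_descriptor_table()` draws each category
from its own latent factor plus independent noise. The factor loading
(default 0.70) is calibrated so the *global* variance structure matches
what real catalyst descriptor sets show — the first two principal
components explaining ~37-40% of the variance — while per-category first
components still recover their generating factors with |r| > 0.9 (the
planted-factor test for the PCA cross sections).

**Outcomes.** `generate_outcomes()` draws the full 3552-well design. Each
ligand has a selectivity skill and an activity level; each substrate
mixes the shared factor with an idiosyncratic one:
`u_ls = λ_s z_l + sqrt(1 - λ_s²) ε_ls`. The default loadings solve the
published pairwise rank correlations (ΔΔG‡: 0.82 / 0.83 / 0.80 for
SM1-SM2 / SM1-SM3 / SM2-SM3; conversion: 0.59 / 0.77 / 0.65), giving
λ = (0.923, 0.889, 0.900) for selectivity and (0.836, 0.706, 0.921) for
conversion, with λ = 0 for SM4/SM5. ΔΔG‡ is scaled (5 kJ/mol for SM1-SM3,
2 kJ/mol with a +1 offset for SM4/SM5) and clipped to the published
ranges (−15..15 and −5..7 kJ/mol); per-well replicate noise is applied on
the ΔΔG scale *before* clipping (0.1 kJ/mol), because additive ee-scale
noise near |ee| ≈ 1 would blow up the back-transformed free energies.
Conversion is a steep logistic of the activity latent
(`plogis(4 (a + 0.7))`) plus noise (sd 0.03), which produces the bimodal,
high-skewed distribution with ≈60% of wells above the 0.8 threshold. In
`descriptor_driven` mode the shared factors are sparse ±1 linear
combinations of five descriptor columns, so descriptors carry genuine
signal; in `identity_driven` mode they carry none.

Each generator mixes the user seed with a per-generator tag before
seeding the RNG. This keeps every generator individually deterministic
while guaranteeing that a descriptor table and an outcome table built
from the same user seed are statistically independent — without it the
two generators would read the same random stream and silently correlate.

**Not emulated:** solvent, pressure and time effects on outcomes
(conditions only select design rows), plate or batch effects,
conformational ensembles, and any mechanistic link between toy geometry
and toy outcome. Passing tests on this data therefore validate the
*machinery* — featurization, splits, metrics, the statistical signatures
of the benchmark — not chemical predictivity on real screens, whose
published accuracies require the real dataset.

## 7. The benchmark

**Targets.** Conversion is classified (threshold 0.8 out-of-domain — the
published balance point; per-substrate median in-domain) and
enantioselectivity is regressed as ΔΔG‡ computed at each well's
temperature.

**Cases and splits.** Seven out-of-domain cases contrast correlated and
uncorrelated training substrates. Fully out-of-domain trains on all
training-substrate wells and tests on every target well; partially
out-of-domain moves a seed-deterministic random half of the target
catalysts into training; in-domain splits catalysts 80:20 with the floor
rule on the training side (192 catalysts → 153 train, 39 test). No
target-substrate catalyst ever appears on both sides — asserted on every
run. The enumerated grids are 168 fully out-of-domain models (7 cases x 2
targets x 3 ligand representations x 4 substrate representations), 504
partially out-of-domain (x 3 split seeds) and 90 in-domain (5 substrates
x 3 ligand representations x 2 targets x 3 seeds), with random-descriptor
controls enumerated separately.

**Learner.** ranger random forests with impurity (Gini) importances
normalized to sum 1. The default tuning grid — trees {100, 300}, depth
{3, 5, 10}, minimum node size {1, 3}, 5-fold CV scored by the reported
metric — is small, standard and config-overridable; one-hot features use
unbounded depth (nodes expand until leaves are pure), because a depth cap
is a specific bottleneck for indicator features. Untuned runs
(`tune = FALSE`) use 300 trees, the deepest gridded depth and minimal
leaves. Perfectly correlated duplicate columns split their importance
between them — a documented, tested property of impurity importances
worth remembering when reading importance plots.

**Monte-Carlo subset study.** For catalyst fractions 0.9 down to 0.1,
`n_splits` random subsets are drawn, each split 80:20 and fit with a
fixed 100-tree forest (untuned by design — the study measures score
inflation, not model quality). Membership logs plus the seed reproduce
every split exactly. On null-signal data the maximum test R² at the 10%
fraction (test sets of ~4 catalysts) far exceeds the median at 90% — the
chance-correlation trap on tiny test sets that motivates the study.

**Problem sizes.** The test suite and acceptance script run the full
192-ligand screen for enumeration, correlation and Monte-Carlo checks
(1000 splits per fraction), five replicate screens for the
domain-transfer and random-descriptor deltas, and three for the planted
signal recovery; geometry oracles use 1e6 Monte-Carlo points and 1e6
brute-force directions. These sizes are the package's chosen trade-off
between statistical stability of stochastic checks and a test suite that
stays pleasant to run.

## 8. Known limitations

- Bond perception is a pure distance rule: no haptic-bond model beyond
  the metal-donor cutoff, no multi-metal complexes.
- The olefin locator needs a hint for ring-internal or multiple C=C
  sites; aromatic carbons are excluded by the ring test, not by
  electronic structure.
- Quadrant descriptors depend on the documented frame; comparing
  enantiomers requires the quadrant permutation noted above.
- Circular fingerprints and SMILES embedding run through an external
  rdkit helper; without a python+rdkit on the PATH those two encoders
  (only) are unavailable.
- The synthetic outcome model is a statistical emulator, not a chemical
  one; see section 6 for exactly what that implies about test evidence.
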