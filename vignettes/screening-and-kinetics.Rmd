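---
title: "Pharmacophore screening and inhibition kinetics with phorekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pharmacophore screening and inhibition kinetics with phorekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phorekit)
```

`phorekit` implements a ligand-based virtual-screening funnel around a
five-point 3D pharmacophore, plus the enzyme-kinetics analyses used to
characterise screening hits. This vignette is the package's account of the
underlying models, the choices that were genuinely open, and what the tests
do and do not demonstrate.

## The pharmacophore model

The query (`canonical_query()`) describes a peptide–p38α interaction at an
allosteric site as five labelled spheres in the crystallographic frame of
the complex: P1/P2 hydrophobic–aromatic (radius 1.5 Å), P3/P4 hydrogen-bond
acceptors and P5 a donor (radius 1.2 Å). The radii are tolerance spheres: a
conformer fulfils the query if some injective, kind-compatible assignment of
its features to the points exists such that after rigid least-squares
superposition each assigned feature lies inside its point's sphere.
Acceptance is therefore *per point*, not an aggregate RMSD threshold — a
conformer with four perfect features and one outside its sphere fails.

```{r}
canonical_query()
round(interpoint_distances(canonical_query()), 2)
```

### Feature perception

Perception (`perceive_features()`) is topology-plus-geometry and
deliberately simple; the scheme used by the original commercial screen is
proprietary, so these rules are this package's documented stand-in:

* *hydrophobic/aromatic*: the centroid of each smallest ring whose atoms are
  all aromatic (explicit aromatic bond flags honoured, otherwise an
  even-membered single/double alternation test), plus the centroid of each
  maximal patch of ≥ 3 aliphatic carbons with only carbon heavy neighbours;
* *acceptor*: N or O with an available lone pair and non-positive formal
  charge (ether and carbonyl oxygens, pyridine-type ring nitrogens);
* *donor*: N or O bearing at least one hydrogen (implicit hydrogens from a
  standard charge-adjusted valence model count, so conformer libraries
  without explicit hydrogens work), plus aliphatic amine nitrogens.

The last clause is the package's single protonation heuristic: an aliphatic
amine (pKa ≈ 10–11) is treated as protonated at assay pH, which makes it a
donor and a cation and suppresses its acceptor role. No pKa calculation is
attempted; conjugated nitrogens (anilines, amides) are excluded from the
rule by a neighbour check. Donor geometry is handled at the match level by
the sphere tolerance, so hydrogen coordinates are never required.

### Matching

`match_conformer()` enumerates assignments depth-first in query-point order.
A partial assignment dies as soon as one feature-pair distance deviates from
the corresponding center-pair distance by more than the sum of the two radii
— a rigid motion can change neither distance, so by the triangle inequality
no completion could place both features inside their spheres. This pruning
is what keeps exhaustive search cheap, and the test suite proves it exact by
comparing against an unpruned brute-force matcher (with an independent
superposition routine from `bio3d`) on hundreds of random feature sets.

Superposition is the closed-form SVD solution with a determinant guard
(reflections rejected). Among accepted assignments the minimal-RMSD one is
returned; exact ties resolve lexicographically (point order, then feature
index), which is simply the first one visited.

## Pose placement, refinement, scoring

Matched conformers are rigidly placed into the site frame by their match
transform. The original workflow refined poses by force-field minimisation
inside the protein; `phorekit` replaces this with a bounded rigid local
search (by default 8 seeded perturbations of up to 0.3 Å / 5° about the pose
centroid, keeping the least-clashing variant) followed by the same two
checks the original applied: discard poses that clash with the receptor
cloud (any ligand heavy atom within 2.0 Å of a receptor atom) and poses that
no longer fulfil the pharmacophore *in place* (no further superposition).
This preserves the funnel's observable behaviour — refined poses that break
the hypothesis are discarded — at desk scale, without any force field.

The pose score is a deterministic stand-in for an empirical docking score:
contact pairs within 4.5 Å, plus 2 per satisfied polar query point, minus 10
per clash. It is not an energy; it exists to rank poses reproducibly and to
drive representative selection. All cutoffs (2.0, 4.5 Å) are arguments.

## Diversity analysis

`tat_fingerprint()` encodes a conformer as a bit string over typed atom
triangles: each heavy atom is typed (cation, anion, donor, acceptor,
hydrophobe, other), every trio with at least one typed atom becomes a
canonical edge list of (type, type, binned distance) triples, hashed to one
of 2048 bits with a deterministic polynomial string hash (base 131, modulus
2³¹ − 1); collisions OR into the same bit. Distance bins are 1 Å wide,
capped at 15 Å — no binning was published for the original, and 1 Å resolves
ring-scale geometry while tolerating conformer noise; both are arguments.
Because the descriptor uses only pairwise distances and sorted types, the
fingerprint is exactly invariant to rigid motion and atom reindexing, and it
is computed on the matched pose geometry, since the triangle content is
geometric.

`jarvis_patrick()` clusters fingerprints by shared nearest neighbours: K
nearest by Tanimoto distance, two items join iff each is in the other's
K-list and the lists share ≥ J members; clusters are connected components of
the join graph. Neighbour-list ties are broken by item id (not input
position), which makes the partition invariant to input order — with
bit-string similarities ties are common, and an index tie-break would let
the same library cluster differently after a shuffle. K = 10, J = 6 are
defaults in the usual range for this algorithm; the original study's values
are unpublished, so its reported cluster count (31) is not a target.
Representatives are the best-scoring member per cluster, ties to the
smallest id.

## Enzyme kinetics

`fit_lineweaver_burk()` is ordinary least squares on the double-reciprocal
transform (Km = slope/intercept, Vmax = 1/intercept); `fit_mm_nonlinear()`
is a Levenberg–Marquardt fit of v = Vmax·S/(Km+S) initialised from the
linear estimate. On noiseless data the two agree with the generating
parameters to better than 10⁻⁶ relative (tested); under multiplicative noise
the nonlinear fit is the one to trust, since the reciprocal transform
overweights small velocities.

`classify_inhibition()` reduces per-condition fits to two mean relative
shifts, r_Km = Km_i/Km₀ − 1 and r_V = 1 − Vmax_i/Vmax₀, and applies
thresholds: competitive if r_Km > 0.25 with |r_V| < 0.15, noncompetitive if
r_V > 0.15 with |r_Km| < 0.25, mixed if both, none otherwise. The source
assays report only qualitative "no significant change"; 25 %/15 % are this
package's operational reading, exposed as arguments. Ki comes from the
apparent-parameter relations (Km_app = Km(1+[I]/Ki) or
Vmax_app = Vmax/(1+[I]/Ki)) by through-origin least squares on the
linearised form, which is exact on noiseless data; for mixed calls the
Vmax-based estimate is reported. At 5 % multiplicative noise with two
inhibitor concentrations (15, 25 μM) and Ki = 20 μM the classifier recovers
the generating mode in well over 95 % of seeded simulations (tested at study
scale in the acceptance suite).

`fit_ic50()` fits the four-parameter logistic
response = bottom + (top − bottom)/(1 + (dose/IC50)^hill). Fits are
normalised to top > bottom via the equivalent hill-sign flip, and a ladder
of offset starts guards against the singular initial Jacobian that an
exactly-interpolating start can produce. `normalize_mutant_inhibition()`
expresses inhibition within each enzyme variant against that variant's own
ligand-free control, so a mutation's intrinsic activity change cancels.

## Trajectory analytics

RMSD series are per-frame best-fit superpositions onto a reference frame;
RMSF uses the iterated-mean-structure reference (superpose, average, repeat
until the mean moves < 10⁻⁶ Å) rather than the first frame, removing drift
bias. Hydrogen bonds use standard geometric criteria — donor–acceptor ≤
3.5 Å and donor–H–acceptor angle ≥ 120° — and fall back to a stricter
3.2 Å distance-only rule, flagged in the output, when hydrogen positions are
absent; the original study's detection settings are unstated. Multi-model
PDB is the only trajectory format; binary formats are out of scope.

One numerical caveat worth knowing: a least-squares superposition absorbs
six degrees of freedom, so measured RMSF is biased low by roughly a factor
√(1 − 2/N) for N fitted atoms. The σ√3 recovery tests therefore use a probe
atom among ~40 anchors (bias ≈ 2–3 %), and the doubling-linearity check uses
a 2 % tolerance — the superposition itself is slightly nonlinear in the
jitter amplitude.

## Synthetic data: what it emulates, and what it does not

The generators define the package's study conditions. Planted actives are
geometric constructs — two aromatic six-rings centred on P1/P2, ether
oxygens on P3/P4, an aliphatic amine on P5, linked into one graph and
rigidly scattered — whose perceived features land within a set jitter
(default 0.3 Å) of the query centers. Decoys violate the query in one of
three controlled ways (one interpoint distance inflated by 8 Å beyond any
tolerance, the donor replaced by an acceptor, or fully random placement).
Bond lengths to the heteroatoms are not chemically realistic and are not
meant to be: the fixtures probe the geometry pipeline, not chemistry.
Passing tests therefore show that the matcher, funnel, fingerprints and
fits behave exactly as designed on inputs of known truth — they do not show
that the feature-perception rules match any particular commercial
implementation on real drug-like molecules, nor do they reproduce the
original screen's absolute hit counts, which depended on a ~650 k compound
commercial database and a proprietary scorer.

Kinetics data are Michaelis–Menten curves on an 8-point geometric substrate
grid from 10 to 400 μM (bracketing the 56 μM control Km) with mean-one
log-normal noise — the natural model for plate-reader luminescence, whose
error scales with signal. Dose-response tables are 4PL curves over 0.1 to
1000 μM. Trajectories are base coordinates plus per-atom isotropic Gaussian
jitter and optional cumulative rigid drift, for which RMSF has the closed
form σ√3.

All generators take explicit seeds, use them through an RNG-state-preserving
wrapper, and are bit-reproducible; problem sizes in the test suite (a
1000-molecule screening library, 500 kinetics simulations, 2000-frame
trajectories) were chosen so the full suite runs in a few minutes on one
CPU.

## Known limitations

* Feature perception has no tautomers, no empirical pKa, and honours but
  does not derive aromaticity beyond the alternation test.
* The matcher is rigid-only: conformational flexibility must come from the
  input library's conformers.
* The pose score is a ranking device, not a binding-energy estimate;
  absolute post-docking counts from empirically scored screens cannot be
  compared against it.
* Jarvis–Patrick results depend on K and J, which are not identifiable from
  the original study; only the algorithm's invariants are guaranteed.
* The Lineweaver–Burk fitter is provided for fidelity to the classical
  analysis; for noisy data the nonlinear fitter is preferred.
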