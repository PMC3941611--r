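---
title: "Beta contacts, burial-weighted contact vectors and hot-spot prediction"
author: "betaACV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beta contacts, burial-weighted contact vectors and hot-spot prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betaACV)
```

## The problem

Alanine-scanning mutagenesis replaces an interfacial residue's side chain
beyond C-beta with a hydrogen, and the measured change in binding free
energy (ddG, kcal/mol) quantifies that side chain's contribution to a
protein-protein interaction. Residues with ddG of at least 2 kcal/mol are
*binding hot spots*. This package predicts ddG, and hence hot spots, from
the quaternary structure alone, by representing each mutation as a
52-element *atomic contact vector* (ACV) over a geometrically strict
contact definition, and learning a linear map to ddG with ridge
regression.

Two ideas carry the method:

1. **Beta contacts.** Distance-cutoff contact definitions admit many
   *interrupted* pairs: atoms whose connecting segment passes close to a
   third atom and therefore share no direct contact area. A *beta contact*
   requires three conditions: (i) the centre distance is below the sum of
   the van der Waals radii plus a slack `T_d` (3.3 A: a water diameter of
   2.8 A plus 0.5 A); (ii) the two atoms share a Voronoi facet,
   i.e. are Delaunay neighbours; and (iii) no third atom subtends an angle
   of at least the beta-skeleton threshold at the pair -- the *forbidden
   region* is empty. At a threshold of 90 degrees the forbidden region is
   the sphere on the pair's diameter; smaller thresholds enlarge it. The
   feature graphs use 75 degrees, chosen to be strictly sharper than the
   78-degree angle subtended by a third touching atom over a covalent
   bond (1.8 A carbons, 1.5 A bond -- the triangle with sides 1.5, 3.6,
   3.6).

2. **Water exclusion.** Hot spots sit in solvent-occluded pockets (the
   O-ring picture), so a contact's energetic weight should fall with the
   solvent exposure of its atoms. Each atom's contribution is therefore
   weighted by its *local ASA burial*, the product of an atom-level and a
   residue-level burial term.

## Contact graph construction

`build_contact_graph()` composes three filters over the structure's heavy
atoms (plus bound waters, see below):

* `delaunay_adjacency()` tests each candidate pair exactly for a shared
  Voronoi facet: the centres of spheres touching both atoms and excluding
  every other atom form a convex region on the pair's bisector plane, the
  intersection of one half-plane per third atom. The pair is adjacent iff
  that region has positive area, which is decided by sequential convex
  polygon clipping in compiled code. This per-pair feasibility test is
  exact in the generic case and degrades gracefully on degenerate
  (cospherical) inputs, where a facet of zero area is reported as absent;
  a deterministic jitter of at most 1e-6 A (`jitter` argument) is
  available for exactly symmetric synthetic inputs, and biological
  coordinates essentially never need it. Point sets with fewer than four
  atoms return all pairs by convention.
* `distance_filter()` keeps pairs with `d < r_i + r_j + T_d`, strictly.
* `beta_filter()` scans, for every surviving pair, all atoms of the
  structure (not only contact candidates) and rejects the pair as soon as
  one subtends an angle greater than or equal to the threshold
  (an angle exactly at the threshold rejects, matching the "sharper than"
  reading). A point subtending at least `beta` over a pair at distance
  `d` lies within `d / sin(beta)` of both endpoints, which bounds the
  scan.

Both boundary conventions are strict inequalities; tests pin them at the
boundary. The filters nest by construction -- beta(75) within beta(90)
within the distance-filtered set within the Delaunay set -- and both
geometric kernels are validated against brute-force oracles (full
empty-circumsphere enumeration over point quadruples; a cubic angle
loop).

## Waters

Crystallographic waters are kept as single oxygen atoms and classified by
`detect_bound_waters()`: a water is *bound* when it has at least three
potential hydrogen-bond contacts (N or O heavy atoms within 3.2 A), or two
such contacts plus at least two further contacts within 4 A. Water-water
contacts never count, and donor/acceptor status is read off element
identity alone (N or O) since the heavy-atom record cannot resolve
protonation. Bound waters participate as contact-graph nodes (typed as the
oxygen-with-more-than-one-hydrogen class) and can therefore appear in the
mutation contact sets; free waters are ignored. Waters are excluded from
all ASA computations, from the mutated-residue neighbourhood, and from
both halves of the unbound split; bound-water atoms consequently enter
the burial-weighted sums with unit weight, consistent with their
interface-buried placement by the hydrogen-bond rules.

## Solvent accessibility and burial

`compute_asa()` is a Shrake-Rupley implementation with a deterministic
Fibonacci-spiral point set (960 points per atom, probe 1.4 A by default);
it converges to well under 1% relative change when the resolution doubles,
and reproduces the closed-form sphere area (for an isolated water-sized
sphere, 4 x 3.14 x 2.8^2 = 98.47 A^2) to sampling accuracy. Radii are
Chothia-style values bundled with the 8-class atom typing table.

From per-atom ASA the package derives, in both the bound state (the
complex) and the unbound state (each partner in isolation, rigid split, no
repacking):

* atom-level relative exposure `E_i = ASA_i / 50` and burial
  `B_i = max(0, 1 - E_i)`; 50 A^2 is roughly half the free-water area;
* residue-level exposure of the backbone (N, CA, C, O, with OXT counted
  as backbone) and side chain, scaled by the residue type's reference
  maximum and clamped the same way;
* local terms: `E_loc` and `B_loc` are the product of the atom-level term
  with the matching residue-level term (backbone atoms use the backbone
  factor, side-chain atoms the side-chain factor).

The reference maxima ship as frozen constants (`max_asa_table`), computed
once by `compute_max_asa_table()`: the package builds an idealized fully
extended ALA-X-ALA tripeptide for each residue type from standard internal
coordinates and runs its own ASA code on it. The exact reference
conformation is a free choice; freezing the resulting table (and testing
that a recomputation reproduces it) makes the scaling reproducible. The
absolute values differ from published scales based on other radii sets,
which is immaterial because only ratios against the same table enter the
features.

## The 52-element representation

For a mutation of residue `r` (alanine targets are meaningless and glycine
targets impossible -- both are rejected), the mutant structure deletes the
side-chain atoms beyond C-beta with no repacking. Beta-contact graphs of
wild type and mutant are compared: `M` holds the *mutated* contacts
(present only in the wild type), `N` the *new* contacts (present only in
the mutant); contacts between atoms within three covalent-bond steps are
discarded, because their proximity reflects bond rigidity, and common
contacts carry no signal. Covalent topology comes from per-residue bond
templates plus peptide bonds within 2 A.

The pair block has one element per unordered pair of the 8 atomic types
(36 elements, lexicographic order). In basic mode each contact contributes
`1 / d^2` (positive for `M`, negative for `N`); in burial-weighted mode it
contributes `B_loc(x) B_loc(y) / d^2`, so fully exposed atoms contribute
nothing. `M` contacts are weighted with the wild-type ASA profile and `N`
contacts with the mutant's -- each contact is weighted in the state where
it exists; with deletion-only mutants the choice is nearly always moot
because `N` is small.

The neighbourhood block describes the mutation's environment: `S` contains
the atoms with a 90-degree beta contact to any mutated atom, the mutated
atoms themselves, and one round of covalent-bond nearby atoms (within
three steps) of every member -- "nearby" is the covalent notion, the only
one defined here, and `S` is evaluated on the wild-type geometry. Per
atomic type, the local exposures `E_loc` are summed in the bound and the
unbound state (8 + 8 elements), totalling 52.

A dataset filter requires the mutated atoms to have at least one
distance-cutoff contact with the partner side; mutations failing it (or
targeting ALA/GLY) are rejected by `featurize_mutation()` and skipped with
a warning by the table driver.

The 8-type grouping itself (aliphatic C; sp2/aromatic C; neutral N;
charged N; neutral O; carboxylate O; water O; S) is a documented default
and deliberately swappable data (`default_type_table()`): every downstream
computation is parametric in the table, and the tests fix it.

## Regression and evaluation

`ridge_fit()` z-scores each feature column from the training rows (the
normalisation is unspecified upstream; z-scoring is the conventional
choice), centres the response and solves the penalised normal equations in
closed form; constant columns get zero coefficients. The penalty default
is `lambda = 1` on the normalised scale -- the original statistics-package
default is unknowable, so the penalty is exposed everywhere and results
should be read as lambda-sensitive. The fit is verified against an
independent ridge implementation (`MASS::lm.ridge`) to machine precision
after reconciling the scaling conventions.

`loocv_predict()` re-estimates the normalisation inside every fold;
`evaluate_ddg()` reports the Pearson correlation `R`, the mean squared
error `SE` with an `N - 1` denominator, `delta = sqrt(SE)`, and hot-spot
classification metrics at the inclusive 2 kcal/mol threshold (precision,
recall, F1, accuracy; hot spots are positives). Predictions below -3 or
above 11 kcal/mol are flagged as outliers and `R` is additionally reported
with them removed -- they are never dropped from `SE`. A grouping argument
supports leave-one-complex-out evaluation. When no positive prediction
exists, precision is reported as 0 with an explicit flag (so F1 is 0
rather than an error), which small fixtures need.

## Synthetic fixtures

Because the package is exercised without external structure downloads, the
fixture module generates everything:

* `random_cloud()` -- seeded rejection-sampled points with a minimum
  separation, standing in for heavy-atom packing in the geometric tests;
* `toy_complex()` -- two short idealized helical peptides (built from
  internal coordinates by `build_peptide()`), axis-aligned and posed face
  to face at a 3.2 A closest approach, giving an interface that spans
  several residues. Its geometry exercises all three contact conditions
  (Delaunay edges failing the distance test; distance-passing edges
  failing 75 but passing 90 degrees; full beta contacts), waters can be
  placed to satisfy or violate the bound-water rules by construction, and
  the structure round-trips through PDB text;
* `linear_response_dataset()` -- standard-normal features with a known
  coefficient vector and Gaussian noise, for the regression tests
  (noise sd 0.5 at n = 400 in the stated recovery checks).

All generators are pure functions of their arguments including the seed.
The toy complex is idealized geometry, not physics: no rotamer
preferences, no packing optimisation, mirror-image chain B. Passing tests
therefore demonstrate the correctness of the geometric and statistical
machinery, not predictive accuracy on real interfaces, which requires
curated complexes and measured ddG values.

## Numerical choices and limitations

* Problem sizes in the shipped tests: clouds up to 30 atoms against the
  cubic oracle (100 seeds), up to 15 against the circumsphere oracle, toy
  complexes of about 135 atoms, and regression designs up to n = 500,
  p = 52 -- sizes chosen so the whole suite runs in well under a minute
  of geometry and a few seconds of regression.
* The Voronoi-facet test uses a bounding box of 1e7 A on the bisector
  plane and a positive-area tolerance of 1e-8 A^2; unbounded facets are
  clipped by the box.
* ASA is numerical: rigid-motion invariance of ASA-derived quantities
  holds only to sampling accuracy (roughly 1% per atom at 960 points),
  while the contact geometry is exactly invariant.
* Alternate locations keep the first conformer; residues with missing
  heavy atoms are processed with the atoms present.
* Only alanine mutations of standard residues are supported; no mmCIF,
  no hydrogens, no structure repair or minimisation.
* The non-beta variant of the representation (distance-cutoff ACV minus
  beta ACV) is a vector subtraction away and intentionally not engineered
  as a separate code path.

## A worked run

```{r, eval = FALSE}
s <- toy_complex(waters = "bound")
muts <- toy_mutations(s, seed = 3)
fz <- featurize_mutations(s, muts, contact_params(3.3, 75), mode = "asa")
evaluate_ddg(fz$X, fz$mutations$ddg_exp, lambda = 1)
```

The same pipeline is available from the shell through the bundled CLI
(`inst/cli/betaacv`): `contacts`, `asa`, `featurize`, `train-eval`, the
end-to-end `predict`, and `make-fixture`; every output embeds its resolved
configuration.
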