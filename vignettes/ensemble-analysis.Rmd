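---
title: "Ensemble analysis of the p53 regulatory domain: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble analysis of the p53 regulatory domain: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`regensemble` analyses conformational ensembles of the intrinsically
disordered C-terminal regulatory domain of p53. The construct is the
43-residue segment with author numbering 351-393 (the regulatory domain
plus the five preceding tetramerization-domain residues), carrying up to
seven Ser/Thr phosphosites (S366, S371, S376, T377, S378, T387, S392).
The package takes conformational ensembles as input — multi-model PDB
files, typically exported from molecular-dynamics trajectories — and
computes the descriptors used to compare phosphorylation states: global
size and shape, solvent accessibility, secondary-structure composition
including polyproline-II, Ramachandran region populations, salt-bridge
and hydrogen-bond occupancy, distribution summaries, and tICA-based
free-energy landscapes with cluster-model selection. It does not run
molecular dynamics.

Because microsecond MD ensembles are not reproducible at desk scale,
the package ships synthetic-ensemble generators with closed-form ground
truth, and every analysis stage is validated against those or against
independent oracles (spectral theory for Markov chains, brute-force
surface-point sampling, hand-evaluated cluster metrics, freely-jointed
chain moments).

# Residue chemistry and charge bookkeeping

Formal side-chain charges are +1 (Lys/Arg), -1 (Asp/Glu), and a
configurable charge per phosphosite. The phosphate is monoanionic (-1)
by default, consistent with a phosphate bearing three available oxygen
atoms and one protic hydrogen; a -2 dianion can be set per topology.
Charged-atom sets use standard PDB naming: Lys NZ; Arg NE/NH1/NH2; Asp
OD1/OD2; Glu OE1/OE2; phospho-Ser/Thr O1P/O2P/O3P plus the ester
oxygen; termini (optional groups) N and O/OXT.

Two bookkeeping conventions coexist for this construct and both are
exposed rather than reconciled:

* **Charged species** (`charged_groups()`): one group per K/R/D/E side
  chain and per phosphosite, His never counted. The 43-mer gives 15
  species summing to +5 unmodified, 16 (+4) with S392 phosphorylated,
  and 22 (-2) fully phosphorylated at -1 per site.
* **Formal net charge** (`formal_net_charge()`): side chains plus
  phosphates plus His protonation plus termini (zwitterionic termini are
  net zero). The construct contains three histidines; under the
  `protonated` His convention the net charge is +8 unmodified, +7 with
  one phosphate and +1 with seven — the counterion numbers follow from
  `counterion_count()`. With the physiological-pH `neutral` default the
  net equals the species sum (+5).

The two conventions are genuinely different accountings (His in or
out), not a bug; which one a user wants depends on whether they are
counting salt-bridge-capable species or neutralizing a simulation box.

# Synthetic ensembles

The generators emulate exactly the features the analysis stages
measure, and nothing else:

* `build_peptide()` constructs backbone atoms (N, H, CA, CB, C, O) from
  supplied phi/psi dihedrals with Engh-Huber geometry (N-CA 1.458 A,
  CA-C 1.525 A, C-N 1.329 A, omega fixed at 180 deg). Recomputing
  dihedrals on the output reproduces the inputs to construction
  precision (< 1e-3 deg), which is the invariant the Ramachandran and
  featurization stages rely on. The amide hydrogen sits 1.0 A from N
  along the reversed bisector of the N-C(prev) and N-CA directions;
  prolines and the first residue carry no donor.
* `markov_dihedral_walk()` drives all residues with a single hidden
  Markov chain over named Ramachandran basins, emitting basin centres
  plus Gaussian jitter. The chain's second eigenvalue is the planted
  slow timescale that tICA must recover; its stationary vector is the
  planted basin population.
* `freely_jointed_chain()` draws i.i.d. unit-vector bonds, giving the
  closed forms `<R^2> = N b^2` and `<Rg^2> -> N b^2 / 6` used to
  validate the size estimators. The default bond length 0.38 nm is the
  CA-CA virtual bond.
* `plant_contact_ensemble()` places a charged pair's closest atoms at
  0.7x the cutoff in exactly `round(f * n_frames)` frames and at 2.5x
  the cutoff otherwise, so measured occupancies equal planted fractions
  exactly, with no sampling error.

What the generators do **not** emulate: sterics, solvent, electrostatic
energetics, sequence-dependent basin preferences, or correlated
inter-residue dynamics. Consequently a passing test shows the
*estimator* is correct, not that the synthetic ensembles resemble real
p53 ensembles; in particular, specific salt bridges essentially never
form spontaneously in unbiased walks (the pseudo side-chain atoms sit
on short stalks beyond CB), which is why the contact stages are
validated on planted ensembles. Since tICA consumes dihedrals only, the
landscape driver runs on long dihedral walks directly and skips 3-D
construction.

All generators are seed-deterministic: the same seed gives bit-identical
output.

# Geometry

Radius of gyration is mass-weighted by default (common MD practice;
unweighted is available and is what the point-chain validations use).
End-to-end distance defaults to the alpha-carbons of the first and last
residues; the reference atom is configurable because conventions vary.
`kabsch_rmsd()` superposes with the standard 3x3 covariance SVD and a
determinant guard against improper rotations; fewer than three
non-collinear atoms is an error since the rotation is then
undetermined. Rolling averages use valid windows only (no edge
padding).

# Solvent-accessible surface area

`shrake_rupley()` places `n_points` golden-spiral test points on each
atom's solvent sphere (van der Waals radius + probe) and counts points
outside every neighbour's solvent sphere. Defaults: Bondi radii, probe
0.14 nm, 960 points — field defaults, and refining 240 to 960 points
moves totals by well under 1%. The implementation is compiled (C++)
since this is the one O(atoms x points x neighbours) stage.

Two accounting modes mirror how phosphorylated conditions are compared:
totals over all residues, and totals excluding the phosphosites — the
latter controls for the surface the phosphate groups themselves add.
Per-residue differencing aligns columns by author number regardless of
chemical identity, so a phospho-Ser column is compared directly against
its unmodified Ser counterpart.

# Secondary structure

Hydrogen bonds follow Kabsch-Sander:
`E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN)` kcal/mol with a
-0.5 kcal/mol threshold, amide H reconstructed when absent. Helices
(H/G/I) come from two consecutive 4-/3-/5-turns, strands (E) and
isolated bridges (B) from parallel/antiparallel bridge patterns, T from
turn interiors, S from CA kinks above 70 degrees. Final priority:
phospho class X, then H, E/B, G, I, P, T, S, coil.

The polyproline-II class P is assigned to runs of two or more
consecutive residues within +-29 degrees of (-75, +145) that no
helix/strand pattern already claims — the convention of recent DSSP
implementations that detect PPII from dihedrals. Phosphorylated
residues are always reported as their own class X: with 7 of 43
residues phosphorylated the X fraction is exactly 7/43 = 16.28%, and
1/43 = 2.33% for the single site, frame-independent. Whether the
upstream tools' "bend" and "turn" definitions match this package's
canonical-DSSP defaults exactly is not decidable from text alone, so
the canonical definitions are used.

# Ramachandran regions

Named basins (PPII, beta, normal alpha, deformed alpha, left-handed,
the remaining phi > 0 half-plane, other) are configuration, not code:
`default_region_table()` holds priority-ordered phi/psi intervals and
classification is total and single-valued on `[-180, 180)^2`. The
default bounds follow the standard basin geometry; one published
interval for the beta/PPII region (psi down to -180) is internally
inconsistent with beta-sheet psi values and is treated as a typo rather
than adopted. Region populations are fractions over all defined
(phi, psi) pairs and sum to one.

# Contacts

A salt bridge is a frame where the minimum distance between two
oppositely charged groups' atoms falls below the cutoff. Two cutoffs
coexist deliberately: 0.35 nm (3.5 A) for salt-bridge statistics and
0.30 nm for hydrogen-bond-style heat maps, both configurable, because
both conventions are in active use for this system. Distance is the
minimum over atom pairs by default (a centroid mode exists); there is
no angular criterion, matching the distance-only definition the heat
maps use. Because it is ambiguous whether a "mean occupancy" averages
over all eligible pairs or only observed ones, `occupancy_mean()`
returns both reductions.

# Distribution summaries

`summarize_series()` reports mean, variance, Gaussian-equivalent FWHM
(`2 sqrt(2 ln 2) sd = 2.3548 sd`), bias-uncorrected Fisher skew, and
excess kurtosis. The Gaussian-equivalent FWHM convention was chosen
because published summary tables for this system satisfy it to printed
precision on every row; a literal half-maximum crossing width of the
KDE is available as `fwhm_mode = "kde"`. Kurtosis is excess (values
near zero for near-Gaussian data). The 1-D KDE uses a Gaussian kernel
with Scott's bandwidth.

# Landscapes

Dihedral features are (cos, sin) pairs per defined angle, which removes
periodicity. tICA solves `C(tau) v = lambda C(0) v` with mean-free,
reversible (symmetrized) covariance estimation — chosen so eigenvalues
are real, an estimation choice, not a physical claim — and an epsilon
ridge on `C(0)`; components are normalized so projections have identity
instantaneous covariance, and implied timescales are
`-tau / log(lambda)`.

The free-energy surface is `F = -kT log(rho / rho_max)` over a 2-D
Gaussian KDE of the first two components, so `min(F) = 0` by
construction; kT is the unit (298 K convention). Clustering is
agglomerative (Ward linkage on Euclidean distance in projected space)
cut at each candidate k in 2..10; silhouette and Davies-Bouldin are
computed per k. When the two metrics disagree, the silhouette winner is
selected and the DB optimum reported alongside — mirroring practice for
this system where both metrics are quoted. Clusters under 10 frames are
dropped from the retained list (sparse-state pruning); representatives
are in-cluster medoids with ties broken to the lowest frame index. Lag
time (100 frames), component count (2), linkage and k-range are not
dictated by any published protocol for this system and are therefore
explicit, configurable defaults; landscapes computed with them should
not be presented as reproductions of any specific published landscape.

# Numerical choices and problem sizes

* Internal units are nm and degrees; PDB Angstrom conversion happens at
  I/O. Angles are wrapped to `[-180, 180)`.
* The test and acceptance workloads are sized for interactive runs:
  SASA oracle comparisons use 1e5-1e6 surface points on 5-atom
  clusters; tICA timescale recovery uses 1e5-frame walks; clustering
  model selection uses a few hundred points; the analysis drivers use
  300-frame ensembles of the 43-mer and a 20,000-frame dihedral walk.
* Degenerate inputs fail loudly: non-stochastic transition matrices,
  singular instantaneous covariance without regularization, empty atom
  selections, phosphosites on non-Ser/Thr residues, missing radii.

# Known limitations

* Contact occupancy on synthetic ensembles reflects geometry only;
  absolute occupancies from unbiased walks are near zero and only
  planted ensembles carry known signal.
* The secondary-structure assignment covers the standard classes; pi-
  helix subtypes beyond I and beta-sheet topology graphs are out of
  scope, as is periodic-boundary handling (ensembles are assumed
  whole).
* `crystal_checks()` measures span distances on any supplied structure;
  the package bundles no experimental structures, so those checks run
  on user-provided files or on analytic constructions.
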