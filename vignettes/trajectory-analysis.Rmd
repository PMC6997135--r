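---
title: "Comparative MD trajectory analysis with trajkit: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative MD trajectory analysis with trajkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajkit)
```

trajkit analyzes conformational ensembles of proteins — typically the
frames of a molecular dynamics run, stored as multi-model PDB — and
compares two systems (for example an apo enzyme against its
inhibitor-bound complex). This vignette records the models the package
implements, the choices made where the methods literature leaves room,
and what the synthetic test ensembles do and do not establish.

## Data model and units

A `trajectory` is one topology (an atom table with names, elements,
residue ids as printed in the source file, chains, occupancies and
B-factors) plus an `n_atoms x 3 x n_frames` coordinate array. Units are
Angstrom for length, kJ·mol⁻¹ for energy, ns for time, degrees for
angles, Kelvin for temperature. Only multi-model PDB and delimited
parameter tables are read: these are plain text, bit-stable, and
sufficient for ensembles exported from any MD engine; binary formats
(DCD/XTC/NetCDF) are out of scope. Alternate locations are resolved to
the highest-occupancy variant, ties to the first encountered. Elements
come from PDB columns 77–78 when present, falling back to atom-name
heuristics; hydrogens are kept because the hydrogen-bond machinery
needs them explicitly.

## Superposition and descriptors

RMSD between conformations is computed after optimal rigid-body
superposition (Kabsch, via SVD of the cross-covariance, with the
reflection branch corrected so the rotation is always proper). Optimal
fitting before the deviation sum is the standard reading whenever a
plain "RMSD between conformations" is reported, and without it the
RMSF/B-factor comparison below would be dominated by global tumbling.

RMSF is measured about the ensemble mean structure, with two fit/re-mean
iterations: the mean structure is itself defined by the fit, and two
passes are enough for the fixed point at the noise levels of equilibrated
trajectories. The crystallographic conversion is `B = (8π²/3)·RMSF²`.
Radius of gyration defaults to unit masses (geometric Rg) since mass
weighting is rarely stated in the analyses this package mirrors; element
masses from a built-in table are available via `masses = "element"`.

One subtlety worth knowing when interpreting fixture tests: when a
sub-segment of `k` atoms out of `N` moves rigidly by `d`, the
*unsuperposed* RMSD is exactly `d·sqrt(k/N)`, but the optimal fit
partially compensates (a translation of `d·k/N` plus a rotation), so the
superposed value is systematically smaller and some apparent motion
spreads onto the static atoms in RMSF. The tests assert bands derived
from these identities rather than the naive closed forms.

## Threshold clustering

Conformations are clustered on the pairwise superposed-RMSD matrix with
a distance threshold: frame pairs at or below the threshold are
"same-cluster" edges. That pairwise indicator is not transitive, so it
does not define a partition by itself; the package takes the minimal
completion — connected components of the edge graph, i.e. single-linkage
at the threshold. (The source convention this follows states the
same-cluster rule for the indicator value 1; its prose also assigns the
same meaning to 0, which is read as a typo.) Two preset thresholds are
exposed, 2.4 Å for coarse basin structure and 1.5 Å for the
time-dependent cluster-growth curve whose plateau indicates converged
sampling. The representative of a cluster is its lowest-energy member
when per-frame energies are supplied, and otherwise the medoid (minimum
mean RMSD to the other members), since per-frame potential energies are
not part of this package's inputs.

## Residue contacts

Two residues are in contact when their minimum heavy-atom distance is
below 4.5 Å. Three decisions are surfaced as parameters rather than
hidden:

* *Distance definition.* Minimum heavy-atom distance is the common
  convention at a 4.5 Å cutoff; a Cα-only mode exists for coarse maps.
* *Sequence-neighbor exclusion* defaults to 2 (i, i±1 excluded):
  neighbor contacts are always true and would swamp the statistics.
* *Heteroatoms* (heme, ligand, solvent) are excluded by default and can
  be included with `include_het = TRUE`.

Comparing the first and last snapshots of a run yields common and
snapshot-specific contact sets, from which two statistics derive:
contact **similarity** = common / (common + specific-first +
specific-last), a conservation measure; and the **reduction rate** =
(specific-first − specific-last) / total-first, positive for relaxation
and negative for compaction. Per-segment fractions split the chain into
50-residue segments (the final segment absorbs the remainder) and count
each snapshot's specific contacts with at least one endpoint in the
segment, divided by that snapshot's total contacts; a contact spanning
two segments deliberately counts once in each. A cell-list grid
accelerates the map construction and is tested to be pair-for-pair
identical to the exhaustive path.

## Hydrogen bonds, side-chain states, RDF

A donor–H···acceptor triple is bonded in a frame when the H···A distance
is below 3.5 Å *and* the acceptor–H–donor angle (vertex at the hydrogen
— the angle's name fixes the vertex) exceeds 135°; both thresholds are
parameters. Donors are N/O/S heavy atoms with a hydrogen within 1.2 Å (a
proximity rule, since PDB fixtures carry no CONECT records); acceptors
are N/O atoms. Occupancy is the fraction of frames satisfying the
criterion; mean distance and angle are averaged over satisfying frames
only, matching how bond tables are normally quoted.

Side-chain fold/stretch classification (the arginine-style two-state
geometry) takes a probe angle and distance series and splits at
caller-supplied thresholds; there are deliberately no defaults, because
the split values depend on the residue and probe atoms chosen and
silently defaulting them would manufacture a result.

The radial distribution function normalizes a pair-distance histogram by
the spherical shell volume and mean pair density. With a `box` edge
supplied the minimum-image convention applies (periodic cube) and the
ideal-gas expectation g(r) = 1 holds to arbitrary range; without a box a
normalization volume must be given, and g(r) is biased low at distances
comparable to the system extent because shells are truncated at the open
boundary. That bias is a property of non-periodic geometry, not a bug;
the periodic mode is the one validated against the uniform-gas Poisson
band.

## PCA and the free-energy landscape

PCA operates on superposed Cartesian Cα coordinates (mass-unweighted),
the coordinate set used for every other backbone analysis here.
Eigenvector signs follow a fixed convention (largest-magnitude component
positive) so projections and plots are reproducible run to run. The
free-energy landscape over (PC1, PC2) is the Boltzmann inversion
`ΔG(X) = −k_B·T·ln P(X)` with `k_B = 0.0083145` kJ·mol⁻¹·K⁻¹ and
T = 300 K by default, on a 50×50 histogram padded 2% beyond the
projection range. Bins never visited get `NA` ("unsampled"), not an
infinite or sentinel energy: the inversion diverges at P = 0 and
finite stand-ins would poison downstream arithmetic. The surface is
shifted so the sampled minimum is zero.

Basins are 8-connected regions of sampled bins with ΔG at or below a
depth cut. Two practical points: first, a depth cut only "merges" basins
when the barrier between them is actually sampled — well-separated
states stay separate at any cut because the gap is unsampled; second, a
sparse histogram produces isolated low-count bins that clear any energy
cut, so regions holding under `min_occupancy` (default 1%) of frames are
discarded as sampling noise. Each basin reports floor energy, member
frames, occupancy, and dwell intervals (the smallest set of contiguous
frame runs covering ≥80% of its frames). Non-Gaussianity of a projection
is reported as excess kurtosis and Sarle's bimodality coefficient,
`(skew² + 1)/kurtosis`; strongly non-Gaussian PCs mark functional slow
motions as opposed to harmonic thermal noise.

For a two-state system with populations p₁/p₂ and identical basin
shapes, the gap between basin floors inverts to
`ΔΔG = −k_B·T·ln(p₂/p₁)` — 2.11 kJ·mol⁻¹ for 0.7/0.3 at 300 K. This
closed form is the parameter-recovery anchor for the whole PCA/FEL
stack and is verified at 10⁵ frames in the test suite.

## Pore profiling

At stations spaced along a channel axis (default 0.25 Å), the package
finds the largest probe sphere not overlapping any atom's van der Waals
sphere, maximizing the clearance `min_i(|c − x_i| − r_i)` over the
perpendicular plane. The first station is seeded by a 0.5 Å coarse grid
over the search disk; every later station starts from the previous
station's optimized center (taking the in-plane axis point instead when
it is better), then refines by a deterministic compass pattern search
down to 0.05 Å steps. Tracking the previous center is what keeps the
optimum *inside* the channel: a global search of the full disk will
happily step over the channel wall into open space at a constriction. A
pattern search replaces the simulated-annealing optimizers of the
classic channel-profiling tools purely for determinism; a dense-grid
oracle in the tests bounds its error at 0.1 Å.

Stations are classified by water passage using the established radius
conventions — below 1.15 Å (one water radius) blocked, 1.15–2.30 Å
single-file water, above 2.30 Å two or more waters abreast — and each
station reports the residue of the atom realizing the limiting contact.
vdW radii come from the parameter table when supplied, else a built-in
element table (C 1.7, N 1.55, O 1.52, S 1.8, H 1.2, Fe 2.0 Å).

## Binding free-energy bookkeeping

The end-state ledger is `ΔG_bind = ΔH − TΔS` with
`ΔH = ΔE_vdw + ΔE_ele + ΔG_polar + ΔG_nonpolar`, and the driving-force
split polar = ΔE_ele + ΔG_polar, nonpolar = ΔE_vdw + ΔG_nonpolar. The
package computes the vacuum molecular-mechanics terms itself: Coulomb
with `f = 1389.35458 kJ·mol⁻¹·Å·e⁻²` and 12-6 Lennard-Jones under
Lorentz–Berthelot combination, no cutoff by default. Polar (PB/GB)
solvation and the normal-mode entropy term are accepted as inputs
(per-frame tables or per-residue columns): solving the Poisson–Boltzmann
equation or a vibrational analysis is an engine-scale undertaking that
sits outside this package's contribution, and treating those terms as
data keeps the ledger exact and testable. When absent they enter as zero
and the output is flagged accordingly.

Nonpolar solvation uses the SASA-proportional form `γ·SASA + β` with
γ = 0.0227 kJ·mol⁻¹·Å⁻² and β = 3.849 kJ·mol⁻¹ (the widely used
0.00542 kcal·mol⁻¹·Å⁻² / 0.92 kcal·mol⁻¹ pair converted). SASA itself is
computed by Shrake–Rupley point sampling on a deterministic Fibonacci
lattice (default 960 points, converged to <1% against 4000), chosen over
pairwise-overlap approximations because an isolated atom has the exact
closed form `4π(r + probe)²` to test against.

Per-residue decomposition restricts the Coulomb/LJ sum to one receptor
residue at a time against the ligand, averages over a frame schedule
(default: drop the first 10% of the run, then stride to about 180
frames, the customary end-state sampling density), joins per-residue
GB/GBSUR columns when provided, and ranks by mean total ascending.
The component means sum to the total by construction; the published
per-residue tables this mirrors satisfy the same identity at printed
precision on their exactly-rounding rows, which is what the tests
assert.

## The synthetic ensembles — and what passing tests show

Every analysis stage is exercised on seeded generators with analytic
ground truth:

* `make_two_state_ensemble()` — an ideal 30-residue helix whose terminal
  6 residues are rigidly displaced 4 Å in a fraction of frames, plus
  0.3 Å isotropic Gaussian noise. The segment size and displacement are
  loop-scale motion (comparable to a flexible active-site loop switching
  between open and closed); 0.3 Å noise is the Cα thermal fluctuation
  scale of a well-equilibrated fold. A *rigid contiguous segment* is
  displaced, not individual atoms, so PC1 genuinely captures a
  collective motion.
* `make_pore_cylinder()` — stacked atom rings with analytic clearance
  `ring_radius − vdw` at each plane.
* `make_hbond_trajectory()` — a donor–H–acceptor triple toggling between
  bonded (2.9 Å, 165°) and broken (4.5 Å, 120°) geometry with Bernoulli
  frame states.
* `make_uniform_gas()` — the ideal-gas RDF baseline.
* `make_contact_pair()` — six-residue toys whose contact sets are
  enumerated by hand and re-verified by a brute-force oracle.

All generators are pure functions of their seed; OS entropy never enters
a fixture. What these fixtures establish is *algorithmic correctness*:
recovery of known populations, radii, occupancies and free-energy gaps.
What they do not establish is behavior on real force-field ensembles —
no solvent, no side chains, no anharmonic coupling, Gaussian rather than
Boltzmann-weighted noise — so agreement on fixtures says the arithmetic
is right, not that any particular biological conclusion transfers.

Problem sizes in the shipped tests were chosen to make the statistical
bands tight at desk scale: 10⁵ frames for the FEL population-recovery
check (binomial and Poisson errors well inside the asserted 0.15
kJ·mol⁻¹), 5000 frames for hydrogen-bond occupancies (3·binomial-sd
bands), 1000 particles for the RDF Poisson band, and 100 randomized
structures for each oracle-equivalence sweep.

## Known limitations

* PDB is the only trajectory format; very long runs should be strided
  before export.
* Clustering materializes the full pairwise RMSD matrix (O(n²)); the
  pipeline strides trajectories beyond 400 frames for this stage.
* The pore tracker follows one channel from the axis start; it does not
  discover branched tunnels.
* The cluster-growth curve counts components on each prefix; with
  single-linkage completion a late frame can in principle bridge two
  early clusters, so the curve is non-decreasing in practice but not by
  theorem.
* Polar solvation and entropy are inputs; the ledger is only as good as
  the engine that produced them.
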