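---
title: "Comparative trajectory analysis of GPCR-ligand complexes: models and methods"
author: "MDAllostery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative trajectory analysis of GPCR-ligand complexes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope

MDAllostery compares two simulated conditions of a G protein-coupled
receptor (GPCR) complex -- typically the same receptor bound to two closely
related agonists -- and asks where the two ensembles differ: in the ligand
binding pocket (contacts, head-moiety rotamers), in the transmembrane (TM)
bundle (subsegment displacements), and in the correlated motions that link
the pocket to the receptor--G protein interface. The motivating use case is
the cannabinoid receptor 1 (CB1R) bound to indole-3-carboxamide synthetic
cannabinoids whose head moieties differ by a single methyl group, with a
Gi-protein alpha subunit docked at the intracellular face.

The package operates on coordinate trajectories (multi-model PDB or a
simple binary frame format) over an annotated topology; it does not run
molecular dynamics, build systems, dock ligands, or fit pharmacological
dose-response data.

## The analysis stages

### Frame clustering with gap-statistic state counting

Frames are characterised by the pairwise minimal RMSD of the TM-domain
backbone (Calpha atoms of every scheme residue) after optimal rigid-body
superposition (Kabsch, computed in compiled code). Because k-means needs a
vector space, the RMSD matrix is embedded by classical multidimensional
scaling. Two truncation rules are applied to the embedding:

* keep the leading axes covering 95% of the positive-eigenvalue variance,
  capped at `maxDim` (20) axes;
* drop axes whose eigenvalue falls below `relEig` (5%) of the leading one.

The second rule matters in practice: an RMSD matrix dominated by isotropic
atomic fluctuation spreads its variance across hundreds of near-equal noise
axes, and a pure variance-fraction rule would retain them, drowning the
conformational signal and biasing the gap statistic toward extra splits.

For each bootstrap sample of 10,000 frames (drawn with replacement), the
number of conformational states is chosen by the gap statistic: for
`k = 1..K`, `W_k` is the within-cluster sum of squared distances of the
best of `nInit` k-means++-seeded k-means fits, and

```
Gap(k) = E*[log W_k] - log W_k
```

where the expectation is the mean over `B` Monte-Carlo reference data sets
drawn uniformly over the data's per-dimension bounding box. With
`sd_k` the standard deviation of the reference `log W_k` values and the
simulation error `s_k = sd_k * sqrt(1 + 1/B)`, the selected state count is
the smallest `k` with `Gap(k) >= Gap(k+1) - s_{k+1}`. If the rule never
fires the largest candidate is returned with a warning flag. `B` and the
candidate range are not fixed by the protocol; the defaults are `B = 50`
and `k <= 10`, both configurable.

Two properties of this estimator are worth keeping in mind. On data drawn
from the reference distribution itself, `Gap(k)` is zero within Monte-Carlo
error for every `k` (this is tested). On data whose structure is not a set
of compact isotropic clusters -- e.g. a discrete two-state split plus an
elongated continuous mode -- the uniform reference rewards splitting the
elongated direction, so the selected `k` can exceed the number of discrete
states. That is a property of the method, not a defect of the
implementation, and the synthetic default condition pair exhibits it.

The frames of the most populated cluster ("representative cluster",
overridable) are mapped back to original frame ids and feed every
downstream per-condition analysis.

### Ligand contacts and rotamers

The contact frequency of a binding-site residue is the fraction of frames
in which any of its heavy atoms lies within 6 Angstrom of any ligand heavy
atom. Residues reaching 50% in at least one condition are tabulated for
all conditions, and pairwise condition differences of 25 percentage points
or more are highlighted. The binding-site set defaults to every receptor
residue with a heavy atom within 10 Angstrom of the ligand in the first
frame -- a superset that cannot drop a true contact. Side-chain chi1
rotamers are compared between conditions by circular means (vector
averaging; never arithmetic means on wrapped angles), flagging shifts
above 70 degrees.

### Subsegment conformational analysis

Each TM helix is divided into extracellular (e), middle (m) and
intracellular (i) subsegments by explicit residue ranges; the built-in
human CB1R scheme (21 subsegments, `cb1rScheme()`) is the reference
annotation, and Ballesteros-Weinstein codes are derived per helix from the
scheme's anchors. The per-frame center of mass (COM) of a subsegment is
the mass-weighted mean over the heavy atoms of its residues (a
Calpha-only mode is selectable; the choice is recorded in the report).
Between conditions the report gives `Delta COM = mean COM(A) - mean
COM(B)` per subsegment with its magnitude and, because "inward/outward"
needs a metric, its signed projection onto the unit vector pointing toward
the pocket center (the mean ligand heavy-atom position). COM distances
between subsegment pairs (defaults TM1e-TM3e and TM2e-TM7e) probe the
extracellular pocket geometry per frame.

Dihedral distributions are summarised by a circular histogram (5 degree
bins) smoothed with a wrapped Gaussian kernel (sigma 10 degrees); modes
are local maxima with topographic prominence at least 5% of the peak
density, supports are read at half-prominence, and occupancies split the
samples at the density minima between adjacent modes. These defaults
resolve chi1 rotamer peaks ~45 degrees apart without inventing modes from
histogram noise. A normalised 2D chi1/chi2 occupancy grid accompanies the
1D summaries.

### The correlation network

Three feature regions are assembled over the representative frames:

* **pocket** -- for each polar ligand atom (three head oxygens, linker and
  core nitrogens, tail fluorine), the per-frame minimum heavy-atom
  distance to every residue that is within 6 Angstrom of that atom in at
  least 50% of frames; plus the ligand head dihedrals chi1/chi2;
* **tm** -- all Calpha-Calpha distances between TM residues whose mean
  over the analysed frames is at most 12 Angstrom; plus chi1 dihedrals of
  the conserved activation motifs (CWxP, DRY, PIF, NPxxY), resolved
  through Ballesteros-Weinstein codes;
* **interface** -- receptor/G-alpha Calpha-Calpha distances under the same
  12 Angstrom mean filter.

Pearson correlation is computed for every feature pair. Angular features
enter through their sine/cosine embedding and a pair involving an angle
takes the component with the larger `|r|` (flagged "circular-derived");
naive Pearson on wrapped angles is not meaningful. Constant features give
`r = 0` with a flag rather than `NaN`. Three filters are then applied:

1. keep pairs with signed `r >= 0.85` (an absolute-value switch exists and
   its use is recorded in the report);
2. for distance-distance pairs `d_i = X_i - Y_i`, `d_j = X_j - Y_j`
   (residues canonically ordered `X < Y` within each feature), keep the
   pair only if `|X_i - X_j| >= 8` or `|Y_i - Y_j| >= 8`; residues are
   compared within a chain role only (receptor with receptor, G-alpha
   with G-alpha), and pairs involving a dihedral or a pocket feature pass
   unfiltered (a pocket distance has no second residue in receptor
   numbering space);
3. among surviving pairs sharing a common feature `d_i` whose partners
   `d_j` lie in the same ordered pair of TM subsegments, keep only the
   pair with the maximum residue-number gap
   `max(|X_i - X_j|, |Y_i - Y_j|)`; ties break to the lexicographically
   smallest partner `(X_j, Y_j)`. Residues outside every subsegment form
   a `"loop"` pseudo-segment; G-alpha residues one `"Galpha"` block unless
   secondary-structure blocks are configured.

The whole pipeline -- resample 10,000 frames, select `k`, cluster, take
the representative cluster, assemble, correlate, filter -- is repeated 10
times with child seeds derived from the master seed, and the **consensus
network** is the intersection of the surviving pairs across all
replicates. Per-TM involvement is the percentage of a helix's residues
(per the scheme) that participate in at least one consensus pair.

One computational shortcut is used: the RMSD matrix and its MDS embedding
are computed once per condition on the trajectory's frames, and each
bootstrap replicate indexes its resampled ids into that embedding instead
of re-embedding the duplicated RMSD matrix. Resampling then acts exactly
on the clustering stage (duplicated points reweight k-means and the gap
statistic), while the embedding geometry -- a deterministic function of
the same frames -- is shared. Everything downstream of sampling is
recomputed per replicate.

## The synthetic data generator

Deposited trajectories do not exist for the motivating study, so the
package ships a generator whose outputs carry planted, recoverable ground
truth. `generateReceptor()` builds a coarse 7-helix bundle (ideal-helix
Calpha trace, 5 heavy atoms per residue, inward-tilted extracellular
ends) populating every subsegment of the scheme, a 20-atom ligand with
the polar-atom inventory of an indole-3-carboxamide agonist (three head
oxygens, linker and core nitrogens, tail fluorine) and two head dihedrals
with explicit rotating atom sets, and a 30-residue G-alpha pseudo-helix
docked under the TM6/TM7 intracellular face.

`generateTrajectory()` adds, in a fixed order under one seed:

* **conformational states**: frames drawn over `k*` states; states beyond
  the first rigidly offset the atoms of chosen subsegments (default TM6)
  by a fixed magnitude in state-specific directions;
* **correlated displacements**: each plant group shares a scalar latent
  `z`; member `m` displaces one residue along its feature axis by
  `amplitude * (rho z + sqrt(1 - rho^2) eps_m)` with `rho` computed
  analytically so that the *measured* feature correlation -- after
  attenuation by the coordinate noise (variance `2 sigma^2` on a
  distance) -- equals the target `r`. Realized correlations are recomputed
  from the emitted frames and stored in the ground truth, and tests
  compare against realized values to avoid sampling-noise flakiness.
  Single-member groups give planted *null* features;
* **a dihedral jump process**: a Markov chain over mode angles (stationary
  distribution = requested occupancies) drives the named ligand dihedral
  by rotating its distal atom set about the central bond each frame;
* **contact schedules**: a Bernoulli(`freq`) schedule per frame places the
  residue's closest side-chain heavy atom at 3.5 (contact) or 9 Angstrom
  (apart) from the ligand. Side-chain-only displacement keeps the TM
  backbone clustering blind to the contact schedule, as it should be;
* **rigid subsegment shifts**: a constant displacement of a subsegment,
  "inward" meaning along the unit vector from the subsegment COM to the
  pocket center;
* isotropic Gaussian noise of `sigma` (default 0.3 Angstrom) on every
  atom and frame.

Plants moving the same atom are rejected as conflicting. The default
condition pair (`makeConditionPair()`) mirrors the motivating contrast:
condition A carries a unimodal head chi1, inward TM1e/TM2e shifts (0.5 and
0.8 Angstrom), a 100% pocket contact and a pocket-TM-interface correlated
pathway; condition B a bimodal chi1 (80/160 degrees, 60/40), the same
contact at 46%, no shift, and a TM3-internal correlated pair. The contact
plant sits on a TM3e pocket residue rather than on the TM2e residue the
motivating study highlights, because TM2e already carries the rigid shift
plant and one residue cannot serve two positional plants.

### What the generator does and does not emulate

The generator reproduces the *statistical* structures the analysis stages
consume: discrete conformational states separated well above the noise
floor, pairwise distance correlations of known strength, bimodal dihedral
processes, Bernoulli contact schedules, rigid subsegment offsets. It does
not emulate physical protein mechanics: no bonded constraints, no
solvent, no anisotropic or time-correlated noise (frames are exchangeable
apart from the dihedral Markov chain), no coupling between plants, and
coarse geometry only. Passing tests therefore demonstrate that the
pipeline recovers known statistical structure at realistic noise levels
-- not that any biological conclusion about real trajectories is correct.

## Numerical choices and degenerate inputs

* Dihedrals: IUPAC sign convention, degrees in `(-180, 180]`; cis = 0.
* Distances are Angstrom throughout; masses from a built-in element
  table, unknown elements defaulting to 12.011 Da with a warning.
* The gap statistic errors on degenerate (all-identical) data where
  `log W_k` is undefined; k-means errors when `k` exceeds the number of
  (distinct) points; `selectK` returns `kMax` with a warning flag when
  the selection rule never fires.
* Constant series: `detectModes` reports a single zero-width mode;
  constant features correlate at `r = 0` with a flag.
* Empty feature regions warn and proceed; an entirely empty assembly is
  an error, as is an empty replicate feature matrix in the bootstrap.
* All randomness flows through explicit seeds; child seeds derive
  deterministically from the master seed and are recorded in reports.

## Problem sizes used by the test-suite and acceptance script

Synthetic study conditions use 2,000 frames at `sigma = 0.3` Angstrom
(1,000 for the shift-recovery and comparison runs), with 10 bootstrap
replicates of 10,000 resampled frames for consensus networks; gap
settings within bootstrap replicates are `kMax = 3`, `B = 10`,
`nInit = 5`, which resolve the planted one-to-three-state structures
while keeping a full consensus run in the minutes range. The blob
recovery checks use the classical setting `n = 300`, `sigma = 0.1`,
centers at least 10 sigma apart, `B = 50`. End-to-end determinism is
exercised on a 250-frame pair with 2 bootstrap replicates.

## Known limitations

* The consensus intersection is strict: a pair missing from a single
  replicate is dropped, so consensus size decreases with `nBoot`
  (monotonicity is tested). There is no frequency-weighted relaxation.
* The redundancy filter's tie-break (lexicographic on partner residues)
  is a convention; any deterministic rule would do, and siblings of a
  strongly correlated pair may legitimately replace it in other
  conventions.
* Pocket features are exempt from the separation/redundancy filters
  because their second participant is a ligand atom in a different
  numbering space; a network dominated by pocket features is therefore
  filtered only by the correlation threshold.
* The per-condition clustering mode (clustering each condition
  separately) is the default; merged-frame clustering with per-condition
  occupancy reporting is possible by concatenating trajectories but is
  not orchestrated by `runCompare()`.
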