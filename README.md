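# MDAllostery

Comparative analysis of molecular dynamics (MD) trajectories of GPCR-ligand
complexes, built for the question "what does one small chemical change to an
agonist do to the receptor?" The motivating system is the cannabinoid
receptor CB1R bound to indole-3-carboxamide synthetic cannabinoids whose
head moieties differ by a single methyl group, with a Gi alpha-subunit
docked at the intracellular face. The package takes coordinate trajectories
of two simulated conditions and locates their differences in the binding
pocket, the transmembrane (TM) bundle, and the correlated motions linking
the pocket to the receptor-G protein interface.

## What it computes

- **Conformational states**: frames are clustered on the pairwise
  superposition RMSD of the TM backbone, embedded by classical MDS; the
  number of states k is chosen by the gap statistic
  `Gap(k) = E*[log W_k] - log W_k` against a uniform bounding-box
  reference, selecting the smallest k with
  `Gap(k) >= Gap(k+1) - s_(k+1)`, `s_k = sd_k * sqrt(1 + 1/B)`. The most
  populated cluster's frames feed all downstream analyses.
- **Ligand contacts**: per-residue contact frequency (any heavy atom within
  6 A of any ligand heavy atom), residues reportable at >= 50% in at least
  one condition, and cross-condition differences >= 25 percentage points
  highlighted. Side-chain chi1 rotamer shifts > 70 deg (circular means) are
  flagged.
- **Subsegment conformation** (PIA-GPCR style): mass-weighted centers of
  mass of the 21 TM subsegments of the built-in CB1R scheme
  (`cb1rScheme()`: TM1e = 113-120 ... TM7i = 391-400), their
  between-condition displacements with an "inward" projection toward the
  pocket center, COM-distance distributions (TM1e-TM3e, TM2e-TM7e), and
  dihedral mode detection (circular KDE peaks with prominence and
  occupancy) plus 2D chi1/chi2 maps.
- **Allosteric network**: Pearson correlation over three feature regions
  (ligand-pocket polar-atom distances + head dihedrals; TM Calpha-Calpha
  distances <= 12 A mean + conserved-motif chi1; receptor/G-alpha interface
  distances), filtered by r >= 0.85, by residue separation
  `|X_i - X_j| >= 8 or |Y_i - Y_j| >= 8`, and by a subsegment redundancy
  rule keeping the maximum-gap representative; the **consensus network** is
  the intersection over 10 bootstrap replicates of the full
  sample-cluster-correlate-filter pipeline. Per-TM involvement percentages
  summarise each condition's network.
- **Synthetic ground truth**: a generator builds a coarse 7-TM
  receptor/ligand/G-alpha complex and trajectories with planted states,
  planted correlations of chosen Pearson r, bimodal dihedral processes,
  contact schedules and rigid subsegment shifts, so every stage is
  verifiable without any deposited trajectory.

## Worked example

```r
library(MDAllostery)

# two synthetic conditions: "MDMB-like" (extra methyl) vs "MMB-like"
pair <- makeConditionPair(seed = 42, nFrames = 500)
rep <- runCompareOnPair(pair,
  params = list(nBoot = 2, framesPerBoot = 1500, seed = 42,
                kMax = 3, B = 10, nInit = 5),
  outDir = "results/compare")

d <- rep$contacts$differences
d[d$resno == 194, c("resno", "freqA", "freqB", "diff", "highlighted")]
#>    resno freqA freqB  diff highlighted
#> 11   194     1 0.451 0.549           1

dc <- rep$conformation$deltaCom
dc[dc$subsegment %in% c("TM1e", "TM2e"), c("magnitude", "inward")]
#>   magnitude inward
#> 1      0.50   0.50
#> 4      0.79   0.79

rep$conformation$chi1ModesB
#>   mode location supportLo supportHi occupancy
#> 1    1     82.5      62.5     102.5 0.6473988
#> 2    2    162.5     147.5     177.5 0.3526012
```

Reading the output: the pocket residue planted at 100% vs 46% contact
frequency comes back as 100% vs 45.1%, a 54.9-point difference flagged by
the 25% highlighting rule; the planted 0.5 A (TM1e) and 0.8 A (TM2e)
inward shifts are recovered as 0.50 and 0.79 A, essentially fully along
the inward (pocket-ward) direction; and condition B's ligand head chi1 is
resolved into two rotamer modes near 80 and 160 degrees with roughly
60/40 occupancy, while condition A's is unimodal. `runCompareOnPair()`
also writes per-stage TSV tables, consensus-network edge lists and a
Markdown + JSON report under `outDir`.

A thin command-line front end over the same functions ships at
`inst/scripts/mdallostery.R`
(`simulate | cluster | contacts | conformation | network | compare`).

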