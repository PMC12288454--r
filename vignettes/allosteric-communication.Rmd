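---
title: "Allosteric communication, variant scanning and assay models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allosteric communication, variant scanning and assay models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allosterik)
```

This vignette is the package's account of its models, defaults and design
choices. The system of interest is a dimeric GntR/FadR-family
transcriptional repressor — *E. coli* DgoR, the D-galactonate repressor, is
the reference case — whose N-terminal winged helix-turn-helix DNA-binding
domains (DBD) and C-terminal effector-binding/oligomerization domains (EO)
communicate allosterically: effector binding at the EO end releases operator
DNA bound at the DBD end. The package analyses that communication in
molecular-dynamics-style trajectories, scans natural sequence panels for
substitutions, and quantifies the binding and growth assays used to
phenotype those substitutions.

## The synthetic trajectory generator

Real trajectories for this system come from hundreds of nanoseconds of
all-atom MD on an ~80,000-atom solvated complex. At desk scale the package
replaces them with Gaussian samples from an anisotropic elastic network
model (ANM) of a toy dimer, for one decisive reason: *the second moments are
then known exactly*, so every downstream statistic — RMSF, dynamic
cross-correlation (DCC), PCA eigenvalues — has an analytic oracle and the
analysis stack can be tested quantitatively rather than by eyeball.

**Geometry.** Each monomer is a Cα bead chain with uniform ~3.83 Å bonds:
the DBD and EO domains are compact bodies (ideal α-helical segments, radius
2.3 Å, rise 1.5 Å, 100°/residue) joined by an extended zig-zag linker, so
all cross-domain contact runs through the linker. The two monomers are
related by a two-fold rotation about the EO centroid plus an 8 Å offset:
they dimerize through their EO domains with the DBDs at opposite ends — the
domain arrangement of FadR-family dimers. The zig-zag (rather than straight)
linker matters: a straight bead run leaves free torsion axes in the spring
network and the model degenerates. The default monomer length is 20 residues
for demonstration suites (DBD 1–6, linker 7, EO 8–20 under the proportional
default map) and 229 for full-length panels.

**Sampling.** Springs (default constant 1, in reduced energy/Å² units) join
every bead pair within the contact cutoff, default 7 Å — chosen with the
geometry so that the folded domains share no direct cross-domain contacts;
planted couplings add further springs. Displacements are drawn from
`N(0, τ·H⁺)` where `H` is the 3N×3N ANM Hessian, `H⁺` its pseudo-inverse
with the six rigid-body modes removed (eigenvalue tolerance 1e-8 × largest),
and `τ` the temperature scale (default 1 Å²; 0 freezes the structure). A
network with more than six near-zero modes — disconnected, or hinged about a
free axis — is rejected with an error naming the offending residues.
Sampling is bit-reproducible given the seed carried in the trajectory
specification object.

**Ligand states.** The four conformational states are encoded as planted
spring sets (`state_couplings()`):

* **E** (effector-bound): all-pairs springs (k = 5) between the central 7
  residues of the two EO domains — the effector pockets sit at the dimer
  interface, and occupied pockets rigidify the dimer core.
* **D** (DNA-bound): springs (k = 5) between the central 2 residues of each
  DBD — one operator duplex clamps both recognition helices.
* **ED**: both sets. **APO**: none.

A point worth recording because it is counterintuitive: in a mode-projected
Gaussian network, planting a spring *directly between* the DBD and EO does
**not** raise their correlation — with rigid-body motion removed, two
coupled bodies can only anticorrelate, and stiffening their link shrinks
exactly the hinge modes that carried the signal. What raises DBD×EO
coupling is constraining the *ligand sites* (third bodies), which is also
the physically meaningful statement: ligand binding at one end modulates the
dynamics of the other. This was established on exact analytic covariances
during design, and it is the behaviour the planted-effect tests verify.

**Variants** enter the dynamics layer as scale factors on the planted
springs — a fixture, not a measurement: the effector-response-impaired
linker variant engages the effector springs at 0.25× strength, the
operator-binding-impaired EO variant engages the DNA clamp at 0.25×.

**Sequence panels.** `generate_sequence_panel()` builds a seeded random
229-residue reference carrying the stated wild-type residue at every planted
position, then plants each substitution into disjoint random carrier sets.
The packaged census (`dgor_variant_census()`) lists the twelve substitutions
observed across a reference panel of 340 sequenced natural isolates,
totalling 42 carrier isolates. Named carriers are known for four of the
twelve (2, 2, 1 and 2 isolates); the remaining 35 carriers are distributed
5/5/4/5/4/4/4/4 over the other eight substitutions as a packaged default —
only the total is established, so that split is a fixture, not biology.
What the panel does *not* emulate: real isolate panels contain indels,
truncations, length variants and sequencing artefacts; here every record is
full-length by construction, so the exact-length filter is exercised by
dedicated fixtures rather than by the default panel.

**Assay curves.** `generate_curve()` evaluates the chosen model (Hill, 1:1
isotherm, or lag+exponential growth) and applies multiplicative Gaussian
noise `y = f(x)(1 + ε)`, `ε ~ N(0, cv)` — multiplicative because the
responses are positive and plate-reader error scales with signal. Default
noise is 5 %. Synthetic curves carry their generating truth for test use.

## Trajectory statistics

Frames are superposed onto the user-supplied reference (not an iterated
mean, which is available as an option) by the Kabsch singular-value
solution with a determinant guard, so only proper rotations are applied and
chirality is preserved. All analyses are Cα-based. RMSD is computed per
frame against the reference; RMSF per residue about the trajectory mean,
`RMSF_i = sqrt(⟨|r_i − ⟨r_i⟩|²⟩)`. No equilibration window is discarded by
default — the synthetic sampler is stationary — but a frame slice is
accepted for real data.

## Correlation, essential dynamics, porcupine fields

DCC uses full 3-vector displacement dot products per residue (not
per-coordinate),

$$C_{ij} = \frac{\langle \Delta r_i \cdot \Delta r_j\rangle}
  {\sqrt{\langle|\Delta r_i|^2\rangle\langle|\Delta r_j|^2\rangle}},$$

computed over the full trajectory (no windowing). Zero-variance residues get
unit diagonal and zero off-diagonals, flagged. `interdomain_coupling()`
summarizes mean and max |C| per domain-pair block, split into intra- and
inter-monomer pairs; the DBD×EO block mean is the package's scalar readout
of allosteric coupling strength.

Essential dynamics is the eigendecomposition of the 3N×3N coordinate
covariance (denominator n−1). Eigenvector sign is fixed by making each
mode's largest-magnitude component positive, so the derived displacement
fields are reproducible. The porcupine field scales each residue's PC
components by the projection range (max − min) observed along that mode —
the spread the trajectory actually explored — because the field's arrow
convention in the source figures is not stated; an explicit scale override
is available. The default magnitude cutoff is 3.5 Å, matching the arrow
cutoff used in PC1 motion figures.

## Dynamical networks and suboptimal paths

Nodes are residues; an edge joins residues whose Cα atoms are within 8 Å in
at least 75 % of frames (sequence neighbours within a chain excluded by
default) and whose |C| is at least 0.01; its weight is `w = −ln|C|` with the
natural log, the standard dynamical-network convention. The 8 Å/75 %
contact criterion replaces the heavy-atom 4.5 Å convention, which has no
meaning on Cα-only models; both knobs are configurable.

Communities come from divisive Girvan–Newman clustering: repeatedly remove
the edge of maximal weighted edge betweenness (weights = `w` as distances,
floored at 1e-6), and return the dendrogram level maximizing weighted
modularity computed on the original graph with affinities `1/max(w, 1e-6)`.
Betweenness uses distance semantics and modularity affinity semantics, which
is why the loop is implemented on igraph primitives rather than by a single
library call; ties are broken by lexicographic node order, so the partition
is deterministic and permutation-invariant up to community relabeling.

Suboptimal paths: with sources defaulting to all DBD residues and sinks to
all EO residues (both monomers; a single-representative mode exists for
large systems), `L_opt` is the globally shortest source→sink weight
(Dijkstra), and the ensemble is every simple path with weight ≤ `L_opt + δ`,
found by depth-first branch-and-bound pruned with exact remaining-distance
lower bounds from a single multi-sink Dijkstra pass. The default tolerance
is δ = 0.2·L_opt — the source analyses do not print theirs, so it is an
exposed configuration default, not a reproduction. Results are capped at
100,000 paths with an explicit truncation flag. Path-length histograms bin
at width (max − L_opt)/20 with the origin fixed at `L_opt`. The enumerator
is verified against exhaustive simple-path enumeration on dozens of random
graphs; more paths mean more alternative communication routes, and
right-shifted length distributions mean delayed transmission.

On the packaged demonstration suites the bound states consistently raise the
DBD×EO block |C| mean above APO, and path counts differ across states; the
count *ordering* among the four states is seed- and δ-sensitive on a
40-residue toy and is reported by `path_statistics()` rather than asserted
as a fixed law.

## Assay models

* **Hill (EMSA)**: `f = Pⁿ/(K_Dⁿ + Pⁿ)`; the gel-shift titrations this
  models report apparent K_D near half-saturation. Hill coefficients are
  treated as free fit parameters throughout, never asserted.
* **1:1 isotherm (MST)**: the exact quadratic solution for complex formation
  at fixed total protein. At 500 nM protein with K_D in the tens of µM the
  simple isotherm would be adequate, but variants with stronger binding are
  not guaranteed to stay in that regime, so the quadratic is the default and
  the simple form is its P→0 limit.
* **Fitting** (`fit_binding()`): Levenberg–Marquardt least squares
  (minpack.lm), deterministic initialization (K at the x whose response is
  nearest 0.5, n = 1), standard errors from the Jacobian, non-convergence
  flagged. No random restarts, so fits are reproducible by construction.
* **Release titrations**: "complete release" is a bound fraction ≤ 0.05 at
  the smallest tested concentration, a quantitative stand-in for a
  qualitative gel call; the threshold is configurable.
* **Growth** (`fit_growth()`): growth rate is the ln(OD) slope over the
  sliding 5-point window maximizing R² (positive slopes only); doubling time
  is ln 2 / rate. Lag defaults to the first time smoothed OD exceeds twice
  its initial value — robust to 96-well noise but biased upward by about one
  doubling time, since the culture must double before it can cross the
  threshold; the tangent-intercept definition (where the exponential-window
  line crosses the initial log-OD) is exact on clean data and available via
  `lag_method = "tangent"`.
* **Fold ratios** round to the nearest integer fold and refuse mismatched
  units.

## Problem sizes and numerical choices

The packaged analyses run on a 20-residue-per-monomer dimer (120 Cartesian
degrees of freedom), a few hundred to 5,000 frames, 340-sequence panels, and 11–16
point titrations; these sizes make every statistic testable against its
oracle in seconds while leaving the algorithms identical to what larger
inputs would use. Pseudo-inversion tolerance is 1e-8 × the largest Hessian
eigenvalue; weight floors of 1e-6 guard the betweenness and modularity
transforms; path weights are compared at 1e-9 slack; PDB output rounds to
the format's 3 decimals, and the round-trip test asserts exactly that
precision.

## What passing tests do and do not show

The synthetic generator produces stationary, harmonic, solvent-free
dynamics with exactly Gaussian fluctuations; real trajectories are
anharmonic, non-stationary, and carry water- and ion-mediated couplings.
Passing the analytic-recovery and planted-effect tests therefore shows the
*analysis stack* is correct and sensitive, not that any particular biological
system behaves like the toy. Likewise the panel census recovers planted
truth — it validates the scanning procedure, while per-variant carrier
counts beyond the published total remain fixtures. The assay-model tests
calibrate recovery under the stated noise model only.

## Known limitations

No all-atom force fields, solvent, thermostats or docking (out of scope by
design); no MSA-based variant calling (pairwise-vs-reference only — an MSA
mode is a natural extension); no time-lagged correlations or windowed DCC;
community detection at O(E²V) is meant for residue networks of a few
hundred nodes, not proteome-scale graphs; path enumeration is exponential in
the worst case and relies on its cap and flag for pathological inputs.
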