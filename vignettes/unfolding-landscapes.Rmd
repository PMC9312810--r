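---
title: "Statistical free-energy landscapes for protein unfolding: methods and design"
author: "unfoldscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical free-energy landscapes for protein unfolding: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unfoldscape)
```

# The model

`unfoldscape` analyses thermal-unfolding trajectories of proteins through
a representation in *RMSD space*. The pairwise Cα RMSD matrix over all
frame pairs (each entry the minimum RMSD over rigid motions, computed by
Kabsch SVD superposition) is a metric on conformations; classical
(Torgerson) multidimensional scaling — double centering of the squared
distances followed by eigendecomposition — embeds the frames in a
low-dimensional Euclidean space that preserves those distances as well as
any linear method can. Consecutive-frame displacements in this space are
*MD step vectors*. Two properties make this representation useful:

* the native state appears as a tight cluster of step-vector terminals, so
  the *first point of exit* — the onset of unfolding — is a detectable
  jump: the first frame whose incoming step norm exceeds
  `mean + c * SD` of an early reference window and which stays outside the
  native cluster's radius for `m` consecutive frames (a leader-style
  sequential rule);
* *every* frame contributes to the landscape, not only frames near a
  preselected order parameter, so late, highly unfolded structures are
  represented on the same footing as the native basin.

The **statistical free energy** over a 2D grid on two embedding axes is

$$\Delta F_{ij} = -RT\,\ln\,(P_{ij}/P_0),$$

with $P_{ij}$ the bin population, $P_0$ the maximum population and
$R = 1.9872\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$. The modal bin sits at
zero by construction; empty bins carry an `NA` sentinel and are
impassable to path extraction, since unsampled regions carry no free-energy
information.

The **unfolding reaction coordinate** is extracted as a discrete path from
the native modal bin toward the unfolded region: at each step, among the
8-neighbours making monotone progress toward the end bin, the one with the
lowest $\Delta F$ is taken — on a smooth surface this is the steepest
feasible direction, perpendicular to the isoenergy contours. Its profile
gives the activation free energy $\Delta F^\ddagger$ (profile maximum
minus the start value), and the **channel index**: the fraction of the
path arc lying within $RT$ of the barrier top. A narrow, sharply peaked
barrier scores a small channel index; a broad flat barrier — an extended,
malleable transition state whose member structures vary — scores a large
one. Post-barrier local minima are reported with their well depths
(distance below the lower of the two adjacent maxima); a minimum counts as
a thermally stable intermediate only when its depth exceeds a stability
threshold, by default $RT$, because a well much shallower than the thermal
energy cannot hold a population. The unfolding rate uses transition-state
theory with the order-of-magnitude prefactor conventional for protein
folding, $k_u = 10^{6}\,\exp(-\Delta F^\ddagger/RT)$ s$^{-1}$, evaluated
exactly as written.

**Contacts and the molten globule.** Native contacts are Cα pairs within
8.0 Å at sequence separation $|i-j| \ge 3$ in the native frame. Per frame,
the native-contact count $Q$, the total contact count at the same
definition, and the radius of gyration populate the native-vs-total
contact plane, in which native, molten-globule and unfolded populations
separate. A molten globule — native-like secondary structure without
native tertiary packing — is detected frame-wise as: secondary-structure
persistence $\ge$ 0.6, Rg expanded by $\ge$ 5% over native, and a
native-contact fraction floor of 0.3; native frames instead require a
contact fraction $\ge$ 0.8 without expansion. The transition-state
ensemble is demarcated from the native-exit frame to the end of the last
contiguous molten-globule run anchored at the exit, with runs separated by
at most 10 frames merged (frame-level classification flickers; a
demarcation should not).

Secondary structure is assigned from Cα geometry alone, because the
package's validation models are Cα-only: helix from the
$d(i,i+3) \in [4.8, 5.6]$ Å and $d(i,i+4) \in [5.8, 6.6]$ Å windows of an
ideal α-helix over 5-residue runs; strand from local extension
($d(i-1,i+1) \ge 6.4$ Å) plus a non-local partner within 5.5 Å in runs of
three or more. Frame-level persistence is scored over residues that are
natively structured (H or E): natively-coil residues would otherwise keep
"matching" C in fully unfolded frames and put a floor under the score.

**φ-values.** For a mutant panel,
$\varphi = (\langle Q\rangle^{TS}_{mut} - \langle Q\rangle^{TS}_{wt}) /
(\langle Q\rangle^{F}_{mut} - \langle Q\rangle^{F}_{wt})$ over
transition-state and folded ensembles. The global native-contact form is
the default; a per-mutant native-set variant sits behind
`nativeSetMode = "per-mutant"` in `phiBatch()`, since residue-local
definitions exist in the field and the choice is not universal. A
denominator below `eps = 0.5` contacts — beneath the resolution of a
single contact — flags φ as undefined rather than throwing, so batch runs
complete; φ outside [0, 1] is flagged, never clipped.

# Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| embedding dimension `k` | 3 | – | three axes suffice for unfolding geometry; 2D projections are plotted |
| grid `nBins` | 50 | per axis | resolves a 3 kT barrier to a few % on 10⁶-point samples; too fine a grid on a short trajectory fragments the landscape |
| exit `c` | 5 | SD multiples | conservative jump detection, robust to noise in the reference window |
| exit `m` | 10 | frames | transient excursions should not count as exits |
| reference window | first 5% | of frames | assumed-native calibration region |
| contact cutoff | 8.0 | Å | common Cα contact radius; exposed because no single convention exists |
| `minSeqSep` | 3 | residues | excludes trivially-near backbone neighbours |
| `qHi`, `qFloor`, `qLo` | 0.8, 0.3, 0.6 | fractions | native tightness, molten-globule contact floor, structure persistence |
| `expansionMin` | 1.05 | Rg ratio | an expanded state must be measurably expanded |
| gap tolerance `G` | 10 | frames | merges flickering molten-globule runs into one region |
| stability threshold | RT | kcal/mol | wells shallower than thermal energy are not intermediates |
| TST prefactor | 10⁶ | s⁻¹ | protein-folding order-of-magnitude convention |
| φ guard `eps` | 0.5 | contacts | below one contact the ratio is noise |
| analysis temperature | 498 | K | thermal-unfolding simulation convention |

# The synthetic-data generator

Real unfolding trajectories at this scale are cluster products and are not
shipped; the generator replaces them with ground-truth inputs of two
kinds.

**Brownian samples on analytic surfaces.** Overdamped Langevin
(Euler–Maruyama) sampling of a harmonic well, a quartic double well
$V = h((x/a)^2-1)^2 + \kappa y^2/2\ (+\,\mathrm{tilt}\cdot x)$, or a
*channel* variant whose barrier top is replaced by a flat plateau of
length $L$ at $V = h$. At equilibrium the samples follow
$\exp(-V/kT)$, so the landscape stack can be checked against closed
forms: the double well's barrier is $h$ exactly, and the channel's
analytically flat top gives ground truth for the channel index. The tilt
term exists so the two wells can carry unequal Boltzmann weight, making
the quadrature cross-check of well occupancy non-trivial.

**Toy-protein unfolding.** A Cα-only model with one ideal helix
(rise 1.5 Å, radius 2.3 Å, 100°/residue), a three-residue linker and an
antiparallel hairpin (3.8 Å strand spacing, 4.8 Å inter-strand) packed
against the helix. Trajectories follow a three-phase schedule: native
coordinates plus Gaussian noise; then a plateau in which the hairpin is
rigidly translated away from the helix until Rg/Rg$_{native}$ hits the
scenario's expansion factor (default 1.14 — segment-internal geometry and
hence secondary structure intact, tertiary packing lost: a molten
globule); then interpolation toward a self-avoiding random coil with the
mixing fraction ramping from one third of `finalDisorder` to
`finalDisorder`. The onset jump makes the molten-globule/unfolded boundary
crisp enough to score demarcation recovery at the few-frame level while
native contacts still decay monotonically in the mean;
`finalDisorder = 0` freezes the plateau. The generator records its ground
truth — exit frame, plateau range, per-frame phase, realized contact
retention — in the trajectory metadata.

**Mutant ensembles.** `makePhiEnsembles()` builds wild-type folded
(native + noise) and transition-state (expanded conformation + noise)
ensembles, and mutants whose mean native-contact counts are shifted by a
prescribed integer: whole residues are relocated radially outward so that
the formed-contact degrees of the relocated set sum exactly to the
request, with a minimal single-pair displacement fallback for remainders,
and an "unachievable shift" error otherwise. Before noise is added, every
native-pair distance is pushed out of a ±0.3 Å band around the cutoff, so
frame noise cannot flip marginal contacts and realized ensemble means sit
within a fraction of a contact of the request. Ground-truth φ is
tsShift/fShift by construction.

**What the generator does *not* emulate.** No force field, no solvent, no
kinetics: the native exit is a single discontinuous jump rather than a
diffusive barrier crossing. Consequently a synthetic trajectory's
landscape has *disconnected* native and plateau basins — no sampled
corridor crosses the gap — and barrier statistics on such landscapes are
sampling-depth artifacts, not physics. Passing the recovery tests
demonstrates that the analysis machinery recovers planted structure
(exits, plateau bounds, expansions, φ shifts) and that the landscape stack
is quantitatively correct *on densely sampled surfaces*; it does not
demonstrate that real MD data will be as clean, and barrier work on real
trajectories needs sampling dense enough to populate the transition
corridor.

# Numerical choices

* **Integrator bias.** Euler–Maruyama inflates the sampled variance of a
  well by roughly $dt\,V''/2$ relative, which propagates into a
  systematic underestimate of barrier heights. Validation studies
  therefore run at `dt = 0.002` (with friction 1), where the bias on a
  3 kT barrier is below the few-percent statistical noise of 10⁶-step
  runs; at `dt = 0.01` the bias reaches ~5% and dominates. A divergence
  aborts with an error naming `dt`.
* **Negative MDS eigenvalues.** RMSD matrices are near- but not exactly
  Euclidean; negative eigenvalues are clamped out of the embedding and
  reported as a magnitude fraction (`negativeFraction`). The explained
  fraction is computed over positive eigenvalues only.
* **Binning.** Half-open bins with the global top edge closed; bounds
  default to the data extent padded by one bin. Modal-bin ties break at
  the lowest linear index, for determinism.
* **Path extraction on sparse grids.** The greedy
  perpendicular-to-contours walk requires monotone progress; where
  unsampled bins block it (typical when a short trajectory is binned
  finely) the discrete minimum-free-energy route — the Dijkstra minimax
  path over occupied bins, which the greedy walk approximates on smooth
  surfaces — is used instead. Only genuinely disconnected endpoints error,
  naming the blocking region. The default end bin is the farthest
  occupied bin within the start's connected component.
* **Channel-index arc weights.** Each profile point owns half of its two
  adjacent segments (trapezoid attribution), so the index is an arc
  fraction, not a point count.
* **Degenerate inputs.** All-zero distance matrices embed at the origin;
  coincident or collinear atom selections error in superposition; a
  single-bin path has zero activation and an undefined channel index;
  an exit-less trajectory yields a no-exit report rather than an error.
* **Indexing.** Frames and residues are 1-based internally (R
  convention); user-facing reports carry source-PDB residue numbering so
  per-mutant reporting cannot go off by one.
* **Reproducibility.** Every generator takes an explicit seed, uses one
  private RNG stream, and restores the caller's stream; pipeline
  replicates derive per-replicate seeds deterministically from the base
  seed. Pipeline reruns with the same configuration are byte-identical.

# Validation scale

The shipped tests exercise the stack at sizes a laptop core handles in
minutes, chosen so that statistical tolerances are meaningful: 10⁶-step
Brownian runs for barrier recovery (≈2–9% observed error against the
3 kT closed form), twenty 10⁶-step replicate pairs for channel
discrimination, twenty 250-frame trajectories for exit detection,
one 500-frame trajectory for demarcation recovery, and a 13-mutant panel
for φ recovery. `scripts/acceptance.R` re-runs all of these from a single
seed.

# Known limitations

* PDB and DCD input only; no XTC reader exists in the R stack this
  package builds on.
* The landscape grid is 2D over a chosen axis pair; a third embedding
  axis is marginalized by axis choice rather than binned.
* Only contact-loss (non-positive) shifts are supported when constructing
  mutant ensembles; a mutant with *more* native contacts than wild type
  has no synthetic analogue here.
* The secondary-structure assignment is a Cα pseudo-geometry rule, not a
  hydrogen-bond method; on real all-atom data a DSSP-class assignment
  should replace it.
* TST rates inherit the order-of-magnitude uncertainty of the 10⁶ s⁻¹
  prefactor; they are comparative, not absolute, numbers.
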