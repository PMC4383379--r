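---
title: "Geometry and dynamics of transmembrane helix oligomers: methods"
author: "tmhelix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry and dynamics of transmembrane helix oligomers: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmhelix)
```

## Scope and model

Single-pass membrane receptors transmit signals through configurational
changes of their transmembrane (TM) helices: association/dissociation
(*translation*), axial sliding (*piston*), changes of the inter-helix
crossing angle (*pivot*) and changes of the interacting helix face
(*rotation*). `tmhelix` implements the structural descriptors needed to
quantify these modes for helix dimers and trimers and their juxtamembrane
(JM) coiled-coil extensions, together with trajectory-level measures of
convergence and flexibility, a similarity measure for grouping candidate
models, and a reduced knobs-into-holes (KIH) detector.

Because no experimental structures exist for the systems this toolset
targets, every analysis stage is validated against *synthetic structures
with known ground truth*: the package's generators build ideal helices,
dimers/trimers with prescribed geometry, Crick-parameterized coiled coils,
pseudo-membrane slabs, and noisy or drifting trajectories, and the test
suite checks that analysis recovers what the generator imposed.

## Coordinate conventions

All coordinates are in a right-handed frame with the membrane normal along
+z (extracellular side +z). Helix segments selected for analysis are
renumbered to start at 1, so "residue 4" always means the 4th residue of
the selected segment (about one turn into the membrane) and "residue 11"
a position near the TM center. Angular conventions:

* **Crossing angle** (signed, in (−90°, 90°]): magnitude is the acute
  angle between the two axis directions; the sign is the handedness read
  from the dihedral about the closest-approach vector — **negative =
  right-handed crossing, positive = left-handed**. The sign flips under
  reflection and is invariant under chain swap. Values beyond ±90° are
  folded by the direction-flip identity Ω → Ω ∓ 180°.
* **Rotation angle** (in (−180°, 180]): azimuth of a reference residue's
  CA about its helix axis, measured from the inter-helix approach vector
  projected into the plane normal to the axis; positive sense is
  clockwise viewed from the N-terminal side. In time series the
  *initial-frame* approach vector is held fixed and the frame-0 value is
  subtracted, so the starting structure reads zero by construction. For a
  single structure, its own approach vector is used. The radial vector
  uses CA positions (the only atom guaranteed present in every model).
* **Register (piston) shift**: each residue's axial coordinate is measured
  along its *own* axis from the closest-approach foot point, and the
  difference (B − A) at an equivalent residue is reported. Measuring from
  the mutual-perpendicular feet makes the value invariant under the
  crossing angle; the naive alternative (projection difference along the
  mean axis direction) carries a cos(Ω/2) bias plus a radial term of up to
  a CA radius and cannot recover the generator's shift at large crossings.
  One canonical turn = 5.4 Å.
* **Handedness of bundles** (clockwise/anticlockwise): sense of rotation
  of the chain positions about the bundle axis along its length, viewed
  from the N-terminal side. Classical left-handed coiled coils are
  anticlockwise under this convention, and mirror reflection flips the
  call.

## Helix axis fitting

`fit_helix_axis()` fits a **full parametric regular helix** (axis
direction and position, radius, phase, twist and rise per residue; nine
parameters) to the segment's CA positions by Levenberg–Marquardt least
squares. The initial estimate is closed-form: for a regular helix the
bisector `(CA[i−1] − CA[i]) + (CA[i+1] − CA[i])` points exactly at the
axis, so the direction is the null eigenvector of the summed
unit-bisector outer products, and the axis point follows from a circle
fit in the normal plane. The refined fit has zero residual on an ideal
helix (machine-precision recovery of the construction axis) and is the
maximum-likelihood axis under isotropic coordinate noise; at 0.3 Å
per-coordinate noise on a 20-residue helix the direction error is
typically ~0.6° (max ~1°over seeds). An earlier design based on
sliding-window centroid chains plus a total-least-squares line was
rejected: the centroid chain of an ideal helix is itself a small helix
(radius ≈ 0.075 Å for a 7-residue window), so that estimator can be exact
neither on ideal helices nor statistically efficient under noise.

Kinked or bulged helices (poly-Gly, Pro) are fitted with the same global
model; no discrete kink detection is attempted. Irregularity shows up as
`rms_deviation`, the CA spread about the mean radius.

Two fitted axes meet in the standard mutual-perpendicular construction.
Below an inter-axis angle of about 0.06° the direction of the mutual
perpendicular is numerically degenerate (it is dominated by the fit's
own tolerance), so the parallel-limit tie-break — the perpendicular
dropped from helix A's first-residue projection — is used there; it is
the continuous limit of the skew case.

## Normalized RMSD and model grouping

Candidate models of homologous helix pairs are compared over a central
residue window (default residues 11–25 of renumbered extended peptides;
a centered 14-residue core for TM-only models) after best-fit backbone
superposition with no outlier rejection. Residue correspondence comes
from sequence identity at equal renumbered positions (an explicit pairing
may override), and the aligned-atom RMSD is scaled by the backbone atoms
that could not be used:

RMSD_norm = RMSD_align × (N_bb,1 + N_bb,2) / (N_a,1 + N_a,2)

so a low RMSD resting on few identical residues is penalized. Two
identities pin the formula: full identity gives RMSD_norm = RMSD_align
exactly, and identity at half the positions doubles it. Homodimer chain
labels are arbitrary, so both chain pairings are evaluated and the
smaller RMSD_norm kept. Grouping is single-linkage over the graph with
edges below the closeness threshold (default 3.5 Å); each group's
representative minimizes the within-group distance sum (ties broken by
label order). Raising the threshold can only merge groups, never split
them.

## Trajectory metrics

**Geometry time series.** Per frame: central-region backbone RMSD to the
starting structure after superposition, crossing angle from per-frame
fitted axes, and rotation angles against the fixed initial approach
vector. Axis-fit failures are flagged gaps (NA), not fatal.

**Equilibration.** Means and standard deviations are taken over a
trailing window (default 250 ns). A trajectory passes when the RMSD
series' SD is below 0.5 Å, crossing angles stay within ±10° of the window
mean, and rotation angles within ±25°. "Within ±X" is interpreted as a
range statement, max |value − mean| ≤ X (an SD-based variant is
selectable); tightening any threshold can only turn passes into fails.

**RMSF.** Per-residue RMS fluctuation of the selected atoms about the
trajectory-average structure, after superposing each frame on the
alignment CA set (frames are aligned to frame 1, the average formed, and
frames re-aligned to that average once).

**NH order parameters.** S² is estimated per non-overlapping time block
(default 10 ns) and averaged over blocks, so motions slower than the
block do not depress S² — the block length acts as the correlation-time
cutoff that makes the values comparable to solution NMR. Within a block,
after optional superposition on the central-region CA atoms (removing
global tumbling, as an implicit-membrane proxy), the unit NH vectors
enter the second-moment estimator
S² = 3/2 (⟨x²⟩² + ⟨y²⟩² + ⟨z²⟩² + 2⟨xy⟩² + 2⟨xz⟩² + 2⟨yz⟩²) − 1/2.
An independent route (`method = "p2"`) estimates the plateau of the P2
autocorrelation from frame pairs at long deterministic lags; the two
agree within 0.05 on cone-model trajectories. Missing amide hydrogens are
reconstructed at 1.01 Å along the in-plane bisector-opposed direction of
the C(prev)–N and CA–N bonds (idempotent when H exists); prolines and
chain-initial residues are omitted with a notice. The analytic oracle is
the cone model: NH vectors uniform within a half-angle-θ cone give
S² = [cos θ (1 + cos θ)/2]², i.e. 1 when rigid and 0 on the hemisphere.

**Contacts and membrane distances.** Ser/Thr sidechain contacts are
tracked as the per-frame minimum distance over cross-chain OG/OG1 pairs,
with contact fractions at 3.5 Å (hydrogen-bond-like) and 5.0 Å
(persistent contact). The JM-tail-to-membrane distance is the per-frame
Euclidean distance from the heavy-atom center of mass of the tail's last
three residues to the nearest headgroup atom of the chosen leaflet.

## Synthetic data: what it emulates, and what it does not

The generators reproduce the *geometry* and the *statistics* the
analyses measure, not the physics that produces them:

* `make_ideal_helix()` — canonical α-helix (1.5 Å rise, 100° twist,
  2.3 Å CA radius, i.e. 3.6 residues and 5.4 Å per turn). CA atoms are
  exactly parametric; N and C ride companion helices at offsets derived
  from an internal-coordinate build (φ = −57°, ψ = −47°); O, H, CB and
  Ser/Thr OG/OG1 are placed by standard peptide geometry. Sidechains stop
  at CB plus the hydroxyl oxygens — enough for the contact and KIH
  analyses, nothing more.
* `make_dimer()`/`make_trimer()` — parallel ideal helices separated along
  their mutual perpendicular, with the crossing imposed by rotating helix
  B about that perpendicular at the midpoint (right-hand rule about the
  A→B direction, making positive angles left-handed), per-helix azimuthal
  rotations measured from the partner-facing direction, and the register
  applied along the helix axis. Trimers tilt each helix tangentially
  around the bundle so all three pairwise crossings match the request,
  with the bundle radius solved for the requested pairwise separation.
  Every parameter is exactly recoverable from the noise-free output.
* `make_trajectory()` — three fluctuation models: independent Gaussian
  per-coordinate noise (`sigma_atom`); *parameter jitter*, which rebuilds
  each frame from the dimer spec with the crossing/rotations/register
  drawn around their base values (the honest emulation of collective,
  equilibrated fluctuations — per-atom white noise makes single-residue
  angles far noisier than collective motion at equal RMSF); and linear
  *drift* of a named parameter, the non-equilibrated control. Study
  conditions used in the tests and analyses: crossing SD 3°, rotation SD
  6°, register SD 0.2 Å (rotation fluctuations roughly twice the
  crossing's, mirroring the ±10°/±25° criteria ratio), 60 frames × 5 ns,
  and a 40° crossing drift as the failing control.
* `make_coiled_coil()` — Crick-parameterized bundles: each chain's minor
  helix (3.5 residues/turn in the supercoiling frame) is wound on a
  superhelix of given radius and pitch; positive pitch = left-handed
  supercoil. Heptad `a`/`d` positions carry leucine facing the core, so a
  well-formed bundle shows KIH packing by construction.
* `make_membrane_slab()` — two square grids of headgroup pseudo-atoms at
  √(area-per-lipid) spacing (defaults: 64.3 Å² and 72 per leaflet). No
  tails, no dynamics.

None of this emulates force-field physics, lipid chemistry, or the
sequence-dependent distortions of real TM helices. Passing tests
therefore demonstrate that the *measurements* are correct and their
conventions self-consistent — not that any biological conclusion about a
real receptor would be reproduced.

## Knobs-into-holes surrogate

The KIH detector is a deliberate simplification of full coiled-coil
packing analysis: the sidechain is its CB position (CA for Gly), and a
residue is a knob when that center lies within the cutoff (default
7.0 Å; 8.5 Å as the permissive variant) of the four sidechain centers
forming the `j−3/j, j+1/j+4` diamond on a partner helix. A chain pair is
called coiled-coil only with at least two knobs in *each* direction —
the reciprocity that keeps single contacts from counting as an
interface. The knob set grows monotonically with the cutoff. The
surrogate is validated only against the Crick-generator oracle; it does
not reproduce full-atom packing-angle classification.

## Numerical choices and degenerate inputs

* Angles are reported in degrees; wrapping uses (−180°, 180°] with the
  boundary mapped to +180°.
* Near-parallel axes (< ~0.06°) use the parallel-limit closest-approach
  tie-break (above); coincident axes are an error.
* A reference CA on the axis, anti-aligned axes in a register
  comparison, and chains that are not roughly parallel in a handedness
  call are errors, not silent results.
* Axis fitting needs ≥ 8 residues (two turns); segments enforce this.
* Generator randomness is seeded explicitly (`noise_spec`,
  `make_cone_nh_trajectory`); identical seeds give bit-identical output
  and the caller's RNG state is restored.
* Block averaging for S² uses non-overlapping blocks; the final partial
  block is merged into the last full one.

## Problem sizes

The shipped analyses and tests run at desk scale, chosen so the full
suite completes in minutes while keeping every estimator in its
asymptotic regime: 24-residue helices, 8–12 Å separations, trajectories
of 60 frames × 5 ns for equilibration logic, 400–2000 frames for
fluctuation profiles, and 10⁵ frames for the cone-model S² oracle (where
the closed form is matched within 0.02).

## Known limitations

* Rotation-angle sign: the positive sense (clockwise from the N-terminal
  side) is a package convention; published tables using other conventions
  may differ by a global sign. Tests assert differences and
  equivariances, never absolute signs.
* The identity-based residue correspondence assumes the compared models
  are pre-aligned by the renumbering convention; non-homologous lengths
  are out of scope.
* The KIH surrogate ignores sidechain atoms beyond CB and performs no
  packing-angle classification.
* Multi-model PDB is the only trajectory exchange format; binary
  trajectory formats would sit behind the same `trajectory()` contract.
* The pseudo-membrane is static; lipid dynamics, tails and
  area-per-lipid monitoring are out of scope.
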