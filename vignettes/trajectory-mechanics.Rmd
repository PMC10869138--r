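---
title: "Trajectory mechanics of TCR-pMHC complexes under load: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory mechanics of TCR-pMHC complexes under load: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrmech)
```

# The scientific setting

The alpha-beta T-cell receptor (TCR) discriminates antigenic peptides
presented by MHC molecules while the complex is under piconewton-scale
mechanical load at the T-cell/antigen-presenting-cell interface. Cognate
ligands form catch bonds — bond lifetime increases with force in the
10–20 pN range — and molecular-dynamics studies probe the mechanism by
holding the two ends of a TCR-pMHC complex at a fixed extension with
harmonic restraints and watching how interfacial contacts, interdomain
geometry and framework motion respond to the resulting average load.

`tcrmech` implements the analysis side of that programme as a reusable,
tested package: given a structure and a saved coordinate trajectory it
computes interfacial contact kinetics, rigid-body domain motion through
triads and a bead-on-chain reduction with PCA, scalar order parameters,
buried surface area, and the applied force. A synthetic-trajectory
generator with exact ground truth makes every stage verifiable by
parameter recovery without running MD.

# Contact kinetics

Contacts are detected per frame across a declared interface (two disjoint
atom groups):

* **Hydrogen bonds** (salt bridges included): a donor–acceptor pair within
  `hbond_cutoff` (default 2.4 Å). The cutoff is applied literally on the
  donor and acceptor heavy atoms. 2.4 Å is short for a heavy-atom pair; if
  your structure has hydrogens and you prefer the hydrogen–acceptor
  distance, `contact_criteria(hbond_mode = "hydrogen")` scores annotated
  polar hydrogens instead. Both conventions are available because the
  choice is not derivable from the cutoff value alone.
* **Nonpolar contacts**: a heavy-atom pair within `nonpolar_cutoff`
  (default 3.0 Å) where both partial charges satisfy |q| < 0.3 e. Charges
  come from a user-supplied force-field table and are never computed here.

Multiple atom pairs between one residue pair (and kind) collapse to a
single residue-pair contact, matching per-residue occupancy maps.

From the per-frame presence series two occupancies are derived. The
**average occupancy** over an interval is the fraction of its frames in
which the contact is present — a measure of abundance. The
**instantaneous occupancy** is a 40-frame rolling mean (0.8 ns at the
standard 20-ps stride) — a measure of temporal intensity. The rolling
window is trailing (it ends at the current frame) and is truncated at the
start of the series; any fixed convention works as long as it is stated
and tested, and this one keeps the series causal.

Derived summaries follow the standard recipe, all thresholds
configurable through `occupancy_thresholds()`:

* **High-occupancy count**: average occupancy > 50% *and* maximum
  instantaneous occupancy ≥ 80%, both evaluated after the equilibration
  cut.
* **Heat-map table**: rows are contacts with overall average occupancy
  > 30% and maximum instantaneous occupancy > 80% over the whole run;
  cells are per-time-bin occupancies.
* **Hamming distance H(t)**: the baseline is the set of contacts with
  > 80% average occupancy during the first 50 ns; H(t) counts baseline
  contacts currently lost. The literature does not pin down the
  instantaneous criterion for "lost", so the default rule marks a
  baseline contact lost wherever its rolling occupancy drops below 0.5;
  a "permanent loss after last presence" rule is available
  (`loss_rule = "permanent"`), under which H is non-decreasing.
* **Windowed total occupancy**: contacts selected by the > 50% / > 80%
  rule over the entire run; per 40-ns window (stepping 20 ns from
  200 ns: 200–240, 220–260, …) the selected contacts' window-average
  occupancies are summed. For intermolecular analyses the MHC–Vα,
  MHC–Vβ, peptide–Vα and peptide–Vβ interfaces are the natural groups;
  for intramolecular ones Vα–Vβ, Vα–Cα and Vβ–Cβ (the Cα–Cβ interface is
  excluded, as it is held static by design in the systems of interest).

# Buried surface area

BSA selects receptor-side residues whose maximum instantaneous contact
occupancy with the partner exceeds 80%, then per frame computes
SASA(residue in receptor alone) − SASA(residue in complex), summed over
the selection; the per-residue BSA divides by the number of selected
residues. SASA uses Shrake–Rupley sphere sampling with 960
deterministically placed (golden-spiral) points per atom, probe 1.4 Å
and standard heavy-atom van der Waals radii. 960 points keep the
single-sphere error well under 1%, which the tests verify against the
closed-form sphere and two-sphere spherical-cap areas. SASA is
implemented in-package because no installed R package provides it; the
golden-spiral point set makes it deterministic without a seed.

# Domain triads

Each variable domain's rigid-body orientation is tracked by an
orthonormal triad {e1, e2, e3} fitted to the backbone Cα atoms of six
residues from each of the four central β-strands of its immunoglobulin
core (Vα: S19–Y24, F32–Q37, Y70–I75, Y86–T91; Vβ: T20–Q25, S33–D38,
F74–L79, V88–S93, in renumbered indices). The centroid is the core Cα
centre of mass; **e3** is the major in-plane axis of the least-squares
plane (parallel to the strands), signed towards the CDR3 loop; **e1**
runs from the inner- to the outer-sheet centre of mass, orthogonalised
against e3; **e2 = e3 × e1** completes a right-handed frame.

Two conventions had to be fixed where the construction is under-specified:

* *Sheet partition.* The four listed segments are assigned 1 + 4 = inner
  sheet, 2 + 3 = outer sheet (configurable in `triad_spec()`). This
  matches the strand order of the immunoglobulin fold's two matching
  sheet segments and only affects the sign/direction of e1.
* *e3 sign continuity.* The principal axis has a sign ambiguity per
  frame; the sign is set towards the CDR3 base midpoint at the first
  frame and then kept continuous frame-to-frame, so slow rotations never
  flip the arm.

Angles between matching arms of the Vα and Vβ triads (∠e1, ∠e2, ∠e3 =
arccos of the arm dot product, degrees) quantify relative domain
rotations: a *scissor* motion (counter-rotation about e1) moves ∠e2 and
∠e3 reciprocally while leaving ∠e1 fixed; *flap* and *twist* are the
analogous rotations about e2 and e3. The CDR3 distance — between the
midpoints of the Cα pairs αT92/αK97 and βR94/βE103 at the CDR3 loop
bases — grows monotonically with scissor amplitude, which the tests
assert on generated scissor trajectories.

# The V-C bead-on-chain and hinge angles

The whole TCR is reduced to six beads per frame: the Vα/Vβ triad-core
centroids, Cα/Cβ constant-domain core centroids (Cα: A118–R123,
V132–D137, Y153–T158, S171–S176; Cβ: T143–A148, L158–N163, S192–V197,
F209–Q214), and the hinges Hα (Cα of αN114) and Hβ (midpoint of the
βD117/βL118 Cα atoms). Before beads are emitted, every frame is
least-squares superposed (Kabsch, on the C-module core Cα atoms) onto a
common reference frame, so bead motion reads as V-module motion relative
to the C-module, and average BOCs from different runs are directly
comparable when they share the reference.

The hinge angles ∠TCRα/∠TCRβ are defined pictorially in the source
material; here they are the angle at the hinge bead between its V-bead
and C-bead arms (configurable in `hinge_angles()`), 180° when collinear.

# PCA of triads and beads

PCA is an equal-weight covariance eigen-decomposition of the per-frame
configuration vectors: 18 components for the two triads (six arms × 3)
or 18 for the six beads. Arm tips are unit vectors, so small arm
displacements approximate rotation angles and triad-mode amplitudes are
reported in radians; bead-mode amplitudes are in Å. The mean and
covariance use only post-equilibration frames; projections are reported
for all frames. The **amplitude** of a mode is the standard deviation of
its projections over the analysed interval (equivalent to the square
root of the eigenvalue up to the estimator's n−1 convention; both are
exposed). Mode signs follow a first-nonzero-component-positive
convention purely for determinism — similarity comparisons
(`mode_similarity()`) use the absolute dot product, which is insensitive
to it.

Trajectories fed to triad PCA must be pre-aligned to the two domains'
β-sheet cores (`align_trajectory()`), otherwise global rigid motion
masquerades as arm motion; BOC PCA inherits its alignment from
`build_boc()`.

The **amplitude asymmetry** report contrasts the α- and β-chain content
of each mode: per mode, the rms displacement of the α-group beads/arms
within the unit mode vector minus that of the matched β group, scaled by
the mode amplitude. It is antisymmetric under swapping the chain labels
and vanishes for mirror-symmetric motion, both asserted in tests.

# Force from harmonic restraints

Load is applied through harmonic positional restraints
(k = 1 kcal/(mol Å²) by default) on two anchors — a single Cα on the
MHC-side strand terminus and the centre of mass of the two TCR-side
terminal Cα atoms — plus a flat-bottom pair restraint between the TCR
termini that engages beyond 10 Å with the same stiffness. The estimated
force is the deviation of the anchor's *average* position from the
restraint centre multiplied by the spring constant, converted at
69.479 pN per kcal/(mol Å). Averages use post-equilibration frames;
per-window means on the 40-ns overlapping windows provide the quoted
standard deviation (interpreted as the spread of window means, the
reading consistent with window-resolved force reporting).

The energy convention matters for both the force and the thermal
amplitude. The default is E = ½k|Δx|², under which the restraint force
is kΔx and equipartition gives a per-coordinate rms of
√(k_B T / k) = 0.772 Å at k = 1 kcal/(mol Å²) and 300 K — the ~0.8 Å
fluctuation amplitude expected for this restraint. The alternative
E = kΔx² convention (force 2kΔx, rms smaller by √2) is selectable but
non-default, because only the ½k reading reproduces both the stated
force rule and the stated fluctuation amplitude simultaneously.
k_B is taken as 0.0019872041 kcal/(mol K).

# The synthetic generator: what it emulates, and what it does not

`make_domain_template()` builds a Cα-pseudo-atom complex whose residue
numbering matches the package's default selections: planar four-strand
cores for Vα/Vβ/Cα/Cβ, CDR3 base and hinge residues, a nine-residue
peptide, terminal anchor atoms, and a pool of pre-annotated interfacial
contact sites. The two TCR chains are mirror images, so symmetric modes
must produce zero amplitude asymmetry — a free structural oracle.

`generate_trajectory()` composes, in declared order: rigid-body
rotational modes (scissor/flap/twist about the domain arms, hinge
bending about each chain's own hinge, or arbitrary `mode_rotation()`s),
with sinusoidal, constant or Ornstein–Uhlenbeck waveforms; geometric
contact toggling (the chain-A atom of a scheduled site is placed at its
partner's current position plus an on/off separation, so the *real*
detection code path is exercised rather than labels being set);
restrained-anchor OU motion with stationary variance k_B T/k; and
finally i.i.d. Gaussian positional noise. Noise is added after mode
composition so the injected mode directions remain the exact covariance
eigenvectors in expectation. Mode amplitudes are peak-to-peak angle
ranges, with a baseline offset (defaulting to the amplitude) that keeps
relative angles from folding through zero, where arccos would rectify
them. All randomness flows from one integer seed through local RNG
streams (the session's RNG state is untouched), and identical
config + seed reproduces the trajectory bit-for-bit in the plain-text
frame format.

Ground truth ships with each run: per-frame mode angles, each mode's
direction in triad and BOC coordinates obtained by central finite
differences at the baseline configuration (with the projection standard
deviation it predicts), the scheduled presence matrix, and the restraint
parameters. Recovery tests compare PCA output, occupancies, Hamming
counts and force estimates against these.

What the generator deliberately does **not** emulate: force-field
energetics, solvent, side chains, realistic secondary structure beyond
what triad fitting needs, anharmonic or correlated atomic fluctuations,
and contact formation driven by actual binding physics. Passing recovery
tests therefore demonstrate that the analysis machinery measures what it
claims to measure on trajectories with known content — not that any
biological conclusion about real TCR systems is reproduced. Quantities
that require microsecond all-atom trajectories (per-system contact
counts, CDR3 distances and transverse RMSF values of specific complexes)
are outside what desk-scale synthetic data can validate.

# Numerical choices and degenerate inputs

* Times are ns, coordinates Å, charges e, forces pN after conversion;
  residue indices are 1-based after per-chain sequential renumbering
  (the original numbering is kept as metadata).
* `frames_for_duration()` guards its floor against binary representation
  (1000/0.02 is not exactly 50000 in floating point); interval
  membership uses half-open [start, end) windows with a 1 ns·10⁻⁹ guard.
* Triad fitting rejects collinear cores (second eigenvalue below 10⁻¹⁰
  of the first) and a sheet direction degenerate with e3; hinge angles
  reject coincident beads; PCA reports zero amplitude for modes beyond
  the numerical rank instead of failing.
* The OU integrator uses the exact discrete update (unconditionally
  stable, stationary from the first sample); a step larger than the
  relaxation time γ/k is still rejected, because such a step
  undersamples the dynamics the caller is presumably interested in.
* Superposition is Kabsch via SVD with a determinant correction, checked
  in tests against an independent least-squares fit implementation.
* An empty Hamming baseline yields H ≡ 0 with a warning; an empty BSA
  selection yields 0 with a warning; a failing pipeline stage is
  recorded and isolated rather than aborting the run.

# Problem sizes

The test suite and the acceptance script run entirely on synthetic data:
trajectories of 100–250 frames (2–5 ns at the 20-ps stride) for contact,
triad, BOC and PCA recovery; 20 seeds for the mode-recovery property;
6000 frames for the biased-anchor force recovery; and 10⁶ steps for the
Ornstein–Uhlenbeck equipartition check. These sizes were chosen so each
statistical recovery sits several standard errors inside its tolerance
while the whole suite completes in well under a minute per file.

# Known limitations

* No XTC reader (PDB multi-model, DCD and the plain-text format are
  supported); no automatic interface discovery — interfaces are declared.
* Hydrogen-bond detection without a force-field topology relies on an
  element heuristic for donors/acceptors; supply explicit annotations
  for production use.
* The crystal-structure worked example (CDR3 distance of PDB 1AO7,
  10.9 Å) requires the 1AO7 coordinates, which are not bundled; point
  `TCRMECH_1AO7` at a local copy to run it.
* `compare_systems()` compares in-memory reports; serialised JSON
  reports do not retain mode vectors.
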