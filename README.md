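# tcrmech

Trajectory-analysis machinery for TCRαβ–pMHC complexes under mechanical
load.

T-cell receptors discriminate antigenic peptides while the TCR–pMHC bond
carries piconewton-scale force, and cognate ligands form *catch bonds*
whose lifetime peaks in the 10–20 pN range. Molecular-dynamics studies of
this mechanism hold the complex at a fixed end-to-end extension with
harmonic restraints and then ask how the interface and the TCR framework
respond to the resulting average load. `tcrmech` implements the full
analysis side of that workflow for structural biologists and simulators:

* **Contact kinetics** — per-frame hydrogen-bond (2.4 Å donor–acceptor)
  and nonpolar (3.0 Å, both |q| < 0.3 e) contact detection across declared
  interfaces; average and 40-frame rolling ("instantaneous") occupancy;
  high-occupancy counts (avg > 50%, max-inst ≥ 80%); occupancy heat-map
  tables; the Hamming distance H(t) of initially persistent contacts
  (> 80% occupancy in the first 50 ns) subsequently lost; windowed total
  occupancy on 40-ns windows stepping 20 ns.
* **Buried surface area** — Shrake–Rupley SASA (960 points/atom, probe
  1.4 Å) of interfacial residues selected by instantaneous occupancy.
* **Domain geometry** — orthonormal triads {e1, e2, e3} fitted to each
  variable domain's β-sheet core (e3 along the strands towards CDR3,
  e1 inner→outer sheet, e2 = e3 × e1); triad-arm angles ∠e1/∠e2/∠e3; the
  CDR3 base-midpoint distance; a six-bead V-C bead-on-chain (Vα, Vβ, Cα,
  Cβ + hinges) in a common C-module-aligned frame with hinge angles
  ∠TCRα/∠TCRβ; peptide tilt angle; RMSF and transverse RMSF.
* **Interdomain modes** — 18-dimensional PCA of the paired triad arms
  (amplitudes in radians) and of the six beads (Å), mode similarity via
  absolute dot products, per-frame projections, and the α/β amplitude
  asymmetry of each mode.
* **Force estimation** — F = k·⟨x − x₀⟩ from restrained anchors
  (69.479 pN per kcal/(mol·Å)), per-window force statistics,
  longitudinal/transverse decomposition, flat-bottom pair restraints, and
  the equipartition amplitude √(k_B T/k) ≈ 0.77 Å at the standard
  k = 1 kcal/(mol·Å²), 300 K.
* **A synthetic-trajectory generator** with exact ground truth —
  prescribed scissor/flap/twist/hinge-bend modes, scheduled contact
  toggling through the real detection path, and Ornstein–Uhlenbeck
  restrained anchors — so every stage above is verified by parameter
  recovery without running MD.

Everything is tidyverse-shaped: series come back as tibbles, fitted
objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

Generate a 4-ns synthetic trajectory with a known 10° scissor mode, two
scheduled contacts and a biased harmonic restraint, then recover all
three with the analysis stack:

```r
library(tcrmech)

template <- make_domain_template()
iface <- synthetic_interface(template)
cfg <- synthetic_config(
  template, n_frames = 200, seed = 42,
  modes = list(mode_scissor(10, period = 0.4)),
  contacts = list(list(site = 1, occupancy = 1),
                  list(site = 2, occupancy = 0.6)),
  restraint = list(k = 1, T = 300, friction = 0.05, bias = c(0, 0, 0.25))
)
run <- generate_trajectory(cfg)
run$trajectory
#> <trajectory> 200 frames x 414 atoms, dt_save = 0.02 ns (4 ns total)

tl <- build_timelines(run$trajectory, iface$group_a, iface$group_b,
                      windows = analysis_windows(equilibration_cut = 0))
avg_occupancy(tl)
#> # A tibble: 2 × 3
#>   contact   kind  avg_occupancy
#>   <chr>     <chr>         <dbl>
#> 1 A1-D40/hb hbond           1
#> 2 A2-E40/hb hbond           0.6

gt <- run$ground_truth$restraint
fe <- estimate_force(run$trajectory,
                     restraint_spec(gt$anchor_tcr, gt$center_tcr, k = 1),
                     analysis_windows(equilibration_cut = 1, window = 1,
                                      step = 0.5, window_start = 0))
fe
#> <force_estimate> 19.08 pN (window sd 13.68 pN over 7 windows)

thermal_amplitude(k = 1, T = 300)
#> [1] 0.7721148
```

The scheduled occupancies come back exactly (1 and 0.6); the estimated
19.1 pN sits within sampling error of the imposed
0.25 kcal/(mol·Å) × 69.479 = 17.4 pN bias on this short run (the window
standard deviation quantifies exactly that spread); and the thermal
amplitude of the standard restraint is the equipartition value
√(k_B·300 K / 1 kcal mol⁻¹ Å⁻²) = 0.772 Å.

For real data, point `run_config()` at a structure, a trajectory and
your chain roles, and `run_analysis()` executes every stage and writes a
JSON + CSV bundle; `compare_systems()` sets reports from different
runs/loads side by side. A thin CLI (`inst/cli/tcrmech`) wraps `info`,
`synth`, `run` and `compare`.

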