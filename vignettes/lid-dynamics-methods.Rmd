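---
title: "Methods: adaptive-seeding sampling and Markov state model analysis of lid dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive-seeding sampling and MSM analysis of lid dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pacsmsm)
```

# The scientific problem

Lipase activity rises sharply at water–lipid interfaces. The accepted
mechanism is conformational: a lid formed by the α5 helix (residues
142–146) and the α10 helix (residues 268–287) covers the catalytic triad,
and the equilibrium between its closed, semiopen and open conformations
shifts when the enzyme adsorbs to a hydrophobic surface. Lid opening is
monitored by two Cα–Cα distances — Dist1 (residues 309–144) and Dist2
(residues 146–286) — with Dist2 measuring the opening directly. The
classification convention is: closed for Dist2 ≤ 1.0 nm, semiopen for
1.0 < Dist2 < 2.0 nm, open for Dist2 ≥ 2.0 nm; both boundaries are
assigned inward (1.0 → closed, 2.0 → open), which
`classify_conformation()` implements literally.

Because open–close transitions are rare events on plain simulation
timescales, the sampling protocol of interest is parallel cascade
selection (PaCS): cycles of many short unbiased simulations whose restart
points are chosen by ranking the previous cycle's frames along a progress
variable (the interlid centre-of-mass distance *d* between residues
142–146 and 278–287). Selection introduces a statistical bias into the
pooled frames; the Markov state model built from the *transitions* inside
each short segment removes it, because transition statistics are
unaffected by where segments were started — only by the dynamics within
them. That bias-correction property is the load-bearing claim of the
pipeline, and the test suite demonstrates it directly by comparing the
MSM stationary distribution and the raw frame histogram of the same
campaign against an independent quadrature reference.

# The synthetic engine and what it emulates

All pipeline inputs are generated by an overdamped Langevin engine in the
two-dimensional (Dist1-like, Dist2-like) collective-variable plane. The
potential is a sum of negative isotropic Gaussian wells plus a harmonic
confinement:

$$E(x) = -\sum_m d_m \exp\!\left(-\frac{\lVert x - c_m\rVert^2}{2 w_m^2}\right)
 + \tfrac{1}{2} k_1 (x_1 - o_1)^2 + \tfrac{1}{2} k_2 (x_2 - o_2)^2 \quad [kT]$$

and the integrator is Euler–Maruyama,
$x \leftarrow x + (D/kT)\,F\,\Delta t + \sqrt{2D\Delta t}\,\eta$, compiled
(Rcpp) and driven by R's RNG so that `set.seed()` gives bitwise
reproducibility. Defaults: timestep 0.01 ps, diffusion 0.005 nm²/ps,
kT = 1 (the energy unit throughout; kcal/mol is presentation only). A
per-step displacement larger than three times the narrowest well width
aborts with an integration error naming the step — an explicit stability
guard rather than silent divergence.

Two presets encode the qualitative physics of the two environments:

* `water_like` — three wells in the closed/semiopen/open Dist2 bands with
  the **closed** well deepest (8 kT; semiopen 6.2, open 5.5; widths
  0.27 nm), and the closed↔semiopen separation (≈ 0.81 nm) smaller than
  semiopen↔open (≈ 1.02 nm) so that a semiopen lid relaxes back to closed
  more easily than it opens.
* `interface_like` — the **semiopen** well deepest (8 kT), the open well
  both shallower (4 kT vs 5.5) and narrower (0.23 nm vs 0.27) than in
  water (the interface restricts the low-free-energy area), and the
  semiopen→open separation (≈ 0.76 nm) smaller than semiopen→closed
  (≈ 0.86 nm) so the committor of the semiopen band flips above 0.5.

Depths follow the 4–8 kT range stated for this artifact; no published
kcal/mol values exist for these landscapes, so only the *orderings* —
which band holds the global minimum, which barrier is lower, how the open
well changes between environments — are meaningful claims, and they are
asserted by the test suite rather than quoted.

The confinement is anisotropic on purpose: the Dist1-like axis is confined
stiffly (k₁ = 6 and 8 kT/nm² in the two presets) and the lid-opening axis
softly (k₂ = 1.2 and 2.0). With a weak isotropic confinement the
orthogonal coordinate is nearly flat over several nanometres, and its slow
free diffusion (relaxation time kT/(Dk)) injects spurious slow modes into
the MSM spectrum that compete with the real interband processes; stiff
orthogonal confinement restores a clean three-state spectral gap. This is
a property of the synthetic landscape design, not of the estimators.

What the generator does **not** emulate: atomistic structure (the
structure ensembles used by the interaction operators are separate,
planted-geometry constructions), solvent and surface degrees of freedom,
velocity memory (the dynamics are overdamped, so "reinitialised
velocities" at each restart maps to drawing a fresh noise stream), and any
coupling between the collective variables beyond the well geometry.
Passing tests therefore certify the estimators and the protocol logic, not
force-field realism.

# The PaCS driver

`run_pacs_trial()` performs: a preliminary run (default 1 ns in protocol
units; 500 ps in the desk-scale pipeline), then cycles of `n_rep`
propagations of `cycle_length` (defaults 30 replicas × 0.1 ns, the
published parameters), stopping when any frame's ranking variable crosses
the stage threshold (3.0 nm opening / 0.8 nm closing in the protocol;
2.2 / 0.9 nm in the pipeline defaults, because the synthetic open well
sits near 2.3–2.5 nm) or at `max_cycles` — the latter is recorded as a
termination reason, not an error. Decisions the protocol description
leaves open, resolved here and treated as contracts:

* **Candidate pool**: ranking considers only the immediately preceding
  cycle's frames. Ranking the full history would keep reselecting the
  existing frontier and stall progress.
* **Tie-breaking**: lexicographic by (cycle, replica, frame); determinism
  is required for testing.
* **Seed discipline**: every propagation uses a seed derived by an
  integer hash of (master seed, trial, cycle, replica)
  (`derive_seed()`), so campaigns are pure functions of their master
  seed.
* **Fewer candidates than `n_rep`**: the ranking is recycled from the
  top.
* The published closed-structure bootstrap for the interface system (a
  long closing-stage trial with a fixed cycle cap) is expressible as an
  ordinary `direction = "closing"` trial with `max_cycles` set.

`simulation_cost()` implements the bookkeeping convention
cycle length (ns) × cycles × replicas, reported in microseconds.

# MSM estimation

Frames are clustered by k-means with hand-seeded k-means++
initialisation (`stats::kmeans` provides only random starts) — k = 1000
in the published analysis, k = 60 in the pipeline defaults, because the
synthetic landscape has far fewer distinguishable basins than an
all-atom ensemble. Counting is sliding-window at stride one, strictly
within segments: PaCS pieces are independent restarts and must not be
concatenated. The estimator is restricted to the largest strongly
connected component (ties broken toward the lowest state index) and is,
by default, the maximum-likelihood reversible estimate under detailed
balance, computed by the standard fixed-point iteration on the
symmetrised flux matrix to an elementwise tolerance of 1e-10 (cap 10⁶
sweeps); plain row normalisation is retained as `mode = "nonreversible"`
for oracle tests. The stationary distribution is the unit left
eigenvector; free energies are −kT log π, min-shifted.

The lag time follows the argument that segments of length L support lags
up to L/2: with 100 ps segments the pipeline uses τ = 50 ps, and implied
timescales are tabulated over 1–50 ps to check that the slowest
timescale has flattened (relative change below 25% over the last two
lags by default). Eigenvalues with imaginary parts beyond 1e-8 are
reported by magnitude with a warning; eigenvalues at or above one give
an `Inf` sentinel rather than a negative timescale.

The free-energy landscape assigns each microstate's π to the grid cell
containing its center; unvisited cells are masked (`NA`), never zero,
and the 1-D profile along Dist2 is the exact marginal of the 2-D grid.

# Coarse-graining and kinetics

PCCA+ runs on the first `n_macro` right eigenvectors, computed through
the π-symmetrised transition matrix so they are real and
π-orthonormal. Vertices of the eigenvector simplex are located by the
inner-simplex algorithm (furthest-row selection with Gram–Schmidt
deflation); memberships are the linear map onto those vertices, with
small negative entries clipped and rows renormalised. Degenerate
eigenvalues at the cut raise an error advising a different `n_macro`
rather than returning an arbitrary split. `n_macro` is a user choice
with a crispness diagnostic in the print method, not an automated
selection.

MFPTs are computed on the **microstate** chain with macrostates as state
sets (coarse-graining to a 6×6 chain first would add projection error),
solving the absorbing linear system and averaging over the source set
with π-weights renormalised on the source — the π-weighted convention is
a documented choice where the source literature is silent. Committors
solve the interior Laplace problem with boundary values 0 on A and 1 on
B; the backward committor uses the time-reversed chain
π_j T_ji / π_i, and for reversible chains q⁻ = 1 − q⁺ is asserted in
tests to solver tolerance. TPT uses gross flux
f_ij = π_i q⁻_i T_ij q⁺_j, net flux max(0, f_ij − f_ji), total flux out
of A, per-edge fractions, and pathway decomposition by repeatedly
extracting the widest (maximum-bottleneck) A→B path and subtracting its
bottleneck flux; ties break toward lower state indices.

In the pipeline, the committor's source and sink sets are the closed-band
and open-band **microstates** (classified by their cluster-center Dist2),
independent of the PCCA split. This keeps the headline committor
comparison well-defined even when a preset's closed band carries so
little probability that no macrostate lands there.

# Interaction statistics

The geometric criteria are implemented with strict inequalities exactly
as stated: contacts when any heavy-atom pair of two residues (within
135–151 ∪ 261–293) is **below** 5.0 Å; hydrogen bonds for
acceptor–donor distance **below** 3.0 Å and acceptor–H–donor angle
**above** 135°, donors and acceptors restricted to N/O and the hydrogen
assigned to the nearest same-residue heavy atom within 1.25 Å; ΔP
screening keeps |ΔP| strictly **above** 0.2, with pairs missing from one
macrostate counted as probability zero there. Structures without
hydrogens are rejected by the hydrogen-bond operator (crystal structures
are surveyed by the distance-based operators only). Per-macrostate
sampling draws 25 structures per member microstate, uniformly without
replacement (with replacement, flagged, when a microstate holds fewer
frames). The macrostate probability of an interaction is the
π-weighted mean of per-microstate probabilities, and average counts are
per-microstate means combined with π weights.

The salt-bridge criterion (minimum Asp145 carboxylate-O to Lys290
side-chain-N distance below 4.0 Å) is a package default — the source
analysis names the pair but not a cutoff — and every output that uses it
reports the cutoff alongside.

Sequence-separation filtering beyond excluding self-pairs is off by
default (no published exclusion exists) but configurable.

# Crystal survey

`crystal_survey()` reads standard PDB files through `bio3d`, honouring
models, chains and occupancies; alternate locations resolve to the
highest occupancy with alphabetical tie-break, and insertion-coded
residues are excluded from plain numeric ranges. Because this build runs
without network access, the test suite exercises the survey on synthetic
stand-in structures (generated in code, labelled synthetic) whose planted
Cα and charged-group geometry realises published lid distances; surveying
the deposited entries themselves requires only pointing the same function
at downloaded files.

# Problem sizes and determinism

The shipped configurations are deliberately desk-scale: pipeline defaults
run 4 opening trials × 2 closing continuations with 20 replicas and 100 ps
cycles (frames recorded every 0.5 ps), cluster into 60 microstates, and
analyse at a 50 ps lag — about 60–80k frames and well under a minute per
preset on one CPU; the equilibrium reference used by the coarse-graining
test is a single 400 ns trajectory. Every stochastic operation takes an
explicit seed and restores the caller's RNG state, so campaigns,
ensembles and pipelines are pure functions of their configuration; the
manifest written by `run_pipeline(..., output_dir = )` records per-file
checksums, and rerunning an identical configuration reproduces them
exactly.

# Known limitations

* The synthetic landscape has two degrees of freedom and no memory;
  agreement here does not certify behaviour on rugged atomistic
  landscapes, in particular k-means discretisation error and lag-time
  sensitivity are far milder than in real applications.
* Absolute kinetic numbers (MFPTs in ns, committor values) are properties
  of the preset geometry, not predictions for any enzyme; only their
  orderings between the two presets are designed claims.
* The reversible estimator assumes the pooled segments sample a single
  connected equilibrium; grossly disconnected campaigns are truncated to
  the largest connected set and the dropped states are reported, which
  can hide poorly sampled regions if ignored.
* No error bars are attached to MSM quantities (no Bayesian sampling of
  transition matrices); seed-to-seed variation is the available
  dispersion measure.
* The PDB reader resolves altlocs and models but does not renumber,
  align, or model missing residues; mutant or renumbered entries are
  surveyed as deposited.
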