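# pacsmsm

Adaptive-seeding sampling and Markov state model (MSM) analysis of slow
conformational transitions, built around the lid open–close dynamics of a
lipase in water versus at a water–lipid interface.

Lipases are activated at hydrophobic interfaces: a mobile lid (two helices,
α5 and α10, in *Candida antarctica* lipase B) must move away from the
catalytic pocket before substrate can bind, and the equilibrium between its
closed, semiopen and open conformations shifts with the environment. The
opening is measured by the Cα–Cα distance between residues 146 and 286
(Dist2): closed means Dist2 ≤ 1.0 nm, semiopen 1.0 < Dist2 < 2.0 nm, open
Dist2 ≥ 2.0 nm. Direct simulation of such transitions is expensive because
they are rare events; this package implements the standard remedy — parallel
cascade selection (PaCS) adaptive sampling followed by an MSM that removes
the selection bias — as a reusable, fully tested pipeline, exercised
end-to-end on a two-dimensional Langevin engine whose landscape presets
emulate the aqueous and interfacial systems.

## What the package computes

**PaCS driver** (engine-agnostic). Repeated cycles of `n_rep` short
simulations; after each cycle all frames of the previous cycle are ranked by
a collective variable (the interlid distance `d`), the top `n_rep` become
the next cycle's restart points with fresh noise streams, and the stage
stops when the variable crosses a threshold (opening: `d` above 3.0 nm;
closing: below 0.8 nm, in the published protocol). Any propagator with the
signature `function(state, length_ps, seed) -> trajectory` can be driven.

**MSM core.** Frames are clustered into `k` microstates (k-means with
k-means++ seeding) in the (Dist1, Dist2) feature plane; transitions are
counted at lag τ within segments only, and the transition matrix is the
maximum-likelihood reversible estimate

    T_ij(τ) = P(S(t+τ) = j | S(t) = i),     π T = π,
    F_i = -kT log π_i   (min-shifted),

validated by implied timescales `t_i(τ) = -τ / log λ_i(τ)` over a lag
series. The stationary distribution, not the raw frame histogram, gives the
free-energy landscape over (Dist1, Dist2).

**Coarse kinetics.** PCCA+ memberships on the leading eigenvectors group
microstates into metastable macrostates; mean first-passage times solve the
absorbing linear system `h = τ + T h`; committors `q⁺` solve the discrete
boundary-value problem between the closed (A) and open (B) bands; and
transition path theory gives reactive fluxes
`f_ij = π_i q⁻_i T_ij q⁺_j`, net fluxes, per-edge flux fractions and a
pathway decomposition by iterative bottleneck removal.

**Interaction statistics.** Residue–residue contacts (any heavy-atom pair
strictly below 5.0 Å within residues 135–151 and 261–293), hydrogen bonds
(acceptor–donor below 3.0 Å, acceptor–H–donor angle above 135°, N/O only),
the Asp145–Lys290 salt bridge, macrostate probabilities as
stationary-weighted microstate means

    P^ij = Σ_k π_k p_k^ij / Σ_k π_k,

and transition screening by ΔP^ij with the |ΔP| > 0.2 rule. A crystal
survey (`crystal_survey()`) computes Dist1/Dist2/`d`, the conformational
class and the salt-bridge flag for each chain of standard PDB files.

## Worked example

```r
library(pacsmsm)
preset_landscape("water_like")
#> 2-D multi-well potential (water_like): 3 wells, confinement k = (6, 1.2) kT/nm^2
#>   cv1 cv2 depth_kT width_nm
#>  2.60 0.7      8.0     0.27
#>  2.45 1.5      6.2     0.27
#>  2.25 2.5      5.5     0.27

res <- run_pipeline(pipeline_config("water_like", seed = 1))
res
#> lid-dynamics pipeline (water_like preset, seed 1)
#>   12 trials, 68292 pooled frames, 60/60 active microstates
#>   FEL global minimum: Dist2 = 0.72 nm (closed)
#>   macrostate 1 [open]: Pi = 0.000, F = 8.65 kT, committor 1.000
#>   macrostate 2 [open]: Pi = 0.085, F = 2.38 kT, committor 0.987
#>   macrostate 3 [closed]: Pi = 0.915, F = 0.00 kT, committor 0.028
#>   band committors (closed -> open): closed 0.000, semiopen 0.098, open 1.000

summary(res$msm)
#> MSM summary: 60/60 active states, lag 50 ps (reversible estimator)
#>   leading eigenvalues: 1.0000, 0.8720, 0.6093, 0.4915, 0.0975, 0.0635
#>   implied timescales (ps): 365, 101, 70.4, 21.5, 18.1
```

Reading the output: the free-energy minimum of the water-like landscape sits
in the closed band (Dist2 = 0.72 nm), the closed macrostate carries almost
all stationary probability, and the semiopen band's committor of 0.098 says
a semiopen lid relaxes back to closed far more often than it opens. Running
the same pipeline with `pipeline_config("interface_like", seed = 1)` moves
the free-energy minimum into the semiopen band and pushes the semiopen
committor above 0.5 — the qualitative signature of interfacial activation.
The slowest implied timescale (365 ps at a 50 ps lag) is the closed↔open
relaxation of the synthetic landscape.

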