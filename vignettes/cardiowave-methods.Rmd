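---
title: "cardiowave: model, numerics, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cardiowave: model, numerics, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

cardiowave simulates electrical wave propagation in a two-dimensional
sheet of ventricular tissue and exposes the same model through several
interchangeable compute backends whose agreement is continuously tested.
This vignette records the model, the numerical choices, and the design
decisions a maintainer would want to know about.

## The monodomain model

Tissue is a rectilinear grid of nodes, each carrying a full membrane
state, coupled by diffusion of the transmembrane potential $V_m$:

$$
\frac{\partial V_m}{\partial t}
  = \nabla \cdot (\mathbf{D} \nabla V_m)
  + \frac{-I_{ion}(V_m, \mathbf{g}, [\mathrm{Ca}]_i) + I_{stim}}{C_m},
$$

with no-flux boundaries on all four edges.  The ionic model is
Beeler–Reuter with the Drouhard–Roberge reformulation of the fast inward
sodium current:

* $I_{Na} = (g_{Na}\, m^3 h \,(j) + g_{NaC})(V_m - E_{Na})$ with
  $g_{Na} = 15\ \mathrm{mS/cm^2}$, $E_{Na} = 40$ mV and the
  Drouhard–Roberge $m, h$ kinetics.  That reformulation drops the slow
  inactivation gate $j$; `use_j_gate = TRUE` restores it with its
  Beeler–Reuter kinetics (both because the choice is a known point of
  variation between implementations).  The background conductance
  $g_{NaC} = 0.003\ \mathrm{mS/cm^2}$ keeps the rest state well defined
  and can be set to zero.
* $I_s = g_s\, d f\, (V_m - E_s)$, $E_s = -82.3 - 13.0287 \ln [\mathrm{Ca}]_i$,
  with $d[\mathrm{Ca}]_i/dt = -10^{-7} I_s + 0.07(10^{-7} - [\mathrm{Ca}]_i)$.
* $I_{K1}$ and $I_{x1}$: the Beeler–Reuter closed forms.  These two are
  coded directly (their published coefficients are not free parameters);
  everything else — the 12 gate-rate coefficient rows, conductances,
  reversals, $C_m$, the calcium floor — ships in a versioned plain-text
  `key = value` table (`inst/extdata/brdr_constants_v1.txt`) that users
  can replace.

All gate rates share one canonical form
$(C_1 e^{C_2(V+C_3)} + C_4(V+C_5)) / (e^{C_6(V+C_3)} + C_7)$.  Several
members have removable singularities (numerator and denominator vanish
together); within $10^{-6}$ mV of such a point the stored analytic limit
is returned, because the raw expression evaluates to 0/0 at representable
inputs.  The same treatment is applied to the $(V_m+23)$ factor of
$I_{K1}$.

### Rest state

`find_rest_state()` puts every gate at $g_\infty(V)$, solves the calcium
fixed point consistent with the resulting $I_s$ by iteration, and finds
$V^*$ with $|I_{total}(V^*)| < 10^{-9}\ \mathrm{\mu A/cm^2}$ by bisection
on $[-100, -60]$ mV.  Because the Euler update has the same fixed point
as the flow, a tissue initialized this way is quiescent to well below a
microvolt over hundreds of milliseconds (asserted by tests).  After an
action potential the last millivolt of recovery is slow — the $x_1$ gate
deactivates with $\tau \approx 230$ ms at rest — which is physiology of
this model, not drift.

## Discretization

* **Grid and layout.** Node coordinates are zero-based $(x, y)$; state
  grids are R matrices indexed $[y+1, x+1]$, one contiguous matrix per
  variable (structure-of-arrays).  Defaults $dx = dy = 0.025$ cm.
* **Diffusion tensor.** Fibers at angle $\theta$ rotate
  $\mathrm{diag}(D_\parallel, D_\perp)$; defaults
  $D_\parallel = 10^{-3}$, $D_\perp = 2\times10^{-4}\ \mathrm{cm^2/ms}$
  (anisotropic presets) give conduction velocities around
  0.05 cm/ms along fibers, standard monodomain magnitudes.
* **Stencil.** Centered second differences plus the 4-corner centered
  cross-derivative — the minimal 9-point stencil for an anisotropic
  tensor.  Weights sum to zero and are symmetric under 180° rotation.
  The nine products are accumulated in commutative pairs (SW+NE, NW+SE,
  W+E, S+N, then center) so that mirrored or transposed fields evolve
  exactly symmetrically in floating point.
* **Boundaries.** A one-cell ghost frame implements zero normal flux.
  Two reflection conventions exist in the literature: about the boundary
  *node* (ghost = first interior neighbour) and about the boundary
  *face* (ghost = edge value).  The simulator uses the face convention
  because it makes the discrete operator conserve the plain sum of the
  field exactly — the conservation property the test-suite asserts — at
  the same formal order of accuracy; `pad_noflux(type = "node")` provides
  the node-centred alternative for comparison.  With oblique fibers the
  cross-terms at boundaries use the same reflected ghosts; conservation
  is asserted only for the axis-aligned case, the oblique case is
  covered by the gather/scatter equivalence instead.
* **Time stepping.** Explicit Euler, canonical per-node order: gates from
  the pre-step $V_m$, currents from updated gates and pre-step $V_m$,
  calcium, then $V_m$.  One fixed order is what makes backend
  equivalence a meaningful bitwise statement.  Gates are clamped to
  $[0,1]$ after the update; the clamp is a guard, not a crutch — it never
  engages in a default run.

### Stability

`sim_config()` enforces `dt <= safety_factor * min(dt_CFL, dt_gate)` with
`safety_factor = 0.9`:

* $dt_{CFL} = 1 / \left(2(D_{xx}/dx^2 + D_{yy}/dy^2 + |D_{xy}|/(dx\,dy))\right)$,
  a conservative bound for the 9-point scheme (≈ 0.15–0.26 ms at the
  defaults).
* $dt_{gate} = 2/\max_V(\alpha+\beta)$, the largest step for which one
  Euler gate update is a contraction.  The maximum is taken over
  $[-95, 60]$ mV — the potentials an action potential actually
  traverses — not over the $[-120, 80]$ mV sanity bounds, which exist to
  detect blow-up, not to be visited.  The binding rate is the sodium
  deactivation $\beta_m$ (~100 ms⁻¹ near −90 mV), giving
  $dt_{gate} \approx 0.019$ ms; the default `dt = 0.01` ms clears both
  caps.  A separate, stricter bound $1/\max(\alpha+\beta)$ over the full
  sanity range guarantees the update maps $[0,1]$ into itself with no
  clamping at all; the suite checks that too.

Any node leaving $[-120, 80]$ mV aborts the run with an error naming the
step and node and carrying the last snapshot for post-mortem.

## Backends

The five backends embody the optimization strategies that matter when
porting this kernel to accelerators, in hardware-independent form:

| backend     | layout | loop structure                               |
|-------------|--------|----------------------------------------------|
| `reference` | AoS    | nested x/y scalar loops, per-node stencil + membrane update |
| `gather`    | SoA    | neighbour-read-only stencil pass, then membrane pass |
| `scatter`   | SoA    | each node accumulates writes into its 9 targets (the atomic-operation hazard, serialized) |
| `tiled`     | SoA    | gather, cache-blocked over `tile_x` × `tile_y` blocks |
| `parallel`  | SoA    | gather, strips of the x index over OpenMP workers |

All backends call the same inline membrane update, so the read-only four
produce **bit-identical** trajectories — any worker count, any tile
shape — because the gather formulation writes each node exactly once from
pre-step values.  The scatter backend performs the same arithmetic in a
different accumulation order and is required to agree within
$10^{-9}$ mV over a thousand steps; it is kept as the cross-check oracle
for the neighbour-update-free transformation.  `run_equivalence()` is the
package's central correctness surface; `autotune_tiles()` asserts
equivalence of every tile candidate before timing anything.  Inner loops
run on ghost-padded arrays and carry no boundary branches (the
loop-unswitching idea).

## Protocols

* `plane_wave`: S1 over a five-column strip at the left edge, 2 ms at
  50 µA/cm² (roughly twice diastolic threshold).  Used for activation
  maps, conduction velocity and convergence checks.
* `single_rotor`: cross-field S1–S2.  S2 covers the lower-left quadrant
  and is *auto-triggered*: it fires when the domain-center node
  repolarizes through a threshold, rather than at a hard-coded time,
  because the vulnerable window depends on the model constants.
  `vulnerable_window_scan()` scans the trigger threshold over
  {−40, −50, −60} mV.  Reentry counts as sustained when excited nodes
  exist at every snapshot of the 300 ms post-S2 window *and* the probe
  shows ≥ 3 activations (ruling out a single decaying wave).
* `breakup`: isotropic variant on a larger grid whose milder 2×
  speed-up sits in the steeper-restitution regime where the spiral arm
  fragments.

Two preset choices deserve justification.  First, the repolarizing
kinetics ($d, f, x_1$ rates) are sped up (4× rotor, 2× breakup): at the
native APD$_{90}$ of ≈ 280 ms the excitation wavelength
$\lambda \approx CV \times APD \approx 14$ cm cannot reenter inside a
4.8 cm domain; the speed-up is the standard device for studying spiral
waves in this model family and brings $\lambda$ to ~2–5 cm.  Second, the
rotor preset's probe sits at $(3n_x/4, 3n_y/4)$ rather than the domain
center: the S2 wavebreak forms near the center, so the rotor core — where
amplitudes are small — may park there and undercount activations; an
off-core probe measures what the criterion means.  Elsewhere the probe
default remains the domain center.

Stimuli are current injections (µA/cm², depolarizing positive), never
voltage clamps, so the $V_m$ update stays a single Euler expression at
every node; overlapping events sum.

## Readouts

* `activation_map()`: per-node first upward crossing of −50 mV, linearly
  interpolated between snapshots; never-activated nodes are `NA`.
* `conduction_velocity()`: distance over activation delay along a row.
* `apd()`: width of the action potential at the repolarization level —
  for APD$_{90}$, the crossings of baseline + 0.1 × amplitude.  Both
  thresholds are relative, so the measure is invariant under amplitude
  scaling.
* `benchmark_backends()`: nodes-per-second throughput with snapshot and
  probe output excluded from the timed region.  Counters
  (`node_updates = steps × nx × ny`) are exact integers; timings are
  reported, never asserted — they are hardware-dependent.

## What the fixtures emulate — and what they do not

`make_fixture()` builds impulse, excited-strip, seeded-random and
mirrored-random states on top of the broadcast rest state.  These probe
the *operator* properties (conservation, maximum principle, symmetry,
gather/scatter agreement) under fields rougher than physiology produces.
Passing tests on them says the discrete operators are correct; it does
not validate the model against real tissue, which is heterogeneous, has
curved boundaries and fiber disarray, none of which the generator
emulates (per-node fiber angles are supported, but the presets are
uniform).

## Problem sizes and determinism

The test suite runs its checks at the sizes the science needs and no
larger: operator properties on 6–32 node grids, equivalence on 64 × 64
for 1000 steps, quiescence on 32 × 32 for 100 ms, single-cell
consistency for 500 ms, and one rotor-induction scan on 192 × 192
(≈ 450 ms simulated).  Everything shipped is deterministic: the only RNG
use is fixture generation under explicit seeds, and the config `seed`
field is reserved for future noise experiments.  Identical inputs give
bit-identical outputs on a given platform; across platforms the
trajectories track to rounding, while the *relationships* between
backends (bitwise equality of the read-only family) hold everywhere.

## Known limitations

* Explicit Euler only — no Rush–Larsen or adaptive integration; the gate
  stiffness, not the CFL bound, therefore limits `dt`.
* One ionic model; the backend/protocol machinery is model-agnostic in
  structure but the constants table schema is Beeler–Reuter-shaped.
* 2D monodomain only: no bidomain, no 3D, no curvilinear geometry, no
  spatially varying diffusion magnitude.
* The scatter backend is serialized; it exists as an oracle, not a fast
  path.
* Phase-singularity tracking and dominant-frequency maps are out of
  scope; sustained reentry is detected by the excited-count/probe
  criterion described above.
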