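---
title: "The cross-section model: mechanics, kinetics, and numerical choices"
author: "axoncross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cross-section model: mechanics, kinetics, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The system being modeled

An axon carries two space-filling longitudinal polymer populations —
microtubules (MT, radius 12.5 nm in cross-section) and neurofilaments (NF,
radius 5 nm) — plus a traffic of membranous organelles moving along the
microtubules. In healthy axons the two polymers are interspersed in any
cross-section. In several toxic neuropathies (IDPN, 2,5-hexanedione) and
neurodegenerative disorders they segregate within hours: microtubules and
organelles gather into a central island, neurofilaments are displaced to
the periphery, and the process reverses when the insult is removed.

`axoncross` simulates a single cross-sectional plane as a 2D system of
interacting disks and asks whether the impairment of neurofilament
transport alone is enough to produce this segregation. Axial structure
enters only through cargo exchange: neurofilaments hop in and out of the
plane when they are hauled along their tracks, and organelles sweep
through it as spindles whose cross-sectional radius waxes and wanes.

## Mechanics

Motion is overdamped: for each particle of type $k$ with drag $\mu^k$,

$$\mathrm{d}x_i^k = \frac{F_i^k}{\mu^k}\,\mathrm{d}t
  + \sigma_k\,\mathrm{d}W_i^k,\qquad \sigma_k = \sqrt{2D_k},
  \qquad D_k = k_BT/\mu^k,$$

with independent 2D Wiener processes $W_i^k$. $F_i^k$ sums three
deterministic contributions, all central and all written in terms of the
surface gap $d_{ij} = |x_i - x_j| - r_i - r_j$:

* **Excluded-volume repulsion** between every particle pair (and between
  each particle and the boundary of the disk domain):
  $\varepsilon\,(L_r/d - 1)$ for $0 < d \le L_r$, zero beyond. The force
  diverges at contact and vanishes continuously at the range
  $L_r = 121.2$ nm. A single scale $\varepsilon = 0.5$ pN is used for
  every pair type and the boundary; it models the entropic-brush repulsion
  of neurofilament sidearms and similar polymer coats.
* **Motor springs.** A bonded cargo–microtubule pair is coupled through a
  zero-rest-length spring, $\kappa d$ for $0 \le d \le R_b$, zero beyond
  the capture radius $R_b = 80$ nm (the bond itself persists; only its
  force vanishes). $\kappa^N = 0.18$ pN/nm for neurofilaments,
  $\kappa^O = 0.9$ pN/nm for organelles (several motors act at once).
* **Displaced-fluid heuristic.** While an organelle pushes into the plane
  (axial offset $z < 0$, radius growing) it shoves axoplasm ahead of
  itself; this is represented by doubling the repulsion prefactors
  $\varepsilon^{kO}, \varepsilon^{Ok}$ of all its pairs. Receding
  organelles ($z \ge 0$) use the plain prefactor, and the organelle's own
  boundary term is never doubled. If two growing organelles interact, the
  doubling applies per organelle (factor 4) — the rule is stated per
  organelle and we compose it multiplicatively; the case is rare since it
  requires two freshly entered organelles in contact range.

An organelle is a spindle of half-length $a$ and maximal radius $b$
(default $b = 140$ nm, $a/b = 10$): at axial offset $z$ its
cross-sectional radius is $r^O = b\,(1 - z^2/a^2)$, and it traverses the
plane at $s^O = 1\ \mu$m/s, so each passage lasts $2a/s^O$ (2.8 s at the
defaults).

With the thermal energy fixed at $k_BT = 4.11\times10^{-3}$ pN·µm
(≈298 K), the Einstein relation reproduces the reference diffusivities of
all three species from their drags (73.5, 512, 40.3 pN·s/µm →
5.59×10⁻⁵, 8.02×10⁻⁶, 1.02×10⁻⁴ µm²/s) to within 0.1%, which is the
package's internal consistency check between its mobility and noise
parameters.

## Cargo kinetics

All discrete events are Bernoulli-thinned once per kinetics tick of length
$h_{\text{slow}}$ with probability (rate × tick); at the default rates
every such probability is ≤ 0.04, so first-order thinning error is
negligible. A strict per-substep mode (`strict_kinetics = TRUE`) is
available for checking that the tick-wise treatment does not matter.

* **Neurofilaments.** An unbound filament with at least one microtubule
  within $R_b$ binds at $k_{on}^N = 10^{-2}$/s, choosing its track
  uniformly among candidates; each filament holds at most one bond (the
  stationary bound fraction near a single track is
  $k_{on}/(k_{on}+k_{off}) \approx 0.13$, so dual engagement would occur
  with probability ≈ 0.017 and is neglected). A bound filament draws one
  variate per tick against the cumulative probabilities of unbinding
  ($k_{off}^N = 6.5\times10^{-2}$/s) and departing ($k_{out}^N = 0.1$/s),
  so the two competing fates cannot both fire in a tick. Departure models
  transport out of the plane and conserves filament number: the departed
  filament is immediately re-seeded at gap $R_b$ from an *eligible*
  microtubule — one that already has another neurofilament within $R_b$ —
  at a uniformly drawn collision-free angle. Eligibility encodes the
  physical constraint that a filament can only appear in the plane where
  filaments exist in the adjacent plane, and is what makes remixing after
  segregation proceed inward from the rim of the microtubule island
  rather than by teleportation into its interior. If no eligible track or
  clear placement exists (100 attempts), the departure is cancelled for
  that tick. Only bound filaments depart; unbound ones are not being
  hauled. Replacement draws the track uniformly from all eligible
  microtubules, including possibly the one just left.
* **Organelles** arrive as a Poisson stream at $k_{in}^O = 0.105$/s
  (no-op when no microtubule exists to ride), entering with $z = -a$
  (radius 0) at gap $R_b$ from a uniformly chosen track to which they are
  immediately engaged; they advance deterministically, engage further
  microtubules within $R_b$ at $k_{on}^O = 2$/s (release at
  $k_{off}^O = 2$/s), and leave with all their bonds when $z$ reaches
  $+a$. The optional cap `m_max` limits simultaneous engagements; new
  bonds are simply refused at the cap. Because a mid-passage organelle of
  radius 140 nm reaches microtubule centers up to 232.5 nm away,
  multi-track engagement is geometrically generic — this is the zippering
  that pulls microtubules pairwise together.

Event ordering within a tick is: scheduled parameter changes →
neurofilament events → organelle arrival → organelle engagement kinetics
→ mechanics. Organelle release is evaluated before new engagements inside
the same tick, which biases stationary occupancy upward by $O(kh)\sim1\%$;
the alternative orderings differ at the same order.

## Integration and the contact guard

The Euler–Maruyama scheme (strong order 1.0 here, since the noise
amplitudes are constant) uses the two-level step of the reference
protocol: $h_{\text{slow}} = 1/50$ s while no organelle is present,
$h_{\text{fast}} = 1/1600$ s otherwise. The stiffness that motivates the
fast step is real: a growing organelle advances its surface regardless of
opposing force, and a particle trapped against the surrounding crowd can
be driven to arbitrarily small gaps, where the pair stiffness
$\partial F/\partial d \approx 2\varepsilon L_r/d^2$ exceeds $\mu/h$ below
$d \approx 0.4$ nm and the explicit scheme turns oscillatory-unstable,
ratcheting into overlap.

The integrator therefore enforces a *gap guard*: a proposed displacement
that would take any monitored close pair (or boundary gap) below 0.05 nm
is rejected; the noise is redrawn up to three times, then the step is
halved — down to $h_{\text{fast}}/1024$ — and the reduced step is carried
forward and doubled back toward nominal after successes. The guard value
sits below every force balance the dynamics can produce (an organelle
engaging many tracks can squeeze a trapped particle with several hundred
pN, which the diverging repulsion only matches near 0.1–0.3 nm gaps — a
guard above those equilibria would deadlock), yet crossing from a 1 nm gap
down to it costs ≈40 $k_BT$ against the repulsion, so thermal
trajectories never visit the excluded band; the guard only tames the
bulldozing regime, where the model's forces are effectively hard
constraints. Close approaches are monitored through the pairs that came
within 25 nm during the force evaluation (plus every organelle pair and
near-boundary particle). So that no *unmonitored* pair can reach contact
within a single step, each step is also capped by the forces actually
present: if the largest drift displacement plus a 5-sigma noise allowance
would exceed 10 nm, the step shrinks until it does not. In a relaxed
configuration the cap never binds (typical displacements are ~1 nm at
$h_{\text{slow}}$); it engages exactly where a squeezed particle would
otherwise be kicked tens of nm in one Euler step — which is also where
the explicit scheme needs a smaller step for accuracy. True overlap in an
*input* configuration is reported as an error.

Pair forces are evaluated through a Verlet list built on a uniform grid
(12 nm skin, rebuilt when accumulated displacement could invalidate it);
organelles, never more than a handful, are paired against everything
directly. A plain-R double-loop oracle in the test suite pins the
compiled kernel to the written force laws at machine precision.

All randomness — noise increments and kinetic events alike — comes from
one xoshiro256++ stream (ziggurat normals) seeded by the user-visible
integer seed, making every run bit-reproducible from its metadata; R's
global RNG state is never touched.

## The initial-condition generator, and what "normal" means

Mixed configurations are generated the way the reference protocol
describes: particles seeded on a hexagonal lattice (types assigned to
sites uniformly at random), then randomized under repulsion, boundary
force and Brownian motion alone — no bonds, no cargo exchange — for 60 s
(step $h_{\text{slow}}$), with an optional guard that stops once the mean
pairwise MT distance (PDMT) changes by <1% over 10 s. The
neurofilament-only protocol uses a 1 µm periodic square, $h = 1/200$ s,
and 25 s of randomization.

Two facts about this generator matter for interpreting statistics, and we
measured both. First, microtubules are slow
($D_M = 8\times10^{-6}\ \mu$m²/s ⇒ ~90 nm displacement in 4 minutes), so
the random site assignment leaves a seed-dependent bias in MT-dependent
observables that randomization does not erase: init-only mean PDMT ranges
0.83–0.92 $R_0$ across seeds. Second, prolonging plain randomization does
not converge it to the normal-axon value but drifts it *upward* — the sea
of small neurofilaments pushes the large microtubules toward the boundary
(a depletion effect). The interspersed "normal axon" of the model is the
steady state of the *full control dynamics* (transport and organelle
traffic active), which wanders around ≈0.80–0.85 $R_0$ with ±0.04 slow
fluctuations (correlation time 30–60 min). The package therefore measures
normal-axon PDMT by running the control scenario for a settling period
after initialization and averaging frames, and the segregation trend
checks branch blocked/control/capped arms from the same settled state —
mirroring the reference protocol, which also runs 1 h of normal dynamics
before blocking transport.

## Analysis statistics

* **PDMT** — all microtubule center-to-center pair distances; the
  per-frame mean is the segregation order parameter (≈0.8 $R_0$ normal,
  dropping by tens of percent on segregation). Center distance is used:
  the 35 nm shift to surface distance is negligible against 800 nm and
  nothing in the source indicates otherwise.
* **RDF** $g(r)$ — pair-correlation estimate from 5 nm distance bins
  (bin width chosen to resolve a first peak expected below ~70 nm;
  configurable), normalized by the uniform-pattern expectation
  $\rho\,2\pi r\,\mathrm{d}r$ per reference particle and averaged over
  frames. Periodic domains use minimum-image distances and need no edge
  correction; bounded disks restrict reference particles to those at
  least $r_{\max}$ from the boundary (the simplest unbiased estimator —
  the quantitative RDF protocols here all use the periodic domain, where
  the question is moot). The first-peak locator refines the argmax bin by
  a parabola through its neighbors; its resolution is half a bin either
  way. At 400 NF/µm² the mean spacing is 53.7 nm and the measured peak
  sits at 50 ± 0.3 nm, at the upper edge of the reported 30–50 nm band.
* **OPD** $p_n$ — occupancy counts of circular windows (radius 60 nm)
  placed uniformly (fully interior for disks), pooled over windows and
  frames, with an unweighted least-squares Gaussian fit to the normalized
  histogram (Nelder–Mead, initialized at the empirical moments). Window
  placement uses a small private Lehmer stream so results are reproducible
  without touching the global RNG.

The exact estimator details of the original study's supplementary text
are not available; the defaults above are the package's own documented
choices, and the tests validate them against analytic nulls (Poisson
patterns, lattices) rather than against that text.

## What the synthetic scenarios do and do not show

The presets reproduce the simulated protocols: neurofilament-only
morphometrics (densities 200 and 400 /µm², repulsion 0.5 and 0.25 pN);
the control axon; reversible segregation (binding off at 1 h, restored at
13 h); the engagement-cap sweep (`m_max` 1–16); organelle size/flux
variants (b = 140/70 nm, flux ×1/×1.5/×2); partial blockage (on-rate
×0.5/×0.2/×0); and off-rate blockage (×100). Scenario runs at full
duration (12–20 h simulated) take hours of CPU; the shipped tests instead
use the settled-branch design described above at desk scale (2 h settle,
2.5 h arms, three seeds — sizes chosen to hold the slow PDMT wander to a
fraction of the blocked-arm signal), which exercises the directional
claims (segregation under blockage, none under control or `m_max` = 1)
but not the quantitative endpoints of the full protocols (the ≈40% PDMT
drop, 4–12 h segregation, 2–8 h remixing).

Passing them says the model's mechanism operates as described under the
stated parameters; it does not validate the parameters against new
experimental data, nor does the 2D plane capture longitudinal
accumulation, axonal swelling, cross-linking proteins, or explicit
hydrodynamics — all outside this model's scope by construction.

## Known limitations

* The gap guard substitutes for proper stiff-contact integration; an
  implicit or event-driven scheme would remove the rejection machinery.
* Organelle engagement iterates microtubules in index order when filling
  a small `m_max` cap within one tick, a negligible ordering bias at the
  default rates (engagement probability 0.04 per tick).
* The hexagonal seeding uses a slightly strained lattice in periodic
  boxes so that any count fits the box exactly; randomization erases the
  strain.
* Trajectory storage is plain text (CSV directories); at every-step
  snapshot cadence this is bulky — it is meant for frame cadences of
  0.1 s and coarser.
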