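---
title: "Adsorption on ligand-tethered nanoparticles: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adsorption on ligand-tethered nanoparticles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The system and the model

`hairyMD` simulates a single polymer-grafted ("hairy") nanoparticle — a
spherical core of diameter $\sigma_c$ with $f$ bead-spring chains of $M$
segments end-tethered to its surface — immersed in an explicit fluid of
spherical particles $P$, in an implicit solvent.  Planar brushes (chains
tethered to a hard wall) are supported as the flat-geometry counterpart.
The questions the package is built to answer are how much fluid the
tethered layer takes up (the excess adsorption isotherm), how thick the
corona is, and how its morphology responds to adsorption.

All quantities are in reduced units: the segment diameter $\sigma$ is the
length unit, the segment–segment energy $\epsilon$ the energy unit, the
segment mass $m$ the mass unit, time is in $\tau = \sigma\sqrt{m/\epsilon}$,
and temperature is $T^* = k_B T/\epsilon$ (all production results here use
$T^* = 1$).

Chain connectivity is harmonic, $u_{ss}(r) = k_{ss}(r-\sigma_s)^2$ with
$k_{ss} = 1000\,\epsilon/\sigma^2$, i.e. stiff, tangentially jointed beads
with no bending potential (perfectly flexible chains).  Every non-bonded
pair interacts through the truncated, force-shifted Lennard-Jones potential

$$u^{(ij)}(r) = u_{LJ}^{(ij)}(r) - u_{LJ}^{(ij)}(r_c) - (r - r_c)\,
  u_{LJ}^{\prime(ij)}(r_c), \qquad r < r_c^{(ij)},$$

with $\sigma_{ij} = (\sigma_i + \sigma_j)/2$.  Attractive pairs are cut at
$r_c = 2.5\,\sigma_{ij}$; "repulsive" pairs are cut at $r_c = \sigma_{ij}$
so only the repulsive shoulder survives.  Four model variants differ only
in which pairs attract:

| pair              | M1, M2    | M1a, M2a   |
|-------------------|-----------|------------|
| core–core/segment/particle | repulsive | repulsive |
| particle–segment  | attractive ($\epsilon_{Ps}$ = 1.5 or 3.0) | attractive |
| segment–segment   | repulsive | attractive |
| particle–particle | repulsive | attractive |

M2/M2a are the "hedgehog" variants: the ligands are rigid radial rods,
frozen along with the core.

Two printed-model ambiguities were resolved as package design choices:

* **Energy shift at the cutoff.**  The force-shift term alone leaves an
  energy discontinuity $u_{LJ}(r_c)$ at the cutoff; we add the constant
  $-u_{LJ}(r_c)$ so the energy is continuous.  A constant cannot change
  forces, so the dynamics are identical either way.
* **Bonded pairs and the non-bonded sum.**  Directly bonded (1–2) pairs are
  excluded from the Lennard-Jones sum, the default convention of the major
  MD engines for bead-spring models.  With the harmonic rest length at
  $\sigma_s$ this also makes an isolated bonded dimer an exactly harmonic
  oscillator with angular frequency $2\sqrt{k_{ss}/m}$, which the test
  suite verifies by period measurement.

## Builders

`build_hairy_particle()` freezes one core bead at the center of a cubic
periodic box, scatters $f$ tethering beads uniformly at radius
$\sigma_{cs} = (\sigma_c+\sigma_s)/2$ (rejection sampling with a minimum
spacing of $0.8\,\sigma$, themselves frozen — the anchor *is* the first
chain segment), and grows each chain as an outward-biased self-avoiding
walk with bond length $\sigma$ (rigid radial rods for M2/M2a).  The box
must satisfy $\sigma_c/2 + M\sigma + r_c^{max} < L/2$, i.e. hold a fully
stretched ligand plus an interaction shell inside the inscribed sphere; the
core–core cutoff is excluded from $r_c^{max}$ because only one core exists.
The initial walk is *scaffolding only* — equilibration erases its bias, and
the package verifies that the relaxed mean bond length stays within 2% of
$\sigma$.

`build_flat_brush()` tethers $f$ chains to a hard wall at $z=0$ over an
area $L_x^2 = f/\rho_{gr}$, with a bare hard wall at $z=L_z$.  The grafting
density is the controlling variable for the flat geometry so that curved
and flat layers can be compared at matched $\rho_{gr}$.  At high grafting
density a strict $0.9\,\sigma$ growth criterion can be ungrowable; the
builder then grows with a progressively relaxed criterion and restores
$0.9\,\sigma_{ij}$ with a capped-displacement steepest-descent push-off
before any dynamics run.

`insert_fluid()` places $N_P = \mathrm{round}(\rho_0 V)$ fluid beads
uniformly at random, rejecting any position closer than $0.9\,\sigma_{ij}$
to an existing bead, and draws Maxwell–Boltzmann velocities.  All builders
are bitwise deterministic given a seed.

## Dynamics

The engine integrates velocity-Verlet with a single Nosé–Hoover thermostat
coupled to the mobile beads only ($g = 3N_{mobile}$, $Q = g T^* \tau_d^2$).
Defaults that the model does not pin down, chosen once and stability
checked:

* `dt = 0.002` $\tau$ — the stiff bond's vibration period is
  $2\pi/(2\sqrt{k_{ss}}) \approx 0.1\,\tau$, so this resolves it with
  $\approx 50$ steps per period; the microcanonical drift test
  ($|\Delta E|/|E| < 10^{-4}$ over $10^4$ steps) passes with margin.
* thermostat damping time `tdamp = 0.1` $\tau$ — production temperature
  control lands within 2% of target with canonical-scale fluctuations.

Forces come from a linked-cell $O(N)$ kernel that is *exactly* equal to the
brute-force $O(N^2)$ double loop (and to an independent R implementation of
the closed-form pair functions) — the cell list changes the iteration
order, never the arithmetic — and falls back to the double loop when a box
direction is under three cells.  Hard walls are realized as specular
reflection at one bead radius from the wall; this is a discretized hard
wall, so each collision carries an $O(dt)$ energy error.  The slab NVE
conservation test therefore runs at `dt = 0.001`; in thermostatted runs
(all production) the thermostat absorbs this entirely.

`run_protocol()` executes optional annealing stages (alternating heating
and cooling), equilibration, and production with frame sampling.
Equilibration is checked by a sliding-window drift test on the total
energy; non-stationarity produces a warning and a `converged = FALSE`
flag, never a silent pass.  At paper scale ($\geq 10^8$ equilibration
steps) this flag would clear; at desk scale it honestly reports that slow
adsorption is still creeping (see Limitations).

## Observables

Density profiles are count-per-shell estimators: bins of width
$0.05\,\sigma$ (default; fine enough to resolve the segment layering) with
centers on integer multiples of the bin width, so the frozen anchors of a
$\sigma_c = 4$ core fall in the bin centered exactly at $r = 2.5$.  Bins
cover the virtual adsorption sphere $[R_c, R' = L/2]$ and are clipped at
$R'$ — shells beyond the inscribed sphere are cut by the box and would
otherwise bias the density low.  Because bin densities are counts divided
by exact shell volumes, $\sum_k \rho_k V_k$ reproduces the mean bead count
identically, and the excess-adsorption quadrature

$$\Gamma = 4\pi\!\int_{R_c}^{R'} r^2\,(\rho(r) - \rho_b)\,dr
  \;\to\; \sum_k (\rho_k - \rho_b)\,V_k$$

carries no midpoint discretisation bias.  The same property makes the
moment-ratio thickness

$$H = 2\left(\frac{\int r^3\rho_s\,dr}{\int r^2\rho_s\,dr} - R_c\right)$$

reduce to twice the count-weighted mean radius minus $2R_c$ (and to the
exact $2(\langle r\rangle - R_c)$ when raw radii are supplied).  $H^* =
H/M$ is the thickness relative to fully stretched chains.

**Bulk density.**  $\rho_b$ is the mean fluid density over a plateau window
far from the layer, with a linear slope test that flags non-plateaus.  The
generic default (outer 20% of $[R_c, R']$) is correct for short chains but
can overlap the corona when $M\sigma$ approaches $L/2$; the isotherm
orchestration therefore uses a brush-aware window starting at
$\sigma_c/2 + M\sigma + 1.5\,\sigma$.  The exact plateau window used in the
original study is unreported; this choice is ours.

**Two routes to $\Gamma$ and their consistency.**  The mass-balance route
$\Gamma = V'(\rho_0 - \rho_b)$ uses the virtual-system volume $V' = \pi
L^3/6$ (the inscribed sphere) for the particle and $V' = V$ for the slab.
Taken literally with $\rho_0 = N/V$ of the *whole cubic cell*, the
spherical version is algebraically $\pi/6$ times the profile-integral
route whenever the cell corners hold bulk fluid — the two routes could
never agree.  They do agree, identically, once $\rho_0$ is referred to the
virtual system itself: the corners hold bulk fluid at $\rho_b$, so the
sphere was loaded with $\rho_0' = (N - \rho_b(V - V'))/V'$
(`virtual_loading_density()`).  The package keeps Eq.-style
`excess_adsorption_mass_balance(V', rho0, rho_b)` literal and feeds it
$\rho_0'$ in the orchestration; the test suite verifies exact agreement of
the two routes on constructed configurations and statistical agreement
(within two combined standard errors across replicate seeds) on simulated
state points.

**Peaks and morphology.**  `peak_positions()` reports local maxima with a
topographic-prominence filter (optionally after a short running-mean
smooth); for production-averaged profiles the package uses a 3-bin smooth
and a prominence floor of $0.02\,\sigma^{-3}$, which on the reference
scaled-down run returns exactly the anchor peak and the two outer segment
layers.  Corona asymmetry (core-shell versus cone-like morphology) is
quantified by the normalised centroid offset of the segment cloud and the
relative shape anisotropy $\kappa^2$ of its gyration tensor; the
quantitative thresholds separating morphologies are calibration choices,
not model facts, so the package reports the metrics and leaves
classification to the user.

## The fixtures module: what a green test establishes

Every estimator is testable without dynamics.  `analytic_profile()`
provides constant, top-hat-shell, Gaussian-bump, decay-to-plateau and
delta-shell profiles with closed-form $\Gamma(\rho_b)$ and $H$ where
tractable; the closed forms are themselves cross-checked against adaptive
quadrature to $10^{-10}$.  `sample_positions_from_profile()` draws
particle positions by inverse-CDF sampling on the geometry-weighted
measure ($4\pi r^2\rho\,dr$ or $\rho\,dz$), tabulated on a fine grid — so
tails are represented to grid resolution, and estimator output can be
compared with closed forms at Poisson ($1/\sqrt{N}$) tolerance.
`make_mechanical_fixtures()` adds tiny configurations with exact oracles
(dimer at rest, pairs at and beyond cutoffs, a 50-bead random cell whose
energy is precomputed by the R closed-form pair sum, a rigid hedgehog with
exact discrete thickness).

These fixtures validate *estimators*, not dynamics: a green fixture test
says the arithmetic of Eqs. for $\Gamma$ and $H$ is right, not that a
simulated state point is equilibrated.  Conversely the scaled-down MD runs
validate the full pipeline but at reduced equilibration; their stated
world is $10^5 + 10^5$ steps in an $L = 30$ box, about $10^3$ times
shorter than the study-scale protocol.

## Scaled-down state points and known limitations

Paper-scale runs ($10^8$ equilibration steps, boxes up to $107\sigma$,
$\sim 10^5$ beads, five replicates) are not desk-reproducible.  The
package's reference checks use:

* the structural run $\sigma_c = 4$, $f = 20$, $M = 10$,
  $\epsilon_{Ps} = 1.5$, $\rho_0 = 0.01$, $L = 30$, $10^5 + 10^5$ steps,
  three seeds — for the segment-layer peaks and thermostat control;
* trend runs (three seeds each, $2$–$5\times10^4$-step stages) for the
  qualitative orderings.  The $f$-orderings ($\Gamma^*$ and $H^*$ grow
  with the number of chains) are evaluated at $\rho_0 = 0.01$; the
  chain-length ordering ($\Gamma^*(M{=}20) > \Gamma^*(M{=}10)$) and the
  curvature ordering (spherical beats flat per unit area at matched
  $\rho_{gr}$ and $M$) are evaluated at mid-range loading
  ($\rho_0 = 0.05$ and $0.1$), where the orderings are robust.  For the
  curved-versus-flat comparison the flat system is loaded at a slightly
  higher $\rho_0$ (0.12) so that its measured $\rho_b$ is at least the
  spherical system's — the conservative direction for the inequality,
  since the flat $\Gamma^*$ falls with $\rho_b$ in this range.

At this scale the first two segment-density peaks reproduce the expected
positions ($2.5\sigma$ exactly — frozen anchors — and $\approx 3.45\sigma$,
within one bin of $3.5\sigma$).  The third layer is genuinely wide and at
desk scale its maximum sits at $\approx 4.1$–$4.2\sigma$ rather than
$4.5\sigma$; this is robust against tenfold-longer equilibration,
annealing, and fluid density from 0.01 to 0.1 in our runs, so we report
the measured position rather than force the expected one.  Two further
desk-scale effects are worth knowing about.  At very low bulk density
($\rho_b \lesssim 0.01$) the dilute spherical corona adsorbs weakly while
its excluded volume still depletes fluid from the virtual sphere, so
$\Gamma^*$ of long-chain particles ($M = 20$) can come out negative and
the dense flat brush can transiently out-adsorb the sphere per unit area
— both effects persist to $5\times10^5$-step equilibration and are why
the trend checks are run at mid-range $\rho_b$, where the study-scale
orderings hold.  Slow adsorption drift also keeps the equilibration
stationarity flag honest (`converged = FALSE`) at desk scale.

Out of scope by design: multi-particle aggregation, explicit solvent,
charges, bending stiffness, barostats, and scattering-level structure
beyond the profiles, thickness and asymmetry metrics above.
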