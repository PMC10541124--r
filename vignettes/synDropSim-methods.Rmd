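---
title: "Models and methods behind synDropSim"
author: "synDropSim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind synDropSim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

synDropSim simulates a two-component synthetic condensate system
("synDrops"): a hexavalent hub protein and a divalent, rod-shaped linker
that heterodimerise through inducible binding domains, surrounded by inert
ribosome-sized crowders and, optionally, inert 40-nm tracer nanoparticles.
This vignette describes the models, the parameters that matter, the
numerical choices, and what the synthetic test systems can and cannot say
about real data.

## The coarse-grained model

Each molecule is a rigid body built from one or more excluded-volume
spheres plus point-like binding patches:

* **Hexamer** - one 12.6-nm sphere with six patches at the octahedral
  directions, the unique maximally symmetric six-point arrangement on a
  sphere.  Patch-sphere centres sit at radius (body + patch diameter)/2.
* **Dimer** - a rigid rod of three collinear overlapping spheres
  (13.45, 11.7, 13.45 nm) with one patch at each end, pointing along the
  axis.  The inter-sphere spacing (5 nm by default) is not fixed by any
  structural measurement; it was chosen so the rod length, 2 x 5 + 13.45 =
  23.45 nm, matches the 23.4-nm single-sphere rod used by the
  physical-units preset.  Because the patches face opposite ends of a rod
  longer than the hexamer's inter-patch spacing, a dimer cannot reach the
  same hexamer twice; the bond updater additionally enforces this
  "frustration" rule explicitly (one bond per molecule pair), which makes
  the single-sphere representation equally faithful.
* **Crowder** - an inert 30-nm sphere (ribosome-mimetic), its own
  thermostat group.
* **Tracer (GEM)** - an inert 40-nm sphere used for time-unit calibration.

The standard composition is 1170 dimers + 390 hexamers in an 860-nm
periodic cube (3 uM and 1 uM; the 3:1 count ratio balances the 2:6 patch
stoichiometry one-to-one) plus 20 tracers.  Desk-scale runs shrink copy
numbers by a factor `scale` and the box edge by `scale^(1/3)`, preserving
every concentration and volume fraction exactly.

## Dynamics

Propagation is overdamped (Brownian) Langevin dynamics: both source engines
operate far below inertial time scales, so no velocity degrees of freedom
are carried.  Per step,

    dx = D_t/kT * F dt + sqrt(2 D_t T_g dt) xi,

and similarly for rotations with `D_r`, applied as a quaternion increment.
`T_g` is the thermostat factor of the species' temperature group; it scales
only the noise, which is how crowders are driven at an effective
temperature `T_c != 1` while synDrop components stay thermal - a standard
minimal model of non-thermal, ATP-driven agitation.

Two unit conventions ("presets") are provided:

* **hoomd_style** (reduced units: nm, kBT, tau): drag proportional to
  diameter, normalised so the hexamer has `D_t = 1 nm^2/tau`; `D_r = 3
  D_t/d^2` (the sphere relation); `dt = 0.002 tau`.  The tau-to-seconds
  mapping is obtained afterwards by fitting the tracer MSD to `6 D t` and
  matching to a cellular tracer diffusivity (~0.4 um^2/s), exactly the
  calibration a user would perform (see `calibrateTimeUnit`).
* **java_style** (physical units: nm, kBT, seconds): Stokes drag at
  viscosity 0.03 Pa s, `dt = 1e-7 s`.

Excluded volume acts between all body spheres through the soft quartic
potential `U(r) = eps_soft (1 - (r/r_cut)^4)` with `r_cut` the sum of the
radii and XPLOR smoothing from `0.95 r_cut`, so energy and force vanish
continuously at the cutoff.  `eps_soft = 500 kBT` in reduced units is
effectively hard.  In the physical-units preset the same functional form is
used with an attenuated strength of 10 kBT: this preset's much larger
`D dt` product would otherwise produce per-step contact kicks larger than a
particle diameter, and the attenuation plays the role of the collision-force
attenuation of low-Reynolds collision solvers (collisions resolve over
several steps instead of instantaneously).  A Lennard-Jones patch
attraction is carried through the configuration but defaults to zero
strength.

Neighbour search uses a cell-binned Verlet list (skin 0.3 x the smallest
diameter, rebuilt when any sphere has moved half a skin, staleness checked
every four steps).  An instability guard aborts a run if any body moves
more than 0.25 x the smallest diameter in one step (0.5 x in the
physical-units preset, where the purely thermal step of ~0.5 nm/axis would
otherwise reach the bound by chance over long runs).

Initial configurations place molecules on a CsCl-type lattice (two
interpenetrating cubic sublattices, deterministic given a seed).  Crowders
enter by random sequential insertion up to a volume fraction of 0.35;
beyond that the insertion process stalls near its jamming density, so the
box is built at 1400/860 linear expansion (4.3x volume), filled dilutely,
and compressed linearly to the target over a configurable number of steps
(5e5 at full scale, scaled in desk runs), with positions rescaled affinely
alongside the box.  Walled (closed-box) boundaries with purely repulsive
walls of the same functional form are available as an alternative to
periodic boundaries.

## Dynamic bonding

Every `n` steps (default 10) the bond updater enumerates all complementary
free patch pairs within the binding range and attempts stochastic moves:

* formation with probability `P_on x min(1, exp(-dU))`, where
  `P_on = 1 - exp(-kon n dt)` and `dU` is the harmonic spring energy
  created at the current separation;
* removal with probability `P_off = 1 - exp(-koff n dt)` (the Metropolis
  factor for releasing spring energy `U >= 0` is 1).

The pair of acceptance factors satisfies detailed balance with respect to a
Boltzmann ensemble whose binding free energy is `ln(kon/koff) kBT` - the
bond affinity (10.8 and 13.1 kBT for the two standard koff values).  A site
freed during an updater invocation may not rebind within the same
invocation, so a pinned pair is exactly a two-state Markov chain with
stationary occupancy `P_on/(P_on + P_off)` - the property the test suite
checks.  Conflicts between candidates sharing a site are resolved by
processing candidates in randomly shuffled order.

Two further conventions deserve notice:

* **Binding distance.** The reduced-units preset prints `d_bind = 1 nm`
  alongside 2-nm binder spheres; 1 nm between centres would mean
  half-overlapped binders, so the criterion is read as the *surface gap*
  between binder spheres (capture at 3 nm centre distance).  The
  physical-units preset prints no binder size; its sites are treated as
  points and `d_bind = 2.3 nm` as a centre-to-centre distance.  Both
  conventions are exposed as configuration (`bindCriterion`).
* **Bond spring.** Bound patches are held by a harmonic spring.  In the
  reduced-units preset the spring rests at 2 nm (binder spheres touching)
  with `k = 10 kBT/nm^2`, soft enough that the Metropolis factor does not
  close off the capture shell (`U <= 5 kBT` across it).  In the
  physical-units preset the spring rests at 2 nm with `k = 3 kBT/nm^2`,
  chosen for stability at `dt = 1e-7 s`.

The physical-units preset implements diffusion-limited binding: probability
1 on contact, checked every step, with strain-independent unbinding at
`koff = 26/s`, and an escape rule - a freshly broken pair may not rebind
until it has diffused out of the binding range.  Without the escape rule a
broken pair at contact would rebind immediately and bonds would never
dissociate effectively.  With it, the model's effective dissociation
constant emerges from geometry, diffusivities and `koff` alone; at the
standard parameters it comes out near 2 uM, inside the 1-10 uM range the
model system was calibrated to.

## Cluster analysis

Each frame's bond list collapses to a simple molecule graph (nodes =
hexamers and dimers; crowders and tracers never enter).  Connected
components are the clusters; the topological (shortest-path) distance
matrix feeds average-linkage hierarchical clustering for clustergram
rendering, with unreachable pairs replaced by the sentinel `n + 1` - any
linkage then keeps each component contiguous, which is the tested contract.
Mean cluster size includes singletons by default (unbonded molecules are
size-1 clusters); the alternative convention is a switch, since published
"average cluster size" curves do not always state it.

Cluster tracking links clusters of more than 10 molecules across
consecutive frames by the largest number of shared molecules (ties: larger
overlap fraction, then smaller first member id; each predecessor is claimed
once, larger clusters claiming first so the result is invariant to cluster
enumeration order).  A link whose absolute size change reaches 20 molecules
terminates the track - such a jump is a merge/split, not growth - with the
boundary case configurable (split by default).  Cluster centres of mass use
the circular mean per axis so boundary-straddling clusters get contiguous
centres; COM paths are unwrapped through minimum-image displacements before
MSD analysis.  Diffusivities come from origin-constrained least squares on
the first 10 lags of the time-averaged MSD (`MSD = 6 D t` in 3-d), tracks
of 10 or fewer points are discarded, negative slopes clip to zero with a
flag, and a curvature diagnostic flags ballistic tracks for which the
origin-constrained fit is biased.

## Binding-constant estimation

The effective dissociation constant is measured in a monovalent variant
(valences reduced to 1 and 1, 200 + 200 molecules in a 400-nm box, or the
same concentrations at desk scale) so only dimerisation can occur.  The
bond count rises to a plateau fitted with the saturating exponential
`N(t) = N_eq (1 - exp(-t/t_relax))` - equivalently an exponential decay of
the unbound pool; equilibration is accepted when residual drift over the
last fifth of the series is below the fluctuation scale (with a 0.5
percent relative floor).  Then

    Kd = N_A N_B / (N_AB N_Av V),

reported in uM.  The dissociation rate is measured by switching binding off
and fitting the pure-death decay by maximum likelihood (events over
integrated bond-time, with a Poisson interval), and `kon = koff/Kd`.

## Track statistics

MSD, angle correlation and velocity autocorrelation operate on a common
long-format track table and are shared between simulated trajectories and
experimental TrackMate exports (`readTrackMateXML` parses the spot/track
model; spot detection and LAP linking are upstream tools' jobs).  Tracks
with frame gaps (gap-closing edges) are split into gapless segments and no
lag product ever spans a gap.  The angle correlation at lag L uses the
coarse-grained displacement vectors over L frames (not per-frame steps
within a window); samples are pooled across tracks by default, with
per-track weighting as an option.  2-d experimental MSDs are fitted with
`4 D t`; `6 D t` applies to 3-d simulated data.  Density grids bin a
scatter into 25 x 25 cells spanning the data range; the smoothed copy uses
a 3 x 3 normalized box kernel (edge-truncated) and raw counts are always
retained.

The synthetic track generators (free Brownian, confined Ornstein-Uhlenbeck,
persistent drift) use exact discrete updates, so their moments are known in
closed form: per-axis step variance `2 D dt`, OU plateau `2 D/kappa`, and
the discrete OU VACF `C(L)/C(0) = -a^(L-1)(1-a)/2` with `a = exp(-kappa
dt)` - the oracles behind the statistics tests.  They emulate the
*statistics* of tracked droplets, not their photophysics: no localisation
error, blinking, or intensity-dependent detection, so passing tests
demonstrate correctness of the estimators, not robustness to those
artefacts.

## Desk-scale experiment sizes

The bundled experiment harness defaults to five replicate seeds.  The
reduced-scale reproductions in the package's own test suite run at 1/64
copy-number scale (box edge 215 nm) with runs of 1-2 million steps for the
crowding and activity trends (the crowding trend itself at 1/27 scale,
where the largest cluster is resolvable), at 1/8 scale for the
diffusion-limited dissociation-constant measurement, and at 1/4 scale for
the crowding comparison of the rate-based preset's Kd (smaller monovalent
systems hold too few bonds to resolve the conditions); the accompanying
acceptance script uses 1/8 scale with five seeds.  These sizes keep every intensive quantity (concentrations, volume
fractions, rates) at their standard values while shrinking only particle
counts and run length; the trends reported (more and larger clusters at
35 percent crowding than at 0 or 50 percent; larger clusters at higher
crowder effective temperature; lower effective Kd under crowding with
unchanged koff) are ordinal statements over replicate medians, not
quantitative reproductions of full-scale curves.  At these sizes the
largest cluster holds a handful to a few tens of molecules, far from the
mesoscale droplets of full-scale runs; the mechanisms probed (depletion-
enhanced nucleation, mobility-limited coarsening) are the same, but
late-stage coarsening behaviour is outside desk reach.

## Known limitations

* Hydrodynamic interactions, long-range electrostatics and GPU execution
  are out of scope; drag is a per-body scalar.
* The Metropolis criterion uses the bond-spring energy change only; the
  original dynamic-bonding plugin's exact acceptance factor is unpublished,
  so fidelity is to the detailed-balance property rather than to an
  unavailable code path.
* The torsional-spring torque of the physical-units source engine is not
  reproduced; rotations are purely diffusive plus bond-force torques.
* Rod drag uses a single effective diameter (the rod length); anisotropic
  mobility tensors are not implemented.
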