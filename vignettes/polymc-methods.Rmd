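---
title: "Models, moves and the crystallographic descriptor in polymc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, moves and the crystallographic descriptor in polymc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

polymc simulates coarse-grained systems of spherical monomers — free, or
connected into linear chains — with Metropolis Monte Carlo, and classifies
the local structure of the resulting configurations against reference
crystals. This vignette describes the model, the move set and its
acceptance rules, the structural descriptor, the synthetic generators used
throughout the test suite, and the numerical choices behind them.

## Model and units

All lengths are measured in units of the collision diameter $\sigma$ and
all energies in units of $k_BT$; both are set to 1 internally. A system of
$N_{at}$ monomers holds $N_{ch}$ linear chains of average length $N$ and
$N_s$ single monomers, with $N_{ch} N + N_s = N_{at}$. Cells are
orthogonal; dimensions are periodic unless confined by flat walls, a
cylinder (open or closed ends) or a sphere. Monomer centers keep a
clearance of $\sigma/2$ from every confining surface and from the surface
of each (immobile) spherical or cylindrical nanofiller.

Non-bonded pairs interact through one of

* hard spheres (HS): $\infty$ below $\sigma$, 0 beyond;
* square well / square shoulder (SW/SS): $\mp\varepsilon_{SW}$ on
  $[\sigma, \sigma_2)$, with a hard core below $\sigma$ — the shoulder is
  the sign flip of the well;
* Lennard-Jones: $4\varepsilon_{LJ}[(\sigma_{LJ}/r)^{12} -
  (\sigma_{LJ}/r)^6]$, truncated and shifted at $2.5\,\sigma_{LJ}$ by
  default. The prefactor 4 makes $\varepsilon_{LJ}$ the well depth at
  $r = 2^{1/6}\sigma_{LJ}$ and $\sigma_{LJ}$ the zero-energy point.

Bond lengths are constrained to $[\sigma, \sigma + dl]$ (the bond-gap
interval; tangency $dl = 0$ is a supported limit, and a lower bound below
$\sigma$ can be opted into for fused spheres). Bonded (1–2) pairs are
excluded from the non-bonded sum; 1–3 pairs interact by default, with a
documented switch to exclude them, since either convention appears in
coarse-grained MC codes. Stiffness enters through
$U_{bend} = k_\theta(\theta - \theta_0)^2$ with $\theta$ the supplement of
the internal bond angle in degrees ($\theta_0 = 0$ is fully extended;
$k_\theta$ in $k_BT/\mathrm{deg}^2$, 0 = freely jointed). A torsional term
$k_{tor}(1 - \cos(\phi - \phi_0))$ is available but off by default —
torsions fluctuate freely in every shipped protocol.

Three density measures are reported: the packing density
$\phi = (\pi/6)(N_{at}/V)\sigma^3$ (area-based in 2-d), the effective
density $\phi_{eff} = V_{mon}/(V - V_{fill})$ against the
filler-accessible volume, and the depleted density $\phi_{dep}$ whose
denominator also removes the $\sigma/2$ depletion layer along walls
($d_{wall} - \sigma$ per confined dimension) and around fillers (radius
grown by $\sigma/2$). For cylindrical and spherical confinement the
depleted volume uses the analogous $(\pi/4)(D-\sigma)^2 L$ and
$(\pi/6)(D-\sigma)^3$ forms; the non-depleted cylinder volume in
$\phi_{eff}$ is $(\pi/4)d_{cyl}^2 L_{cyl}$, the natural analog of the
depleted form. By construction $\phi \le \phi_{eff} \le \phi_{dep}$
whenever obstacles are present.

## Move set

Moves draw from a schedule of attempt probabilities. Local moves —
single-site displacement (per-dimension amplitude), internal flip
(rotation of an interior monomer about the axis of its bonded neighbors),
end-monomer rotation, reptation, intermolecular reptation, and end-segment
regrowth — optionally run in a configurational-bias pattern:
$n_{trials}$ candidate positions are generated (bond length uniform in the
gap interval, bending angle drawn from its Boltzmann density by rejection
sampling, torsion uniform), one is selected with probability proportional
to its Boltzmann weight, and the reverse transition regenerates
$n_{trials} - 1$ alternatives around the old state so that the
Rosenbluth-weight ratio restores microscopic reversibility.
$n_{trials} = 1$ reduces exactly to plain Metropolis and skips the reverse
work. Flip and end-rotation amplitudes are schedule parameters (the
literature names these moves without fixing amplitudes).

Connectivity-altering moves — simplified end-bridging (sEB),
intramolecular end-bridging (sIEB) and double bridging (sDB) — delete and
form bonds between sites at bridgeable distance (within the bond-length
bounds) without displacing anything. Identity exchanges IdEx1–3 absorb a
single monomer at a chain end (IdEx1), at the second/penultimate site
(IdEx2, releasing the adjacent end), or at the end of one chain while a
different chain donates an end (IdEx3, which requires dispersity).
Candidates are enumerated exhaustively and drawn uniformly; because the
candidate count changes with the move, the acceptance probability carries
the proposal-asymmetry correction $n_{old}/n_{new}$ — required for
reversibility and chosen here because the source literature leaves the
selection rule open. Length-altering moves (sEB, intermolecular
reptation, IdEx3) multiply the acceptance by
$w(N_a')w(N_b')/(w(N_a)w(N_b))$, the semigrand encoding of relative
chemical potentials as target length-distribution weights: uniform, or
Flory $w(N) \propto p^N$ with $p = 1 - 1/\langle N\rangle$, truncated to
$[N_{min}, N_{max}]$. A monodisperse switch deactivates all three.

Cluster moves detect single-linkage proximity clusters (default linkage
$1.05\sigma$, just above tangency) and rigidly translate or rotate one
cluster about its center of mass. Proposals that would bring a member
within the linkage distance of a non-member are rejected outright: this
reject-on-merge rule keeps every accepted proposal reversible (the reverse
split would otherwise be impossible) and was chosen over symmetrized
cluster algorithms for simplicity. The moves deactivate automatically when
a single cluster spans the system. Volume moves scale the unconfined
dimensions (isotropically or one at a time) and accept with
$\min(1, \exp(-P\Delta V + N_{at}\ln(V'/V) - \Delta E))$.

The athermal compression protocol alternates displacement sweeps (with an
amplitude adapted towards ~40% acceptance) and contraction attempts that
shrink the cell to the tightest current contact — the admissible linear
factor is computed from the closest non-bonded pair, the shortest bond and
the periodic self-image limit, capped by a step that decays on rejection.
Volume is monotone non-increasing by construction; convergence is declared
when the relative volume change per block, averaged over a trailing
window, falls below tolerance. This documented schedule replaces the
wall-wrapping compaction algorithm of the original literature (whose
internals are out of scope here); under confinement it simply scales the
unconfined dimensions. With the slow default-style schedule
(30 sweeps/block, tolerance $5\times10^{-9}$ over a 300-block window),
200 monodisperse hard spheres reach $\phi \approx 0.635$–$0.645$,
bracketing the random-close-packed/maximally-random-jammed window.

## Structural descriptor

Each site's nearest neighbors are identified by Voronoi tessellation,
computed per site as the intersection of half-spaces bounded by the
bisector planes of nearby periodic images; a candidate is a neighbor when
its plane carries a face of non-negligible area. Confining walls truncate
the cell (mirror-free) and wall faces are not neighbors; unbounded cells
(vacuum interfaces) count bounded faces only. Exactly co-spherical shells
(ideal lattices) are disambiguated by a deterministic jitter of amplitude
$10^{-9}\sigma$. The construction reproduces the textbook coordinations:
12 for FCC and HCP, 14 faces for BCC (of which the descriptor keeps the 8
closest), 8 for simple hexagonal with $c = a$, 6 for the 2-d triangular
lattice.

The per-site similarity norm against a reference crystal $X$ keeps the
$N_{coord}(X)$ closest Voronoi neighbors (a constant penalty norm of 1 —
comfortably above any labeling threshold — applies when fewer are
available), normalizes the shell by its mean radius, and applies the
crystal's characteristic symmetry elements at a scanned orientation. The
norm is the orientation-minimized RMS distance between the
symmetry-transformed shell and the original one under nearest-vector
assignment. The element catalog is data and can be overridden; the
defaults are: FCC — three mutually orthogonal fourfold roto-inversion
axes ($N_{coord} = 12$); HCP — one sixfold roto-inversion axis (12);
BCC — four threefold roto-inversion axes along the cube diagonals plus an
inversion center (8); HEX — one sixfold rotation axis (8); FIV — one
fivefold rotation axis over the icosahedral 12-shell; in 2-d TRI/SQU/HON/
PEN carry six/four/three/fivefold in-plane rotations with coordinations
6/4/3/5. In 2-d, in-plane rotations commute with any frame rotation, so
no orientation scan is needed.

The orientation mesh has width $\phi_{step}$ (default 10°) in the polar
and azimuthal angles, with a third Euler angle scanned for the multi-axis
crystals, followed by a pattern-search refinement that halves the step
down to 0.2°; refinement is what drives ideal-lattice own-norms to
$\mathcal{O}(10^{-3})$, well below the 0.05 ideal-fixture bound.
Branch-and-bound pruning (abandon an orientation once its partial
mismatch exceeds the current best) keeps the scan exact. The on-the-fly
mode additionally abandons orientations that can no longer affect the
label and stops a site's scan once a norm at or below the threshold is
found; norms beyond roughly 1.5 times the threshold then become upper
bounds, which is the documented trade-off for time-series monitoring.

A site is labeled by its minimum-norm crystal when that norm is at most
$\varepsilon^{thres} = 0.245$, and amorphous (AMO) otherwise — AMO means
no similarity to any catalog reference, not proof of disorder. With this
calibration the ideal own-crystal norms are $\lesssim 10^{-2}$, every
ideal cross-pair norm exceeds 0.30, and shells jittered by a positional
noise of total RMS amplitude $0.05\sigma$ keep own-crystal norms around
0.15: the published threshold 0.245 separates the two regimes with
margin on both sides. (With the alternative reading of the noise
amplitude as per-coordinate, noisy own-norms overlap the closest
cross-pair and no threshold could satisfy both properties, which is how
the magnitude reading was fixed.)

Equidistant neighbors that straddle the $N_{coord}$ cut — the six second
shell sites of BCC under the 12-neighbor FCC reference, or the six
first-shell sites of the triangular lattice under the 3-neighbor
honeycomb reference — are resolved conservatively: the norm is maximized
over the tied subsets (within a bounded combinatorial budget), so
degenerate shells never acquire spurious crystal labels. This matters:
an alternating triple of a triangular shell is geometrically a honeycomb
shell, and only a tie-break that works against crystal similarity keeps
the 2-d catalog mutually discriminating.

Order summaries report per-crystal site fractions $S^X$, the total
crystallinity $\tau_c = S^{HCP} + S^{FCC}$ (the compact crystals of
hard-sphere packings), the fivefold fraction $S^{FIV}$, clusters of
same-label ordered sites (the proximity linkage restricted to a shared
label), their sizes and gyration-tensor shape metrics, and Voronoi-cell
volume and face-count statistics.

## Synthetic generators and what the tests show

The dilute generator grows non-overlapping random-walk chains (bond
lengths uniform in the gap interval, bending angles Boltzmann-sampled)
and uniformly placed singles, deterministically under a seed. The lattice
generator builds periodic supercells of FCC/HCP/BCC/HEX/TRI/SQU/HON and
isolated central-shell clusters for the non-space-filling fivefold
symmetries, with optional Gaussian jitter. These fixtures emulate ideal
and weakly perturbed crystals and dilute-to-dense amorphous packings;
they do not emulate polydispersity in monomer size, long-range
interactions, or chemically detailed chains, so passing tests speak to
the coarse-grained model class only.

The validation suite follows a dual-route pattern: cell-list energies
against all-pairs sums in plain R; cluster detection against brute-force
union-find; Voronoi volumes against the cell-volume tiling identity;
sampled ensembles against closed forms (bending Boltzmann density by KS
test, NPT densities against the Carnahan–Starling equation of state to
2%, the square-well second virial coefficient against its closed form to
1%, Flory length-distribution decay rate to 5%). Scaled stochastic
benchmarks use desk-scale sizes chosen as the package's own defaults:
200 spheres for jamming (three seeds), 1,000 spheres at $\phi = 0.56$
for the crystallization trend (three production seeds from one prepared
amorphous state, mirroring the shared-initial-configuration comparison
protocol), with a move budget of $\approx 5\times10^8$ attempts per seed
and crystallinity tracked on a 300-site random subsample (an unbiased
fraction estimate with standard error ~0.025). At these conditions the
runs show the expected phenomenology: an induction period in which
fivefold local symmetry grows, nucleation, then rising $\tau_c$ with the
fivefold fraction collapsing — fivefolds act as the structural competitor
to compact crystals.

## Numerical choices and limitations

* Overlap tests treat tangency as allowed (strict inequality with a
  $10^{-12}$ relative guard); bond bounds carry a $10^{-9}$ absolute
  slack.
* Minimum-image distances assume pair separations below 1.5 cell lengths
  (guaranteed for wrapped coordinates); cells thinner than $\sigma$ along
  a periodic dimension are rejected as self-image overlaps, which is what
  stops single-sphere compression exactly at the simple-cubic limit
  $\phi = \pi/6$.
* Cluster moves unwrap members by minimum-image chaining from a seed
  member, valid while cluster diameters stay below half the cell; bonds
  crossing a cluster boundary reject the move (impossible when the
  linkage distance is at least the maximum bond length).
* The Voronoi construction is exact up to the face-area floor
  ($10^{-5}$ of the squared half-distance scale) used to discard
  degenerate contact faces; the candidate set expands adaptively and is
  capped at 160, beyond which open cells are truncated by the bounding
  box.
* Energies are evaluated in local (per-site or per-affected-set) form;
  hard-core violations propagate as infinite-energy sentinels rather than
  exceptions.
* Known limitations: non-orthogonal cells, mobile fillers, branched or
  ring architectures, electrostatics and tabulated potentials are out of
  scope; the cylinder/sphere Voronoi wall treatment uses the tangent
  plane at the nearest boundary point, a first-order approximation to the
  curved wall.
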