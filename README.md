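# polymc

Monte Carlo simulation and crystallographic structure analysis of dense
polymer and sphere packings.

polymc is for researchers studying how coarse-grained chains and monomers
pack, jam and crystallize under extreme conditions: very high packing
density, confinement by walls, cylinders or spheres, and the presence of
nanofillers much larger than the monomers. It couples two components:

* a **Metropolis Monte Carlo engine** for spherical monomers — free or
  connected into linear chains with bond gaps, bending stiffness and an
  optional torsional term — interacting through hard-sphere, square-well/
  shoulder or Lennard-Jones potentials. The move set spans localized moves
  with optional configurational bias (displacement, flip, end rotation,
  reptation, intermolecular reptation, end-segment regrowth),
  connectivity-altering bridging moves (sEB, sIEB, sDB), identity
  exchanges for chain/monomer blends (IdEx1–3), rigid cluster moves,
  volume moves (NVT/NPT/semigrand ensembles) and a compression protocol
  towards jammed states;
* a **structural descriptor** that assigns every site a similarity norm
  against reference crystals (FCC, HCP, BCC, HEX and fivefold local
  symmetry in 3-d; triangular, square, honeycomb, pentagonal in 2-d) by
  applying each crystal's characteristic symmetry elements to the site's
  Voronoi neighbor shell and minimizing the RMS mismatch over scanned
  orientations. Sites with a minimum norm at or below the threshold
  0.245 are labeled with that crystal, otherwise amorphous (AMO); from the
  labels follow the fractions S^X, the crystallinity
  τ_c = S^HCP + S^FCC, ordered-cluster and Voronoi-cell statistics.

All lengths are in units of the collision diameter σ and energies in kT.

## Worked example

Grow a dilute system of 48 hard-sphere chains of length 100 around a
nanosphere of diameter 5σ, and report its density measures:

```r
library(polymc)
set.seed(1)

spec <- interaction_spec("HS", dl = 0.1)
phi  <- 9.9e-3
L    <- (monomer_volume(4800) / phi)^(1/3)
cfg  <- generate_dilute_system(48, 100, 0, cell = sim_cell(rep(L, 3)),
                               spec = spec,
                               fillers = list(filler_sphere(rep(L/2, 3), 5)))
packing_density(cfg)     # 0.0099
effective_density(cfg)   # 0.0099026  -> 0.01 at two decimals
depleted_density(cfg)    # 0.0099044  (sigma/2 depletion layers)
```

Compress 200 hard spheres towards their jammed state and classify the
local structure:

```r
set.seed(1)
cfg <- generate_dilute_system(0, 0, 200, phi = 0.3)
jam <- compress_to_jamming(cfg, interaction_spec("HS"),
         compression_schedule(sweeps_per_block = 30, max_blocks = 30000,
                              tol = 5e-9, window = 300))
jam$phi
#> [1] 0.6431684
res <- cce_norms(jam$config, crystals = c("FCC", "HCP", "FIV"))
order_summary(res, jam$config)$fractions
#>   FCC   HCP   FIV   AMO
#> 0.000 0.055 0.095 0.850
```

The jammed packing lands in the random-close-packed window (φ ≈ 0.64)
and is predominantly amorphous, with fivefold local symmetry outweighing
the compact crystals — the signature of a maximally random jammed state.

A command-line interface is installed with the package
(`exec/polymc`): verbs `generate`, `simulate`, `describe`, `analyze` and
`scenario` operate on extended-XYZ configurations and YAML run
configurations, e.g.

```sh
polymc describe --in config.xyz --out per_site.csv
```

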