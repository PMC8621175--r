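test_that("pair energies reproduce the printed potentials", {
  sw <- interaction_spec("SW", sigma2 = 1.15, eps_sw = 1.2)
  expect_equal(pair_energy(1.1, sw), -1.2)        # inside the well
  expect_equal(pair_energy(1.15, sw), 0)          # interval is [sigma, sigma2)
  expect_equal(pair_energy(0.99, sw), Inf)
  ss <- interaction_spec("SS", sigma2 = 1.15, eps_sw = 1.2)
  expect_equal(pair_energy(1.1, ss), 1.2)         # shoulder = sign flip
  hs <- interaction_spec("HS")
  expect_equal(pair_energy(c(0.5, 1, 2), hs), c(Inf, 0, 0))
  lj <- interaction_spec("LJ", eps_lj = 0.8, sigma_lj = 1, rcut = 1e6)
  expect_equal(pair_energy(1, lj), 0, tolerance = 1e-10)       # zero-energy point
  expect_equal(pair_energy(2^(1 / 6), lj), -0.8, tolerance = 1e-9)  # minimum = -eps
  ljc <- interaction_spec("LJ", eps_lj = 1, sigma_lj = 1)      # default 2.5 cut
  expect_equal(pair_energy(2.5 + 1e-9, ljc), 0)
  expect_equal(pair_energy(2.4999999, ljc), 0, tolerance = 1e-6)  # shifted to 0
})

test_that("bending energy is harmonic in the supplement angle", {
  sp <- interaction_spec("HS", k_theta = 9, theta0 = 10)
  expect_equal(bending_energy(10, sp), 0)
  expect_equal(bending_energy(12, sp), 36)   # k (theta - theta0)^2
  free <- interaction_spec("HS", k_theta = 0)
  expect_equal(bending_energy(c(0, 45, 180), free), c(0, 0, 0))  # freely jointed
})

test_that("cell-list energies equal the all-pairs oracle on random systems", {
  set.seed(31)
  specs <- list(
    interaction_spec("HS", dl = 0.1),
    interaction_spec("SW", sigma2 = 1.3, eps_sw = 0.7, dl = 0.1),
    interaction_spec("SS", sigma2 = 1.3, eps_sw = 0.5, dl = 0.1),
    interaction_spec("LJ", eps_lj = 0.5, sigma_lj = 1, dl = 0.1),
    interaction_spec("HS", dl = 0.1, k_theta = 0.002, theta0 = 90))
  for (sp in specs) {
    for (rep in 1:4) {
      cfg <- generate_dilute_system(2, 6, 8, phi = runif(1, 0.05, 0.25), spec = sp)
      expect_equal(total_energy(cfg, sp), oracle_total_energy(cfg, sp),
                   tolerance = 1e-9)
    }
  }
})

test_that("site energy sums neighbor and bonded terms around one site", {
  sp <- interaction_spec("SW", sigma2 = 1.5, eps_sw = 1)
  # tangent trimer: middle site sees two bonded (excluded) + none else
  co <- rbind(c(2, 2, 2), c(3, 2, 2), c(4, 2, 2))
  cfg <- configuration(co, sim_cell(rep(10, 3)), topology_from_lengths(3))
  expect_equal(site_energy(cfg, 2, sp), 0)  # 1-2 excluded; 1-3 pair not at i=2
  # ends see each other at r = 2 (outside the 1.5 well): 0
  expect_equal(site_energy(cfg, 1, sp), 0)
  # bring a free monomer into the well of site 1
  cfg2 <- configuration(rbind(co, c(2, 3.2, 2)), sim_cell(rep(10, 3)),
                        chain_topology(list(1:3), 4))
  expect_equal(site_energy(cfg2, 4, sp), -1)
  # isolated pair beyond range
  far <- configuration(rbind(c(1, 1, 1), c(5, 5, 5)), sim_cell(rep(12, 3)))
  expect_equal(total_energy(far, sp), 0)
})

test_that("overlap detection includes tangency, walls and fillers", {
  hs <- interaction_spec("HS")
  mk <- function(co, ...) configuration(co, sim_cell(rep(10, 3)), ...)
  expect_false(has_overlap(mk(rbind(c(1, 1, 1), c(2, 1, 1))), hs))  # exactly tangent
  expect_true(has_overlap(mk(rbind(c(1, 1, 1), c(1.99, 1, 1))), hs))
  # wall clearance: sigma/2 allowed, less is not
  slit <- sim_cell(c(10, 10, 5), conf_walls(3))
  expect_false(has_overlap(configuration(matrix(c(5, 5, 0.5), 1, 3), slit), hs))
  expect_true(has_overlap(configuration(matrix(c(5, 5, 0.49), 1, 3), slit), hs))
  # filler depletion layer: center must stay (d + sigma)/2 away
  f <- filler_sphere(c(5, 5, 5), 4)
  expect_true(has_overlap(mk(matrix(c(5, 5, 7.49), 1, 3), fillers = list(f)), hs))
  expect_false(has_overlap(mk(matrix(c(5, 5, 7.51), 1, 3), fillers = list(f)), hs))
  # random dense configs match the brute-force oracle
  set.seed(41)
  for (k in 1:6) {
    cfg <- generate_dilute_system(1, 5, 10, phi = 0.2,
                                  spec = interaction_spec("HS", dl = 0.1))
    expect_false(has_overlap(cfg, interaction_spec("HS", dl = 0.1)))
    expect_identical(has_overlap(cfg, interaction_spec("HS", dl = 0.1)),
                     oracle_overlap(cfg, interaction_spec("HS", dl = 0.1)))
    # shrink the box slightly so overlaps appear, re-check equality
    cfg2 <- cfg
    cfg2$cell$lengths <- cfg$cell$lengths * 0.97
    cfg2$coords <- cfg$coords * 0.97
    expect_identical(has_overlap(cfg2, interaction_spec("HS", dl = 0.1)),
                     oracle_overlap(cfg2, interaction_spec("HS", dl = 0.1)))
  }
})
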