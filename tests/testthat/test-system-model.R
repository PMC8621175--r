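test_that("cells validate lengths, confinement and aspect ratio", {
  cell <- sim_cell(c(10, 5, 20))
  expect_equal(cell$zeta, 4)
  expect_true(all(cell$periodic))
  expect_error(sim_cell(c(10, -1, 5)), "positive")
  slit <- sim_cell(c(20, 20, 5), conf_walls(3))
  expect_identical(slit$periodic, c(TRUE, TRUE, FALSE))
  expect_equal(slit$d_conf, 1L)
  cyl <- sim_cell(c(6, 6, 30), conf_cylinder(axis = 3, ends = "open"))
  expect_identical(cyl$periodic, c(FALSE, FALSE, TRUE))
  expect_equal(sim_cell(c(6, 6, 30), conf_cylinder(3, "closed"))$d_conf, 3L)
  expect_error(sim_cell(c(5, 6, 30), conf_cylinder(3)), "diameter")
  sph <- sim_cell(rep(8, 3), conf_sphere())
  expect_equal(sph$d_conf, 3L)
})

test_that("topology bookkeeping obeys n_ch * N + n_s = n_at", {
  topo <- topology_from_lengths(c(10, 10, 10), n_singles = 7)
  expect_equal(topo$n_at, 37L)
  expect_equal(topo$n_ch * topo$mean_length + topo$n_s, topo$n_at)
  expect_equal(sort(c(unlist(topo$chains), topo$singles)), 1:37)
  expect_error(chain_topology(list(1:5, 5:9), n_at = 10), "more than one")
  expect_error(chain_topology(list(3L), n_at = 5), "at least 2")
})

test_that("packing density matches the sphere-volume identity and Fig-scale values", {
  # rho sigma^3 = 6/pi in a unit box -> phi exactly 1
  n <- 6
  cell <- sim_cell(rep((n * pi / 6)^(1 / 3) * (pi / 6 * 6 / pi)^0 , 3))
  cfg <- configuration(matrix(runif(3 * n), n, 3) * cell$lengths[1], cell)
  expect_equal(packing_density(cfg), pi / 6 * n / cell_volume(cell))
  # exact identity case
  V <- n * pi / 6
  cfg1 <- configuration(matrix(runif(3 * n), n, 3) * V^(1 / 3),
                        sim_cell(rep(V^(1 / 3), 3)))
  expect_equal(packing_density(cfg1), 1.0)
  # jammed-state bookkeeping: N_at = 4800 at phi = 0.637 round-trips
  V <- 4800 * pi / 6 / 0.637
  cfg2 <- configuration(matrix(0.5, 1, 3), sim_cell(rep(V^(1 / 3), 3)))
  cfg2$coords <- matrix(runif(4800 * 3) * V^(1 / 3), 4800, 3)
  cfg2$topology <- chain_topology(list(), 4800)
  expect_equal(packing_density(cfg2), 0.637, tolerance = 1e-12)
  # random (n, V): direct summation of sphere volumes over V
  set.seed(4)
  for (k in 1:5) {
    n <- sample(10:200, 1)
    L <- runif(1, 5, 20)
    cfg3 <- configuration(matrix(runif(3 * n) * L, n, 3), sim_cell(rep(L, 3)))
    expect_equal(packing_density(cfg3), sum(rep(pi / 6, n)) / L^3)
  }
})

test_that("effective density removes filler volume (nanocomposite worked example)", {
  # one nanosphere d = 5 in the 48 x 100 system at phi = 9.9e-3
  V <- 4800 * pi / 6 / 9.9e-3
  L <- V^(1 / 3)
  cfg <- configuration(matrix(runif(4800 * 3) * L, 4800, 3), sim_cell(rep(L, 3)),
                       fillers = list(filler_sphere(rep(L / 2, 3), 5)))
  expect_equal(effective_density(cfg), packing_density(cfg) * V / (V - pi / 6 * 125))
  expect_equal(round(effective_density(cfg), 2), 0.01)
  # no fillers -> identical to phi
  cfg0 <- configuration(cfg$coords, cfg$cell)
  expect_identical(effective_density(cfg0), packing_density(cfg0))
  # degenerate: filler bigger than the cell
  cfg_bad <- configuration(matrix(1, 1, 3), sim_cell(rep(2, 3)),
                           fillers = list(filler_sphere(c(1, 1, 1), 10)))
  expect_error(effective_density(cfg_bad), "degenerate")
})

test_that("depleted density shrinks walls by sigma and filler radii by sigma/2", {
  # slit of d_wall = 5: phi_dep = phi * d_wall / (d_wall - 1)
  cfg <- configuration(matrix(c(5, 5, 2.5), 1, 3),
                       sim_cell(c(10, 10, 5), conf_walls(3)))
  expect_equal(depleted_density(cfg), packing_density(cfg) * 5 / 4)
  # bulk, no fillers: phi_dep = phi_eff = phi
  cfgb <- configuration(matrix(2, 3, 3), sim_cell(rep(8, 3)))
  expect_equal(depleted_density(cfgb), packing_density(cfgb))
  expect_equal(effective_density(cfgb), packing_density(cfgb))
  # sphere filler: against Monte-Carlo integration of the center-accessible
  # volume (depletion radius (d+sigma)/2)
  set.seed(9)
  L <- 10
  f <- filler_sphere(c(5, 5, 5), 3)
  cfgf <- configuration(matrix(1, 20, 3) + matrix(runif(60), 20, 3), sim_cell(rep(L, 3)),
                        fillers = list(f))
  pts <- matrix(runif(3 * 2e5) * L, ncol = 3)
  inside <- sqrt(rowSums(sweep(pts, 2, c(5, 5, 5))^2)) > (3 + 1) / 2
  v_mc <- L^3 * mean(inside)
  v_dep <- 20 * pi / 6 / depleted_density(cfgf)
  expect_equal(v_dep, v_mc, tolerance = 0.01)
  # ordering: phi_dep >= phi_eff >= phi when obstacles are present
  expect_gt(depleted_density(cfgf), effective_density(cfgf))
  expect_gt(effective_density(cfgf), packing_density(cfgf))
})

test_that("minimum-image distance matches 27-image brute force and is a metric", {
  set.seed(12)
  cell <- sim_cell(c(7, 9, 11), conf_walls(2))
  for (k in 1:30) {
    p <- runif(3) * cell$lengths
    q <- runif(3) * cell$lengths
    expect_equal(min_image_distance(p, q, cell),
                 oracle_min_image(p, q, cell$lengths, cell$periodic))
    expect_equal(min_image_distance(p, q, cell), min_image_distance(q, p, cell))
  }
  # degenerate and boundary cases
  expect_equal(min_image_distance(c(1, 1, 1), c(1, 1, 1), cell), 0)
  cb <- sim_cell(c(10, 10, 10))
  expect_equal(min_image_distance(c(0.1, 5, 5), c(9.9, 5, 5), cb), 0.2)
  # triangle inequality on sampled triples
  for (k in 1:20) {
    a <- runif(3) * 10; b <- runif(3) * 10; c <- runif(3) * 10
    expect_lte(min_image_distance(a, c, cb),
               min_image_distance(a, b, cb) + min_image_distance(b, c, cb) + 1e-12)
  }
})
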