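# Voronoi tessellation and the crystallographic similarity descriptor.

test_that("Voronoi coordination of the ideal lattices is exact", {
  expect_true(all(voronoi_neighbors(generate_ideal_lattice("FCC", 3))$n_vor == 12))
  hcp <- voronoi_neighbors(generate_ideal_lattice("HCP", 3))
  expect_true(all(hcp$n_vor == 12))
  bcc <- voronoi_neighbors(generate_ideal_lattice("BCC", 3))
  expect_true(all(bcc$n_vor == 14))   # 8 + 6 faces; the 8 closest serve BCC
  expect_true(all(voronoi_neighbors(generate_ideal_lattice("HEX", 3))$n_vor == 8))
  expect_true(all(voronoi_neighbors(generate_ideal_lattice("TRI", 4))$n_vor == 6))
  # neighbor lists are sorted by distance: BCC first 8 are the corner shell
  d <- bcc$neighbors[[1]]
  expect_equal(length(d), 14L)
})

test_that("Voronoi cell volumes tile the periodic cell", {
  set.seed(81)
  cfg <- generate_dilute_system(0, 0, 30, phi = 0.15)
  vor <- voronoi_neighbors(cfg)
  expect_equal(sum(vor$cell_volume), cell_volume(cfg$cell), tolerance = 1e-6)
  # ideal FCC: every cell is the rhombic dodecahedron of volume V/n
  fcc <- generate_ideal_lattice("FCC", 3)
  vf <- voronoi_neighbors(fcc, sites = 1:4)
  expect_equal(vf$cell_volume,
               rep(cell_volume(fcc$cell) / n_sites(fcc), 4), tolerance = 1e-6)
})

test_that("own-crystal norms vanish and refine with the mesh", {
  for (cr in c("FCC", "HCP", "BCC", "HEX", "FIV")) {
    cfg <- generate_ideal_lattice(cr, 3)
    sites <- if (cr == "FIV") 1L else 1:2
    res10 <- cce_norms(cfg, sites = sites)
    expect_lt(max(res10$norms[, cr]), 0.05)
    expect_true(all(res10$labels == cr))
  }
  # coarse mesh without refinement must not beat the finer mesh (one
  # single-axis and one multi-axis crystal)
  for (cr in c("HCP", "FCC")) {
    cfg <- generate_ideal_lattice(cr, 3)
    c15 <- cce_norms(cfg, crystals = cr, sites = 1L, phi_step = 15, refine = FALSE)
    c7 <- cce_norms(cfg, crystals = cr, sites = 1L, phi_step = 7.5, refine = FALSE)
    expect_lte(c7$norms[1, cr], c15$norms[1, cr] + 1e-9)
  }
})

test_that("cross-crystal norms discriminate above the labeling threshold", {
  cats3 <- c("FCC", "HCP", "BCC", "HEX", "FIV")
  for (cr in cats3) {
    cfg <- generate_ideal_lattice(cr, 3)
    sites <- if (cr == "FIV") 1L else 1:2
    res <- cce_norms(cfg, sites = sites)
    for (other in setdiff(cats3, cr)) {
      expect_gt(min(res$norms[, other]), 0.245)
      # labeling a foreign lattice against that crystal alone says AMO
      m <- res$norms[, other, drop = FALSE]
      expect_true(all(label_sites(m) == "AMO"))
    }
  }
})

test_that("the 2-d catalog discriminates its four crystals", {
  cats2 <- c("TRI", "SQU", "HON", "PEN")
  for (cr in cats2) {
    cfg <- generate_ideal_lattice(cr, 4)
    sites <- if (cr == "PEN") 1L else 1:2
    res <- cce_norms(cfg, sites = sites)
    expect_lt(max(res$norms[, cr]), 0.05)
    expect_true(all(res$labels == cr))
    for (other in setdiff(cats2, cr)) {
      expect_gt(min(res$norms[, other]), 0.245)
    }
  }
})

test_that("under-coordinated shells receive the constant penalty norm", {
  # HEX sites have 8 Voronoi neighbors < n_coord of the 12-shell crystals
  hex <- generate_ideal_lattice("HEX", 3)
  res <- cce_norms(hex, crystals = c("FCC", "FIV"), sites = 1:2)
  expect_true(all(res$norms == 1.0))
  expect_true(all(res$labels == "AMO"))
})

test_that("labeling thresholds behave at the limits", {
  fcc <- generate_ideal_lattice("FCC", 3)
  res <- cce_norms(fcc, sites = 1:4)
  # threshold 0 labels everything amorphous
  expect_true(all(label_sites(res$norms, eps_thres = 0) == "AMO"))
  # norms far above threshold label amorphous
  m <- matrix(0.9, 2, 2, dimnames = list(NULL, c("FCC", "HCP")))
  expect_identical(label_sites(m, 0.245), c("AMO", "AMO"))
})

test_that("noisy FCC shells stay FCC-labeled (0.05 sigma positional noise)", {
  set.seed(82)
  cfg <- generate_ideal_lattice("FCC", 3, noise = 0.05 / sqrt(3))
  res <- cce_norms(cfg, sites = sample.int(108, 40))
  expect_gte(mean(res$labels == "FCC"), 0.95)
})

test_that("norms are invariant under rigid rotation of the configuration", {
  set.seed(83)
  cfg <- generate_ideal_lattice("FIV")   # isolated cluster: free rotation
  res0 <- cce_norms(cfg, sites = 1L)
  ang <- 0.7; ax <- c(1, 2, 3) / sqrt(14)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
  ctr <- rep(4, 3)
  cfg$coords <- sweep(sweep(cfg$coords, 2, ctr) %*% t(R), 2, ctr, "+")
  res1 <- cce_norms(cfg, sites = 1L)
  expect_lt(max(abs(res1$norms - res0$norms)), 0.02)
})

test_that("on-the-fly mode matches full labels on ordered and noisy shells", {
  set.seed(84)
  cfg <- generate_ideal_lattice("HCP", 3, noise = 0.02)
  full <- cce_norms(cfg, sites = 1:10)
  otf <- cce_norms(cfg, sites = 1:10, on_the_fly = TRUE)
  expect_identical(full$labels, otf$labels)
})

test_that("order summary integrates labels, clusters and Voronoi statistics", {
  fcc <- generate_ideal_lattice("FCC", 3)
  res <- cce_norms(fcc, on_the_fly = TRUE)
  osum <- order_summary(res, fcc, linkage = 1.1)
  expect_equal(sum(osum$fractions), 1)
  expect_equal(osum$tau_c, 1)                       # perfect FCC: all ordered
  expect_equal(unname(osum$fractions["FIV"]), 0)
  expect_equal(length(osum$clusters), 1L)           # one percolating grain
  # two spatially separated ideal grains -> two ordered clusters
  a <- generate_ideal_lattice("FCC", 3)
  L <- a$cell$lengths[1]
  co <- rbind(a$coords, sweep(a$coords, 2, rep(2 * L, 3), "+"))
  big <- configuration(co, sim_cell(rep(4 * L, 3)))
  res2 <- cce_norms(big, crystals = "FCC")
  osum2 <- order_summary(res2, big, linkage = 1.1)
  # grain interiors label FCC (vacuum-facing surface shells may not)
  expect_equal(length(osum2$clusters), 2L)
  expect_equal(osum2$cluster_sizes[1], osum2$cluster_sizes[2])
  expect_true(!is.null(osum2$cluster_shapes))
})
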