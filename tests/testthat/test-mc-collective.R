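test_that("cluster detection equals brute-force union-find", {
  set.seed(71)
  # all sites far apart: every site its own cluster
  cfg <- generate_dilute_system(0, 0, 25, phi = 0.005)
  cs <- detect_clusters(cfg, linkage = 1.05)
  expect_equal(length(cs$clusters), 25L)
  # two tangent dimers far apart: 2 clusters of 2 at linkage 1.1
  co <- rbind(c(2, 2, 2), c(3, 2, 2), c(8, 8, 8), c(8, 9, 8))
  cfg2 <- configuration(co, sim_cell(rep(12, 3)))
  cs2 <- detect_clusters(cfg2, linkage = 1.1)
  expect_equal(sort(cs2$sizes), c(2L, 2L))
  # random configurations against the all-pairs oracle
  for (k in 1:5) {
    cfg3 <- generate_dilute_system(0, 0, 40, phi = runif(1, 0.05, 0.3))
    link <- runif(1, 1.05, 1.6)
    cs3 <- detect_clusters(cfg3, link)
    ref <- oracle_clusters(cfg3, link)
    # same partition: membership labels must be a relabeling of each other
    expect_equal(length(unique(ref)), length(cs3$clusters))
    tab <- table(cs3$membership, ref)
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
  # label condition: differently labeled tangent sites never link
  lab <- c("A", "B", "A", "A")
  cs4 <- detect_clusters(cfg2, linkage = 1.1, labels = lab)
  expect_equal(sort(cs4$sizes), c(1L, 1L, 2L))
})

test_that("cluster moves are rigid, reject merges, and deactivate when single", {
  set.seed(72)
  sp <- interaction_spec("SW", sigma2 = 1.3, eps_sw = 1)
  # two compact tetrahedral clusters far apart
  tet <- rbind(c(0, 0, 0), c(1.05, 0, 0), c(0.525, 0.909, 0),
               c(0.525, 0.303, 0.857))
  co <- rbind(sweep(tet, 2, c(3, 3, 3), "+"), sweep(tet, 2, c(10, 10, 10), "+"))
  cfg <- configuration(co, sim_cell(rep(15, 3)))
  d_intra <- function(cfg, idx) sort(c(dist(cfg$coords[idx, ])))
  ref1 <- d_intra(cfg, 1:4)
  sched <- move_schedule(c(cludis = 0.5, clurot = 0.5), linkage = 1.3,
                         amp_cludis = 0.4, amp_clurot = 40)
  out <- run_mc(cfg, sp, sched, n_steps = 400, debug = TRUE)
  expect_gt(sum(out$stats$accepts), 0)
  # rigid-body contract: intra-cluster distances preserved to 1e-10
  expect_equal(d_intra(out$config, 1:4), ref1, tolerance = 1e-10)
  expect_equal(d_intra(out$config, 5:8), sort(c(dist(tet))), tolerance = 1e-10)
  # single cluster: the move auto-deactivates (counted as skips)
  cfg1 <- configuration(sweep(tet, 2, c(5, 5, 5), "+"), sim_cell(rep(12, 3)))
  out1 <- run_mc(cfg1, sp, sched, n_steps = 100)
  expect_equal(sum(out1$stats$skips), 100)
})

test_that("cluster moves accelerate square-well aggregation", {
  set.seed(73)
  sp <- interaction_spec("SW", sigma2 = 1.25, eps_sw = 2)
  mk <- function() generate_dilute_system(0, 0, 24, phi = 0.03)
  run_one <- function(cluster_on) {
    cfg <- mk()
    probs <- if (cluster_on) {
      c(displace = 0.7, cludis = 0.2, clurot = 0.1)
    } else c(displace = 1)
    out <- run_mc(cfg, sp, move_schedule(probs, l_disp = 0.4, linkage = 1.25,
                                         amp_cludis = 1.5),
                  n_steps = 4e4)
    length(detect_clusters(out$config, 1.25)$clusters)
  }
  set.seed(74); n_on <- run_one(TRUE)
  set.seed(74); n_off <- run_one(FALSE)
  expect_lte(n_on, n_off)
})

test_that("NPT volume moves obey the acceptance rule and avoid overlaps", {
  set.seed(75)
  sp <- interaction_spec("HS")
  cfg <- generate_dilute_system(0, 0, 40, phi = 0.2)
  ens <- ensemble_spec("NPT", pressure = 2)
  sched <- move_schedule(c(displace = 0.9, volume = 0.1), l_disp = 0.3,
                         amp_vol = 0.05)
  out <- run_mc(cfg, sp, sched, ens, n_steps = 2e4, debug = TRUE)
  expect_false(has_overlap(out$config, sp))
  expect_gt(out$stats$accepts[out$stats$move == "volume"], 0)
  # volume moves are skipped outside NPT
  out2 <- run_mc(cfg, sp, move_schedule(c(volume = 1)), ensemble_spec("NVT"),
                 n_steps = 50)
  expect_equal(out2$stats$skips[out2$stats$move == "volume"], 50)
})

test_that("compression is monotone and respects the self-image limit", {
  set.seed(76)
  # single sphere in a periodic box: the simple-cubic self-image limit
  cfg1 <- configuration(matrix(2, 1, 3), sim_cell(rep(4, 3)))
  out1 <- compress_to_jamming(cfg1, interaction_spec("HS"),
                              compression_schedule(sweeps_per_block = 1,
                                                   shrink0 = 0.02,
                                                   max_blocks = 1000,
                                                   tol = 1e-12, window = 10))
  expect_equal(out1$phi, pi / 6, tolerance = 1e-6)
  # volume monotone non-increasing by construction
  set.seed(77)
  cfg <- generate_dilute_system(0, 0, 60, phi = 0.2)
  out <- suppressWarnings(          # short block budget by design
    compress_to_jamming(cfg, interaction_spec("HS"),
                        compression_schedule(sweeps_per_block = 5,
                                             max_blocks = 300, tol = 0)))
  expect_true(all(diff(out$series$phi) >= -1e-12))
  expect_false(has_overlap(out$config, interaction_spec("HS")))
})

test_that("bonded constraints survive compression of chain systems", {
  set.seed(78)
  sp <- interaction_spec("HS", dl = 0.1)
  cfg <- generate_dilute_system(5, 8, 0, phi = 0.1, spec = sp)
  out <- compress_to_jamming(cfg, sp, compression_schedule(
    sweeps_per_block = 10, max_blocks = 2000), phi_stop = 0.35)
  cfg2 <- out$config
  expect_false(has_overlap(cfg2, sp))
  for (ch in cfg2$topology$chains) {
    for (k in seq_len(length(ch) - 1)) {
      r <- min_image_distance(cfg2$coords[ch[k], ], cfg2$coords[ch[k + 1], ],
                              cfg2$cell)
      expect_gte(r, sp$sigma - 1e-9)
      expect_lte(r, sp$sigma + sp$dl + 1e-9)
    }
  }
})
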