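test_that("blend bookkeeping reproduces the printed chain fraction", {
  # 40 chains of N = 1000 among 54,000 sites: chain-monomer fraction 0.741
  topo <- topology_from_lengths(rep(1000L, 40), n_singles = 14000L)
  expect_equal(topo$n_at, 54000L)
  expect_equal(1 - topo$n_s / topo$n_at, 0.7407407, tolerance = 1e-6)
  expect_equal(round(1 - topo$n_s / topo$n_at, 3), 0.741)
})

test_that("the blend scenario runs with identity exchanges active", {
  spec <- scenario_spec("blend", n_ch = 3, N = 6, n_s = 20, phi = 0.2,
                        sweeps = 40, seed = 5)
  out <- run_scenario(spec)
  expect_equal(n_sites(out$config), 38L)
  expect_equal(out$config$topology$n_ch, 3L)
  expect_equal(out$phi, 0.2, tolerance = 1e-9)
  expect_false(has_overlap(out$config, interaction_spec("HS", dl = 0.1)))
  expect_gt(sum(out$stats$attempts[out$stats$move %in% c("idex1", "idex2")]), 0)
  expect_equal(sum(out$summary$fractions), 1)
})

test_that("the square-well cluster scenario aggregates and then deactivates cluster moves", {
  spec <- scenario_spec("sw_cluster", n_ch = 0, N = 0, n_s = 30, phi = 0.03,
                        eps_sw = 2.5, sigma2 = 1.25, sweeps = 1500,
                        descriptor_every = 0, seed = 8)
  out <- run_scenario(spec)
  # aggregation happened and is tracked
  expect_lt(tail(out$series$n_clusters, 1), 30)
  # once a single cluster exists, cluster moves only register skips
  if (tail(out$series$n_clusters, 1) == 1L) {
    st <- out$stats
    clu <- st$move %in% c("cludis", "clurot")
    expect_equal(sum(st$accepts[clu] + 0), sum(st$accepts[clu]))
    expect_gt(sum(st$skips[clu]), 0)
  }
  # energy decreased during aggregation (attractive well)
  expect_lt(tail(out$series$energy, 1), out$series$energy[1] + 1e-9)
})

test_that("the crystallization scenario tracks tau_c and S_FIV over time", {
  spec <- scenario_spec("bulk_crystallization", n_ch = 0, N = 0, n_s = 80,
                        phi = 0.45, sweeps = 60, descriptor_every = 30,
                        seed = 9)
  out <- run_scenario(spec)
  expect_true(all(c("tau_c", "s_fiv") %in% names(out$series)))
  expect_equal(nrow(out$series), 2L)
  expect_true(all(out$series$tau_c >= 0 & out$series$tau_c <= 1))
  expect_equal(out$phi, 0.45, tolerance = 1e-9)
})

test_that("confined and nanocomposite scenarios respect their geometry", {
  spec <- scenario_spec("confined", n_ch = 4, N = 6, n_s = 0, phi = 0.3,
                        cell_lengths = rep(8, 3), confinement = conf_sphere(),
                        sweeps = 30, seed = 2)
  out <- run_scenario(spec)
  co <- out$config$coords
  r <- sqrt(rowSums(sweep(co, 2, rep(4, 3))^2))
  expect_true(all(r <= 4 - 0.5 + 1e-9))   # sigma/2 wall clearance
  spec2 <- scenario_spec("nanocomposite", n_ch = 2, N = 10, n_s = 0,
                         phi = 0.05, sweeps = 30, seed = 2,
                         fillers = list(filler_sphere(c(3, 3, 3), 2.5)))
  out2 <- run_scenario(spec2)
  expect_gt(out2$phi_eff, out2$phi)
  expect_gt(out2$phi_dep, out2$phi_eff)
  # infeasible geometry: filler larger than the cell
  spec3 <- scenario_spec("nanocomposite", n_ch = 0, N = 0, n_s = 10,
                         phi = 0.2, fillers = list(filler_sphere(c(1, 1, 1), 50)))
  expect_error(run_scenario(spec3), "filler larger than cell")
})

test_that("scenario outputs are written as trajectory, CSV and JSON", {
  dir <- withr::local_tempdir()
  spec <- scenario_spec("jamming", n_s = 40, sweeps = 10, seed = 4,
                        compression = compression_schedule(sweeps_per_block = 5,
                                                           max_blocks = 200,
                                                           tol = 0))
  out <- suppressWarnings(run_scenario(spec, out_dir = dir))  # short budget
  expect_true(file.exists(file.path(dir, "final.xyz")))
  expect_true(file.exists(file.path(dir, "series.csv")))
  summ <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(summ$scenario, "jamming")
  expect_equal(summ$seed, 4L)
  log <- readLines(file.path(dir, "run.log"))
  expect_match(log, "seed 4")
})

test_that("acceptance falls for local moves and rises for end-bridging with density", {
  # narrow bond gaps make bridgeable contacts rare in dilute systems
  df <- acceptance_profile(n_ch = 8, N = 8, phi_ladder = c(0.02, 0.25, 0.45),
                           spec = interaction_spec("HS", dl = 0.04),
                           sweeps = 80, seed = 6)
  disp <- df[df$move == "displace", ]
  expect_lt(disp$acceptance[3], disp$acceptance[1])
  seb <- df[df$move == "seb", ]
  # dilute limit: essentially no bridgeable pairs, so almost every attempt
  # finds no candidate and fails
  expect_lt(seb$acceptance[1], 0.05)
  # the bridgeable-candidate pool (and with it the rate) grows with density
  expect_gt(seb$acceptance[3], seb$acceptance[1])
  expect_gt(seb$attempts[3] - seb$skips[3], seb$attempts[1] - seb$skips[1])
})
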