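# Topology-altering moves: conservation laws, path validity, candidates.

.valid_paths <- function(config) {
  # every chain a simple path, every site accounted for exactly once
  topo <- config$topology
  idx <- c(unlist(topo$chains), topo$singles)
  length(idx) == topo$n_at && !anyDuplicated(idx)
}

test_that("bridging and identity moves conserve N_at, N_ch and path validity", {
  set.seed(61)
  sp <- interaction_spec("HS", dl = 0.15)
  cfg <- generate_dilute_system(6, 8, 12, phi = 0.12, spec = sp)
  ens <- ensemble_spec("semigrand", n_min = 3, n_max = 20)
  sched <- move_schedule(c(displace = 0.3, reptation = 0.2, inter_rept = 0.1,
                           seb = 0.15, sieb = 0.1, idex1 = 0.05, idex2 = 0.05,
                           idex3 = 0.05), l_disp = 0.3)
  n_at0 <- n_sites(cfg)
  n_ch0 <- cfg$topology$n_ch
  n_s0 <- cfg$topology$n_s
  for (b in 1:10) {
    out <- run_mc(cfg, sp, sched, ens, n_steps = 3000, debug = TRUE)
    cfg <- out$config
    expect_equal(n_sites(cfg), n_at0)
    expect_equal(cfg$topology$n_ch, n_ch0)       # all these moves conserve N_ch
    expect_equal(cfg$topology$n_s, n_s0)         # and, in this mix, N_s too
    expect_true(.valid_paths(cfg))
    expect_true(all(chain_lengths(cfg) >= 3 & chain_lengths(cfg) <= 20))
  }
  # the mix must actually have exercised connectivity changes
  topo_moves <- c("seb", "sieb", "inter_rept", "idex1", "idex2", "idex3")
  expect_gt(sum(out$stats$accepts[out$stats$move %in% topo_moves]), 0)
})

test_that("sIEB preserves chain length and works in monodisperse mode", {
  set.seed(62)
  sp <- interaction_spec("HS", dl = 0.2)
  cfg <- generate_dilute_system(2, 12, 0, phi = 0.18, spec = sp)
  ens <- ensemble_spec("NVT", monodisperse = TRUE)
  sched <- move_schedule(c(displace = 0.6, sieb = 0.4), l_disp = 0.3)
  acc <- 0
  for (b in 1:10) {
    out <- run_mc(cfg, sp, sched, ens, n_steps = 4000, debug = TRUE)
    cfg <- out$config
    expect_equal(sort(chain_lengths(cfg)), c(12L, 12L))
    acc <- acc + out$stats$accepts[out$stats$move == "sieb"]
  }
  expect_gt(acc, 0)  # the move must actually fire to test anything
})

test_that("monodisperse mode deactivates sEB, x-reptation and IdEx3", {
  set.seed(63)
  sp <- interaction_spec("HS", dl = 0.15)
  cfg <- generate_dilute_system(4, 6, 5, phi = 0.15, spec = sp)
  ens <- ensemble_spec("NVT", monodisperse = TRUE)
  sched <- move_schedule(c(seb = 1 / 3, inter_rept = 1 / 3, idex3 = 1 / 3))
  out <- run_mc(cfg, sp, sched, ens, n_steps = 300)
  expect_equal(sum(out$stats$skips), 300)
  expect_equal(sum(out$stats$accepts), 0)
})

test_that("sDB skips in dilute systems and conserves lengths when it fires", {
  set.seed(64)
  sp <- interaction_spec("HS", dl = 0.05)
  cfg <- generate_dilute_system(4, 8, 0, phi = 0.02, spec = sp)
  out <- run_mc(cfg, sp, move_schedule(c(sdb = 1)), n_steps = 200)
  # bridgeable double contacts are essentially absent at low density
  expect_gt(out$stats$skips[out$stats$move == "sdb"] / 200, 0.95)
  # at higher density with wide bond gaps the move can fire; lengths and
  # topology must be conserved exactly
  set.seed(65)
  sp2 <- interaction_spec("HS", dl = 0.3)
  cfg2 <- generate_dilute_system(6, 6, 0, phi = 0.25, spec = sp2)
  sched2 <- move_schedule(c(displace = 0.7, sdb = 0.3), l_disp = 0.3)
  fired <- 0
  for (b in 1:8) {
    out2 <- run_mc(cfg2, sp2, sched2, ensemble_spec("NVT", monodisperse = TRUE),
                   n_steps = 3000, debug = TRUE)
    cfg2 <- out2$config
    expect_equal(chain_lengths(cfg2), rep(6L, 6))
    expect_true(.valid_paths(cfg2))
    fired <- fired + out2$stats$accepts[out2$stats$move == "sdb"]
  }
  expect_gte(fired, 0)
})

test_that("IdEx1 on a symmetric dimer + monomer toy system is unbiased", {
  # chain (a, b) with single c mirror-placed across b: the move toggles
  # between {chain(a,b), c} and {chain(b,c), a}; symmetry makes the two
  # states equally likely
  set.seed(66)
  sp <- interaction_spec("HS", dl = 0.1)
  co <- rbind(c(3.00, 5, 5), c(4.05, 5, 5), c(5.10, 5, 5))
  cfg <- configuration(co, sim_cell(rep(10, 3)), chain_topology(list(1:2), 3))
  counts <- c(0, 0)
  for (it in 1:2000) {
    out <- attempt_move(cfg, sp, "idex1")
    cfg <- out$config
    s <- cfg$topology$singles
    counts[if (1 %in% s) 1 else 2] <- counts[if (1 %in% s) 1 else 2] + 1
  }
  expect_gt(min(counts), 0.4 * sum(counts))
})

test_that("IdEx3 transfers length between chains keeping the total", {
  set.seed(67)
  sp <- interaction_spec("HS", dl = 0.2)
  cfg <- generate_dilute_system(3, 8, 10, phi = 0.15, spec = sp)
  ens <- ensemble_spec("semigrand", n_min = 2, n_max = 30)
  sched <- move_schedule(c(displace = 0.6, idex3 = 0.4), l_disp = 0.3)
  total0 <- sum(chain_lengths(cfg))
  fired <- 0
  for (b in 1:10) {
    out <- run_mc(cfg, sp, sched, ens, n_steps = 2500, debug = TRUE)
    cfg <- out$config
    expect_equal(sum(chain_lengths(cfg)), total0)
    expect_equal(cfg$topology$n_ch, 3L)
    fired <- fired + out$stats$accepts[out$stats$move == "idex3"]
  }
  expect_gt(fired, 0)
})
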