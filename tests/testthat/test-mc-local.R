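test_that("zero-amplitude displacement is the identity and always accepted", {
  set.seed(51)
  cfg <- generate_dilute_system(0, 0, 20, phi = 0.05)
  out <- run_mc(cfg, interaction_spec("HS"), move_schedule(l_disp = 0),
                n_steps = 200)
  expect_equal(out$stats$accepts[1], 200)
  expect_equal(out$config$coords, cfg$coords)
})

test_that("dilute hard-sphere displacement acceptance is near one", {
  set.seed(52)
  cfg <- generate_dilute_system(0, 0, 60, phi = 0.005)
  out <- run_mc(cfg, interaction_spec("HS"), move_schedule(l_disp = 0.3),
                n_steps = 2e4)
  p <- out$stats$accepts[1] / out$stats$attempts[1]
  # binomial 3-sigma band around ~1 (tiny collision probability remains)
  expect_gt(p, 1 - 0.02 - 3 * sqrt(0.02 / 2e4))
})

test_that("no local move ever creates an overlap or breaks a bond bound", {
  set.seed(53)
  sp <- interaction_spec("HS", dl = 0.1, k_theta = 0.001, theta0 = 90)
  cfg <- generate_dilute_system(3, 8, 6, phi = 0.25, spec = sp)
  sched <- move_schedule(c(displace = 0.4, flip = 0.2, end_rot = 0.1,
                           reptation = 0.2, end_regrow = 0.1), n_trials = 3,
                         l_disp = 0.4)
  # debug mode asserts overlap/bond/clearance invariants after every
  # accepted move inside the engine
  out <- run_mc(cfg, sp, sched, n_steps = 2e4, debug = TRUE)
  expect_false(has_overlap(out$config, sp))
})

test_that("configurational-bias selection is weight-proportional", {
  set.seed(54)
  w <- c(0.1, 0.6, 0.3)
  picks <- tabulate(vapply(1:6000, function(i) cb_select(w), 1L), 3)
  expect_gt(chisq.test(picks, p = w)$p.value, 1e-4)
  expect_true(is.na(cb_select(c(0, 0))))
  # n_trials = 1 reduces to the plain Metropolis ratio
  expect_equal(cb_acceptance(exp(-2), exp(-1)), exp(-1))
  expect_equal(cb_acceptance(exp(-1), exp(-2)), 1)
})

test_that("a biased two-level chain samples the Boltzmann distribution", {
  # states 0/1 with energies 0 and dE; trials drawn uniformly, selected by
  # weight, accepted via the Rosenbluth ratio with the n-1 reverse rule
  set.seed(55)
  dE <- 1.3
  w <- function(s) exp(-dE * s)
  ntr <- 3
  state <- 0L
  hits <- c(0, 0)
  for (it in 1:20000) {
    trials <- sample(0:1, ntr, replace = TRUE)
    wf <- w(trials)
    k <- cb_select(wf)
    rev_trials <- c(sample(0:1, ntr - 1, replace = TRUE), state)
    if (runif(1) < cb_acceptance(wf, w(rev_trials))) state <- trials[k]
    hits[state + 1] <- hits[state + 1] + 1
  }
  expect_equal(hits[2] / hits[1], exp(-dE), tolerance = 0.08)
})

test_that("freely jointed chain moves reproduce uniform cos(theta) statistics", {
  # quasi-ideal chain: tiny hard core, wide bond interval
  set.seed(56)
  sp <- interaction_spec("HS", sigma = 0.2, bond_lo = 0.2, dl = 0.8)
  cfg <- generate_dilute_system(1, 10, 0, cell = sim_cell(rep(30, 3)), spec = sp)
  sched <- move_schedule(c(flip = 0.4, end_rot = 0.2, reptation = 0.4),
                         amp_flip = 180, amp_rot = 180)
  cosines <- c()
  for (b in 1:60) {
    out <- run_mc(cfg, sp, sched, n_steps = 400)
    cfg <- out$config
    ch <- cfg$topology$chains[[1]]
    co <- cfg$coords
    for (k in 2:(length(ch) - 1)) {
      u <- co[ch[k], ] - co[ch[k - 1], ]
      v <- co[ch[k + 1], ] - co[ch[k], ]
      cosines <- c(cosines, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
    }
  }
  expect_gt(ks.test(cosines, "punif", -1, 1)$p.value, 0.01)
})

test_that("two hard spheres sample the accessible-volume pair density", {
  # detailed-balance smoke test: conditional on r < L/2 the minimum-image
  # pair distance density is proportional to r^2
  set.seed(57)
  L <- 4
  cfg <- configuration(rbind(c(1, 1, 1), c(3, 2, 1)), sim_cell(rep(L, 3)))
  sp <- interaction_spec("HS")
  rs <- numeric(0)
  for (b in 1:400) {
    out <- run_mc(cfg, sp, move_schedule(l_disp = 0.6), n_steps = 60)
    cfg <- out$config
    rs <- c(rs, min_image_distance(cfg$coords[1, ], cfg$coords[2, ], cfg$cell))
  }
  rmax <- 0.99 * L / 2
  rs <- rs[rs <= rmax]
  cdf <- function(r) (r^3 - 1) / (rmax^3 - 1)
  expect_gt(ks.test(rs, cdf)$p.value, 0.01)
})

test_that("local-move acceptance falls monotonically with packing density", {
  set.seed(58)
  sp <- interaction_spec("HS")
  cfg <- generate_dilute_system(0, 0, 150, phi = 0.05)
  accs <- c()
  for (phi in c(0.05, 0.2, 0.35, 0.45)) {
    cfg <- compress_to_jamming(cfg, sp, compression_schedule(
      sweeps_per_block = 5, max_blocks = 20000), phi_stop = phi)$config
    out <- run_mc(cfg, sp, move_schedule(l_disp = 0.25), n_steps = 1.5e4)
    cfg <- out$config
    accs <- c(accs, out$stats$accepts[1] / out$stats$attempts[1])
  }
  expect_true(all(diff(accs) < 0))
})
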