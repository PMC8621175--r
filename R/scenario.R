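#' Scenario specifications
#'
#' Scripted, seeded experiment protocols covering the main application
#' classes of the simulator: athermal jamming, bulk entropy-driven
#' crystallization, polymer/monomer blends, square-well cluster formation,
#' confined chains and polymer nanocomposites.  Each scenario runs
#' generation, preparation (compression to the target density) and
#' production with a scenario-appropriate move mix, evaluating the
#' structural descriptor at a fixed cadence.
#'
#' System sizes default to desk scale; all parameters are exposed.
#'
#' @param scenario One of `"jamming"`, `"bulk_crystallization"`, `"blend"`,
#'   `"sw_cluster"`, `"confined"`, `"nanocomposite"`.
#' @param n_ch,N,n_s Chains, chain length, single monomers.
#' @param phi Target packing density (ignored by `jamming`, which
#'   compresses to convergence).
#' @param k_theta,theta0 Bending parameters (kT/deg^2, degrees).
#' @param dl Bond gap.
#' @param eps_sw,sigma2 Square-well parameters (used by `sw_cluster`).
#' @param confinement Confinement for `confined` (e.g. [conf_sphere()]).
#' @param cell_lengths Explicit cell lengths for confined scenarios.
#' @param fillers Fillers for `nanocomposite`.
#' @param sweeps Production sweeps (one sweep = `n_at` move attempts).
#' @param descriptor_every Sweeps between descriptor evaluations (0 = final
#'   state only).
#' @param descriptor_crystals Crystal names to evaluate (default FCC, HCP,
#'   FIV for 3-d scenarios).
#' @param schedule Optional [move_schedule()] override.
#' @param compression Optional [compression_schedule()] override.
#' @param seed Integer RNG seed.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario = c("jamming", "bulk_crystallization",
                                       "blend", "sw_cluster", "confined",
                                       "nanocomposite"),
                          n_ch = 0L, N = 0L, n_s = 200L, phi = 0.2,
                          k_theta = 0, theta0 = 0, dl = 0.1,
                          eps_sw = 1.2, sigma2 = 1.15,
                          confinement = conf_none(), cell_lengths = NULL,
                          fillers = list(), sweeps = 200L,
                          descriptor_every = 0L,
                          descriptor_crystals = c("FCC", "HCP", "FIV"),
                          schedule = NULL, compression = NULL, seed = 1L) {
  scenario <- match.arg(scenario)
  if (descriptor_every < 0) stop("descriptor cadence must be >= 0")
  structure(as.list(environment()), class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> %s: n_ch = %d, N = %d, n_s = %d, phi = %g, seed = %d\n",
              x$scenario, x$n_ch, x$N, x$n_s, x$phi, x$seed))
  invisible(x)
}

.scenario_interaction <- function(spec) {
  if (spec$scenario == "sw_cluster") {
    interaction_spec("SW", sigma2 = spec$sigma2, eps_sw = spec$eps_sw,
                     dl = spec$dl, k_theta = spec$k_theta, theta0 = spec$theta0)
  } else {
    interaction_spec("HS", dl = spec$dl, k_theta = spec$k_theta,
                     theta0 = spec$theta0)
  }
}

.scenario_schedule <- function(spec) {
  if (!is.null(spec$schedule)) return(spec$schedule)
  has_chains <- spec$n_ch > 0
  blend <- has_chains && spec$n_s > 0
  probs <- c(displace = 0.6)
  if (has_chains) {
    probs <- c(displace = 0.45, flip = 0.15, end_rot = 0.1, reptation = 0.15,
               end_regrow = 0.08, sieb = 0.02)
  }
  if (blend) probs <- c(probs, idex1 = 0.02, idex2 = 0.02)
  if (spec$scenario == "sw_cluster") {
    probs <- c(probs, cludis = 0.04, clurot = 0.04)
  }
  move_schedule(probs, l_disp = 0.2)
}

#' Run a scenario
#'
#' Executes the scenario protocol and collects packing density, energy,
#' per-move acceptance and descriptor time series.
#'
#' @param spec A [scenario_spec()].
#' @param out_dir Optional output directory; when given, the trajectory
#'   (extended-XYZ), the time series (CSV), a summary (JSON) and a log with
#'   the seed and package version are written there.
#' @return List with `config` (final state), `series` (data frame with
#'   sweep, phi, energy, tau_c, s_fiv when the descriptor cadence is
#'   active), `stats` (move statistics), `summary` (an [order_summary()]
#'   of the final state, where a descriptor applies) and `phi`.
#' @export
run_scenario <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  ispec <- .scenario_interaction(spec)
  sched <- .scenario_schedule(spec)
  comp <- if (is.null(spec$compression)) compression_schedule() else spec$compression

  gen_phi <- min(0.05, spec$phi)
  if (spec$scenario %in% c("confined")) {
    if (is.null(spec$cell_lengths)) stop("confined scenario needs cell_lengths")
    cell <- sim_cell(spec$cell_lengths, spec$confinement)
    cfg <- generate_dilute_system(spec$n_ch, spec$N, spec$n_s, cell = cell,
                                  spec = ispec)
    if (packing_density(cfg) > spec$phi + 1e-9) {
      stop("scenario-infeasible geometry: cell below target density")
    }
  } else if (spec$scenario == "nanocomposite") {
    n_at <- spec$n_ch * spec$N + spec$n_s
    V <- monomer_volume(n_at, ispec$sigma, 3L) / spec$phi
    cell <- sim_cell(rep(V^(1 / 3), 3L))
    for (f in spec$fillers) {
      if (f$diameter >= min(cell$lengths)) {
        stop("scenario-infeasible geometry: filler larger than cell")
      }
    }
    cfg <- generate_dilute_system(spec$n_ch, spec$N, spec$n_s, cell = cell,
                                  spec = ispec, fillers = spec$fillers)
  } else {
    cfg <- generate_dilute_system(spec$n_ch, spec$N, spec$n_s, phi = gen_phi,
                                  spec = ispec)
    if (spec$phi > gen_phi + 1e-9) {
      cfg <- compress_to_jamming(cfg, ispec, comp, phi_stop = spec$phi)$config
    }
  }

  if (spec$scenario == "jamming") {
    out <- compress_to_jamming(cfg, ispec, comp)
    cfg <- out$config
    res <- cce_norms(cfg, crystals = spec$descriptor_crystals,
                     on_the_fly = FALSE)
    osum <- order_summary(res, cfg)
    series <- data.frame(block = out$series$block, phi = out$series$phi)
    final <- list(config = cfg, series = series, stats = NULL,
                  summary = osum, phi = out$phi, descriptor = res)
  } else {
    n_at <- n_sites(cfg)
    cadence <- spec$descriptor_every
    blocks <- if (cadence > 0) ceiling(spec$sweeps / cadence) else 1L
    per_block <- if (cadence > 0) cadence else spec$sweeps
    rows <- list()
    stats_acc <- NULL
    n_clusters <- NA_integer_
    for (b in seq_len(blocks)) {
      out <- run_mc(cfg, ispec, sched, ensemble_spec("NVT"),
                    n_steps = per_block * n_at)
      cfg <- out$config
      stats_acc <- if (is.null(stats_acc)) out$stats else {
        within(stats_acc, {
          attempts <- attempts + out$stats$attempts
          accepts <- accepts + out$stats$accepts
          skips <- skips + out$stats$skips
        })
      }
      row <- data.frame(sweep = b * per_block,
                        phi = packing_density(cfg, ispec$sigma),
                        energy = total_energy(cfg, ispec))
      if (cadence > 0 && cfg$cell$dim == 3L) {
        res <- cce_norms(cfg, crystals = spec$descriptor_crystals,
                         on_the_fly = TRUE)
        osum <- order_summary(res, cfg)
        row$tau_c <- osum$tau_c
        row$s_fiv <- osum$s_fiv
      }
      if (spec$scenario == "sw_cluster") {
        cs <- detect_clusters(cfg, linkage = sched$linkage)
        row$n_clusters <- length(cs$clusters)
        n_clusters <- row$n_clusters
      }
      rows[[b]] <- row
    }
    series <- do.call(rbind, rows)
    res <- cce_norms(cfg, crystals = spec$descriptor_crystals,
                     on_the_fly = FALSE)
    osum <- order_summary(res, cfg)
    final <- list(config = cfg, series = series, stats = stats_acc,
                  summary = osum, phi = packing_density(cfg, ispec$sigma),
                  descriptor = res)
  }
  if (spec$scenario == "nanocomposite") {
    final$phi_eff <- effective_density(cfg, ispec$sigma)
    final$phi_dep <- depleted_density(cfg, ispec$sigma)
  }
  if (!is.null(out_dir)) .write_scenario_outputs(final, spec, out_dir)
  final
}

.write_scenario_outputs <- function(final, spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_xyz(final$config, file.path(out_dir, "final.xyz"))
  utils::write.csv(final$series, file.path(out_dir, "series.csv"),
                   row.names = FALSE)
  if (!is.null(final$stats)) {
    utils::write.csv(final$stats, file.path(out_dir, "moves.csv"),
                     row.names = FALSE)
  }
  summ <- list(scenario = spec$scenario, seed = spec$seed, phi = final$phi,
               fractions = as.list(final$summary$fractions),
               tau_c = final$summary$tau_c, s_fiv = final$summary$s_fiv,
               cluster_sizes = final$summary$cluster_sizes,
               schema_version = "1")
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(sprintf("polymc %s | scenario %s | seed %d | %s",
                     as.character(utils::packageVersion("polymc")),
                     spec$scenario, spec$seed, format(Sys.time())),
             file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Per-move acceptance across a packing-density ladder
#'
#' Prepares (by compression) a system at each density of the ladder, runs a
#' fixed number of sweeps with the given move mix, and tabulates per-move
#' acceptance rates.  Local-move acceptance decreases with density while
#' bridging-move acceptance increases with it (richer contact network).
#'
#' @param n_ch,N Chains and chain length.
#' @param phi_ladder Densities to visit (increasing).
#' @param spec An [interaction_spec()].
#' @param schedule A [move_schedule()].
#' @param ensemble An [ensemble_spec()] (semigrand enables bridging).
#' @param sweeps Production sweeps per density.
#' @param seed RNG seed.
#' @return Data frame: one row per (phi, move) with attempts, accepts,
#'   skips and the acceptance fraction (of attempts, with skips removed).
#' @export
acceptance_profile <- function(n_ch, N, phi_ladder, spec = interaction_spec("HS", dl = 0.1),
                               schedule = move_schedule(
                                 c(displace = 0.3, flip = 0.15, end_rot = 0.1,
                                   reptation = 0.15, end_regrow = 0.1,
                                   seb = 0.1, sieb = 0.1)),
                               ensemble = ensemble_spec("semigrand",
                                                        n_min = max(2L, floor(N / 2)),
                                                        n_max = 2L * N),
                               sweeps = 50L, seed = 1L) {
  set.seed(seed)
  cfg <- generate_dilute_system(n_ch, N, 0L, phi = min(0.05, min(phi_ladder)),
                                spec = spec)
  rows <- list()
  for (phi in sort(phi_ladder)) {
    if (packing_density(cfg, spec$sigma) < phi - 1e-9) {
      cfg <- compress_to_jamming(cfg, spec, compression_schedule(),
                                 phi_stop = phi)$config
    }
    out <- run_mc(cfg, spec, schedule, ensemble,
                  n_steps = sweeps * n_sites(cfg))
    cfg <- out$config
    st <- out$stats
    st$phi <- phi
    # skipped attempts (no eligible candidate) count as unsuccessful, as in
    # per-move acceptance-rate profiles
    st$acceptance <- ifelse(st$attempts > 0, st$accepts / st$attempts, NA)
    rows[[length(rows) + 1L]] <- st
  }
  do.call(rbind, rows)
}
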