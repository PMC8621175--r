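.move_names <- c("displace", "flip", "end_rot", "reptation", "inter_rept",
                 "end_regrow", "seb", "sieb", "sdb", "idex1", "idex2",
                 "idex3", "cludis", "clurot", "volume")

#' Monte Carlo move schedule
#'
#' Attempt probabilities, configurational-bias trial counts and amplitudes
#' for every move class.  Probabilities are normalized to sum to 1.  Local
#' chain moves (`flip`, `end_rot`, `reptation`, `inter_rept`, `end_regrow`)
#' and single-monomer displacement support configurational-bias execution
#' with `n_trials >= 1` trial configurations; `n_trials = 1` is the
#' conventional Metropolis execution.  The reverse transition of a biased
#' move regenerates `n_trials - 1` alternatives around the old state.
#'
#' @param probs Named numeric vector of attempt probabilities; names from
#'   `displace, flip, end_rot, reptation, inter_rept, end_regrow, seb, sieb,
#'   sdb, idex1, idex2, idex3, cludis, clurot, volume`.  Unnamed moves get
#'   probability 0.
#' @param n_trials Integer scalar or named vector of CB trial counts
#'   (default 1: conventional execution).
#' @param l_disp Displacement amplitude per dimension (scalar recycled).
#' @param amp_flip,amp_rot Angular amplitudes (degrees) of the internal flip
#'   and end-monomer rotation.
#' @param n_regrow Maximum number of terminal segments rebuilt by
#'   `end_regrow`.
#' @param linkage Euclidean linkage distance (sigma units) for cluster
#'   detection driving the cluster moves.
#' @param amp_cludis Cluster displacement amplitude.
#' @param amp_clurot Cluster rotation amplitude (degrees).
#' @param amp_vol Volume-move amplitude as a relative volume change.
#' @param vol_aniso Logical: scale a single random unconfined dimension
#'   instead of all of them.
#' @return An object of class `move_schedule`.
#' @examples
#' move_schedule(c(displace = 0.8, reptation = 0.2), n_trials = 3)
#' @export
move_schedule <- function(probs = c(displace = 1), n_trials = 1L,
                          l_disp = 0.2, amp_flip = 60, amp_rot = 60,
                          n_regrow = 2L, linkage = 1.05, amp_cludis = 0.5,
                          amp_clurot = 30, amp_vol = 0.02,
                          vol_aniso = FALSE) {
  if (is.null(names(probs)) || !all(names(probs) %in% .move_names)) {
    stop("probs must be named after moves: ", paste(.move_names, collapse = ", "))
  }
  p <- setNames(numeric(length(.move_names)), .move_names)
  p[names(probs)] <- probs
  if (any(p < 0) || sum(p) <= 0) stop("probabilities must be >= 0 and sum > 0")
  p <- p / sum(p)
  nt <- setNames(rep(1L, length(.move_names)), .move_names)
  if (length(n_trials) == 1L && is.null(names(n_trials))) {
    nt[] <- as.integer(n_trials)
  } else {
    nt[names(n_trials)] <- as.integer(n_trials)
  }
  if (any(nt < 1L)) stop("n_trials must be >= 1")
  structure(list(probs = p, n_trials = nt,
                 l_disp = rep(as.numeric(l_disp), length.out = 3L),
                 amp_flip = amp_flip, amp_rot = amp_rot,
                 n_regrow = as.integer(n_regrow), linkage = linkage,
                 amp_cludis = amp_cludis, amp_clurot = amp_clurot,
                 amp_vol = amp_vol, vol_aniso = isTRUE(vol_aniso)),
            class = "move_schedule")
}

#' @export
print.move_schedule <- function(x, ...) {
  on <- x$probs[x$probs > 0]
  cat("<move_schedule> ",
      paste(sprintf("%s %.3g", names(on), on), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Ensemble specification
#'
#' `NVT` (constant volume), `NPT` (constant pressure `P`, in kT/sigma^3,
#' sampled through volume moves) or `semigrand`: fixed site and chain counts
#' with a fluctuating chain-length distribution controlled by relative
#' chemical potentials, encoded as target length-distribution weights `w(N)`
#' on `[n_min, n_max]` (uniform, or Flory `w(N) ~ p^N` with
#' `p = 1 - 1/mean_length`).  Acceptance of length-altering moves picks up
#' the factor `w(N_a') w(N_b') / (w(N_a) w(N_b))`.
#'
#' In monodisperse mode the length-altering moves (`seb`, `inter_rept`,
#' `idex3`) are deactivated and counted as skips.
#'
#' @param ensemble `"NVT"`, `"NPT"` or `"semigrand"`.
#' @param pressure Pressure for NPT, kT/sigma^3.
#' @param n_min,n_max Chain-length bounds (weights vanish outside).
#' @param family `"uniform"` or `"flory"`.
#' @param mean_length Target mean chain length of the Flory distribution.
#' @param weights Optional explicit weight vector over `n_min:n_max`
#'   (overrides `family`).
#' @param monodisperse Deactivate all length-altering moves.
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(ensemble = c("NVT", "NPT", "semigrand"),
                          pressure = NA_real_, n_min = 2L, n_max = 10000L,
                          family = c("uniform", "flory"), mean_length = NULL,
                          weights = NULL, monodisperse = FALSE) {
  ensemble <- match.arg(ensemble)
  family <- match.arg(family)
  n_min <- as.integer(n_min); n_max <- as.integer(n_max)
  if (n_min < 2L || n_max < n_min) stop("need 2 <= n_min <= n_max")
  if (ensemble == "NPT" && (!is.finite(pressure) || pressure <= 0)) {
    stop("NPT requires a positive pressure")
  }
  if (is.null(weights)) {
    ns <- n_min:n_max
    wlog <- if (family == "flory") {
      if (is.null(mean_length)) stop("flory weights need mean_length")
      if (mean_length <= 1) stop("mean_length must exceed 1")
      ns * log1p(-1 / mean_length)
    } else {
      numeric(length(ns))
    }
  } else {
    if (length(weights) != n_max - n_min + 1L) {
      stop("weights must cover n_min:n_max")
    }
    if (any(weights <= 0)) stop("weights must be positive on [n_min, n_max]")
    wlog <- log(weights)
  }
  structure(list(ensemble = ensemble, pressure = pressure, n_min = n_min,
                 n_max = n_max, family = family, mean_length = mean_length,
                 wlog = wlog, monodisperse = isTRUE(monodisperse)),
            class = "ensemble_spec")
}

#' @export
print.ensemble_spec <- function(x, ...) {
  cat(sprintf("<ensemble_spec> %s%s, N in [%d, %d] (%s)%s\n", x$ensemble,
              if (x$ensemble == "NPT") sprintf(" P = %g", x$pressure) else "",
              x$n_min, x$n_max, x$family,
              if (x$monodisperse) ", monodisperse" else ""))
  invisible(x)
}

.pack_schedule <- function(schedule) {
  list(probs = unname(schedule$probs), n_trials = unname(schedule$n_trials),
       l_disp = schedule$l_disp,
       amp_flip = schedule$amp_flip, amp_rot = schedule$amp_rot,
       n_regrow = schedule$n_regrow, linkage = schedule$linkage,
       amp_cludis = schedule$amp_cludis, amp_clurot = schedule$amp_clurot,
       amp_vol = schedule$amp_vol, vol_aniso = schedule$vol_aniso)
}

.pack_ensemble <- function(ensemble) {
  list(type = match(ensemble$ensemble, c("NVT", "NPT", "semigrand")) - 1L,
       pressure = ifelse(is.na(ensemble$pressure), 0, ensemble$pressure),
       n_min = ensemble$n_min, n_max = ensemble$n_max,
       wlog = ensemble$wlog, monodisperse = ensemble$monodisperse)
}

#' Run a Monte Carlo simulation
#'
#' Executes `n_steps` elementary move attempts drawn from the schedule and
#' accepted by the Metropolis criterion (with Rosenbluth-weight ratios for
#' configurational-bias moves and length-distribution weight ratios for the
#' semigrand ensemble).  With `debug = TRUE`, every accepted move is followed
#' by a full overlap/bond assertion (slow; for testing).
#'
#' @param config A [configuration()].
#' @param spec An [interaction_spec()].
#' @param schedule A [move_schedule()].
#' @param ensemble An [ensemble_spec()].
#' @param n_steps Number of move attempts.
#' @param sample_every Record packing density / energy every so many steps
#'   (0 = only at the end).
#' @param debug Assert invariants after every accepted move.
#' @return A list with elements `config` (final state), `stats` (data frame
#'   of attempts/accepts/skips per move), `series` (data frame of sampled
#'   step, phi, energy), and `chain_lengths` (final lengths).
#' @examples
#' set.seed(1)
#' cfg <- generate_dilute_system(0, 0, 20, phi = 0.05)
#' out <- run_mc(cfg, interaction_spec("HS"), move_schedule(), n_steps = 500)
#' out$stats
#' @export
run_mc <- function(config, spec, schedule = move_schedule(),
                   ensemble = ensemble_spec("NVT"), n_steps = 1000L,
                   sample_every = 0L, debug = FALSE) {
  stopifnot(inherits(config, "configuration"), inherits(spec, "interaction_spec"),
            inherits(schedule, "move_schedule"), inherits(ensemble, "ensemble_spec"))
  p <- .pack(config, spec)
  st <- cpp_run_mc(p, .pack_schedule(schedule), .pack_ensemble(ensemble),
                   as.integer(n_steps), as.integer(sample_every),
                   isTRUE(debug))
  out_cfg <- .unpack(st, config)
  stats <- data.frame(move = .move_names, attempts = st$attempts,
                      accepts = st$accepts, skips = st$skips)
  series <- data.frame(step = st$s_step, phi = st$s_phi, energy = st$s_energy)
  list(config = out_cfg, stats = stats, series = series,
       chain_lengths = chain_lengths(out_cfg))
}

#' Single-move attempt helpers
#'
#' Thin wrappers over [run_mc()] that attempt exactly one move of the given
#' kind; useful for move-level testing.
#'
#' @inheritParams run_mc
#' @param move Move name (see [move_schedule()]).
#' @return As [run_mc()], plus logical `accepted` and `skipped`.
#' @export
attempt_move <- function(config, spec, move, schedule = move_schedule(),
                         ensemble = ensemble_spec("NVT"), debug = FALSE) {
  move <- match.arg(move, .move_names)
  pr <- setNames(1, move)
  sched <- schedule
  sched$probs[] <- 0
  sched$probs[move] <- 1
  out <- run_mc(config, spec, sched, ensemble, n_steps = 1L, debug = debug)
  out$accepted <- out$stats$accepts[match(move, .move_names)] > 0L
  out$skipped <- out$stats$skips[match(move, .move_names)] > 0L
  out
}

#' Configurational-bias selection and acceptance
#'
#' `cb_select()` picks one of `n_trials` candidates with probability
#' proportional to its (Boltzmann) weight.  `cb_acceptance()` returns the
#' Metropolis acceptance probability `min(1, W_new / W_old)` from the summed
#' forward and reverse Rosenbluth weights.
#'
#' @param weights Non-negative trial weights (not all zero).
#' @return `cb_select()`: chosen index; `cb_acceptance()`: probability.
#' @examples
#' set.seed(1)
#' cb_select(c(1, 1, 1))
#' cb_acceptance(c(0.5, 0.2), c(0.4, 0.1))
#' @export
cb_select <- function(weights) {
  if (any(weights < 0)) stop("weights must be >= 0")
  s <- sum(weights)
  if (s <= 0) return(NA_integer_)
  sample.int(length(weights), 1L, prob = weights)
}

#' @param forward,reverse Forward and reverse trial weight vectors (the
#'   reverse set holds the `n_trials - 1` regenerated alternatives plus the
#'   weight of the old state).
#' @rdname cb_select
#' @export
cb_acceptance <- function(forward, reverse) {
  wf <- sum(forward); wr <- sum(reverse)
  if (wf <= 0) return(0)
  if (wr <= 0) stop("reverse Rosenbluth weight must be positive")
  min(1, wf / wr)
}
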