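#' Interaction specification
#'
#' Bonded and non-bonded interaction parameters.  Non-bonded modes:
#' \describe{
#'   \item{HS}{hard spheres: infinite below the collision diameter `sigma`,
#'     zero beyond.}
#'   \item{SW / SS}{square well / square shoulder: infinite below `sigma`,
#'     `-eps_sw` (well) or `+eps_sw` (shoulder) on `[sigma, sigma2)`, zero
#'     beyond.  The shoulder is the sign flip of the well.}
#'   \item{LJ}{Lennard-Jones `4 eps_lj [(sigma_lj/r)^12 - (sigma_lj/r)^6]`,
#'     truncated and shifted to zero at `rcut` (default `2.5 sigma_lj`).}
#' }
#'
#' Bond lengths are constrained to `[bond_lo, sigma + dl]`; by default
#' `bond_lo = sigma` so bonds live in the bond-gap interval `[sigma,
#' sigma + dl]` with tangency (`dl = 0`) as a supported limit.  Setting
#' `bond_lo < sigma` permits fused spheres on bonded pairs (non-bonded pairs
#' are always hard-core checked at `sigma`).  Bonded (1-2) pairs are excluded
#' from the non-bonded sum; 1-3 pairs interact unless `exclude_13 = TRUE`.
#'
#' Chain stiffness enters through the bending potential
#' `k_theta * (theta - theta0)^2` where `theta` is the supplement of the
#' internal bond angle in degrees (`theta0 = 0` is fully extended) and
#' `k_theta` is in kT/deg^2; `k_theta = 0` gives freely jointed chains.  An
#' optional torsional term `k_tor * (1 - cos(phi - tor0))` is off by default
#' (torsions fluctuate freely).
#'
#' @param mode `"HS"`, `"SW"`, `"SS"` or `"LJ"`.
#' @param sigma Collision diameter (characteristic length, default 1).
#' @param sigma2 Outer range of the well/shoulder (`> sigma`).
#' @param eps_sw Well depth / shoulder height, kT units.
#' @param eps_lj,sigma_lj Lennard-Jones depth (kT) and zero-energy distance.
#' @param rcut LJ cut-off radius.
#' @param dl Bond gap: allowed bond-length slack above `sigma`.
#' @param bond_lo Lower bond-length bound (default `sigma`).
#' @param k_theta Bending constant, kT/deg^2.
#' @param theta0 Equilibrium bending-angle supplement, degrees.
#' @param k_tor,tor0 Torsion amplitude (kT) and reference dihedral (degrees).
#' @param exclude_13 Exclude 1-3 pairs from the non-bonded sum.
#' @return An object of class `interaction_spec`.
#' @examples
#' interaction_spec("SW", sigma2 = 1.15, eps_sw = 1.2)
#' interaction_spec("HS", dl = 0.1, k_theta = 0.002, theta0 = 120)
#' @export
interaction_spec <- function(mode = c("HS", "SW", "SS", "LJ"), sigma = 1,
                             sigma2 = NA_real_, eps_sw = NA_real_,
                             eps_lj = 1, sigma_lj = 1, rcut = 2.5 * sigma_lj,
                             dl = 0, bond_lo = NULL, k_theta = 0, theta0 = 0,
                             k_tor = 0, tor0 = 0, exclude_13 = FALSE) {
  mode <- match.arg(mode)
  if (sigma <= 0) stop("sigma must be positive")
  if (mode %in% c("SW", "SS")) {
    if (!is.finite(sigma2) || sigma2 <= sigma) stop("SW/SS requires sigma2 > sigma")
    if (!is.finite(eps_sw)) stop("SW/SS requires eps_sw")
  }
  if (dl < 0) stop("dl must be >= 0")
  if (k_theta < 0) stop("k_theta must be >= 0")
  if (is.null(bond_lo)) bond_lo <- sigma
  if (bond_lo > sigma + dl) stop("bond_lo exceeds the upper bond bound sigma + dl")
  structure(list(mode = mode, sigma = sigma, sigma2 = sigma2, eps_sw = eps_sw,
                 eps_lj = eps_lj, sigma_lj = sigma_lj, rcut = rcut, dl = dl,
                 bond_lo = bond_lo, k_theta = k_theta, theta0 = theta0,
                 k_tor = k_tor, tor0 = tor0, exclude_13 = exclude_13),
            class = "interaction_spec")
}

#' @export
print.interaction_spec <- function(x, ...) {
  cat(sprintf("<interaction_spec> %s, sigma = %g", x$mode, x$sigma))
  if (x$mode %in% c("SW", "SS")) cat(sprintf(", sigma2 = %g, eps_sw = %g", x$sigma2, x$eps_sw))
  if (x$mode == "LJ") cat(sprintf(", eps_lj = %g, sigma_lj = %g, rcut = %g", x$eps_lj, x$sigma_lj, x$rcut))
  cat(sprintf("\n  bonds in [%g, %g], k_theta = %g kT/deg^2, theta0 = %g deg\n",
              x$bond_lo, x$sigma + x$dl, x$k_theta, x$theta0))
  invisible(x)
}

#' Non-bonded pair energy
#'
#' @param r Numeric vector of pair distances (sigma units).
#' @param spec An [interaction_spec()].
#' @return Energies in kT (`Inf` inside the hard core).
#' @examples
#' pair_energy(1.1, interaction_spec("SW", sigma2 = 1.15, eps_sw = 1.2))  # -1.2
#' @export
pair_energy <- function(r, spec) {
  stopifnot(inherits(spec, "interaction_spec"))
  r <- as.numeric(r)
  if (any(r <= 0)) stop("pair distance must be positive")
  switch(spec$mode,
    HS = ifelse(r < spec$sigma, Inf, 0),
    SW = ifelse(r < spec$sigma, Inf,
                ifelse(r < spec$sigma2, -spec$eps_sw, 0)),
    SS = ifelse(r < spec$sigma, Inf,
                ifelse(r < spec$sigma2, +spec$eps_sw, 0)),
    LJ = {
      lj <- function(x) 4 * spec$eps_lj * ((spec$sigma_lj / x)^12 - (spec$sigma_lj / x)^6)
      ifelse(r < spec$rcut, lj(r) - lj(spec$rcut), 0)
    })
}

#' Bending energy of a bond-angle supplement
#'
#' @param theta Bending-angle supplement(s), degrees in `[0, 180]`.
#' @param spec An [interaction_spec()].
#' @return `k_theta * (theta - theta0)^2` in kT.
#' @export
bending_energy <- function(theta, spec) {
  stopifnot(inherits(spec, "interaction_spec"))
  spec$k_theta * (theta - spec$theta0)^2
}

# pack a configuration + spec into the flat representation used by the
# C++ kernels (0-based links, padded 3-d coordinates)
.pack <- function(config, spec = interaction_spec("HS")) {
  cell <- config$cell
  co <- config$coords
  if (cell$dim == 2L) co <- cbind(co, 0)
  L <- cell$lengths
  per <- cell$periodic
  if (cell$dim == 2L) { L <- c(L, 1e6); per <- c(per, FALSE) }
  conf <- switch(cell$conf$type, none = 0L, walls = 1L, cylinder = 2L, sphere = 3L)
  caxis <- if (cell$conf$type == "cylinder") cell$conf$axis else 0L
  fl <- matrix(0, 0, 6)
  for (f in config$fillers) {
    if (f$kind == "sphere") {
      ctr <- f$center
      if (cell$dim == 2L) ctr <- c(ctr, 0)
      fl <- rbind(fl, c(0, ctr, f$diameter, 0))
    } else {
      trans <- setdiff(1:3, f$axis)
      ctr <- numeric(3)
      ctr[trans] <- f$anchor
      fl <- rbind(fl, c(1, ctr, f$diameter, f$axis))
    }
  }
  lk <- .topo_links(config$topology)
  list(coords = co, dim = cell$dim, L = L, periodic = per,
       conf = conf, conf_axis = caxis, fillers = fl,
       nxt = lk$nxt, prv = lk$prv, chain = lk$chain,
       spec = .pack_spec(spec))
}

.pack_spec <- function(spec) {
  mode <- match(spec$mode, c("HS", "SW", "SS", "LJ")) - 1L
  c(mode, spec$sigma,
    ifelse(is.na(spec$sigma2), 0, spec$sigma2),
    ifelse(is.na(spec$eps_sw), 0, spec$eps_sw),
    spec$eps_lj, spec$sigma_lj, spec$rcut, spec$dl, spec$bond_lo,
    spec$k_theta, spec$theta0, spec$k_tor, spec$tor0,
    as.numeric(spec$exclude_13))
}

# rebuild an R configuration from C++ state
.unpack <- function(st, template) {
  cell <- template$cell
  cell$lengths <- st$L[seq_len(cell$dim)]
  cell$zeta <- max(cell$lengths) / min(cell$lengths)
  topo <- .links_to_topology(st$nxt, st$prv, nrow(st$coords))
  configuration(st$coords[, seq_len(cell$dim), drop = FALSE], cell, topo,
                template$fillers, wrap = FALSE)
}

#' Total potential energy
#'
#' Sum of non-bonded pair terms (cell-list accelerated), bending and torsion
#' terms.  Hard-core overlaps and bond-length violations are reported as an
#' infinite-energy sentinel rather than an error.
#'
#' @param config A [configuration()].
#' @param spec An [interaction_spec()].
#' @return Total energy in kT.
#' @export
total_energy <- function(config, spec) {
  p <- .pack(config, spec)
  cpp_total_energy(p)
}

#' Energy of one site
#'
#' Non-bonded terms between `i` and all neighbors in range, plus every
#' bonded term (bond validity, bending, torsion) involving `i`.
#'
#' @param config A [configuration()].
#' @param i Site index (1-based).
#' @param spec An [interaction_spec()].
#' @return Energy in kT.
#' @export
site_energy <- function(config, i, spec) {
  p <- .pack(config, spec)
  cpp_site_energy(p, as.integer(i) - 1L)
}

#' Hard-overlap / clearance test
#'
#' `TRUE` if any center pair is closer than `sigma` (bonded pairs checked
#' against their own bounds instead), any center lies within `sigma/2` of a
#' wall or filler surface, or outside a closed confinement.  Tangency at
#' exactly `sigma` is allowed.
#'
#' @param config A [configuration()].
#' @param spec An [interaction_spec()].
#' @param i Optional site index; test only this site against the rest.
#' @return Logical.
#' @export
has_overlap <- function(config, spec = interaction_spec("HS"), i = NULL) {
  p <- .pack(config, spec)
  cpp_has_overlap(p, if (is.null(i)) -1L else as.integer(i) - 1L)
}
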