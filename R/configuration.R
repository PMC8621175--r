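#' System configuration
#'
#' Couples site coordinates with a [sim_cell()], a [chain_topology()] and an
#' optional list of [nano_filler]s.  Coordinates on periodic dimensions are
#' wrapped into `[0, L)`; confined dimensions are never wrapped.
#'
#' @param coords Numeric matrix, `n_at x dim`, site centers in sigma units.
#' @param cell A [sim_cell()].
#' @param topology A [chain_topology()]; defaults to all-singles.
#' @param fillers List of [nano_filler] objects.
#' @param wrap Wrap periodic coordinates into the cell (default `TRUE`).
#' @return An object of class `configuration`.
#' @export
configuration <- function(coords, cell, topology = NULL, fillers = list(),
                          wrap = TRUE) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  stopifnot(inherits(cell, "sim_cell"))
  if (ncol(coords) != cell$dim) stop("coords must have one column per cell dimension")
  if (is.null(topology)) topology <- chain_topology(list(), n_at = nrow(coords))
  stopifnot(inherits(topology, "species_topology"))
  if (topology$n_at != nrow(coords)) stop("topology n_at does not match coords")
  if (inherits(fillers, "nano_filler")) fillers <- list(fillers)
  if (!all(vapply(fillers, inherits, TRUE, "nano_filler"))) {
    stop("fillers must be nano_filler objects")
  }
  if (wrap) coords <- wrap_coords(coords, cell)
  structure(list(coords = coords, cell = cell, topology = topology,
                 fillers = fillers),
            class = "configuration")
}

#' @export
print.configuration <- function(x, ...) {
  cat(sprintf("<configuration> %d site(s) in a %d-d cell [%s]\n",
              nrow(x$coords), x$cell$dim,
              paste(format(x$cell$lengths, digits = 6), collapse = ", ")))
  t <- x$topology
  cat(sprintf("  %d chain(s) <N> = %.2f, %d single(s); %d filler(s); confinement: %s\n",
              t$n_ch, t$mean_length, t$n_s, length(x$fillers), x$cell$conf$type))
  invisible(x)
}

#' Number of sites
#' @param config A [configuration()].
#' @return Integer.
#' @export
n_sites <- function(config) nrow(config$coords)

#' Wrap coordinates into the cell on periodic dimensions
#' @param coords Numeric matrix of coordinates.
#' @param cell A [sim_cell()].
#' @return Wrapped coordinate matrix.
#' @export
wrap_coords <- function(coords, cell) {
  for (d in seq_len(cell$dim)) {
    if (cell$periodic[d]) {
      coords[, d] <- coords[, d] %% cell$lengths[d]
    }
  }
  coords
}

#' Species tag per site
#' @param config A [configuration()].
#' @return Character vector, `"chain"` or `"single"` per site.
#' @export
species_tags <- function(config) {
  tags <- rep("chain", n_sites(config))
  tags[config$topology$singles] <- "single"
  tags
}

#' Minimum-image distance between two points
#'
#' Euclidean distance using the minimum-image convention on periodic
#' dimensions only; confined dimensions contribute their plain difference.
#'
#' @param p,q Numeric vectors (cell coordinates).
#' @param cell A [sim_cell()].
#' @return Numeric scalar distance.
#' @export
min_image_distance <- function(p, q, cell) {
  stopifnot(inherits(cell, "sim_cell"),
            length(p) == cell$dim, length(q) == cell$dim)
  cpp_min_image_dist(as.numeric(p), as.numeric(q),
                     cell$lengths, cell$periodic)
}

#' Packing density
#'
#' Fraction of the cell volume occupied by the monomers:
#' `phi = (pi/6) (n_at / V) sigma^3` in 3-d (Eq. for spheres), or
#' `(pi/4) (n_at / A) sigma^2` in 2-d (disks).
#'
#' @param config A [configuration()].
#' @param sigma Monomer (collision) diameter, sigma units (default 1).
#' @return Dimensionless packing fraction.
#' @export
packing_density <- function(config, sigma = 1) {
  stopifnot(inherits(config, "configuration"))
  V <- cell_volume(config$cell)
  if (!is.finite(V) || V <= 0) stop("invalid cell: non-positive volume")
  monomer_volume(n_sites(config), sigma, config$cell$dim) / V
}

#' Total volume occupied by n monomers
#'
#' `(pi/6) n sigma^3` in 3-d, `(pi/4) n sigma^2` (area) in 2-d.
#'
#' @param n Number of monomers.
#' @param sigma Monomer diameter.
#' @param dim Dimensionality (2 or 3).
#' @return Numeric scalar.
#' @export
monomer_volume <- function(n, sigma = 1, dim = 3L) {
  if (dim == 2L) n * pi / 4 * sigma^2 else n * pi / 6 * sigma^3
}

#' Effective packing density
#'
#' Packing density computed against the volume accessible to monomers once
#' the filler volume is removed: `phi_eff = V_mon / (V - V_fill)` with
#' `V_fill` the summed sphere and cylinder filler volumes.
#'
#' @inheritParams packing_density
#' @return Dimensionless effective packing fraction.
#' @export
effective_density <- function(config, sigma = 1) {
  stopifnot(inherits(config, "configuration"))
  V <- cell_volume(config$cell)
  vf <- sum(vapply(config$fillers, filler_volume, 0, cell = config$cell))
  if (vf >= V) stop("degenerate geometry: filler volume exceeds cell volume")
  monomer_volume(n_sites(config), sigma, config$cell$dim) / (V - vf)
}

#' Depleted effective packing density
#'
#' Accounts for the sigma/2 depletion layer next to confining walls and
#' filler surfaces: the monomer-center-accessible lengths shrink by sigma at
#' walls, and filler radii grow by sigma/2,
#' `V_dep = prod_conf (d_wall - sigma) * prod_free l_j
#'          - (pi/6)(d_sph + sigma)^3 N_sph - (pi/4)(d_cyl + sigma)^2 L_cyl N_cyl`.
#' Cylindrical and spherical confinement use the analogous depleted volumes
#' `(pi/4)(D - sigma)^2 L` and `(pi/6)(D - sigma)^3`.
#'
#' @inheritParams packing_density
#' @return Dimensionless depleted packing fraction.
#' @export
depleted_density <- function(config, sigma = 1) {
  stopifnot(inherits(config, "configuration"))
  cell <- config$cell
  conf <- cell$conf
  if (conf$type == "cylinder") {
    Dd <- cell$lengths[setdiff(seq_len(cell$dim), conf$axis)][1] - sigma
    La <- cell$lengths[conf$axis] - if (conf$ends == "closed") sigma else 0
    if (Dd <= 0 || La <= 0) stop("degenerate geometry: depleted volume <= 0")
    vdep <- pi / 4 * Dd^2 * La
  } else if (conf$type == "sphere") {
    Dd <- cell$lengths[1] - sigma
    if (Dd <= 0) stop("degenerate geometry: depleted volume <= 0")
    vdep <- pi / 6 * Dd^3
  } else {
    len <- cell$lengths
    len[!cell$periodic] <- len[!cell$periodic] - sigma
    if (any(len <= 0)) stop("degenerate geometry: depleted volume <= 0")
    vdep <- prod(len)
  }
  for (f in config$fillers) {
    d <- f$diameter + sigma
    vdep <- vdep - if (f$kind == "sphere") {
      if (cell$dim == 2L) pi / 4 * d^2 else pi / 6 * d^3
    } else {
      (pi / 4) * d^2 * cell$lengths[f$axis]
    }
  }
  if (vdep <= 0) stop("degenerate geometry: depleted volume <= 0")
  monomer_volume(n_sites(config), sigma, cell$dim) / vdep
}
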