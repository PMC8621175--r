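#' Simulation cell with optional confinement
#'
#' An orthogonal simulation cell of 2 or 3 dimensions.  Dimensions are
#' periodic unless they are confined.  Confinement can take the form of flat
#' parallel walls in one or more dimensions, a cylinder (open or closed ends)
#' or a sphere.  Confined dimensions are never wrapped and the inter-wall
#' distance along a confined dimension equals the cell length there.
#'
#' For a cylinder the two transverse cell lengths must equal the cylinder
#' diameter; for a sphere all cell lengths must equal the sphere diameter.
#' Walls sit at coordinate 0 and at the cell length of the confined
#' dimension.
#'
#' @param lengths Numeric vector of cell edge lengths (sigma units), one per
#'   dimension.  All must be positive.
#' @param confinement A confinement specification built with [conf_none()],
#'   [conf_walls()], [conf_cylinder()] or [conf_sphere()].
#' @return An object of class `sim_cell` with fields `lengths`, `dim`,
#'   `periodic`, `conf`, `d_conf` (number of confined dimensions) and
#'   `zeta` (cell aspect ratio, max over min inter-wall distance).
#' @examples
#' sim_cell(c(10, 10, 10))
#' sim_cell(c(20, 20, 5), conf_walls(3))
#' @export
sim_cell <- function(lengths, confinement = conf_none()) {
  lengths <- as.numeric(lengths)
  dim <- length(lengths)
  if (!dim %in% c(2L, 3L)) stop("cell must be 2- or 3-dimensional")
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("all cell lengths must be positive and finite")
  }
  conf <- confinement
  if (!inherits(conf, "polymc_conf")) stop("confinement must be built with conf_*()")
  periodic <- rep(TRUE, dim)
  if (conf$type == "walls") {
    if (any(conf$dims > dim)) stop("confined dimension exceeds cell dimensionality")
    periodic[conf$dims] <- FALSE
  } else if (conf$type == "cylinder") {
    if (dim != 3L) stop("cylindrical confinement requires a 3-d cell")
    if (conf$axis > dim) stop("cylinder axis exceeds cell dimensionality")
    trans <- setdiff(seq_len(dim), conf$axis)
    if (abs(diff(lengths[trans])) > 1e-9) {
      stop("transverse cell lengths must both equal the cylinder diameter")
    }
    periodic[trans] <- FALSE
    if (conf$ends == "closed") periodic[conf$axis] <- FALSE
  } else if (conf$type == "sphere") {
    if (max(lengths) - min(lengths) > 1e-9) {
      stop("all cell lengths must equal the sphere diameter")
    }
    periodic[] <- FALSE
  }
  d_conf <- sum(!periodic)
  cell <- structure(
    list(lengths = lengths, dim = dim, periodic = periodic, conf = conf,
         d_conf = d_conf, zeta = max(lengths) / min(lengths)),
    class = "sim_cell")
  cell
}

#' @rdname sim_cell
#' @export
conf_none <- function() {
  structure(list(type = "none"), class = "polymc_conf")
}

#' @param dims Integer vector of confined dimensions (walls at 0 and at the
#'   cell length of each listed dimension).
#' @rdname sim_cell
#' @export
conf_walls <- function(dims) {
  dims <- sort(unique(as.integer(dims)))
  if (length(dims) < 1L) stop("at least one confined dimension is required")
  structure(list(type = "walls", dims = dims), class = "polymc_conf")
}

#' @param axis Integer, the cell dimension along the cylinder axis.
#' @param ends `"open"` (periodic along the axis) or `"closed"` (walls at the
#'   cylinder ends).
#' @rdname sim_cell
#' @export
conf_cylinder <- function(axis = 3L, ends = c("open", "closed")) {
  ends <- match.arg(ends)
  structure(list(type = "cylinder", axis = as.integer(axis), ends = ends),
            class = "polymc_conf")
}

#' @rdname sim_cell
#' @export
conf_sphere <- function() {
  structure(list(type = "sphere"), class = "polymc_conf")
}

#' @export
print.sim_cell <- function(x, ...) {
  cat(sprintf("<sim_cell> %d-d, lengths [%s] sigma\n", x$dim,
              paste(format(x$lengths, digits = 6), collapse = ", ")))
  cat(sprintf("  periodic: %s | confinement: %s | d_conf = %d | zeta = %.3f\n",
              paste(ifelse(x$periodic, "T", "F"), collapse = ""),
              x$conf$type, x$d_conf, x$zeta))
  invisible(x)
}

#' Cell volume (3-d) or area (2-d)
#' @param cell A [sim_cell()].
#' @return Numeric scalar, product of the cell lengths.
#' @export
cell_volume <- function(cell) {
  stopifnot(inherits(cell, "sim_cell"))
  prod(cell$lengths)
}

#' Immobile nanofillers
#'
#' Nanofillers are impenetrable inclusions: spheres with a fixed center, or
#' cylinders that span the whole simulation cell along one axis and whose
#' direction is held fixed.  Monomer centers cannot approach a filler surface
#' closer than sigma/2 (depletion layer).
#'
#' @param center Numeric vector, sphere center (cell coordinates).
#' @param diameter Filler diameter in sigma units.
#' @param mobile Logical; fillers default to immobile inclusions.
#' @return An object of class `nano_filler`.
#' @examples
#' filler_sphere(c(5, 5, 5), diameter = 5)
#' filler_cylinder(axis = 3, anchor = c(5, 5), diameter = 5)
#' @export
filler_sphere <- function(center, diameter, mobile = FALSE) {
  stopifnot(diameter > 0)
  structure(list(kind = "sphere", center = as.numeric(center),
                 diameter = diameter, mobile = mobile),
            class = "nano_filler")
}

#' @param axis Integer, cell dimension along the cylinder axis; the cylinder
#'   spans the full cell length there.
#' @param anchor Numeric vector of length 2, axis position in the two
#'   transverse dimensions (in increasing dimension order).
#' @rdname filler_sphere
#' @export
filler_cylinder <- function(axis, anchor, diameter, mobile = FALSE) {
  stopifnot(diameter > 0, length(anchor) == 2L)
  structure(list(kind = "cylinder", axis = as.integer(axis),
                 anchor = as.numeric(anchor), diameter = diameter,
                 mobile = mobile),
            class = "nano_filler")
}

#' @export
print.nano_filler <- function(x, ...) {
  if (x$kind == "sphere") {
    cat(sprintf("<nano_filler> sphere d = %g at (%s)\n", x$diameter,
                paste(format(x$center), collapse = ", ")))
  } else {
    cat(sprintf("<nano_filler> cylinder d = %g along axis %d, anchor (%s)\n",
                x$diameter, x$axis, paste(format(x$anchor), collapse = ", ")))
  }
  invisible(x)
}

#' Volume occupied by a filler inside a cell
#' @param filler A [filler_sphere()] or [filler_cylinder()].
#' @param cell The containing [sim_cell()].
#' @return Numeric scalar (sigma^3, or sigma^2 in 2-d).
#' @export
filler_volume <- function(filler, cell) {
  stopifnot(inherits(filler, "nano_filler"), inherits(cell, "sim_cell"))
  d <- filler$diameter
  if (filler$kind == "sphere") {
    if (cell$dim == 2L) pi / 4 * d^2 else pi / 6 * d^3
  } else {
    (pi / 4) * d^2 * cell$lengths[filler$axis]
  }
}
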