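#' Generate ideal (optionally jittered) reference lattices
#'
#' Builds a periodic supercell of an ideal crystal, or a central-site cluster
#' for the non-space-filling local symmetries (FIV: icosahedral shell, PEN:
#' pentagonal ring).  These fixtures drive the validation of the structural
#' descriptor.
#'
#' @param crystal One of `"FCC"`, `"HCP"`, `"BCC"`, `"HEX"`, `"FIV"` (3-d) or
#'   `"TRI"`, `"SQU"`, `"HON"`, `"PEN"` (2-d).
#' @param repeats Integer, number of unit-cell repeats per dimension (ignored
#'   for the FIV/PEN cluster fixtures).  At least 3 repeats are required for
#'   a periodicity-consistent Voronoi tessellation.
#' @param spacing Nearest-neighbor distance, sigma units.
#' @param noise Standard deviation of Gaussian jitter added per coordinate.
#' @return A [configuration()] of single monomers.
#' @examples
#' fcc <- generate_ideal_lattice("FCC", repeats = 3)
#' @export
generate_ideal_lattice <- function(crystal, repeats = 3L, spacing = 1,
                                   noise = 0) {
  crystal <- toupper(crystal)
  repeats <- as.integer(repeats)
  d <- spacing
  if (crystal %in% c("FIV", "PEN")) {
    return(.cluster_fixture(crystal, d, noise))
  }
  if (repeats < 3L) stop("at least 3 repeats are required for a PBC-consistent Voronoi tessellation")
  uc <- switch(crystal,
    FCC = {
      a <- d * sqrt(2)
      list(cell = c(a, a, a),
           frac = rbind(c(0, 0, 0), c(.5, .5, 0), c(.5, 0, .5), c(0, .5, .5)))
    },
    BCC = {
      a <- 2 * d / sqrt(3)
      list(cell = c(a, a, a), frac = rbind(c(0, 0, 0), c(.5, .5, .5)))
    },
    HCP = {
      a <- d; c3 <- 2 * d * sqrt(2 / 3)
      list(cell = c(a, a * sqrt(3), c3),
           frac = rbind(c(0, 0, 0), c(.5, .5, 0),
                        c(.5, 1 / 6, .5), c(0, 2 / 3, .5)))
    },
    HEX = {  # simple hexagonal, c = a
      a <- d
      list(cell = c(a, a * sqrt(3), a),
           frac = rbind(c(0, 0, 0), c(.5, .5, 0)))
    },
    TRI = {
      a <- d
      list(cell = c(a, a * sqrt(3)), frac = rbind(c(0, 0), c(.5, .5)))
    },
    SQU = list(cell = c(d, d), frac = rbind(c(0, 0))),
    HON = {
      a <- d * sqrt(3)
      list(cell = c(a, 3 * d),
           frac = rbind(c(0, 0), c(.5, 1 / 6), c(.5, .5), c(0, 2 / 3)))
    },
    stop("unknown crystal '", crystal, "'"))
  dim <- length(uc$cell)
  shifts <- as.matrix(do.call(expand.grid, rep(list(seq_len(repeats) - 1L), dim)))
  coords <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(k) {
    sweep(uc$frac, 2, shifts[k, ], "+")
  }))
  coords <- sweep(coords, 2, uc$cell, "*")
  cell <- sim_cell(uc$cell * repeats)
  if (noise > 0) coords <- coords + matrix(rnorm(length(coords), 0, noise), ncol = dim)
  configuration(coords, cell)
}

# central site + ideal first shell, isolated in a large periodic box
.cluster_fixture <- function(crystal, d, noise) {
  if (crystal == "FIV") {
    g <- (1 + sqrt(5)) / 2
    v <- rbind(c(0, 1, g), c(0, -1, g), c(0, 1, -g), c(0, -1, -g),
               c(1, g, 0), c(-1, g, 0), c(1, -g, 0), c(-1, -g, 0),
               c(g, 0, 1), c(g, 0, -1), c(-g, 0, 1), c(-g, 0, -1))
    v <- v / sqrt(1 + g^2) * d
    box <- 8 * d
    ctr <- rep(box / 2, 3)
  } else {
    ang <- 2 * pi * (0:4) / 5
    v <- cbind(cos(ang), sin(ang)) * d
    box <- 8 * d
    ctr <- rep(box / 2, 2)
  }
  coords <- rbind(ctr, sweep(v, 2, ctr, "+"))
  if (noise > 0) coords <- coords + matrix(rnorm(length(coords), 0, noise), ncol = ncol(coords))
  configuration(coords, sim_cell(rep(box, ncol(coords))))
}
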