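# Independent brute-force oracles used across the suite.  These deliberately
# avoid the package's cell-list/energy kernels: plain R, all-pairs.

# minimum-image displacement matrix of q relative to p (single pair)
oracle_min_image <- function(p, q, lengths, periodic) {
  # brute force over all 27 (or 9) integer image shifts
  dim <- length(p)
  shifts <- do.call(expand.grid, lapply(seq_len(dim), function(d) {
    if (periodic[d]) -1:1 else 0L
  }))
  best <- Inf
  for (k in seq_len(nrow(shifts))) {
    d <- q + unlist(shifts[k, ]) * lengths - p
    best <- min(best, sqrt(sum(d^2)))
  }
  best
}

# all-pairs minimum-image distance matrix
oracle_dists <- function(coords, cell) {
  n <- nrow(coords)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) {
        d <- coords[j, ] - coords[i, ]
        for (k in seq_len(cell$dim)) {
          if (cell$periodic[k]) {
            L <- cell$lengths[k]
            d[k] <- d[k] - L * round(d[k] / L)
          }
        }
        m[i, j] <- m[j, i] <- sqrt(sum(d^2))
      }
    }
  }
  m
}

# all-pairs total energy (non-bonded + bond validity + bending), plain R
oracle_total_energy <- function(config, spec) {
  co <- config$coords
  n <- nrow(co)
  dm <- oracle_dists(co, config$cell)
  lk <- polymc:::.topo_links(config$topology)
  bonded <- matrix(FALSE, n, n)
  for (ch in config$topology$chains) {
    for (k in seq_len(length(ch) - 1)) {
      bonded[ch[k], ch[k + 1]] <- bonded[ch[k + 1], ch[k]] <- TRUE
    }
  }
  E <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (bonded[i, j]) {
        if (dm[i, j] < spec$bond_lo - 1e-9 ||
            dm[i, j] > spec$sigma + spec$dl + 1e-9) return(Inf)
      } else {
        E <- E + pair_energy(dm[i, j], spec)
      }
    }
  }
  if (spec$k_theta > 0) {
    for (ch in config$topology$chains) {
      if (length(ch) < 3) next
      for (k in 2:(length(ch) - 1)) {
        u <- .mi_vec(co[ch[k - 1], ], co[ch[k], ], config$cell)
        v <- .mi_vec(co[ch[k], ], co[ch[k + 1], ], config$cell)
        th <- acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
        E <- E + spec$k_theta * (th - spec$theta0)^2
      }
    }
  }
  E
}

.mi_vec <- function(a, b, cell) {
  d <- b - a
  for (k in seq_len(cell$dim)) {
    if (cell$periodic[k]) {
      L <- cell$lengths[k]
      d[k] <- d[k] - L * round(d[k] / L)
    }
  }
  d
}

# all-pairs overlap test (tangency allowed), walls/fillers via clearance
oracle_overlap <- function(config, spec) {
  co <- config$coords
  dm <- oracle_dists(co, config$cell)
  lk <- polymc:::.topo_links(config$topology)
  n <- nrow(co)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      b <- lk$nxt[i] == j - 1L || lk$prv[i] == j - 1L
      if (b) {
        if (dm[i, j] < spec$bond_lo - 1e-9 ||
            dm[i, j] > spec$sigma + spec$dl + 1e-9) return(TRUE)
      } else if (dm[i, j] < spec$sigma * (1 - 1e-12)) return(TRUE)
    }
  }
  cell <- config$cell
  h <- spec$sigma / 2 * (1 - 1e-12)
  for (i in seq_len(n)) {
    x <- co[i, ]
    if (cell$conf$type == "walls") {
      for (d in which(!cell$periodic)) {
        if (x[d] < h || x[d] > cell$lengths[d] - h) return(TRUE)
      }
    }
    for (f in config$fillers) {
      if (f$kind == "sphere") {
        if (sqrt(sum(.mi_vec(f$center, x, cell)^2)) < (f$diameter + spec$sigma) / 2 * (1 - 1e-12)) {
          return(TRUE)
        }
      } else {
        trans <- setdiff(seq_len(cell$dim), f$axis)
        d <- x[trans] - f$anchor
        for (w in seq_along(trans)) {
          if (cell$periodic[trans[w]]) {
            L <- cell$lengths[trans[w]]
            d[w] <- d[w] - L * round(d[w] / L)
          }
        }
        if (sqrt(sum(d^2)) < (f$diameter + spec$sigma) / 2 * (1 - 1e-12)) return(TRUE)
      }
    }
  }
  FALSE
}

# single-linkage clusters by brute-force union-find over all pairs
oracle_clusters <- function(config, linkage) {
  dm <- oracle_dists(config$coords, config$cell)
  n <- nrow(dm)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i && dm[i, j] <= linkage) {
        parent[find(i)] <- find(j)
      }
    }
  }
  vapply(seq_len(n), find, 1L)
}

# Carnahan-Starling pressure for hard spheres: P sigma^3/kT = Z * 6 phi / pi
cs_pressure <- function(phi) {
  Z <- (1 + phi + phi^2 - phi^3) / (1 - phi)^3
  Z * 6 * phi / pi
}

# density (phi) solving the CS equation of state at given pressure
cs_phi_at_pressure <- function(P) {
  uniroot(function(phi) cs_pressure(phi) - P, c(1e-6, 0.54), tol = 1e-10)$root
}

# closed-form square-well second virial coefficient
b2_sw_closed <- function(sigma, sigma2, eps) {
  (2 * pi / 3) * sigma^3 * (1 - (sigma2^3 / sigma^3 - 1) * (exp(eps) - 1))
}

# random non-overlapping configuration via the package generator (chains +
# singles); used as input to equality property tests
random_config <- function(n_ch, N, n_s, phi, spec, dim3 = TRUE) {
  generate_dilute_system(n_ch, N, n_s, phi = phi, spec = spec)
}
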