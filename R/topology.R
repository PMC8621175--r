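#' Chain/monomer species topology
#'
#' Records which sites belong to linear chains (ordered site indices) and
#' which are single monomers.  Every site index in `1:n_at` must appear
#' exactly once, chains are simple paths, and the bookkeeping identity
#' `n_ch * N + n_s = n_at` holds with `N` the average chain length.
#'
#' @param chains List of integer vectors, each an ordered list of site
#'   indices along one chain (length >= 2).
#' @param n_at Total number of sites; sites not listed in `chains` are single
#'   monomers.
#' @return An object of class `species_topology` with fields `chains`,
#'   `singles`, `n_ch`, `n_s`, `n_at` and `mean_length`.
#' @examples
#' chain_topology(list(1:5, 6:10), n_at = 12)  # two pentamers + two singles
#' @export
chain_topology <- function(chains = list(), n_at) {
  chains <- lapply(chains, as.integer)
  n_at <- as.integer(n_at)
  idx <- unlist(chains, use.names = FALSE)
  if (anyDuplicated(idx)) stop("a site index appears in more than one chain position")
  if (length(idx) && (min(idx) < 1L || max(idx) > n_at)) {
    stop("chain site indices out of range")
  }
  if (any(vapply(chains, length, 1L) < 2L)) {
    stop("chains must have at least 2 monomers")
  }
  singles <- setdiff(seq_len(n_at), idx)
  n_ch <- length(chains)
  structure(
    list(chains = chains, singles = singles, n_ch = n_ch,
         n_s = length(singles), n_at = n_at,
         mean_length = if (n_ch) length(idx) / n_ch else 0),
    class = "species_topology")
}

#' Build a topology from chain lengths
#'
#' Site indices are assigned consecutively: chains first, singles last.
#'
#' @param chain_lengths Integer vector of chain lengths.
#' @param n_singles Number of single monomers.
#' @return A [chain_topology()].
#' @export
topology_from_lengths <- function(chain_lengths = integer(), n_singles = 0L) {
  chain_lengths <- as.integer(chain_lengths)
  ends <- cumsum(chain_lengths)
  starts <- ends - chain_lengths + 1L
  chains <- Map(seq.int, starts, ends)
  chain_topology(chains, n_at = sum(chain_lengths) + as.integer(n_singles))
}

#' @export
print.species_topology <- function(x, ...) {
  cat(sprintf("<species_topology> n_at = %d: %d chain(s), <N> = %.2f, %d single(s)\n",
              x$n_at, x$n_ch, x$mean_length, x$n_s))
  invisible(x)
}

#' Chain lengths of a topology or configuration
#' @param x A `species_topology` or `configuration`.
#' @return Integer vector of chain lengths.
#' @export
chain_lengths <- function(x) {
  if (inherits(x, "configuration")) x <- x$topology
  stopifnot(inherits(x, "species_topology"))
  vapply(x$chains, length, 1L)
}

# successor/predecessor arrays (0-based, -1 = none) for the C++ kernels
.topo_links <- function(topology) {
  n <- topology$n_at
  nxt <- rep(-1L, n)
  prv <- rep(-1L, n)
  chain <- rep(0L, n)
  for (k in seq_along(topology$chains)) {
    ch <- topology$chains[[k]]
    m <- length(ch)
    nxt[ch[-m]] <- ch[-1L] - 1L
    prv[ch[-1L]] <- ch[-m] - 1L
    chain[ch] <- k
  }
  list(nxt = nxt, prv = prv, chain = chain)
}

# rebuild a topology from successor/predecessor arrays returned by C++
.links_to_topology <- function(nxt, prv, n_at) {
  heads <- which(prv < 0L & nxt >= 0L)
  chains <- vector("list", length(heads))
  for (k in seq_along(heads)) {
    ch <- integer(0)
    i <- heads[k]
    repeat {
      ch <- c(ch, i)
      nx <- nxt[i]
      if (nx < 0L) break
      i <- nx + 1L
    }
    chains[[k]] <- ch
  }
  chain_topology(chains, n_at = n_at)
}
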