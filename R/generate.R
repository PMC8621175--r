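#' Generate a dilute non-overlapping chain/monomer system
#'
#' Random-walk chains with bond lengths uniform in `[sigma, sigma + dl]` and
#' uniformly placed single monomers, all respecting hard-core, wall and
#' filler clearances.  Generation is deterministic under a fixed R random
#' seed (`set.seed()`).
#'
#' @param n_ch Number of chains.
#' @param N Chain length (monomers per chain); all chains start monodisperse.
#' @param n_s Number of single monomers.
#' @param cell A [sim_cell()], or `NULL` to build a cubic periodic cell from
#'   `phi`.
#' @param phi Target packing density used when `cell` is `NULL`.
#' @param spec An [interaction_spec()]; its `sigma`, `dl` and bending
#'   parameters steer generation (bending angles are sampled from the
#'   bending Boltzmann density).
#' @param fillers List of [nano_filler] objects.
#' @param max_retry Placement attempts per monomer before the chain is
#'   restarted.
#' @return A [configuration()].
#' @examples
#' set.seed(1)
#' cfg <- generate_dilute_system(2, 10, 5, phi = 0.01)
#' @export
generate_dilute_system <- function(n_ch, N, n_s = 0L, cell = NULL, phi = 0.01,
                                   spec = interaction_spec("HS"),
                                   fillers = list(), max_retry = 2000L) {
  n_at <- n_ch * N + n_s
  if (n_at < 1L) stop("empty system requested")
  if (is.null(cell)) {
    V <- monomer_volume(n_at, spec$sigma, 3L) / phi
    cell <- sim_cell(rep(V^(1 / 3), 3L))
  }
  topo <- topology_from_lengths(rep(N, n_ch), n_s)
  cfg0 <- configuration(matrix(0, 0, cell$dim), cell, fillers = fillers)
  p <- .pack(cfg0, spec)
  res <- cpp_generate_dilute(p, as.integer(rep(N, n_ch)), as.integer(n_s),
                             as.integer(max_retry))
  if (!res$ok) {
    stop("placement failed after max retries; use a larger cell or lower phi")
  }
  configuration(res$coords[, seq_len(cell$dim), drop = FALSE], cell, topo,
                fillers = fillers, wrap = FALSE)
}
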