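#' Compression schedule towards jamming
#'
#' Parameters of the athermal compression protocol: blocks of displacement
#' sweeps alternate with volume-shrink attempts whose amplitude decays when
#' rejected, until the accepted relative volume change over a trailing
#' window falls below `tol` (or `max_blocks` is exhausted).
#'
#' @param sweeps_per_block Displacement sweeps (N attempts each) per block.
#' @param shrink0 Initial relative volume-shrink step.
#' @param shrink_min Smallest shrink step attempted.
#' @param decay Multiplicative decay of the shrink step after a rejected
#'   shrink.
#' @param tol Convergence threshold on the relative volume change per block,
#'   averaged over `window` blocks.
#' @param window Trailing window (blocks) for the convergence test.
#' @param max_blocks Hard cap on blocks.
#' @param amp0 Initial displacement amplitude (adapted towards ~40%
#'   acceptance during the run).
#' @return An object of class `compression_schedule`.
#' @export
compression_schedule <- function(sweeps_per_block = 50L, shrink0 = 2e-3,
                                 shrink_min = 1e-7, decay = 0.9, tol = 1e-7,
                                 window = 20L, max_blocks = 5000L,
                                 amp0 = 0.3) {
  structure(list(sweeps_per_block = as.integer(sweeps_per_block),
                 shrink0 = shrink0, shrink_min = shrink_min, decay = decay,
                 tol = tol, window = as.integer(window),
                 max_blocks = as.integer(max_blocks), amp0 = amp0),
            class = "compression_schedule")
}

#' Compress an athermal system towards its jammed state
#'
#' Alternates displacement sweeps with isotropic (or, under confinement,
#' anisotropic over the unconfined dimensions) volume-shrink attempts; a
#' shrink is accepted only if no hard overlap, wall/filler clearance or bond
#' bound is violated after affine rescaling, so the volume is monotone
#' non-increasing by construction.
#'
#' @param config A [configuration()].
#' @param spec An [interaction_spec()] (hard-core modes).
#' @param schedule A [compression_schedule()].
#' @param phi_stop Stop once this packing density is reached and rescale
#'   affinely to it exactly (default 1: compress to convergence/jamming).
#' @return List with `config` (final state), `phi` (final packing density),
#'   `series` (data frame of block, phi, accepted displacement fraction),
#'   and `converged` (logical; `FALSE` means the block budget ran out first).
#' @examples
#' set.seed(1)
#' cfg <- generate_dilute_system(0, 0, 30, phi = 0.1)
#' out <- compress_to_jamming(cfg, interaction_spec("HS"),
#'                            compression_schedule(max_blocks = 50))
#' out$phi
#' @export
compress_to_jamming <- function(config, spec = interaction_spec("HS"),
                                schedule = compression_schedule(),
                                phi_stop = 1) {
  stopifnot(inherits(config, "configuration"),
            inherits(schedule, "compression_schedule"))
  p <- .pack(config, spec)
  st <- cpp_compress(p, schedule$sweeps_per_block, schedule$shrink0,
                     schedule$shrink_min, schedule$decay, schedule$tol,
                     schedule$window, schedule$max_blocks, schedule$amp0,
                     as.numeric(phi_stop))
  out_cfg <- .unpack(st, config)
  if (!st$converged) {
    warning("compression did not converge within max_blocks; returning best state")
  }
  list(config = out_cfg, phi = packing_density(out_cfg, spec$sigma),
       series = data.frame(block = st$s_block, phi = st$s_phi,
                           acc_disp = st$s_acc),
       converged = st$converged)
}
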