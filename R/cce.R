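#' Reference-crystal catalog for the symmetry-element descriptor
#'
#' Each reference crystal is identified by a characteristic set of symmetry
#' elements (axes with a multiplicity, proper or roto-inverted, applied at
#' the listed generator powers, plus optionally a standalone inversion
#' center) and a coordination number `n_coord`:
#' \itemize{
#' \item FCC: three mutually orthogonal fourfold roto-inversion axes,
#'   `n_coord = 12`.
#' \item HCP: one sixfold roto-inversion axis, `n_coord = 12`.
#' \item BCC: four threefold roto-inversion axes along the cube diagonals
#'   plus an inversion center, `n_coord = 8` (the 8 nearest of its 14
#'   Voronoi neighbors).
#' \item HEX: one sixfold rotation axis, `n_coord = 8`.
#' \item FIV: one fivefold rotation axis (icosahedral shell),
#'   `n_coord = 12`.
#' \item 2-d: TRI sixfold (`n_coord = 6`), SQU fourfold (4), HON threefold
#'   (3), PEN fivefold (5), all proper in-plane rotations.
#' }
#' The catalog is data: entries may be dropped, or replaced by modified
#' copies, before being passed to [cce_norms()].
#'
#' @param dim 2 or 3.
#' @return Named list of crystal definitions (class `cce_catalog`).
#' @export
cce_reference_crystals <- function(dim = 3L) {
  ax_z <- matrix(c(0, 0, 1), 1)
  if (dim == 3L) {
    out <- list(
      FCC = list(name = "FCC", n_coord = 12L, axes = diag(3), mult = 4L,
                 improper = TRUE, powers = 1:3, inversion = FALSE,
                 roll_max = 90),
      HCP = list(name = "HCP", n_coord = 12L, axes = ax_z, mult = 6L,
                 improper = TRUE, powers = 1:5, inversion = FALSE,
                 roll_max = 0),
      BCC = list(name = "BCC", n_coord = 8L,
                 axes = rbind(c(1, 1, 1), c(1, -1, -1),
                              c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3),
                 mult = 3L, improper = TRUE, powers = c(1L, 2L, 4L, 5L),
                 inversion = TRUE, roll_max = 90),
      HEX = list(name = "HEX", n_coord = 8L, axes = ax_z, mult = 6L,
                 improper = FALSE, powers = 1:5, inversion = FALSE,
                 roll_max = 0),
      FIV = list(name = "FIV", n_coord = 12L, axes = ax_z, mult = 5L,
                 improper = FALSE, powers = 1:4, inversion = FALSE,
                 roll_max = 0))
  } else if (dim == 2L) {
    out <- list(
      TRI = list(name = "TRI", n_coord = 6L, axes = ax_z, mult = 6L,
                 improper = FALSE, powers = 1:5, inversion = FALSE,
                 roll_max = 0),
      SQU = list(name = "SQU", n_coord = 4L, axes = ax_z, mult = 4L,
                 improper = FALSE, powers = 1:3, inversion = FALSE,
                 roll_max = 0),
      HON = list(name = "HON", n_coord = 3L, axes = ax_z, mult = 3L,
                 improper = FALSE, powers = 1:2, inversion = FALSE,
                 roll_max = 0),
      PEN = list(name = "PEN", n_coord = 5L, axes = ax_z, mult = 5L,
                 improper = FALSE, powers = 1:4, inversion = FALSE,
                 roll_max = 0))
  } else stop("dim must be 2 or 3")
  structure(out, class = "cce_catalog")
}

#' Voronoi neighbors of every site
#'
#' Neighbors are the sites whose Voronoi cells share a face (3-d) or edge
#' (2-d) of non-negligible measure with the site's cell, under the periodic
#' images of the cell; confining walls truncate the tessellation
#' (mirror-free), and faces against walls or against the bounding of an
#' unbounded cell do not count as neighbors.  Exactly co-spherical
#' degeneracies (e.g. ideal lattices) are resolved by a deterministic 1e-9
#' jitter, recorded in the result.
#'
#' @param config A [configuration()].
#' @param sites Optional integer vector restricting the analysis.
#' @return List with `neighbors` (list of site-index vectors, by increasing
#'   distance), `n_vor`, `cell_volume` and `n_faces` per analyzed site.
#' @examples
#' fcc <- generate_ideal_lattice("FCC", repeats = 3)
#' vor <- voronoi_neighbors(fcc)
#' table(vor$n_vor)  # all 12
#' @export
voronoi_neighbors <- function(config, sites = NULL) {
  stopifnot(inherits(config, "configuration"))
  p <- .pack(config)
  idx <- if (is.null(sites)) seq_len(n_sites(config)) else as.integer(sites)
  res <- cpp_voronoi(p, idx - 1L)
  list(neighbors = lapply(res$neighbors, function(v) v + 1L),
       n_vor = res$n_vor, cell_volume = res$volume, n_faces = res$n_faces,
       jitter = 1e-9, sites = idx)
}

#' Per-site crystallographic similarity norms
#'
#' For every analyzed site and reference crystal `X`, keeps the
#' `n_coord(X)` closest Voronoi neighbors (a constant penalty norm of 1 is
#' assigned when fewer are available), normalizes the shell by its mean
#' radius, and minimizes over scanned symmetry-element orientations the RMS
#' mismatch between the symmetry-transformed shell and the original one
#' under nearest-vector assignment.  The orientation mesh has width
#' `phi_step` (degrees, same step for azimuthal and polar angles; a third
#' Euler angle is scanned for multi-axis crystals), followed by a local
#' refinement pass around the mesh optimum.  Equidistant neighbors spanning
#' the `n_coord` cut are resolved conservatively: the subset maximizing the
#' norm is kept, so degenerate shells never produce spurious labels.
#'
#' The lower the norm, the higher the similarity; a site is labeled by its
#' minimum-norm crystal when that norm is at most `eps_thres`, and `AMO`
#' (no similarity to any reference) otherwise.
#'
#' @param config A [configuration()].
#' @param crystals A [cce_reference_crystals()] catalog (defaults to the
#'   full catalog of the configuration's dimensionality).
#' @param phi_step Orientation mesh width, degrees.
#' @param eps_thres Labeling threshold (default 0.245).
#' @param on_the_fly Stop scanning a site as soon as a norm at or below
#'   `eps_thres` is found (preliminary identification; remaining norms for
#'   that site are upper bounds).
#' @param refine Run the local mesh-refinement pass.
#' @param sites Optional integer vector restricting the analysis.
#' @return An object of class `cce_result`: `norms` (matrix, site x
#'   crystal), `labels`, `n_vor`, `eps_thres`, `phi_step`, plus the Voronoi
#'   statistics of [voronoi_neighbors()].
#' @examples
#' fcc <- generate_ideal_lattice("FCC", repeats = 3)
#' res <- cce_norms(fcc)
#' table(res$labels)
#' @export
cce_norms <- function(config, crystals = NULL, phi_step = 10,
                      eps_thres = 0.245, on_the_fly = FALSE, refine = TRUE,
                      sites = NULL) {
  stopifnot(inherits(config, "configuration"))
  if (is.null(crystals)) crystals <- cce_reference_crystals(config$cell$dim)
  if (!inherits(crystals, "cce_catalog")) {
    if (is.character(crystals)) {
      cat0 <- cce_reference_crystals(config$cell$dim)
      missing <- setdiff(crystals, names(cat0))
      if (length(missing)) stop("unknown crystal name(s): ", paste(missing, collapse = ", "))
      crystals <- structure(cat0[crystals], class = "cce_catalog")
    } else stop("crystals must be a cce_catalog or crystal names")
  }
  p <- .pack(config)
  idx <- if (is.null(sites)) seq_len(n_sites(config)) else as.integer(sites)
  vor <- cpp_voronoi(p, idx - 1L)
  cats <- lapply(unname(crystals), function(cr) {
    list(n_coord = as.integer(cr$n_coord), axes = cr$axes,
         mult = as.integer(cr$mult), improper = isTRUE(cr$improper),
         powers = as.integer(cr$powers), inversion = isTRUE(cr$inversion),
         roll_max = as.numeric(cr$roll_max))
  })
  nm <- cpp_cce(p, vor, cats, as.numeric(phi_step), as.numeric(eps_thres),
                isTRUE(on_the_fly), isTRUE(refine))
  colnames(nm) <- names(crystals)
  rownames(nm) <- NULL
  structure(list(norms = nm, labels = label_sites(nm, eps_thres),
                 n_vor = vor$n_vor, cell_volume = vor$volume,
                 n_faces = vor$n_faces,
                 neighbors = lapply(vor$neighbors, function(v) v + 1L),
                 eps_thres = eps_thres, phi_step = phi_step, sites = idx),
            class = "cce_result")
}

#' @export
print.cce_result <- function(x, ...) {
  cat(sprintf("<cce_result> %d site(s), crystals: %s, eps_thres = %g\n",
              nrow(x$norms), paste(colnames(x$norms), collapse = ", "),
              x$eps_thres))
  print(table(x$labels))
  invisible(x)
}

#' Label sites from a norm matrix
#'
#' @param norms Numeric matrix (site x crystal) of similarity norms, or a
#'   `cce_result`.
#' @param eps_thres Labeling threshold.
#' @return Character vector: the minimum-norm crystal where that norm is at
#'   most `eps_thres`, `"AMO"` otherwise.
#' @export
label_sites <- function(norms, eps_thres = 0.245) {
  if (inherits(norms, "cce_result")) norms <- norms$norms
  if (is.null(colnames(norms))) stop("norms must have crystal column names")
  k <- apply(norms, 1, which.min)
  lab <- colnames(norms)[k]
  lab[norms[cbind(seq_len(nrow(norms)), k)] > eps_thres] <- "AMO"
  lab
}

#' Order fractions, crystallinity and ordered-cluster statistics
#'
#' Summarizes a labeling: per-crystal site fractions `S^X` (summing to 1
#' with `S^AMO`), total crystallinity `tau_c = S^HCP + S^FCC` (the compact
#' crystals of hard-sphere packings), the fivefold fraction, clusters of
#' same-label ordered sites (proximity linkage restricted to a shared
#' label), their sizes and gyration-tensor shape metrics, and Voronoi-cell
#' statistics.
#'
#' @param result A `cce_result` from [cce_norms()].
#' @param config The analyzed [configuration()].
#' @param linkage Linkage distance for ordered-cluster detection (sigma
#'   units).
#' @return An object of class `order_summary`: `fractions`, `tau_c`,
#'   `s_fiv`, `clusters` (a [detect_clusters()] result over ordered sites),
#'   `cluster_shapes`, `voronoi` (summary of cell volumes and face counts).
#' @export
order_summary <- function(result, config, linkage = 1.2) {
  stopifnot(inherits(result, "cce_result"), inherits(config, "configuration"))
  labs <- result$labels
  cryst <- colnames(result$norms)
  frac <- vapply(c(cryst, "AMO"), function(x) mean(labs == x), 0)
  tau_c <- sum(frac[intersect(c("HCP", "FCC"), cryst)])
  s_fiv <- if ("FIV" %in% cryst) frac[["FIV"]] else NA_real_
  ordered <- which(labs != "AMO")
  if (length(ordered)) {
    lab_cond <- rep(NA_character_, n_sites(config))
    lab_cond[result$sites] <- ifelse(labs == "AMO", NA, labs)
    cl_all <- detect_clusters(config, linkage, labels = lab_cond)
    keep <- vapply(cl_all$clusters, function(g) !is.na(lab_cond[g[1]]), TRUE)
    clusters <- cl_all$clusters[keep]
    shapes <- if (length(clusters)) shape_metrics(config, clusters) else NULL
  } else {
    clusters <- list()
    shapes <- NULL
  }
  structure(list(fractions = frac, tau_c = tau_c, s_fiv = s_fiv,
                 clusters = clusters,
                 cluster_sizes = vapply(clusters, length, 1L),
                 cluster_shapes = shapes,
                 voronoi = list(
                   mean_volume = mean(result$cell_volume),
                   sd_volume = stats::sd(result$cell_volume),
                   face_counts = table(result$n_faces))),
            class = "order_summary")
}

#' @export
print.order_summary <- function(x, ...) {
  cat("<order_summary> fractions:\n")
  print(round(x$fractions, 4))
  cat(sprintf("  tau_c = %.4f, S_FIV = %s, %d ordered cluster(s)\n",
              x$tau_c, format(x$s_fiv, digits = 4), length(x$clusters)))
  invisible(x)
}
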