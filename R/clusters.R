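#' Detect proximity clusters
#'
#' Single-linkage connected components of the graph joining site pairs whose
#' minimum-image distance is at most `linkage`.  An optional label vector
#' restricts linkage to pairs sharing the same label (e.g. the same crystal
#' similarity).
#'
#' @param config A [configuration()].
#' @param linkage Linkage distance, sigma units.
#' @param labels Optional per-site labels; pairs with differing labels are
#'   never linked.  `NA`-labeled sites are left as singletons among
#'   themselves.
#' @return An object of class `cluster_set`: list with `membership`
#'   (cluster id per site), `clusters` (list of member indices, decreasing
#'   size), `sizes`, and the `linkage` used.
#' @examples
#' set.seed(1)
#' cfg <- generate_dilute_system(0, 0, 30, phi = 0.02)
#' detect_clusters(cfg, linkage = 1.5)
#' @export
detect_clusters <- function(config, linkage, labels = NULL) {
  stopifnot(inherits(config, "configuration"), linkage > 0)
  p <- .pack(config)
  lab <- if (is.null(labels)) integer(n_sites(config)) else {
    if (length(labels) != n_sites(config)) stop("labels must have one entry per site")
    as.integer(factor(labels, exclude = NULL))
  }
  memb <- cpp_detect_clusters(p, as.numeric(linkage), lab)
  ids <- sort(unique(memb))
  clusters <- lapply(ids, function(k) which(memb == k))
  ord <- order(-vapply(clusters, length, 1L))
  clusters <- clusters[ord]
  memb2 <- integer(length(memb))
  for (k in seq_along(clusters)) memb2[clusters[[k]]] <- k
  structure(list(membership = memb2, clusters = clusters,
                 sizes = vapply(clusters, length, 1L), linkage = linkage,
                 detected_at = Sys.time()),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s) at linkage %g; sizes: %s\n",
              length(x$clusters), x$linkage,
              paste(utils::head(x$sizes, 8L), collapse = ", ")))
  invisible(x)
}

#' Gyration-tensor shape metrics of site groups
#'
#' Radius of gyration, asphericity and acylindricity computed from the
#' eigenvalues of the gyration tensor of each group (coordinates unwrapped
#' to the first member's image).
#'
#' @param config A [configuration()].
#' @param groups List of integer site-index vectors.
#' @return Data frame with one row per group: `size`, `rg`, `asphericity`,
#'   `acylindricity`.
#' @export
shape_metrics <- function(config, groups) {
  cell <- config$cell
  res <- lapply(groups, function(g) {
    x <- config$coords[g, , drop = FALSE]
    ref <- x[1, ]
    for (d in seq_len(cell$dim)) {
      if (cell$periodic[d]) {
        L <- cell$lengths[d]
        x[, d] <- ref[d] + ((x[, d] - ref[d] + L / 2) %% L) - L / 2
      }
    }
    xc <- sweep(x, 2, colMeans(x))
    ev <- sort(eigen(crossprod(xc) / nrow(xc), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev <- c(ev, numeric(3 - length(ev)))
    data.frame(size = nrow(x), rg = sqrt(sum(ev)),
               asphericity = ev[1] - 0.5 * (ev[2] + ev[3]),
               acylindricity = ev[2] - ev[3])
  })
  do.call(rbind, res)
}
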