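#' Read and write extended-XYZ configurations
#'
#' The dialect stores the site count on line 1, a `key=value` header on line
#' 2 (cell lengths, periodicity, dimensionality, confinement, fillers) and
#' one line per site: species tag (`chain`/`single`), x, y, z, chain id
#' (0 for singles) and monomer-in-chain index.  Coordinates survive a
#' write/read round trip to better than 1e-12.
#'
#' @param path File path.
#' @return `read_xyz()` returns a [configuration()]; `write_xyz()` returns
#'   `path` invisibly.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("xyz parse error at line 1: missing header")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 0) stop("xyz parse error at line 1: invalid site count")
  if (length(lines) < 2L + n) {
    stop(sprintf("xyz parse error: expected %d site lines, found %d",
                 n, length(lines) - 2L))
  }
  hdr <- .parse_xyz_header(lines[2])
  cell <- sim_cell(hdr$lengths, hdr$conf)
  if (n == 0L) {
    return(configuration(matrix(0, 0, cell$dim), cell, fillers = hdr$fillers))
  }
  fields <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  bad <- which(vapply(fields, length, 1L) != 6L)
  if (length(bad)) stop(sprintf("xyz parse error at line %d: expected 6 fields", bad[1] + 2L))
  m <- matrix(as.numeric(unlist(lapply(fields, `[`, 2:6))), ncol = 5, byrow = TRUE)
  coords <- m[, 1:cell$dim, drop = FALSE]
  chain_id <- as.integer(m[, 4])
  mono <- as.integer(m[, 5])
  chains <- list()
  for (k in sort(unique(chain_id[chain_id > 0L]))) {
    sel <- which(chain_id == k)
    chains[[length(chains) + 1L]] <- sel[order(mono[sel])]
  }
  configuration(coords, cell, chain_topology(chains, n_at = n),
                fillers = hdr$fillers, wrap = FALSE)
}

.parse_xyz_header <- function(line) {
  kv <- regmatches(line, gregexpr('[a-z_]+="[^"]*"|[a-z_]+=[^ ]+', line))[[1]]
  if (!length(kv)) stop("xyz parse error at line 2: no key=value entries")
  keys <- sub("=.*$", "", kv)
  vals <- gsub('^"|"$', "", sub("^[a-z_]+=", "", kv))
  get <- function(k, default = NULL) {
    if (k %in% keys) vals[match(k, keys)] else default
  }
  lengths <- as.numeric(strsplit(get("cell"), "\\s+")[[1]])
  conf_s <- get("conf", "none")
  cp <- strsplit(conf_s, ":")[[1]]
  conf <- switch(cp[1],
    none = conf_none(),
    walls = conf_walls(as.integer(strsplit(cp[2], ",")[[1]])),
    cylinder = conf_cylinder(as.integer(cp[2]), cp[3]),
    sphere = conf_sphere(),
    stop("xyz parse error at line 2: unknown confinement '", cp[1], "'"))
  fillers <- list()
  fs <- get("fillers", "")
  if (nzchar(fs)) {
    for (tok in strsplit(fs, ";")[[1]]) {
      p <- strsplit(tok, ":")[[1]]
      fillers[[length(fillers) + 1L]] <- if (p[1] == "sphere") {
        filler_sphere(as.numeric(p[2:(length(p) - 1L)]), as.numeric(p[length(p)]))
      } else {
        filler_cylinder(as.integer(p[2]), as.numeric(p[3:4]), as.numeric(p[5]))
      }
    }
  }
  list(lengths = lengths, conf = conf, fillers = fillers)
}

#' @param config A [configuration()] to write.
#' @rdname read_xyz
#' @export
write_xyz <- function(config, path) {
  stopifnot(inherits(config, "configuration"))
  cell <- config$cell
  conf <- cell$conf
  conf_s <- switch(conf$type,
    none = "none",
    walls = paste0("walls:", paste(conf$dims, collapse = ",")),
    cylinder = paste0("cylinder:", conf$axis, ":", conf$ends),
    sphere = "sphere")
  fl <- vapply(config$fillers, function(f) {
    if (f$kind == "sphere") {
      paste(c("sphere", sprintf("%.17g", c(f$center, f$diameter))), collapse = ":")
    } else {
      paste(c("cylinder", f$axis, sprintf("%.17g", c(f$anchor, f$diameter))), collapse = ":")
    }
  }, "")
  hdr <- sprintf('cell="%s" pbc="%s" dim=%d conf=%s%s',
                 paste(sprintf("%.17g", cell$lengths), collapse = " "),
                 paste(ifelse(cell$periodic, "T", "F"), collapse = " "),
                 cell$dim, conf_s,
                 if (length(fl)) sprintf(' fillers="%s"', paste(fl, collapse = ";")) else "")
  n <- n_sites(config)
  lk <- .topo_links(config$topology)
  mono <- integer(n)
  for (ch in config$topology$chains) mono[ch] <- seq_along(ch)
  co <- config$coords
  if (cell$dim == 2L) co <- cbind(co, 0)
  body <- sprintf("%s %.17g %.17g %.17g %d %d",
                  ifelse(lk$chain > 0L, "chain", "single"),
                  co[, 1], co[, 2], co[, 3], lk$chain, mono)
  writeLines(c(sprintf("%d", n), hdr, if (n) body), path)
  invisible(path)
}
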