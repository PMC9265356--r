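# Shared fixtures: small configs and brute-force oracles, built in code.

small_cfg <- function(n = 60, seed = 11, ...) {
  synth_config(grid_shape = c(n, n), seed = seed, ...)
}

random_ple_raster <- function(n = 50, cell_size = 100, seed = 42,
                              k = 4, clump = 1.5) {
  set.seed(seed)
  # mildly autocorrelated categorical field so patches are non-trivial
  f <- matrix(stats::rnorm(n * n), n, n)
  f <- pleconflict:::smooth_gaussian(f, clump)
  brk <- stats::quantile(f, probs = seq(0, 1, length.out = k + 1))
  m <- matrix(findInterval(f, brk[-c(1, k + 1)]) + 1L, n, n)
  land_raster(m, cell_size = cell_size, classes = ple_classes())
}

# Moran's I with the rook-neighbor double sum (independent oracle).
morans_i_rook <- function(m) {
  z <- m - mean(m)
  nr <- nrow(m); nc <- ncol(m)
  num <- 0; w <- 0
  for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    ri <- seq_len(nr) + sh[1]; ci <- seq_len(nc) + sh[2]
    ok_r <- ri >= 1 & ri <= nr; ok_c <- ci >= 1 & ci <= nc
    a <- z[which(ok_r), which(ok_c), drop = FALSE]
    b <- z[ri[ok_r], ci[ok_c], drop = FALSE]
    num <- num + sum(a * b)
    w <- w + length(a)
  }
  (length(z) / w) * num / sum(z^2)
}

# Brute-force flood fill (recursive frontier) for patch labelling.
flood_fill_label <- function(m, connectivity = 8) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 8) {
    expand.grid(dr = -1:1, dc = -1:1)[-5, ]
  } else {
    data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (is.na(m[i, j]) || lab[i, j] > 0L) next
    cur <- cur + 1L
    frontier <- list(c(i, j))
    lab[i, j] <- cur
    while (length(frontier)) {
      nxt <- list()
      for (cell in frontier) {
        for (t in seq_len(nrow(offs))) {
          a <- cell[1] + offs$dr[t]; b <- cell[2] + offs$dc[t]
          if (a >= 1 && a <= nr && b >= 1 && b <= nc && lab[a, b] == 0L &&
              !is.na(m[a, b]) && m[a, b] == m[i, j]) {
            lab[a, b] <- cur
            nxt[[length(nxt) + 1]] <- c(a, b)
          }
        }
      }
      frontier <- nxt
    }
  }
  lab
}

# Patch labelling via igraph connected components (independent library route).
igraph_label <- function(m, connectivity = 8) {
  nr <- nrow(m); nc <- ncol(m)
  id <- function(i, j) (j - 1L) * nr + i
  edges <- integer(0)
  offs <- if (connectivity == 8) list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
          else list(c(1, 0), c(0, 1))
  for (sh in offs) {
    for (j in seq_len(nc)) for (i in seq_len(nr)) {
      a <- i + sh[1]; b <- j + sh[2]
      if (a >= 1 && a <= nr && b >= 1 && b <= nc &&
          !is.na(m[i, j]) && !is.na(m[a, b]) && m[i, j] == m[a, b]) {
        edges <- c(edges, id(i, j), id(a, b))
      }
    }
  }
  g <- igraph::make_graph(edges, n = nr * nc, directed = FALSE)
  comp <- igraph::components(g)$membership
  lab <- matrix(comp, nr, nc)
  lab[is.na(m)] <- 0L
  lab
}

# Brute-force per-cell edge counting for patch perimeters.
brute_perimeter <- function(m, lab, cell_size) {
  out <- numeric(max(lab))
  nr <- nrow(m); nc <- ncol(m)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (lab[i, j] == 0L) next
    for (sh in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      a <- i + sh[1]; b <- j + sh[2]
      exposed <- a < 1 || a > nr || b < 1 || b > nc ||
        is.na(m[a, b]) || m[a, b] != m[i, j]
      if (exposed) out[lab[i, j]] <- out[lab[i, j]] + cell_size
    }
  }
  out
}

table3_areas <- function() {
  tibble::tibble(
    date = rep(c("2000", "2005", "2010", "2015", "2020"), each = 6),
    class = rep(names(lu_classes()), 5),
    area_km2 = c(1561.89, 25.48, 0.06, 192.14, 234.60, 2.83,
                 1549.37, 25.22, 0.07, 201.56, 238.29, 2.50,
                 1508.80, 35.04, 0.00, 212.02, 261.04, 0.14,
                 1497.35, 34.45, 0.00, 211.83, 273.19, 0.14,
                 1497.68, 31.97, 0.11, 214.04, 269.93, 2.36)
  )
}
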