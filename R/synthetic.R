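#' Configuration for the synthetic landscape generator
#'
#' Defines the study conditions the generator emulates: a flat plain-type
#' county dominated by cultivated land with a growing construction core,
#' substantial water, a little woodland and trace grassland/unused land.
#' Default class proportions follow that structure
#' (77% / 1.3% / 0.1% / 9.5% / 11.6% / 0.5% for cultivated, woodland,
#' grassland, water, construction, unused), the default grid is 200 x 200
#' cells of 30 m (6 km x 6 km, so a 1000 m evaluation grid gives 36 whole
#' units), and the default transition matrix encodes slow cultivated-land
#' loss to construction and water over one calibration interval.
#'
#' @param grid_shape integer vector `c(rows, cols)`.
#' @param cell_size_m cell edge in meters.
#' @param class_proportions 6-vector of target class shares, summing to 1.
#' @param autocorrelation_range spatial range of driver fields, in cells
#'   (Gaussian smoothing sigma).
#' @param true_transition 6x6 row-stochastic matrix of per-interval class
#'   transition probabilities injected by [evolve_landuse()].
#' @param driver_count number of continuous driver rasters (13 mirrors a
#'   typical driver set: terrain, climate, socio-economy, accessibility).
#' @param seed integer seed; every generator is deterministic given it.
#' @return A `synth_config` list.
#' @examples
#' cfg <- synth_config(grid_shape = c(60, 60), seed = 1)
#' @export
synth_config <- function(grid_shape = c(200, 200),
                         cell_size_m = 30,
                         class_proportions = c(0.770, 0.013, 0.001,
                                               0.095, 0.116, 0.005),
                         autocorrelation_range = 8,
                         true_transition = default_transition(),
                         driver_count = 13,
                         seed = 1L) {
  if (length(grid_shape) != 2 || any(grid_shape < 1)) {
    stop("`grid_shape` must be two positive integers", call. = FALSE)
  }
  if (cell_size_m <= 0) stop("`cell_size_m` must be positive", call. = FALSE)
  if (length(class_proportions) != 6 ||
      abs(sum(class_proportions) - 1) > 1e-9 || any(class_proportions < 0)) {
    stop("`class_proportions` must be 6 non-negative values summing to 1",
         call. = FALSE)
  }
  check_row_stochastic(true_transition)
  if (driver_count < 1) stop("`driver_count` must be >= 1", call. = FALSE)
  structure(
    list(grid_shape = as.integer(grid_shape),
         cell_size_m = cell_size_m,
         class_proportions = class_proportions,
         autocorrelation_range = autocorrelation_range,
         true_transition = true_transition,
         driver_count = as.integer(driver_count),
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Default per-interval transition matrix of the synthetic landscape
#'
#' Row-stochastic 6x6 matrix over one calibration interval: cultivated land
#' slowly converts to construction and water, woodland and water are nearly
#' persistent, construction is almost absorbing, trace classes churn.
#'
#' @return 6x6 matrix with rows/cols named by [lu_classes()].
#' @export
default_transition <- function() {
  P <- rbind(
    c(0.950, 0.005, 0.000, 0.015, 0.030, 0.000),
    c(0.050, 0.900, 0.000, 0.020, 0.030, 0.000),
    c(0.100, 0.050, 0.800, 0.020, 0.030, 0.000),
    c(0.020, 0.005, 0.000, 0.955, 0.020, 0.000),
    c(0.010, 0.000, 0.000, 0.010, 0.980, 0.000),
    c(0.100, 0.020, 0.020, 0.050, 0.010, 0.800)
  )
  dimnames(P) <- list(names(lu_classes()), names(lu_classes()))
  P
}

check_row_stochastic <- function(P, tol = 1e-9) {
  if (!is.matrix(P) || nrow(P) != ncol(P)) {
    stop("transition matrix must be square", call. = FALSE)
  }
  if (any(P < -tol)) stop("transition matrix has negative entries", call. = FALSE)
  bad <- abs(rowSums(P) - 1) > tol
  if (any(bad)) {
    stop(sprintf("transition matrix rows %s do not sum to 1",
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

# Separable Gaussian smoothing with reflected edges; sigma in cells.
smooth_gaussian <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  # mirror-reflect an index into 1..n (period 2n - 2), valid for any offset
  fold <- function(j, n) {
    if (n == 1) return(rep(1L, length(j)))
    j <- abs(j - 1) %% (2 * n - 2)
    as.integer(ifelse(j >= n, 2 * n - 2 - j, j) + 1)
  }
  conv1 <- function(mat) {
    n <- nrow(mat)
    idx <- seq_len(n)
    out <- matrix(0, n, ncol(mat))
    for (off in seq(-half, half)) {
      out <- out + k[off + half + 1] * mat[fold(idx + off, n), , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(m))))
}

#' Generate standardized driver rasters
#'
#' Builds `driver_count` continuous surfaces as Gaussian-smoothed white
#' noise (spatial range = `autocorrelation_range` cells); odd-numbered
#' layers get an additional monotone linear gradient so some drivers carry
#' broad trends (elevation- or distance-like), the rest purely local
#' structure. Each layer is standardized to mean 0, sd 1.
#'
#' @param cfg a [synth_config()].
#' @return A `driver_stack`: list of matrices with attributes.
#' @export
gen_drivers <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  nr <- cfg$grid_shape[1]; nc <- cfg$grid_shape[2]
  set.seed(cfg$seed)
  layers <- vector("list", cfg$driver_count)
  grad_r <- matrix(seq_len(nr), nr, nc) / nr
  grad_c <- matrix(seq_len(nc), nr, nc, byrow = TRUE) / nc
  for (i in seq_len(cfg$driver_count)) {
    f <- smooth_gaussian(matrix(stats::rnorm(nr * nc), nr, nc),
                         cfg$autocorrelation_range)
    if (i %% 2 == 1) {
      ang <- stats::runif(1, 0, 2 * pi)
      f <- f + stats::sd(f) * 2 * (cos(ang) * grad_r + sin(ang) * grad_c)
    }
    layers[[i]] <- (f - mean(f)) / stats::sd(f)
  }
  names(layers) <- paste0("driver", seq_len(cfg$driver_count))
  structure(layers, class = "driver_stack",
            cell_size = cfg$cell_size_m, seed = cfg$seed)
}

# Fixed class-score loadings: each class scores cells by a seeded linear
# combination of drivers (unit norm), so suitability is learnable.
class_loadings <- function(cfg) {
  set.seed(cfg$seed + 1000L)
  B <- matrix(stats::rnorm(cfg$driver_count * 6), cfg$driver_count, 6)
  sweep(B, 2, sqrt(colSums(B^2)), "/")
}

class_scores <- function(cfg, drivers) {
  X <- vapply(drivers, as.vector, numeric(length(drivers[[1]])))
  X %*% class_loadings(cfg)
}

# Largest-remainder rounding of `x` (non-negative) to integers summing to
# `total`.
largest_remainder <- function(x, total) {
  fl <- floor(x)
  rem <- total - sum(fl)
  if (rem > 0) {
    ord <- order(x - fl, decreasing = TRUE)
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  } else if (rem < 0) {
    ord <- order(x - fl)
    take <- ord[fl[ord] > 0][seq_len(-rem)]
    fl[take] <- fl[take] - 1
  }
  as.integer(fl)
}

#' Generate a categorical land-use raster from drivers
#'
#' Assigns each cell one of the six classes so that realized class shares
#' hit `class_proportions` up to integer rounding, and placement follows a
#' linear driver score per class (plus seeded noise): classes are filled in
#' decreasing target-size order, each taking its top-scoring unassigned
#' cells. Suitability is therefore learnable from the drivers by design.
#'
#' @param cfg a [synth_config()].
#' @param drivers a `driver_stack` from [gen_drivers()].
#' @param noise_sd sd of the seeded score noise relative to the unit-norm
#'   driver score.
#' @return A categorical [land_raster()].
#' @export
gen_landuse <- function(cfg, drivers, noise_sd = 0.5) {
  stopifnot(inherits(cfg, "synth_config"), inherits(drivers, "driver_stack"))
  nr <- cfg$grid_shape[1]; nc <- cfg$grid_shape[2]
  if (!identical(dim(drivers[[1]]), c(nr, nc))) {
    stop("driver stack shape does not match config", call. = FALSE)
  }
  ncell <- nr * nc
  set.seed(cfg$seed + 2000L)
  S <- class_scores(cfg, drivers) + noise_sd * matrix(stats::rnorm(ncell * 6), ncell, 6)
  targets <- largest_remainder(cfg$class_proportions * ncell, ncell)
  out <- integer(ncell)
  free <- rep(TRUE, ncell)
  for (k in order(targets, decreasing = TRUE)) {
    if (targets[k] == 0) next
    idx <- which(free)
    pick <- idx[order(S[idx, k], decreasing = TRUE)[seq_len(targets[k])]]
    out[pick] <- k
    free[pick] <- FALSE
  }
  land_raster(matrix(out, nr, nc), cell_size = cfg$cell_size_m)
}

#' Evolve a land-use raster by a known transition matrix
#'
#' Produces a second-date raster whose per-class transition frequencies
#' match `P` up to largest-remainder rounding. Within each source class the
#' number of cells converting to each target is fixed at `n_c * P[c, k]`
#' (largest-remainder), and converting cells are chosen as the
#' top-suitability cells for the target class (driver score plus seeded
#' noise), so change has spatial structure.
#'
#' @param lu a categorical [land_raster()] (date t).
#' @param P 6x6 row-stochastic transition matrix.
#' @param cfg the [synth_config()] (provides score loadings).
#' @param drivers the `driver_stack`.
#' @param seed integer seed for the placement noise.
#' @param noise_sd sd of the placement noise.
#' @return A [land_raster()] for date t+1.
#' @export
evolve_landuse <- function(lu, P, cfg, drivers, seed = cfg$seed + 3000L,
                           noise_sd = 0.5) {
  stopifnot(is_land_raster(lu))
  check_row_stochastic(P)
  if (!identical(dim(lu$values), dim(drivers[[1]]))) {
    stop("raster and driver shapes differ", call. = FALSE)
  }
  v <- as.vector(lu$values)
  set.seed(seed)
  S <- class_scores(cfg, drivers) +
    noise_sd * matrix(stats::rnorm(length(v) * 6), length(v), 6)
  out <- v
  for (c0 in seq_len(6)) {
    cells <- which(v == c0)
    n_c <- length(cells)
    if (n_c == 0) next
    counts <- largest_remainder(P[c0, ] * n_c, n_c)
    free <- rep(TRUE, n_c)
    # fill targets (excluding self) in decreasing count order, self keeps rest
    for (k in setdiff(order(counts, decreasing = TRUE), c0)) {
      if (counts[k] == 0) next
      idx <- which(free)
      pick <- idx[order(S[cells[idx], k], decreasing = TRUE)[seq_len(counts[k])]]
      out[cells[pick]] <- k
      free[pick] <- FALSE
    }
  }
  land_raster(matrix(out, nrow(lu$values), ncol(lu$values)),
              cell_size = lu$cell_size, nodata = lu$nodata,
              classes = lu$classes)
}

#' Generate a binary restriction mask
#'
#' Emulates an ecological-reserve or basic-farmland constraint layer: the
#' top `fraction` of cells by a seeded driver score is restricted (those
#' cells never change class during simulation).
#'
#' @param cfg a [synth_config()].
#' @param drivers a `driver_stack`.
#' @param fraction share of cells restricted.
#' @param class_for class whose score locates the reserve (default water,
#'   a wetland-reserve analogue).
#' @return Logical matrix, `TRUE` = restricted.
#' @export
gen_restriction <- function(cfg, drivers, fraction = 0.05, class_for = 4L) {
  stopifnot(inherits(cfg, "synth_config"))
  s <- class_scores(cfg, drivers)[, class_for]
  n <- length(s)
  mask <- rep(FALSE, n)
  mask[order(s, decreasing = TRUE)[seq_len(max(1L, round(fraction * n)))]] <- TRUE
  matrix(mask, cfg$grid_shape[1], cfg$grid_shape[2])
}

#' Write a synthetic scene to disk
#'
#' Writes the land-use rasters as ESRI ASCII grids plus a JSON sidecar with
#' the injected transition matrix and seeds, so downstream stages can be
#' validated against known truth.
#'
#' @param scene named list of [land_raster()]s.
#' @param cfg the [synth_config()] used.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(scene)) {
    write_ascii_grid(scene[[nm]], file.path(dir, paste0(nm, ".asc")))
  }
  sidecar <- list(
    seed = cfg$seed,
    cell_size_m = cfg$cell_size_m,
    grid_shape = cfg$grid_shape,
    class_proportions = cfg$class_proportions,
    true_transition = cfg$true_transition
  )
  jsonlite::write_json(sidecar, file.path(dir, "scene.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
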