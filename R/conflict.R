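#' Partition a raster into square evaluation units
#'
#' Tiles the raster extent with `unit_size` x `unit_size` (m) grid units.
#' Boundary units that are only partly covered are kept; all index
#' denominators nevertheless use the full nominal unit area, so partial
#' units are "calculated according to a complete unit area". Cells are
#' assigned to the unit containing their upper-left corner.
#'
#' @param r a [land_raster()].
#' @param unit_size evaluation-unit edge, meters (default 1000).
#' @return List: `unit_id` (integer matrix, same shape as `r`), `units`
#'   tibble (`unit`, `urow`, `ucol`, `cells`, `coverage`), `nominal_area_m2`,
#'   `n_units`.
#' @examples
#' r <- land_raster(matrix(1L, 200, 200), cell_size = 30)
#' partition_grid(r)$n_units  # 6 km x 6 km -> 36 units
#' @export
partition_grid <- function(r, unit_size = 1000) {
  stopifnot(is_land_raster(r))
  d <- dim(r$values)
  if (prod(d) == 0) stop("empty raster", call. = FALSE)
  cs <- r$cell_size
  urow <- floor((seq_len(d[1]) - 1) * cs / unit_size) + 1L
  ucol <- floor((seq_len(d[2]) - 1) * cs / unit_size) + 1L
  nuc <- max(ucol)
  unit_id <- matrix(0L, d[1], d[2])
  unit_id[] <- (urow[row(unit_id)] - 1L) * nuc + ucol[col(unit_id)]
  data_cells <- r$values != r$nodata & !is.na(r$values)
  tab <- table(unit_id[data_cells])
  cells_per_unit_full <- (unit_size / cs)^2
  units <- tibble::tibble(
    unit = as.integer(names(tab)),
    cells = as.integer(tab)
  )
  units$urow <- (units$unit - 1L) %/% nuc + 1L
  units$ucol <- (units$unit - 1L) %% nuc + 1L
  units$coverage <- units$cells / cells_per_unit_full
  list(unit_id = unit_id, units = units[, c("unit", "urow", "ucol",
                                            "cells", "coverage")],
       nominal_area_m2 = unit_size^2, n_units = nrow(units),
       unit_size = unit_size)
}

# Label connected components of an integer vector-of-classes matrix.
# Returns integer matrix of patch labels (0 = background/NA).
label_components <- function(m, connectivity = 8) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  if (connectivity == 8) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L)
    dc <- c(0L, 0L, -1L, 1L)
  }
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (is.na(m[i, j]) || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    cls <- m[i, j]
    stack <- matrix(c(i, j), 1, 2)
    lab[i, j] <- nxt
    while (nrow(stack)) {
      cur <- stack[nrow(stack), ]
      stack <- stack[-nrow(stack), , drop = FALSE]
      for (t in seq_along(dr)) {
        ni <- cur[1] + dr[t]; nj <- cur[2] + dc[t]
        if (ni >= 1 && ni <= nr && nj >= 1 && nj <= nc &&
            lab[ni, nj] == 0L && !is.na(m[ni, nj]) && m[ni, nj] == cls) {
          lab[ni, nj] <- nxt
          stack <- rbind(stack, c(ni, nj))
        }
      }
    }
  }
  lab
}

# Perimeter of each labelled patch: exposed cell edges (different class,
# nodata/NA, or matrix boundary) x cell_size. `m` is the class matrix of
# one unit (NA outside data).
patch_measurements <- function(m, lab, cell_size) {
  nl <- max(lab)
  if (nl == 0) {
    return(tibble::tibble(patch = integer(), class = integer(),
                          cells = integer(), area_m2 = numeric(),
                          perimeter_m = numeric()))
  }
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(NA_integer_, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  exposed <- matrix(0L, nr, nc)
  for (sh in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
    nb <- pad[2:(nr + 1) + sh[1], 2:(nc + 1) + sh[2]]
    exposed <- exposed + (is.na(nb) | nb != core)
  }
  exposed[is.na(core)] <- 0L
  cells <- tabulate(lab, nbins = nl)
  per <- vapply(seq_len(nl), function(p) sum(exposed[lab == p]), integer(1))
  cls <- vapply(seq_len(nl), function(p) m[which(lab == p)[1]], m[1, 1])
  tibble::tibble(patch = seq_len(nl), class = cls, cells = cells,
                 area_m2 = cells * cell_size^2,
                 perimeter_m = per * cell_size)
}

#' Extract landscape patches per evaluation unit
#'
#' Patches are maximal connected components of same-class cells *within* a
#' unit (patches are clipped at unit boundaries; unit-boundary edges count
#' toward perimeter, as do edges facing nodata or a different class).
#'
#' @param ple a classified [land_raster()] (PLE or land-use codes).
#' @param partition result of [partition_grid()].
#' @param connectivity 8 (queen, default) or 4 (rook).
#' @return Tibble: `unit`, `patch`, `class`, `cells`, `area_m2`,
#'   `perimeter_m`.
#' @export
extract_patches <- function(ple, partition, connectivity = 8) {
  stopifnot(is_land_raster(ple), connectivity %in% c(4, 8))
  v <- ple$values
  v[v == ple$nodata] <- NA_integer_
  uid <- partition$unit_id
  purrr::map_dfr(partition$units$unit, function(u) {
    idx <- which(uid == u, arr.ind = TRUE)
    ri <- range(idx[, 1]); ci <- range(idx[, 2])
    sub <- v[ri[1]:ri[2], ci[1]:ci[2], drop = FALSE]
    # mask cells of other units sharing the bounding box (straddling cells)
    subu <- uid[ri[1]:ri[2], ci[1]:ci[2], drop = FALSE]
    sub[subu != u] <- NA_integer_
    lab <- label_components(sub, connectivity)
    out <- patch_measurements(sub, lab, ple$cell_size)
    out$unit <- u
    out[, c("unit", "patch", "class", "cells", "area_m2", "perimeter_m")]
  })
}

#' Vulnerability scores of the four PLE space types
#'
#' Living-production space is most vulnerable to conflict (4), then
#' production-ecological (3), ecological-production (2), ecological (1).
#'
#' @return Named numeric vector over LP, PE, EP, ECO.
#' @export
vulnerability_weights <- function() {
  c(LP = 4, PE = 3, EP = 2, ECO = 1)
}

# SCI (AWMPFD): sum over patches of 2 ln(0.25 P) / ln(a) * a / A.
sci_from_patches <- function(area_m2, perimeter_m, nominal_area_m2) {
  if (any(log(area_m2) == 0)) {
    stop("patch with area 1 m2: ln(a) = 0; use cells >= 1 m", call. = FALSE)
  }
  sum(2 * log(0.25 * perimeter_m) / log(area_m2) * area_m2 / nominal_area_m2)
}

#' Per-unit conflict indices
#'
#' Computes, per evaluation unit: the spatial complexity index SCI
#' (area-weighted mean patch fractal dimension over the unit's patches,
#' weights a/A with A the *nominal* unit area), the spatial vulnerability
#' index SVI (sum of class vulnerability x class area / A), the patch
#' density PD, and the spatial stability index SRI = 1 - min-max-scaled PD
#' (min/max over the units of the same date).
#'
#' @param patches tibble from [extract_patches()] on a PLE raster.
#' @param partition result of [partition_grid()].
#' @param weights vulnerability scores, named by PLE type
#'   ([vulnerability_weights()]).
#' @param pd_mode `"patches"` (PD = patch count / A, default) or `"types"`
#'   (PD = number of distinct space types / A).
#' @return Tibble: `unit`, `n_patches`, `pd`, `sci`, `svi`, `sri`.
#' @export
conflict_indices <- function(patches, partition,
                             weights = vulnerability_weights(),
                             pd_mode = c("patches", "types")) {
  pd_mode <- match.arg(pd_mode)
  A <- partition$nominal_area_m2
  ple_code <- ple_classes()
  w_by_code <- stats::setNames(weights[names(ple_code)], ple_code)
  bad <- setdiff(unique(patches$class), as.integer(ple_code))
  if (length(bad)) {
    stop(sprintf("no vulnerability weight for class code(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  per_unit <- dplyr::summarise(
    dplyr::group_by(patches, .data$unit),
    n_patches = dplyr::n(),
    n_types = dplyr::n_distinct(.data$class),
    sci = sci_from_patches(.data$area_m2, .data$perimeter_m, A),
    svi = sum(w_by_code[as.character(.data$class)] * .data$area_m2) / A,
    .groups = "drop"
  )
  per_unit$pd <- if (pd_mode == "patches") per_unit$n_patches / A else
    per_unit$n_types / A
  rng <- range(per_unit$pd)
  if (rng[1] == rng[2]) {
    message("no fragmentation contrast across units; SRI set to 1")
    per_unit$sri <- 1
  } else {
    per_unit$sri <- 1 - (per_unit$pd - rng[1]) / (rng[2] - rng[1])
  }
  per_unit[, c("unit", "n_patches", "pd", "sci", "svi", "sri")]
}

#' Normalize the conflict composite index and assign levels
#'
#' `scci_raw = SCI + SVI - SRI`; `scci_norm` min-max scales the raw index
#' over the supplied pool to `[0, 1]`, and the level is one of five
#' equal-interval bins `[0,0.2) [0.2,0.4) [0.4,0.6) [0.6,0.8) [0.8,1]`
#' (weaker, weak, medium, strong, stronger spatial conflict).
#'
#' @param units tibble with `sci`, `svi`, `sri` columns (one or several
#'   dates row-bound together form the normalization pool).
#' @return The input with `scci_raw`, `scci_norm`, `level` appended.
#' @export
scci <- function(units) {
  units$scci_raw <- units$sci + units$svi - units$sri
  rng <- range(units$scci_raw)
  if (rng[1] == rng[2]) {
    message("degenerate SCCI pool (max = min); all normalized values set to 0")
    units$scci_norm <- 0
  } else {
    units$scci_norm <- (units$scci_raw - rng[1]) / (rng[2] - rng[1])
  }
  units$level <- pmin(5L, findInterval(units$scci_norm,
                                       c(0, 0.2, 0.4, 0.6, 0.8)))
  units
}

#' Conflict level names
#' @return Character vector of the five level names.
#' @export
conflict_level_names <- function() {
  c("weaker", "weak", "medium", "strong", "stronger")
}

#' Assess PLE spatial conflict on one or more dated rasters
#'
#' Full per-unit pipeline: partition into evaluation units, extract
#' clipped patches, compute SCI/SVI/SRI per date, pool the raw composite
#' index, normalize, and assign five conflict levels. By default the
#' normalization pool is *joint* across all supplied dates so levels are
#' commensurable over time; `pool = "per_date"` normalizes each date
#' separately. SRI min-max scaling is always within-date.
#'
#' @param ple_rasters named list of PLE [land_raster()]s (names = dates).
#' @param unit_size evaluation-unit edge in meters.
#' @param connectivity patch connectivity, 8 or 4.
#' @param weights vulnerability scores.
#' @param pool `"joint"` or `"per_date"`.
#' @param pd_mode passed to [conflict_indices()].
#' @return A `conflict_result`: list with `units` tibble (`date`, `unit`,
#'   `urow`, `ucol`, `coverage`, indices, `scci_raw`, `scci_norm`, `level`,
#'   `dominant_ple`), the `partition`, and the call parameters.
#' @export
conflict_assess <- function(ple_rasters, unit_size = 1000, connectivity = 8,
                            weights = vulnerability_weights(),
                            pool = c("joint", "per_date"),
                            pd_mode = c("patches", "types")) {
  pool <- match.arg(pool)
  pd_mode <- match.arg(pd_mode)
  if (is_land_raster(ple_rasters)) ple_rasters <- list(date1 = ple_rasters)
  if (is.null(names(ple_rasters))) {
    names(ple_rasters) <- paste0("date", seq_along(ple_rasters))
  }
  part <- partition_grid(ple_rasters[[1]], unit_size)
  ple_names <- names(ple_classes())
  per_date <- purrr::imap(ple_rasters, function(r, date) {
    check_same_geometry(ple_rasters[[1]], r)
    pat <- extract_patches(r, part, connectivity)
    ind <- conflict_indices(pat, part, weights, pd_mode)
    dom <- dplyr::summarise(
      dplyr::group_by(pat, .data$unit, .data$class),
      area = sum(.data$area_m2), .groups = "drop_last") |>
      dplyr::slice_max(order_by = .data$area, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::transmute(unit = .data$unit,
                       dominant_ple = ple_names[.data$class])
    ind <- dplyr::left_join(ind, dom, by = "unit")
    ind$date <- date
    ind
  })
  units <- dplyr::bind_rows(per_date)
  if (pool == "joint") {
    units <- scci(units)
  } else {
    units <- dplyr::bind_rows(lapply(split(units, units$date), scci))
  }
  units <- dplyr::left_join(units, part$units, by = "unit")
  units <- units[order(units$date, units$unit),
                 c("date", "unit", "urow", "ucol", "coverage", "n_patches",
                   "pd", "sci", "svi", "sri", "scci_raw", "scci_norm",
                   "level", "dominant_ple")]
  structure(list(units = tibble::as_tibble(units), partition = part,
                 unit_size = unit_size, connectivity = connectivity,
                 pool = pool, pd_mode = pd_mode),
            class = "conflict_result")
}

#' @export
print.conflict_result <- function(x, ...) {
  cat(sprintf("<conflict_result> %d units x %d date(s), %g m grid, %d-connectivity, %s pool\n",
              x$partition$n_units, length(unique(x$units$date)),
              x$unit_size, x$connectivity, x$pool))
  print(summarize_conflict(x))
  invisible(x)
}

#' Summaries of a conflict assessment
#'
#' Per-level unit counts and percentages per date, and the cross-tab of
#' level by area-dominant PLE type (percent of all units).
#'
#' @param result a `conflict_result` from [conflict_assess()].
#' @return Tibble: `date`, `level`, `level_name`, `n_units`, `pct`.
#' @export
summarize_conflict <- function(result) {
  u <- result$units
  out <- dplyr::summarise(
    dplyr::group_by(u, .data$date, .data$level),
    n_units = dplyr::n(), .groups = "drop_last")
  out <- dplyr::mutate(out, pct = 100 * .data$n_units / sum(.data$n_units)) |>
    dplyr::ungroup()
  full <- tidyr::expand_grid(date = unique(u$date), level = 1:5)
  out <- dplyr::left_join(full, out, by = c("date", "level")) |>
    dplyr::mutate(n_units = dplyr::coalesce(.data$n_units, 0L),
                  pct = dplyr::coalesce(.data$pct, 0),
                  level_name = conflict_level_names()[.data$level])
  out[, c("date", "level", "level_name", "n_units", "pct")]
}

#' @rdname summarize_conflict
#' @export
conflict_crosstab <- function(result) {
  u <- result$units
  out <- dplyr::summarise(
    dplyr::group_by(u, .data$date, .data$dominant_ple, .data$level),
    n_units = dplyr::n(), .groups = "drop_last")
  dplyr::group_by(out, .data$date) |>
    dplyr::mutate(pct = 100 * .data$n_units / sum(.data$n_units)) |>
    dplyr::ungroup()
}

#' Conflict level raster at unit resolution
#'
#' @param result a `conflict_result`.
#' @param date which date's levels to rasterize (default first).
#' @return A [land_raster()] at the evaluation-unit resolution (one cell
#'   per unit; 0 = no data).
#' @export
level_raster <- function(result, date = NULL) {
  u <- result$units
  date <- date %||% u$date[1]
  u <- u[u$date == date, ]
  nr <- max(result$partition$units$urow)
  nc <- max(result$partition$units$ucol)
  m <- matrix(0L, nr, nc)
  m[cbind(u$urow, u$ucol)] <- u$level
  land_raster(m, cell_size = result$unit_size, nodata = 0L,
              classes = stats::setNames(1:5, conflict_level_names()))
}
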