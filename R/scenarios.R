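#' Built-in simulation scenarios
#'
#' The three planning scenarios with their conversion-allowance matrices
#' (1 = conversion allowed, 0 = not allowed; rows = source class, columns
#' = target class, order cultivated, woodland, grassland, water,
#' construction, unused), the common neighborhood weights
#' (0.56, 0.25, 0.36, 0.43, 1, 0.25), and worked demand vectors (km2):
#'
#' * `ND` (natural development): every class may convert to construction;
#'   construction converts to nothing else.
#' * `CL` (cultivated-land protection): conversion toward cultivated land
#'   is broadly allowed and construction-to-other conversion is blocked;
#'   combined with a basic-farmland restriction mask and a demand vector
#'   that keeps cultivated loss smallest.
#' * `EP` (ecological protection): woodland and grassland rows allow only
#'   themselves; water converts only to itself or unused.
#'
#' @return Named list of three `scenario_spec` objects (fields `name`,
#'   `allowance`, `weights`, `demand_km2`, `restriction`).
#' @examples
#' builtin_scenarios()$ND$allowance
#' @export
builtin_scenarios <- function() {
  cls <- names(lu_classes())
  mk <- function(name, rows, demand) {
    M <- do.call(rbind, rows)
    dimnames(M) <- list(cls, cls)
    structure(list(name = name, allowance = M,
                   weights = stats::setNames(
                     c(0.56, 0.25, 0.36, 0.43, 1, 0.25), cls),
                   demand_km2 = stats::setNames(demand, cls),
                   restriction = NULL),
              class = "scenario_spec")
  }
  list(
    ND = mk("ND", list(
      c(1, 1, 1, 0, 1, 0),
      c(1, 1, 1, 0, 1, 1),
      c(1, 1, 1, 0, 1, 1),
      c(0, 0, 0, 1, 1, 1),
      c(0, 0, 0, 0, 1, 0),
      c(1, 1, 1, 0, 1, 1)),
      c(1453.65, 37.67, 0.15, 225.29, 297.63, 2.24)),
    CL = mk("CL", list(
      c(1, 1, 1, 0, 1, 1),
      c(1, 1, 1, 0, 1, 1),
      c(1, 1, 1, 0, 1, 1),
      c(0, 0, 0, 1, 0, 1),
      c(0, 0, 0, 0, 1, 0),
      c(1, 1, 1, 0, 1, 1)),
      c(1467.38, 33.24, 0.15, 225.51, 288.12, 2.24)),
    EP = mk("EP", list(
      c(1, 1, 1, 0, 1, 0),
      c(0, 1, 0, 0, 0, 0),
      c(0, 0, 1, 0, 0, 0),
      c(0, 0, 0, 1, 0, 1),
      c(0, 1, 1, 0, 1, 0),
      c(1, 1, 1, 0, 1, 1)),
      c(1458.42, 38.13, 0.15, 226.10, 291.59, 2.24))
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> %s\n", x$name))
  print(x$allowance)
  invisible(x)
}

#' Conflict-level transition codes between two dates
#'
#' Per evaluation unit, `code = 10 * level(t1) + level(t2)` with levels in
#' 1..5 (e.g. 41 = strong conflict at t1 ending as weaker conflict at t2).
#' Units missing a level at either date are flagged (`NA` code).
#'
#' @param levels_t1,levels_t2 tibbles with `unit` and `level` columns (as
#'   in a `conflict_result$units` subset), or named integer vectors.
#' @return List: `codes` tibble (`unit`, `level_t1`, `level_t2`, `code`)
#'   and `count_matrix` (5 x 5, rows = t1 level, summing to the number of
#'   units with both levels).
#' @export
transition_codes <- function(levels_t1, levels_t2) {
  as_tbl <- function(x, suff) {
    if (is.data.frame(x)) x[, c("unit", "level")]
    else tibble::tibble(unit = as.integer(names(x)), level = as.integer(x))
  }
  t1 <- as_tbl(levels_t1); t2 <- as_tbl(levels_t2)
  stopifnot(all(t1$level %in% 1:5), all(t2$level %in% 1:5))
  m <- dplyr::full_join(t1, t2, by = "unit", suffix = c("_t1", "_t2"))
  m$code <- ifelse(is.na(m$level_t1) | is.na(m$level_t2), NA_integer_,
                   10L * m$level_t1 + m$level_t2)
  if (anyNA(m$code)) {
    warning(sum(is.na(m$code)), " unit(s) missing a level at one date",
            call. = FALSE)
  }
  ok <- !is.na(m$code)
  cm <- table(factor(m$level_t1[ok], 1:5), factor(m$level_t2[ok], 1:5))
  cm <- matrix(as.integer(cm), 5, 5,
               dimnames = list(t1 = 1:5, t2 = 1:5))
  list(codes = tibble::as_tibble(m[order(m$unit), ]), count_matrix = cm)
}

#' Functional zone names
#' @return Character vector of the five conflict-transition zones.
#' @export
zone_names <- function() {
  c("ecological protection", "ecological conservation",
    "modern agricultural", "development coordination",
    "urban optimization")
}

# The 15 observed transition codes and their zones.
zone_code_table <- function() {
  c(`11` = 1L, `21` = 1L, `41` = 1L,
    `22` = 2L, `32` = 2L, `42` = 2L,
    `13` = 3L, `23` = 3L, `33` = 3L,
    `43` = 4L, `34` = 4L, `44` = 4L,
    `45` = 5L, `54` = 5L, `55` = 5L)
}

#' Assign conflict-transition functional zones
#'
#' Maps the 15 transition codes of the zoning rule table to five functional
#' zones: ecological protection (11, 21, 41), ecological conservation
#' (22, 32, 42), modern agricultural (13, 23, 33), development coordination
#' (43, 34, 44), urban optimization (45, 54, 55). The ten codes the rule
#' table omits are handled by `fallback`: `"end_level"` (default) assigns
#' by the level at t2 (1-2 conservation, 3 modern agricultural,
#' 4 development coordination, 5 urban optimization) and flags the unit;
#' `"unassigned"` leaves them explicitly unassigned.
#'
#' @param codes tibble from [transition_codes()] (`$codes`) with `unit`,
#'   `level_t2`, `code`.
#' @param fallback `"end_level"` or `"unassigned"`.
#' @return List: `zones` tibble (`unit`, `code`, `zone`, `fallback` flag)
#'   and `summary` tibble (`zone`, `n_units`, `pct`, `n_fallback`).
#' @export
assign_zones <- function(codes, fallback = c("end_level", "unassigned")) {
  fallback <- match.arg(fallback)
  if (is.list(codes) && !is.data.frame(codes)) codes <- codes$codes
  tab <- zone_code_table()
  zi <- unname(tab[as.character(codes$code)])
  is_fb <- is.na(zi) & !is.na(codes$code)
  if (fallback == "end_level") {
    fb_zone <- c(2L, 2L, 3L, 4L, 5L)[codes$level_t2]
    zi[is_fb] <- fb_zone[is_fb]
    zone <- ifelse(is.na(zi), NA_character_, zone_names()[zi])
  } else {
    zone <- ifelse(is.na(zi), "unassigned", zone_names()[zi])
    zone[is.na(codes$code)] <- NA_character_
  }
  zones <- tibble::tibble(unit = codes$unit, code = codes$code,
                          zone = zone, fallback = is_fb)
  lvls <- c(zone_names(), if (fallback == "unassigned") "unassigned")
  smry <- dplyr::summarise(
    dplyr::group_by(zones[!is.na(zones$zone), ],
                    zone = factor(.data$zone, levels = lvls)),
    n_units = dplyr::n(), n_fallback = sum(.data$fallback),
    .groups = "drop")
  smry <- tidyr::complete(smry, zone,
                          fill = list(n_units = 0L, n_fallback = 0L))
  smry$pct <- 100 * smry$n_units / sum(smry$n_units)
  smry$zone <- as.character(smry$zone)
  list(zones = zones, summary = smry[, c("zone", "n_units", "pct",
                                         "n_fallback")])
}

#' Zone raster at evaluation-unit resolution
#'
#' @param zones tibble from [assign_zones()] (`$zones`).
#' @param partition the [partition_grid()] used for the conflict grids.
#' @return A [land_raster()] with zone codes 1-5 (0 = unassigned/no data).
#' @export
zone_raster <- function(zones, partition) {
  if (is.list(zones) && !is.data.frame(zones)) zones <- zones$zones
  u <- dplyr::left_join(zones, partition$units, by = "unit")
  nr <- max(partition$units$urow); nc <- max(partition$units$ucol)
  m <- matrix(0L, nr, nc)
  zi <- match(u$zone, zone_names())
  ok <- !is.na(zi)
  m[cbind(u$urow[ok], u$ucol[ok])] <- zi[ok]
  land_raster(m, cell_size = partition$unit_size, nodata = 0L,
              classes = stats::setNames(1:5, zone_names()))
}
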