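#' Mapping from land-use classes to PLE space types
#'
#' The four production-living-ecological space types are living-production
#' (LP: construction), production-ecological (PE: agricultural land that
#' also provides ecological services), ecological-production (EP: woodland
#' and water, ecological land with some production), and ecological (ECO:
#' unused land, mainly other grassland).
#'
#' Two mappings are shipped. `"default"` places grassland in PE, the
#' reading consistent with the primary-class area accounting of the four
#' space types; `"legend"` places grassland in ECO, following the
#' secondary-legend division framework where barren grassland is ecological
#' space. The placement of grassland at the 6-class level is genuinely
#' ambiguous, so both are exposed.
#'
#' @param which `"default"` or `"legend"`.
#' @return Named integer vector: land-use code -> PLE code (see
#'   [ple_classes()]).
#' @examples
#' ple_mapping()
#' @export
ple_mapping <- function(which = c("default", "legend")) {
  which <- match.arg(which)
  p <- ple_classes()
  m <- c(cultivated = p[["PE"]], woodland = p[["EP"]],
         grassland = if (which == "default") p[["PE"]] else p[["ECO"]],
         water = p[["EP"]], construction = p[["LP"]],
         unused = p[["ECO"]])
  stats::setNames(as.integer(m), names(lu_classes()))
}

#' Reclassify a land-use raster into PLE space
#'
#' Pure per-cell recode; nodata is preserved. Every class code present in
#' the raster must be mapped.
#'
#' @param lu categorical [land_raster()] with codes 1-6.
#' @param mapping integer vector from [ple_mapping()] (position = land-use
#'   code).
#' @return A [land_raster()] of PLE codes 1-4.
#' @export
classify_ple <- function(lu, mapping = ple_mapping()) {
  stopifnot(is_land_raster(lu))
  v <- lu$values
  codes <- sort(unique(v[v != lu$nodata & !is.na(v)]))
  unmapped <- setdiff(codes, seq_along(mapping))
  if (length(unmapped)) {
    stop(sprintf("land-use code(s) %s have no PLE mapping",
                 paste(unmapped, collapse = ", ")), call. = FALSE)
  }
  out <- v
  keep <- v != lu$nodata & !is.na(v)
  out[keep] <- mapping[v[keep]]
  land_raster(out, cell_size = lu$cell_size, nodata = lu$nodata,
              classes = ple_classes())
}

#' Per-date class area table
#'
#' Tabulates class areas (km2) for a dated series of categorical rasters.
#' Internally exact cell counts; km2 = count x cell area.
#'
#' @param rasters named list of [land_raster()]s sharing geometry; names
#'   are the dates (e.g. `"2000"`).
#' @param classes class legend to tabulate (defaults to the first raster's).
#' @return Tibble with columns `date`, `class`, `cells`, `area_km2`.
#' @examples
#' r <- land_raster(matrix(c(1L, 1L, 5L, 4L), 2, 2), cell_size = 1000)
#' area_table(list(`2000` = r))
#' @export
area_table <- function(rasters, classes = NULL) {
  if (!length(rasters)) stop("need at least one raster", call. = FALSE)
  if (is.null(names(rasters)) || any(names(rasters) == "")) {
    stop("`rasters` must be a named list (names are dates)", call. = FALSE)
  }
  for (r in rasters[-1]) check_same_geometry(rasters[[1]], r)
  classes <- classes %||% rasters[[1]]$classes
  purrr::imap_dfr(rasters, function(r, date) {
    n <- class_counts(r, classes)
    tibble::tibble(date = date, class = names(n), cells = unname(n),
                   area_km2 = unname(n) * (r$cell_size / 1000)^2)
  })
}

#' Interval changes of an area table
#'
#' For each consecutive date pair and for the first-to-last interval,
#' computes the absolute change (km2, later minus earlier) and the change
#' rate (%, 100 x change / earlier area; `NA` when the earlier area is 0).
#'
#' @param tab tibble from [area_table()] (or any tibble with `date`,
#'   `class`, `area_km2`).
#' @return Tibble with `interval`, `class`, `change_km2`, `rate_pct`.
#' @examples
#' tab <- tibble::tibble(date = c("2000", "2020"), class = "cultivated",
#'                       area_km2 = c(1561.89, 1497.68))
#' area_changes(tab)
#' @export
area_changes <- function(tab) {
  dates <- unique(tab$date)
  if (length(dates) < 2) {
    return(tibble::tibble(interval = character(), class = character(),
                          change_km2 = numeric(), rate_pct = numeric()))
  }
  pairs <- purrr::map(seq_len(length(dates) - 1),
                      ~ c(dates[.x], dates[.x + 1]))
  if (length(dates) > 2) pairs <- c(pairs, list(c(dates[1], dates[length(dates)])))
  purrr::map_dfr(pairs, function(p) {
    a <- tab[tab$date == p[1], c("class", "area_km2")]
    b <- tab[tab$date == p[2], c("class", "area_km2")]
    m <- dplyr::inner_join(a, b, by = "class", suffix = c("_t1", "_t2"))
    tibble::tibble(
      interval = paste(p, collapse = "-"),
      class = m$class,
      change_km2 = m$area_km2_t2 - m$area_km2_t1,
      rate_pct = ifelse(m$area_km2_t1 == 0, NA_real_,
                        100 * (m$area_km2_t2 - m$area_km2_t1) / m$area_km2_t1)
    )
  })
}

#' Per-date class proportions of total area
#'
#' @param tab tibble from [area_table()].
#' @return Tibble with `date`, `class`, `area_km2`, `share_pct`; shares sum
#'   to 100 per date.
#' @export
proportion_table <- function(tab) {
  totals <- tapply(tab$area_km2, tab$date, sum)
  if (any(totals == 0)) stop("zero total area for at least one date",
                             call. = FALSE)
  dplyr::mutate(
    dplyr::group_by(tab[, c("date", "class", "area_km2")], .data$date),
    share_pct = 100 * .data$area_km2 / sum(.data$area_km2)
  ) |>
    dplyr::ungroup()
}

#' Aggregate a land-use area table to PLE space types
#'
#' Sums class areas under a PLE mapping; because reclassification is a pure
#' per-cell recode, this equals the area table of the reclassified raster
#' exactly.
#'
#' @param tab tibble from [area_table()] over the six land-use classes.
#' @param mapping from [ple_mapping()].
#' @return Tibble with `date`, `class` (PLE type), `area_km2` (and `cells`
#'   if present in `tab`).
#' @export
aggregate_to_ple <- function(tab, mapping = ple_mapping()) {
  lu <- lu_classes()
  ple_names <- names(ple_classes())
  missing <- setdiff(unique(tab$class), names(lu))
  if (length(missing)) {
    stop(sprintf("unknown land-use class(es): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  tab$class <- ple_names[mapping[match(tab$class, names(lu))]]
  cols <- intersect(c("cells", "area_km2"), names(tab))
  out <- dplyr::summarise(
    dplyr::group_by(tab, .data$date, .data$class),
    dplyr::across(dplyr::all_of(cols), sum), .groups = "drop"
  )
  out$class <- factor(out$class, levels = ple_names)
  dplyr::arrange(out, .data$date, .data$class) |>
    dplyr::mutate(class = as.character(.data$class))
}
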