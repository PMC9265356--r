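#' Scenario demand ratios relative to natural development
#'
#' Per-class ratios of the cultivated-land-protection and
#' ecological-protection demand changes to the natural-development demand
#' change, derived from the published 2035 demand forecasts (e.g. CL keeps
#' about 69% of the ND cultivated-land loss, EP about 108% of the ND
#' woodland gain). Used to derive scenario demand vectors from the
#' Markov (natural evolution) projection on synthetic landscapes.
#'
#' @return Named list of two 6-vectors (`CL`, `EP`).
#' @export
scenario_demand_ratios <- function() {
  cls <- names(lu_classes())
  list(CL = stats::setNames(c(0.688, 0.223, 1, 1.020, 0.657, 1), cls),
       EP = stats::setNames(c(0.892, 1.081, 1, 1.072, 0.782, 1), cls))
}

#' Derive a scenario demand vector
#'
#' Natural development takes the Markov projection as is; the other
#' scenarios scale each class's projected change from the base state by
#' [scenario_demand_ratios()], then conserve the total by
#' largest-remainder rounding.
#'
#' @param natural_cells Markov-projected demand in cells.
#' @param base_cells class cell counts at the base date.
#' @param scenario `"ND"`, `"CL"` or `"EP"`.
#' @return Integer demand vector summing to `sum(base_cells)`.
#' @export
scenario_demand <- function(natural_cells, base_cells,
                            scenario = c("ND", "CL", "EP")) {
  scenario <- match.arg(scenario)
  total <- sum(base_cells)
  if (scenario == "ND") return(demand_to_cells(natural_cells, total))
  ratio <- scenario_demand_ratios()[[scenario]]
  target <- pmax(0, base_cells + ratio * (natural_cells - base_cells))
  demand_to_cells(target, total)
}

#' Make a demand vector feasible under a conversion-allowance matrix
#'
#' A class no other class may convert into cannot grow, and a class that
#' may not convert out cannot shrink (published scenario tables do contain
#' such combinations: conversions into water are disallowed in all three
#' scenarios while demand still projects water growth). Demand is clamped
#' accordingly and the displaced cells are redistributed over the
#' unconstrained classes by largest-remainder rounding so the total is
#' conserved.
#'
#' @param demand integer demand per class.
#' @param counts current class cell counts.
#' @param allowance 6 x 6 0/1 allowance matrix.
#' @return Adjusted integer demand vector with the same total.
#' @export
feasible_demand <- function(demand, counts, allowance) {
  no_in <- (colSums(allowance) - diag(allowance)) == 0
  no_out <- (rowSums(allowance) - diag(allowance)) == 0
  d <- as.numeric(demand)
  d[no_in] <- pmin(d[no_in], counts[no_in])
  d[no_out] <- pmax(d[no_out], counts[no_out])
  diff <- sum(demand) - sum(d)
  if (diff != 0) {
    adj <- if (diff > 0) !no_in else !no_out
    if (!any(adj)) stop("demand infeasible: no adjustable class", call. = FALSE)
    share <- d[adj] / sum(d[adj])
    d[adj] <- d[adj] + diff * share
  }
  stats::setNames(largest_remainder(pmax(d, 0), sum(demand)), names(demand))
}

#' Default pipeline configuration
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param ... overrides for any field.
#' @return Named list of pipeline settings.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    grid_shape = c(200L, 200L),
    cell_size_m = 30,
    class_proportions = c(0.770, 0.013, 0.001, 0.095, 0.116, 0.005),
    autocorrelation_range = 8,
    driver_count = 13,
    dates = c(t1 = "2005", t2 = "2020", future = "2035"),
    unit_size = 1000,
    connectivity = 8,
    pool = "joint",
    scenarios = c("ND", "CL", "EP"),
    mapping = "default",
    hidden = 12,
    sample_frac = 0.08,
    window = 3,
    max_iter = 300,
    restriction_fraction = 0.05,
    seed = as.integer(seed)
  )
  utils::modifyList(cfg, list(...))
}

#' Run the full conflict-simulation pipeline
#'
#' End-to-end workflow on a synthetic landscape: generate drivers and two
#' dated land-use rasters linked by the configured transition matrix;
#' reclassify to PLE space and build area/change/proportion tables; assess
#' spatial conflict at both dates; calibrate the Markov matrix and the
#' neural-network suitability model; validate the coupled model by
#' reallocating date 1 to date 2 demand and scoring Cohen's kappa against
#' the actual date-2 raster; simulate the future date under each requested
#' scenario; assess future conflict (jointly normalized with the base
#' date); and derive conflict-transition functional zones from the base
#' date to the cultivated-land-protection future (or the first simulated
#' scenario).
#'
#' @param config list from [pipeline_config()], or a path to a YAML file
#'   with the same fields.
#' @param out_dir optional directory; when given, rasters (ESRI ASCII
#'   grid), tables (CSV) and a JSON manifest (seeds, versions, file
#'   hashes) are written there.
#' @return A `ple_pipeline` list with every intermediate result.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (is.character(config)) {
    config <- utils::modifyList(pipeline_config(), yaml::read_yaml(config))
  }
  config$scenarios <- as.character(unlist(config$scenarios))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  cfg <- stage("config", synth_config(
    grid_shape = config$grid_shape, cell_size_m = config$cell_size_m,
    class_proportions = config$class_proportions,
    autocorrelation_range = config$autocorrelation_range,
    driver_count = config$driver_count, seed = config$seed))
  dates <- config$dates

  drivers <- stage("synth", gen_drivers(cfg))
  lu_t1 <- stage("synth", gen_landuse(cfg, drivers))
  lu_t2 <- stage("synth", evolve_landuse(lu_t1, cfg$true_transition, cfg,
                                         drivers, seed = cfg$seed + 3000L))
  lus <- stats::setNames(list(lu_t1, lu_t2), dates[c("t1", "t2")])

  mapping <- ple_mapping(config$mapping)
  ples <- stage("ple", lapply(lus, classify_ple, mapping = mapping))
  areas_lu <- stage("ple", area_table(lus))
  areas_ple <- stage("ple", area_table(ples, classes = ple_classes()))
  changes <- stage("ple", area_changes(areas_lu))
  proportions <- stage("ple", proportion_table(areas_ple))

  conflict_now <- stage("conflict", conflict_assess(
    ples, unit_size = config$unit_size, connectivity = config$connectivity,
    pool = config$pool))

  markov <- stage("calibrate", fit_markov(lu_t1, lu_t2, interval =
    suppressWarnings(diff(as.numeric(dates[c("t1", "t2")])))))
  suit <- stage("calibrate", train_suitability(
    lu_t2, drivers, sample_frac = config$sample_frac,
    hidden = config$hidden, seed = cfg$seed + 4000L))

  # model validation: reallocate date 1 toward actual date-2 demand
  suit_t1 <- stage("validate", train_suitability(
    lu_t1, drivers, sample_frac = config$sample_frac,
    hidden = config$hidden, seed = cfg$seed + 4500L))
  val_run <- stage("validate", allocate_landuse(
    lu_t1, suit_t1, demand_cells = class_counts(lu_t2),
    N = config$window, max_iter = config$max_iter,
    seed = cfg$seed + 5000L))
  kappa <- stage("validate", kappa_coefficient(lu_t2, val_run$raster))

  S_base <- class_counts(lu_t2)
  natural <- stage("demand", project_demand(markov$P, S_base, steps = 1))
  specs <- builtin_scenarios()[config$scenarios]
  sims <- list()
  for (nm in names(specs)) {
    sc <- specs[[nm]]
    demand <- stage("demand", scenario_demand(natural, S_base, nm))
    demand <- stage("demand", feasible_demand(demand, S_base, sc$allowance))
    restriction <- switch(nm,
      EP = gen_restriction(cfg, drivers, config$restriction_fraction,
                           class_for = 4L),
      CL = gen_restriction(cfg, drivers, config$restriction_fraction,
                           class_for = 1L),
      NULL)
    sims[[nm]] <- stage(paste0("simulate-", nm), allocate_landuse(
      lu_t2, suit, demand, allowance = sc$allowance,
      weights = sc$weights, restriction = restriction,
      N = config$window, max_iter = config$max_iter,
      seed = cfg$seed + 6000L + match(nm, names(specs))))
  }

  result <- list(config = config, synth_config = cfg, drivers = drivers,
                 landuse = lus, ple = ples, areas_landuse = areas_lu,
                 areas_ple = areas_ple, changes = changes,
                 proportions = proportions, conflict_now = conflict_now,
                 markov = markov, suitability = suit,
                 validation = list(run = val_run, kappa = kappa),
                 demand_natural = natural, simulations = sims)

  if (length(sims)) {
    fut_ples <- lapply(sims, function(s) classify_ple(s$raster, mapping))
    names(fut_ples) <- paste0(dates[["future"]], "_", names(sims))
    pool_rasters <- c(ples[dates[["t2"]]], fut_ples)
    conflict_future <- stage("conflict-future", conflict_assess(
      pool_rasters, unit_size = config$unit_size,
      connectivity = config$connectivity, pool = config$pool))
    zoning_scenario <- if ("CL" %in% names(sims)) "CL" else names(sims)[1]
    u <- conflict_future$units
    codes <- stage("zoning", transition_codes(
      u[u$date == dates[["t2"]], ],
      u[u$date == paste0(dates[["future"]], "_", zoning_scenario), ]))
    zones <- stage("zoning", assign_zones(codes))
    result$conflict_future <- conflict_future
    result$zoning <- c(codes, zones,
                       list(scenario = zoning_scenario,
                            raster = zone_raster(zones,
                                                 conflict_future$partition)))
  }
  class(result) <- "ple_pipeline"
  if (!is.null(out_dir)) write_pipeline(result, out_dir)
  result
}

#' @export
print.ple_pipeline <- function(x, ...) {
  cat("<ple_pipeline>\n")
  cat(sprintf("  grid %d x %d @ %g m; dates %s -> %s; scenarios: %s\n",
              x$synth_config$grid_shape[1], x$synth_config$grid_shape[2],
              x$synth_config$cell_size_m,
              x$config$dates[["t1"]], x$config$dates[["t2"]],
              paste(names(x$simulations), collapse = ", ")))
  cat(sprintf("  validation kappa: %.4f\n", x$validation$kappa))
  cat(sprintf("  conflict units: %d\n", x$conflict_now$partition$n_units))
  invisible(x)
}

#' Write pipeline artifacts
#'
#' Rasters as ESRI ASCII grids, tables as CSV, and a JSON manifest with
#' the package version, seeds and md5 hashes of every artifact.
#'
#' @param result a `ple_pipeline`.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) {
    utils::write.csv(x, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  for (nm in names(result$landuse)) {
    write_ascii_grid(result$landuse[[nm]],
                     file.path(out_dir, paste0("landuse_", nm, ".asc")))
    write_ascii_grid(result$ple[[nm]],
                     file.path(out_dir, paste0("ple_", nm, ".asc")))
  }
  for (nm in names(result$simulations)) {
    write_ascii_grid(result$simulations[[nm]]$raster,
                     file.path(out_dir, paste0("sim_", nm, ".asc")))
    wr(result$simulations[[nm]]$log, paste0("sim_", nm, "_log"))
  }
  wr(result$areas_landuse, "areas_landuse")
  wr(result$areas_ple, "areas_ple")
  wr(result$changes, "changes")
  wr(result$proportions, "proportions")
  wr(result$conflict_now$units, "conflict_units")
  wr(summarize_conflict(result$conflict_now), "conflict_summary")
  wr(as.data.frame(result$markov$P), "transition_matrix")
  if (!is.null(result$conflict_future)) {
    wr(result$conflict_future$units, "conflict_units_future")
    wr(summarize_conflict(result$conflict_future), "conflict_summary_future")
    wr(result$zoning$zones, "zones")
    wr(result$zoning$summary, "zone_summary")
    write_ascii_grid(result$zoning$raster, file.path(out_dir, "zones.asc"))
  }
  files <- sort(list.files(out_dir, full.names = TRUE))
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    package = "pleconflict",
    version = as.character(utils::packageVersion("pleconflict")),
    seed = result$synth_config$seed,
    dates = as.list(result$config$dates),
    scenarios = names(result$simulations),
    kappa = result$validation$kappa,
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
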