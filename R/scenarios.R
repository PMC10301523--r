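# The six cultivation scenarios (trophic mode x residence time), scenario
# configuration handling and report generation.

# Case table: id, mode, residence time, pinned outlet concentrations from
# the continuous-simulation results (biomass g/L, chlorophyll ug/L), and
# glucose dose (35 g/L for organic-carbon-fed modes).
CASE_TABLE <- data.frame(
  case_id = c("F1", "F2", "H1", "H2", "M1", "M2"),
  mode = c("phototrophic", "phototrophic", "heterotrophic", "heterotrophic",
           "mixotrophic", "mixotrophic"),
  residence_time = c(72, 288, 72, 288, 72, 288),
  biomass_g_l = c(0.04, 0.56, 1.83, 1.81, 1.57, 1.85),
  chl_ug_l = c(4240, 20540, 930, 520, 12970, 3330),
  glucose_dose = c(0, 0, 35, 35, 35, 35),
  stringsAsFactors = FALSE)

#' Scenario specification for one study case
#'
#' The six cases pair a trophic mode with a residence time: F1/F2
#' phototrophic, H1/H2 heterotrophic, M1/M2 mixotrophic, at 72 h (1) and
#' 288 h (2). Each case carries the pinned outlet concentrations of the
#' continuous simulation and the glucose dose (35 g/L for the
#' organic-carbon-fed modes, 0 for phototrophic).
#'
#' @param case_id One of `"F1"`, `"F2"`, `"H1"`, `"H2"`, `"M1"`, `"M2"`.
#' @return An object of class `case_spec` with fields `case_id`, `mode`,
#'   `residence_time`, `override` (list `biomass_g_l`, `chl_ug_l`) and
#'   `glucose_dose`.
#' @examples
#' case_spec("M1")
#' @export
case_spec <- function(case_id) {
  i <- match(case_id, CASE_TABLE$case_id)
  if (is.na(i)) stop("unknown case id '", case_id, "'; expected one of ",
                     paste(CASE_TABLE$case_id, collapse = ", "))
  row <- CASE_TABLE[i, ]
  structure(list(case_id = row$case_id, mode = row$mode,
                 residence_time = row$residence_time,
                 override = list(biomass_g_l = row$biomass_g_l,
                                 chl_ug_l = row$chl_ug_l),
                 glucose_dose = row$glucose_dose),
            class = "case_spec")
}

#' @export
print.case_spec <- function(x, ...) {
  cat(sprintf("Case %s: %s, %g h residence, glucose %g g/L\n",
              x$case_id, x$mode, x$residence_time, x$glucose_dose))
  cat(sprintf("  pinned outlet: %.3g g/L biomass, %.5g ug/L chlorophyll\n",
              x$override$biomass_g_l, x$override$chl_ug_l))
  invisible(x)
}

#' All six case ids in canonical order
#' @return Character vector F1, F2, H1, H2, M1, M2.
#' @export
case_ids <- function() CASE_TABLE$case_id

#' Load a scenario configuration file
#'
#' Reads a YAML (or JSON) scenario configuration with optional sections
#' `farm`, `harvest`, `extraction`, `growth`, `economics` (prices and cost
#' factors) and merges each over the shipped defaults; anything not named
#' keeps its default.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A named list of spec objects: `farm_args`, `harvest`,
#'   `extraction`, `growth_args`, `prices`, `factors`.
#' @export
load_scenario <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.list(cfg)) stop("scenario config must be a mapping")
  known <- c("farm", "harvest", "extraction", "growth", "economics")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(known, collapse = ", "), ")")
  call_with <- function(fun, args, where) {
    ok <- names(formals(fun))
    bad <- setdiff(names(args), ok)
    if (length(bad))
      stop(sprintf("unknown field(s) in config section '%s': %s",
                   where, paste(bad, collapse = ", ")))
    do.call(fun, args)
  }
  list(farm_args = cfg$farm %||% list(),
       harvest = call_with(harvest_spec, cfg$harvest %||% list(), "harvest"),
       extraction = call_with(extraction_spec, cfg$extraction %||% list(),
                              "extraction"),
       growth_args = cfg$growth %||% list(),
       prices = call_with(price_table,
                          (cfg$economics %||% list())$prices %||% list(),
                          "economics/prices"),
       factors = call_with(cost_factors,
                           (cfg$economics %||% list())$factors %||% list(),
                           "economics/factors"))
}

#' Evaluate one study case
#'
#' Runs a cultivation-only evaluation (the basis on which the six cases
#' are compared) or the full chlorophyll process (cultivation through
#' evaporation; the reference design applies it to M1), and attaches the
#' operating-cost report. Deterministic for a fixed configuration.
#'
#' @param case_id Case id (`"F1"` ... `"M2"`) or a [case_spec()].
#' @param scope `"cultivation"` (default) or `"process"`.
#' @param config Optional configuration as returned by [load_scenario()],
#'   or a path to a config file.
#' @param use_override Use the pinned outlet concentrations (default TRUE).
#' @return A list of class `case_result` with `result` (the process or
#'   cultivation evaluation) and `costs` (a `cost_report`).
#' @examples
#' cr <- run_case("M1")
#' cr$costs$total
#' @export
run_case <- function(case_id, scope = c("cultivation", "process"),
                     config = NULL, use_override = TRUE) {
  scope <- match.arg(scope)
  case <- if (inherits(case_id, "case_spec")) case_id else case_spec(case_id)
  if (is.character(config)) config <- load_scenario(config)
  cfg <- config %||% list()
  prices <- cfg$prices %||% price_table()
  factors <- cfg$factors %||% cost_factors()
  harvest <- cfg$harvest %||% harvest_spec()
  extraction <- cfg$extraction %||% extraction_spec()
  growth <- do.call(growth_params,
                    c(list(mode = case$mode), cfg$growth_args %||% list()))
  farm <- do.call(farm_spec,
                  c(list(residence_time = case$residence_time),
                    cfg$farm_args %||% list()))
  result <- if (scope == "process")
    run_process(case, growth, farm, harvest, extraction,
                operating_days = factors$operating_days,
                use_override = use_override)
  else
    run_cultivation(case, growth, farm,
                    operating_days = factors$operating_days,
                    use_override = use_override)
  costs <- rollup(result, prices, factors, case = case)
  structure(list(case = case, scope = scope, result = result, costs = costs),
            class = "case_result")
}

#' @export
print.case_result <- function(x, ...) {
  cat(sprintf("Case %s (%s scope)\n", x$case$case_id, x$scope))
  cat(sprintf("  annual biomass %.6g kg, chlorophyll %.6g kg\n",
              x$result$annual$dry_biomass_kg,
              x$result$annual$chlorophyll_kg))
  cat(sprintf("  annual operating cost %.6g USD\n", x$costs$total))
  invisible(x)
}

#' Compare the six study cases
#'
#' Evaluates annual biomass and chlorophyll production for every case
#' (cultivation basis, pinned outlet concentrations) and ranks them.
#' Ties preserve the canonical case order F1, F2, H1, H2, M1, M2.
#'
#' @param config Optional configuration (see [run_case()]).
#' @return Data frame with one row per case: outlet concentrations, feed
#'   flow, annual productions and rank columns `rank_biomass`,
#'   `rank_chlorophyll` (1 = highest).
#' @examples
#' compare_cases()
#' @export
compare_cases <- function(config = NULL) {
  rows <- lapply(case_ids(), function(id) {
    cr <- run_case(id, scope = "cultivation", config = config)
    data.frame(case_id = id, mode = cr$case$mode,
               residence_time = cr$case$residence_time,
               biomass_g_l = cr$result$conc$biomass_g_l,
               chl_ug_l = cr$result$conc$chl_ug_l,
               feed_flow_l_h = feed_flow_for_residence(cr$case$residence_time),
               annual_biomass_kg = cr$result$annual$dry_biomass_kg,
               annual_chlorophyll_kg = cr$result$annual$chlorophyll_kg)
  })
  out <- do.call(rbind, rows)
  # stable ranking: ties keep canonical order
  out$rank_biomass <- rank(-out$annual_biomass_kg, ties.method = "first")
  out$rank_chlorophyll <- rank(-out$annual_chlorophyll_kg,
                               ties.method = "first")
  out
}

#' Write scenario reports to disk
#'
#' Emits the cost matrix as CSV (stage x category) and the full result as
#' JSON (costs, shares, unit costs, annual production, farm sizing with
#' both the computed and the in-use reactor count, and the calibrated
#' factors in effect).
#'
#' @param case_result A `case_result` from [run_case()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (named `csv`, `json`).
#' @export
emit_report <- function(case_result, dir) {
  stopifnot(inherits(case_result, "case_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- case_result$case$case_id
  csv_path <- file.path(dir, sprintf("%s_costs.csv", id))
  json_path <- file.path(dir, sprintf("%s_report.json", id))
  m <- case_result$costs$matrix
  utils::write.csv(data.frame(stage = rownames(m), m, check.names = FALSE),
                   csv_path, row.names = FALSE, quote = FALSE)
  farm <- if (!is.null(case_result$result$specs))
    case_result$result$specs$farm
  else farm_spec(residence_time = case_result$case$residence_time)
  sz <- size_farm(farm)
  payload <- list(
    case = unclass(case_result$case),
    scope = case_result$scope,
    farm = list(n_units_computed = sz$n_units_computed,
                n_units_used = sz$n_units,
                total_volume_l = sz$total_volume,
                feed_flow_l_h = farm$feed_flow,
                residence_time_h = farm$residence_time),
    factors = unclass(case_result$costs$factors),
    annual_production = case_result$result$annual,
    costs = list(total_usd_yr = case_result$costs$total,
                 matrix = as.data.frame(case_result$costs$matrix),
                 category_shares = as.list(case_result$costs$category_shares),
                 stage_shares = as.list(case_result$costs$stage_shares),
                 unit_costs = as.list(case_result$costs$unit_costs),
                 specific_energy_kwh_kg =
                   case_result$costs$specific_energy_kwh_kg))
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv = csv_path, json = json_path))
}
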