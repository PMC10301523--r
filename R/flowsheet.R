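# Steady-state continuous mass-balance flowsheet: medium preparation,
# photobioreactor farm, chitosan flocculation, filter press, methanol
# extraction, evaporation with solvent recycle. All aqueous streams and
# methanol are treated at 1 kg/L for volume <-> mass conversion.

# Bold's Basal Medium reagents; stock solutions are dosed at 1 mL per L of
# culture, so a stock strength in g/L contributes the same number of g/m^3.
BBM_REAGENTS <- c("KH2PO4", "CaCl2_2H2O", "MgSO4_7H2O", "NaNO3", "K2HPO4",
                  "NaCl", "H3BO3", "ZnSO4_7H2O", "MnCl2_4H2O", "MoO3",
                  "CuSO4_5H2O", "CoNO3_6H2O", "Na2EDTA", "KOH", "FeSO4",
                  "H2SO4")

STREAM_COMPONENTS <- c("water", "dry_biomass", "chlorophyll", "glucose",
                       "chitosan", "acetic_acid", "methanol", BBM_REAGENTS)

#' Bold's Basal Medium dosing
#'
#' Reagent doses in g per m^3 of culture medium: macronutrients dosed
#' directly (mg/L of medium) and stock solutions (microelements, EDTA/KOH,
#' iron/sulfuric acid) dosed at 1 mL of stock per L of medium. Concentrated
#' sulfuric acid is dosed at 1 mL per L of stock (1.84 g/mL).
#'
#' @return Named numeric vector, g per m^3 of medium, over the BBM reagents.
#' @export
bbm_dosing <- function() {
  c(KH2PO4 = 175, CaCl2_2H2O = 25, MgSO4_7H2O = 75, NaNO3 = 250,
    K2HPO4 = 75, NaCl = 25, H3BO3 = 11.42,
    ZnSO4_7H2O = 8.82, MnCl2_4H2O = 1.44, MoO3 = 0.71, CuSO4_5H2O = 1.57,
    CoNO3_6H2O = 0.49, Na2EDTA = 50, KOH = 3.1, FeSO4 = 4.98,
    H2SO4 = 1.84)
}

#' Construct a process stream
#'
#' A stream is a volumetric flow plus component mass flows over a closed
#' component set (water, dry biomass, chlorophyll, glucose, chitosan,
#' acetic acid, methanol, and the itemized BBM reagents).
#'
#' @param vol_flow Volumetric flow, L/h (>= 0).
#' @param ... Named component mass flows, kg/h (e.g. `water = 100`).
#'   Unnamed components default to 0.
#' @param temperature Optional stream temperature, degrees C.
#' @return An object of class `stream`.
#' @examples
#' s <- stream(1000, water = 998, dry_biomass = 1.57, chlorophyll = 0.013)
#' stream_conc(s)   # biomass concentration, g/L
#' @export
stream <- function(vol_flow, ..., temperature = NA_real_) {
  comp <- list(...)
  mass <- setNames(numeric(length(STREAM_COMPONENTS)), STREAM_COMPONENTS)
  if (length(comp)) {
    if (is.null(names(comp)) || any(names(comp) == ""))
      stop("component mass flows must be named")
    bad <- setdiff(names(comp), STREAM_COMPONENTS)
    if (length(bad))
      stop("unknown stream component(s): ", paste(bad, collapse = ", "))
    mass[names(comp)] <- unlist(comp)
  }
  if (!is.numeric(vol_flow) || vol_flow < 0 || !is.finite(vol_flow))
    stop("vol_flow must be a finite non-negative number (L/h)")
  if (any(mass < -1e-12)) stop("component mass flows must be non-negative")
  mass <- pmax(mass, 0)
  structure(list(vol_flow = vol_flow, mass = mass,
                 temperature = temperature),
            class = "stream")
}

stream_from_mass <- function(mass, vol_flow = sum(mass),
                             temperature = NA_real_) {
  mass <- pmax(mass[STREAM_COMPONENTS], 0)
  structure(list(vol_flow = vol_flow, mass = mass,
                 temperature = temperature),
            class = "stream")
}

#' @rdname stream
#' @param s A `stream`.
#' @export
stream_conc <- function(s) {
  if (s$vol_flow == 0) return(0)
  1000 * s$mass[["dry_biomass"]] / s$vol_flow  # g/L
}

total_mass <- function(s) sum(s$mass)

#' @export
print.stream <- function(x, ...) {
  cat(sprintf("Stream: %.4g L/h, %.4g kg/h total", x$vol_flow, total_mass(x)))
  if (is.finite(x$temperature)) cat(sprintf(", %.1f degC", x$temperature))
  cat("\n")
  nz <- x$mass[x$mass > 0]
  if (length(nz)) {
    for (nm in names(nz)) cat(sprintf("  %-12s %12.6g kg/h\n", nm, nz[[nm]]))
  } else cat("  (empty)\n")
  invisible(x)
}

# sum of component masses across a list of streams
mass_of <- function(streams) {
  Reduce(`+`, lapply(streams, function(s) s$mass),
         setNames(numeric(length(STREAM_COMPONENTS)), STREAM_COMPONENTS))
}

assert_balance <- function(ins, outs, unit, tol = 1e-9) {
  min_ <- mass_of(ins); mout <- mass_of(outs)
  scale <- pmax(abs(min_), abs(mout), 1e-12)
  rel <- abs(min_ - mout) / scale
  rel[min_ == 0 & mout == 0] <- 0
  if (any(rel > tol))
    stop(sprintf("mass balance violated in unit '%s' (max rel err %.3g)",
                 unit, max(rel)))
  invisible(TRUE)
}

#' Photobioreactor farm specification
#'
#' Geometry and feed of the 1-ha cultivation farm: the covered area, the
#' footprint and working volume of one airlift unit, the unit count, and
#' the feed flow at the chosen residence time. The default unit count is
#' the equipment-table value 2176, overriding the value computed from the
#' area (ceil(10,000/4.6) = 2174); [size_farm()] reports both.
#'
#' @param total_area Total cultivation area, m^2 (default 10,000 = 1 ha).
#' @param area_per_unit Footprint per reactor, m^2 (default 4.6).
#' @param unit_volume Working volume per reactor, L (default 300).
#' @param n_units Unit count used for costing and power (default 2176);
#'   `NULL` to use the computed value.
#' @param residence_time Residence time, h (72 or 288 in the study cases).
#' @param feed_flow Feed flow, L/h; defaults to the reference scaling
#'   8160 L/h at 72 h (2040 L/h at 288 h).
#' @return An object of class `farm_spec`.
#' @export
farm_spec <- function(total_area = 10000, area_per_unit = 4.6,
                      unit_volume = 300, n_units = 2176,
                      residence_time = 72, feed_flow = NULL) {
  stopifnot(total_area > 0, area_per_unit > 0, unit_volume > 0,
            residence_time > 0)
  if (area_per_unit > total_area)
    stop("area_per_unit exceeds total_area: no reactor fits")
  if (is.null(feed_flow))
    feed_flow <- feed_flow_for_residence(residence_time)
  stopifnot(feed_flow > 0)
  if (!is.null(n_units) && n_units < 1) stop("n_units must be >= 1")
  structure(list(total_area = total_area, area_per_unit = area_per_unit,
                 unit_volume = unit_volume, n_units = n_units,
                 residence_time = residence_time, feed_flow = feed_flow),
            class = "farm_spec")
}

#' Size the photobioreactor farm
#'
#' @param spec A [farm_spec()].
#' @return List with `n_units_computed` (ceiling of area ratio),
#'   `n_units` (the value in use: the override when set), `total_volume`
#'   (L) and `per_unit_throughput` (L/h per reactor).
#' @export
size_farm <- function(spec) {
  stopifnot(inherits(spec, "farm_spec"))
  n_comp <- as.integer(ceiling(spec$total_area / spec$area_per_unit))
  n_used <- if (is.null(spec$n_units)) n_comp else as.integer(spec$n_units)
  list(n_units_computed = n_comp,
       n_units = n_used,
       total_volume = n_used * spec$unit_volume,
       per_unit_throughput = spec$feed_flow / n_used)
}

#' Feed flow at a residence time
#'
#' Scales a reference (residence, flow) pair at constant volume per
#' residence period: `flow = flow_ref * tau_ref / tau`. The study reference
#' is 8160 L/h at 72 h, giving 2040 L/h at 288 h.
#'
#' @param tau Residence time, h (> 0).
#' @param reference Numeric `c(tau_ref, flow_ref)`.
#' @return Feed flow, L/h.
#' @export
feed_flow_for_residence <- function(tau, reference = c(72, 8160)) {
  if (!is.numeric(tau) || any(tau <= 0)) stop("tau must be positive")
  stopifnot(length(reference) == 2L, all(reference > 0))
  reference[2L] * reference[1L] / tau
}

#' Harvest train specification
#'
#' Chitosan flocculation followed by a plate-and-frame filter press.
#' Flocculation recovers 80% of the biomass into a 50 g/L concentrate;
#' the flocculant is 1 g/L chitosan in 20:80 (v/v) acetic acid:water,
#' dosed as litres of solution per m^3 of culture. The filter press
#' recovers 90% of the incoming biomass into a 200 g/L paste, with a
#' configurable water wash.
#'
#' @param floc_recovery Biomass recovery of flocculation, fraction (0, 1].
#' @param floc_outlet_conc Concentrate biomass concentration, g/L.
#' @param chitosan_conc Chitosan in the flocculant solution, g/L.
#' @param acetic_fraction Acetic acid volume fraction of the solution.
#' @param floc_dose Flocculant solution dose, L per m^3 of culture. The
#'   physical default is 10; [calibrate_floc_dose()] provides the
#'   cost-calibrated alternative.
#' @param filter_recovery Biomass recovery of the filter press, fraction.
#' @param filter_outlet_conc Paste concentration, g/L.
#' @param wash_water_ratio Wash water, L per kg of biomass entering the
#'   filter press.
#' @return An object of class `harvest_spec`.
#' @export
harvest_spec <- function(floc_recovery = 0.80, floc_outlet_conc = 50,
                         chitosan_conc = 1, acetic_fraction = 0.20,
                         floc_dose = 10,
                         filter_recovery = 0.90, filter_outlet_conc = 200,
                         wash_water_ratio = 10) {
  stopifnot(floc_recovery > 0, floc_recovery <= 1,
            filter_recovery > 0, filter_recovery <= 1,
            floc_outlet_conc > 0, filter_outlet_conc > 0,
            chitosan_conc >= 0, acetic_fraction >= 0, acetic_fraction <= 1,
            floc_dose >= 0, wash_water_ratio >= 0)
  if (filter_outlet_conc <= floc_outlet_conc)
    stop("outlet concentrations must increase along the harvest train")
  structure(list(floc_recovery = floc_recovery,
                 floc_outlet_conc = floc_outlet_conc,
                 chitosan_conc = chitosan_conc,
                 acetic_fraction = acetic_fraction,
                 floc_dose = floc_dose,
                 filter_recovery = filter_recovery,
                 filter_outlet_conc = filter_outlet_conc,
                 wash_water_ratio = wash_water_ratio),
            class = "harvest_spec")
}

#' Solvent extraction and evaporation specification
#'
#' Paste is mixed with methanol at 2:1 (v/v, biomass paste : solvent) for
#' 5 min, settled at 4 degC for 24 h, and the organic phase is evaporated
#' at 60 degC with the solvent recycled. The extraction efficiency and
#' solvent recovery are design parameters (not reported in the reference
#' design) with defaults 0.90 and 0.95.
#'
#' @param biomass_to_solvent Paste-to-methanol volume ratio (default 2,
#'   i.e. 2:1 paste:solvent).
#' @param mix_time Mixer residence time, min.
#' @param settle_time Settling time, h.
#' @param settle_temp Settling temperature, degC.
#' @param extraction_efficiency Fraction of chlorophyll transferred to the
#'   organic phase, (0, 1].
#' @param evap_temp Evaporation temperature, degC.
#' @param solvent_recovery Fraction of methanol recovered for recycle,
#'   (0, 1].
#' @return An object of class `extraction_spec`.
#' @export
extraction_spec <- function(biomass_to_solvent = 2, mix_time = 5,
                            settle_time = 24, settle_temp = 4,
                            extraction_efficiency = 0.90,
                            evap_temp = 60, solvent_recovery = 0.95) {
  stopifnot(biomass_to_solvent > 0,
            extraction_efficiency >= 0, extraction_efficiency <= 1,
            solvent_recovery >= 0, solvent_recovery <= 1,
            settle_temp > -273.15, evap_temp > -273.15)
  structure(list(biomass_to_solvent = biomass_to_solvent,
                 mix_time = mix_time, settle_time = settle_time,
                 settle_temp = settle_temp,
                 extraction_efficiency = extraction_efficiency,
                 evap_temp = evap_temp, solvent_recovery = solvent_recovery),
            class = "extraction_spec")
}

# Split an inlet stream into a biomass-rich stream at a target concentration
# and a lean stream. Biomass and chlorophyll (intracellular) split by
# `recovery`; water and dissolved species split with the aqueous phase.
split_at_concentration <- function(inlet, recovery, target_conc_g_l, unit) {
  conc_in <- stream_conc(inlet)
  if (conc_in >= target_conc_g_l)
    stop(sprintf("unit '%s': inlet biomass concentration (%.3g g/L) must be below the outlet target (%.3g g/L)",
                 unit, conc_in, target_conc_g_l))
  bio_rich <- recovery * inlet$mass[["dry_biomass"]]
  chl_rich <- recovery * inlet$mass[["chlorophyll"]]
  vol_rich <- 1000 * bio_rich / target_conc_g_l           # L/h at 1 kg/L
  aq_rich <- vol_rich - bio_rich - chl_rich               # kg/h aqueous
  aq_components <- setdiff(STREAM_COMPONENTS,
                           c("dry_biomass", "chlorophyll"))
  aq_total <- sum(inlet$mass[aq_components])
  if (aq_rich > aq_total + 1e-9)
    stop(sprintf("unit '%s': not enough carrier liquid to form the concentrate", unit))
  frac_aq <- if (aq_total > 0) aq_rich / aq_total else 0
  rich <- inlet$mass * frac_aq
  rich[["dry_biomass"]] <- bio_rich
  rich[["chlorophyll"]] <- chl_rich
  lean <- inlet$mass - rich
  list(rich = stream_from_mass(rich, vol_flow = vol_rich),
       lean = stream_from_mass(lean,
                               vol_flow = total_mass(inlet) - vol_rich))
}

#' Chitosan flocculation
#'
#' Doses flocculant solution (chitosan in dilute acetic acid) into the
#' culture and splits it into a biomass concentrate at the target
#' concentration and a supernatant. Intracellular chlorophyll follows the
#' biomass; dissolved species follow the water. Mass is conserved
#' component-wise to 1e-9 relative.
#'
#' @param inlet Culture `stream` (biomass concentration below the
#'   concentrate target).
#' @param spec A [harvest_spec()].
#' @return List of streams `concentrate`, `supernatant`, `floc_solution`.
#' @export
flocculate <- function(inlet, spec = harvest_spec()) {
  stopifnot(inherits(inlet, "stream"), inherits(spec, "harvest_spec"))
  sol_vol <- spec$floc_dose * inlet$vol_flow / 1000       # L/h of solution
  sol <- stream(sol_vol,
                chitosan = sol_vol * spec$chitosan_conc / 1000,
                acetic_acid = sol_vol * spec$acetic_fraction,
                water = sol_vol * (1 - spec$acetic_fraction) -
                  sol_vol * spec$chitosan_conc / 1000)
  mixed <- stream_from_mass(inlet$mass + sol$mass,
                            vol_flow = inlet$vol_flow + sol_vol)
  parts <- split_at_concentration(mixed, spec$floc_recovery,
                                  spec$floc_outlet_conc, "flocculation")
  out <- list(concentrate = parts$rich, supernatant = parts$lean,
              floc_solution = sol)
  assert_balance(list(inlet, sol), list(out$concentrate, out$supernatant),
                 "flocculation")
  out
}

#' Filter press dewatering
#'
#' Concentrates the flocculated biomass to a paste at the target
#' concentration, recovering `filter_recovery` of the incoming biomass;
#' the cake is washed with water which leaves in the filtrate.
#'
#' @param inlet Concentrate `stream` from flocculation.
#' @param spec A [harvest_spec()].
#' @return List of streams `paste`, `filtrate`, `wash_water`.
#' @export
filter_press <- function(inlet, spec = harvest_spec()) {
  stopifnot(inherits(inlet, "stream"), inherits(spec, "harvest_spec"))
  wash_vol <- spec$wash_water_ratio * inlet$mass[["dry_biomass"]]  # L/h
  wash <- stream(wash_vol, water = wash_vol)
  parts <- split_at_concentration(inlet, spec$filter_recovery,
                                  spec$filter_outlet_conc, "filter press")
  # wash water passes straight to the filtrate
  filtrate_mass <- parts$lean$mass + wash$mass
  out <- list(paste = parts$rich,
              filtrate = stream_from_mass(filtrate_mass,
                                          vol_flow = sum(filtrate_mass)),
              wash_water = wash)
  assert_balance(list(inlet, wash), list(out$paste, out$filtrate),
                 "filter press")
  out
}

#' Methanol extraction
#'
#' Mixes the paste with methanol at the configured paste:solvent volume
#' ratio; a fraction `extraction_efficiency` of the chlorophyll transfers
#' to the organic phase, everything else leaves in the spent-biomass
#' stream.
#'
#' @param paste Paste `stream` (non-zero volume).
#' @param spec An [extraction_spec()].
#' @return List with streams `organic`, `spent`, `methanol_feed` and the
#'   scalar `methanol_demand_l_h`.
#' @export
extract_chlorophyll <- function(paste, spec = extraction_spec()) {
  stopifnot(inherits(paste, "stream"), inherits(spec, "extraction_spec"))
  if (paste$vol_flow <= 0) stop("paste stream has zero volume")
  meoh_vol <- paste$vol_flow / spec$biomass_to_solvent    # L/h
  meoh <- stream(meoh_vol, methanol = meoh_vol)           # 1 kg/L
  chl_in <- paste$mass[["chlorophyll"]]
  chl_org <- spec$extraction_efficiency * chl_in
  organic <- stream(meoh_vol + chl_org / 1,
                    methanol = meoh$mass[["methanol"]],
                    chlorophyll = chl_org,
                    temperature = spec$settle_temp)
  spent_mass <- paste$mass
  spent_mass[["chlorophyll"]] <- chl_in - chl_org
  spent <- stream_from_mass(spent_mass, vol_flow = paste$vol_flow)
  assert_balance(list(paste, meoh), list(organic, spent), "extraction")
  list(organic = organic, spent = spent, methanol_feed = meoh,
       methanol_demand_l_h = meoh_vol)
}

#' Evaporation with solvent recycle
#'
#' Boils the methanol off the organic phase; `solvent_recovery` of the
#' methanol is condensed and recycled, the remainder is lost. The
#' chlorophyll (non-volatile) leaves entirely in the product. The steady
#' state make-up requirement equals the loss.
#'
#' @param organic Organic-phase `stream` containing methanol.
#' @param spec An [extraction_spec()].
#' @return List with streams `product`, `recycled`, `loss` and the scalar
#'   `makeup_kg_h`.
#' @export
evaporate <- function(organic, spec = extraction_spec()) {
  stopifnot(inherits(organic, "stream"), inherits(spec, "extraction_spec"))
  meoh <- organic$mass[["methanol"]]
  rec <- spec$solvent_recovery * meoh
  lost <- meoh - rec
  chl <- organic$mass[["chlorophyll"]]
  out <- list(product = stream(chl, chlorophyll = chl,
                               temperature = spec$evap_temp),
              recycled = stream(rec, methanol = rec),
              loss = stream(lost, methanol = lost),
              makeup_kg_h = lost)
  assert_balance(list(organic), out[c("product", "recycled", "loss")],
                 "evaporation")
  out
}

#' Continuous cultivation of one scenario
#'
#' Builds the medium inlet stream (water, itemized BBM salts, glucose for
#' the heterotrophic/mixotrophic modes), evaluates the outlet
#' concentrations at the residence time (the scenario's pinned outlet
#' concentrations override the growth model when present), and annualizes
#' production over the operating year.
#'
#' @param case A [case_spec()].
#' @param growth A [growth_params()]; defaults to the shipped parameters
#'   for the case's mode.
#' @param farm A [farm_spec()]; defaults to the case's residence time.
#' @param operating_days Operating days per year (default 330).
#' @param use_override Use the scenario's pinned outlet concentrations when
#'   available (default TRUE).
#' @return List with streams `inlet`, `outlet`, the `generation` record
#'   (biomass and chlorophyll produced, glucose consumed, kg/h), outlet
#'   concentrations `conc`, `annual` production (kg/yr) and
#'   `operating_hours`.
#' @export
run_cultivation <- function(case, growth = growth_params(case$mode),
                            farm = farm_spec(residence_time = case$residence_time),
                            operating_days = 330, use_override = TRUE) {
  stopifnot(inherits(case, "case_spec"), inherits(growth, "growth_params"),
            inherits(farm, "farm_spec"))
  if (abs(farm$residence_time - case$residence_time) > 1e-9)
    stop(sprintf("farm residence time (%g h) does not match case '%s' (%g h)",
                 farm$residence_time, case$case_id, case$residence_time))
  flow <- farm$feed_flow                                   # L/h
  hours <- operating_days * 24
  dose <- bbm_dosing()                                     # g/m^3
  salts <- dose * flow / 1000 / 1000                       # kg/h per reagent
  glucose <- case$glucose_dose * flow / 1000               # g/L * m3/h = kg/h
  solutes <- sum(salts) + glucose
  inlet_mass <- setNames(numeric(length(STREAM_COMPONENTS)),
                         STREAM_COMPONENTS)
  inlet_mass[BBM_REAGENTS] <- salts
  inlet_mass[["glucose"]] <- glucose
  inlet_mass[["water"]] <- flow - solutes
  inlet <- stream_from_mass(inlet_mass, vol_flow = flow)

  ov <- if (use_override) case$override else NULL
  conc <- concentration_at_residence(growth, case$residence_time, ov)

  bio_out <- conc$biomass_g_l * flow / 1000                # kg/h
  chl_out <- conc$chl_ug_l * flow / 1e9                    # kg/h
  glu_consumed <- growth$glucose_consumption * glucose
  out_mass <- inlet_mass
  out_mass[["dry_biomass"]] <- bio_out
  out_mass[["chlorophyll"]] <- chl_out
  out_mass[["glucose"]] <- glucose - glu_consumed
  # water balances the reactor: biosynthesis draws on glucose/CO2 and water
  out_mass[["water"]] <- inlet_mass[["water"]] +
    (glu_consumed - bio_out - chl_out)
  if (out_mass[["water"]] < 0)
    stop("cultivation water balance went negative; check concentrations")
  outlet <- stream_from_mass(out_mass, vol_flow = flow)

  generation <- c(dry_biomass = bio_out, chlorophyll = chl_out,
                  glucose = -glu_consumed,
                  water = out_mass[["water"]] - inlet_mass[["water"]])
  list(case = case, inlet = inlet, outlet = outlet, generation = generation,
       conc = conc,
       annual = list(dry_biomass_kg = bio_out * hours,
                     chlorophyll_kg = chl_out * hours,
                     medium_m3 = flow * hours / 1000),
       operating_hours = hours)
}

#' Run the full chlorophyll production flowsheet
#'
#' Chains medium preparation and cultivation, chitosan flocculation, the
#' filter press, methanol extraction and evaporation with solvent recycle
#' for one scenario, checks component-wise closure of the global balance,
#' and annualizes production over the operating year.
#'
#' @inheritParams run_cultivation
#' @param harvest A [harvest_spec()].
#' @param extraction An [extraction_spec()].
#' @return An object of class `process_result`: named `streams`, the
#'   cultivation `generation` record, per-unit results, `annual` masses
#'   (reactor biomass/chlorophyll, paste biomass, product chlorophyll,
#'   methanol make-up), the global `balance` data frame and the specs in
#'   use.
#' @examples
#' pr <- run_process(case_spec("M1"))
#' pr$annual$product_chlorophyll_kg
#' @export
run_process <- function(case, growth = growth_params(case$mode),
                        farm = farm_spec(residence_time = case$residence_time),
                        harvest = harvest_spec(),
                        extraction = extraction_spec(),
                        operating_days = 330, use_override = TRUE) {
  cult <- run_cultivation(case, growth, farm, operating_days, use_override)
  fl <- flocculate(cult$outlet, harvest)
  fp <- filter_press(fl$concentrate, harvest)
  ex <- extract_chlorophyll(fp$paste, extraction)
  ev <- evaporate(ex$organic, extraction)
  hours <- cult$operating_hours

  streams <- list(medium = cult$inlet, culture = cult$outlet,
                  floc_solution = fl$floc_solution,
                  concentrate = fl$concentrate,
                  supernatant = fl$supernatant,
                  wash_water = fp$wash_water,
                  paste = fp$paste, filtrate = fp$filtrate,
                  methanol_makeup = stream(ev$makeup_kg_h,
                                           methanol = ev$makeup_kg_h),
                  methanol_recycle = ev$recycled,
                  organic = ex$organic, spent_biomass = ex$spent,
                  solvent_loss = ev$loss, product = ev$product)

  # Global closure: boundary inputs + reactor generation = boundary outputs.
  gen <- setNames(numeric(length(STREAM_COMPONENTS)), STREAM_COMPONENTS)
  gen[names(cult$generation)] <- cult$generation
  ins <- mass_of(streams[c("medium", "floc_solution", "wash_water",
                           "methanol_makeup")]) + gen
  outs <- mass_of(streams[c("supernatant", "filtrate", "spent_biomass",
                            "solvent_loss", "product")])
  scale <- pmax(abs(ins), abs(outs), 1e-12)
  rel <- abs(ins - outs) / scale
  rel[ins == 0 & outs == 0] <- 0
  balance <- data.frame(component = STREAM_COMPONENTS,
                        inputs_kg_h = unname(ins),
                        outputs_kg_h = unname(outs),
                        rel_err = unname(rel), row.names = NULL)
  if (max(rel) > 1e-6)
    stop(sprintf("global mass balance failed to close (max rel err %.3g)",
                 max(rel)))

  structure(list(
    case = case, streams = streams, generation = cult$generation,
    conc = cult$conc,
    annual = list(
      dry_biomass_kg = cult$annual$dry_biomass_kg,
      chlorophyll_kg = cult$annual$chlorophyll_kg,
      paste_biomass_kg = fp$paste$mass[["dry_biomass"]] * hours,
      product_chlorophyll_kg = ev$product$mass[["chlorophyll"]] * hours,
      methanol_makeup_kg = ev$makeup_kg_h * hours,
      wash_water_m3 = fp$wash_water$vol_flow * hours / 1000,
      floc_solution_m3 = fl$floc_solution$vol_flow * hours / 1000,
      medium_m3 = cult$annual$medium_m3),
    balance = balance,
    operating_hours = hours,
    specs = list(growth = growth, farm = farm, harvest = harvest,
                 extraction = extraction)),
    class = "process_result")
}

#' @export
print.process_result <- function(x, ...) {
  cat(sprintf("Process result: case %s (%s, %g h residence)\n",
              x$case$case_id, x$case$mode, x$case$residence_time))
  cat(sprintf("  outlet: %.4g g/L biomass, %.4g ug/L chlorophyll (%s)\n",
              x$conc$biomass_g_l, x$conc$chl_ug_l, x$conc$source))
  a <- x$annual
  cat(sprintf("  annual: %.6g kg biomass, %.6g kg chlorophyll at reactor\n",
              a$dry_biomass_kg, a$chlorophyll_kg))
  cat(sprintf("          %.6g kg biomass in paste, %.6g kg chlorophyll in product\n",
              a$paste_biomass_kg, a$product_chlorophyll_kg))
  cat(sprintf("  balance closure: max rel err %.3g\n", max(x$balance$rel_err)))
  invisible(x)
}
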