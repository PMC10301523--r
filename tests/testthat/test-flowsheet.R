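test_that("farm sizing computes the area-based count and honours the override", {
  fs <- farm_spec()
  sz <- size_farm(fs)
  expect_identical(sz$n_units_computed, 2174L)  # ceil(10000/4.6)
  expect_identical(sz$n_units, 2176L)           # equipment-table override
  expect_equal(sz$total_volume, 2176 * 300)
  computed <- size_farm(farm_spec(n_units = NULL))
  expect_identical(computed$n_units, 2174L)
  one <- size_farm(farm_spec(total_area = 4.6, n_units = NULL))
  expect_identical(one$n_units, 1L)
  expect_error(farm_spec(total_area = 2, area_per_unit = 4.6), "fits")
})

test_that("feed flow scales at constant volume per residence period", {
  expect_equal(feed_flow_for_residence(288), 2040)
  expect_equal(feed_flow_for_residence(72), 8160)
  expect_equal(feed_flow_for_residence(288) * 288,
               feed_flow_for_residence(72) * 72)  # 587,520 L per period
  taus <- c(24, 72, 100, 288)
  expect_equal(unique(feed_flow_for_residence(taus) * taus),
               72 * 8160)
  expect_error(feed_flow_for_residence(0), "positive")
})

test_that("stream construction enforces the closed component set", {
  s <- stream(1000, water = 990, dry_biomass = 10)
  expect_equal(stream_conc(s), 10)  # g/L
  expect_error(stream(100, plutonium = 1), "unknown")
  expect_error(stream(100, water = -5), "non-negative")
  expect_error(stream(-1), "non-negative")
})

test_that("flocculation recovers 80% into a 50 g/L concentrate and conserves mass", {
  inlet <- stream(60000, dry_biomass = 100, water = 59900)
  out <- flocculate(inlet, harvest_spec())
  expect_equal(out$concentrate$mass[["dry_biomass"]], 80)
  expect_equal(out$supernatant$mass[["dry_biomass"]], 20)
  expect_equal(out$concentrate$vol_flow, 80 / 0.050)  # 1600 L/h
  expect_equal(stream_conc(out$concentrate), 50)
  expect_equal(stream_total_mass(out$concentrate) +
                 stream_total_mass(out$supernatant),
               stream_total_mass(inlet) + stream_total_mass(out$floc_solution),
               tolerance = 1e-9)
  # full recovery leaves a biomass-free supernatant
  all_in <- flocculate(inlet, harvest_spec(floc_recovery = 1))
  expect_equal(all_in$supernatant$mass[["dry_biomass"]], 0)
  # precondition: already above the target concentration
  thick <- stream(1000, dry_biomass = 60, water = 940)
  expect_error(flocculate(thick), "below the outlet target")
})

test_that("the filter press yields a 200 g/L paste with 90% recovery", {
  conc <- stream(1600, dry_biomass = 80, water = 1520)
  out <- filter_press(conc, harvest_spec())
  expect_equal(out$paste$mass[["dry_biomass"]], 72)  # 0.9 * 80
  expect_equal(stream_conc(out$paste), 200)
  expect_equal(stream_total_mass(out$paste) + stream_total_mass(out$filtrate),
               stream_total_mass(conc) + stream_total_mass(out$wash_water),
               tolerance = 1e-9)
  # overall culture -> paste recovery is the product of the two recoveries
  expect_equal(0.80 * 0.90, 0.72)
  # no wash, full recovery: the filtrate is pure displaced medium
  dry <- filter_press(conc, harvest_spec(filter_recovery = 1,
                                         wash_water_ratio = 0))
  expect_equal(dry$filtrate$mass[["dry_biomass"]], 0)
  expect_equal(dry$filtrate$mass[["water"]],
               conc$mass[["water"]] - dry$paste$mass[["water"]])
})

test_that("extraction doses methanol at the 2:1 paste:solvent ratio", {
  paste_s <- stream(1000, dry_biomass = 200, water = 799, chlorophyll = 1)
  ex <- extract_chlorophyll(paste_s, extraction_spec())
  expect_equal(ex$methanol_demand_l_h, 500)
  expect_equal(ex$organic$mass[["chlorophyll"]], 0.9)
  expect_equal(ex$spent$mass[["chlorophyll"]], 0.1)
  none <- extract_chlorophyll(paste_s,
                              extraction_spec(extraction_efficiency = 0))
  expect_equal(none$organic$mass[["chlorophyll"]], 0)
  expect_equal(none$spent$mass[["chlorophyll"]], 1)
  expect_error(extract_chlorophyll(stream(0), extraction_spec()), "zero volume")
})

test_that("evaporation recycles solvent and reports the make-up", {
  org <- stream(500.9, methanol = 500, chlorophyll = 0.9)
  ev <- evaporate(org, extraction_spec(solvent_recovery = 0.95))
  expect_equal(ev$makeup_kg_h, 25)  # (1 - 0.95) * 500
  expect_equal(ev$recycled$mass[["methanol"]], 475)
  expect_equal(ev$product$mass[["chlorophyll"]], 0.9)  # non-volatile
  full <- evaporate(org, extraction_spec(solvent_recovery = 1))
  expect_equal(full$makeup_kg_h, 0)
})

test_that("mass is conserved component-wise at every unit over random feeds", {
  set.seed(2024)
  for (i in 1:20) {
    vol <- runif(1, 5000, 20000)
    bio <- runif(1, 0.5, 3) * vol / 1000
    chl <- runif(1, 1000, 20000) * vol / 1e9
    inlet <- stream(vol, dry_biomass = bio, chlorophyll = chl,
                    glucose = runif(1, 0, 2), water = vol - bio - chl - 1)
    hs <- harvest_spec(floc_recovery = runif(1, 0.5, 1),
                       filter_recovery = runif(1, 0.5, 1),
                       floc_dose = runif(1, 0, 50),
                       wash_water_ratio = runif(1, 0, 20))
    fl <- flocculate(inlet, hs)
    fp <- filter_press(fl$concentrate, hs)
    es <- extraction_spec(extraction_efficiency = runif(1),
                          solvent_recovery = runif(1))
    ex <- extract_chlorophyll(fp$paste, es)
    ev <- evaporate(ex$organic, es)
    ins <- stream_total_mass(inlet) + stream_total_mass(fl$floc_solution) +
      stream_total_mass(fp$wash_water) + stream_total_mass(ex$methanol_feed)
    outs <- stream_total_mass(fl$supernatant) + stream_total_mass(fp$filtrate) +
      stream_total_mass(ex$spent) + stream_total_mass(ev$product) +
      stream_total_mass(ev$recycled) + stream_total_mass(ev$loss)
    expect_equal(ins, outs, tolerance = 1e-9)
  }
})

test_that("cultivation annualizes production over the 330-day year", {
  m1 <- run_cultivation(case_spec("M1"))
  expect_equal(m1$annual$dry_biomass_kg, 1.57 * 8160 * 7920 / 1000)
  expect_equal(m1$annual$chlorophyll_kg, 0.01297 * 8160 * 7920 / 1000,
               tolerance = 1e-9)
  expect_equal(m1$operating_hours, 7920)
  # scales to zero with the feed
  tiny <- run_cultivation(case_spec("M1"),
                          farm = farm_spec(residence_time = 72,
                                           feed_flow = 1e-6))
  expect_equal(tiny$annual$dry_biomass_kg, 1.57 * 1e-6 * 7920 / 1000)
  # mismatched residence/flow combination is rejected
  expect_error(run_cultivation(case_spec("M1"),
                               farm = farm_spec(residence_time = 288)),
               "does not match")
})

test_that("the full process closes its global balance and chains recoveries", {
  pr <- run_process(case_spec("M1"))
  expect_lt(max(pr$balance$rel_err), 1e-6)
  # chlorophyll in product = reactor output x floc x filter x extraction
  expect_equal(pr$annual$product_chlorophyll_kg,
               pr$annual$chlorophyll_kg * 0.80 * 0.90 * 0.90,
               tolerance = 1e-9)
  expect_equal(pr$annual$product_chlorophyll_kg, 543.2, tolerance = 1e-3)
  # concentrations increase strictly along the train
  concs <- c(stream_conc(pr$streams$culture),
             stream_conc(pr$streams$concentrate),
             stream_conc(pr$streams$paste))
  expect_equal(concs, c(1.57, 50, 200), tolerance = 0.02)
  expect_true(all(diff(concs) > 0))
  # ideal recoveries pass the reactor output straight through
  ideal <- run_process(case_spec("M1"),
                       harvest = harvest_spec(floc_recovery = 1,
                                              filter_recovery = 1),
                       extraction = extraction_spec(extraction_efficiency = 1))
  expect_equal(ideal$annual$product_chlorophyll_kg,
               ideal$annual$chlorophyll_kg, tolerance = 1e-9)
})

test_that("product chlorophyll is monotone in every recovery fraction", {
  base <- run_process(case_spec("M1"))$annual$product_chlorophyll_kg
  grid <- seq(0.3, 1, by = 0.1)
  for (param in c("floc_recovery", "filter_recovery")) {
    vals <- vapply(grid, function(v) {
      hs <- do.call(harvest_spec, setNames(list(v), param))
      run_process(case_spec("M1"), harvest = hs)$annual$product_chlorophyll_kg
    }, 0)
    expect_true(all(diff(vals) >= 0))
  }
  effs <- vapply(grid, function(v)
    run_process(case_spec("M1"),
                extraction = extraction_spec(extraction_efficiency = v)
                )$annual$product_chlorophyll_kg, 0)
  expect_true(all(diff(effs) >= 0))
  expect_lte(base, max(effs))
})
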