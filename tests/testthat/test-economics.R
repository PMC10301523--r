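test_that("medium unit cost sums doses times prices plus water", {
  # macronutrient salts only, at the printed doses and prices
  macro <- bbm_dosing()[c("KH2PO4", "CaCl2_2H2O", "MgSO4_7H2O", "NaNO3",
                          "K2HPO4", "NaCl", "H3BO3")]
  dosing <- bbm_dosing() * 0
  dosing[names(macro)] <- macro
  mu <- medium_unit_cost(price_table(), glucose_dose_g_l = 0, dosing = dosing)
  expect_equal(as.numeric(mu), 0.599, tolerance = 2e-3)  # salts 0.339 + water 0.260
  # zero dosing leaves only the water charge
  none <- medium_unit_cost(price_table(), dosing = bbm_dosing() * 0)
  expect_equal(as.numeric(none), 0.26)
  # doubling the doses doubles the non-water part exactly
  full <- medium_unit_cost(price_table(), glucose_dose_g_l = 35)
  dbl <- medium_unit_cost(price_table(), glucose_dose_g_l = 70,
                          dosing = bbm_dosing() * 2)
  expect_equal(as.numeric(dbl) - 0.26, 2 * (as.numeric(full) - 0.26),
               tolerance = 1e-12)
  # a dosed reagent without a price is a named error
  pt <- price_table()
  pt$bbm_usd_ton <- pt$bbm_usd_ton[-1]
  expect_error(medium_unit_cost(pt), "KH2PO4")
})

test_that("raw-material cost is linear in feed flow (72 h vs 288 h cases)", {
  m1 <- run_case("M1")
  m2 <- run_case("M2")
  # same medium composition; flow ratio 8160/2040 = 4 exactly
  expect_equal(sum(m1$costs$raw_materials$usd_yr),
               4 * sum(m2$costs$raw_materials$usd_yr), tolerance = 1e-12)
})

test_that("dosing calibration reproduces the reference raw-material spend", {
  s <- calibrate_dosing()
  cr <- run_case("M1", config = list(factors = cost_factors(dose_scale = s)))
  expect_equal(sum(cr$costs$raw_materials$usd_yr), 45874, tolerance = 0.05)
  expect_true(s > 0 && s < 1)
})

test_that("flocculant-dose calibration hits the raw-material share", {
  pr <- run_process(case_spec("M1"))
  d <- calibrate_floc_dose(pr, share = 0.878)
  pr2 <- run_process(case_spec("M1"), harvest = harvest_spec(floc_dose = d))
  rm2 <- annual_raw_material_cost(pr2)
  floc_items <- c("chitosan", "acetic_acid", "flocculant_water")
  share <- sum(rm2$usd_yr[rm2$item %in% floc_items]) / sum(rm2$usd_yr)
  expect_equal(share, 0.878, tolerance = 1e-9)
})

test_that("utility model reproduces the specific energy and power dominance", {
  pr <- run_process(case_spec("M1"))
  ut <- annual_utility_cost(pr)
  expect_equal(attr(ut, "specific_energy_kwh_kg"), 173.21, tolerance = 0.02)
  expect_gte(attr(ut, "pbr_share_of_power"), 0.99)
  # switching the photobioreactor drives off zeroes the cultivation power
  ut0 <- annual_utility_cost(pr, factors = cost_factors(pbr_power_per_unit = 0))
  expect_equal(ut0$usd_yr[ut0$stage == "cultivation"], 0)
})

test_that("labor cost follows operators x rate x hours", {
  expect_equal(annual_labor_cost(), 8327, tolerance = 0.02)
  one <- annual_labor_cost(cost_factors(operators = 1))
  expect_equal(one, 0.37 * 7920)  # 2930.40 USD/yr
  expect_equal(annual_labor_cost(cost_factors(operators = 0)), 0)
})

test_that("factored facility cost lands in the reference band and scales linearly", {
  fac <- annual_facility_cost()
  cult <- fac$usd_yr[fac$stage == "cultivation"]
  expect_gte(cult, 4768000)
  expect_lte(cult, 4770000)
  dbl <- annual_facility_cost(factors = cost_factors(dfc_multiplier = 12))
  expect_equal(attr(dbl, "total"), 2 * attr(fac, "total"))
  # photobioreactors dominate the equipment purchase cost
  eq <- equipment_list()
  pbr_share <- eq$cost_usd[eq$name == "photobioreactor"] / sum(eq$cost_usd)
  expect_identical(floor(100 * pbr_share), 95)
  # stage allocation conserves the total
  expect_equal(sum(fac$usd_yr), attr(fac, "total"))
})

test_that("the cost rollup normalizes shares and allocates consistently", {
  rep1 <- rollup(run_process(case_spec("M1")))
  expect_equal(sum(rep1$category_shares), 1, tolerance = 1e-9)
  expect_equal(sum(rep1$stage_shares), 1, tolerance = 1e-9)
  expect_true(all(rep1$matrix >= 0))
  expect_equal(sum(rep1$matrix), rep1$total)
  # the cultivation stage dominates the operating cost
  expect_gt(rep1$stage_shares[["cultivation"]], 0.70)
  # stage sums per category match the component computations
  expect_equal(sum(rep1$matrix[, "labor"]), rep1$labor_usd_yr)
  expect_equal(sum(rep1$matrix[, "facility"]), attr(rep1$facility, "total"))
  # unit costs: wet basis is the 200 g/L paste (dry / 0.2)
  expect_equal(rep1$unit_costs[["usd_per_kg_wet"]],
               rep1$total / (rep1$total / rep1$unit_costs[["usd_per_kg_dry"]] *
                               0.72 / 0.2),
               tolerance = 1e-9)
})

test_that("zero production makes specific energy infinite with a warning", {
  idle <- list(annual = list(dry_biomass_kg = 0, medium_m3 = 0),
               streams = NULL)
  expect_warning(ut <- annual_utility_cost(
    idle, farm = farm_spec(residence_time = 72)), "infinite")
  expect_equal(attr(ut, "specific_energy_kwh_kg"), Inf)
})
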