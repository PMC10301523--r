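test_that("default coefficients carry the fitted assay constants", {
  cc <- calibration_coefficients()
  expect_equal(cc$od_slope, 0.2983)
  expect_equal(cc$od_intercept, -0.05)
  expect_equal(unname(cc$chl_matrix),
               matrix(c(-8.0962, 16.5169, 27.4405, -12.1688), 2, byrow = TRUE))
  expect_equal(c(cc$chl_a_tol, cc$chl_b_tol), c(0.04696, 0.05776))
  # determinant of the pigment system: (-8.0962)(-12.1688) - (16.5169)(27.4405)
  expect_equal(det(cc$chl_matrix),
               (-8.0962) * (-12.1688) - 16.5169 * 27.4405)
  expect_equal(det(cc$chl_matrix), -354.711, tolerance = 1e-5)
  expect_error(calibration_coefficients(chl_matrix = matrix(c(1, 2, 2, 4), 2)),
               "singular")
})

test_that("OD to dry cell weight evaluates, clips and rejects correctly", {
  expect_equal(as.numeric(od_to_dcw(1.0)), 0.2983 - 0.05)
  root <- 0.05 / 0.2983
  expect_equal(as.numeric(od_to_dcw(root)), 0, tolerance = 1e-12)
  at_zero <- od_to_dcw(0)
  expect_equal(as.numeric(at_zero), 0)
  expect_true(attr(at_zero, "clipped"))
  expect_false(attr(od_to_dcw(1), "clipped"))
  expect_error(od_to_dcw(-0.1), "non-negative")
  expect_error(od_to_dcw(NaN), "finite")
})

test_that("DCW/OD transforms are exact affine inverses on the feasible domain", {
  expect_equal(dcw_to_od(0.2483), 1.0)
  expect_equal(dcw_to_od(0), 0.05 / 0.2983)
  for (x in c(0.1, 1.0, 2.0687)) {
    expect_equal(as.numeric(od_to_dcw(dcw_to_od(x))), x, tolerance = 1e-12)
  }
  ods <- seq(0.2, 3, length.out = 23)
  expect_equal(dcw_to_od(as.numeric(od_to_dcw(ods))), ods, tolerance = 1e-9)
  expect_error(dcw_to_od(-0.2), "non-negative")
})

test_that("chlorophyll quantification matches hand-evaluated pigment sums", {
  z <- chlorophyll_from_absorbance(0, 0)
  expect_equal(unlist(z, use.names = FALSE), c(0, 0, 0))
  w <- chlorophyll_from_absorbance(0.1, 0.1)
  expect_equal(w$chl_a, 0.1 * (-8.0962 + 16.5169), tolerance = 1e-12)
  expect_equal(w$chl_b, 0.1 * (27.4405 - 12.1688), tolerance = 1e-12)
  expect_equal(w$chl_total, w$chl_a + w$chl_b)
  expect_equal(round(c(w$chl_a, w$chl_b, w$chl_total), 5),
               c(0.84207, 1.52717, 2.36924))
  expect_error(chlorophyll_from_absorbance(-0.1, 0.2), "non-negative")
})

test_that("negative raw pigment values are clipped to zero and flagged", {
  v <- chlorophyll_from_absorbance(0.2, 0)
  expect_equal(v$chl_a, 0)            # raw -1.61924
  expect_equal(v$chl_b, 27.4405 * 0.2, tolerance = 1e-12)
  expect_equal(round(v$chl_b, 5), 5.48810)
  cl <- attr(v, "clipped")
  expect_true(cl[1, "chl_a"])
  expect_false(cl[1, "chl_b"])
})

test_that("the pigment system inverts exactly on feasible pairs", {
  ab <- absorbance_from_chlorophyll(0.84207, 1.52717)
  expect_equal(c(ab$a652, ab$a665), c(0.1, 0.1), tolerance = 1e-5)
  z <- absorbance_from_chlorophyll(0, 0)
  expect_equal(c(z$a652, z$a665), c(0, 0))
  # round trip is identity within 1e-9 across a grid of pigment pairs
  grid <- expand.grid(a = c(0.01, 0.5, 2.5, 15.4), b = c(0, 0.4, 5.1))
  ab <- absorbance_from_chlorophyll(grid$a, grid$b)
  back <- chlorophyll_from_absorbance(ab$a652, ab$a665)
  expect_equal(back$chl_a, grid$a, tolerance = 1e-9)
  expect_equal(back$chl_b, grid$b, tolerance = 1e-9)
  expect_error(absorbance_from_chlorophyll(-1, 0), "non-negative")
})

test_that("quantification is linear in the absorbances before clipping", {
  # absorbance pairs chosen inside the region where both pigments are
  # positive, so clipping is inactive and additivity holds exactly
  a1 <- c(0.2, 0.3); a2 <- c(0.3, 0.4)
  f <- function(a, b) {
    v <- chlorophyll_from_absorbance(a, b)
    cbind(v$chl_a, v$chl_b)
  }
  # all values positive here, so clipping is inactive and additivity exact
  expect_equal(f(a1[1] + a1[2], a2[1] + a2[2]),
               f(a1[1], a2[1]) + f(a1[2], a2[2]), tolerance = 1e-12)
})

test_that("assay CSV round-trips through the dialect", {
  d <- data.frame(time_h = c(0, 24, 24), od680 = c(0.17, 0.5, 0.52),
                  a652 = c(0.01, 0.2, 0.21), a665 = c(0.02, 0.3, 0.31))
  p <- withr::local_tempfile(fileext = ".csv")
  write_assay_csv(d, p)
  expect_identical(readLines(p)[1], "time_h,od680,a652,a665")
  back <- read_assay_csv(p)
  expect_equal(back, d)
  # absorbance columns are optional when only biomass is measured
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(d[c("time_h", "od680")], p2, row.names = FALSE)
  expect_named(read_assay_csv(p2), c("time_h", "od680"))
})
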