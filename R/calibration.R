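# Spectrophotometric assay calibrations: OD680 -> dry cell weight and
# two-wavelength (A652/A665) chlorophyll a/b quantification in methanol
# extracts, with exact inverses used by the synthetic-data generator.

#' Calibration coefficients for the spectrophotometric assays
#'
#' Bundles the fitted OD680-to-dry-cell-weight line and the 2x2 coefficient
#' matrix of the two-wavelength chlorophyll a/b quantification in methanol,
#' together with the quantification tolerances reported for each pigment.
#' The defaults are the consortium calibration used throughout the package:
#' \deqn{DCW = 0.2983\,OD_{680} - 0.05 \quad (g/L)}
#' \deqn{Chl\,a = -8.0962\,A_{652} + 16.5169\,A_{665} \quad (\mu g/mL)}
#' \deqn{Chl\,b = 27.4405\,A_{652} - 12.1688\,A_{665} \quad (\mu g/mL)}
#'
#' @param od_slope Slope of the OD680 to DCW line, (g/L) per OD unit.
#' @param od_intercept Intercept of the line, g/L.
#' @param chl_matrix 2x2 numeric matrix of pigment coefficients
#'   (rows: chl_a, chl_b; columns: a652, a665), ug/mL per absorbance unit.
#'   Must be invertible.
#' @param chl_a_tol,chl_b_tol Reported quantification tolerances, ug/mL.
#'   Stored as metadata only; never used in computation.
#' @return An object of class `calibration_coefficients`.
#' @examples
#' cc <- calibration_coefficients()
#' od_to_dcw(1.0, cc)          # 0.2483 g/L
#' chlorophyll_from_absorbance(0.1, 0.1, cc)
#' @export
calibration_coefficients <- function(od_slope = 0.2983,
                                     od_intercept = -0.05,
                                     chl_matrix = matrix(
                                       c(-8.0962, 16.5169,
                                         27.4405, -12.1688),
                                       nrow = 2, byrow = TRUE,
                                       dimnames = list(c("chl_a", "chl_b"),
                                                       c("a652", "a665"))),
                                     chl_a_tol = 0.04696,
                                     chl_b_tol = 0.05776) {
  stopifnot(is.numeric(od_slope), length(od_slope) == 1L, is.finite(od_slope),
            is.numeric(od_intercept), length(od_intercept) == 1L,
            is.finite(od_intercept),
            is.matrix(chl_matrix), all(dim(chl_matrix) == c(2L, 2L)),
            all(is.finite(chl_matrix)))
  if (od_slope == 0) stop("od_slope must be non-zero")
  if (abs(det(chl_matrix)) < .Machine$double.eps * 100)
    stop("chl_matrix is singular: the pigment system cannot be inverted")
  structure(list(od_slope = od_slope,
                 od_intercept = od_intercept,
                 chl_matrix = chl_matrix,
                 chl_a_tol = chl_a_tol,
                 chl_b_tol = chl_b_tol),
            class = "calibration_coefficients")
}

#' @export
print.calibration_coefficients <- function(x, ...) {
  cat("Assay calibration coefficients\n")
  cat(sprintf("  DCW (g/L) = %.4f * OD680 %+.4f\n", x$od_slope, x$od_intercept))
  cat("  Chlorophyll (ug/mL) = M %*% (A652, A665), M =\n")
  print(x$chl_matrix)
  cat(sprintf("  quantification tolerances: chl_a +/- %.5f, chl_b +/- %.5f ug/mL\n",
              x$chl_a_tol, x$chl_b_tol))
  invisible(x)
}

check_absorbance <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop(sprintf("%s must be finite numeric (got non-finite value)", name))
  if (any(x < 0))
    stop(sprintf("%s must be non-negative: absorbance readings below 0 are not physical", name))
  invisible(x)
}

#' Convert optical density at 680 nm to dry cell weight
#'
#' Applies the linear calibration `DCW = slope * OD680 + intercept`. Because
#' the fitted intercept is negative, very low optical densities map to
#' negative raw concentrations; these are clipped to zero (concentrations are
#' physical quantities) and flagged via the `"clipped"` attribute.
#'
#' @param od680 Numeric vector of absorbance readings at 680 nm (>= 0).
#' @param coeffs A [calibration_coefficients()] object.
#' @return Numeric vector of dry-cell-weight concentrations, g/L, with a
#'   logical attribute `"clipped"` marking entries whose raw value was
#'   negative.
#' @seealso [dcw_to_od()] for the exact inverse on the feasible domain.
#' @export
od_to_dcw <- function(od680, coeffs = calibration_coefficients()) {
  check_absorbance(od680, "od680")
  raw <- coeffs$od_slope * od680 + coeffs$od_intercept
  out <- pmax(raw, 0)
  attr(out, "clipped") <- raw < 0
  out
}

#' Convert dry cell weight to the optical density it calibrates to
#'
#' Exact affine inverse of [od_to_dcw()]: `OD680 = (DCW - intercept)/slope`.
#' Zero biomass maps to the root of the calibration line (~0.1676 OD), not to
#' zero absorbance, because the fitted line has a negative intercept.
#'
#' @inheritParams od_to_dcw
#' @param dcw Numeric vector of dry-cell-weight concentrations, g/L (>= 0).
#' @return Numeric vector of OD680 values.
#' @export
dcw_to_od <- function(dcw, coeffs = calibration_coefficients()) {
  if (!is.numeric(dcw) || any(!is.finite(dcw)))
    stop("dcw must be finite numeric")
  if (any(dcw < 0)) stop("dcw must be non-negative")
  (dcw - coeffs$od_intercept) / coeffs$od_slope
}

#' Quantify chlorophyll a and b from methanol-extract absorbances
#'
#' Evaluates the two-wavelength linear quantification at 652 and 665 nm.
#' Raw per-pigment values can be negative for absorbance pairs far from the
#' calibration domain; negatives are clipped to zero and flagged. The total
#' is the sum of the clipped components.
#'
#' @param a652,a665 Numeric vectors of extract absorbances (>= 0), recycled
#'   to a common length.
#' @param coeffs A [calibration_coefficients()] object.
#' @return A data frame with columns `chl_a`, `chl_b`, `chl_total` (ug/mL)
#'   and a logical matrix attribute `"clipped"` (columns chl_a, chl_b).
#' @export
chlorophyll_from_absorbance <- function(a652, a665,
                                        coeffs = calibration_coefficients()) {
  check_absorbance(a652, "a652")
  check_absorbance(a665, "a665")
  n <- max(length(a652), length(a665))
  a652 <- rep_len(a652, n)
  a665 <- rep_len(a665, n)
  raw <- cbind(a652, a665) %*% t(coeffs$chl_matrix)  # n x 2, cols chl_a chl_b
  clipped <- raw < 0
  colnames(clipped) <- c("chl_a", "chl_b")
  chl <- pmax(raw, 0)
  out <- data.frame(chl_a = chl[, 1L], chl_b = chl[, 2L],
                    chl_total = chl[, 1L] + chl[, 2L])
  attr(out, "clipped") <- clipped
  out
}

#' Absorbances implied by a chlorophyll a/b pair
#'
#' Solves the 2x2 pigment system exactly, inverting
#' [chlorophyll_from_absorbance()]. Used by the synthetic-data generator to
#' turn ground-truth pigment concentrations into instrument readings. With
#' the default coefficient matrix both inverse columns are positive, so any
#' non-negative pigment pair is feasible; an infeasible pair (negative
#' implied absorbance under a custom matrix) is an error naming the pair.
#'
#' @param chl_a,chl_b Numeric vectors of pigment concentrations, ug/mL (>= 0),
#'   recycled to a common length.
#' @param coeffs A [calibration_coefficients()] object.
#' @return A data frame with columns `a652`, `a665`.
#' @export
absorbance_from_chlorophyll <- function(chl_a, chl_b,
                                        coeffs = calibration_coefficients()) {
  if (!is.numeric(chl_a) || !is.numeric(chl_b) ||
      any(!is.finite(chl_a)) || any(!is.finite(chl_b)))
    stop("chlorophyll concentrations must be finite numeric")
  if (any(chl_a < 0) || any(chl_b < 0))
    stop("chlorophyll concentrations must be non-negative")
  n <- max(length(chl_a), length(chl_b))
  chl_a <- rep_len(chl_a, n)
  chl_b <- rep_len(chl_b, n)
  inv <- solve(coeffs$chl_matrix)
  ab <- cbind(chl_a, chl_b) %*% t(inv)
  bad <- ab < -1e-12
  if (any(bad)) {
    i <- which(rowSums(bad) > 0L)[1L]
    stop(sprintf(paste0("infeasible pigment pair (chl_a = %.6g, chl_b = %.6g):",
                        " implied absorbance is negative"),
                 chl_a[i], chl_b[i]))
  }
  ab <- pmax(ab, 0)  # absorb -0 / rounding dust
  data.frame(a652 = ab[, 1L], a665 = ab[, 2L])
}

#' Read or write an assay time series CSV
#'
#' The assay dialect has header `time_h,od680,a652,a665` (the absorbance
#' columns may be absent when only biomass is measured). Replicate readings
#' are stored as repeated `time_h` rows.
#'
#' @param path File path.
#' @return `read_assay_csv()` returns a data frame with a numeric `time_h`
#'   column and the available reading columns.
#' @export
read_assay_csv <- function(path) {
  df <- utils::read.csv(path, check.names = TRUE)
  if (!"time_h" %in% names(df)) stop("assay CSV must have a 'time_h' column")
  if (!"od680" %in% names(df)) stop("assay CSV must have an 'od680' column")
  keep <- intersect(c("time_h", "od680", "a652", "a665"), names(df))
  df <- df[keep]
  if (any(!is.finite(df$time_h)) || any(df$time_h < 0))
    stop("time_h must be finite and non-negative")
  df
}

#' @rdname read_assay_csv
#' @param data Data frame with columns `time_h`, `od680` and optionally
#'   `a652`, `a665`.
#' @export
write_assay_csv <- function(data, path) {
  stopifnot(is.data.frame(data), all(c("time_h", "od680") %in% names(data)))
  keep <- intersect(c("time_h", "od680", "a652", "a665"), names(data))
  utils::write.csv(data[keep], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
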