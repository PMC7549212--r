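# Biochemical variables: standard-curve inversion for proline and
# hydrogen peroxide, and the 80%-acetone pigment equations.

#' Assay standard curves
#'
#' Linear absorbance-vs-concentration calibrations used by the assays:
#' proline (acidic ninhydrin, `y = 0.0467 x - 0.0734`, R^2 = 0.963, valid
#' 0--40 ug/ml) and hydrogen peroxide (KI oxidation at 390 nm,
#' `y = 0.0188 x + 0.046`, R^2 = 0.987, valid 0--40 mM).
#'
#' @param slope,intercept,r2 calibration parameters (absorbance per
#'   concentration unit, absorbance offset, fit quality).
#' @param valid_range concentration interval over which the calibration
#'   was established.
#' @return object of class `"standard_curve"`.
#' @export
standard_curve <- function(slope, intercept, r2 = NA_real_,
                           valid_range = c(0, Inf)) {
  if (slope == 0) stop("`slope` must be non-zero")
  if (length(valid_range) != 2L || valid_range[1] >= valid_range[2]) {
    stop("`valid_range` must be a non-empty interval")
  }
  structure(list(slope = slope, intercept = intercept, r2 = r2,
                 valid_range = valid_range),
            class = "standard_curve")
}

#' @rdname standard_curve
#' @export
proline_standard_curve <- function() {
  standard_curve(0.0467, -0.0734, r2 = 0.963, valid_range = c(0, 40))
}

#' @rdname standard_curve
#' @export
h2o2_standard_curve <- function() {
  standard_curve(0.0188, 0.046, r2 = 0.987, valid_range = c(0, 40))
}

#' Invert a standard curve
#'
#' `x = (y - intercept) / slope`.  Concentrations outside the curve's
#' calibrated range are flagged (attribute `out_of_range`), not rejected.
#'
#' @param curve a [standard_curve()].
#' @param absorbance numeric vector of absorbance readings.
#' @return numeric vector of concentrations, with logical attribute
#'   `out_of_range`.
#' @examples
#' invert_standard_curve(proline_standard_curve(), 0.8606)  # 20 ug/ml
#' @export
invert_standard_curve <- function(curve, absorbance) {
  if (!inherits(curve, "standard_curve")) stop("`curve` must be a standard_curve")
  x <- (absorbance - curve$intercept) / curve$slope
  attr(x, "out_of_range") <- x < curve$valid_range[1] | x > curve$valid_range[2]
  x
}

#' Pigment contents from absorbance readings
#'
#' The 80%-acetone equations, applied as printed:
#' `Cha = (12.21 A663 - 2.81 A646) * ml / mg`,
#' `Chb = (20.13 A646 - 2.81 A663) * ml / mg`,
#' `Carot = ((1000 A470 - 3.27 Cha - 104 Chb) / 227) * ml / mg`, where the
#' `Cha`/`Chb` entering the carotenoid formula are the volume/mass-scaled
#' values, and total chlorophyll `TC = Cha + Chb`.  The formulas can go
#' negative for unphysical absorbance combinations; negative results are
#' returned as-is with a warning rather than clamped.
#'
#' @param reading list or one-row data.frame with `A663`, `A646`, `A470`,
#'   `acetone_ml`, `sample_mg`.
#' @return `chlorophyll_a`/`chlorophyll_b`/`carotenoids` return scalars;
#'   see also [total_chlorophyll()].
#' @name pigments
NULL

check_reading <- function(reading) {
  for (f in c("A663", "A646", "A470")) {
    if (!is.null(reading[[f]]) && reading[[f]] < 0) {
      stop(sprintf("absorbance %s must be >= 0", f))
    }
  }
  if (reading$acetone_ml <= 0 || reading$sample_mg <= 0) {
    stop("`acetone_ml` and `sample_mg` must be positive")
  }
  invisible(TRUE)
}

#' @rdname pigments
#' @export
chlorophyll_a <- function(reading) {
  check_reading(reading)
  v <- (12.21 * reading$A663 - 2.81 * reading$A646) *
    reading$acetone_ml / reading$sample_mg
  if (v < 0) warning("negative chlorophyll a content (reported, not clamped)")
  v
}

#' @rdname pigments
#' @export
chlorophyll_b <- function(reading) {
  check_reading(reading)
  v <- (20.13 * reading$A646 - 2.81 * reading$A663) *
    reading$acetone_ml / reading$sample_mg
  if (v < 0) warning("negative chlorophyll b content (reported, not clamped)")
  v
}

#' @rdname pigments
#' @param cha,chb scaled chlorophyll contents computed from the same
#'   reading.
#' @export
carotenoids <- function(reading, cha = chlorophyll_a(reading),
                        chb = chlorophyll_b(reading)) {
  check_reading(reading)
  v <- ((1000 * reading$A470 - 3.27 * cha - 104 * chb) / 227) *
    reading$acetone_ml / reading$sample_mg
  if (v < 0) warning("negative carotenoid content (reported, not clamped)")
  v
}

#' Total chlorophyll content
#'
#' @param cha,chb chlorophyll a and b contents.
#' @return `cha + chb`, exactly.
#' @export
total_chlorophyll <- function(cha, chb) cha + chb

#' Process one biochemical assay reading into trait values
#'
#' Applies the standard-curve inversions and pigment equations to the raw
#' absorbances of one plant.  `P` is the proline concentration converted
#' to mg per g fresh weight through `dilution_proline` (default 0.005:
#' 5 ul extraction buffer per mg fresh tissue, i.e. 2.5 ml extract per
#' 0.5 g, so 1 ug/ml in the supernatant is 0.005 mg/g FW); `HP` uses
#' `dilution_h2o2` (default 10: 5 ml extract per 0.5 g, so 1 mM reads as
#' 10 umol/g FW).
#'
#' @param reading list with `proline_abs`, `h2o2_abs`, `A663`, `A646`,
#'   `A470`, `acetone_ml`, `sample_mg`.
#' @param dilution_proline,dilution_h2o2 unit-conversion factors from
#'   standard-curve concentration to per-gram fresh-weight content.
#' @return list with `P`, `HP`, `Cha`, `Chb`, `TC`, `Carot`.
#' @export
process_biochem_reading <- function(reading, dilution_proline = 0.005,
                                    dilution_h2o2 = 10) {
  p_conc <- invert_standard_curve(proline_standard_curve(), reading$proline_abs)
  h_conc <- invert_standard_curve(h2o2_standard_curve(), reading$h2o2_abs)
  cha <- chlorophyll_a(reading)
  chb <- chlorophyll_b(reading)
  list(
    P = as.numeric(p_conc) * dilution_proline,
    HP = as.numeric(h_conc) * dilution_h2o2,
    Cha = cha,
    Chb = chb,
    TC = total_chlorophyll(cha, chb),
    Carot = carotenoids(reading, cha, chb)
  )
}

#' Process a table of assay readings
#'
#' Vectorised wrapper around [process_biochem_reading()]: takes a
#' data.frame with columns `proline_abs`, `h2o2_abs`, `A663`, `A646`,
#' `A470`, `acetone_ml`, `sample_mg` and appends `P`, `HP`, `Cha`, `Chb`,
#' `TC`, `Carot`.
#'
#' @param readings data.frame of raw readings, one row per sample.
#' @inheritParams process_biochem_reading
#' @return the input with the six trait columns appended.
#' @export
process_biochem <- function(readings, dilution_proline = 0.005,
                            dilution_h2o2 = 10) {
  out <- lapply(seq_len(nrow(readings)), function(i) {
    as.data.frame(process_biochem_reading(as.list(readings[i, ]),
                                          dilution_proline, dilution_h2o2))
  })
  cbind(readings, do.call(rbind, out))
}
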