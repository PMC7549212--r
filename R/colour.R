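# CIELab colour analysis of plant silhouettes.
#
# Conversions follow the sRGB standard: 8-bit sRGB -> linear RGB (sRGB
# transfer function) -> CIE XYZ (sRGB/D65 primaries) -> CIELab with the D65
# white point (Xn = 95.047, Yn = 100, Zn = 108.883).

.XN <- c(X = 95.047, Y = 100.000, Z = 108.883)

.RGB2XYZ <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                     0.2126729, 0.7151522, 0.0721750,
                     0.0193339, 0.1191920, 0.9503041),
                   nrow = 3, byrow = TRUE)

#' Convert 8-bit sRGB colours to CIELab (D65)
#'
#' @param rgb numeric matrix (n x 3) of sRGB intensities in `[0, 255]`,
#'   columns red, green, blue; a length-3 vector is treated as one colour.
#' @return n x 3 matrix with columns `L_star`, `a_star`, `b_star`.
#' @examples
#' srgb_to_lab(c(255, 255, 255))  # white point: L* = 100, a* = b* = 0
#' @export
srgb_to_lab <- function(rgb) {
  if (is.null(dim(rgb))) rgb <- matrix(rgb, ncol = 3, byrow = TRUE)
  if (ncol(rgb) != 3L) stop("`rgb` must have three columns")
  v <- rgb / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(.RGB2XYZ) * 100
  f <- function(t) {
    d <- 6 / 29
    ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
  }
  fx <- f(xyz[, 1] / .XN[1])
  fy <- f(xyz[, 2] / .XN[2])
  fz <- f(xyz[, 3] / .XN[3])
  out <- cbind(L_star = 116 * fy - 16,
               a_star = 500 * (fx - fy),
               b_star = 200 * (fy - fz))
  out
}

#' Convert CIELab (D65) colours to 8-bit sRGB
#'
#' Inverse of [srgb_to_lab()]; out-of-gamut channels are clamped to
#' `[0, 255]`.
#'
#' @param lab numeric matrix (n x 3) with columns L*, a*, b*, or a length-3
#'   vector.
#' @return n x 3 numeric matrix of sRGB intensities in `[0, 255]`
#'   (continuous; round for 8-bit storage).
#' @export
lab_to_srgb <- function(lab) {
  if (is.null(dim(lab))) lab <- matrix(lab, ncol = 3, byrow = TRUE)
  if (ncol(lab) != 3L) stop("`lab` must have three columns")
  d <- 6 / 29
  fy <- (lab[, 1] + 16) / 116
  fx <- fy + lab[, 2] / 500
  fz <- fy - lab[, 3] / 200
  finv <- function(t) ifelse(t > d, t^3, 3 * d^2 * (t - 4 / 29))
  xyz <- cbind(finv(fx) * .XN[1], finv(fy) * .XN[2], finv(fz) * .XN[3]) / 100
  lin <- xyz %*% t(solve(.RGB2XYZ))
  lin <- clamp(lin, 0, 1)
  v <- ifelse(lin <= 0.0031308, 12.92 * lin, 1.055 * lin^(1 / 2.4) - 0.055)
  clamp(v, 0, 1) * 255
}

#' Mean CIELab colour of a plant over its silhouette
#'
#' Converts every foreground pixel of `image` to CIELab (D65) and returns
#' the arithmetic per-plant mean of L*, a*, b*.
#'
#' @param image numeric array H x W x 3, sRGB intensities in `[0, 255]`.
#' @param mask logical H x W matrix marking plant pixels.
#' @param summary `"mean"` (default) or `"median"` per-axis summary.
#' @return named numeric vector `c(L_star, a_star, b_star)`.
#' @export
rgb_to_lab <- function(image, mask, summary = c("mean", "median")) {
  summary <- match.arg(summary)
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("`image` must be an H x W x 3 array")
  }
  if (!identical(dim(image)[1:2], dim(mask))) {
    stop("`image` and `mask` dimensions differ")
  }
  idx <- which(mask)
  if (length(idx) == 0L) stop("empty mask: plant colour is undefined")
  px <- cbind(image[, , 1][idx], image[, , 2][idx], image[, , 3][idx])
  lab <- srgb_to_lab(px)
  fun <- if (summary == "mean") colMeans else function(m) apply(m, 2, stats::median)
  out <- fun(lab)
  names(out) <- c("L_star", "a_star", "b_star")
  out
}

#' Total colour difference between two CIELab colours
#'
#' `deltaE = sqrt((L* - L0*)^2 + (a* - a0*)^2 + (b* - b0*)^2)`, the
#' Euclidean (CIE76) distance in CIELab space.
#'
#' @param sample,reference length-3 numeric vectors (L*, a*, b*).
#' @return non-negative scalar.
#' @examples
#' delta_e(c(53, 4, 0), c(50, 0, 0))  # 3-4-5 triangle: 5
#' @export
delta_e <- function(sample, reference) {
  if (length(sample) != 3L || length(reference) != 3L) {
    stop("`sample` and `reference` must be length-3 Lab triplets")
  }
  if (!all(is.finite(sample)) || !all(is.finite(reference))) {
    stop("Lab triplets must be finite")
  }
  sqrt(sum((as.numeric(sample) - as.numeric(reference))^2))
}

#' Per-plant colour difference against the salt-free control
#'
#' The reference colour of each population is the mean (L*, a*, b*) of its
#' 0 mM control plants; every plant, controls included, is scored against
#' its own population's reference.
#'
#' @param records data.frame with columns `population`, `treatment_mM`,
#'   `L_star`, `a_star`, `b_star` (one row per plant).
#' @param control_mM treatment level defining the reference (default 0).
#' @return numeric vector of deltaE values aligned with `records` rows.
#' @export
cohort_delta_e <- function(records, control_mM = 0) {
  need <- c("population", "treatment_mM", "L_star", "a_star", "b_star")
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    stop("`records` lacks columns: ", paste(missing, collapse = ", "))
  }
  out <- rep(NA_real_, nrow(records))
  for (pop in unique(records$population)) {
    in_pop <- records$population == pop
    ctrl <- in_pop & records$treatment_mM == control_mM
    if (!any(ctrl)) {
      stop(sprintf("population '%s' has no %s mM control plants", pop,
                   format(control_mM)))
    }
    ref <- colMeans(records[ctrl, c("L_star", "a_star", "b_star"), drop = FALSE])
    d <- sweep(as.matrix(records[in_pop, c("L_star", "a_star", "b_star")]),
               2, ref)
    out[in_pop] <- sqrt(rowSums(d^2))
  }
  out
}
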