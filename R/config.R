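# Generator configuration for the synthetic two-population salinity trial.

.TREATMENTS <- c(0, 200, 400, 800, 1000)

#' Treatment response curve
#'
#' A per-treatment mean with a common within-cell standard deviation;
#' the building block of the generator's trait and assay models.
#'
#' @param means numeric vector of means, one per treatment.
#' @param sd common standard deviation (>= 0).
#' @param treatments treatment levels the means belong to (default the
#'   trial's NaCl series 0, 200, 400, 800, 1000 mM).
#' @return list with named `mean` vector and `sd`.
#' @examples
#' response_curve(c(190, 260, 310, 260, 205), sd = 12)
#' @export
response_curve <- function(means, sd, treatments = .TREATMENTS) {
  stopifnot(length(means) == length(treatments), sd >= 0)
  list(mean = stats::setNames(as.numeric(means), as.character(treatments)),
       sd = as.numeric(sd))
}

curve_mean <- function(curve, treatment) {
  unname(curve$mean[[as.character(treatment)]])
}

#' Default trait response curves
#'
#' Treatment-to-(mean, sd) maps for the structural and colour traits of the
#' reference population (C).  Size and complexity traits (height, branch
#' count, projected area, branching depth, fractal dimension) are unimodal
#' with their optimum at 400 mM NaCl; shoot diameter rises monotonically
#' (succulence); the CIELab colour centre drifts monotonically lighter
#' (L* up), less green (a* towards 0) and more yellow (b* up).
#' Pixel units refer to the default 384 x 384 px image.
#'
#' @return named list of response curves.
#' @export
default_response_curves <- function() {
  list(
    H = response_curve(c(190, 260, 310, 260, 205), 12),      # height, px
    B = response_curve(c(7, 10, 13, 9, 6), 1),               # first-order branches
    S = response_curve(c(7, 8, 9, 10, 11), 0.6),             # stem diameter, px
    A = response_curve(c(6000, 11000, 16000, 11500, 7000), 800),  # area, px^2
    FD = response_curve(c(1.72, 1.80, 1.85, 1.79, 1.70), 0.02),
    branching_depth = response_curve(c(2, 3, 4, 3, 2), 0),
    L_star = response_curve(c(63, 66, 69, 73, 77), 1),
    a_star = response_curve(c(-16, -13, -10, -7, -4), 0.8),
    b_star = response_curve(c(26, 29, 32, 36, 40), 1)
  )
}

#' Default biochemical response curves
#'
#' Assay-scale means: proline as supernatant concentration on the
#' 0--40 ug/ml standard-curve scale (rising with salinity), hydrogen
#' peroxide on the 0--40 mM standard-curve scale (rising sharply at extreme
#' salinity), and the three pigment absorbances A663, A646, A470 (falling
#' with salinity as chlorophylls and carotenoids are lost).
#'
#' @return named list of response curves.
#' @export
default_biochem_curves <- function() {
  list(
    proline = response_curve(c(6, 9, 14, 22, 30), 1.5),
    h2o2 = response_curve(c(5, 6, 8, 16, 28), 1.2),
    A663 = response_curve(c(0.62, 0.55, 0.45, 0.33, 0.24), 0.020),
    A646 = response_curve(c(0.30, 0.27, 0.22, 0.17, 0.12), 0.012),
    A470 = response_curve(c(0.45, 0.40, 0.33, 0.26, 0.20), 0.015)
  )
}

#' Default between-population effects
#'
#' Multiplicative effects of the industrial (I) population relative to the
#' natural-brine (C) population, per treatment.  The I population is
#' programmed with higher biomass and complexity, with the advantage
#' smallest near the 400 mM optimum and largest at 1000 mM, so that the
#' populations diverge most under extreme stress; I accumulates more
#' proline, less hydrogen peroxide at high salt, and drifts less in colour
#' (C shows the larger total colour change).
#'
#' @return named list of per-treatment multiplier vectors plus the scalar
#'   per-population `colour_drift` factors and additive `L0_offset`.
#' @export
default_pop_effects <- function() {
  tr <- as.character(.TREATMENTS)
  eff <- function(v) stats::setNames(v, tr)
  list(
    H = eff(c(1.05, 1.04, 1.03, 1.10, 1.18)),
    B = eff(c(1.10, 1.15, 1.08, 1.30, 1.50)),
    S = eff(c(1.05, 1.05, 1.04, 1.15, 1.25)),
    A = eff(c(1.10, 1.08, 1.05, 1.25, 1.50)),
    FD = eff(c(1.00, 1.00, 1.00, 1.02, 1.03)),
    proline = eff(c(1.05, 1.10, 1.20, 1.25, 1.25)),
    h2o2 = eff(c(1.00, 1.00, 0.95, 0.80, 0.80)),
    A663 = eff(c(1.10, 1.08, 1.02, 1.00, 1.00)),
    A646 = eff(c(1.10, 1.08, 1.02, 1.00, 1.00)),
    A470 = eff(c(1.08, 1.05, 1.02, 1.00, 1.00)),
    colour_drift = c(C = 1.15, I = 0.90),
    L0_offset = c(C = 0, I = 1)
  )
}

#' Default RAPD band configuration
#'
#' Three decamer primers; each contributes five monomorphic bands (present
#' in every individual of both populations) and the per-primer polymorphic
#' counts 3 (K01), 6 (M02) and 6 (OPB11), for 15 polymorphic bands in
#' total.  Polymorphic bands are population-differentiated: presence
#' frequency `freq_high` in one population and `freq_low` in the other,
#' alternating, so individuals cluster by population.
#'
#' @return named list describing the band panel.
#' @export
default_band_config <- function() {
  list(
    primers = c("K01", "M02", "OPB11"),
    monomorphic = c(K01 = 5, M02 = 5, OPB11 = 5),
    polymorphic = c(K01 = 3, M02 = 6, OPB11 = 6),
    individuals_per_population = 30,
    freq_high = 0.8,
    freq_low = 0.2
  )
}

#' Configuration for the synthetic salinity trial generator
#'
#' Bundles the full factorial design (2 populations x 5 NaCl treatments x
#' `replicates` plants), the trait and biochemistry response curves, the
#' between-population effects, and the RAPD band panel into one validated
#' object.  All randomness downstream is derived deterministically from
#' `seed` and the design labels, so any plant can be regenerated in
#' isolation.
#'
#' @param seed integer master seed.
#' @param image_size `c(height, width)` in pixels.
#' @param populations population labels (default `c("C", "I")`, a natural
#'   and an industrial saline site).
#' @param treatments NaCl concentrations in mM.
#' @param replicates plants per population x treatment cell.
#' @param response_curves see [default_response_curves()].
#' @param pop_effects see [default_pop_effects()].
#' @param biochem_curves see [default_biochem_curves()].
#' @param band_config see [default_band_config()].
#' @param colour_noise_sd per-pixel Lab noise sd around the plant's colour
#'   centre.
#' @param assay_noise_sd sd of absorbance noise added on top of the
#'   standard-curve mapping.
#' @param margin blank border kept around the plant, px.
#' @return an object of class `"plant_config"`.
#' @examples
#' cfg <- plant_config(seed = 1, replicates = 2)
#' @export
plant_config <- function(seed = 1L,
                         image_size = c(384L, 384L),
                         populations = c("C", "I"),
                         treatments = .TREATMENTS,
                         replicates = 12L,
                         response_curves = default_response_curves(),
                         pop_effects = default_pop_effects(),
                         biochem_curves = default_biochem_curves(),
                         band_config = default_band_config(),
                         colour_noise_sd = 2,
                         assay_noise_sd = 0.005,
                         margin = 10L) {
  stopifnot_scalar_number(seed, "seed")
  if (replicates < 1) stop("`replicates` must be >= 1")
  if (length(image_size) != 2L || any(image_size < 32)) {
    stop("`image_size` must be two pixel counts >= 32")
  }
  for (nm in names(response_curves)) {
    if (response_curves[[nm]]$sd < 0) stop("negative sd in response curve ", nm)
  }
  for (nm in names(biochem_curves)) {
    if (biochem_curves[[nm]]$sd < 0) stop("negative sd in biochem curve ", nm)
  }
  # The optimum of the size/complexity traits must sit at 400 mM when the
  # default treatment set is used (moderate-salinity growth optimum).
  if ("400" %in% names(response_curves$H$mean)) {
    for (nm in intersect(c("H", "A", "branching_depth"), names(response_curves))) {
      m <- response_curves[[nm]]$mean
      if (m[["400"]] < max(m)) {
        stop(sprintf("response curve '%s' must peak at 400 mM", nm))
      }
      ends <- m[names(m) %in% c("0", "1000")]
      if (any(ends >= m[["400"]])) {
        stop(sprintf("response curve '%s' must decline at the 0/1000 mM extremes", nm))
      }
    }
  }
  # Colour centres must drift monotonically with salinity.
  mono <- function(x) all(diff(x) >= 0)
  if (!mono(response_curves$L_star$mean) || !mono(response_curves$a_star$mean) ||
      !mono(response_curves$b_star$mean)) {
    stop("colour centres must drift monotonically: L* up, a* towards 0, b* up")
  }
  if (any(band_config$freq_high > 1) || any(band_config$freq_low < 0)) {
    stop("band frequencies must lie in [0, 1]")
  }
  structure(list(
    seed = as.integer(seed),
    image_size = as.integer(image_size),
    populations = populations,
    treatments = treatments,
    replicates = as.integer(replicates),
    response_curves = response_curves,
    pop_effects = pop_effects,
    biochem_curves = biochem_curves,
    band_config = band_config,
    colour_noise_sd = colour_noise_sd,
    assay_noise_sd = assay_noise_sd,
    margin = as.integer(margin)
  ), class = "plant_config")
}

#' @export
print.plant_config <- function(x, ...) {
  cat("Synthetic salinity-trial configuration\n")
  cat(sprintf("  design: %d population(s) x %d treatment(s) x %d replicate(s) = %d plants\n",
              length(x$populations), length(x$treatments), x$replicates,
              length(x$populations) * length(x$treatments) * x$replicates))
  cat(sprintf("  image: %d x %d px, seed %d\n",
              x$image_size[1], x$image_size[2], x$seed))
  invisible(x)
}

# Trait mean for one design cell: population effect applied to the C curve.
cell_mean <- function(config, trait, population, treatment) {
  m <- curve_mean(config$response_curves[[trait]], treatment)
  eff <- config$pop_effects[[trait]]
  if (!is.null(eff) && population != config$populations[1]) {
    m <- m * unname(eff[[as.character(treatment)]])
  }
  m
}

biochem_cell_mean <- function(config, trait, population, treatment) {
  m <- curve_mean(config$biochem_curves[[trait]], treatment)
  eff <- config$pop_effects[[trait]]
  if (!is.null(eff) && population != config$populations[1]) {
    m <- m * unname(eff[[as.character(treatment)]])
  }
  m
}

# Programmed Lab colour centre of a design cell.  The colour of population
# p at treatment t is base(0) + drift_p * (base(t) - base(0)): C drifts
# further than I, and populations differ slightly at 0 mM (L0 offset).
cell_lab_centre <- function(config, population, treatment) {
  rc <- config$response_curves
  base0 <- c(curve_mean(rc$L_star, config$treatments[1]),
             curve_mean(rc$a_star, config$treatments[1]),
             curve_mean(rc$b_star, config$treatments[1]))
  baset <- c(curve_mean(rc$L_star, treatment),
             curve_mean(rc$a_star, treatment),
             curve_mean(rc$b_star, treatment))
  drift <- config$pop_effects$colour_drift
  dr <- if (!is.null(drift) && population %in% names(drift)) drift[[population]] else 1
  off <- config$pop_effects$L0_offset
  l0 <- if (!is.null(off) && population %in% names(off)) off[[population]] else 0
  centre <- base0 + dr * (baset - base0)
  centre[1] <- centre[1] + l0
  stats::setNames(centre, c("L_star", "a_star", "b_star"))
}

check_labels <- function(config, population, treatment, replicate) {
  if (!population %in% config$populations) {
    stop(sprintf("unknown population '%s'", population))
  }
  if (!treatment %in% config$treatments) {
    stop(sprintf("unknown treatment %s mM", format(treatment)))
  }
  if (replicate < 1 || replicate > config$replicates) {
    stop(sprintf("replicate %d outside 1..%d", replicate, config$replicates))
  }
  invisible(TRUE)
}
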