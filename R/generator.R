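# Synthetic plant generator: stochastic recursive branching silhouettes
# rasterised with known geometry, so every measurement operation can be
# tested against exact ground truth.
#
# Geometry model: a vertical main stem of sampled height and stroke width
# anchored at the image base; first-order laterals leave the stem at sampled
# relative positions and angles (alternating sides) and branch recursively
# (two children per segment per extra depth level) with geometric length and
# width decay.  Lateral extents are capped so that no geodesic path through
# a lateral outruns the main stem and no tip leaves the stem's vertical
# span, which keeps height and branch-count ground truth exact.

# -- segment sampling ---------------------------------------------------------

.LENGTH_DECAY <- 0.70
.WIDTH_DECAY <- 0.92

sample_plant_structure <- function(config, population, treatment) {
  rc <- config$response_curves
  h_img <- config$image_size[1]
  w_img <- config$image_size[2]
  margin <- config$margin

  height <- stats::rnorm(1, cell_mean(config, "H", population, treatment),
                         rc$H$sd)
  height <- max(20, height)
  stem_w <- max(2, stats::rnorm(1, cell_mean(config, "S", population, treatment),
                                rc$S$sd))
  depth <- as.integer(round(curve_mean(rc$branching_depth, treatment)))
  n_branch <- if (depth == 0L) 0L else {
    max(0L, as.integer(round(stats::rnorm(
      1, cell_mean(config, "B", population, treatment), rc$B$sd))))
  }

  if (height + 2 * margin > h_img) {
    stop(sprintf(
      "image height %d px too small for sampled plant height %.0f px (+%d px margin)",
      h_img, height, margin), call. = FALSE)
  }

  base_y <- h_img - margin          # image row of the stem base; rows grow downwards
  top_y <- base_y - height + 1
  x0 <- w_img / 2
  x_min <- margin
  x_max <- w_img - margin

  segs <- list()
  add <- function(x1, y1, x2, y2, w) {
    segs[[length(segs) + 1L]] <<- c(x1, y1, x2, y2, w)
  }
  # main stem: vertical
  add(x0, base_y, x0, top_y, stem_w)

  # Clip a segment length so the tip stays inside the stem's vertical span
  # and the lateral frame; keeps height ground truth exact by construction.
  clip_len <- function(x, y, angle, len) {
    dx <- sin(angle)
    dy <- -cos(angle)     # rows decrease upwards
    # laterals stay a few px below the stem apex so the apex is unambiguous
    if (dy < 0) len <- min(len, (top_y + 3 - y) / dy)
    if (dy > 0) len <- min(len, (base_y - y) / dy)
    if (dx > 0) len <- min(len, (x_max - x) / dx)
    if (dx < 0) len <- min(len, (x_min - x) / dx)
    max(len, 0)
  }

  # Recursive laterals: each segment carries one near-continuation child at
  # its tip and one outward-turning child part-way along, so subtrees fan
  # away from the stem instead of folding back over it.
  grow <- function(x, y, angle, len, w, level) {
    len <- clip_len(x, y, angle, len)
    if (len < 4) return(invisible())
    x2 <- x + sin(angle) * len
    y2 <- y - cos(angle) * len
    add(x, y, x2, y2, w)
    if (level > 1L) {
      out_side <- if (angle >= 0) 1 else -1
      # continuation from the tip
      cont_angle <- clamp(angle + stats::runif(1, -0.12, 0.12), -1.35, 1.35)
      grow(x2, y2, cont_angle, len * .LENGTH_DECAY,
           max(1.5, w * .WIDTH_DECAY), level - 1L)
      # outward child part-way along
      frac <- stats::runif(1, 0.45, 0.65)
      cx <- x + sin(angle) * len * frac
      cy <- y - cos(angle) * len * frac
      child_angle <- clamp(angle + out_side * stats::runif(1, 0.25, 0.45),
                           -1.35, 1.35)
      grow(cx, cy, child_angle, len * .LENGTH_DECAY,
           max(1.5, w * .WIDTH_DECAY), level - 1L)
    }
    invisible()
  }

  if (n_branch > 0L) {
    # alternate sides; within a side, spread attachment heights evenly with
    # jitter and tie the angle to the height (lower branches flatter, upper
    # steeper), so same-side laterals run near-parallel instead of crossing
    sides <- rep(c(-1, 1), length.out = n_branch)
    n_side <- table(factor(sides, levels = c(-1, 1)))
    u <- numeric(n_branch)
    for (s in c(-1, 1)) {
      k_s <- which(sides == s)
      m <- length(k_s)
      if (!m) next
      slots <- seq(0.15, 0.85, length.out = m + 1)
      u[k_s] <- utils::head(slots, m) + stats::runif(m, 0.42, 0.58) * diff(slots)[1]
    }
    for (k in seq_len(n_branch)) {
      ang <- sides[k] * clamp(0.5 + 0.8 * (1 - u[k]) + stats::rnorm(1, 0, 0.06),
                              0.35, 1.25)
      ay <- base_y - u[k] * height
      len <- stats::runif(1, 0.33, 0.55) * height
      grow(x0, ay, ang, len, max(1.5, stem_w * 0.95), depth)
    }
  }

  seg_mat <- do.call(rbind, segs)
  colnames(seg_mat) <- c("x1", "y1", "x2", "y2", "w")
  # horizontal containment check on the stroke envelope
  half <- seg_mat[, "w"] / 2
  xs <- c(seg_mat[, "x1"] - half, seg_mat[, "x1"] + half,
          seg_mat[, "x2"] - half, seg_mat[, "x2"] + half)
  if (min(xs) < 1 || max(xs) > w_img) {
    stop("image width too small for the sampled branching structure",
         call. = FALSE)
  }
  list(segments = seg_mat, height = height, stem_w = stem_w,
       n_branch = n_branch, depth = depth, base_y = base_y, top_y = top_y,
       x0 = x0)
}

# Rasterise thick line segments onto a logical matrix.  A pixel (row, col)
# is foreground when its centre lies within w/2 of a segment.
rasterise_segments <- function(segments, h, w) {
  mask <- matrix(FALSE, h, w)
  for (k in seq_len(nrow(segments))) {
    s <- segments[k, ]
    half <- s[["w"]] / 2
    r0 <- max(1L, floor(min(s[["y1"]], s[["y2"]]) - half))
    r1 <- min(h, ceiling(max(s[["y1"]], s[["y2"]]) + half))
    c0 <- max(1L, floor(min(s[["x1"]], s[["x2"]]) - half))
    c1 <- min(w, ceiling(max(s[["x1"]], s[["x2"]]) + half))
    if (r0 > r1 || c0 > c1) next
    rows <- r0:r1
    cols <- c0:c1
    py <- matrix(rows, length(rows), length(cols))
    px <- matrix(cols, length(rows), length(cols), byrow = TRUE)
    dx <- s[["x2"]] - s[["x1"]]
    dy <- s[["y2"]] - s[["y1"]]
    len2 <- dx * dx + dy * dy
    if (len2 == 0) {
      d2 <- (px - s[["x1"]])^2 + (py - s[["y1"]])^2
    } else {
      t <- clamp(((px - s[["x1"]]) * dx + (py - s[["y1"]]) * dy) / len2, 0, 1)
      d2 <- (px - s[["x1"]] - t * dx)^2 + (py - s[["y1"]] - t * dy)^2
    }
    hit <- d2 <= half^2
    mask[rows, cols] <- mask[rows, cols] | hit
  }
  mask
}

# -- public generator operations ----------------------------------------------

#' Generate one synthetic plant photograph with ground truth
#'
#' Draws a recursive branching silhouette for the given design cell,
#' rasterises it onto a white background, colours the foreground by
#' sampling CIELab values around the cell's programmed colour centre, and
#' returns the exact rasterised mask together with the sampled ground
#' truth.  Deterministic given `(config$seed, population, treatment,
#' replicate)`.
#'
#' @param config a [plant_config()].
#' @param population,treatment,replicate design labels.
#' @return list with components `image` (H x W x 3 sRGB array, 0--255),
#'   `mask` (logical H x W), and `truth` (list: `true_height`,
#'   `true_branch_count`, `true_stem_diameter`, `true_lab_mean`,
#'   `true_area`, `branching_depth`, plus the design labels).
#' @examples
#' p <- generate_plant_image(plant_config(seed = 1), "C", 400, 1)
#' p$truth$true_branch_count
#' @export
generate_plant_image <- function(config, population, treatment, replicate) {
  check_labels(config, population, treatment, replicate)
  seed <- derive_seed(config$seed, "plant", population, treatment, replicate)
  with_seed(seed, {
    str <- sample_plant_structure(config, population, treatment)
    h <- config$image_size[1]
    w <- config$image_size[2]
    mask <- rasterise_segments(str$segments, h, w)

    centre <- cell_lab_centre(config, population, treatment)
    # per-plant colour centre jitter around the cell centre
    plant_centre <- centre + stats::rnorm(3, 0, c(
      config$response_curves$L_star$sd,
      config$response_curves$a_star$sd,
      config$response_curves$b_star$sd))

    img <- array(255, dim = c(h, w, 3))
    idx <- which(mask)
    if (length(idx)) {
      n <- length(idx)
      lab <- cbind(plant_centre[1] + stats::rnorm(n, 0, config$colour_noise_sd),
                   plant_centre[2] + stats::rnorm(n, 0, config$colour_noise_sd),
                   plant_centre[3] + stats::rnorm(n, 0, config$colour_noise_sd))
      rgb <- round(lab_to_srgb(lab))
      img[, , 1][idx] <- rgb[, 1]
      img[, , 2][idx] <- rgb[, 2]
      img[, , 3][idx] <- rgb[, 3]
    }
    truth <- list(
      true_height = str$height,
      true_branch_count = str$n_branch,
      true_stem_diameter = str$stem_w,
      true_lab_mean = plant_centre,
      # the projected ("inside the borderline") area: enclosed background
      # pockets between overlapping shoots belong to the silhouette
      true_area = sum(fill_mask_holes(mask)),
      branching_depth = str$depth,
      population = population,
      treatment_mM = treatment,
      replicate = replicate
    )
    list(image = img, mask = mask, truth = truth)
  })
}

#' Generate the full factorial cohort of synthetic plants
#'
#' One plant per (population, treatment, replicate) combination; the
#' default configuration yields the complete 2 x 5 x 12 = 120-plant trial.
#'
#' @param config a [plant_config()].
#' @return list of [generate_plant_image()] results, in population >
#'   treatment > replicate order.
#' @export
generate_cohort <- function(config) {
  out <- vector("list",
                length(config$populations) * length(config$treatments) *
                  config$replicates)
  k <- 0L
  for (pop in config$populations) {
    for (tr in config$treatments) {
      for (rep in seq_len(config$replicates)) {
        k <- k + 1L
        out[[k]] <- generate_plant_image(config, pop, tr, rep)
      }
    }
  }
  out
}

#' Generate one plant's biochemical assay readings
#'
#' Draws true proline and hydrogen-peroxide concentrations from the
#' configured response curves, maps them through the assay standard curves
#' (proline: `y = 0.0467 x - 0.0734`; H2O2: `y = 0.0188 x + 0.046`) with
#' additive absorbance noise, and draws pigment absorbances A663, A646,
#' A470 declining with salinity.  Negative sampled absorbances are clamped
#' to zero with a warning.
#'
#' @inheritParams generate_plant_image
#' @param acetone_ml,sample_mg extraction volume and fresh mass recorded
#'   with the pigment reading.
#' @return list with the raw absorbances (`proline_abs`, `h2o2_abs`,
#'   `A663`, `A646`, `A470`), the bookkeeping fields `acetone_ml` and
#'   `sample_mg`, and the true sampled concentrations (`true_proline`,
#'   `true_h2o2`) for recovery tests.
#' @export
generate_biochem <- function(config, population, treatment, replicate,
                             acetone_ml = 5, sample_mg = 100) {
  check_labels(config, population, treatment, replicate)
  seed <- derive_seed(config$seed, "biochem", population, treatment, replicate)
  with_seed(seed, {
    bc <- config$biochem_curves
    draw <- function(trait) {
      max(0, stats::rnorm(1, biochem_cell_mean(config, trait, population, treatment),
                          bc[[trait]]$sd))
    }
    true_p <- draw("proline")
    true_h <- draw("h2o2")
    pc <- proline_standard_curve()
    hc <- h2o2_standard_curve()
    noise <- function() stats::rnorm(1, 0, config$assay_noise_sd)
    abs_p <- pc$slope * true_p + pc$intercept + noise()
    abs_h <- hc$slope * true_h + hc$intercept + noise()
    a663 <- draw("A663") + noise()
    a646 <- draw("A646") + noise()
    a470 <- draw("A470") + noise()
    vals <- c(proline_abs = abs_p, h2o2_abs = abs_h,
              A663 = a663, A646 = a646, A470 = a470)
    if (any(vals < 0)) {
      warning(sprintf("negative sampled absorbance clamped to 0 (%s)",
                      paste(names(vals)[vals < 0], collapse = ", ")))
      vals[vals < 0] <- 0
    }
    c(as.list(vals),
      list(acetone_ml = acetone_ml, sample_mg = sample_mg,
           true_proline = true_p, true_h2o2 = true_h,
           population = population, treatment_mM = treatment,
           replicate = replicate))
  })
}

#' Generate a RAPD band presence/absence matrix
#'
#' Monomorphic bands are present in every individual of both populations;
#' polymorphic bands are sampled Bernoulli with population-specific
#' frequencies (alternating which population carries the high frequency),
#' giving the population-structured polymorphism the clustering stage
#' expects.
#'
#' @param config a [plant_config()]; only `seed` and `band_config` are used.
#' @return integer matrix of 0/1 with individual IDs (`C1`..`I30`) as row
#'   names, band IDs (`<primer>_<n>`) as column names, and attributes
#'   `population` (per row) and `primer` (per column).
#' @export
generate_band_matrix <- function(config) {
  bc <- config$band_config
  if (any(bc$monomorphic + bc$polymorphic < 1)) {
    stop("each primer needs at least one band")
  }
  if (bc$freq_high <= 0 || bc$freq_high >= 1 || bc$freq_low <= 0 ||
      bc$freq_low >= 1) {
    stop("polymorphic band frequencies must lie strictly inside (0, 1)")
  }
  pops <- config$populations
  n_ind <- bc$individuals_per_population
  ind_pop <- rep(pops, each = n_ind)
  ids <- paste0(ind_pop, rep(seq_len(n_ind), times = length(pops)))

  band_primer <- character(0)
  band_name <- character(0)
  band_type <- character(0)
  for (pr in bc$primers) {
    n_m <- bc$monomorphic[[pr]]
    n_p <- bc$polymorphic[[pr]]
    band_primer <- c(band_primer, rep(pr, n_m + n_p))
    band_name <- c(band_name, paste0(pr, "_", seq_len(n_m + n_p)))
    band_type <- c(band_type, rep(c("mono", "poly"), c(n_m, n_p)))
  }

  seed <- derive_seed(config$seed, "rapd")
  mat <- with_seed(seed, {
    m <- matrix(0L, nrow = length(ids), ncol = length(band_name),
                dimnames = list(ids, band_name))
    poly_i <- 0L
    for (j in seq_along(band_name)) {
      if (band_type[j] == "mono") {
        m[, j] <- 1L
      } else {
        poly_i <- poly_i + 1L
        # alternate which population carries the high frequency
        freqs <- if (poly_i %% 2L == 1L) {
          c(bc$freq_high, bc$freq_low)
        } else {
          c(bc$freq_low, bc$freq_high)
        }
        for (p in seq_along(pops)) {
          rows <- which(ind_pop == pops[p])
          f <- freqs[((p - 1L) %% 2L) + 1L]
          m[rows, j] <- stats::rbinom(length(rows), 1L, f)
        }
      }
    }
    m
  })
  attr(mat, "population") <- ind_pop
  attr(mat, "primer") <- band_primer
  mat
}

#' Draw per-plant trait records directly from the programmed curves
#'
#' Statistical twin of the full image pipeline: samples all twelve
#' analysis variables (A, B, S, H, P, HP, Cha, Chb, TC, Carot, FD, deltaE)
#' per plant from the configured response curves without rasterising or
#' measuring images.  Useful for repeated-run statistical checks of the
#' multivariate layer where the imaging stages would dominate the cost;
#' it shares the curves, population effects and assay model with the
#' image path but not its measurement noise.
#'
#' @param config a [plant_config()].
#' @return data.frame, one row per plant, with design labels and the 12
#'   analysis variables.
#' @export
simulate_trait_records <- function(config) {
  rows <- list()
  k <- 0L
  rc <- config$response_curves
  for (pop in config$populations) {
    for (tr in config$treatments) {
      for (rep in seq_len(config$replicates)) {
        k <- k + 1L
        seed <- derive_seed(config$seed, "traits", pop, tr, rep)
        rows[[k]] <- with_seed(seed, {
          draw <- function(trait) {
            stats::rnorm(1, cell_mean(config, trait, pop, tr), rc[[trait]]$sd)
          }
          centre <- cell_lab_centre(config, pop, tr)
          lab <- centre + stats::rnorm(3, 0, c(rc$L_star$sd, rc$a_star$sd,
                                               rc$b_star$sd))
          bio <- generate_biochem(config, pop, tr, rep)
          rec <- process_biochem_reading(bio)
          data.frame(
            id = paste0(pop, "_", tr, "_", rep),
            population = pop, treatment_mM = tr, replicate = rep,
            A = max(0, draw("A")), B = max(0, round(draw("B"))),
            S = max(0, draw("S")), H = max(0, draw("H")),
            P = rec$P, HP = rec$HP, Cha = rec$Cha, Chb = rec$Chb,
            TC = rec$TC, Carot = rec$Carot,
            FD = clamp(draw("FD"), 1, 2),
            L_star = lab[1], a_star = lab[2], b_star = lab[3],
            stringsAsFactors = FALSE
          )
        })
      }
    }
  }
  out <- do.call(rbind, rows)
  out$deltaE <- cohort_delta_e(out)
  rownames(out) <- NULL
  out
}
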