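# Reusable measurement campaigns over the synthetic generator: the
# branching-complexity sweep and the optimal-growth calibration sample.

# Configuration holding a single treatment cell with an explicit branching
# depth, inheriting that treatment's default curves and population effects.
single_depth_config <- function(seed, depth, treatment = 400,
                                replicates = 20L) {
  key <- as.character(treatment)
  pick <- function(curves) {
    lapply(curves, function(cv) {
      response_curve(cv$mean[[key]], cv$sd, treatments = treatment)
    })
  }
  rc <- pick(default_response_curves())
  rc$branching_depth <- response_curve(depth, 0, treatments = treatment)
  pe <- lapply(default_pop_effects(), function(v) {
    if (!is.null(names(v)) && key %in% names(v)) v[key] else v
  })
  plant_config(seed = seed, treatments = treatment, replicates = replicates,
               response_curves = rc, biochem_curves = pick(default_biochem_curves()),
               pop_effects = pe)
}

# Segment a generated image and return the fractal dimension of its
# filled silhouette (the pipeline's FD measurement).
fd_of_image <- function(image) {
  mask <- withCallingHandlers(
    segment(to_greyscale(image), fill_holes = FALSE),
    warning = function(w) invokeRestart("muffleWarning"))
  fractal_dimension(fill_mask_holes(mask))$fd
}

#' Fractal-dimension sweep across branching complexity
#'
#' Generates silhouettes across the full branching-depth range (both
#' populations, fixed per-depth configurations at the 400 mM geometry)
#' and measures each one's box-counting dimension through the standard
#' segmentation path.  With the defaults this is a 200-silhouette sweep
#' (5 depths x 2 populations x 20 replicates) used to check that FD stays
#' inside [1, 2] and grows with programmed branching complexity.
#'
#' @param seed integer seed.
#' @param depths branching depths to span (default 0:4).
#' @param replicates plants per population at each depth (default 20).
#' @return data.frame with columns `depth`, `population`, `replicate`,
#'   `fd`.
#' @export
fd_complexity_sweep <- function(seed, depths = 0:4, replicates = 20L) {
  rows <- list()
  k <- 0L
  for (d in depths) {
    cfg <- single_depth_config(derive_seed(seed, "fd-sweep", d), d,
                               replicates = replicates)
    for (pop in cfg$populations) {
      for (r in seq_len(replicates)) {
        k <- k + 1L
        p <- generate_plant_image(cfg, pop, 400, r)
        rows[[k]] <- data.frame(depth = d, population = pop, replicate = r,
                                fd = fd_of_image(p$image))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fractal dimension at the optimal-growth treatment
#'
#' Generates the default cohort's 400 mM cell (both populations,
#' `replicates` plants each) and measures each silhouette's box-counting
#' dimension; the generator is calibrated so the mean sits at the
#' moderate-salinity complexity peak (about 1.85).
#'
#' @param seed integer seed.
#' @param replicates plants per population (default 12, the trial's cell
#'   size).
#' @return numeric vector of per-plant FD values.
#' @export
fd_optimum_sample <- function(seed, replicates = 12L) {
  cfg <- plant_config(seed = seed, replicates = replicates)
  fds <- numeric(0)
  for (pop in cfg$populations) {
    for (r in seq_len(replicates)) {
      p <- generate_plant_image(cfg, pop, 400, r)
      fds <- c(fds, fd_of_image(p$image))
    }
  }
  fds
}
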