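# Orchestration: generate -> measure -> score -> analyse in one
# reproducible run, plus measurement of user-supplied photographs.

#' Measure one plant image
#'
#' Applies the measurement half of the pipeline to a single RGB image:
#' greyscale conversion, band-threshold segmentation, the four
#' morphometric traits, fractal dimension, and the CIELab colour summary.
#'
#' @param image numeric H x W x 3 sRGB array (0--255).
#' @param t_low,t_high segmentation thresholds.
#' @param scale physical length per pixel.
#' @param spur_prune_px spur-pruning length for branch counting.
#' @param count_branches_px skip branch counting when `FALSE` (it is the
#'   most expensive trait).
#' @return one-row data.frame with `A`, `B`, `S`, `H`, `FD`, `L_star`,
#'   `a_star`, `b_star`, and `empty_mask` flag (all measures `NA` when
#'   segmentation is empty).
#' @export
measure_plant <- function(image, t_low = 135, t_high = 240, scale = 1,
                          spur_prune_px = 5, count_branches_px = TRUE) {
  grey <- to_greyscale(image)
  # holes are filled only for the area trait (inside-the-borderline count);
  # colour, diameter and the skeleton operate on the raw silhouette
  mask <- withCallingHandlers(
    segment(grey, t_low = t_low, t_high = t_high, fill_holes = FALSE),
    warning = function(w) invokeRestart("muffleWarning"))
  if (!any(mask)) {
    return(data.frame(A = NA_real_, B = NA_real_, S = NA_real_, H = NA_real_,
                      FD = NA_real_, L_star = NA_real_, a_star = NA_real_,
                      b_star = NA_real_, empty_mask = TRUE))
  }
  lab <- rgb_to_lab(image, mask)
  # area and fractal dimension describe the projected silhouette (holes
  # filled); diameter, branch topology and colour use the raw strokes
  filled <- fill_mask_holes(mask)
  data.frame(
    A = projected_area(filled, fill_holes = FALSE, scale = scale),
    B = if (count_branches_px) count_branches(mask, spur_prune_px) else NA_real_,
    S = shoot_diameter(mask, scale = scale),
    H = shoot_height(mask, scale = scale),
    FD = fractal_dimension(filled)$fd,
    L_star = lab[["L_star"]], a_star = lab[["a_star"]],
    b_star = lab[["b_star"]],
    empty_mask = FALSE
  )
}

#' Run the full synthetic trial end to end
#'
#' Generates the factorial cohort plant by plant, measures every image
#' (morphometry, fractal dimension, colour), simulates and processes the
#' biochemical assays, scores the colour difference against each
#' population's salt-free controls, assembles the trait matrix, and runs
#' the multivariate layer (PCA with Kaiser retention, per-treatment
#' population distances, Pearson correlations, per-trait two-way ANOVA)
#' and the RAPD stage (band matrix, classification, Jaccard/UPGMA,
#' Newick).  Identical config and seed give an identical bundle.
#'
#' @param config a [plant_config()].
#' @param outdir optional directory; when given, all tables and results
#'   are written there via [write_bundle()].
#' @param verbose print stage progress.
#' @return object of class `"result_bundle"`: list with `per_plant`,
#'   `ground_truth`, `trait_matrix`, `pca`, `distances`, `pearson`,
#'   `anova`, `rapd`, `band_matrix`, `meta`.
#' @export
run_all <- function(config, outdir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  say("stage generate+measure: %d plants",
      length(config$populations) * length(config$treatments) * config$replicates)
  rows <- list()
  truths <- list()
  k <- 0L
  stage("generate/measure", {
    for (pop in config$populations) {
      for (tr in config$treatments) {
        for (rep in seq_len(config$replicates)) {
          k <- k + 1L
          plant <- generate_plant_image(config, pop, tr, rep)
          meas <- measure_plant(plant$image)
          bio <- generate_biochem(config, pop, tr, rep)
          bio_rec <- process_biochem_reading(bio)
          rows[[k]] <- cbind(
            data.frame(id = paste0(pop, "_", tr, "_", rep),
                       population = pop, treatment_mM = tr, replicate = rep),
            meas,
            as.data.frame(bio_rec))
          tr_truth <- plant$truth
          truths[[k]] <- data.frame(
            id = paste0(pop, "_", tr, "_", rep),
            population = pop, treatment_mM = tr, replicate = rep,
            true_height = tr_truth$true_height,
            true_branch_count = tr_truth$true_branch_count,
            true_stem_diameter = tr_truth$true_stem_diameter,
            true_area = tr_truth$true_area,
            true_L_star = tr_truth$true_lab_mean[[1]],
            true_a_star = tr_truth$true_lab_mean[[2]],
            true_b_star = tr_truth$true_lab_mean[[3]],
            branching_depth = tr_truth$branching_depth,
            true_proline = bio$true_proline,
            true_h2o2 = bio$true_h2o2)
        }
      }
    }
  })
  per_plant <- do.call(rbind, rows)
  ground_truth <- do.call(rbind, truths)

  say("stage colour: population-wise deltaE")
  per_plant$deltaE <- stage("colour", cohort_delta_e(per_plant))

  say("stage stats: trait matrix, PCA, distances, correlations, ANOVA")
  complete <- !per_plant$empty_mask
  trait_matrix <- stage("stats", build_trait_matrix(per_plant[complete, ]))
  pca <- stage("stats", pca_traits(trait_matrix))
  distances <- stage("stats", population_distances(pca, config))
  pearson <- stage("stats", pearson_matrix(per_plant[complete, ]))
  anova <- stage("stats", {
    out <- list()
    for (trait in .TRAIT_COLUMNS) {
      out[[trait]] <- two_way_anova(per_plant[[trait]][complete],
                                    per_plant$population[complete],
                                    per_plant$treatment_mM[complete])
    }
    out
  })

  say("stage rapd: band matrix, classification, UPGMA")
  band_matrix <- stage("rapd", generate_band_matrix(config))
  rapd <- stage("rapd", {
    cls <- classify_bands(band_matrix)
    jd <- jaccard_matrix(band_matrix)
    dend <- upgma(jd)
    list(classification = cls, jaccard = jd, dendrogram = dend,
         newick = write_newick(dend))
  })

  bundle <- structure(list(
    per_plant = per_plant,
    ground_truth = ground_truth,
    trait_matrix = trait_matrix,
    pca = pca,
    distances = distances,
    pearson = pearson,
    anova = anova,
    band_matrix = band_matrix,
    rapd = rapd,
    meta = list(seed = config$seed,
                config_hash = config_fingerprint(config),
                n_plants = nrow(per_plant),
                r_version = as.character(getRversion()),
                package_version = as.character(utils::packageVersion("phenosal")))
  ), class = "result_bundle")

  if (!is.null(outdir)) write_bundle(bundle, outdir)
  bundle
}

# Per-treatment Euclidean distance between the two populations' factorial
# scores (first three components).
population_distances <- function(pca, config) {
  if (length(config$populations) != 2) return(NULL)
  p1 <- config$populations[1]
  p2 <- config$populations[2]
  nc <- min(3, ncol(pca$scores))
  D <- vapply(config$treatments, function(tr) {
    r1 <- paste0(p1, tr)
    r2 <- paste0(p2, tr)
    pc_distance(pca$scores[r1, ], pca$scores[r2, ], n_components = nc)
  }, numeric(1))
  data.frame(treatment_mM = config$treatments, D = D)
}

#' @export
print.result_bundle <- function(x, ...) {
  cat(sprintf("Salinity-trial result bundle: %d plants, %d x %d trait matrix\n",
              nrow(x$per_plant), nrow(x$trait_matrix), ncol(x$trait_matrix)))
  cat(sprintf("  PCA: %d retained components; PC1+PC2 = %.1f%% of variance\n",
              x$pca$retained, sum(x$pca$variance_pct[1:2])))
  if (!is.null(x$distances)) {
    cat("  population distances: ",
        paste(sprintf("%s mM: %.2f", x$distances$treatment_mM, x$distances$D),
              collapse = ", "), "\n", sep = "")
  }
  cat(sprintf("  RAPD: %d polymorphic bands\n",
              x$rapd$classification$n_polymorphic))
  invisible(x)
}

#' Write a result bundle to disk
#'
#' CSV tables (per-plant records, ground truth, trait matrix, distances,
#' correlations, ANOVA letters, band matrix), JSON results (PCA, run
#' manifest) and the Newick dendrogram, under one directory.
#'
#' @param bundle a [run_all()] result.
#' @param outdir output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(outdir, name), row.names = FALSE)
  }
  w(bundle$per_plant, "per_plant.csv")
  w(bundle$ground_truth, "ground_truth.csv")
  utils::write.csv(bundle$trait_matrix, file.path(outdir, "trait_matrix.csv"))
  if (!is.null(bundle$distances)) w(bundle$distances, "population_distances.csv")
  utils::write.csv(bundle$pearson$r, file.path(outdir, "pearson_r.csv"))
  letters_all <- do.call(rbind, lapply(names(bundle$anova), function(tr) {
    cbind(trait = tr, bundle$anova[[tr]]$letters)
  }))
  w(letters_all, "anova_letters.csv")
  utils::write.csv(bundle$band_matrix, file.path(outdir, "band_matrix.csv"))
  jsonlite::write_json(
    list(eigenvalues = bundle$pca$eigenvalues,
         variance_pct = bundle$pca$variance_pct,
         retained = bundle$pca$retained,
         scores = as.data.frame(bundle$pca$scores)),
    file.path(outdir, "pca.json"), auto_unbox = TRUE, digits = NA)
  writeLines(bundle$rapd$newick, file.path(outdir, "dendrogram.nwk"))
  jsonlite::write_json(bundle$meta, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Measure a directory of plant photographs
#'
#' Applies segmentation and all image measures to every PNG/TIFF file
#' named `<population>_<treatment>_<replicate>.<ext>`; files whose
#' segmentation comes up empty are flagged and kept in the table, and
#' unparseable filenames abort with an error.
#'
#' @param image_dir directory of images.
#' @param t_low,t_high segmentation thresholds.
#' @param scale physical length per pixel.
#' @return data.frame, one row per image, with design labels and the
#'   measured traits.
#' @export
measure_images <- function(image_dir, t_low = 135, t_high = 240, scale = 1) {
  files <- list.files(image_dir, pattern = "\\.(png|tif|tiff)$",
                      ignore.case = TRUE)
  if (!length(files)) stop("no PNG/TIFF images in ", image_dir)
  rows <- lapply(files, function(f) {
    stem <- sub("\\.[^.]+$", "", f)
    parts <- strsplit(stem, "_", fixed = TRUE)[[1]]
    if (length(parts) != 3) {
      stop(sprintf("cannot parse '%s': expected <population>_<treatment>_<replicate>.<ext>", f))
    }
    img <- read_plant_image(file.path(image_dir, f))
    meas <- measure_plant(img, t_low = t_low, t_high = t_high, scale = scale)
    cbind(data.frame(id = stem, population = parts[1],
                     treatment_mM = as.numeric(parts[2]),
                     replicate = as.integer(parts[3])),
          meas)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read and write plant images
#'
#' Thin wrappers over the png and tiff packages using the package's
#' 0--255 H x W x 3 array convention.  `write_mask`/`read_mask` store
#' binary masks as 0/255 greyscale PNGs.
#'
#' @param path file path (`.png`, `.tif`, `.tiff`).
#' @return `read_plant_image`: H x W x 3 numeric array in 0--255.
#' @export
read_plant_image <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  raw <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else {
    stop("unsupported image format: ", ext)
  }
  if (length(dim(raw)) == 2) {
    raw <- array(rep(raw, 3), dim = c(dim(raw), 3))
  }
  raw <- raw[, , 1:3, drop = FALSE]
  round(raw * 255)
}

#' @rdname read_plant_image
#' @param image H x W x 3 array in 0--255.
#' @export
write_plant_image <- function(image, path) {
  png::writePNG(clamp(image / 255, 0, 1), path)
  invisible(path)
}

#' @rdname read_plant_image
#' @param mask logical H x W matrix.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' @rdname read_plant_image
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m > 0.5
}
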