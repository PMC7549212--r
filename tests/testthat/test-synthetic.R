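# Synthetic trial generator: determinism, design structure, ground truth.

test_that("plant generation is deterministic and labelled correctly", {
  cfg <- small_config(seed = 7)
  p1 <- generate_plant_image(cfg, "C", 400, 1)
  p2 <- generate_plant_image(cfg, "C", 400, 1)
  expect_identical(p1$image, p2$image)
  expect_identical(p1$mask, p2$mask)
  expect_identical(p1$truth, p2$truth)
  # different replicate gives a different plant
  p3 <- generate_plant_image(cfg, "C", 400, 2)
  expect_false(identical(p1$mask, p3$mask))
  expect_equal(p1$truth$population, "C")
  expect_equal(p1$truth$treatment_mM, 400)
  # invalid labels rejected
  expect_error(generate_plant_image(cfg, "X", 400, 1), "population")
  expect_error(generate_plant_image(cfg, "C", 123, 1), "treatment")
  expect_error(generate_plant_image(cfg, "C", 400, 99), "replicate")
})

test_that("cohort size is the design product", {
  cfg <- small_config(seed = 1, replicates = 3)
  cohort <- generate_cohort(cfg)
  expect_length(cohort, 2 * 5 * 3)
  one <- plant_config(seed = 1, populations = "C", treatments = 400,
                      replicates = 1,
                      response_curves = small_config()$response_curves,
                      image_size = c(128L, 128L), margin = 6L)
  expect_length(generate_cohort(one), 1)
})

test_that("an image too small for the sampled plant fails loudly", {
  rc <- default_response_curves()  # heights near 300 px
  expect_error(
    generate_plant_image(plant_config(seed = 1, image_size = c(96L, 96L),
                                      response_curves = rc), "C", 400, 1),
    "too small")
})

test_that("degenerate structure: no branches gives a plain bar of the true width", {
  cfg <- single_cell_config(seed = 3, depth = 0, n_branch = 0, stem_w = 7)
  p <- generate_plant_image(cfg, "C", 400, 1)
  expect_equal(p$truth$true_branch_count, 0L)
  # single vertical bar: away from the rounded stroke caps every
  # foreground row has the same run width
  widths <- apply(p$mask, 1, sum)
  widths <- widths[widths > 0]
  cap <- ceiling(p$truth$true_stem_diameter / 2) + 1
  widths <- widths[(cap + 1):(length(widths) - cap)]
  expect_true(length(unique(widths)) == 1)
  expect_equal(shoot_diameter(p$mask), p$truth$true_stem_diameter,
               tolerance = 1 / p$truth$true_stem_diameter)
})

test_that("depth-1 plants carry exactly the programmed laterals (flood-fill oracle)", {
  cfg <- single_cell_config(seed = 11, depth = 1, n_branch = 4)
  p <- generate_plant_image(cfg, "C", 400, 1)
  # remove a vertical band around the stem; remaining far components are
  # the laterals (counted with an independent queue-based flood fill)
  m <- p$mask
  x0 <- ncol(m) / 2
  w <- ceiling(p$truth$true_stem_diameter / 2) + 2
  m[, (x0 - w):(x0 + w)] <- FALSE
  lab <- flood_components(m)
  sizes <- tabulate(lab[lab > 0])
  expect_equal(sum(sizes > 10), 4)
})

test_that("programmed responses are unimodal with the optimum at 400 mM", {
  rc <- default_response_curves()
  for (trait in c("H", "A", "branching_depth")) {
    m <- rc[[trait]]$mean
    expect_equal(names(which.max(m)), "400")
    expect_lt(m[["0"]], m[["400"]])
    expect_lt(m[["1000"]], m[["400"]])
  }
  # with sd = 0 the sampled ground truth equals the programmed mean
  rc0 <- lapply(rc, function(cv) response_curve(cv$mean, 0))
  cfg <- plant_config(seed = 5, response_curves = rc0)
  for (pop in c("C", "I")) {
    h <- vapply(c(0, 400, 1000), function(tr) {
      generate_plant_image(cfg, pop, tr, 1)$truth$true_height
    }, numeric(1))
    expect_gt(h[2], h[1])
    expect_gt(h[2], h[3])
  }
})

test_that("misconfigured response curves are rejected", {
  rc <- default_response_curves()
  rc$H <- response_curve(c(300, 260, 200, 260, 300), 10)  # dips at 400
  expect_error(plant_config(response_curves = rc), "peak at 400")
  rc <- default_response_curves()
  rc$L_star <- response_curve(c(70, 65, 60, 55, 50), 1)   # darkening
  expect_error(plant_config(response_curves = rc), "monotonically")
  expect_error(plant_config(replicates = 0), "replicates")
})

test_that("biochemical generator inverts exactly at sd = 0", {
  bc <- lapply(default_biochem_curves(), function(cv) response_curve(cv$mean, 0))
  cfg <- plant_config(seed = 2, biochem_curves = bc, assay_noise_sd = 0)
  for (tr in c(0, 400, 1000)) {
    b <- generate_biochem(cfg, "C", tr, 1)
    pc <- proline_standard_curve()
    hc <- h2o2_standard_curve()
    expect_equal(b$proline_abs, pc$slope * b$true_proline + pc$intercept,
                 tolerance = 1e-12)
    expect_equal(b$h2o2_abs, hc$slope * b$true_h2o2 + hc$intercept,
                 tolerance = 1e-12)
    # measurement-model round trip
    expect_equal(as.numeric(invert_standard_curve(pc, b$proline_abs)),
                 b$true_proline, tolerance = 1e-9)
    expect_equal(as.numeric(invert_standard_curve(hc, b$h2o2_abs)),
                 b$true_h2o2, tolerance = 1e-9)
  }
})

test_that("band matrix has monomorphic rows fixed and population structure", {
  cfg <- plant_config(seed = 4)
  bm <- generate_band_matrix(cfg)
  expect_equal(dim(bm), c(60, 30))
  expect_equal(rownames(bm)[1], "C1")
  expect_equal(rownames(bm)[31], "I1")
  pops <- attr(bm, "population")
  mono_cols <- grepl("_[1-5]$", colnames(bm))
  expect_true(all(bm[, mono_cols] == 1))
  # determinism
  expect_identical(bm, generate_band_matrix(cfg))
  # invalid frequencies rejected
  bad <- cfg
  bad$band_config$freq_high <- 1.2
  expect_error(plant_config(band_config = bad$band_config), "frequencies")
})

test_that("validation fractals match their construction counts", {
  expect_equal(sum(generate_validation_fractal("filled_square", size = 256)),
               65536)
  line <- generate_validation_fractal("line", size = 128)
  expect_equal(sum(line), 128)
  for (d in 1:4) {
    s <- generate_validation_fractal("sierpinski_triangle", depth = d,
                                     size = 64)
    block <- 64 / 2^d
    expect_equal(sum(s), 3^d * block^2)
  }
  for (d in 1:3) {
    k <- generate_validation_fractal("koch_curve", depth = d, size = 256)
    expect_equal(attr(k, "n_segments"), 4^d)
  }
  expect_error(generate_validation_fractal("blob", size = 64), "arg")
  expect_error(generate_validation_fractal("line", size = 100), "power of 2")
})

test_that("trait-record simulation matches the design and programmed ordering", {
  cfg <- plant_config(seed = 9, replicates = 3)
  rec <- simulate_trait_records(cfg)
  expect_equal(nrow(rec), 2 * 5 * 3)
  expect_true(all(c("A", "B", "S", "H", "P", "HP", "Cha", "Chb", "TC",
                    "Carot", "FD", "deltaE") %in% names(rec)))
  expect_identical(rec, simulate_trait_records(cfg))
  agg <- aggregate(P ~ treatment_mM, rec, mean)
  expect_true(all(diff(agg$P[order(agg$treatment_mM)]) > 0))
})
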