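# Independent oracles and small fixtures used across the test files.

# Brute-force box counter: explicit double loop over grid boxes, sharing no
# code with box_count().
brute_box_count <- function(mask, eps) {
  h <- nrow(mask)
  w <- ncol(mask)
  n <- 0L
  for (r0 in seq(1, h, by = eps)) {
    for (c0 in seq(1, w, by = eps)) {
      blk <- mask[r0:min(h, r0 + eps - 1), c0:min(w, c0 + eps - 1)]
      if (any(blk)) n <- n + 1L
    }
  }
  n
}

# Queue-based flood fill (4+diagonal neighbourhood), independent of
# EBImage and igraph; returns a label matrix.
flood_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  h <- nrow(mask)
  w <- ncol(mask)
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      px <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (px - 1L) %% h + 1L
      cc <- (px - 1L) %/% h + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr
        ccc <- cc + dc
        if (rr >= 1 && rr <= h && ccc >= 1 && ccc <= w) {
          q <- (ccc - 1L) * h + rr
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  lab
}

# Reduced-scale trial configuration: same design, smaller plants and
# images, for fast end-to-end tests.
small_config <- function(seed = 1, replicates = 2) {
  rc <- default_response_curves()
  rc$H <- response_curve(c(55, 70, 85, 70, 58), 4)
  rc$B <- response_curve(c(2, 3, 4, 3, 2), 0.5)
  rc$S <- response_curve(c(3, 3.5, 4, 4.5, 5), 0.3)
  rc$branching_depth <- response_curve(c(1, 1, 2, 1, 1), 0)
  plant_config(seed = seed, image_size = c(128L, 128L),
               replicates = replicates, response_curves = rc, margin = 6L)
}

# Single-treatment configuration with a fixed branching depth and branch
# count, used for exact branch-count recovery checks.
single_cell_config <- function(seed, depth = 1, n_branch = 4, height = 120,
                               stem_w = 5, image_size = c(192L, 192L)) {
  rc <- list(
    H = response_curve(height, 0, treatments = 400),
    B = response_curve(n_branch, 0, treatments = 400),
    S = response_curve(stem_w, 0, treatments = 400),
    A = response_curve(5000, 0, treatments = 400),
    FD = response_curve(1.8, 0, treatments = 400),
    branching_depth = response_curve(depth, 0, treatments = 400),
    L_star = response_curve(69, 0, treatments = 400),
    a_star = response_curve(-10, 0, treatments = 400),
    b_star = response_curve(33, 0, treatments = 400)
  )
  bc <- lapply(default_biochem_curves(), function(cv) {
    response_curve(cv$mean[["400"]], cv$sd, treatments = 400)
  })
  pe <- lapply(default_pop_effects(), function(v) {
    if (!is.null(names(v)) && "400" %in% names(v)) v["400"] else v
  })
  plant_config(seed = seed, image_size = image_size, treatments = 400,
               replicates = 12L, response_curves = rc, biochem_curves = bc,
               pop_effects = pe, margin = 8L)
}

# Draw a 1-px-wide line on a logical matrix (test fixture construction).
draw_test_line <- function(mask, r1, c1, r2, c2) {
  n <- max(abs(r2 - r1), abs(c2 - c1)) + 1
  rs <- round(seq(r1, r2, length.out = n))
  cs <- round(seq(c1, c2, length.out = n))
  mask[cbind(rs, cs)] <- TRUE
  mask
}

expect_no_na <- function(x) expect_false(anyNA(x))
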