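# Trait matrix, PCA, distances, correlations, ANOVA.

test_that("trait matrix averages replicates into design cells", {
  rec <- data.frame(
    population = rep(c("C", "I"), each = 10),
    treatment_mM = rep(rep(c(0, 200, 400, 800, 1000), each = 2), 2)
  )
  for (v in c("A", "B", "S", "H", "P", "HP", "Cha", "Chb", "TC", "Carot",
              "FD", "deltaE")) {
    rec[[v]] <- seq_len(20)
  }
  rec$A <- rep(c(10, 20), 10)
  tm <- build_trait_matrix(rec)
  expect_equal(dim(tm), c(10, 12))
  expect_equal(rownames(tm),
               c("C0", "C200", "C400", "C800", "C1000",
                 "I0", "I200", "I400", "I800", "I1000"))
  expect_true(all(tm[, "A"] == 15))
  expect_equal(colnames(tm)[c(1, 12)], c("A", "deltaE"))
  # missing variable rejected
  expect_error(build_trait_matrix(rec[, -3]), "lack")
})

test_that("PCA matches an independent eigensolver on a hand matrix", {
  x <- matrix(c(2.1, 4.3, 0.5,
                3.9, 1.2, 2.2,
                0.7, 5.5, 1.9,
                4.8, 2.0, 3.1), nrow = 4, byrow = TRUE)
  colnames(x) <- c("v1", "v2", "v3")
  res <- pca_traits(x)
  ref <- eigen(stats::cor(x), symmetric = TRUE)
  expect_equal(res$eigenvalues, ref$values, tolerance = 1e-8)
  # loadings agree up to sign
  for (k in 1:3) {
    expect_equal(abs(res$loadings[, k]), abs(ref$vectors[, k]),
                 tolerance = 1e-8, ignore_attr = TRUE)
    # sign convention: largest-magnitude loading positive
    expect_gt(res$loadings[which.max(abs(res$loadings[, k])), k], 0)
  }
  expect_equal(sum(res$eigenvalues), 3, tolerance = 1e-10)
  expect_equal(sum(res$variance_pct), 100, tolerance = 1e-6)
})

test_that("collinear data load fully on the first component", {
  x <- cbind(a = 1:10, b = 2 * (1:10) + 1)
  res <- pca_traits(x)
  expect_equal(res$variance_pct[1], 100, tolerance = 1e-8)
  # near-spherical data spread eigenvalues around 1
  set.seed(2)
  y <- matrix(rnorm(4000), ncol = 4)
  ey <- pca_traits(y)$eigenvalues
  expect_true(all(abs(ey - 1) < 0.2))
  expect_error(pca_traits(cbind(a = rep(1, 5), b = 1:5)), "zero-variance")
  expect_error(pca_traits(x[1:2, ]), "3 rows")
})

test_that("standardised data reconstruct from scores and loadings", {
  set.seed(5)
  x <- matrix(rnorm(60), ncol = 6)
  res <- pca_traits(x)
  z <- scale(x)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  expect_equal(unname(res$scores %*% t(res$loadings)), unname(z),
               tolerance = 1e-8)
  expect_equal(res$retained, sum(res$eigenvalues > 1))
  # loadings orthonormal
  expect_equal(unname(t(res$loadings) %*% res$loadings), diag(6),
               tolerance = 1e-10)
})

test_that("factorial-score distance is the 3-D Euclidean metric", {
  expect_equal(pc_distance(c(0, 0, 0), c(1, 2, 2)), 3)
  expect_equal(pc_distance(c(1, 1, 1), c(2, 3, 3)), 3)
  expect_equal(pc_distance(c(5, 5, 5), c(5, 5, 5)), 0)
  # extra components beyond the third are ignored
  expect_equal(pc_distance(c(0, 0, 0, 99), c(1, 2, 2, -99)), 3)
  expect_error(pc_distance(c(1, 2), c(1, 2, 3)), "components")
  set.seed(8)
  for (i in 1:50) {
    a <- rnorm(3); b <- rnorm(3); c <- rnorm(3)
    expect_equal(pc_distance(a, b), pc_distance(b, a))
    expect_lte(pc_distance(a, c), pc_distance(a, b) + pc_distance(b, c) + 1e-12)
  }
})

test_that("Pearson matrix matches cor.test and is well formed", {
  set.seed(4)
  x <- data.frame(a = rnorm(20))
  x$b <- 2 * x$a + 1
  x$c <- rnorm(20)
  pm <- pearson_matrix(x)
  expect_equal(pm$r["a", "a"], 1)
  expect_equal(pm$r["a", "b"], 1, tolerance = 1e-12)
  ct <- stats::cor.test(x$a, x$c)
  expect_equal(pm$r["a", "c"], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(pm$p["a", "c"], ct$p.value, tolerance = 1e-10)
  # hand data against brute-force covariance arithmetic
  u <- c(1, 4, 2, 8, 5)
  v <- c(2, 3, 7, 6, 9)
  r_hand <- sum((u - mean(u)) * (v - mean(v))) /
    sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  pm2 <- pearson_matrix(cbind(u, v))
  expect_equal(pm2$r["u", "v"], r_hand, tolerance = 1e-12)
  # symmetry, unit diagonal, PSD
  expect_identical(pm$r, t(pm$r))
  expect_true(all(diag(pm$r) == 1))
  expect_true(all(abs(pm$r) <= 1 + 1e-12))
  expect_gte(min(eigen(pm$r, symmetric = TRUE)$values), -1e-10)
  # zero-variance column reported as missing
  pm3 <- pearson_matrix(cbind(a = rep(2, 5), b = 1:5))
  expect_true(is.na(pm3$r["a", "b"]))
  expect_error(pearson_matrix(cbind(a = 1:2, b = 2:3)), "3 observations")
})

test_that("Holm-Sidak step-down reproduces the textbook example", {
  expect_equal(holm_sidak(c(0.01, 0.02, 0.04)),
               c(1 - 0.99^3, 1 - 0.98^2, 0.04), tolerance = 1e-12)
  # order-independence and monotonicity
  p <- c(0.04, 0.01, 0.02)
  adj <- holm_sidak(p)
  expect_equal(adj[order(p)], sort(adj))
  expect_true(all(adj >= p))
  expect_true(all(holm_sidak(runif(10)) <= 1))
  expect_error(holm_sidak(c(0.5, 1.2)), "0, 1")
})

test_that("two-way ANOVA recovers hand-computed F statistics", {
  set.seed(6)
  pop <- rep(c("C", "I"), each = 12)
  tr <- rep(rep(c(0, 400), each = 6), 2)
  y <- rnorm(24, mean = 10 + 2 * (pop == "I") + 0.01 * tr)
  rep_an <- two_way_anova(y, pop, tr)
  # independent balanced-design sums of squares
  n <- length(y)
  gm <- mean(y)
  ss_pop <- sum(tapply(y, pop, function(v) length(v) * (mean(v) - gm)^2))
  ss_tr <- sum(tapply(y, tr, function(v) length(v) * (mean(v) - gm)^2))
  cellm <- tapply(y, list(pop, tr), mean)
  ss_cells <- 6 * sum((cellm - gm)^2)
  ss_int <- ss_cells - ss_pop - ss_tr
  ss_err <- sum((y - ave(y, pop, tr))^2)
  f_pop <- (ss_pop / 1) / (ss_err / 20)
  f_int <- (ss_int / 1) / (ss_err / 20)
  tab <- rep_an$anova_table
  expect_equal(tab$F[tab$term == "population"], f_pop, tolerance = 1e-10)
  expect_equal(tab$F[tab$term == "interaction"], f_int, tolerance = 1e-10)
})

test_that("overwhelming separation is flagged; identical data are not", {
  set.seed(9)
  pop <- rep(c("C", "I"), each = 24)
  tr <- rep(rep(c(0, 400), each = 12), 2)
  y <- ifelse(pop == "C", 0, 10) + rnorm(48, sd = 0.1)
  rep_an <- two_way_anova(y, pop, tr)
  expect_true(all(rep_an$between_population$significant))
  expect_true(all(rep_an$between_population$flag == "*"))

  y0 <- rep(5, 48)
  rep0 <- two_way_anova(y0, pop, tr)
  expect_false(any(rep0$within_population$significant))
  expect_true(all(rep0$letters$letter == "a"))
  expect_error(two_way_anova(1:4, c("C", "C", "I", "I"), c(0, 400, 0, 400)),
               "2 replicates")
})

test_that("compact letters reflect the pairwise pattern", {
  # three treatments, strong ordering 0 << 400 << 1000, two populations
  set.seed(10)
  pop <- rep(c("C", "I"), each = 30)
  tr <- rep(rep(c(0, 400, 1000), each = 10), 2)
  y <- ifelse(tr == 0, 0, ifelse(tr == 400, 5, 10)) + rnorm(60, sd = 0.3)
  rep_an <- two_way_anova(y, pop, tr)
  lets <- rep_an$letters
  for (p in c("C", "I")) {
    l <- lets$letter[lets$population == p]
    expect_equal(length(unique(l)), 3)  # all three differ
  }
  # intermediate group shares letters when not separable
  y2 <- ifelse(tr == 0, 0, ifelse(tr == 400, 0.35, 0.7)) + rnorm(60, sd = 0.3)
  rep2 <- two_way_anova(y2, pop, tr)
  expect_true(all(nchar(rep2$letters$letter) >= 1))
  sig <- rep2$within_population
  # letters are consistent: significant pairs never share a letter
  for (k in seq_len(nrow(sig))) {
    if (!sig$significant[k]) next
    l1 <- rep2$letters$letter[rep2$letters$population == sig$population[k] &
                                rep2$letters$treatment == sig$treatment_1[k]]
    l2 <- rep2$letters$letter[rep2$letters$population == sig$population[k] &
                                rep2$letters$treatment == sig$treatment_2[k]]
    shared <- intersect(strsplit(l1, "")[[1]], strsplit(l2, "")[[1]])
    expect_length(shared, 0)
  }
})
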