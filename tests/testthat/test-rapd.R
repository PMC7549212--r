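# Band classification, Jaccard distances, UPGMA and Newick export.

test_that("bands are classified by within-group frequency", {
  m <- rbind(C1 = c(1, 1, 1, 0), C2 = c(1, 0, 1, 0),
             I1 = c(1, 1, 0, 1), I2 = c(1, 1, 0, 1))
  colnames(m) <- paste0("K01_", 1:4)
  cls <- classify_bands(m, grouping = c("C", "C", "I", "I"))
  # band 1: fixed present everywhere -> monomorphic
  expect_equal(cls$per_band$overall[1], "monomorphic")
  # band 2: frequency 0.5 in C, 1 in I -> polymorphic overall
  expect_equal(cls$per_band$status_C[2], "polymorphic")
  expect_equal(cls$per_band$overall[2], "polymorphic")
  # bands 3/4: fixed but differently between groups -> polymorphic overall
  expect_equal(cls$per_band$overall[3], "polymorphic")
  expect_equal(cls$n_polymorphic, 3)
  expect_error(classify_bands(m, grouping = c("C", "C")), "length")
  expect_error(classify_bands(m * 2, grouping = c("C", "C", "I", "I")), "0/1")
})

test_that("the default band panel yields 15 polymorphic bands (3/6/6 by primer)", {
  cfg <- plant_config(seed = 1)
  bm <- generate_band_matrix(cfg)
  cls <- classify_bands(bm)
  expect_equal(cls$n_polymorphic, 15)
  expect_equal(unname(cls$per_primer[c("K01", "M02", "OPB11")]), c(3, 6, 6))
  # an all-monomorphic panel classifies zero polymorphic bands
  cfg0 <- cfg
  cfg0$band_config$polymorphic[] <- 0
  cls0 <- classify_bands(generate_band_matrix(cfg0))
  expect_equal(cls0$n_polymorphic, 0)
})

test_that("Jaccard distance follows the shared-presence formula", {
  expect_equal(jaccard_distance(c(1, 1, 0), c(1, 0, 1)), 2 / 3)
  expect_equal(jaccard_distance(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(jaccard_distance(c(1, 1, 0, 0), c(0, 0, 1, 1)), 1)
  # shared absences are ignored
  expect_equal(jaccard_distance(c(1, 1, 0, 0, 0), c(1, 0, 1, 0, 0)),
               jaccard_distance(c(1, 1, 0), c(1, 0, 1)))
  expect_error(jaccard_distance(c(0, 0), c(0, 0)), "all-zero")
  expect_error(jaccard_distance(c(1, 0), c(1, 0, 1)), "length")
})

test_that("Jaccard is a metric and matches vegan", {
  set.seed(12)
  vs <- matrix(rbinom(10 * 20, 1, 0.5), nrow = 10)
  vs[, 1] <- 1  # avoid all-zero rows
  for (i in 1:9) for (j in (i + 1):10) {
    dij <- jaccard_distance(vs[i, ], vs[j, ])
    expect_equal(dij, jaccard_distance(vs[j, ], vs[i, ]))
    for (k in seq_len(10)) {
      if (k == i || k == j) next
      expect_lte(dij, jaccard_distance(vs[i, ], vs[k, ]) +
                   jaccard_distance(vs[k, ], vs[j, ]) + 1e-12)
    }
  }
  ref <- as.matrix(vegan::vegdist(vs, method = "jaccard", binary = TRUE))
  mine <- jaccard_matrix(vs)
  expect_equal(unname(mine), unname(ref), tolerance = 1e-12)
})

test_that("UPGMA reproduces the hand-computed three-taxon tree", {
  d <- matrix(c(0, 0.2, 0.6,
                0.2, 0, 0.6,
                0.6, 0.6, 0), nrow = 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  dend <- upgma(d)
  expect_equal(dend$height, c(0.1, 0.3))
  expect_equal(sort(dend$merge[1, ]), c(-2, -1))  # A and B first
  coph <- cophenetic_distances(dend)
  expect_equal(coph["A", "B"], 0.2)
  expect_equal(coph["A", "C"], 0.6)
  expect_error(upgma(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  expect_error(upgma(matrix(c(1, 0, 0, 1), 2, 2)), "diagonal")
})

test_that("equal distances collapse to index-ordered merges at one height", {
  d <- matrix(0.4, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  dend <- upgma(d)
  expect_true(all(abs(dend$height - 0.2) < 1e-12))
  expect_equal(dend$merge[1, ], c(-1, -2))  # smallest (row, col) pair first
})

test_that("UPGMA agrees with hclust average linkage on random matrices", {
  set.seed(14)
  for (i in 1:5) {
    x <- matrix(runif(7 * 5), nrow = 7)
    rownames(x) <- paste0("t", 1:7)
    d <- as.matrix(dist(x))
    dend <- upgma(d)
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    ref <- as.matrix(stats::cophenetic(hc))
    mine <- cophenetic_distances(dend)
    expect_equal(mine[rownames(ref), colnames(ref)], ref, tolerance = 1e-12)
  }
})

test_that("UPGMA trees are ultrametric and reproduce ultrametric inputs", {
  set.seed(15)
  x <- matrix(runif(6 * 4), nrow = 6)
  rownames(x) <- paste0("u", 1:6)
  coph <- cophenetic_distances(upgma(as.matrix(dist(x))))
  labs <- rownames(coph)
  for (i in 1:5) for (j in (i + 1):6) for (k in seq_len(6)) {
    if (k == i || k == j) next
    expect_lte(coph[i, j], max(coph[i, k], coph[j, k]) + 1e-12)
  }
  # already-ultrametric input is reproduced exactly
  again <- cophenetic_distances(upgma(coph))
  expect_equal(again[labs, labs], coph, tolerance = 1e-12)
})

test_that("relabelling individuals permutes leaves without changing heights", {
  set.seed(16)
  x <- matrix(runif(6 * 8), nrow = 6)
  rownames(x) <- paste0("s", 1:6)
  d <- as.matrix(dist(x))
  perm <- sample(6)
  d2 <- d[perm, perm]
  c1 <- cophenetic_distances(upgma(d))
  c2 <- cophenetic_distances(upgma(d2))
  expect_equal(c2[rownames(c1), colnames(c1)], c1, tolerance = 1e-12)
})

test_that("Newick export round-trips through ape", {
  expect_equal(write_newick(upgma(matrix(0, 1, 1, dimnames = list("A", "A")))),
               "A;")
  d2 <- matrix(c(0, 0.5, 0.5, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(write_newick(d2 |> upgma()), "(A:0.25,B:0.25);")

  d <- matrix(c(0, 0.2, 0.6,
                0.2, 0, 0.6,
                0.6, 0.6, 0), nrow = 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  dend <- upgma(d)
  tree <- ape::read.tree(text = write_newick(dend))
  coph_tree <- ape::cophenetic.phylo(tree)
  coph_mine <- cophenetic_distances(dend)
  expect_equal(coph_tree[rownames(coph_mine), colnames(coph_mine)],
               coph_mine, tolerance = 1e-9)
})

test_that("population-structured band matrices split by population at the root", {
  cfg <- plant_config(seed = 19)
  cfg$band_config$freq_high <- 0.9
  cfg$band_config$freq_low <- 0.1
  bm <- generate_band_matrix(cfg)
  dend <- upgma(jaccard_matrix(bm))
  halves <- root_split(dend)
  pops <- lapply(halves, function(h) unique(substr(h, 1, 1)))
  expect_true(all(lengths(pops) == 1))
  expect_setequal(unlist(pops), c("C", "I"))
  # cross-check the split with an independent clustering implementation
  hc <- stats::hclust(stats::as.dist(jaccard_matrix(bm)), method = "average")
  ref_split <- stats::cutree(hc, k = 2)
  expect_equal(length(unique(ref_split[substr(names(ref_split), 1, 1) == "C"])), 1)
})
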