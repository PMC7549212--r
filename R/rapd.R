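# RAPD band classification and Jaccard/UPGMA clustering of individuals.

#' Classify bands as monomorphic or polymorphic
#'
#' A band is monomorphic within a group when its presence frequency there
#' is exactly 0 or 1, polymorphic otherwise.  Overall, a band is
#' polymorphic when it is polymorphic in at least one group or fixed at
#' different values in different groups (a fixed inter-population
#' difference still varies among individuals).
#'
#' @param matrix 0/1 matrix, individuals x bands.
#' @param grouping vector of group labels per individual; defaults to the
#'   matrix's `population` attribute.
#' @param primers optional per-band primer labels; defaults to the
#'   matrix's `primer` attribute, else parsed from column names
#'   (`<primer>_<n>`).
#' @return list with `per_band` (data.frame: band, primer, per-group
#'   status, overall status), `per_primer` (polymorphic counts by primer),
#'   and `n_polymorphic`.
#' @export
classify_bands <- function(matrix, grouping = attr(matrix, "population"),
                           primers = attr(matrix, "primer")) {
  m <- as.matrix(matrix)
  if (!all(m %in% c(0, 1))) stop("band matrix entries must be 0/1")
  if (is.null(grouping)) stop("no `grouping` given and no population attribute")
  if (length(grouping) != nrow(m)) stop("`grouping` length != individuals")
  if (is.null(primers)) {
    primers <- sub("_[0-9]+$", "", colnames(m))
  }
  groups <- unique(grouping)
  if (any(table(grouping) == 0)) stop("every group must be non-empty")

  freq <- sapply(groups, function(g) colMeans(m[grouping == g, , drop = FALSE]))
  freq <- matrix(freq, ncol = length(groups),
                 dimnames = list(colnames(m), groups))
  poly_within <- freq > 0 & freq < 1
  fixed_diff <- apply(freq, 1, function(f) {
    fx <- f[f == 0 | f == 1]
    length(fx) == length(f) && length(unique(fx)) > 1
  })
  overall_poly <- rowSums(poly_within) > 0 | fixed_diff

  per_band <- data.frame(
    band = colnames(m),
    primer = primers,
    stringsAsFactors = FALSE
  )
  for (g in groups) {
    per_band[[paste0("status_", g)]] <-
      ifelse(poly_within[, g], "polymorphic", "monomorphic")
  }
  per_band$overall <- ifelse(overall_poly, "polymorphic", "monomorphic")

  tp <- tapply(overall_poly, primers, sum)
  per_primer <- stats::setNames(as.numeric(tp), names(tp))
  list(per_band = per_band,
       per_primer = per_primer[unique(primers)],
       n_polymorphic = sum(overall_poly))
}

#' Jaccard distance between two binary band profiles
#'
#' With `a` shared presences, `b` and `c` the presences private to each
#' profile, similarity is `J = a / (a + b + c)` and distance `1 - J`;
#' shared absences carry no information for dominant markers and are
#' ignored.
#'
#' @param v1,v2 equal-length 0/1 vectors, not both all-zero.
#' @return distance in `[0, 1]`.
#' @examples
#' jaccard_distance(c(1, 1, 0), c(1, 0, 1))  # 2/3
#' @export
jaccard_distance <- function(v1, v2) {
  if (length(v1) != length(v2)) stop("profiles differ in length")
  v1 <- as.logical(v1)
  v2 <- as.logical(v2)
  a <- sum(v1 & v2)
  bc <- sum(xor(v1, v2))
  if (a + bc == 0) {
    stop("Jaccard distance is undefined for two all-zero profiles")
  }
  1 - a / (a + bc)
}

#' Pairwise Jaccard distance matrix of a band matrix
#'
#' @param matrix 0/1 matrix, individuals x bands.
#' @return symmetric distance matrix with the matrix's row names.
#' @export
jaccard_matrix <- function(matrix) {
  m <- as.matrix(matrix)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- jaccard_distance(m[i, ], m[j, ])
    }
  }
  d
}

#' UPGMA dendrogram from a distance matrix
#'
#' Classic unweighted pair-group method with arithmetic mean: repeatedly
#' merge the closest pair of clusters at height `d/2` (molecular-clock
#' convention) and update distances as the size-weighted mean of the
#' members' distances.  Ties are broken by the smallest (row, column)
#' index pair, so the result is deterministic.
#'
#' @param d symmetric, zero-diagonal, non-negative distance matrix (or a
#'   `dist` object).
#' @return object of class `"upgma_dendrogram"`: list with `merge` and
#'   `height` in `hclust` convention (heights are the merge heights,
#'   i.e. `d/2`), `labels`, and `n`.
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-12)) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  if (any(d < 0)) stop("distances must be non-negative")
  n <- nrow(d)
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (n == 1) {
    return(structure(list(merge = matrix(numeric(0), 0, 2),
                          height = numeric(0), labels = labels, n = 1L),
                     class = "upgma_dendrogram"))
  }
  # active clusters: id < 0 => leaf -id; id > 0 => internal node (merge row)
  ids <- -seq_len(n)
  sizes <- rep(1, n)
  D <- d
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    k <- nrow(D)
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        if (D[i, j] < best_d) {
          best_d <- D[i, j]
          best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- c(ids[i], ids[j])
    height[step] <- best_d / 2
    # size-weighted average distances to the new cluster
    new_d <- (sizes[i] * D[i, ] + sizes[j] * D[j, ]) / (sizes[i] + sizes[j])
    new_d <- new_d[-c(i, j)]
    D <- D[-c(i, j), -c(i, j), drop = FALSE]
    D <- rbind(cbind(D, new_d), c(new_d, 0))
    sizes <- c(sizes[-c(i, j)], sizes[i] + sizes[j])
    ids <- c(ids[-c(i, j)], step)
  }
  structure(list(merge = merge, height = height, labels = labels,
                 n = as.integer(n)),
            class = "upgma_dendrogram")
}

#' @export
print.upgma_dendrogram <- function(x, ...) {
  cat(sprintf("UPGMA dendrogram over %d individuals; root height %.4f\n",
              x$n, if (length(x$height)) max(x$height) else 0))
  invisible(x)
}

#' Cophenetic distances implied by a UPGMA dendrogram
#'
#' The cophenetic distance between two leaves is twice the height of
#' their lowest common ancestor; for input distances that are already
#' ultrametric this reproduces them exactly.
#'
#' @param dendrogram an [upgma()] result.
#' @return symmetric matrix of cophenetic distances.
#' @export
cophenetic_distances <- function(dendrogram) {
  n <- dendrogram$n
  out <- matrix(0, n, n, dimnames = list(dendrogram$labels, dendrogram$labels))
  members <- vector("list", max(1, n - 1))
  for (step in seq_len(n - 1)) {
    kids <- lapply(dendrogram$merge[step, ], function(id) {
      if (id < 0) -id else members[[id]]
    })
    for (a in kids[[1]]) {
      for (b in kids[[2]]) {
        out[a, b] <- out[b, a] <- 2 * dendrogram$height[step]
      }
    }
    members[[step]] <- c(kids[[1]], kids[[2]])
  }
  out
}

#' Leaves under each side of the dendrogram root
#'
#' @param dendrogram an [upgma()] result with at least 2 leaves.
#' @return list of two character vectors of leaf labels.
#' @export
root_split <- function(dendrogram) {
  n <- dendrogram$n
  if (n < 2) stop("root split needs at least two leaves")
  members <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    kids <- lapply(dendrogram$merge[step, ], function(id) {
      if (id < 0) -id else members[[id]]
    })
    members[[step]] <- c(kids[[1]], kids[[2]])
  }
  root <- dendrogram$merge[n - 1, ]
  lapply(root, function(id) {
    dendrogram$labels[if (id < 0) -id else members[[id]]]
  })
}

#' Write a dendrogram as a Newick string
#'
#' Branch lengths are differences of merge heights (leaves sit at height
#' 0), so re-parsing the string reproduces the cophenetic distances.
#'
#' @param dendrogram an [upgma()] result.
#' @param digits significant digits for branch lengths.
#' @return Newick string, semicolon-terminated.
#' @export
write_newick <- function(dendrogram, digits = 10) {
  n <- dendrogram$n
  if (n == 1) return(paste0(dendrogram$labels, ";"))
  fmt <- function(x) sprintf("%.*g", digits, x)
  build <- function(id, parent_h) {
    if (id < 0) {
      paste0(dendrogram$labels[-id], ":", fmt(parent_h))
    } else {
      h <- dendrogram$height[id]
      paste0("(", build(dendrogram$merge[id, 1], h), ",",
             build(dendrogram$merge[id, 2], h), "):", fmt(parent_h - h))
    }
  }
  root_h <- dendrogram$height[n - 1]
  paste0("(", build(dendrogram$merge[n - 1, 1], root_h), ",",
         build(dendrogram$merge[n - 1, 2], root_h), ");")
}
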