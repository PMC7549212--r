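# Silhouette morphometry: segmentation and the four size/shape traits
# (projected area A, branch count B, shoot diameter S, shoot height H).
#
# Conventions: masks are logical matrices, 0-based geometry is never used —
# indices are R's 1-based rows/columns, origin top-left, row index grows
# downwards, so the plant "base" is the bottom-most foreground row.

#' Convert an RGB image to greyscale
#'
#' ITU-R BT.601 luminance, `0.299 R + 0.587 G + 0.114 B`, rounded half-up
#' to integers (the convention of mainstream image-analysis tools).
#'
#' @param image numeric H x W x 3 array of sRGB intensities in `[0, 255]`.
#' @return H x W numeric matrix of integers in `[0, 255]`.
#' @export
to_greyscale <- function(image) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("`image` must be an H x W x 3 array")
  }
  g <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  g <- floor(g + 0.5)
  dim(g) <- dim(image)[1:2]
  g
}

#' Segment a greyscale image into a plant silhouette
#'
#' Band thresholding: pixels with intensity in `[t_low, t_high]`
#' (inclusive) are foreground.  By default only the largest connected
#' component is kept and interior holes are filled, mirroring the manual
#' clean-up a human operator performs.
#'
#' @param grey H x W numeric matrix of intensities in `[0, 255]`.
#' @param t_low,t_high inclusive threshold band (defaults 135 and 240).
#' @param keep_largest keep only the largest 8-connected component.
#' @param fill_holes fill enclosed background holes.
#' @return logical H x W mask.  An empty segmentation raises a warning and
#'   returns an all-`FALSE` mask.
#' @export
segment <- function(grey, t_low = 135, t_high = 240, keep_largest = TRUE,
                    fill_holes = TRUE) {
  if (t_low < 0 || t_high > 255 || t_low > t_high) {
    stop("need 0 <= t_low <= t_high <= 255")
  }
  mask <- grey >= t_low & grey <= t_high
  if (!any(mask)) {
    warning("segmentation produced an empty mask")
    return(mask)
  }
  if (keep_largest) mask <- largest_component(mask)
  if (fill_holes) mask <- fill_mask_holes(mask)
  mask
}

# 8-connected component labelling: EBImage::bwlabel is 4-connected, so
# merge labels that touch diagonally (union-find over label pairs).
label_components <- function(mask) {
  lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(mask * 1)))
  n <- max(lab)
  if (n <= 1) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  h <- nrow(lab)
  w <- ncol(lab)
  for (off in list(c(1, 1), c(1, -1))) {
    a <- lab[seq_len(h - 1), if (off[2] == 1) seq_len(w - 1) else 2:w]
    b <- lab[2:h, if (off[2] == 1) 2:w else seq_len(w - 1)]
    sel <- a > 0 & b > 0 & a != b
    if (any(sel)) {
      for (k in which(sel)) {
        ra <- find(a[k])
        rb <- find(b[k])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  lab[lab > 0] <- remap[lab[lab > 0]]
  lab
}

# Largest 8-connected foreground component.
largest_component <- function(mask) {
  lab <- label_components(mask)
  tab <- tabulate(lab[lab > 0])
  mask & (lab == which.max(tab))
}

fill_mask_holes <- function(mask) {
  filled <- EBImage::fillHull(mask * 1)
  as.matrix(EBImage::imageData(filled)) > 0
}

#' Projected area of the silhouette
#'
#' Number of pixels inside the plant's outline (holes are filled first by
#' default, so enclosed background counts as plant), times `scale^2`.
#'
#' @param mask logical H x W silhouette.
#' @param scale physical length per pixel (default 1, i.e. px^2).
#' @param fill_holes fill enclosed holes before counting.
#' @return area in `scale`^2 units.
#' @export
projected_area <- function(mask, scale = 1, fill_holes = TRUE) {
  if (!any(mask)) return(0)
  if (fill_holes) mask <- fill_mask_holes(mask)
  sum(mask) * scale^2
}

#' Shoot height from the silhouette
#'
#' Vertical extent from the base (bottom-most foreground row) to the apex
#' (top-most foreground row), inclusive, times `scale`.  The axis
#' convention is fixed: a horizontal bar has height equal to its stroke
#' width, not its length.
#'
#' @inheritParams projected_area
#' @return height in `scale` units.
#' @export
shoot_height <- function(mask, scale = 1) {
  rows <- which(rowSums(mask) > 0)
  if (!length(rows)) stop("empty mask: height is undefined")
  (max(rows) - min(rows) + 1) * scale
}

#' Shoot diameter at the middle segment of the stem
#'
#' Over the rows spanning the middle third of the plant's vertical extent,
#' measures in each row the contiguous foreground run that intersects the
#' main-stem column (the column of the foreground centroid of that middle
#' band); the diameter is the lower quartile of the run lengths, times
#' `scale` (rows where a lateral crosses the stem column report the
#' merged run, inflating the upper half of the distribution).  Rows whose
#' runs miss the stem column (e.g. detached branch cross-sections) are
#' skipped; if more than half the rows miss, the stem is considered
#' unidentifiable.
#'
#' @inheritParams projected_area
#' @return diameter in `scale` units.
#' @export
shoot_diameter <- function(mask, scale = 1) {
  rows <- which(rowSums(mask) > 0)
  if (!length(rows)) stop("empty mask: diameter is undefined")
  top <- min(rows)
  bot <- max(rows)
  extent <- bot - top + 1
  mid_rows <- seq(top + floor(extent / 3), top + ceiling(2 * extent / 3) - 1)
  mid_rows <- intersect(mid_rows, rows)
  if (!length(mid_rows)) stop("no foreground rows in the middle third")
  band <- mask[mid_rows, , drop = FALSE]
  stem_col <- round(sum(t(band) * seq_len(ncol(mask))) / sum(band))
  measure_at <- function(col) {
    vapply(mid_rows, function(r) run_width_at(mask[r, ], col), numeric(1))
  }
  widths <- measure_at(stem_col)
  if (sum(!is.na(widths)) < length(widths) / 2) {
    # asymmetric branch mass can pull the centroid off the stem into
    # background; fall back to the column crossing the most middle rows
    stem_col <- which.max(colSums(band))
    widths <- measure_at(stem_col)
  }
  hit <- !is.na(widths)
  if (sum(hit) < length(widths) / 2) {
    stop("main stem not identifiable: most middle-third rows miss the stem column")
  }
  # lower quartile rather than median: rows where a lateral crosses the
  # stem column report the merged stem+branch run, inflating the upper
  # half of the run-length distribution on heavily branched shoots
  stats::quantile(widths[hit], 0.25, names = FALSE, type = 7) * scale
}

# Length of the contiguous TRUE run in `row` containing column `col`,
# NA when `col` is background.
run_width_at <- function(row, col) {
  if (col < 1 || col > length(row) || !row[col]) return(NA_real_)
  left <- col
  while (left > 1 && row[left - 1]) left <- left - 1
  right <- col
  while (right < length(row) && row[right + 1]) right <- right + 1
  right - left + 1
}

# -- skeleton machinery -------------------------------------------------------

shift_mat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Skeletonise a binary silhouette
#'
#' Zhang--Suen iterative thinning to a (mostly) single-pixel-wide,
#' 8-connected medial axis.
#'
#' @param mask logical H x W matrix.
#' @return logical H x W skeleton mask.
#' @export
skeletonize <- function(mask) {
  m <- mask
  # neighbour order P2..P9: N, NE, E, SE, S, SW, W, NW
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      nb <- lapply(offs, function(o) shift_mat(m, -o[1], -o[2]))
      # nb[[k]][r, c] is the value of neighbour k of pixel (r, c)
      bsum <- Reduce(`+`, nb)
      a <- matrix(0L, nrow(m), ncol(m))
      for (k in 1:8) {
        nxt <- if (k == 8) 1 else k + 1
        a <- a + (!nb[[k]] & nb[[nxt]])
      }
      if (sub == 1) {
        c1 <- !(nb[[1]] & nb[[3]] & nb[[5]])
        c2 <- !(nb[[3]] & nb[[5]] & nb[[7]])
      } else {
        c1 <- !(nb[[1]] & nb[[3]] & nb[[7]])
        c2 <- !(nb[[1]] & nb[[5]] & nb[[7]])
      }
      del <- m & bsum >= 2 & bsum <= 6 & a == 1 & c1 & c2
      if (any(del)) {
        m[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Build an igraph over skeleton pixels (8-neighbourhood).  Vertex names are
# linear indices into the mask.
skeleton_graph <- function(skel) {
  idx <- which(skel)
  h <- nrow(skel)
  pos <- cbind(row = (idx - 1L) %% h + 1L, col = (idx - 1L) %/% h + 1L)
  key <- match(seq_len(length(skel)), idx)  # linear index -> vertex id
  edges <- integer(0)
  for (o in list(c(1, 0), c(0, 1), c(1, 1), c(-1, 1))) {
    nr <- pos[, "row"] + o[1]
    nc <- pos[, "col"] + o[2]
    ok <- nr >= 1 & nr <= h & nc >= 1 & nc <= ncol(skel)
    nidx <- (nc - 1L) * h + nr
    ok[ok] <- skel[nidx[ok]]
    from <- which(ok)
    to <- key[nidx[ok]]
    edges <- c(edges, rbind(from, to))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  list(graph = g, pos = pos, idx = idx)
}

# Remove terminal skeleton twigs shorter than min_len pixels (walk from
# each endpoint to the nearest junction; prune the walked chain when it is
# short).  Pure paths with no junction are never pruned.  Vertices must be
# named; returns the pruned graph.
prune_spurs <- function(g, min_len) {
  repeat {
    deg <- igraph::degree(g)
    ends <- which(deg == 1)
    to_drop <- character(0)
    for (e in ends) {
      path <- e
      cur <- e
      prev <- 0L
      hit_junction <- FALSE
      while (length(path) <= min_len) {
        nbs <- setdiff(as.integer(igraph::neighbors(g, cur)), c(prev, path))
        if (length(nbs) == 0L) break
        if (deg[nbs[1]] >= 3) {
          hit_junction <- TRUE
          break
        }
        prev <- cur
        cur <- nbs[1]
        path <- c(path, cur)
      }
      if (hit_junction && length(path) < min_len) {
        to_drop <- c(to_drop, igraph::V(g)$name[path])
      }
    }
    if (!length(to_drop)) break
    g <- igraph::delete_vertices(g, unique(to_drop))
  }
  g
}

#' Count first-order branches of a plant silhouette
#'
#' Skeletonises the mask, prunes terminal twigs shorter than
#' `spur_prune_px` (thinning artefacts), identifies the main axis as the
#' longest geodesic skeleton path through the basal-most skeleton pixel,
#' and counts the lateral subtrees attached to that axis.
#'
#' @param mask logical H x W silhouette; if disconnected, the largest
#'   component is used with a warning.
#' @param spur_prune_px minimum terminal-segment length kept, px.
#' @return non-negative integer branch count.
#' @export
count_branches <- function(mask, spur_prune_px = 5) {
  if (!any(mask)) stop("empty mask: branch count is undefined")
  lab <- label_components(mask)
  ncomp <- max(lab)
  if (ncomp > 1) {
    warning(sprintf("mask has %d components; using the largest", ncomp))
    mask <- largest_component(mask)
  }
  skel <- skeletonize(mask)
  sg <- skeleton_graph(skel)
  n <- igraph::vcount(sg$graph)
  if (n <= 1) return(0L)
  g0 <- igraph::set_vertex_attr(sg$graph, "name",
                                value = as.character(seq_len(n)))
  g <- prune_spurs(g0, spur_prune_px)
  if (igraph::vcount(g) <= 1) return(0L)
  # restrict to the largest remaining skeleton component
  comp <- igraph::components(g)
  sel <- which(comp$membership == which.max(comp$csize))
  g <- igraph::induced_subgraph(g, sel)
  pos <- sg$pos[as.integer(igraph::V(g)$name), , drop = FALSE]

  # main axis: basal-most pixel (max row, tie-break smallest column) to
  # apical-most pixel (min row); for a plant the base-to-apex geodesic is
  # the stem, whereas the longest geodesic can exit through a deep lateral
  basal <- which(pos[, "row"] == max(pos[, "row"]))
  basal <- basal[which.min(pos[basal, "col"])]
  apex <- which(pos[, "row"] == min(pos[, "row"]))
  apex <- apex[which.min(abs(pos[apex, "col"] - pos[basal, "col"]))]
  main_path <- as.integer(igraph::shortest_paths(g, from = basal, to = apex,
                                                 output = "vpath")$vpath[[1]])
  if (!length(main_path)) return(0L)
  off <- setdiff(seq_len(igraph::vcount(g)), main_path)
  if (!length(off)) return(0L)
  sub_idx <- off
  sub <- igraph::induced_subgraph(g, sub_idx)
  comps <- igraph::components(sub)
  # Distance of every pixel to the main axis: thinning a thick stem with
  # attached laterals leaves redundant skeleton strands running alongside
  # the axis within about a stroke width; a genuine lateral must extend
  # beyond that reach.
  axis_img <- matrix(1, nrow(mask), ncol(mask))
  axis_img[pos[main_path, , drop = FALSE]] <- 0
  axis_dist <- as.matrix(EBImage::imageData(EBImage::distmap(axis_img)))
  fg_dist <- as.matrix(EBImage::imageData(EBImage::distmap(mask * 1)))
  stroke_w <- 2 * stats::median(fg_dist[pos])
  reach <- max(spur_prune_px, stroke_w)

  # Attachment sites: main-path positions adjacent to a far-reaching
  # off-path component.  One component may carry several laterals that
  # merge further out, so sites are counted per component, clustering
  # sites closer than 1.5 * reach along the axis into one lateral.
  path_pos <- integer(igraph::vcount(g))
  path_pos[main_path] <- seq_along(main_path)
  on_path <- path_pos > 0
  count <- 0L
  for (ci in seq_len(comps$no)) {
    members <- sub_idx[comps$membership == ci]
    if (max(axis_dist[pos[members, , drop = FALSE]]) <= reach) next
    nb <- unique(unlist(igraph::adjacent_vertices(g, members)))
    sites <- sort(path_pos[nb[on_path[nb]]])
    if (!length(sites)) next
    count <- count + 1L + sum(diff(sites) > 1.5 * reach)
  }
  count
}
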