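# Deterministic reference shapes with known box-counting dimension, used
# to validate the fractal estimator.

#' Generate a validation shape of known fractal dimension
#'
#' Deterministic binary masks for estimator validation: a 1-px horizontal
#' `line` (dimension 1), a `filled_square` (dimension 2), a
#' `sierpinski_triangle` of the given recursion depth (dimension
#' log 3 / log 2), and a `koch_curve` rasterised at 1-px stroke
#' (dimension log 4 / log 3).
#'
#' @param kind one of `"line"`, `"filled_square"`,
#'   `"sierpinski_triangle"`, `"koch_curve"`.
#' @param depth recursion depth (ignored for line and square).
#' @param size image side length in px; must be a power of 2.
#' @return logical `size` x `size` matrix.  For `koch_curve` the attribute
#'   `n_segments` records the number of generator segments (4^depth).
#' @examples
#' sum(generate_validation_fractal("filled_square", size = 256))  # 65536
#' @export
generate_validation_fractal <- function(kind, depth = 1L, size = 256L) {
  kind <- match.arg(kind, c("line", "filled_square", "sierpinski_triangle",
                            "koch_curve"))
  size <- as.integer(size)
  if (size < 2L || bitwAnd(size, size - 1L) != 0L) {
    stop("`size` must be a power of 2")
  }
  depth <- as.integer(depth)
  if (depth < 0L) stop("`depth` must be >= 0")

  switch(kind,
    line = {
      m <- matrix(FALSE, size, size)
      m[size %/% 2L, ] <- TRUE
      m
    },
    filled_square = matrix(TRUE, size, size),
    sierpinski_triangle = {
      # Right Sierpinski triangle via the bitwise-AND construction: cell
      # block (i, j) at resolution 2^depth is filled iff i AND j == 0,
      # giving exactly 3^depth filled sub-triangle blocks.
      if (depth > log2(size)) stop("`depth` exceeds log2(size)")
      block <- size %/% 2L^depth
      i <- (seq_len(size) - 1L) %/% block
      keep <- outer(i, i, function(a, b) bitwAnd(a, b) == 0L)
      keep
    },
    koch_curve = {
      segs <- koch_segments(depth)
      # scale unit-length curve into the frame with a small border
      pad <- max(2, size %/% 32)
      scale <- size - 2 * pad
      m <- matrix(FALSE, size, size)
      y0 <- round(size * 0.7)
      for (k in seq_len(nrow(segs))) {
        m <- draw_line_px(m,
                          pad + segs[k, 1] * scale, y0 - segs[k, 2] * scale,
                          pad + segs[k, 3] * scale, y0 - segs[k, 4] * scale)
      }
      attr(m, "n_segments") <- nrow(segs)
      m
    })
}

# Koch curve generator: returns an n x 4 matrix (x1, y1, x2, y2) of unit
# segments after `depth` substitutions of the classic 4-segment motif.
koch_segments <- function(depth) {
  segs <- matrix(c(0, 0, 1, 0), ncol = 4)
  for (d in seq_len(depth)) {
    out <- matrix(0, nrow = 4 * nrow(segs), ncol = 4)
    r <- 0L
    for (k in seq_len(nrow(segs))) {
      p <- segs[k, 1:2]
      q <- segs[k, 3:4]
      v <- (q - p) / 3
      a <- p + v
      b <- p + 2 * v
      # peak of the equilateral bump
      peak <- a + c(v[1] * 0.5 - v[2] * sqrt(3) / 2,
                    v[1] * sqrt(3) / 2 + v[2] * 0.5)
      pts <- rbind(p, a, peak, b, q)
      for (s in 1:4) {
        r <- r + 1L
        out[r, ] <- c(pts[s, ], pts[s + 1, ])
      }
    }
    segs <- out
  }
  segs
}

# 1-px Bresenham-style line rasteriser used by the reference shapes.
draw_line_px <- function(mask, x1, y1, x2, y2) {
  n <- max(2L, ceiling(max(abs(x2 - x1), abs(y2 - y1))) + 1L)
  xs <- round(seq(x1, x2, length.out = n))
  ys <- round(seq(y1, y2, length.out = n))
  ok <- xs >= 1 & xs <= ncol(mask) & ys >= 1 & ys <= nrow(mask)
  mask[cbind(ys[ok], xs[ok])] <- TRUE
  mask
}
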