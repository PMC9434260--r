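#' Closed planar outline
#'
#' Constructs an outline from ordered x,y coordinates. Consecutive duplicate
#' points are removed and the traversal orientation (signed shoelace area) is
#' recorded.
#'
#' @param points Two-column matrix (or data frame) of x,y coordinates in
#'   traversal order; the closing edge back to the first point is implicit.
#' @return An `outline` object.
#' @export
outline <- function(points) {
  p <- as.matrix(points)
  stopifnot(ncol(p) == 2)
  mode(p) <- "numeric"
  if (nrow(p) > 1) {
    dup <- c(FALSE, rowSums(abs(diff(p))) == 0)
    p <- p[!dup, , drop = FALSE]
    if (nrow(p) > 1 && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  }
  if (nrow(p) < 3) stop_("an outline needs at least 3 distinct points")
  colnames(p) <- c("x", "y")
  structure(list(points = p, closed = TRUE,
                 orientation = if (shoelace_area(p) >= 0) "ccw" else "cw"),
            class = "outline")
}

#' @export
print.outline <- function(x, ...) {
  cat(sprintf("Closed outline: %d points (%s), perimeter %.4g\n",
              nrow(x$points), x$orientation, outline_perimeter(x)))
  invisible(x)
}

#' @export
plot.outline <- function(x, ..., asp = 1, type = "l") {
  p <- rbind(x$points, x$points[1, ])
  graphics::plot(p, asp = asp, type = type, xlab = "x", ylab = "y", ...)
  invisible(x)
}

## signed area (positive = counterclockwise in a y-up frame)
shoelace_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

outline_perimeter <- function(o) {
  p <- o$points
  d <- rbind(diff(p), p[1, ] - p[nrow(p), ])
  sum(sqrt(rowSums(d^2)))
}

## force counterclockwise traversal (deterministic EFA coefficients)
ensure_ccw <- function(o) {
  if (o$orientation == "cw") outline(o$points[rev(seq_len(nrow(o$points))), ]) else o
}

#' Resample an outline at equal arc-length steps
#'
#' Places `k` points equally spaced by cumulative arc length along the closed
#' polyline, starting at the outline's first point. The study design
#' interpolates all outlines to a common count (16,570 in the original
#' analysis) because Procrustes alignment and Fourier analysis need equal
#' point numbers.
#'
#' @param x An [outline()].
#' @param k Number of points (>= 3).
#' @return An `outline` with `k` points.
#' @export
interpolate_outline <- function(x, k) {
  stopifnot(inherits(x, "outline"), k >= 3)
  p <- rbind(x$points, x$points[1, ])
  seg <- sqrt(rowSums(diff(p)^2))
  per <- sum(seg)
  if (per <= 0) stop_("zero-perimeter outline cannot be interpolated")
  s <- c(0, cumsum(seg))
  target <- per * (seq_len(k) - 1) / k
  i <- findInterval(target, s, rightmost.closed = TRUE)
  i[i >= length(s)] <- length(s) - 1L
  frac <- (target - s[i]) / seg[i]
  outline(p[i, , drop = FALSE] + frac * (p[i + 1L, , drop = FALSE] - p[i, , drop = FALSE]))
}
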