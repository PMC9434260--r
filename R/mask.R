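#' Rasterise a closed outline to a binary mask
#'
#' Scanline-fills the outline polygon on a square pixel grid, producing the
#' kind of black-and-white silhouette image the outline tracer consumes.
#' The outline is fitted into the grid with a uniform scale and a margin;
#' the world-to-pixel transform is attached as attributes so traced
#' coordinates can be mapped back.
#'
#' @param x An [outline()].
#' @param resolution Grid side length in pixels (>= 16).
#' @param margin Fractional margin around the bounding box (default 0.05).
#' @return Logical `resolution x resolution` matrix (`TRUE` = foreground);
#'   rows are image rows (y increases downward in pixel space, upward in
#'   world space via the attached transform). Attributes: `pixel_size`,
#'   `x_origin`, `y_origin` such that a pixel at (row i, col j) has world
#'   centre `x = x_origin + (j - 0.5) * pixel_size`,
#'   `y = y_origin + (i - 0.5) * pixel_size`.
#' @export
render_outline_mask <- function(x, resolution = 512, margin = 0.05) {
  stopifnot(inherits(x, "outline"))
  if (resolution < 16) stop_("resolution must be >= 16")
  p <- x$points
  if (abs(shoelace_area(p)) < 1e-12) stop_("zero-area outline cannot be rasterised")
  rng_x <- range(p[, 1]); rng_y <- range(p[, 2])
  span <- max(diff(rng_x), diff(rng_y))
  h <- span * (1 + 2 * margin) / resolution      # pixel size (world units)
  x0 <- mean(rng_x) - resolution * h / 2
  y0 <- mean(rng_y) - resolution * h / 2
  ## closed edge list in pixel coordinates
  px <- (p[, 1] - x0) / h
  py <- (p[, 2] - y0) / h
  x1 <- px; y1 <- py
  x2 <- c(px[-1], px[1]); y2 <- c(py[-1], py[1])
  mask <- matrix(FALSE, resolution, resolution)
  for (i in seq_len(resolution)) {
    yc <- i - 0.5                                 # scanline at pixel centres
    cross <- (y1 <= yc) != (y2 <= yc)
    if (!any(cross)) next
    xi <- sort(x1[cross] + (yc - y1[cross]) / (y2[cross] - y1[cross]) *
                 (x2[cross] - x1[cross]))
    for (k in seq(1, length(xi) - 1, by = 2)) {
      j1 <- max(1L, ceiling(xi[k] + 0.5))
      j2 <- min(resolution, floor(xi[k + 1] + 0.5))
      if (j1 <= j2) mask[i, j1:j2] <- TRUE
    }
  }
  if (!any(mask)) stop_("outline rasterised to an empty mask; raise resolution")
  structure(mask, pixel_size = h, x_origin = x0, y_origin = y0)
}

#' Trace the boundary of the largest object in a binary mask
#'
#' Finds the largest 8-connected foreground component and walks its outer
#' boundary with Moore-neighbour tracing (Jacob's stopping criterion),
#' returning the ordered boundary pixel centres as a closed outline. This is
#' the entry point for silhouette images of combs (photographs thresholded
#' to black objects on white).
#'
#' @param mask Logical or 0/1 matrix; rows are image rows. A
#'   `render_outline_mask()` result can be passed directly, in which case
#'   coordinates are returned in the original world units via its attached
#'   transform; otherwise coordinates are pixel (col = x, row = y) centres.
#' @return An `outline` of boundary points.
#' @export
trace_outline <- function(mask) {
  m <- mask > 0
  if (!any(m)) stop_("empty mask: no foreground pixels")
  if (any(m[1, ]) && any(m[nrow(m), ]) && any(m[, 1]) && any(m[, ncol(m)]))
    warning("foreground touches all four image borders; object may be cropped")
  comp <- largest_component(m)
  b <- moore_trace(comp)
  xs <- b[, 2] - 0.5; ys <- b[, 1] - 0.5          # pixel centres
  h <- attr(mask, "pixel_size")
  if (!is.null(h)) {
    xs <- attr(mask, "x_origin") + (b[, 2] - 0.5) * h
    ys <- attr(mask, "y_origin") + (b[, 1] - 0.5) * h
  }
  outline(cbind(xs, ys))
}

## largest 8-connected component, by iterative frontier dilation
largest_component <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  dilate8 <- function(f) {
    v <- f
    if (nr > 1) {
      v[-nr, ] <- v[-nr, ] | f[-1, ]
      v[-1, ] <- v[-1, ] | f[-nr, ]
    }
    g <- v
    if (nc > 1) {
      g[, -nc] <- g[, -nc] | v[, -1]
      g[, -1] <- g[, -1] | v[, -nc]
    }
    g
  }
  unvisited <- m
  best <- NULL; best_size <- -1L
  while (any(unvisited)) {
    seed <- which(unvisited)[1]
    comp <- matrix(FALSE, nr, nc); comp[seed] <- TRUE
    repeat {
      grown <- dilate8(comp) & m
      if (sum(grown) == sum(comp)) break
      comp <- grown
    }
    sz <- sum(comp)
    if (sz > best_size) { best <- comp; best_size <- sz }
    unvisited <- unvisited & !comp
  }
  best
}

## Moore-neighbour boundary tracing with Jacob's stopping criterion;
## returns ordered (row, col) boundary pixels of one 8-connected object
moore_trace <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  at <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && m[r, c]
  ## Moore neighbourhood in clockwise order (image coords, rows downward):
  ## W, NW, N, NE, E, SE, S, SW
  dr <- c(0, -1, -1, -1, 0, 1, 1, 1)
  dc <- c(-1, -1, 0, 1, 1, 1, 0, -1)
  dir_index <- function(off) which(dr == off[1] & dc == off[2])
  ## start: first foreground pixel in row-major scan; its West neighbour is
  ## background by construction and serves as the initial backtrack
  start <- NULL
  for (r in seq_len(nr)) {
    c <- which(m[r, ])[1]
    if (!is.na(c)) { start <- c(r, c); break }
  }
  if (sum(m) == 1) return(matrix(start, 1))
  back0 <- start + c(0L, -1L)
  cur <- start; back <- back0
  boundary <- matrix(NA_integer_, 8 * sum(m) + 8, 2)
  nb <- 0L
  repeat {
    nb <- nb + 1L
    boundary[nb, ] <- cur
    d0 <- dir_index(back - cur)
    nxt <- NULL
    for (s in 1:8) {                       # s = 0 is the backtrack itself
      k <- ((d0 - 1L + s) %% 8L) + 1L
      r2 <- cur[1] + dr[k]; c2 <- cur[2] + dc[k]
      if (at(r2, c2)) {
        kp <- ((d0 - 1L + s - 1L) %% 8L) + 1L
        back <- cur + c(dr[kp], dc[kp])    # last background cell scanned
        nxt <- c(r2, c2)
        break
      }
    }
    if (is.null(nxt)) break                # isolated pixel
    cur <- nxt
    ## Jacob's criterion: start re-entered with the original backtrack
    if (all(cur == start) && all(back == back0)) break
    if (nb >= nrow(boundary)) break
  }
  b <- boundary[seq_len(nb), , drop = FALSE]
  unique_rows_preserve(b)
}

## remove revisited pixels, keeping first occurrence and order
unique_rows_preserve <- function(b) {
  key <- paste(b[, 1], b[, 2])
  b[!duplicated(key), , drop = FALSE]
}
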