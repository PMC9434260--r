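#' Generalised Procrustes alignment of outlines
#'
#' Centres every outline at the origin, scales it to unit centroid size, and
#' iteratively rotates each to minimise its summed squared distance to the
#' re-estimated mean shape, until the mean shape stabilises. Point
#' correspondence is by index, so outlines must share a point count
#' (interpolate first with [interpolate_outline()]).
#'
#' @param outlines List of [outline()] objects with equal point counts.
#' @param tol Convergence tolerance on the mean-shape change (default 1e-8).
#' @param max_iter Iteration cap (default 100).
#' @return An `aligned_outlines` object: list with `outlines` (aligned),
#'   `centroid_sizes` (original scales), `rotations` (applied angles,
#'   radians), `iterations`, and the per-iteration alignment `objective`.
#' @export
align_outlines <- function(outlines, tol = 1e-8, max_iter = 100) {
  if (length(outlines) < 2) stop_("alignment needs at least 2 outlines")
  stopifnot(all(vapply(outlines, inherits, TRUE, "outline")))
  k <- unique(vapply(outlines, function(o) nrow(o$points), 1L))
  if (length(k) != 1) stop_("outlines have unequal point counts; interpolate first")
  mats <- lapply(outlines, function(o) o$points)
  sizes <- numeric(length(mats))
  for (i in seq_along(mats)) {
    m <- scale(mats[[i]], scale = FALSE)     # centre
    sizes[i] <- sqrt(sum(m^2))               # centroid size
    if (sizes[i] <= 0) stop_("degenerate outline (zero centroid size)")
    mats[[i]] <- m / sizes[i]
  }
  rot <- numeric(length(mats))
  rotate_to <- function(m, ref) {
    th <- atan2(sum(m[, 1] * ref[, 2] - m[, 2] * ref[, 1]),
                sum(m[, 1] * ref[, 1] + m[, 2] * ref[, 2]))
    list(m = m %*% matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2),
         theta = th)
  }
  mean_shape <- mats[[1]]
  objective <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    for (i in seq_along(mats)) {
      r <- rotate_to(mats[[i]], mean_shape)
      mats[[i]] <- r$m
      rot[i] <- rot[i] + r$theta
    }
    new_mean <- Reduce(`+`, mats) / length(mats)
    new_mean <- scale(new_mean, scale = FALSE)
    objective <- c(objective,
                   sum(vapply(mats, function(m) sum((m - new_mean)^2), 0)))
    delta <- sqrt(sum((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol || iter >= max_iter) break
  }
  structure(list(outlines = lapply(mats, outline),
                 centroid_sizes = sizes,
                 rotations = rot,
                 iterations = iter,
                 objective = objective,
                 mean_shape = mean_shape),
            class = "aligned_outlines")
}

#' @export
print.aligned_outlines <- function(x, ...) {
  cat(sprintf("%d aligned outlines (%d points each), %d GPA iterations\n",
              length(x$outlines), nrow(x$outlines[[1]]$points), x$iterations))
  invisible(x)
}

#' Principal component analysis of shape coefficients
#'
#' Column-mean-centred (unscaled -- coefficients share units) PCA of an
#' individuals x coefficient matrix, as applied to elliptic Fourier
#' coefficients to obtain shape scores (PC1, PC2, ...).
#'
#' @param x Numeric matrix, individuals in rows; no missing values.
#' @return A `shape_pca` object: `scores` (individuals x components),
#'   `loadings` (components x coefficient-space), `variance_fraction`
#'   (per component, relative to total variance), `center`.
#' @export
shape_pca <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop_("PCA needs at least 2 individuals")
  if (anyNA(x)) stop_("missing values in coefficient matrix")
  total_var <- sum(apply(x, 2, stats::var))
  if (total_var <= 0) stop_("constant coefficient matrix has zero variance")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / total_var
  structure(list(scores = pc$x,
                 loadings = t(pc$rotation),
                 variance_fraction = vf,
                 center = pc$center),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  k <- min(5, length(x$variance_fraction))
  cat("Shape PCA:", nrow(x$scores), "individuals,",
      ncol(x$scores), "components\n")
  cat("  variance fractions:",
      paste0(sprintf("PC%d %.1f%%", seq_len(k),
                     100 * x$variance_fraction[seq_len(k)]),
             collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.shape_pca <- function(x, n = 10, ...) {
  k <- min(n, length(x$variance_fraction))
  graphics::barplot(100 * x$variance_fraction[seq_len(k)],
                    names.arg = paste0("PC", seq_len(k)),
                    ylab = "% variance explained", ...)
  invisible(x)
}
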