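test_that("outline construction validates and deduplicates", {
  expect_error(outline(cbind(c(0, 0), c(1, 1))), "3 distinct")
  o <- outline(rbind(c(0, 0), c(0, 0), c(1, 0), c(1, 1), c(0, 0)))
  expect_equal(nrow(o$points), 3)
  expect_equal(o$orientation, "ccw")
  o_cw <- outline(rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0)))
  expect_equal(o_cw$orientation, "cw")
})

test_that("outline tracing recovers rectangles, disks, and rejects empty masks", {
  ## 10 x 6 filled rectangle: boundary has 2*(10+6) - 4 = 28 pixels
  m <- matrix(FALSE, 20, 24)
  m[6:11, 4:13] <- TRUE
  o <- trace_outline(m)
  expect_equal(nrow(o$points), 28)
  expect_true(all(o$points[, 1] >= 3.5 & o$points[, 1] <= 12.5))

  ## disk of radius 50: boundary within 1.5 px of the radius
  ij <- expand.grid(i = 1:120, j = 1:120)
  mk <- matrix((ij$i - 60)^2 + (ij$j - 60)^2 <= 50^2, 120, 120)
  od <- trace_outline(mk)
  r <- sqrt((od$points[, 1] - 59.5)^2 + (od$points[, 2] - 59.5)^2)
  expect_true(all(abs(r - 50) < 1.5))

  expect_error(trace_outline(matrix(FALSE, 8, 8)), "empty mask")

  ## largest of several components wins
  m2 <- matrix(FALSE, 30, 30)
  m2[2:4, 2:4] <- TRUE
  m2[10:25, 10:25] <- TRUE
  o2 <- trace_outline(m2)
  expect_true(all(o2$points >= 9))
})

test_that("arc-length interpolation hits corners and midpoints of a square", {
  sq <- outline(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  o8 <- interpolate_outline(sq, 8)
  expect_equal(o8$points,
               cbind(x = c(0, .5, 1, 1, 1, .5, 0, 0),
                     y = c(0, 0, 0, .5, 1, 1, 1, .5)))
  ## identity on an already equally spaced outline
  circ <- ellipse_outline(1, 1, 100)
  o100 <- interpolate_outline(circ, 100)
  expect_equal(o100$points, circ$points, tolerance = 1e-10)
  ## perimeter preserved for k >= original count
  blob <- blob_outline(2)
  per0 <- sum(sqrt(rowSums((rbind(blob$points[-1, ], blob$points[1, ]) - blob$points)^2)))
  big <- interpolate_outline(blob, 2000)
  per1 <- sum(sqrt(rowSums((rbind(big$points[-1, ], big$points[1, ]) - big$points)^2)))
  expect_lt(abs(per1 - per0) / per0, 0.001)
})

test_that("generalized Procrustes alignment superposes, centres, and descends", {
  blob <- interpolate_outline(blob_outline(4), 200)
  th <- 30 * pi / 180
  rot <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
  copy <- outline(2 * blob$points %*% rot + 5)
  al <- align_outlines(list(blob, copy))
  expect_lt(max(abs(al$outlines[[1]]$points - al$outlines[[2]]$points)), 1e-6)

  ## random shape set: centred at 0, unit size, objective non-increasing
  shapes <- lapply(1:20, function(i) interpolate_outline(blob_outline(i), 100))
  al2 <- align_outlines(shapes)
  for (o in al2$outlines) {
    expect_lt(max(abs(colMeans(o$points))), 1e-10)
    expect_equal(sum(scale(o$points, scale = FALSE)^2), 1, tolerance = 1e-9)
  }
  expect_true(all(diff(al2$objective) <= 1e-10))
  expect_error(align_outlines(shapes[1]), "at least 2")
})

test_that("EFA matches a numeric-integration Fourier oracle on analytic shapes", {
  ## ellipse with semi-axes 2 and 1
  cf <- efa_decompose(ellipse_outline(2, 1, 500), H = 8)
  hp <- harmonic_power(cf)
  expect_gt(hp$cumulative[1], 0.9999)
  expect_lt(abs(abs(cf$a[1]) - 2) / 2, 0.01)
  expect_lt(abs(abs(cf$d[1]) - 1) / 1, 0.01)

  ## circle: harmonic 1 only, total power ~ r^2
  r <- 1.7
  cfc <- efa_decompose(ellipse_outline(r, r, 400), H = 6)
  pw <- (cfc$a^2 + cfc$b^2 + cfc$c^2 + cfc$d^2) / 2
  expect_lt(max(pw[-1]) / sum(pw), 1e-6)
  expect_equal(sum(pw), r^2, tolerance = 1e-3)

  ## irregular blob against the independent oracle
  set.seed(8)
  xfun <- function(u) cos(u) * (1 + 0.2 * cos(3 * u)) + 0.1 * sin(2 * u)
  yfun <- function(u) sin(u) * (1 + 0.2 * cos(3 * u))
  u <- seq(0, 2 * pi, length.out = 2001)[-2001]
  cfb <- efa_decompose(outline(cbind(xfun(u), yfun(u))), H = 6)
  orc <- fourier_oracle(xfun, yfun, 6)
  expect_equal(cfb$a, orc$a, tolerance = 1e-4)
  expect_equal(cfb$b, orc$b, tolerance = 1e-4)
  expect_equal(cfb$c, orc$c, tolerance = 1e-4)
  expect_equal(cfb$d, orc$d, tolerance = 1e-4)
  expect_equal(cfb$A0, orc$A0, tolerance = 1e-4)
  expect_equal(cfb$C0, orc$C0, tolerance = 1e-4)

  expect_error(efa_decompose(ellipse_outline(), H = 0), "H must be")
})

test_that("EFA is equivariant under translation and scaling", {
  blob <- blob_outline(5)
  cf <- efa_decompose(blob, H = 6)
  shifted <- outline(sweep(blob$points, 2, c(3, -2), `+`))
  cfs <- efa_decompose(shifted, H = 6)
  expect_equal(cfs$a, cf$a, tolerance = 1e-10)
  expect_equal(cfs$d, cf$d, tolerance = 1e-10)
  expect_equal(c(cfs$A0 - cf$A0, cfs$C0 - cf$C0), c(3, -2), tolerance = 1e-8)
  scaled <- outline(2.5 * blob$points)
  cfk <- efa_decompose(scaled, H = 6)
  expect_equal(cfk$a, 2.5 * cf$a, tolerance = 1e-10)
  expect_equal(cfk$b, 2.5 * cf$b, tolerance = 1e-10)
  expect_equal(cfk$c, 2.5 * cf$c, tolerance = 1e-10)
  expect_equal(cfk$d, 2.5 * cf$d, tolerance = 1e-10)
})

test_that("reconstruction error decreases in H and inverts decomposition", {
  blob <- interpolate_outline(blob_outline(6), 1000)
  errs <- vapply(c(1, 2, 4, 8, 16, 26), function(H) {
    rec <- efa_reconstruct(efa_decompose(blob, H = H), k = 1000)
    mean(sqrt(rowSums((rec$points - blob$points)^2)))
  }, 1)
  expect_true(all(diff(errs) <= 1e-12))
  ## H = 26 round trip: error below 0.5% of centroid size
  size <- sqrt(sum(scale(blob$points, scale = FALSE)^2) / nrow(blob$points))
  expect_lt(errs[6] / size, 0.005)

  ## a1 = d1 = 1 gives the unit circle
  circ <- efa_reconstruct(list(a = 1, b = 0, c = 0, d = 1, A0 = 0, C0 = 0), k = 100)
  expect_equal(sqrt(rowSums(circ$points^2)), rep(1, 100), tolerance = 1e-12)
  tri <- efa_reconstruct(list(a = 1, b = 0, c = 0, d = 1, A0 = 0, C0 = 0), k = 3)
  expect_equal(nrow(tri$points), 3)
  expect_error(efa_reconstruct(list(a = numeric(0)), k = 10), "empty")
})

test_that("harmonic power identifies required harmonics, checked against the oracle", {
  cf <- efa_decompose(ellipse_outline(2, 1, 500), H = 10)
  hp <- harmonic_power(cf, threshold = 0.99)
  expect_equal(hp$n_required, 1)
  expect_equal(hp$cumulative[10], 1)
  expect_true(all(diff(hp$cumulative) >= 0))

  ## square: only odd harmonics carry power; n_required matches the oracle
  side <- seq(0, 1, length.out = 101)[-101]
  sq_pts <- rbind(cbind(side, 0), cbind(1, side), cbind(1 - side, 1), cbind(0, 1 - side))
  cfs <- efa_decompose(outline(sq_pts), H = 9)
  pw <- (cfs$a^2 + cfs$b^2 + cfs$c^2 + cfs$d^2) / 2
  expect_lt(sum(pw[c(2, 4, 6, 8)]) / sum(pw), 1e-6)
  ## uniform-speed parametric square oracle
  sq_x <- function(u) { s <- (u / (2 * pi) * 4) %% 4
    ifelse(s < 1, s, ifelse(s < 2, 1, ifelse(s < 3, 3 - s, 0))) }
  sq_y <- function(u) { s <- (u / (2 * pi) * 4) %% 4
    ifelse(s < 1, 0, ifelse(s < 2, s - 1, ifelse(s < 3, 1, 4 - s))) }
  orc <- fourier_oracle(sq_x, sq_y, 9)
  pw_orc <- (orc$a^2 + orc$b^2 + orc$c^2 + orc$d^2) / 2
  expect_equal(pw, pw_orc, tolerance = 1e-3)
  n_req_orc <- which(cumsum(pw_orc) / sum(pw_orc) >= 0.99)[1]
  expect_equal(harmonic_power(cfs, 0.99)$n_required, n_req_orc)

  expect_error(harmonic_power(cf, threshold = 1.5), "threshold")
})

test_that("shape PCA agrees with a brute-force eigendecomposition", {
  set.seed(13)
  x <- matrix(rnorm(60), 10, 6)
  p <- shape_pca(x)
  ## independent route: eigen of the covariance matrix
  ev <- eigen(cov(x), symmetric = TRUE)
  for (k in 1:5) {
    expect_equal(abs(sum(p$loadings[k, ] * ev$vectors[, k])), 1, tolerance = 1e-8)
    sc <- scale(x, scale = FALSE) %*% ev$vectors[, k]
    expect_equal(abs(as.numeric(cor(p$scores[, k], sc))), 1, tolerance = 1e-8)
  }
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-12)
  expect_true(all(diff(p$variance_fraction) <= 1e-12))

  ## rank-1 data loads a single component
  v <- rnorm(6)
  x1 <- outer(rnorm(20), v) + 3
  p1 <- shape_pca(x1)
  expect_gt(p1$variance_fraction[1], 0.9999)

  ## row order only permutes scores (up to sign)
  perm <- sample(10)
  p2 <- shape_pca(x[perm, ])
  expect_equal(abs(p2$scores[order(perm), 1]), abs(p$scores[, 1]), tolerance = 1e-8)

  expect_error(shape_pca(matrix(1, 5, 3)), "zero variance")
  expect_error(shape_pca(matrix(c(1, NA, 2, 3), 2)), "missing")
})

test_that("render -> trace -> interpolate -> EFA recovers planted coefficients", {
  ## unit circle rasterisation: area within 2% of pi r^2
  circ <- ellipse_outline(1, 1, 720)
  msk <- render_outline_mask(circ, 512)
  area_px <- sum(msk) * attr(msk, "pixel_size")^2
  expect_lt(abs(area_px - pi) / pi, 0.02)

  ## round trip on smooth blobs: harmonic amplitudes within 1% (harmonics 1-5);
  ## the traced outline starts at an arbitrary boundary point, so coefficients
  ## are compared through the rotation/start-invariant per-harmonic amplitude
  for (s in 1:3) {
    blob <- interpolate_outline(blob_outline(s, irregularity = 0.1), 1200)
    cf0 <- efa_decompose(blob, H = 5)
    tr <- trace_outline(render_outline_mask(blob, 512))
    cf1 <- efa_decompose(interpolate_outline(tr, 1200), H = 5)
    amp0 <- sqrt(cf0$a^2 + cf0$b^2 + cf0$c^2 + cf0$d^2)
    amp1 <- sqrt(cf1$a^2 + cf1$b^2 + cf1$c^2 + cf1$d^2)
    expect_lt(max(abs(amp1 - amp0)) / amp0[1], 0.01)
  }

  ## degenerate outline and resolution guards
  degenerate <- structure(list(points = cbind(c(0, 1, 2), c(0, 0, 0)),
                               closed = TRUE, orientation = "ccw"),
                          class = "outline")
  expect_error(render_outline_mask(degenerate), "zero-area")
  expect_error(render_outline_mask(circ, resolution = 8), "resolution")
})
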