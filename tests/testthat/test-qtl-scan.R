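test_that("Haldane map function matches its closed form", {
  expect_equal(haldane_recomb(0), 0)
  expect_equal(haldane_recomb(16), 0.13693, tolerance = 1e-4)
  expect_lt(abs(haldane_recomb(500) - 0.5), 1e-4)
  expect_error(haldane_recomb(-1), "non-negative")
})

test_that("genotype probabilities reduce to indicators at typed markers", {
  fx <- sim_trait_cross(seed = 61, n = 30)
  pr <- genotype_probabilities(fx$cross, error_prob = 0)
  g <- fx$cross$geno
  for (i in c(1, 7, 23)) for (j in c(1, 40, 105)) {
    expected <- c(0, 0, 0); expected[g[i, j] + 1] <- 1
    expect_equal(pr$prob[i, j, ], expected, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  expect_equal(rowSums(pr$prob[, 50, ]), rep(1, 30), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("midpoint probabilities match a hand-enumerated three-point oracle", {
  ## two markers 20 cM apart, one pseudomarker at the midpoint; individual
  ## typed RR at both flanks. Oracle: P(g) ~ T1[RR, g] * T2[g, RR] over the
  ## 3 middle states (prior cancels by stationarity).
  map <- data.frame(marker = c("m1", "m2"), chr = "1", pos = c(0, 20),
                    bp = c(0, 6e6), stringsAsFactors = FALSE)
  class(map) <- c("genetic_map", "data.frame")
  g <- matrix(0L, 4, 2, dimnames = list(NULL, map$marker))  # all RR
  cross <- cross_data(map, g)
  pr <- genotype_probabilities(cross, step = 10, error_prob = 0)
  mid <- which(pr$positions$pos == 10)
  r <- haldane_recomb(10)
  T1 <- combqtl:::f2_transition(r)
  w <- T1[1, ] * T1[, 1]
  oracle <- w / sum(w)
  expect_equal(pr$prob[1, mid, ], oracle, tolerance = 1e-9, ignore_attr = TRUE)
  expect_gt(oracle[1], 0.93)

  ## all genotypes missing: stationary prior everywhere
  g2 <- matrix(NA_integer_, 3, 2, dimnames = list(NULL, map$marker))
  pr2 <- genotype_probabilities(cross_data(map, g2), step = 10)
  for (j in 1:3)
    expect_equal(pr2$prob[1, j, ], c(0.25, 0.5, 0.25), tolerance = 1e-9,
                 ignore_attr = TRUE)
})

test_that("scan LOD equals a direct least-squares oracle at every marker", {
  ## 50-individual, 20-marker fixture with sex + batch + weight covariates
  cfg <- sim_config(n_chromosomes = 2, chr_length = 90, marker_spacing = 10,
                    n_individuals = 50, n_per_generation = 50, seed = 71)
  map <- simulate_map(cfg)
  g <- simulate_ail_genotypes(map, cfg)
  q <- qtl_spec("1", 40, additive_effect = 0.8, dominance_effect = 0.3)
  ph <- simulate_quantitative_trait(g, map, q,
                                    covariate_effects = list(sex = 0.5, weight = 0.002),
                                    noise_sd = 1, trait_name = "y", seed = 72)
  cross <- make_cross(g, ph)
  pr <- genotype_probabilities(cross)
  sc <- hk_scan(cross, "y", c("sex", "batch", "weight"), probs = pr)
  expect_equal(nrow(sc), 20)

  X0 <- model.matrix(~ sex + batch + weight, data = cross$covar)
  y <- cross$pheno$y
  rss0 <- sum(lm.fit(X0, y)$residuals^2)
  for (j in seq_len(20)) {
    rss1 <- sum(lm.fit(cbind(X0, pr$xa[, j], pr$xd[, j]), y)$residuals^2)
    expect_equal(sc$lod[j], (50 / 2) * log10(rss0 / rss1), tolerance = 1e-8)
  }
})

test_that("a perfectly fitting trait saturates the LOD and guards fire", {
  fx <- sim_trait_cross(seed = 81, n = 60)
  pr <- genotype_probabilities(fx$cross)
  cross <- fx$cross
  cross$pheno$perfect <- pr$xa[, 33] + 2
  sc <- hk_scan(cross, "perfect", probs = pr)
  expect_gt(sc$lod[33], 100)

  cross$pheno$flat <- rep(1, 60)
  expect_error(hk_scan(cross, "flat", probs = pr), "zero variance")
  cross$covar$dup <- as.numeric(cross$covar$weight)
  expect_error(hk_scan(cross, "y", c("weight", "dup"), probs = pr),
               "collinear")
  expect_error(hk_scan(cross, "nope", probs = pr), "unknown trait")
})

test_that("LOD is invariant to affine trait rescaling and inert covariates", {
  fx <- sim_trait_cross(seed = 91, qtl = qtl_spec("2", 100, 0.6), n = 200)
  cross <- fx$cross
  pr <- genotype_probabilities(cross)
  sc1 <- hk_scan(cross, "y", probs = pr)
  cross$pheno$y2 <- 3.7 * cross$pheno$y - 11
  sc2 <- hk_scan(cross, "y2", probs = pr)
  expect_equal(sc1$lod, sc2$lod, tolerance = 1e-9)

  ## an irrelevant balanced covariate barely moves a null trait's LOD curve
  fx0 <- sim_trait_cross(seed = 92, n = 200)
  cross0 <- fx0$cross
  pr0 <- genotype_probabilities(cross0)
  s0 <- hk_scan(cross0, "y", probs = pr0)
  cross0$covar$inert <- lm.fit(cbind(1, cross0$pheno$y),
                               rep(c(-1, 1), 100))$residuals
  s0i <- hk_scan(cross0, "y", covariates = "inert", probs = pr0)
  expect_lt(max(abs(s0i$lod - s0$lod)), 0.05)
})

test_that("interacting-covariate scans nest the additive model", {
  fx <- sim_trait_cross(seed = 95, qtl = qtl_spec("1", 100, 0.6), n = 200,
                        covariate_effects = list(sex = 0.5))
  pr <- genotype_probabilities(fx$cross)
  sc_add <- hk_scan(fx$cross, "y", covariates = "sex", probs = pr)
  sc_int <- hk_scan(fx$cross, "y", covariates = "sex", intcovar = "sex",
                    probs = pr)
  ## the interaction model can only fit better at every position
  expect_true(all(sc_int$lod >= sc_add$lod - 1e-8))
})

test_that("permutation thresholds are ordered, seeded, and tie-inclusive", {
  fx <- sim_trait_cross(seed = 101, n = 150)
  pr <- genotype_probabilities(fx$cross)
  pm1 <- perm_thresholds(fx$cross, "y", c("sex", "batch"), n_perm = 200,
                         seed = 5, probs = pr)
  pm2 <- perm_thresholds(fx$cross, "y", c("sex", "batch"), n_perm = 200,
                         seed = 5, probs = pr)
  expect_identical(pm1$maxima, pm2$maxima)
  expect_gte(pm1$thresholds[["95%"]], pm1$thresholds[["80%"]])
  ## ties at the threshold count as exceeding
  expect_equal(genome_scan_pvalue(pm1, max(pm1$maxima)), 1 / 200)
  expect_equal(genome_scan_pvalue(pm1, 0), 1)
  expect_error(perm_thresholds(fx$cross, "y", n_perm = 50, probs = pr),
               "n_perm")
  expect_error(perm_thresholds(fx$cross, "y", n_perm = 200, quantiles = 1.2,
                               probs = pr), "quantiles")
})

test_that("permutation seeds differ by about the expected noise envelope", {
  fx <- sim_trait_cross(seed = 104, n = 150)
  pr <- genotype_probabilities(fx$cross)
  pmA <- perm_thresholds(fx$cross, "y", n_perm = 1000, seed = 1, probs = pr)
  pmB <- perm_thresholds(fx$cross, "y", n_perm = 1000, seed = 2, probs = pr)
  expect_lt(abs(pmA$thresholds[["95%"]] - pmB$thresholds[["95%"]]), 0.3)
})

test_that("LOD-drop intervals solve the triangular case and snap to markers", {
  ## triangular LOD curve: peak 10 at 50 cM, slope 0.1/cM, markers every 2 cM
  pos <- seq(0, 100, 2)
  tri <- data.frame(chr = "1", pos = pos, marker = sprintf("m%02d", seq_along(pos)),
                    lod = 10 - 0.1 * abs(pos - 50))
  class(tri) <- c("hk_scan", "data.frame")
  ci <- lod_drop_interval(tri, "1", 50, drop = 1.8)
  expect_equal(c(ci$start, ci$end), c(32, 68))

  ## flat curve spans the chromosome
  flat <- tri; flat$lod <- 5
  ci2 <- lod_drop_interval(flat, "1", 50, drop = 1.8)
  expect_equal(c(ci2$start, ci2$end), c(0, 100))

  expect_error(lod_drop_interval(tri, "1", 33), "not on the scan grid")
  expect_error(lod_drop_interval(tri, "2", 50), "not in scan")
})

test_that("effect estimation recovers planted effects and bounded %var", {
  cfg <- small_config(n = 200, seed = 111)
  map <- simulate_map(cfg)
  g <- simulate_ail_genotypes(map, cfg)
  q <- qtl_spec("4", 120, additive_effect = 1, dominance_effect = 0.5)
  ph <- simulate_quantitative_trait(g, map, q, noise_sd = 0,
                                    trait_name = "y", seed = 112)
  ## add an infinitesimal jitter so the least-squares fit is non-degenerate
  set.seed(113)
  ph$y <- ph$y + rnorm(200, 0, 1e-8)
  cross <- make_cross(g, ph)
  pk <- qtl_fit(cross, "y", NULL, "4", 120, error_prob = 0)
  expect_equal(unname(coef(pk)), c(1, 0.5), tolerance = 1e-6)
  expect_true(pk$pct_var >= 0 && pk$pct_var <= 100)
  expect_gt(pk$additive_se, 0)
  expect_gt(pk$dominance_se, 0)
})

test_that("additive-effect estimates are unbiased across replicates", {
  cfg <- small_config(n = 300, seed = 1)
  map <- simulate_map(cfg)
  q <- qtl_spec("3", 100, additive_effect = 0.5)
  set.seed(120)
  est <- replicate(100, {
    s <- sample.int(1e6, 1)
    g <- simulate_ail_genotypes(map, cfg, seed = s)
    nsd <- noise_sd_for_pve(g, map, q, 0.10)
    ph <- simulate_quantitative_trait(g, map, q, noise_sd = nsd,
                                      trait_name = "y", seed = s + 1)
    qtl_fit(make_cross(g, ph), "y", NULL, "3", 100)$additive
  })
  expect_lt(abs(mean(est) - 0.5), 2 * sd(est) / sqrt(length(est)))
})
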