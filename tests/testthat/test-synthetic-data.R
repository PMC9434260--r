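test_that("simulated maps are regular grids with deterministic bp positions", {
  m <- simulate_map(sim_config(n_chromosomes = 1, chr_length = 100,
                               marker_spacing = 20))
  expect_equal(nrow(m), 6)
  expect_equal(m$pos, seq(0, 100, 20))
  expect_equal(m$bp, m$pos * 3e5)

  m2 <- simulate_map(sim_config(n_chromosomes = 10, chr_length = 920,
                                marker_spacing = 16))
  expect_equal(nrow(m2), 580)                       # floor(920/16) + 1 per chr
  expect_equal(as.vector(table(m2$chr)), rep(58L, 10))
  expect_false(anyDuplicated(m2$marker) > 0)
  for (ch in unique(m2$chr))
    expect_true(all(diff(m2$pos[m2$chr == ch]) > 0))

  expect_error(sim_config(marker_spacing = 0), "marker_spacing")
  expect_error(sim_config(chr_length = 5, marker_spacing = 10), "chr_length")
})

test_that("F1 individuals are fully heterozygous and F8 frequencies stay near 0.5", {
  cfg <- sim_config(n_generations = 2, n_individuals = 40, seed = 3)
  g1 <- simulate_ail_genotypes(simulate_map(cfg), cfg)
  expect_true(all(g1$geno == 1L))

  cfg8 <- small_config(n = 300, seed = 11)
  g8 <- simulate_ail_genotypes(simulate_map(cfg8), cfg8)
  expect_true(all(g8$geno %in% 0:2))
  freq_w <- colMeans(g8$geno) / 2
  expect_gt(mean(freq_w >= 0.35 & freq_w <= 0.65), 0.95)
})

test_that("breeding guard rejects designs that would force selfing", {
  cfg <- sim_config(n_generations = 8, n_per_generation = 1, n_individuals = 10)
  expect_error(simulate_ail_genotypes(simulate_map(cfg), cfg), "selfing")
})

test_that("the genetic map expands: more recombinant neighbours at F8 than F2", {
  base <- list(n_chromosomes = 4, chr_length = 816, marker_spacing = 16,
               n_individuals = 200, n_per_generation = 200)
  cfg2 <- do.call(sim_config, c(base, list(n_generations = 3, seed = 21)))
  cfg8 <- do.call(sim_config, c(base, list(n_generations = 8, seed = 21)))
  map <- simulate_map(cfg2)
  diff_frac <- function(g) {
    chr <- map$chr
    same_chr <- chr[-length(chr)] == chr[-1]
    d <- g$geno[, -1, drop = FALSE] != g$geno[, -ncol(g$geno), drop = FALSE]
    colMeans(d)[same_chr]
  }
  f2 <- diff_frac(simulate_ail_genotypes(map, cfg2))
  f8 <- diff_frac(simulate_ail_genotypes(map, cfg8))
  expect_gte(length(f2), 200)                       # adjacent pairs compared
  expect_gt(mean(f8), mean(f2))
})

test_that("seeded genotype simulation is bit-reproducible", {
  cfg <- small_config(n = 50, seed = 9)
  map <- simulate_map(cfg)
  g1 <- simulate_ail_genotypes(map, cfg)
  g2 <- simulate_ail_genotypes(map, cfg)
  expect_identical(g1$geno, g2$geno)
  expect_identical(g1$family, g2$family)
  g3 <- simulate_ail_genotypes(map, cfg, seed = 10)
  expect_false(identical(g1$geno, g3$geno))
})

test_that("quantitative trait generator matches its model", {
  cfg <- small_config(n = 300, seed = 31)
  map <- simulate_map(cfg)
  g <- simulate_ail_genotypes(map, cfg)

  ## pure noise: variance ~ 1
  ph0 <- simulate_quantitative_trait(g, map, list(), noise_sd = 1,
                                     trait_name = "y", seed = 1)
  expect_lt(abs(var(ph0$y) - 1), 0.15)
  expect_equal(attr(ph0, "genetic_value"), rep(0, 300))

  ## noise-free single QTL: exactly 3 values separated by the allele dose
  q <- qtl_spec("2", 60, additive_effect = 1, dominance_effect = 0)
  ph1 <- simulate_quantitative_trait(g, map, q, noise_sd = 0,
                                     trait_name = "y", seed = 2)
  expect_equal(sort(unique(ph1$y)), c(-1, 0, 1))
  expect_equal(ph1$y, g$geno[, nearest <- which(map$chr == "2" & map$pos == 60)] - 1,
               ignore_attr = TRUE)

  ## off-map QTL errors
  expect_error(simulate_quantitative_trait(g, map, qtl_spec("9", 10),
                                           trait_name = "y"), "off the map")

  ## PVE targeting: realized R2 within [5%, 15%] across replicates
  q2 <- qtl_spec("3", 100, additive_effect = 0.5)
  r2 <- replicate(50, {
    s <- sample.int(1e6, 1)
    gg <- simulate_ail_genotypes(map, cfg, seed = s)
    nsd <- noise_sd_for_pve(gg, map, q2, 0.10)
    ph <- simulate_quantitative_trait(gg, map, q2, noise_sd = nsd,
                                      trait_name = "y", seed = s + 1)
    summary(lm(ph$y ~ attr(ph, "genetic_value")))$r.squared
  })
  expect_gt(mean(r2), 0.05)
  expect_lt(mean(r2), 0.15)
})

test_that("trait generator PVE converges to its target at large n", {
  cfg <- sim_config(n_individuals = 1000, n_per_generation = 1000, seed = 5)
  map <- simulate_map(cfg)
  q <- qtl_spec("1", 100, additive_effect = 1)
  pve <- replicate(20, {
    s <- sample.int(1e6, 1)
    g <- simulate_ail_genotypes(map, cfg, seed = s)
    nsd <- noise_sd_for_pve(g, map, q, 0.10)
    ph <- simulate_quantitative_trait(g, map, q, noise_sd = nsd,
                                      trait_name = "y", seed = s + 1)
    summary(lm(ph$y ~ attr(ph, "genetic_value")))$r.squared
  })
  expect_lt(abs(mean(pve) - 0.10), 0.03)
})

test_that("expression simulator plants recoverable architecture", {
  cfg <- small_config(n = 200, seed = 41)
  map <- simulate_map(cfg)
  g <- simulate_ail_genotypes(map, cfg)

  ## variance decomposition with no genetic effects
  pp <- data.frame(probe = sprintf("p%03d", 1:100),
                   chr = rep("1", 100), pos = seq(0, 198, 2))
  spec0 <- expression_spec(pp, cis_effects = 0, batch_effect_sd = 0.3,
                           noise_sd = 0.5)
  ex0 <- simulate_expression_matrix(g, map, spec0, seed = 8)
  pv <- apply(ex0$values, 1, var)
  expect_lt(abs(mean(pv) - (0.5^2 + 0.3^2)), 0.05)
  expect_true(all(ex0$truth$class == "none"))

  ## planted trans regulator on another chromosome is labeled trans
  spec1 <- expression_spec(data.frame(probe = "tp", chr = "1", pos = 50),
    trans_pairs = data.frame(probe = "tp", chr = "4", pos = 120, effect = 2),
    batch_effect_sd = 0, noise_sd = 0.5)
  ex1 <- simulate_expression_matrix(g, map, spec1, seed = 9)
  expect_equal(ex1$truth$class, "trans")
  expect_equal(ex1$truth$qtl_chr, "4")

  ## unknown chromosome errors
  expect_error(simulate_expression_matrix(g, map,
    expression_spec(data.frame(probe = "x", chr = "99", pos = 1)), seed = 1),
    "unknown chromosome")
})

test_that("outline population generator is the inverse of the EFA chain", {
  cfg <- small_config(n = 150, seed = 51)
  map <- simulate_map(cfg)
  g <- simulate_ail_genotypes(map, cfg)
  mean_cf <- efa_decompose(blob_outline(3), H = 6)
  sq <- qtl_spec("2", 60)

  ## no effect, no noise: all outlines identical to the mean reconstruction
  o0 <- simulate_outline_population(g, sq, mean_cf, effect_vector = 0,
                                    noise_sd = 0, n_points = 120, seed = 1)
  ref <- efa_reconstruct(mean_cf, k = 120)
  expect_true(all(vapply(o0, function(o) max(abs(o$points - ref$points)), 1) < 1e-12))

  ## pure first-harmonic mean: ellipse of aspect ratio 2
  ell_cf <- structure(list(a = c(2, 0), b = c(0, 0), c = c(0, 0), d = c(1, 0),
                           A0 = 0, C0 = 0, T = 2 * pi, H = 2L), class = "efa")
  oe <- simulate_outline_population(g, sq, ell_cf, effect_vector = 0,
                                    noise_sd = 0, n_points = 360, seed = 2)
  asp <- diff(range(oe[[1]]$points[, 1])) / diff(range(oe[[1]]$points[, 2]))
  expect_lt(abs(asp - 2), 0.01)

  ## noise-free effect on one coefficient: PC1 collinear with allele dose
  eff <- numeric(4 * mean_cf$H); eff[2] <- 0.05
  o1 <- simulate_outline_population(g, sq, mean_cf, effect_vector = eff,
                                    noise_sd = 0, n_points = 150, seed = 3)
  coeffs <- lapply(o1, efa_decompose, H = mean_cf$H)
  pca <- shape_pca(efa_coefficient_matrix(coeffs))
  expect_gt(abs(cor(pca$scores[, 1], attr(o1, "dose"))), 0.99)

  ## degenerate mean errors
  bad <- structure(list(a = 0, b = 0, c = 0, d = 0, A0 = 0, C0 = 0,
                        T = 2 * pi, H = 1L), class = "efa")
  expect_error(simulate_outline_population(g, sq, bad), "degenerate")
})
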