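## Shared fixture builders. Everything is generated in code, seeded.

## small scan substrate: 5 chromosomes x 200 cM, 10 cM spacing
small_config <- function(n = 300, seed = 1) {
  sim_config(n_chromosomes = 5, chr_length = 200, marker_spacing = 10,
             n_individuals = n, n_per_generation = n, seed = seed)
}

small_map <- function() simulate_map(small_config())

## one-trait cross with an optional planted QTL
sim_trait_cross <- function(seed, qtl = NULL, pve = 0.10, n = 300,
                            covariate_effects = list(), map = NULL, cfg = NULL) {
  cfg <- cfg %||% small_config(n = n, seed = seed)
  map <- map %||% simulate_map(cfg)
  g <- simulate_ail_genotypes(map, cfg, seed = seed)
  if (is.null(qtl)) {
    ph <- simulate_quantitative_trait(g, map, list(), covariate_effects,
                                      noise_sd = 1, trait_name = "y",
                                      seed = seed + 1)
  } else {
    nsd <- noise_sd_for_pve(g, map, qtl, pve)
    ph <- simulate_quantitative_trait(g, map, qtl, covariate_effects,
                                      noise_sd = nsd, trait_name = "y",
                                      seed = seed + 1)
  }
  list(cross = make_cross(g, ph), geno = g, map = map,
       genetic_value = attr(ph, "genetic_value"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## smooth closed test shapes
ellipse_outline <- function(a = 2, b = 1, n = 500) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  outline(cbind(a * cos(th), b * sin(th)))
}

blob_outline <- function(seed = 1, n = 400, irregularity = 0.15) {
  set.seed(seed)
  amp <- stats::rnorm(3, 0, irregularity)
  ph <- stats::runif(3, 0, 2 * pi)
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- 1 + amp[1] * cos(2 * th + ph[1]) + amp[2] * cos(3 * th + ph[2]) +
    amp[3] * cos(5 * th + ph[3])
  outline(cbind(r * cos(th), r * sin(th)))
}

## independent numeric-integration oracle for the Fourier coefficients of a
## parametric closed curve x(u), y(u), u in [0, 2*pi) traversed uniformly
fourier_oracle <- function(xfun, yfun, H, n_grid = 20000) {
  u <- seq(0, 2 * pi, length.out = n_grid + 1)[-(n_grid + 1)]
  du <- 2 * pi / n_grid
  x <- xfun(u); y <- yfun(u)
  res <- list(a = numeric(H), b = numeric(H), c = numeric(H), d = numeric(H),
              A0 = mean(x), C0 = mean(y))
  for (n in seq_len(H)) {
    res$a[n] <- sum(x * cos(n * u)) * du / pi
    res$b[n] <- sum(x * sin(n * u)) * du / pi
    res$c[n] <- sum(y * cos(n * u)) * du / pi
    res$d[n] <- sum(y * sin(n * u)) * du / pi
  }
  res
}

## run expr under a temporary seed, restoring the caller's RNG stream
with_seed_local <- function(seed, expr) combqtl:::with_seed(seed, expr)

## one draw of the random-region placement process used by the
## enrichment null (same placement rule, one iteration)
place_regions <- function(n, len, genome) {
  p <- combqtl:::place_random_regions(n, len, genome, 1)
  genomic_intervals(names(genome)[p$chr[1, ]], p$start[1, ], p$end[1, ])
}
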