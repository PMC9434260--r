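#' Simulation configuration for the advanced intercross
#'
#' Bundles the parameters of the simulated study design: the marker map
#' (number of chromosomes, chromosome length, inter-marker spacing in cM),
#' the breeding design (number of intercross generations, founder pairs,
#' intermediate and final population sizes) and the master RNG seed.
#'
#' The full-scale design mirrors the real intercross (a ~9,200 cM map with
#' ~16 cM marker spacing scanned in 326 F8 birds); the default is a
#' scaled-down version (5 chromosomes x 200 cM, 10 cM spacing, n = 300)
#' sized for routine simulation studies.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chr_length Chromosome length in cM (recycled across chromosomes).
#' @param marker_spacing Inter-marker distance in cM; markers sit on a
#'   regular grid from 0 to `chr_length`.
#' @param n_generations Intercross generation of the mapped individuals
#'   (2 = F1, 8 = F8).
#' @param n_founder_pairs Number of founder dam/sire pairs.
#' @param n_individuals Number of individuals in the final mapped generation.
#' @param n_per_generation Population size of the intermediate generations
#'   (F1 .. F(g-1)); defaults to `n_individuals`.
#' @param bp_per_cm Physical distance assigned per cM (deterministic affine
#'   cM-to-bp bridge), default 300 kb/cM.
#' @param seed Master RNG seed.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_chromosomes = 2, chr_length = 100, marker_spacing = 20)
#' @export
sim_config <- function(n_chromosomes = 5, chr_length = 200, marker_spacing = 10,
                       n_generations = 8, n_founder_pairs = 10,
                       n_individuals = 300, n_per_generation = n_individuals,
                       bp_per_cm = 3e5, seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chr_length = rep_len(as.numeric(chr_length), n_chromosomes),
              marker_spacing = as.numeric(marker_spacing),
              n_generations = as.integer(n_generations),
              n_founder_pairs = as.integer(n_founder_pairs),
              n_individuals = as.integer(n_individuals),
              n_per_generation = as.integer(n_per_generation),
              bp_per_cm = as.numeric(bp_per_cm),
              seed = as.integer(seed))
  if (cfg$n_generations < 2L)
    stop_("n_generations must be >= 2 (F1 is generation 2)")
  if (!is.finite(cfg$marker_spacing) || cfg$marker_spacing <= 0)
    stop_("marker_spacing must be > 0")
  if (any(cfg$chr_length < cfg$marker_spacing))
    stop_("chr_length must be >= marker_spacing")
  if (cfg$n_founder_pairs < 1L) stop_("need at least one founder pair")
  if (cfg$n_individuals < 1L) stop_("n_individuals must be >= 1")
  structure(cfg, class = "sim_config")
}

#' Full-scale simulation configuration
#'
#' The study-scale design: 10 chromosomes x 920 cM with 16 cM spacing
#' (580 markers over 9,200 cM) and 326 F8 individuals.
#'
#' @param seed Master RNG seed.
#' @return A `sim_config`.
#' @export
sim_config_full <- function(seed = 1L) {
  sim_config(n_chromosomes = 10, chr_length = 920, marker_spacing = 16,
             n_generations = 8, n_founder_pairs = 20,
             n_individuals = 326, n_per_generation = 326, seed = seed)
}

#' Build an evenly spaced genetic map
#'
#' Places markers on a regular cM grid per chromosome and assigns each a
#' deterministic physical position (`cM * bp_per_cm`).
#'
#' @param config A [sim_config()].
#' @return A `genetic_map`: data frame with columns `marker`, `chr`
#'   (character), `pos` (cM) and `bp`.
#' @examples
#' m <- simulate_map(sim_config(n_chromosomes = 1, chr_length = 100,
#'                              marker_spacing = 20))
#' nrow(m)  # 6 markers at 0, 20, ..., 100
#' @export
simulate_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  chrs <- lapply(seq_len(config$n_chromosomes), function(i) {
    pos <- seq(0, config$chr_length[i], by = config$marker_spacing)
    data.frame(marker = sprintf("c%dm%03d", i, seq_along(pos)),
               chr = as.character(i), pos = pos,
               bp = round(pos * config$bp_per_cm),
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, chrs)
  rownames(map) <- NULL
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("Genetic map: %d markers on %d chromosomes, %.0f cM total\n",
              nrow(x), length(unique(x$chr)),
              sum(tapply(x$pos, x$chr, max))))
  invisible(x)
}

## Validate a genetic_map-shaped data frame (also used by the cross reader).
validate_map <- function(map) {
  stopifnot(all(c("marker", "chr", "pos") %in% names(map)))
  if (anyDuplicated(map$marker)) stop_("duplicated marker names in map")
  for (ch in unique(map$chr)) {
    p <- map$pos[map$chr == ch]
    if (any(diff(p) <= 0))
      stop_("marker positions not strictly increasing on chromosome ", ch)
  }
  invisible(map)
}

#' Haldane map function
#'
#' Converts a map distance in cM to a recombination fraction assuming no
#' crossover interference: `r = (1 - exp(-2 d / 100)) / 2`.
#'
#' @param d Map distance in cM (vectorised, must be non-negative).
#' @return Recombination fraction in `[0, 0.5)`.
#' @examples
#' haldane_recomb(16)  # ~0.1369
#' @export
haldane_recomb <- function(d) {
  if (any(d < 0)) stop_("map distance must be non-negative")
  (1 - exp(-2 * d / 100)) / 2
}
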