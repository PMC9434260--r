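#' Simulate advanced intercross genotypes
#'
#' Breeds an advanced intercross line (AIL) forward from two differentially
#' fixed founder lines -- a Red Junglefowl-like line carrying the `R` allele
#' at every marker and a White Leghorn-like line carrying `W` -- and returns
#' marker genotypes for the final generation. Meiosis follows Haldane's model
#' (no crossover interference), under which the allele-origin process along a
#' marker grid is an exact Markov chain with switch probability
#' [haldane_recomb()] of the inter-marker distance, so gametes are simulated
#' directly at the marker loci. Mating from F2 on is random between distinct
#' dams and sires (no selfing), with uniform litter contributions.
#'
#' @param map A `genetic_map` from [simulate_map()].
#' @param config A [sim_config()]; `n_generations = 2` yields F1 individuals
#'   (all heterozygous), `8` the F8 of the study design.
#' @param seed RNG seed; defaults to `config$seed`.
#' @return A `marker_genotypes` object: list with `geno` (individuals x
#'   markers integer matrix counting `W` alleles, 0/1/2), `sex` (factor F/M),
#'   `family` (dam identity in the penultimate generation, the population-
#'   structure covariate), `generation`, and the `map`.
#' @examples
#' cfg <- sim_config(n_chromosomes = 1, chr_length = 100, marker_spacing = 20,
#'                   n_individuals = 20, n_per_generation = 20)
#' g <- simulate_ail_genotypes(simulate_map(cfg), cfg)
#' table(g$geno)
#' @export
simulate_ail_genotypes <- function(map, config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  validate_map(map)
  if (nrow(map) == 0L) stop_("empty map")
  n_gen <- config$n_generations
  if (n_gen > 2L && config$n_per_generation < 2L)
    stop_("cannot breed beyond F1 without at least 2 individuals per generation (no selfing)")

  ## switch probability entering each marker: 0.5 at a chromosome start
  ## (random choice of parental haplotype), Haldane r elsewhere
  chr_first <- !duplicated(map$chr)
  p_switch <- numeric(nrow(map))
  p_switch[chr_first] <- 0.5
  d <- diff(map$pos)
  p_switch[!chr_first] <- haldane_recomb(d[diff(as.integer(factor(map$chr,
    levels = unique(map$chr)))) == 0])

  M <- nrow(map)
  gamete <- function(h1, h2) {
    ## h1, h2: n x M parental haplotype matrices (allele 0 = R, 1 = W)
    n <- nrow(h1)
    sw <- matrix(stats::runif(n * M), n, M) < rep(p_switch, each = n)
    state <- sw
    for (j in which(!chr_first)) state[, j] <- xor(state[, j - 1L], sw[, j])
    h1 + state * (h2 - h1)
  }

  with_seed(seed, {
    ## F1: every individual has one R and one W haplotype
    n1 <- if (n_gen == 2L) config$n_individuals else config$n_per_generation
    H1 <- matrix(0L, n1, M)
    H2 <- matrix(1L, n1, M)
    sex <- rep_len(c("F", "M"), n1)
    dam_of <- rep(NA_integer_, n1)
    if (n_gen > 2L) {
      for (g in 3L:n_gen) {
        n_off <- if (g == n_gen) config$n_individuals else config$n_per_generation
        dams <- which(sex == "F"); sires <- which(sex == "M")
        if (!length(dams) || !length(sires))
          stop_("a generation lacks one sex; increase n_per_generation")
        dam <- dams[sample.int(length(dams), n_off, replace = TRUE)]
        sire <- sires[sample.int(length(sires), n_off, replace = TRUE)]
        Hm <- gamete(H1[dam, , drop = FALSE], H2[dam, , drop = FALSE])
        Hp <- gamete(H1[sire, , drop = FALSE], H2[sire, , drop = FALSE])
        H1 <- Hm; H2 <- Hp
        dam_of <- dam
        sex <- sample(rep_len(c("F", "M"), n_off))
      }
    }
    geno <- H1 + H2
    dimnames(geno) <- list(sprintf("ind%03d", seq_len(nrow(geno))), map$marker)
    fam <- if (all(is.na(dam_of))) rep("fam1", nrow(geno))
           else sprintf("fam%03d", dam_of)
    structure(list(geno = geno,
                   sex = factor(sex, levels = c("F", "M")),
                   family = factor(fam),
                   generation = n_gen,
                   map = map),
              class = "marker_genotypes")
  })
}

#' @export
print.marker_genotypes <- function(x, ...) {
  cat(sprintf("F%d intercross genotypes: %d individuals x %d markers\n",
              x$generation, nrow(x$geno), ncol(x$geno)))
  invisible(x)
}

#' Genotype codes from allele counts
#'
#' @param geno Integer matrix/vector of `W` allele counts (0, 1, 2).
#' @return Character codes `RR`, `RW`, `WW` (NA preserved).
#' @export
geno_codes <- function(geno) {
  out <- c("RR", "RW", "WW")[as.integer(geno) + 1L]
  if (is.matrix(geno)) out <- matrix(out, nrow(geno), dimnames = dimnames(geno))
  out
}

## nearest marker (row index of map) to a chromosome/position; ties -> lower pos
nearest_marker <- function(map, chr, pos) {
  i <- which(map$chr == as.character(chr))
  if (!length(i)) stop_("chromosome ", chr, " not on map")
  i[which.min(abs(map$pos[i] - pos))]
}
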