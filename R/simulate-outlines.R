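#' Simulate a population of genotype-dependent outlines
#'
#' Generative inverse of the morphometrics chain: each individual's elliptic
#' Fourier coefficient vector is the population mean plus its allele dose at
#' the shape QTL times an effect vector in coefficient space, plus Gaussian
#' coefficient noise; the outline is the inverse Fourier reconstruction.
#' Planted shape QTL are therefore recoverable by
#' trace/interpolate/EFA/PCA/scan.
#'
#' @param genotypes A `marker_genotypes` object.
#' @param shape_qtl A [qtl_spec()] giving the locus whose allele dose
#'   (`x_a = -1, 0, +1`) moves the coefficients.
#' @param mean_coeffs An `efa` object: the population mean shape (its first
#'   harmonic must carry positive power).
#' @param effect_vector Numeric vector of length `4H` (order
#'   `a1..aH, b1..bH, c1..cH, d1..dH`): coefficient shift per allele dose.
#' @param noise_sd SD of i.i.d. Gaussian noise added to every coefficient.
#' @param n_points Points per reconstructed outline.
#' @param seed RNG seed.
#' @return List of [outline()]s with attributes `dose` (allele doses) and
#'   `coeff_matrix` (the true per-individual coefficient vectors).
#' @export
simulate_outline_population <- function(genotypes, shape_qtl, mean_coeffs,
                                        effect_vector = 0, noise_sd = 0,
                                        n_points = 200, seed = NULL) {
  stopifnot(inherits(genotypes, "marker_genotypes"),
            inherits(mean_coeffs, "efa"))
  p1 <- (mean_coeffs$a[1]^2 + mean_coeffs$b[1]^2 +
           mean_coeffs$c[1]^2 + mean_coeffs$d[1]^2) / 2
  if (!is.finite(p1) || p1 <= 0)
    stop_("mean coefficients are degenerate: first harmonic has no power")
  H <- mean_coeffs$H
  mu <- efa_to_vector(mean_coeffs)
  eff <- rep_len(effect_vector, 4 * H)
  map <- genotypes$map
  m <- nearest_marker(map, shape_qtl$chromosome, shape_qtl$position)
  dose <- genotypes$geno[, m] - 1
  n <- length(dose)
  with_seed(seed, {
    noise <- matrix(stats::rnorm(n * 4 * H, 0, noise_sd), n)
    cm <- matrix(mu, n, 4 * H, byrow = TRUE) + outer(dose, eff) + noise
    outlines <- lapply(seq_len(n), function(i)
      efa_reconstruct(vector_to_efa(cm[i, ], mean_coeffs), k = n_points))
    attr(outlines, "dose") <- dose
    attr(outlines, "coeff_matrix") <- cm
    outlines
  })
}
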