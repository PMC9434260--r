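#' Specify a simulated QTL
#'
#' Holds the location and the additive (`a`, per `W`-allele dose) and
#' dominance (`d`) effects of a planted quantitative trait locus.
#'
#' @param chromosome Chromosome id (matching the map).
#' @param position Position in cM.
#' @param additive_effect Additive effect `a`: phenotype shift per allele
#'   dose, coded `x_a = -1, 0, +1` for `RR`, `RW`, `WW`.
#' @param dominance_effect Dominance effect `d`, coded `x_d = 1` for
#'   heterozygotes.
#' @param trait_name Trait the QTL acts on.
#' @return A `qtl_spec` list.
#' @export
qtl_spec <- function(chromosome, position, additive_effect = 0,
                     dominance_effect = 0, trait_name = "trait") {
  structure(list(chromosome = as.character(chromosome),
                 position = as.numeric(position),
                 additive_effect = as.numeric(additive_effect),
                 dominance_effect = as.numeric(dominance_effect),
                 trait_name = trait_name),
            class = "qtl_spec")
}

## additive/dominance codings from a W-allele count vector/matrix
dose_codes <- function(g) list(xa = g - 1, xd = as.numeric(g == 1))

## deterministic balanced batch assignment shared by trait and expression sims
assign_batches <- function(n, n_batches = 3L)
  factor(rep_len(sprintf("b%d", seq_len(n_batches)), n))

#' Simulate a quantitative trait on intercross genotypes
#'
#' Realises the scan model `y = mu + covariates + a x_a + d x_d + e`: each
#' planted QTL contributes through the marker nearest its position, sex and
#' batch enter as balanced categorical covariates, family (population
#' structure) as a random per-family shift, weight as a continuous covariate,
#' and noise is i.i.d. Gaussian.
#'
#' @param genotypes A `marker_genotypes` object.
#' @param map The genetic map the genotypes were simulated on.
#' @param qtls A single [qtl_spec()] or list of them (positions must be on
#'   the map).
#' @param covariate_effects Named list of covariate coefficients:
#'   `sex` (shift for males), `batch` (vector of per-batch shifts),
#'   `family_sd` (SD of per-family random shifts), `weight` (slope on
#'   centred weight). All default to 0.
#' @param noise_sd Residual SD.
#' @param trait_name Column name for the phenotype.
#' @param mu Trait mean.
#' @param seed RNG seed.
#' @return A `phenotype_table` data frame with columns `id`, `sex`, `batch`,
#'   `family`, `weight` and the trait; the per-individual true genetic value
#'   is attached as attribute `genetic_value`.
#' @export
simulate_quantitative_trait <- function(genotypes, map, qtls,
                                        covariate_effects = list(),
                                        noise_sd = 1, trait_name = "trait",
                                        mu = 0, seed = NULL) {
  stopifnot(inherits(genotypes, "marker_genotypes"))
  if (inherits(qtls, "qtl_spec")) qtls <- list(qtls)
  n <- nrow(genotypes$geno)
  gvalue <- numeric(n)
  for (q in qtls) {
    i <- which(map$chr == q$chromosome)
    if (!length(i) || q$position < min(map$pos[i]) - 1e-9 ||
        q$position > max(map$pos[i]) + 1e-9)
      stop_("QTL at ", q$chromosome, ":", q$position, " is off the map")
    m <- nearest_marker(map, q$chromosome, q$position)
    dc <- dose_codes(genotypes$geno[, m])
    gvalue <- gvalue + q$additive_effect * dc$xa + q$dominance_effect * dc$xd
  }
  ce <- utils::modifyList(list(sex = 0, batch = 0, family_sd = 0, weight = 0),
                          covariate_effects)
  with_seed(seed, {
    batch <- assign_batches(n)
    weight <- stats::rnorm(n, 1500, 150)
    fam_eff <- stats::rnorm(nlevels(genotypes$family), 0, ce$family_sd)
    cov_part <- ce$sex * (genotypes$sex == "M") +
      rep_len(ce$batch, nlevels(batch))[as.integer(batch)] +
      fam_eff[as.integer(genotypes$family)] +
      ce$weight * (weight - mean(weight))
    y <- mu + gvalue + cov_part + stats::rnorm(n, 0, noise_sd)
    out <- data.frame(id = rownames(genotypes$geno), sex = genotypes$sex,
                      batch = batch, family = genotypes$family,
                      weight = weight, stringsAsFactors = FALSE)
    out[[trait_name]] <- y
    attr(out, "genetic_value") <- gvalue
    class(out) <- c("phenotype_table", "data.frame")
    out
  })
}

#' Residual SD that targets a given proportion of variance explained
#'
#' Given realised genotypes at the marker nearest a planted QTL, returns the
#' noise SD under which the QTL explains approximately `pve` of the trait
#' variance (covariate-free design).
#'
#' @param genotypes A `marker_genotypes` object.
#' @param map Genetic map.
#' @param qtl A [qtl_spec()].
#' @param pve Target proportion of variance explained, in (0, 1).
#' @return Noise SD.
#' @export
noise_sd_for_pve <- function(genotypes, map, qtl, pve) {
  stopifnot(pve > 0, pve < 1)
  m <- nearest_marker(map, qtl$chromosome, qtl$position)
  dc <- dose_codes(genotypes$geno[, m])
  vg <- stats::var(qtl$additive_effect * dc$xa + qtl$dominance_effect * dc$xd)
  if (vg <= 0) stop_("QTL has zero genetic variance at the nearest marker")
  sqrt(vg * (1 - pve) / pve)
}

#' Specify a simulated expression architecture
#'
#' @param probe_positions Data frame with columns `probe`, `chr`, `pos`
#'   (cM; optional `bp`) placing each probe on the map.
#' @param cis_effects Per-probe cis effect size (recycled); 0 = no cis eQTL.
#'   A cis effect acts through the marker nearest the probe itself.
#' @param trans_pairs Data frame with columns `probe`, `chr`, `pos`,
#'   `effect`: trans effects acting through the marker nearest a regulator
#'   position elsewhere on the map.
#' @param batch_effect_sd SD of per-probe, per-batch shifts.
#' @param noise_sd Residual SD of expression.
#' @param baseline_mean,baseline_sd Distribution of per-probe baselines
#'   (log2-scale array units).
#' @return An `expression_spec` list.
#' @export
expression_spec <- function(probe_positions, cis_effects = 0,
                            trans_pairs = NULL, batch_effect_sd = 0.2,
                            noise_sd = 0.5, baseline_mean = 8,
                            baseline_sd = 1) {
  stopifnot(is.data.frame(probe_positions),
            all(c("probe", "chr", "pos") %in% names(probe_positions)),
            nrow(probe_positions) >= 1L)
  if (anyDuplicated(probe_positions$probe)) stop_("duplicated probe ids")
  structure(list(probe_positions = probe_positions,
                 cis_effects = rep_len(cis_effects, nrow(probe_positions)),
                 trans_pairs = trans_pairs,
                 batch_effect_sd = batch_effect_sd, noise_sd = noise_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd),
            class = "expression_spec")
}

#' Simulate an expression matrix with planted cis and trans eQTL
#'
#' Expression of probe `p` in individual `j` is
#' `baseline_p + cis_p x_a(nearest marker to p) + sum of trans terms +
#' batch_pj + noise`, with the same deterministic batch assignment used by
#' [simulate_quantitative_trait()] so that expression and phenotype
#' covariates agree.
#'
#' @param genotypes A `marker_genotypes` object.
#' @param map Genetic map.
#' @param spec An [expression_spec()].
#' @param seed RNG seed.
#' @return An `expression_matrix` object: list with `values` (probes x
#'   individuals), `annotation` (probe, chr, pos, bp) and `truth` (probe,
#'   planted class `cis`/`trans`/`none`, and the planted locus).
#' @export
simulate_expression_matrix <- function(genotypes, map, spec, seed = NULL) {
  stopifnot(inherits(spec, "expression_spec"))
  ann <- spec$probe_positions
  bad <- setdiff(unique(ann$chr), unique(map$chr))
  if (length(bad)) stop_("probe on unknown chromosome: ", paste(bad, collapse = ", "))
  if (!is.null(spec$trans_pairs)) {
    badt <- setdiff(unique(spec$trans_pairs$chr), unique(map$chr))
    if (length(badt)) stop_("trans regulator on unknown chromosome: ",
                            paste(badt, collapse = ", "))
  }
  n <- nrow(genotypes$geno)
  P <- nrow(ann)
  batch <- assign_batches(n)
  with_seed(seed, {
    vals <- matrix(stats::rnorm(P * n, 0, spec$noise_sd), P, n,
                   dimnames = list(ann$probe, rownames(genotypes$geno)))
    baseline <- stats::rnorm(P, spec$baseline_mean, spec$baseline_sd)
    vals <- vals + baseline
    truth_class <- rep("none", P)
    truth_chr <- rep(NA_character_, P); truth_pos <- rep(NA_real_, P)
    for (p in seq_len(P)) {
      if (spec$cis_effects[p] != 0) {
        m <- nearest_marker(map, ann$chr[p], ann$pos[p])
        vals[p, ] <- vals[p, ] + spec$cis_effects[p] * (genotypes$geno[, m] - 1)
        truth_class[p] <- "cis"
        truth_chr[p] <- map$chr[m]; truth_pos[p] <- map$pos[m]
      }
    }
    if (!is.null(spec$trans_pairs)) {
      tp <- spec$trans_pairs
      for (k in seq_len(nrow(tp))) {
        p <- match(tp$probe[k], ann$probe)
        if (is.na(p)) stop_("trans pair names unknown probe: ", tp$probe[k])
        m <- nearest_marker(map, tp$chr[k], tp$pos[k])
        vals[p, ] <- vals[p, ] + tp$effect[k] * (genotypes$geno[, m] - 1)
        if (truth_class[p] == "none") {
          truth_class[p] <- "trans"
          truth_chr[p] <- map$chr[m]; truth_pos[p] <- map$pos[m]
        }
      }
    }
    if (spec$batch_effect_sd > 0) {
      be <- matrix(stats::rnorm(P * nlevels(batch), 0, spec$batch_effect_sd),
                   P, nlevels(batch))
      vals <- vals + be[, as.integer(batch)]
    }
    if (is.null(ann$bp)) ann$bp <- NA_real_
    structure(list(values = vals, annotation = ann,
                   truth = data.frame(probe = ann$probe, class = truth_class,
                                      qtl_chr = truth_chr, qtl_pos = truth_pos,
                                      stringsAsFactors = FALSE),
                   batch = batch),
              class = "expression_matrix")
  })
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d probes x %d individuals (%d planted cis, %d trans)\n",
              nrow(x$values), ncol(x$values),
              sum(x$truth$class == "cis"), sum(x$truth$class == "trans")))
  invisible(x)
}
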