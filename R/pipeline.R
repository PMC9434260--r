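#' Default pipeline configuration
#'
#' A scaled-down version of the study design used for simulation studies:
#' 5 chromosomes x 200 cM with 10 cM marker spacing and 300 F8 individuals,
#' one planted size QTL, one shape QTL acting on outline coefficients, and a
#' small expression panel with planted cis and trans eQTL.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @return A nested configuration list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = seed,
    sim = list(n_chromosomes = 5, chr_length = 200, marker_spacing = 10,
               n_generations = 8, n_founder_pairs = 10, n_individuals = 300),
    trait = list(name = "area", chromosome = "3", position = 100,
                 additive_effect = 1, dominance_effect = 0.25, pve = 0.10),
    shape = list(chromosome = "2", position = 60, effect = 0.06,
                 noise_sd = 0.01, n_points = 200, harmonics = 8),
    expression = list(n_probes = 30, n_cis = 3, n_trans = 2,
                      cis_effect = 1.5, trans_effect = 1.5, noise_sd = 0.5),
    scan = list(covariates = c("sex", "batch", "weight"), n_perm = 500,
                quantiles = c(0.95, 0.80), drop = 1.8),
    coloc = list(iterations = 2000)
  )
}

#' Run the full simulate/morpho/scan/escan/coloc pipeline
#'
#' Orchestrates every stage on one seeded configuration: simulates the
#' intercross and its phenotypes, generates and re-measures comb-like
#' outlines (render, trace, interpolate, EFA, PCA), interval-maps the size
#' trait and the shape PC scores, maps the expression panel, overlaps QTL
#' and eQTL confidence intervals and runs the enrichment permutation test.
#' All stage outputs and a manifest (parameters, seeds, package version)
#' are written to `outdir`; a re-run with the same configuration reproduces
#' the tables exactly.
#'
#' @param config Configuration list (see [default_pipeline_config()]) or a
#'   path to a YAML file with the same structure.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = default_pipeline_config(), outdir = tempfile("run")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop_("config must provide a seed")
  cfg <- utils::modifyList(default_pipeline_config(config$seed), config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  ## -- simulate ------------------------------------------------------------
  scfg <- do.call(sim_config, c(cfg$sim, list(seed = derive_seed(cfg$seed, "sim"))))
  map <- simulate_map(scfg)
  geno <- simulate_ail_genotypes(map, scfg)
  tq <- qtl_spec(cfg$trait$chromosome, cfg$trait$position,
                 cfg$trait$additive_effect, cfg$trait$dominance_effect,
                 cfg$trait$name)
  nsd <- noise_sd_for_pve(geno, map, tq, cfg$trait$pve)
  phen <- simulate_quantitative_trait(geno, map, tq,
                                      covariate_effects = list(sex = 0.3 * nsd),
                                      noise_sd = nsd, trait_name = cfg$trait$name,
                                      seed = derive_seed(cfg$seed, "trait"))
  ## comb-like mean shape: a squashed ellipse with a ripple (finger-like)
  mean_shape <- comb_like_coeffs(cfg$shape$harmonics)
  shape_q <- qtl_spec(cfg$shape$chromosome, cfg$shape$position)
  eff <- numeric(4 * cfg$shape$harmonics); eff[2] <- cfg$shape$effect
  outlines <- simulate_outline_population(geno, shape_q, mean_shape, eff,
                                          noise_sd = cfg$shape$noise_sd,
                                          n_points = cfg$shape$n_points,
                                          seed = derive_seed(cfg$seed, "shape"))
  expr <- simulate_expression_panel(geno, map, cfg$expression,
                                    seed = derive_seed(cfg$seed, "expr"))

  write_expression_csv(expr, file.path(outdir, "expression.csv"))
  write_outlines_csv(outlines, file.path(outdir, "outlines.csv"))

  ## -- morphometrics -------------------------------------------------------
  interp <- lapply(outlines, interpolate_outline, k = cfg$shape$n_points)
  aligned <- align_outlines(interp)
  coeffs <- lapply(aligned$outlines, efa_decompose, H = cfg$shape$harmonics)
  pca <- shape_pca(efa_coefficient_matrix(coeffs))
  phen$PC1 <- pca$scores[, 1]
  phen$PC2 <- pca$scores[, 2]

  ## -- qtl scan ------------------------------------------------------------
  cross <- make_cross(geno, phen)
  write_cross_csv(cross, file.path(outdir, "cross.csv"))
  probs <- genotype_probabilities(cross)
  peaks <- list(); scans <- list()
  for (tr in c(cfg$trait$name, "PC1", "PC2")) {
    sc <- hk_scan(cross, tr, cfg$scan$covariates, probs = probs)
    pm <- perm_thresholds(cross, tr, cfg$scan$covariates,
                          n_perm = cfg$scan$n_perm,
                          quantiles = cfg$scan$quantiles,
                          seed = derive_seed(cfg$seed, paste0("perm_", tr)),
                          probs = probs)
    best <- sc[which.max(sc$lod), ]
    if (best$lod >= min(pm$thresholds)) {
      pk <- qtl_fit(cross, tr, cfg$scan$covariates, best$chr, best$pos,
                    probs = probs, scan = sc, perms = pm, drop = cfg$scan$drop)
      peaks[[tr]] <- data.frame(trait = tr, marker = pk$marker %||% NA,
                                chr = pk$chr, pos = pk$pos, lod = pk$lod,
                                p_value = pk$p_value,
                                ci_start = pk$ci$start, ci_end = pk$ci$end,
                                add_effect = pk$additive, add_se = pk$additive_se,
                                dom_effect = pk$dominance, dom_se = pk$dominance_se,
                                pct_var = pk$pct_var, stringsAsFactors = FALSE)
    }
    scans[[tr]] <- sc
  }
  scan_tab <- data.frame(as.data.frame(scans[[1]])[c("chr", "pos", "marker")],
                         sapply(scans, function(s) s$lod))
  utils::write.csv(scan_tab, file.path(outdir, "scans.csv"), row.names = FALSE)
  peaks_tab <- if (length(peaks)) do.call(rbind, peaks) else NULL
  if (!is.null(peaks_tab))
    utils::write.csv(peaks_tab, file.path(outdir, "peaks.csv"), row.names = FALSE)

  ## -- eqtl scan -----------------------------------------------------------
  eqtl <- scan_expression(cross, expr, n_perm = cfg$scan$n_perm,
                          seed = derive_seed(cfg$seed, "escan"), probs = probs)
  utils::write.csv(as.data.frame(eqtl), file.path(outdir, "eqtl.csv"),
                   row.names = FALSE)

  ## -- colocalization ------------------------------------------------------
  coloc <- NULL
  if (!is.null(peaks_tab) && nrow(eqtl) > 0) {
    qtl_iv <- genomic_intervals(peaks_tab$chr, peaks_tab$ci_start,
                                peaks_tab$ci_end, peaks_tab$trait)
    eqtl_iv <- genomic_intervals(eqtl$chr, eqtl$ci_start, eqtl$ci_end,
                                 eqtl$probe)
    ov <- find_overlaps(qtl_iv, eqtl_iv)
    genome <- stats::setNames(tapply(map$pos, map$chr, max), unique(map$chr))
    enr <- enrichment_permutation(
      n_a = nrow(qtl_iv), len_a = mean(qtl_iv$end - qtl_iv$start),
      n_b = nrow(eqtl_iv), len_b = mean(eqtl_iv$end - eqtl_iv$start),
      genome = genome, observed = length(unique(ov$b)),
      iterations = cfg$coloc$iterations,
      seed = derive_seed(cfg$seed, "coloc"))
    qtl_bp <- do.call(rbind, lapply(seq_len(nrow(peaks_tab)), function(i)
      map_ci_to_physical(peaks_tab$chr[i], peaks_tab$ci_start[i],
                         peaks_tab$ci_end[i], map, peaks_tab$trait[i])))
    attr(qtl_bp, "axis") <- "bp"
    write_regions_bed(qtl_bp, file.path(outdir, "qtl_ci.bed"))
    jsonlite::write_json(list(observed = enr$observed, p_value = enr$p_value,
                              iterations = enr$parameters$iterations),
                         file.path(outdir, "enrichment.json"),
                         auto_unbox = TRUE, digits = NA)
    coloc <- list(overlaps = ov, enrichment = enr)
  }

  manifest <- list(package = "combqtl",
                   version = as.character(utils::packageVersion("combqtl")),
                   seed = cfg$seed,
                   stage_seeds = list(sim = derive_seed(cfg$seed, "sim"),
                                      trait = derive_seed(cfg$seed, "trait"),
                                      shape = derive_seed(cfg$seed, "shape"),
                                      expr = derive_seed(cfg$seed, "expr"),
                                      escan = derive_seed(cfg$seed, "escan"),
                                      coloc = derive_seed(cfg$seed, "coloc")),
                   config = cfg)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(cross = cross, scans = scans, peaks = peaks_tab, pca = pca,
                 eqtl = eqtl, coloc = coloc, outdir = outdir))
}

## A smooth comb-like mean outline: wide ellipse with a dorsal ripple.
comb_like_coeffs <- function(H = 8) {
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  r <- 1 + 0.15 * sin(3 * th)
  pts <- cbind(1.6 * r * cos(th), r * sin(th))
  efa_decompose(outline(pts), H = H)
}

## Expression panel with planted cis and trans architecture.
simulate_expression_panel <- function(geno, map, ecfg, seed) {
  with_seed(seed, {
    chrs <- unique(map$chr)
    chr_len <- tapply(map$pos, map$chr, max)
    pchr <- sample(chrs, ecfg$n_probes, replace = TRUE)
    pp <- data.frame(probe = sprintf("probe%03d", seq_len(ecfg$n_probes)),
                     chr = pchr,
                     pos = stats::runif(ecfg$n_probes) * chr_len[pchr],
                     stringsAsFactors = FALSE)
    cis_eff <- numeric(ecfg$n_probes)
    cis_eff[seq_len(ecfg$n_cis)] <- ecfg$cis_effect
    tp <- NULL
    if (ecfg$n_trans > 0) {
      ti <- ecfg$n_cis + seq_len(ecfg$n_trans)
      reg_chr <- vapply(pp$chr[ti], function(ch) sample(setdiff(chrs, ch), 1), "")
      tp <- data.frame(probe = pp$probe[ti], chr = reg_chr,
                       pos = stats::runif(ecfg$n_trans, 0, min(
                         tapply(map$pos, map$chr, max))),
                       effect = ecfg$trans_effect, stringsAsFactors = FALSE)
    }
    spec <- expression_spec(pp, cis_effects = cis_eff, trans_pairs = tp,
                            noise_sd = ecfg$noise_sd)
    simulate_expression_matrix(geno, map, spec,
                               seed = derive_seed(seed, "matrix"))
  })
}
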