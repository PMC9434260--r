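#' Genome-wide eQTL scan with cis/trans classification
#'
#' Treats every expression probe as a phenotype and interval-maps it with
#' [hk_scan()] (batch as the default fixed covariate, the study's model),
#' applies permutation thresholds, and emits one record per probe whose
#' genome-wide maximum LOD reaches the suggestive (0.80-quantile) threshold.
#' Records carry the significance tier, a [lod_drop_interval()] support
#' interval, and the cis/trans label from [classify_cis_trans()]. One seeded
#' set of permutation index vectors is shared across probes, so every probe
#' is judged against a null built from the same label shufflings.
#'
#' @param cross A [cross_data()] whose individuals match the expression
#'   columns.
#' @param expr An `expression_matrix` from [simulate_expression_matrix()],
#'   or a plain probes x individuals matrix plus `annotation`.
#' @param annotation Probe annotation data frame (`probe`, `chr`, `pos`);
#'   taken from `expr` when it is an `expression_matrix`. Probes absent from
#'   it (or on chromosomes off the map) are scanned but left unclassified.
#' @param covariates Covariate column names (default `"batch"` when present
#'   in the cross covariates, else none).
#' @param n_perm Permutations for the shared threshold null (default 1000).
#' @param quantiles Significant and suggestive quantiles (default
#'   `c(0.95, 0.80)`).
#' @param window cis window in cM (default 50): a peak is cis when the probe
#'   lies on the peak chromosome within this distance of the peak marker.
#' @param drop LOD drop for support intervals (default 1.8).
#' @param seed RNG seed for the shared permutations.
#' @param probs Optional precomputed `genoprob`.
#' @return An `eqtl_records` data frame: `probe`, `class` (cis/trans/`NA`),
#'   `tier` (significant/suggestive), `peak_marker`, `chr`, `pos`, `lod`,
#'   `p_value`, `ci_start`, `ci_end`.
#' @export
scan_expression <- function(cross, expr, annotation = NULL,
                            covariates = if ("batch" %in% names(cross$covar)) "batch" else NULL,
                            n_perm = 1000, quantiles = c(0.95, 0.80),
                            window = 50, drop = 1.8, seed = NULL,
                            probs = NULL) {
  if (inherits(expr, "expression_matrix")) {
    annotation <- annotation %||% expr$annotation
    values <- expr$values
  } else values <- as.matrix(expr)
  if (nrow(values) < 1) stop_("empty expression matrix")
  if (!is.null(colnames(values))) {
    mismatch <- c(setdiff(colnames(values), cross$ids),
                  setdiff(cross$ids, colnames(values)))
    if (length(mismatch))
      stop_("individual ids mismatch between expression and cross: ",
            paste(utils::head(mismatch, 10), collapse = ", "))
    values <- values[, cross$ids, drop = FALSE]
  } else if (ncol(values) != nrow(cross$geno))
    stop_("expression matrix has ", ncol(values), " individuals; cross has ",
          nrow(cross$geno))
  if (is.null(probs)) probs <- genotype_probabilities(cross)
  n <- nrow(cross$geno)
  perm_index <- with_seed(seed, t(replicate(n_perm, sample.int(n))))
  records <- list()
  for (p in seq_len(nrow(values))) {
    y <- values[p, ]
    pd <- prepare_scan(cross, trait = rownames(values)[p] %||% paste0("probe", p),
                       covariates, NULL, probs, y = y)
    lod <- scan_core(pd$z, pd$rss0, pd$Q0, pd$A, pd$D, pd$n)
    pi_use <- if (pd$n == n) perm_index
              else with_seed(seed, t(replicate(n_perm, sample.int(pd$n))))
    maxima <- perm_scan_maxima(pd, pi_use)
    thr <- stats::quantile(maxima, quantiles, type = 7)
    best <- which.max(lod)
    if (lod[best] < min(thr)) next
    scan <- cbind(pd$positions, lod = lod)
    class(scan) <- c("hk_scan", "data.frame")
    ci <- lod_drop_interval(scan, pd$positions$chr[best], pd$positions$pos[best],
                            drop, cross$map)
    probe_id <- rownames(values)[p] %||% paste0("probe", p)
    ann_row <- if (!is.null(annotation)) match(probe_id, annotation$probe) else NA
    cls <- if (!is.na(ann_row))
      classify_cis_trans(pd$positions$chr[best], pd$positions$pos[best],
                         annotation$chr[ann_row], annotation$pos[ann_row],
                         window = window,
                         map_chrs = unique(cross$map$chr))
    else NA_character_
    records[[length(records) + 1L]] <- data.frame(
      probe = probe_id, class = cls,
      tier = if (lod[best] >= max(thr)) "significant" else "suggestive",
      peak_marker = pd$positions$marker[best] %||% NA,
      chr = pd$positions$chr[best], pos = pd$positions$pos[best],
      lod = lod[best], p_value = mean(maxima >= lod[best]),
      ci_start = ci$start, ci_end = ci$end, stringsAsFactors = FALSE)
  }
  out <- if (length(records)) do.call(rbind, records)
         else data.frame(probe = character(), class = character(),
                         tier = character(), peak_marker = character(),
                         chr = character(), pos = numeric(), lod = numeric(),
                         p_value = numeric(), ci_start = numeric(),
                         ci_end = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "window") <- window
  attr(out, "n_perm") <- n_perm
  class(out) <- c("eqtl_records", "data.frame")
  out
}

#' Classify an eQTL peak as cis (local) or trans
#'
#' A peak is cis when the probe lies on the same chromosome as the peak
#' marker and within `window` cM of it (boundary inclusive: a distance of
#' exactly `window` is cis); everything else placed on the map is trans.
#' Probes on chromosomes absent from the map are unclassifiable (`NA`).
#'
#' @param peak_chr,peak_pos Peak marker location (vectorised).
#' @param probe_chr,probe_pos Probe location.
#' @param window cis distance in cM (default 50).
#' @param map_chrs Optional chromosome namespace; probes outside it are
#'   `NA`.
#' @return Character vector `"cis"`/`"trans"`/`NA`.
#' @export
classify_cis_trans <- function(peak_chr, peak_pos, probe_chr, probe_pos,
                               window = 50, map_chrs = NULL) {
  out <- ifelse(as.character(probe_chr) == as.character(peak_chr) &
                  abs(probe_pos - peak_pos) <= window, "cis", "trans")
  unplaced <- is.na(probe_chr) | is.na(probe_pos)
  if (!is.null(map_chrs))
    unplaced <- unplaced | !(as.character(probe_chr) %in% as.character(map_chrs))
  out[unplaced] <- NA_character_
  out
}

#' @export
print.eqtl_records <- function(x, ...) {
  cat(sprintf("%d eQTL (%d significant, %d suggestive; %d cis, %d trans)\n",
              nrow(x), sum(x$tier == "significant"), sum(x$tier == "suggestive"),
              sum(x$class == "cis", na.rm = TRUE),
              sum(x$class == "trans", na.rm = TRUE)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  invisible(x)
}
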