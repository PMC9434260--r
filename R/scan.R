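#' Haley-Knott genome scan
#'
#' Interval mapping by regression of a phenotype on expected additive and
#' dominance dosages. At each evaluation position the LOD score is
#' `(n/2) * log10(RSS0 / RSS1)`, where the null model regresses the trait on
#' an intercept plus the additive covariates (plus the interacting
#' covariate's main effect when given) and the full model adds `x_a`, `x_d`
#' (and their interactions with the interacting covariate). Individuals
#' missing the trait or any covariate are dropped listwise; missing
#' genotypes are handled upstream by the hidden Markov model of
#' [genotype_probabilities()].
#'
#' @param cross A [cross_data()].
#' @param trait Phenotype column name.
#' @param covariates Character vector of covariate column names entering
#'   additively (e.g. `c("sex", "batch", "family", "weight")`), or `NULL`.
#' @param intcovar Optional name of one covariate interacting with the QTL
#'   (the study scanned sex this way); its main effect joins the null model.
#' @param probs A `genoprob` object (computed if omitted).
#' @param step,error_prob Passed to [genotype_probabilities()] when `probs`
#'   is omitted.
#' @return An `hk_scan` object: data frame with columns `chr`, `pos`,
#'   `marker`, `lod`, carrying the model descriptor and sample size as
#'   attributes. Methods: `print`, `summary`, `plot`, `max`.
#' @seealso [perm_thresholds()] for genome-wide significance,
#'   [lod_drop_interval()] for support intervals, [qtl_fit()] for effect
#'   estimates at a peak.
#' @export
hk_scan <- function(cross, trait, covariates = NULL, intcovar = NULL,
                    probs = NULL, step = 0, error_prob = 1e-4) {
  pd <- prepare_scan(cross, trait, covariates, intcovar, probs, step, error_prob)
  lod <- if (is.null(intcovar)) {
    scan_core(pd$z, pd$rss0, pd$Q0, pd$A, pd$D, pd$n)
  } else {
    scan_core_int(pd$y, pd$X0, pd$A, pd$D, pd$IC, pd$n)
  }
  out <- cbind(pd$positions, lod = lod)
  attr(out, "trait") <- trait
  attr(out, "covariates") <- covariates
  attr(out, "intcovar") <- intcovar
  attr(out, "n") <- pd$n
  class(out) <- c("hk_scan", "data.frame")
  out
}

## Shared model preparation: listwise deletion, covariate design, dosages.
prepare_scan <- function(cross, trait, covariates, intcovar = NULL,
                         probs = NULL, step = 0, error_prob = 1e-4,
                         y = NULL) {
  stopifnot(inherits(cross, "cross_data"))
  if (is.null(y)) {
    if (!trait %in% names(cross$pheno)) stop_("unknown trait: ", trait)
    y <- cross$pheno[[trait]]
  }
  y <- as.numeric(y)
  all_cov <- unique(c(covariates, intcovar))
  missing_cov <- setdiff(all_cov, names(cross$covar))
  if (length(missing_cov)) stop_("unknown covariates: ",
                                 paste(missing_cov, collapse = ", "))
  cv <- cross$covar[all_cov]
  keep <- !is.na(y)
  if (length(all_cov)) keep <- keep & stats::complete.cases(cv)
  if (sum(keep) < length(all_cov) + 4L) stop_("too few complete observations")
  y <- y[keep]
  if (stats::var(y) == 0) stop_("trait '", trait, "' has zero variance")
  if (is.null(probs)) probs <- genotype_probabilities(cross, step, error_prob)
  A <- probs$xa[keep, , drop = FALSE]
  D <- probs$xd[keep, , drop = FALSE]
  n <- sum(keep)
  if (length(all_cov)) {
    cv <- droplevels(as.data.frame(lapply(cv[keep, , drop = FALSE], function(col)
      if (is.character(col)) factor(col) else col)))
    X0 <- stats::model.matrix(~ ., data = cv)
    qx <- qr(X0)
    if (qx$rank < ncol(X0)) {
      bad <- colnames(X0)[qx$pivot[(qx$rank + 1):ncol(X0)]]
      stop_("collinear covariate design; offending column(s): ",
            paste(bad, collapse = ", "))
    }
  } else X0 <- matrix(1, n, 1)
  Q0 <- qr.Q(qr(X0))
  z <- y - Q0 %*% crossprod(Q0, y)
  IC <- NULL
  if (!is.null(intcovar)) {
    icv <- cross$covar[[intcovar]][keep]
    if (is.character(icv)) icv <- factor(icv)
    IC <- if (is.factor(icv)) stats::model.matrix(~ icv)[, -1, drop = FALSE]
          else matrix(as.numeric(icv), ncol = 1)
  }
  list(y = y, z = as.numeric(z), rss0 = sum(z^2), Q0 = Q0, X0 = X0,
       A = A, D = D, IC = IC, n = n, positions = probs$positions,
       probs = probs, keep = keep)
}

## Vectorised Haley-Knott LOD over all positions (no QTL-covariate
## interactions). A, D: n x m dosage matrices; Q0 orthonormal null basis.
scan_core <- function(z, rss0, Q0, A, D, n) {
  Ar <- A - Q0 %*% crossprod(Q0, A)
  Dr <- D - Q0 %*% crossprod(Q0, D)
  u1 <- as.numeric(crossprod(Ar, z))
  u2 <- as.numeric(crossprod(Dr, z))
  S11 <- colSums(Ar^2); S22 <- colSums(Dr^2); S12 <- colSums(Ar * Dr)
  lod_from_quadform(u1, u2, S11, S22, S12, rss0, n)
}

## Solve the per-position 2x2 normal equations and convert to LOD,
## falling back to a single regressor when the pair is (near-)collinear.
lod_from_quadform <- function(u1, u2, S11, S22, S12, rss0, n) {
  det <- S11 * S22 - S12^2
  scale <- pmax(S11 * S22, .Machine$double.eps)
  qf <- ifelse(det > 1e-10 * scale,
               (u1^2 * S22 - 2 * u1 * u2 * S12 + u2^2 * S11) / det,
               pmax(ifelse(S11 > 1e-12, u1^2 / S11, 0),
                    ifelse(S22 > 1e-12, u2^2 / S22, 0)))
  rss1 <- pmax(rss0 - qf, rss0 * 1e-12)
  pmax((n / 2) * log10(rss0 / rss1), 0)
}

## Generic per-position least squares for interacting-covariate scans.
scan_core_int <- function(y, X0, A, D, IC, n) {
  rss0 <- sum(stats::lsfit(cbind(X0), y, intercept = FALSE)$residuals^2)
  m <- ncol(A)
  lod <- numeric(m)
  for (j in seq_len(m)) {
    G <- cbind(A[, j], D[, j], A[, j] * IC, D[, j] * IC)
    r <- stats::lsfit(cbind(X0, G), y, intercept = FALSE)$residuals
    rss1 <- max(sum(r^2), rss0 * 1e-12)
    lod[j] <- max((n / 2) * log10(rss0 / rss1), 0)
  }
  lod
}

#' @export
print.hk_scan <- function(x, ...) {
  cat(sprintf("Haley-Knott scan of '%s': %d positions, n = %d\n",
              attr(x, "trait"), nrow(x), attr(x, "n")))
  if (!is.null(attr(x, "covariates")))
    cat("  covariates:", paste(attr(x, "covariates"), collapse = ", "), "\n")
  if (!is.null(attr(x, "intcovar")))
    cat("  interacting covariate:", attr(x, "intcovar"), "\n")
  m <- x[which.max(x$lod), ]
  cat(sprintf("  max LOD %.2f at chr %s, %.1f cM\n", m$lod, m$chr, m$pos))
  invisible(x)
}

#' @export
summary.hk_scan <- function(object, threshold = 0, ...) {
  peaks <- do.call(rbind, lapply(split(as.data.frame(object), object$chr),
                                 function(d) d[which.max(d$lod), ]))
  peaks <- peaks[peaks$lod >= threshold, ]
  peaks[order(-peaks$lod), ]
}

#' @export
max.hk_scan <- function(x, ..., na.rm = FALSE) {
  as.data.frame(x)[which.max(x$lod), ]
}

#' @export
plot.hk_scan <- function(x, ...) {
  chrs <- unique(x$chr)
  offs <- c(0, cumsum(tapply(x$pos, factor(x$chr, levels = chrs), max) + 10))
  xpos <- x$pos + offs[match(x$chr, chrs)]
  graphics::plot(xpos, x$lod, type = "l", xlab = "position (cM, chromosomes concatenated)",
                 ylab = "LOD", ...)
  graphics::abline(v = offs[-1] - 5, col = "grey80", lty = 3)
  invisible(x)
}

#' Genome-wide permutation LOD thresholds
#'
#' Builds the null distribution of the genome-wide maximum LOD by shuffling
#' individual labels: trait and covariate rows are permuted jointly against
#' the genotypes, the scan is re-run, and the maximum LOD recorded, 1,000
#' times by default. Thresholds are empirical quantiles (0.95 genome-wide
#' significant, 0.80 suggestive, the study's convention) with the linear
#' interpolation quantile rule; the genome-wide p-value of an observed peak
#' is the fraction of permutation maxima at or above it.
#'
#' @inheritParams hk_scan
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param quantiles Quantiles of the null maxima to report (default
#'   `c(0.95, 0.80)`).
#' @param seed RNG seed for the permutations.
#' @param perm_index Optional precomputed permutation matrix
#'   (`n_perm` rows, one permutation of `1:n` each); used by the expression
#'   scan to share one null across probes.
#' @return A `scan_perms` object: `thresholds` (named by quantile),
#'   `maxima`, `n_perm`.
#' @export
perm_thresholds <- function(cross, trait, covariates = NULL, n_perm = 1000,
                            quantiles = c(0.95, 0.80), seed = NULL,
                            intcovar = NULL, probs = NULL, step = 0,
                            error_prob = 1e-4, perm_index = NULL) {
  if (n_perm < 100) stop_("n_perm must be >= 100")
  if (any(quantiles <= 0 | quantiles >= 1)) stop_("quantiles must be in (0, 1)")
  pd <- prepare_scan(cross, trait, covariates, intcovar, probs, step, error_prob)
  if (is.null(perm_index))
    perm_index <- with_seed(seed, t(replicate(n_perm, sample.int(pd$n))))
  stopifnot(ncol(perm_index) == pd$n)
  maxima <- perm_scan_maxima(pd, perm_index, intcovar)
  thresholds <- stats::quantile(maxima, quantiles, type = 7)
  structure(list(thresholds = thresholds, maxima = maxima,
                 n_perm = nrow(perm_index), quantiles = quantiles),
            class = "scan_perms")
}

## genome-wide maxima of permuted scans; fast path without interactions
perm_scan_maxima <- function(pd, perm_index, intcovar = NULL) {
  n_perm <- nrow(perm_index)
  maxima <- numeric(n_perm)
  if (is.null(intcovar)) {
    ## With y and covariates permuted jointly against genotypes, RSS0 and
    ## the dosage cross products G'G are permutation-invariant; only the
    ## projections of the (effectively) permuted dosages onto the null
    ## space and onto the null residual change.
    A <- pd$A; D <- pd$D; Q0 <- pd$Q0; z <- pd$z; rss0 <- pd$rss0; n <- pd$n
    AA <- colSums(A^2); DD <- colSums(D^2); AD <- colSums(A * D)
    for (i in seq_len(n_perm)) {
      p <- perm_index[i, ]
      zp <- z[p]
      Qp <- Q0[p, , drop = FALSE]
      u1 <- as.numeric(crossprod(A, zp))
      u2 <- as.numeric(crossprod(D, zp))
      QtA <- crossprod(Qp, A); QtD <- crossprod(Qp, D)
      S11 <- AA - colSums(QtA^2)
      S22 <- DD - colSums(QtD^2)
      S12 <- AD - colSums(QtA * QtD)
      maxima[i] <- max(lod_from_quadform(u1, u2, S11, S22, S12, rss0, n))
    }
  } else {
    for (i in seq_len(n_perm)) {
      p <- perm_index[i, ]
      maxima[i] <- max(scan_core_int(pd$y[p],
                                     pd$X0[p, , drop = FALSE],
                                     pd$A, pd$D,
                                     pd$IC[p, , drop = FALSE], pd$n))
    }
  }
  maxima
}

#' @export
print.scan_perms <- function(x, ...) {
  cat(sprintf("Permutation null of the genome-wide max LOD (%d permutations)\n",
              x$n_perm))
  for (i in seq_along(x$thresholds))
    cat(sprintf("  %s threshold: %.2f\n", names(x$thresholds)[i], x$thresholds[i]))
  invisible(x)
}

#' Genome-wide empirical p-value of an observed LOD peak
#'
#' Fraction of permutation maxima greater than or equal to the observed LOD
#' (ties count as exceeding).
#'
#' @param perms A `scan_perms` object.
#' @param lod Observed LOD score(s).
#' @return Empirical p-value(s).
#' @export
genome_scan_pvalue <- function(perms, lod) {
  vapply(lod, function(l) mean(perms$maxima >= l), 0)
}

#' LOD-drop support interval
#'
#' Walks outward from a LOD peak until the curve first falls more than
#' `drop` LOD units below the peak (1.8 by default, comparable to a 95%
#' confidence interval in intercrosses) and reports the outermost positions
#' still within the drop, snapped to the closest map markers (equidistant
#' ties resolve to the lower position).
#'
#' @param scan An `hk_scan` result.
#' @param chr Chromosome of the peak.
#' @param pos Peak position (must be on the scan grid).
#' @param drop LOD units to drop (default 1.8).
#' @param map Genetic map used for marker snapping (defaults to the scan
#'   grid's marker positions).
#' @return List with `start`, `end` (cM), `start_marker`, `end_marker`.
#' @export
lod_drop_interval <- function(scan, chr, pos, drop = 1.8, map = NULL) {
  d <- scan[scan$chr == as.character(chr), ]
  if (!nrow(d)) stop_("chromosome ", chr, " not in scan")
  ipk <- which(abs(d$pos - pos) < 1e-8)
  if (!length(ipk)) stop_("peak position ", pos, " is not on the scan grid")
  ipk <- ipk[1]
  thr <- d$lod[ipk] - drop
  lo <- ipk
  while (lo > 1 && d$lod[lo - 1] >= thr) lo <- lo - 1
  hi <- ipk
  while (hi < nrow(d) && d$lod[hi + 1] >= thr) hi <- hi + 1
  snap <- function(p) {
    if (is.null(map)) {
      md <- d[!is.na(d$marker), ]
      if (!nrow(md)) md <- d
    } else md <- map[map$chr == as.character(chr), ]
    i <- which.min(abs(md$pos - p))     # which.min takes the first = lower tie
    list(pos = md$pos[i], marker = if (!is.null(md$marker)) md$marker[i] else NA)
  }
  s <- snap(d$pos[lo]); e <- snap(d$pos[hi])
  list(start = s$pos, end = e$pos,
       start_marker = s$marker, end_marker = e$marker)
}

#' Fit the QTL model at a peak and estimate effects
#'
#' Least-squares fit of the full Haley-Knott model at one position,
#' returning additive and dominance effect estimates with standard errors
#' and the percent variance explained (partial R-squared of the genotype
#' dosages given the covariates, times 100).
#'
#' @inheritParams hk_scan
#' @param chr,pos Peak location (must be on the evaluation grid).
#' @param scan Optional `hk_scan` used to attach the LOD and a
#'   [lod_drop_interval()] support interval.
#' @param perms Optional `scan_perms` used to attach the genome-wide
#'   p-value.
#' @param drop LOD drop for the support interval (default 1.8).
#' @return A `qtl_peak` object with `coef` and `print` methods.
#' @export
qtl_fit <- function(cross, trait, covariates = NULL, chr, pos,
                    probs = NULL, scan = NULL, perms = NULL, drop = 1.8,
                    step = 0, error_prob = 1e-4) {
  pd <- prepare_scan(cross, trait, covariates, NULL, probs, step, error_prob)
  j <- which(pd$positions$chr == as.character(chr) &
               abs(pd$positions$pos - pos) < 1e-8)
  if (!length(j)) stop_("peak ", chr, ":", pos, " is not on the evaluation grid")
  j <- j[1]
  G <- cbind(add = pd$A[, j], dom = pd$D[, j])
  fit <- stats::lm(pd$y ~ pd$X0 + G - 1)
  sm <- summary(fit)$coefficients
  rows <- grep("Gadd|Gdom", rownames(sm))
  est <- sm[rows, , drop = FALSE]
  rss1 <- sum(fit$residuals^2)
  pve <- 100 * (pd$rss0 - rss1) / pd$rss0
  lod <- (pd$n / 2) * log10(pd$rss0 / max(rss1, pd$rss0 * 1e-12))
  ci <- if (!is.null(scan)) lod_drop_interval(scan, chr, pos, drop, cross$map)
  peak_marker <- pd$positions$marker[j]
  structure(list(trait = attr(scan, "trait") %||% trait,
                 marker = peak_marker, chr = as.character(chr), pos = pos,
                 lod = lod,
                 p_value = if (!is.null(perms)) genome_scan_pvalue(perms, lod),
                 ci = ci,
                 additive = est[1, 1], additive_se = est[1, 2],
                 dominance = est[2, 1], dominance_se = est[2, 2],
                 pct_var = pve, n = pd$n),
            class = "qtl_peak")
}

#' @export
coef.qtl_peak <- function(object, ...) {
  c(additive = object$additive, dominance = object$dominance)
}

#' @export
print.qtl_peak <- function(x, ...) {
  cat(sprintf("QTL for '%s' at %s (chr %s, %.1f cM)\n",
              x$trait, x$marker %||% "-", x$chr, x$pos))
  cat(sprintf("  LOD %.2f%s\n", x$lod,
              if (!is.null(x$p_value)) sprintf(", genome-wide p = %.3g", x$p_value) else ""))
  if (!is.null(x$ci))
    cat(sprintf("  %0.4g-%0.4g cM support interval (markers %s-%s)\n",
                x$ci$start, x$ci$end, x$ci$start_marker, x$ci$end_marker))
  cat(sprintf("  additive %.4g +/- %.3g, dominance %.4g +/- %.3g, %%var %.2f\n",
              x$additive, x$additive_se, x$dominance, x$dominance_se, x$pct_var))
  invisible(x)
}
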