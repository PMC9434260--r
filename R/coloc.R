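#' Genomic interval set
#'
#' A set of closed intervals on either the genetic (cM) or physical (bp)
#' axis. Intervals are closed on both ends: touching endpoints overlap,
#' matching marker-snapped confidence intervals.
#'
#' @param chrom Chromosome ids.
#' @param start,end Interval bounds (`start <= end`).
#' @param label Optional labels.
#' @param axis `"cM"` or `"bp"`.
#' @return A `genomic_intervals` data frame with attribute `axis`.
#' @export
genomic_intervals <- function(chrom, start, end, label = NULL,
                              axis = c("cM", "bp")) {
  axis <- match.arg(axis)
  if (any(start > end)) stop_("interval start exceeds end")
  out <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                    end = as.numeric(end),
                    label = label %||% sprintf("iv%d", seq_along(chrom)),
                    stringsAsFactors = FALSE)
  attr(out, "axis") <- axis
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

#' Convert a cM confidence interval to physical coordinates
#'
#' Maps each endpoint of a genetic-map confidence interval to the physical
#' position of its closest marker (equidistant ties resolve to the
#' lower-position marker), the rule used to place QTL and eQTL confidence
#' intervals on the genome for overlap analysis.
#'
#' @param chr Chromosome of the interval.
#' @param start,end Interval bounds in cM.
#' @param map Genetic map with a `bp` column.
#' @param label Optional label.
#' @return A one-row `genomic_intervals` on the bp axis.
#' @export
map_ci_to_physical <- function(chr, start, end, map, label = NULL) {
  if (is.null(map$bp) || all(is.na(map$bp))) stop_("map has no bp positions")
  i <- which(map$chr == as.character(chr))
  if (!length(i)) stop_("no markers on chromosome ", chr)
  snap <- function(p) map$bp[i][which.min(abs(map$pos[i] - p))]
  bp <- sort(c(snap(start), snap(end)))
  genomic_intervals(chr, bp[1], bp[2], label = label, axis = "bp")
}

#' All overlapping pairs between two interval sets
#'
#' Reports every pair `(i, j)` where interval `i` of `a` and interval `j`
#' of `b` share a chromosome and intersect (closed intervals, so touching
#' endpoints count). The search is a per-chromosome vectorised sweep over
#' start-sorted intervals.
#'
#' @param a,b `genomic_intervals` on the same axis.
#' @return Data frame with columns `a`, `b` (row indices), duplicate-free.
#' @export
find_overlaps <- function(a, b) {
  ax_a <- attr(a, "axis") %||% "cM"; ax_b <- attr(b, "axis") %||% "cM"
  if (!identical(ax_a, ax_b)) stop_("interval sets are on different axes (",
                                    ax_a, " vs ", ax_b, ")")
  res_a <- integer(0); res_b <- integer(0)
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == ch); ib <- which(b$chrom == ch)
    ## sweep b over a sorted by start: candidates are a-intervals whose
    ## start is <= b's end; among those, keep ends >= b's start
    oa <- ia[order(a$start[ia])]
    sa <- a$start[oa]; ea <- a$end[oa]
    hi <- findInterval(b$end[ib], sa)
    for (k in seq_along(ib)) {
      if (hi[k] < 1) next
      cand <- seq_len(hi[k])
      hit <- cand[ea[cand] >= b$start[ib[k]]]
      if (length(hit)) {
        res_a <- c(res_a, oa[hit])
        res_b <- c(res_b, rep(ib[k], length(hit)))
      }
    }
  }
  out <- data.frame(a = res_a, b = res_b)
  out[order(out$a, out$b), , drop = FALSE]
}

#' Random-region permutation test of overlap enrichment
#'
#' Tests whether an observed number of overlaps between two interval sets
#' exceeds chance: each iteration places `n_a` regions of length `len_a`
#' and `n_b` regions of length `len_b` uniformly on the genome (starts
#' uniform on the concatenated chromosomes, shifted back where a region
#' would run off a chromosome end) and counts overlaps; the one-tailed
#' p-value is `(1 + #\{null >= observed\}) / (1 + iterations)`. The study
#' design used 10 QTL-sized vs 1,184 eQTL-sized regions (and 645
#' sweep-sized regions) over 10,000 iterations.
#'
#' @param n_a,len_a Number and (mean) length of the first region set.
#' @param n_b,len_b Number and (mean) length of the second set.
#' @param genome Named vector of chromosome lengths.
#' @param observed Observed overlap count under `count_rule`.
#' @param iterations Number of random placements (>= 100; default 10000).
#' @param seed RNG seed.
#' @param count_rule `"b_overlapping_a"` (default: number of `b` regions
#'   overlapping at least one `a` region) or `"pairs"` (all overlapping
#'   pairs).
#' @return An `enrichment_result`: `observed`, `null_counts`, `p_value`,
#'   `parameters`.
#' @export
enrichment_permutation <- function(n_a, len_a, n_b, len_b, genome, observed,
                                   iterations = 10000, seed = NULL,
                                   count_rule = c("b_overlapping_a", "pairs")) {
  count_rule <- match.arg(count_rule)
  if (iterations < 100) stop_("iterations must be >= 100")
  if (is.null(names(genome))) names(genome) <- as.character(seq_along(genome))
  if (max(len_a, len_b) > max(genome)) stop_("region length exceeds every chromosome")
  if (observed < 0 || (count_rule == "b_overlapping_a" && observed > n_b))
    stop_("observed count out of range [0, n_b]")
  null_counts <- with_seed(seed,
    null_overlap_counts(n_a, len_a, n_b, len_b, genome, iterations, count_rule))
  p <- (1 + sum(null_counts >= observed)) / (1 + iterations)
  structure(list(observed = observed, null_counts = null_counts, p_value = p,
                 parameters = list(n_a = n_a, len_a = len_a, n_b = n_b,
                                   len_b = len_b, genome = genome,
                                   iterations = iterations, seed = seed,
                                   count_rule = count_rule)),
            class = "enrichment_result")
}

## place n intervals of length len per iteration; returns list of
## iterations x n matrices (chrom index, start, end)
place_random_regions <- function(n, len, genome, iterations) {
  total <- sum(genome)
  cum <- c(0, cumsum(genome))
  s <- stats::runif(iterations * n, 0, total)
  chr <- findInterval(s, cum, rightmost.closed = TRUE)
  within <- s - cum[chr]
  ## shift back so the region fits its chromosome (clamp at 0)
  start <- pmax(pmin(within, genome[chr] - len), 0)
  list(chr = matrix(chr, iterations),
       start = matrix(start, iterations),
       end = matrix(pmin(start + len, genome[chr]), iterations))
}

## vectorised overlap counts across iterations
null_overlap_counts <- function(n_a, len_a, n_b, len_b, genome, iterations,
                                count_rule) {
  A <- place_random_regions(n_a, len_a, genome, iterations)
  B <- place_random_regions(n_b, len_b, genome, iterations)
  if (count_rule == "b_overlapping_a") {
    hit <- matrix(FALSE, iterations, n_b)
    for (j in seq_len(n_a)) {
      hit <- hit | (B$chr == A$chr[, j] & B$start <= A$end[, j] &
                      B$end >= A$start[, j])
    }
    rowSums(hit)
  } else {
    cnt <- integer(iterations)
    for (j in seq_len(n_a)) {
      cnt <- cnt + rowSums(B$chr == A$chr[, j] & B$start <= A$end[, j] &
                             B$end >= A$start[, j])
    }
    cnt
  }
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Overlap enrichment: observed %d vs null mean %.2f (%d iterations)\n",
              x$observed, mean(x$null_counts), x$parameters$iterations))
  cat(sprintf("  one-tailed p = %.4g\n", x$p_value))
  invisible(x)
}

#' @export
plot.enrichment_result <- function(x, ...) {
  graphics::hist(x$null_counts, breaks = 30, main = "Null overlap counts",
                 xlab = "overlaps", ...)
  graphics::abline(v = x$observed, col = "red", lwd = 2)
  invisible(x)
}

#' Correlate expression of an eQTL with a QTL phenotype
#'
#' Pearson correlation (via [stats::cor.test()]) between a probe's
#' expression and a phenotype over paired non-missing observations; the
#' two-sided p comes from the t distribution with n - 2 degrees of freedom.
#' Pairs with p < 0.05 are flagged significant, mirroring how only
#' significant expression-phenotype correlations were retained in the
#' motivating analysis.
#'
#' @param expression Numeric expression vector.
#' @param trait Numeric phenotype vector (same individuals).
#' @param probe,trait_name Labels for the pair.
#' @return A `trait_correlation`: `probe`, `trait`, `r`, `p_value`, `n`,
#'   `significant`.
#' @export
trait_expression_correlation <- function(expression, trait, probe = "probe",
                                         trait_name = "trait") {
  ok <- !is.na(expression) & !is.na(trait)
  if (sum(ok) < 3) stop_("need at least 3 paired non-missing observations")
  e <- expression[ok]; t <- trait[ok]
  if (stats::var(e) == 0 || stats::var(t) == 0)
    stop_("zero variance: correlation undefined")
  ct <- stats::cor.test(e, t, method = "pearson")
  structure(list(probe = probe, trait = trait_name,
                 r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok),
                 significant = ct$p.value < 0.05),
            class = "trait_correlation")
}

#' @export
print.trait_correlation <- function(x, ...) {
  cat(sprintf("%s ~ %s: r = %.3f, p = %.4g (n = %d)%s\n", x$probe, x$trait,
              x$r, x$p_value, x$n, if (x$significant) " *" else ""))
  invisible(x)
}
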