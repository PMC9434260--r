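#' Genotype probabilities along the genome
#'
#' Computes, for every evaluation position, the probability of each of the
#' three intercross genotypes (`RR`, `RW`, `WW`) given the observed marker
#' genotypes, by a three-state forward-backward (hidden Markov) pass per
#' chromosome. Transitions between adjacent positions use F2-type
#' probabilities built from the Haldane recombination fraction of the
#' inter-position distance; emissions allow a small genotyping error rate.
#' The stationary prior is (1/4, 1/2, 1/4). Expected additive and dominance
#' dosages `x_a = P(WW) - P(RR)` and `x_d = P(RW)` are derived for
#' Haley-Knott regression.
#'
#' @param cross A [cross_data()].
#' @param step Pseudomarker grid step in cM; 0 (default) evaluates at the
#'   markers only, matching marker-level scans.
#' @param error_prob Genotyping error probability (default 1e-4).
#' @return A `genoprob` object: `positions` (chr, pos, marker -- `NA` for
#'   pseudomarkers), `prob` (individuals x positions x 3 array), `xa`, `xd`
#'   (individuals x positions dosage matrices).
#' @export
genotype_probabilities <- function(cross, step = 0, error_prob = 1e-4) {
  stopifnot(inherits(cross, "cross_data"))
  map <- cross$map
  n <- nrow(cross$geno)
  chrs <- unique(map$chr)
  pos_list <- list(); prob_list <- list()
  for (ch in chrs) {
    mi <- which(map$chr == ch)
    if (!length(mi)) stop_("chromosome ", ch, " has no markers")
    mpos <- map$pos[mi]
    if (step > 0) {
      grid <- seq(min(mpos), max(mpos), by = step)
      allpos <- sort(unique(c(mpos, grid)))
    } else allpos <- mpos
    at_marker <- match(allpos, mpos)            # NA for pseudomarkers
    P <- length(allpos)
    ## emissions: n x 3 per position
    emis <- vector("list", P)
    for (j in seq_len(P)) {
      if (is.na(at_marker[j])) { emis[[j]] <- NULL; next }
      obs <- cross$geno[, mi[at_marker[j]]]
      E <- matrix(1, n, 3)
      typed <- !is.na(obs)
      if (any(typed)) {
        E[typed, ] <- error_prob / 2
        E[cbind(which(typed), obs[typed] + 1L)] <- 1 - error_prob
      }
      emis[[j]] <- E
    }
    trans <- lapply(seq_len(max(P - 1, 0)), function(j) {
      r <- haldane_recomb(allpos[j + 1] - allpos[j])
      f2_transition(r)
    })
    prior <- c(0.25, 0.5, 0.25)
    ## forward
    alpha <- vector("list", P)
    a <- matrix(prior, n, 3, byrow = TRUE)
    if (!is.null(emis[[1]])) a <- a * emis[[1]]
    a <- a / rowSums(a)
    alpha[[1]] <- a
    for (j in seq_len(P - 1)) {
      a <- alpha[[j]] %*% trans[[j]]
      if (!is.null(emis[[j + 1]])) a <- a * emis[[j + 1]]
      a <- a / rowSums(a)
      alpha[[j + 1]] <- a
    }
    ## backward
    post <- array(NA_real_, c(n, P, 3))
    b <- matrix(1, n, 3)
    post[, P, ] <- alpha[[P]] * b
    for (j in rev(seq_len(P - 1))) {
      be <- b
      if (!is.null(emis[[j + 1]])) be <- be * emis[[j + 1]]
      b <- be %*% t(trans[[j]])
      b <- b / rowSums(b)
      post[, j, ] <- alpha[[j]] * b
    }
    post <- post / array(rowSums(post, dims = 2), c(n, P, 3))
    pos_list[[ch]] <- data.frame(chr = ch, pos = allpos,
                                 marker = map$marker[mi][at_marker],
                                 stringsAsFactors = FALSE)
    prob_list[[ch]] <- post
  }
  positions <- do.call(rbind, pos_list)
  rownames(positions) <- NULL
  prob <- array(NA_real_, c(n, nrow(positions), 3),
                dimnames = list(rownames(cross$geno), NULL,
                                c("RR", "RW", "WW")))
  off <- 0L
  for (ch in chrs) {
    P <- dim(prob_list[[ch]])[2]
    prob[, off + seq_len(P), ] <- prob_list[[ch]]
    off <- off + P
  }
  structure(list(positions = positions, prob = prob,
                 xa = prob[, , 3] - prob[, , 1], xd = prob[, , 2],
                 step = step, error_prob = error_prob),
            class = "genoprob")
}

## F2 genotype transition matrix for recombination fraction r
f2_transition <- function(r) {
  matrix(c((1 - r)^2, 2 * r * (1 - r), r^2,
           r * (1 - r), (1 - r)^2 + r^2, r * (1 - r),
           r^2, 2 * r * (1 - r), (1 - r)^2),
         3, 3, byrow = TRUE)
}

#' @export
print.genoprob <- function(x, ...) {
  cat(sprintf("Genotype probabilities at %d positions (step %g cM, error prob %g)\n",
              nrow(x$positions), x$step, x$error_prob))
  invisible(x)
}
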