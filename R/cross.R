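#' Cross data container
#'
#' Bundles the scan substrate: a genetic map, marker genotypes coded
#' `RR`/`RW`/`WW` (or `NA`), numeric phenotype columns, and covariate
#' columns (sex, batch, family/structure, weight, ...).
#'
#' @param map A `genetic_map` (marker, chr, pos, optional bp).
#' @param genotypes Individuals x markers matrix, either character codes
#'   `RR`/`RW`/`WW` or integer `W`-allele counts 0/1/2; `NA` = missing.
#'   Columns must match the map's markers.
#' @param phenotypes Data frame of numeric traits (one row per individual).
#' @param covariates Data frame of covariates (one row per individual).
#' @return A `cross_data` object.
#' @export
cross_data <- function(map, genotypes, phenotypes = NULL, covariates = NULL) {
  validate_map(map)
  g <- genotypes
  if (is.character(g)) {
    codes <- match(g, c("RR", "RW", "WW")) - 1L
    if (any(!is.na(g) & is.na(codes)))
      stop_("invalid genotype codes: ",
            paste(utils::head(setdiff(unique(g[!is.na(g)]), c("RR", "RW", "WW"))), collapse = ", "))
    g <- matrix(codes, nrow(genotypes), dimnames = dimnames(genotypes))
  }
  g <- as.matrix(g)
  storage.mode(g) <- "integer"
  if (any(!is.na(g) & (g < 0L | g > 2L))) stop_("genotype counts must be 0, 1 or 2")
  if (!identical(colnames(g), map$marker)) {
    if (is.null(colnames(g)) && ncol(g) == nrow(map)) colnames(g) <- map$marker
    else {
      if (!setequal(colnames(g), map$marker))
        stop_("genotype columns do not match map markers")
      g <- g[, map$marker, drop = FALSE]
    }
  }
  n <- nrow(g)
  if (is.null(rownames(g))) rownames(g) <- sprintf("ind%03d", seq_len(n))
  if (!is.null(phenotypes) && nrow(phenotypes) != n)
    stop_("phenotype row count does not match genotypes")
  if (!is.null(covariates) && nrow(covariates) != n)
    stop_("covariate row count does not match genotypes")
  structure(list(map = map, geno = g,
                 pheno = phenotypes %||% data.frame(row.names = seq_len(n)),
                 covar = covariates %||% data.frame(row.names = seq_len(n)),
                 ids = rownames(g)),
            class = "cross_data")
}

#' Assemble a cross from simulated genotypes and phenotypes
#'
#' @param genotypes A `marker_genotypes` object.
#' @param phenotypes One `phenotype_table` (or a list of them sharing
#'   covariates) from [simulate_quantitative_trait()].
#' @return A `cross_data`.
#' @export
make_cross <- function(genotypes, phenotypes) {
  stopifnot(inherits(genotypes, "marker_genotypes"))
  if (inherits(phenotypes, "data.frame")) phenotypes <- list(phenotypes)
  covar_cols <- c("sex", "batch", "family", "weight")
  first <- phenotypes[[1]]
  covar <- first[intersect(covar_cols, names(first))]
  traits <- lapply(phenotypes, function(p)
    p[setdiff(names(p), c("id", covar_cols))])
  pheno <- do.call(cbind, traits)
  cross_data(genotypes$map, genotypes$geno, pheno, covar)
}

#' @export
print.cross_data <- function(x, ...) {
  cat(sprintf("Cross: %d individuals, %d markers on %d chromosomes\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chr))))
  cat("  phenotypes:", paste(names(x$pheno), collapse = ", "), "\n")
  cat("  covariates:", paste(names(x$covar), collapse = ", "), "\n")
  n_miss <- sum(is.na(x$geno))
  if (n_miss) cat(sprintf("  missing genotypes: %d (%.1f%%)\n", n_miss,
                          100 * n_miss / length(x$geno)))
  invisible(x)
}

#' @export
summary.cross_data <- function(object, ...) {
  gf <- table(factor(geno_codes(object$geno), levels = c("RR", "RW", "WW")))
  out <- list(n = nrow(object$geno), markers = ncol(object$geno),
              geno_freq = gf / sum(gf),
              traits = names(object$pheno), covariates = names(object$covar))
  class(out) <- "summary.cross_data"
  out
}

#' @export
print.summary.cross_data <- function(x, ...) {
  cat(sprintf("Cross of %d individuals, %d markers\n", x$n, x$markers))
  cat("  genotype frequencies:",
      paste(sprintf("%s %.3f", names(x$geno_freq), x$geno_freq), collapse = ", "), "\n")
  invisible(x)
}
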