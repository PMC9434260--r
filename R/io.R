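#' Cross-file dialect
#'
#' Describes how a cross CSV encodes genotypes: the mapping from on-disk
#' codes to the internal `RR`/`RW`/`WW` classes, the missing-value token,
#' and which leading columns are phenotypes vs covariates.
#'
#' @param genotypes Named character vector mapping internal codes to disk
#'   codes, e.g. `c(RR = "AA", RW = "AB", WW = "BB")`.
#' @param missing Missing-genotype token (default `"-"`).
#' @param covariate_cols Names of non-marker columns to treat as covariates
#'   (default `sex`, `batch`, `family`, `weight`); remaining non-marker
#'   columns are phenotypes.
#' @return A `cross_dialect` list.
#' @export
cross_dialect <- function(genotypes = c(RR = "AA", RW = "AB", WW = "BB"),
                          missing = "-",
                          covariate_cols = c("sex", "batch", "family", "weight")) {
  stopifnot(setequal(names(genotypes), c("RR", "RW", "WW")))
  if (anyDuplicated(c(genotypes, missing)))
    stop_("genotype code mapping is not a bijection")
  structure(list(genotypes = genotypes, missing = missing,
                 covariate_cols = covariate_cols),
            class = "cross_dialect")
}

#' Read a cross CSV file
#'
#' Reads the standard interval-mapping cross layout: a header row of
#' phenotype/covariate names followed by marker names; a second row blank
#' for phenotypes and carrying chromosome ids for markers; a third row
#' blank then cM positions; then one row per individual. Genotype codes are
#' translated per the dialect; unknown codes become missing with a counted
#' warning; non-monotone marker positions are re-sorted with a warning.
#'
#' @param path CSV file path.
#' @param dialect A [cross_dialect()].
#' @return A [cross_data()].
#' @export
read_cross_csv <- function(path, dialect = cross_dialect()) {
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         check.names = FALSE)
  if (nrow(raw) < 4) stop_("cross file has fewer than 4 rows")
  hdr <- as.character(raw[1, ])
  chr_row <- as.character(raw[2, ])
  pos_row <- as.character(raw[3, ])
  is_marker <- chr_row != ""
  if (!any(is_marker)) stop_("no marker columns (second row is all blank)")
  mk <- hdr[is_marker]
  if (anyDuplicated(mk)) stop_("duplicated marker names: ",
                               paste(unique(mk[duplicated(mk)]), collapse = ", "))
  collide <- intersect(mk, hdr[!is_marker])
  if (length(collide)) stop_("phenotype/marker column collision: ",
                             paste(collide, collapse = ", "))
  map <- data.frame(marker = mk, chr = chr_row[is_marker],
                    pos = as.numeric(pos_row[is_marker]),
                    stringsAsFactors = FALSE)
  ## re-sort non-monotone chromosomes
  for (ch in unique(map$chr)) {
    i <- which(map$chr == ch)
    if (is.unsorted(map$pos[i], strictly = TRUE)) {
      warning("marker positions not increasing on chromosome ", ch,
              "; re-sorting")
      map[i, ] <- map[i, ][order(map$pos[i]), ]
    }
  }
  map <- map[order(match(map$chr, unique(map$chr)), map$pos), ]
  class(map) <- c("genetic_map", "data.frame")
  body <- raw[-(1:3), , drop = FALSE]
  gcodes <- as.matrix(body[, which(is_marker)[match(map$marker, mk)], drop = FALSE])
  colnames(gcodes) <- map$marker
  inv <- stats::setNames(names(dialect$genotypes), dialect$genotypes)
  translated <- inv[gcodes]
  translated[gcodes == dialect$missing] <- NA
  unknown <- !(gcodes %in% c(dialect$genotypes, dialect$missing))
  if (any(unknown)) {
    warning(sum(unknown), " unknown genotype code(s) set to missing")
    translated[unknown] <- NA
  }
  geno <- matrix(translated, nrow(body), dimnames = list(NULL, map$marker))
  phen_block <- body[, !is_marker, drop = FALSE]
  names(phen_block) <- hdr[!is_marker]
  phen_block[] <- lapply(phen_block, function(col) {
    num <- suppressWarnings(as.numeric(col))
    if (all(is.na(num) == (col == "" | is.na(col)))) num else col
  })
  if ("id" %in% names(phen_block)) rownames(geno) <- phen_block$id
  cov_cols <- intersect(dialect$covariate_cols, names(phen_block))
  phe_cols <- setdiff(names(phen_block), c(cov_cols, "id"))
  cross_data(map, geno,
             phenotypes = phen_block[phe_cols],
             covariates = phen_block[cov_cols])
}

#' Write a cross CSV file
#'
#' Inverse of [read_cross_csv()]: phenotype and covariate columns first
#' (with blank chromosome/position rows), then markers in map order.
#' Output is deterministic for fixed input.
#'
#' @param cross A [cross_data()].
#' @param path Output path.
#' @param dialect A [cross_dialect()].
#' @return `path`, invisibly.
#' @export
write_cross_csv <- function(cross, path, dialect = cross_dialect()) {
  stopifnot(inherits(cross, "cross_data"))
  codes <- geno_codes(cross$geno)
  disk <- matrix(dialect$genotypes[codes], nrow(codes),
                 dimnames = dimnames(codes))
  disk[is.na(codes)] <- dialect$missing
  phen <- cbind(data.frame(id = cross$ids, stringsAsFactors = FALSE),
                cross$pheno, cross$covar)
  phen[] <- lapply(phen, as.character)
  hdr <- c(names(phen), cross$map$marker)
  row2 <- c(rep("", ncol(phen)), cross$map$chr)
  row3 <- c(rep("", ncol(phen)), format(cross$map$pos, trim = TRUE))
  body <- cbind(as.matrix(phen), disk)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(hdr, collapse = ","), con)
  writeLines(paste(row2, collapse = ","), con)
  writeLines(paste(row3, collapse = ","), con)
  utils::write.table(body, con, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a BED region file
#'
#' Reads BED 3+1 columns (chrom, start, end, optional name). On-disk
#' coordinates are 0-based half-open; internally intervals are 1-based
#' closed, so `chr1 99 200` becomes `chr1:[100, 200]`.
#'
#' @param path BED file path.
#' @return A `genomic_intervals` on the bp axis.
#' @export
read_regions_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(genomic_intervals(character(), numeric(), numeric(), axis = "bp"))
  parts <- strsplit(lines, "[ \t]+")
  n_fields <- lengths(parts)
  bad <- which(n_fields < 3)
  if (length(bad)) stop_("malformed BED line ", bad[1], ": fewer than 3 fields")
  chrom <- vapply(parts, `[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop_("malformed BED line ", bad[1], ": non-numeric coordinates")
  bad <- which(start > end)
  if (length(bad)) stop_("BED line ", bad[1], ": start exceeds end")
  label <- vapply(seq_along(parts), function(i)
    if (n_fields[i] >= 4) parts[[i]][4] else sprintf("region%d", i), "")
  genomic_intervals(chrom, start + 1, end, label = label, axis = "bp")
}

#' Write a BED region file
#'
#' Inverse of [read_regions_bed()]: internal 1-based closed intervals are
#' written as 0-based half-open BED lines; a read/write round trip is the
#' identity.
#'
#' @param intervals A `genomic_intervals`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(intervals, path) {
  lines <- sprintf("%s\t%s\t%s\t%s", intervals$chrom,
                   format(intervals$start - 1, scientific = FALSE, trim = TRUE),
                   format(intervals$end, scientific = FALSE, trim = TRUE),
                   intervals$label)
  writeLines(lines, path)
  invisible(path)
}

#' Read a chrom.sizes file
#'
#' @param path Two-column (name, length) whitespace-separated file.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  d <- utils::read.table(path, header = FALSE, col.names = c("chrom", "size"),
                         colClasses = c("character", "numeric"))
  stats::setNames(d$size, d$chrom)
}

#' Write a binary mask as PNG
#'
#' Foreground pixels are written black on a white background (the silhouette
#' convention of thresholded comb photographs).
#'
#' @param mask Logical matrix (`TRUE` = foreground).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(1 - (mask > 0) * 1, path)
  invisible(path)
}

#' Read a binary mask from PNG
#'
#' @param path PNG path; dark pixels (< 0.5 intensity) are foreground.
#' @return Logical matrix.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img < 0.5
}

#' Write an expression matrix as CSV with a position-annotation sidecar
#'
#' @param expr An `expression_matrix` (or plain probes x individuals
#'   matrix).
#' @param path Output CSV (probes in rows, individuals in columns).
#' @param annot_path Optional sidecar CSV (probe, chr, pos, bp); defaults
#'   to `path` with an `_annotation.csv` suffix. Only written when the
#'   annotation is available.
#' @return `path`, invisibly.
#' @export
write_expression_csv <- function(expr, path,
                                 annot_path = sub("\\.csv$", "_annotation.csv", path)) {
  values <- if (inherits(expr, "expression_matrix")) expr$values else as.matrix(expr)
  utils::write.csv(as.data.frame(values), path, row.names = TRUE)
  if (inherits(expr, "expression_matrix"))
    utils::write.csv(expr$annotation, annot_path, row.names = FALSE)
  invisible(path)
}

#' Write outlines as a long-format coordinate CSV
#'
#' One row per point with columns `id`, `x`, `y`, points in traversal
#' order per outline.
#'
#' @param outlines List of [outline()]s (names become ids when present).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_outlines_csv <- function(outlines, path) {
  ids <- names(outlines) %||% sprintf("outline%03d", seq_along(outlines))
  long <- do.call(rbind, lapply(seq_along(outlines), function(i)
    data.frame(id = ids[i], x = outlines[[i]]$points[, 1],
               y = outlines[[i]]$points[, 2])))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read outlines from a long-format coordinate CSV
#'
#' @param path CSV with columns `id`, `x`, `y`.
#' @return Named list of [outline()]s.
#' @export
read_outlines_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("id", "x", "y") %in% names(d)))
  lapply(split(d[c("x", "y")], factor(d$id, levels = unique(d$id))),
         function(s) outline(cbind(s$x, s$y)))
}
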