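#' Construct a genotype dataset
#'
#' The central container of the package: a sample-by-marker matrix of counted
#' allele dosages in \{0, 1, 2\} (NA for missing calls), a marker map, and a
#' sample table. Markers are stored sorted by (chromosome, position); positions
#' are 1-based inclusive base pairs as in array map files.
#'
#' @param geno integer matrix, samples in rows, markers in columns; entries
#'   0/1/2 count copies of the counted allele, NA marks a missing call.
#' @param map data.frame with columns \code{chr} (integer chromosome id),
#'   \code{snp} (marker id), \code{bp} (position), \code{a1} (counted allele),
#'   \code{a2} (other allele). One row per column of \code{geno}.
#' @param samples data.frame with columns \code{id} and \code{farm}, one row
#'   per row of \code{geno}.
#' @return an object of class \code{genotype_dataset}.
#' @export
genotype_dataset <- function(geno, map, samples) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  stopifnot(is.data.frame(map), is.data.frame(samples))
  if (nrow(map) != ncol(geno))
    stop("map has ", nrow(map), " rows but genotype matrix has ",
         ncol(geno), " columns")
  if (nrow(samples) != nrow(geno))
    stop("sample table has ", nrow(samples), " rows but genotype matrix has ",
         nrow(geno), " rows")
  need <- c("chr", "snp", "bp")
  if (!all(need %in% names(map)))
    stop("map must contain columns: ", paste(need, collapse = ", "))
  if (is.null(map$a1)) map$a1 <- "A"
  if (is.null(map$a2)) map$a2 <- "B"
  if (!"id" %in% names(samples)) stop("sample table must contain column 'id'")
  if (is.null(samples$farm)) samples$farm <- "F1"
  bad <- geno[!is.na(geno) & !(geno %in% 0:2)]
  if (length(bad))
    stop("genotype entries must be 0, 1, 2 or NA; found ", bad[[1L]])
  ord <- order(map$chr, map$bp)
  map <- map[ord, , drop = FALSE]
  geno <- geno[, ord, drop = FALSE]
  if (anyDuplicated(map[c("chr", "bp")]) == 0) {
    by_chr <- split(map$bp, map$chr)
    if (!all(vapply(by_chr, function(x) !is.unsorted(x, strictly = TRUE),
                    logical(1L))))
      stop("positions must be strictly increasing within chromosome")
  }
  rownames(map) <- NULL
  rownames(samples) <- NULL
  dimnames(geno) <- list(as.character(samples$id), as.character(map$snp))
  structure(list(geno = geno, map = map, samples = samples),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$geno), "samples x", ncol(x$geno),
      "markers on", length(unique(x$map$chr)), "chromosome(s)\n")
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing calls: %.3f%%; farms: %s\n", 100 * miss,
              paste(sort(unique(as.character(x$samples$farm))),
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$geno)

n_samples <- function(ds) nrow(ds$geno)
n_markers <- function(ds) ncol(ds$geno)

## Subset a dataset by sample and/or marker index, keeping the pieces aligned.
subset_dataset <- function(ds, samples = NULL, markers = NULL) {
  if (!is.null(samples)) {
    ds$geno <- ds$geno[samples, , drop = FALSE]
    ds$samples <- ds$samples[samples, , drop = FALSE]
    rownames(ds$samples) <- NULL
  }
  if (!is.null(markers)) {
    ds$geno <- ds$geno[, markers, drop = FALSE]
    ds$map <- ds$map[markers, , drop = FALSE]
    rownames(ds$map) <- NULL
  }
  ds
}

## Allele frequency of the counted allele, per marker (missing calls dropped).
counted_allele_freq <- function(ds) {
  nm <- colSums(!is.na(ds$geno))
  colSums(ds$geno, na.rm = TRUE) / (2 * nm)
}

#' Recode every marker so the counted allele is the minor allele
#'
#' Markers whose counted-allele frequency exceeds 0.5 are flipped (dosage
#' \code{2 - g}, alleles swapped). Frequency ties (0.5) and monomorphic
#' markers keep the allele that sorts first lexicographically, so the coding
#' is deterministic for any input.
#'
#' @param ds a \code{genotype_dataset}.
#' @return the dataset with minor-allele dosage coding.
#' @export
recode_minor <- function(ds) {
  p <- counted_allele_freq(ds)
  p[is.nan(p)] <- 0
  a1 <- as.character(ds$map$a1)
  a2 <- as.character(ds$map$a2)
  flip <- p > 0.5 | (p == 0.5 & a2 < a1)
  if (any(flip)) {
    ds$geno[, flip] <- 2L - ds$geno[, flip, drop = FALSE]
    tmp <- a1[flip]
    ds$map$a1 <- replace(a1, flip, a2[flip])
    ds$map$a2 <- replace(a2, flip, tmp)
  }
  ds
}
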