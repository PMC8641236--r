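#' Apply genotype quality control
#'
#' Filters follow the conventional order: samples by call rate, then markers
#' by call rate, then restriction to autosomes, then a minor-allele-frequency
#' filter. After filtering, markers are recoded so the counted allele is the
#' minor allele in the retained samples.
#'
#' @param ds a [genotype_dataset()].
#' @param sample_cr minimum per-sample call rate (default 0.90).
#' @param marker_cr minimum per-marker call rate (default 0.90).
#' @param autosomes_only drop markers with chromosome id outside
#'   \code{1..autosome_max}.
#' @param autosome_max largest autosome id (26 for sheep).
#' @param maf_min minimum minor allele frequency, or \code{NULL} to skip.
#' @return the filtered dataset, with a \code{data.frame} of per-step removal
#'   counts attached as attribute \code{"qc_report"}.
#' @export
apply_qc <- function(ds, sample_cr = 0.90, marker_cr = 0.90,
                     autosomes_only = TRUE, autosome_max = 26L,
                     maf_min = NULL) {
  stopifnot(sample_cr >= 0, sample_cr <= 1, marker_cr >= 0, marker_cr <= 1)
  report <- data.frame(step = character(), removed = integer(),
                       remaining_samples = integer(),
                       remaining_markers = integer(),
                       stringsAsFactors = FALSE)
  note <- function(step, removed) {
    report <<- rbind(report, data.frame(
      step = step, removed = as.integer(removed),
      remaining_samples = n_samples(ds), remaining_markers = n_markers(ds)))
  }

  cr_s <- rowMeans(!is.na(ds$geno))
  keep_s <- cr_s >= sample_cr
  ds <- subset_dataset(ds, samples = which(keep_s))
  note("sample_call_rate", sum(!keep_s))
  if (n_samples(ds) == 0L) stop("QC removed every sample (sample_cr = ",
                                sample_cr, ")")

  cr_m <- colMeans(!is.na(ds$geno))
  keep_m <- cr_m >= marker_cr
  ds <- subset_dataset(ds, markers = which(keep_m))
  note("marker_call_rate", sum(!keep_m))

  if (autosomes_only) {
    keep_a <- ds$map$chr >= 1L & ds$map$chr <= autosome_max
    ds <- subset_dataset(ds, markers = which(keep_a))
    note("autosomes_only", sum(!keep_a))
  }

  ds <- recode_minor(ds)
  if (!is.null(maf_min)) {
    maf <- counted_allele_freq(ds)
    maf[is.nan(maf)] <- 0
    keep_f <- maf >= maf_min
    ds <- subset_dataset(ds, markers = which(keep_f))
    note("maf_min", sum(!keep_f))
  }
  if (n_markers(ds) == 0L) stop("QC removed every marker")
  attr(ds, "qc_report") <- report
  ds
}

#' Per-marker and per-sample diversity statistics
#'
#' Computes per-SNP observed heterozygosity Ho (heterozygote fraction among
#' non-missing calls) and expected heterozygosity He = 2p(1-p), and the
#' per-sample inbreeding coefficient
#' F = (O_hom - E_hom) / (N_nm - E_hom), where O_hom is the sample's observed
#' homozygote count over its N_nm non-missing markers and
#' E_hom = sum_j [1 - 2 p_j (1 - p_j) T_j / (T_j - 1)] is the expected count
#' under Hardy-Weinberg equilibrium, with T_j the number of observed allele
#' copies at marker j (the small-sample correction used by the standard
#' command-line tool for this statistic). He summaries are reported without
#' the correction.
#'
#' @param ds a [genotype_dataset()] (at least 2 samples).
#' @return a list of class \code{diversity_summary} with elements
#'   \code{per_snp} (snp, chr, bp, maf, ho, he), \code{per_sample}
#'   (id, n_nonmissing, o_hom, e_hom, f) and \code{summary} (means and SDs).
#' @export
diversity <- function(ds) {
  if (n_samples(ds) < 2L) stop("diversity statistics need at least 2 samples")
  g <- ds$geno
  nonmiss <- !is.na(g)
  n_j <- colSums(nonmiss)
  p <- counted_allele_freq(ds)
  het <- !is.na(g) & g == 1L
  ho <- colSums(het) / n_j
  he <- 2 * p * (1 - p)
  t_j <- 2 * n_j
  ehom_j <- 1 - 2 * p * (1 - p) * t_j / (t_j - 1)
  ehom_j[t_j < 2] <- NA_real_

  o_hom <- rowSums(nonmiss & g != 1L, na.rm = TRUE)
  e_hom <- as.vector(nonmiss %*% ifelse(is.na(ehom_j), 0, ehom_j))
  n_nm <- rowSums(nonmiss)
  denom <- n_nm - e_hom
  f <- ifelse(abs(denom) < sqrt(.Machine$double.eps), NA_real_,
              (o_hom - e_hom) / denom)

  per_snp <- data.frame(snp = ds$map$snp, chr = ds$map$chr, bp = ds$map$bp,
                        maf = pmin(p, 1 - p), ho = ho, he = he,
                        stringsAsFactors = FALSE)
  per_sample <- data.frame(id = ds$samples$id, n_nonmissing = n_nm,
                           o_hom = o_hom, e_hom = e_hom, f = f,
                           stringsAsFactors = FALSE)
  summ <- data.frame(
    statistic = c("Ho", "He", "F"),
    mean = c(mean(ho, na.rm = TRUE), mean(he, na.rm = TRUE),
             mean(f, na.rm = TRUE)),
    sd = c(stats::sd(ho, na.rm = TRUE), stats::sd(he, na.rm = TRUE),
           stats::sd(f, na.rm = TRUE)))
  structure(list(per_snp = per_snp, per_sample = per_sample, summary = summ),
            class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat("Diversity over", nrow(x$per_snp), "markers,", nrow(x$per_sample),
      "samples\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  mean %s = %.4f (SD %.4f)\n", s$statistic[i], s$mean[i],
                s$sd[i]))
  invisible(x)
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of genotype dosages over the samples
#' non-missing at both markers.
#'
#' @param ds a [genotype_dataset()].
#' @param marker_a,marker_b marker ids (names) or column indices.
#' @return scalar r-squared.
#' @export
ld_r2 <- function(ds, marker_a, marker_b) {
  idx <- function(m) {
    if (is.character(m)) {
      j <- match(m, ds$map$snp)
      if (is.na(j)) stop("unknown marker: ", m)
      j
    } else as.integer(m)
  }
  x <- ds$geno[, idx(marker_a)]
  y <- ds$geno[, idx(marker_b)]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) stop("fewer than 2 complete genotype pairs")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    stop("marker is monomorphic over the complete pairs; r2 undefined")
  stats::cor(x[ok], y[ok])^2
}
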