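#' Per-SNP run-membership frequency
#'
#' For every marker, the fraction of samples whose run set covers the
#' marker's position (a run covers positions \code{start_bp..end_bp} on its
#' chromosome).
#'
#' @param runs run data.frame from [detect_roh()] or [detect_rohet()].
#' @param ds the [genotype_dataset()] the runs came from.
#' @return data.frame (snp, chr, bp, frequency), one row per marker, in map
#'   order — ready for a Manhattan-style plot.
#' @export
snp_run_frequency <- function(runs, ds) {
  n <- n_samples(ds)
  freq <- numeric(n_markers(ds))
  if (nrow(runs)) {
    for (ch in unique(runs$chr)) {
      jj <- which(ds$map$chr == ch)
      bp <- ds$map$bp[jj]
      rr <- runs[runs$chr == ch, , drop = FALSE]
      cnt <- integer(length(jj))
      for (k in seq_len(nrow(rr))) {
        inside <- bp >= rr$start_bp[k] & bp <= rr$end_bp[k]
        cnt[inside] <- cnt[inside] + 1L
      }
      freq[jj] <- cnt / n
    }
  }
  data.frame(snp = ds$map$snp, chr = ds$map$chr, bp = ds$map$bp,
             frequency = freq, stringsAsFactors = FALSE)
}

#' Call homozygosity/heterozygosity islands
#'
#' The threshold is the empirical \code{quantile} of the genome-wide per-SNP
#' run frequencies (R's default interpolating quantile definition, type 7).
#' Markers with frequency greater than or equal to the threshold are island
#' members; members that are consecutive on a chromosome, with inter-SNP
#' gaps at most \code{max_gap_bp}, are merged into one island.
#'
#' @param freq data.frame from [snp_run_frequency()].
#' @param quantile quantile defining the threshold (default 0.999).
#' @param max_gap_bp maximum gap between member SNPs merged into one island.
#' @return data.frame of islands (chr, start_bp, end_bp, n_snp,
#'   peak_frequency) with the threshold attached as attribute
#'   \code{"threshold"}; zero rows when no marker qualifies.
#' @export
call_islands <- function(freq, quantile = 0.999, max_gap_bp = 250000) {
  stopifnot(quantile > 0, quantile < 1)
  thr <- stats::quantile(freq$frequency, probs = quantile, names = FALSE,
                         type = 7)
  if (length(unique(freq$frequency)) == 1L)
    warning("per-SNP run frequency is constant (", freq$frequency[1L],
            "); every SNP meets the threshold — islands are degenerate")
  member <- freq$frequency >= thr
  out <- list()
  for (ch in unique(freq$chr)) {
    jj <- which(freq$chr == ch)
    mem <- member[jj]
    if (!any(mem)) next
    bp <- freq$bp[jj]
    gap_break <- c(diff(bp) > max_gap_bp, FALSE)
    for (se in stretch_bounds(mem, gap_break)) {
      s <- se[1L]; e <- se[2L]
      out[[length(out) + 1L]] <- data.frame(
        chr = ch, start_bp = bp[s], end_bp = bp[e], n_snp = e - s + 1L,
        peak_frequency = max(freq$frequency[jj][s:e]))
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chr = integer(), start_bp = numeric(), end_bp = numeric(),
               n_snp = integer(), peak_frequency = numeric())
  rownames(res) <- NULL
  attr(res, "threshold") <- thr
  attr(res, "quantile") <- quantile
  res
}
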