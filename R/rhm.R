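#' Sliding SNP windows along chromosomes
#'
#' Per chromosome, windows of \code{size} consecutive SNPs start at indices
#' 1, 1 + (size - overlap), ...; when the regular sequence leaves trailing
#' SNPs uncovered, a final window is anchored to the chromosome's last SNP
#' (full size, possibly overlapping the previous window by more than
#' \code{overlap}). Chromosomes with fewer than \code{size} SNPs yield one
#' whole-chromosome window.
#'
#' @param ds a [genotype_dataset()].
#' @param size SNPs per window (default 100).
#' @param overlap SNP overlap between consecutive windows (default 30).
#' @return data.frame: window id, chr, start_idx/end_idx (global marker
#'   indices), start_bp, end_bp, n_snp.
#' @export
make_windows <- function(ds, size = 100L, overlap = 30L) {
  size <- as.integer(size); overlap <- as.integer(overlap)
  stopifnot(size > overlap, overlap >= 0L)
  step <- size - overlap
  out <- list()
  for (ch in unique(ds$map$chr)) {
    jj <- which(ds$map$chr == ch)
    m <- length(jj)
    if (m <= size) {
      starts <- 1L
      ends <- m
    } else {
      starts <- seq.int(1L, m - size + 1L, by = step)
      ends <- starts + size - 1L
      if (ends[length(ends)] < m) {
        starts <- c(starts, m - size + 1L)
        ends <- c(ends, m)
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      chr = ch, start_idx = jj[starts], end_idx = jj[ends],
      start_bp = ds$map$bp[jj[starts]], end_bp = ds$map$bp[jj[ends]],
      n_snp = ends - starts + 1L)
  }
  res <- do.call(rbind, out)
  res <- cbind(window = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  res
}

## VanRaden GRM restricted to a marker index set; NULL when no polymorphic
## marker remains.
grm_subset <- function(ds, markers) {
  if (!length(markers)) return(NULL)
  sub <- subset_dataset(ds, markers = markers)
  p <- counted_allele_freq(sub)
  poly <- !is.nan(p) & p > 0 & p < 1
  if (!any(poly)) return(NULL)
  suppressWarnings(compute_grm(sub))$G
}

#' Regional heritability scan
#'
#' For each window fits y = W alpha + u_region + u_polygenic + e, where
#' u_region ~ N(0, Vg_region G_region) uses only the window's SNPs and
#' u_polygenic ~ N(0, Vg_poly G_rest) uses all remaining SNPs (each GRM
#' VanRaden-scaled on its own SNP set), by average-information REML. The
#' likelihood-ratio statistic compares against the reduced model without
#' the regional term; its P value uses a 50:50 mixture of chi-square(0) and
#' chi-square(1) by default (one variance tested on its boundary), or plain
#' chi-square(1) with \code{null = "chisq1"}. Regional heritability is
#' Vg_region / (Vg_region + Vg_poly + Ve), with a delta-method SE from the
#' inverse average-information matrix.
#'
#' @param spec a [mixed_model_spec()].
#' @param ds the post-QC [genotype_dataset()].
#' @param windows data.frame from [make_windows()].
#' @param null \code{"mixture"} (default) or \code{"chisq1"}.
#' @return data.frame of class \code{rhm_result}: window, chr, start_bp,
#'   end_bp, n_snp, vg_region, vg_poly, ve, h2_region, se_h2_region, lrt, p,
#'   reason for NA rows.
#' @export
rhm_scan <- function(spec, ds, windows, null = c("mixture", "chisq1")) {
  null <- match.arg(null)
  n <- length(spec$y)
  if (n_samples(ds) != n) stop("dataset samples do not match the phenotype")
  m <- n_markers(ds)
  res <- windows[c("window", "chr", "start_bp", "end_bp", "n_snp")]
  k <- nrow(windows)
  res$vg_region <- res$vg_poly <- res$ve <- res$h2_region <-
    res$se_h2_region <- res$lrt <- res$p <- rep(NA_real_, k)
  res$reason <- rep(NA_character_, k)

  for (w in seq_len(k)) {
    inside <- seq.int(windows$start_idx[w], windows$end_idx[w])
    outside <- setdiff(seq_len(m), inside)
    Gi <- grm_subset(ds, inside)
    Gout <- grm_subset(ds, outside)
    if (is.null(Gi)) {
      res$reason[w] <- "no_polymorphic_snp_in_window"
      next
    }
    Klist_full <- if (is.null(Gout)) list(Gi) else list(Gi, Gout)
    full <- tryCatch(reml_ai(spec$y, spec$W, Klist_full),
                     error = function(e) NULL)
    if (is.null(full) || !full$converged) {
      res$reason[w] <- "reml_non_convergence"
      next
    }
    ll_red <- if (is.null(Gout)) reml_null_loglik(spec$y, spec$W) else {
      red <- tryCatch(reml_ai(spec$y, spec$W, list(Gout)),
                      error = function(e) NULL)
      if (is.null(red) || !red$converged) NA_real_ else red$loglik
    }
    if (is.na(ll_red)) {
      res$reason[w] <- "reml_non_convergence"
      next
    }
    lrt <- 2 * (full$loglik - ll_red)
    # the two REML optimizations each carry ~1e-8 relative tolerance; small
    # negative statistics are numerical and clamped, large ones are an error
    if (lrt < -0.01)
      stop("negative likelihood-ratio statistic (", signif(lrt, 4),
           ") for window ", windows$window[w],
           "; the REML optimizer failed")
    lrt <- max(lrt, 0)
    th <- full$theta  # (vg_region, [vg_poly], ve)
    vgr <- th[1L]
    vgp <- if (is.null(Gout)) 0 else th[2L]
    ve <- th[length(th)]
    tot <- vgr + vgp + ve
    h2r <- vgr / tot
    se_h2r <- NA_real_
    if (all(is.finite(full$ai_inv))) {
      nk <- length(th)
      grad <- -rep(vgr, nk) / tot^2
      grad[1L] <- (tot - vgr) / tot^2
      v <- drop(t(grad) %*% full$ai_inv %*% grad)
      if (is.finite(v) && v >= 0) se_h2r <- sqrt(v)
    }
    pw <- if (null == "mixture") {
      if (lrt <= 0) 1 else
        0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)
    } else {
      stats::pchisq(lrt, df = 1, lower.tail = FALSE)
    }
    res$vg_region[w] <- vgr
    res$vg_poly[w] <- vgp
    res$ve[w] <- ve
    res$h2_region[w] <- h2r
    res$se_h2_region[w] <- se_h2r
    res$lrt[w] <- lrt
    res$p[w] <- pw
  }
  attr(res, "null") <- null
  class(res) <- c("rhm_result", "data.frame")
  res
}

#' Bonferroni thresholds for a regional heritability scan
#'
#' @param n_regions number of tested regions.
#' @param alpha genome-wide type-I error rate.
#' @return as [bonferroni_thresholds()].
#' @export
rhm_thresholds <- function(n_regions, alpha = 0.05) {
  bonferroni_thresholds(n_regions, alpha)
}
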