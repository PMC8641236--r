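#' Mixed-model genome-wide association scan
#'
#' For every SNP fits y = W alpha + x beta + u + e with u ~ N(0, Vg G) by
#' generalized least squares after eigendecomposition of G. In \code{fast}
#' mode the variance ratio is fixed at the null-model REML estimate (one
#' rotation, then weighted least squares per SNP); in \code{exact} mode the
#' ratio is re-optimized for each SNP by maximizing the rotated REML
#' likelihood. Missing dosages are mean-imputed; SNPs below \code{maf_min}
#' or collinear with the fixed effects give NA rows with a reason. Wald P
#' values use a t distribution with n - rank(W) - 1 degrees of freedom
#' (normal approximation by flag).
#'
#' @param spec a [mixed_model_spec()] aligned with \code{ds} samples.
#' @param g a [compute_grm()] result or symmetric matrix.
#' @param ds the [genotype_dataset()] providing the SNP dosages.
#' @param mode \code{"fast"} or \code{"exact"}.
#' @param maf_min minimum minor allele frequency for a SNP to be tested.
#' @param use_t logical; FALSE switches to the normal approximation.
#' @param null_fit optional pre-computed [reml_univariate()] null fit.
#' @return data.frame of class \code{gwas_result}: chr, snp, bp, maf, beta,
#'   se, stat, p, reason (NA rows), ordered by (chr, bp); the null variance
#'   components and mode are attached as attributes.
#' @export
lmm_gwas <- function(spec, g, ds, mode = c("fast", "exact"), maf_min = 0.01,
                     use_t = TRUE, null_fit = NULL) {
  mode <- match.arg(mode)
  G <- if (inherits(g, "grm")) g$G else g
  n <- length(spec$y)
  if (n_samples(ds) != n) stop("dataset samples do not match the phenotype")
  if (is.null(null_fit)) null_fit <- reml_univariate(spec, G)
  vg <- null_fit$vg; ve <- null_fit$ve

  e <- eigen(G, symmetric = TRUE)
  d <- pmax(e$values, 0)
  U <- e$vectors
  yr <- drop(crossprod(U, spec$y))
  Wr <- crossprod(U, spec$W)
  p <- ncol(spec$W)
  df <- n - p - 1L

  X <- ds$geno
  pfreq <- counted_allele_freq(ds)
  maf <- pmin(pfreq, 1 - pfreq)
  maf[is.nan(maf)] <- 0
  Ximp <- X
  for (j in which(colSums(is.na(X)) > 0L))
    Ximp[is.na(X[, j]), j] <- 2 * pfreq[j]
  storage.mode(Ximp) <- "double"
  Xr <- crossprod(U, Ximp)

  m <- ncol(X)
  beta <- se <- stat <- pval <- rep(NA_real_, m)
  reason <- rep(NA_character_, m)

  wls_snp <- function(xr, v) {
    sw <- 1 / sqrt(v)
    A <- cbind(Wr, xr) * sw
    qz <- qr(A)
    if (qz$rank < p + 1L) return(NULL)
    fit <- qr.coef(qz, yr * sw)
    res <- yr * sw - A %*% fit
    s2 <- sum(res^2) / df
    R <- qr.R(qz)
    XtXinv_last <- chol2inv(R)[p + 1L, p + 1L]
    c(fit[p + 1L], sqrt(s2 * XtXinv_last))
  }

  for (j in seq_len(m)) {
    if (maf[j] < maf_min) {
      reason[j] <- "maf_below_threshold"
      next
    }
    xr <- Xr[, j]
    if (mode == "fast") {
      v <- vg * d + ve
      out <- wls_snp(xr, v)
    } else {
      # re-optimize the heritability ratio for this SNP's model
      A_full <- cbind(Wr, xr)
      nll <- function(logit_h) {
        h <- 1 / (1 + exp(-logit_h))
        v <- h * d + (1 - h)
        sw <- 1 / sqrt(v)
        Aw <- A_full * sw
        qz <- qr(Aw)
        if (qz$rank < p + 1L) return(Inf)
        res <- yr * sw - Aw %*% qr.coef(qz, yr * sw)
        rss <- sum(res^2)
        R <- qr.R(qz)
        # profiled REML: sigma2 = rss / (n - p - 1)
        0.5 * (sum(log(v)) + 2 * sum(log(abs(diag(R)))) +
                 (n - p - 1L) * log(rss))
      }
      op <- stats::optimize(nll, c(-10, 10))
      h <- 1 / (1 + exp(-op$minimum))
      out <- wls_snp(xr, h * d + (1 - h))
    }
    if (is.null(out)) {
      reason[j] <- "collinear_with_fixed_effects"
      next
    }
    beta[j] <- out[1L]
    se[j] <- out[2L]
    stat[j] <- out[1L] / out[2L]
    pval[j] <- if (use_t)
      2 * stats::pt(abs(stat[j]), df = df, lower.tail = FALSE)
    else 2 * stats::pnorm(abs(stat[j]), lower.tail = FALSE)
  }
  res <- data.frame(chr = ds$map$chr, snp = ds$map$snp, bp = ds$map$bp,
                    maf = maf, beta = beta, se = se, stat = stat, p = pval,
                    reason = reason, stringsAsFactors = FALSE)
  attr(res, "mode") <- mode
  attr(res, "vg") <- vg
  attr(res, "ve") <- ve
  attr(res, "df") <- df
  class(res) <- c("gwas_result", "data.frame")
  res
}

#' Bonferroni genome-wide and suggestive significance thresholds
#'
#' Genome-wide threshold: alpha / n_tests. Suggestive threshold (one false
#' positive expected per genome scan): 1 / n_tests. The -log10 values are
#' also reported rounded to 2 decimals for display.
#'
#' @param n_tests number of tests in the scan.
#' @param alpha genome-wide type-I error rate (default 0.05).
#' @return list: \code{genomewide_p}, \code{suggestive_p},
#'   \code{genomewide_neglog10}, \code{suggestive_neglog10} (rounded to 2
#'   decimals).
#' @export
bonferroni_thresholds <- function(n_tests, alpha = 0.05) {
  if (length(n_tests) != 1L || is.na(n_tests) || n_tests < 1)
    stop("n_tests must be a positive count")
  gw <- alpha / n_tests
  sug <- min(1 / n_tests, 1)
  list(genomewide_p = gw, suggestive_p = sug,
       genomewide_neglog10 = round(-log10(gw), 2L),
       suggestive_neglog10 = round(-log10(sug), 2L))
}

#' Genomic-control inflation correction
#'
#' lambda = median(chi-square) / qchisq(0.5, 1); the Wald chi-square is the
#' squared test statistic. When lambda exceeds 1, statistics are divided by
#' lambda and P values recomputed from the 1-df chi-square distribution;
#' lambda is reported in all cases.
#'
#' @param result a [lmm_gwas()] result (>= 100 non-NA tests recommended for
#'   a stable median).
#' @return the result with added columns \code{chisq}, \code{chisq_gc},
#'   \code{p_gc}, and \code{lambda} as an attribute.
#' @export
genomic_control <- function(result) {
  chisq <- result$stat^2
  ok <- is.finite(chisq)
  if (sum(ok) < 100L)
    warning("fewer than 100 tests; the inflation factor may be unstable")
  lambda <- stats::median(chisq[ok]) / stats::qchisq(0.5, df = 1)
  result$chisq <- chisq
  if (lambda > 1) {
    result$chisq_gc <- chisq / lambda
    result$p_gc <- stats::pchisq(result$chisq_gc, df = 1, lower.tail = FALSE)
  } else {
    result$chisq_gc <- chisq
    result$p_gc <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  }
  attr(result, "lambda") <- lambda
  result
}
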