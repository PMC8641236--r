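#' Configuration for the synthetic sheep dataset
#'
#' Defaults emulate a medium-density ovine dairy study: 538 ewes genotyped at
#' ~47.6k autosomal SNPs on 26 autosomes, three farm subpopulations with
#' Balding-Nichols divergence visible in a PCA, daily temperatures with mean
#' 15.51 and SD 8.45 degrees C, about 19 test-day records per ewe, milk-level
#' and heat-slope heritabilities 0.26 and 0.20 with genetic correlation
#' -0.94, and population mean reaction-norm slopes of 0.003 kg/degree C at
#' 10 degrees C and -0.006 at 25 degrees C.
#'
#' @param n_individuals,n_snps,n_chromosomes,chromosome_length_bp genome
#'   dimensions.
#' @param n_farms,farm_divergence number of farm subpopulations and their
#'   Fst-like divergence (Balding-Nichols).
#' @param planted_roh,planted_rohet data.frames (chr, start_bp, end_bp,
#'   carrier_fraction) of regions forced homozygous / heterozygous in a
#'   fraction of individuals; NULL for none.
#' @param maf_range range the ancestral minor allele frequencies are drawn
#'   from.
#' @param missing_rate probability a genotype call is missing.
#' @param h2_resilience,h2_milk,rg_milk_resilience genetic parameters of the
#'   slope (resilience) and milk-level traits.
#' @param slope_mean_cold,slope_mean_hot population mean reaction-norm slope
#'   (kg per degree C) at 10 and 25 degrees C.
#' @param slope_sd,level_sd phenotypic SDs of the individual slope (at 25
#'   degrees C) and milk level.
#' @param curvature_sd SD of the per-animal quadratic (curvature)
#'   reaction-norm coefficient, kg per squared degree C; permanent
#'   environment only, so the genetic parameters of the 25-degree slope are
#'   exactly the configured values.
#' @param temp_mean,temp_sd daily temperature distribution (degrees C).
#' @param records_mean mean number of test-day records per animal.
#' @param mu_milk population mean test-day milk yield (kg).
#' @param resid_sd residual SD of a test-day record (kg).
#' @param seed integer seed; identical configurations give bit-identical
#'   datasets.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_individuals = 538L, n_snps = 47600L,
                       n_chromosomes = 26L, chromosome_length_bp = 1e8,
                       n_farms = 3L, farm_divergence = 0.05,
                       planted_roh = NULL, planted_rohet = NULL,
                       maf_range = c(0.05, 0.5), missing_rate = 0.002,
                       h2_resilience = 0.20, h2_milk = 0.26,
                       rg_milk_resilience = -0.94,
                       slope_mean_cold = 0.003, slope_mean_hot = -0.006,
                       slope_sd = 0.015, level_sd = 0.5,
                       curvature_sd = 5e-4,
                       temp_mean = 15.51, temp_sd = 8.45,
                       records_mean = 19, mu_milk = 1.8, resid_sd = 0.3,
                       seed = 1L) {
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_snps = as.integer(n_snps),
              n_chromosomes = as.integer(n_chromosomes),
              chromosome_length_bp = chromosome_length_bp,
              n_farms = as.integer(n_farms),
              farm_divergence = farm_divergence,
              planted_roh = planted_roh, planted_rohet = planted_rohet,
              maf_range = maf_range, missing_rate = missing_rate,
              h2_resilience = h2_resilience, h2_milk = h2_milk,
              rg_milk_resilience = rg_milk_resilience,
              slope_mean_cold = slope_mean_cold,
              slope_mean_hot = slope_mean_hot,
              slope_sd = slope_sd, level_sd = level_sd,
              curvature_sd = curvature_sd,
              temp_mean = temp_mean, temp_sd = temp_sd,
              records_mean = records_mean, mu_milk = mu_milk,
              resid_sd = resid_sd, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_individuals >= 1, n_snps >= 1, n_chromosomes >= 1,
              chromosome_length_bp > 0, n_farms >= 1,
              farm_divergence >= 0, farm_divergence < 1,
              maf_range[1L] > 0, maf_range[2L] <= 0.5,
              maf_range[1L] <= maf_range[2L],
              missing_rate >= 0, missing_rate <= 1,
              h2_resilience >= 0, h2_resilience <= 1,
              h2_milk >= 0, h2_milk <= 1,
              abs(rg_milk_resilience) <= 1,
              slope_sd > 0, level_sd > 0, curvature_sd >= 0, temp_sd > 0,
              records_mean >= 1, resid_sd >= 0)
  })
  for (pl in list(cfg$planted_roh, cfg$planted_rohet)) {
    if (!is.null(pl)) {
      stopifnot(is.data.frame(pl),
                all(c("chr", "start_bp", "end_bp", "carrier_fraction")
                    %in% names(pl)))
      if (any(pl$chr < 1 | pl$chr > cfg$n_chromosomes |
                pl$start_bp < 1 | pl$end_bp > cfg$chromosome_length_bp |
                pl$start_bp >= pl$end_bp))
        stop("planted regions must lie within chromosome bounds")
      stopifnot(all(pl$carrier_fraction >= 0 & pl$carrier_fraction <= 1))
    }
  }
  structure(cfg, class = "sim_config")
}

#' Simulate array genotypes with farm structure and planted runs
#'
#' Genotypes are drawn as two independent Bernoulli haplotypes per SNP with
#' farm-specific allele frequencies from the Balding-Nichols model (ancestral
#' frequencies uniform in \code{maf_range}, divergence
#' \code{farm_divergence}), which produces PCA-visible farm structure.
#' Planted homozygous runs copy one haplotype over the other inside the
#' region for each carrier and force the two flanking markers on each side
#' heterozygous, so the homozygous tract is exactly the planted interval;
#' planted heterozygous runs force heterozygote calls. Missing calls are
#' sprinkled first, so carriers of a planted region are complete inside it
#' and satisfy the run detectors by construction.
#'
#' @param config a [sim_config()].
#' @return list with elements \code{dataset} (a [genotype_dataset()]) and
#'   \code{truth} (planted-region bookkeeping: marker indices, carrier ids,
#'   warnings for regions smaller than the detector minimum, drawn allele
#'   frequencies).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  m <- config$n_snps
  nc <- config$n_chromosomes
  m_per <- rep(m %/% nc, nc) + c(rep(1L, m %% nc), rep(0L, nc - m %% nc))
  chr <- rep(seq_len(nc), m_per)
  bp <- unlist(lapply(m_per, function(k)
    sort(sample.int(config$chromosome_length_bp, k))))
  map <- data.frame(chr = chr,
                    snp = sprintf("c%d_s%d", chr,
                                  unlist(lapply(m_per, seq_len))),
                    bp = bp, a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  p_anc <- stats::runif(m, config$maf_range[1L], config$maf_range[2L])
  farm <- rep_len(paste0("F", seq_len(config$n_farms)), n)
  fst <- config$farm_divergence
  p_farm <- matrix(p_anc, config$n_farms, m, byrow = TRUE)
  if (fst > 0) {
    a <- p_anc * (1 - fst) / fst
    b <- (1 - p_anc) * (1 - fst) / fst
    for (f in seq_len(config$n_farms))
      p_farm[f, ] <- stats::rbeta(m, a, b)
    # keep every SNP segregating somewhere
    p_farm <- pmin(pmax(p_farm, 1e-4), 1 - 1e-4)
  }
  h1 <- matrix(0L, n, m)
  h2 <- matrix(0L, n, m)
  for (f in seq_len(config$n_farms)) {
    rows <- which(farm == paste0("F", f))
    pf <- p_farm[f, ]
    h1[rows, ] <- matrix(stats::rbinom(length(rows) * m, 1L,
                                       rep(pf, each = length(rows))),
                         length(rows), m)
    h2[rows, ] <- matrix(stats::rbinom(length(rows) * m, 1L,
                                       rep(pf, each = length(rows))),
                         length(rows), m)
  }
  geno <- h1 + h2
  if (config$missing_rate > 0) {
    nmiss <- stats::rbinom(1L, n * m, config$missing_rate)
    if (nmiss > 0)
      geno[sample.int(n * m, nmiss)] <- NA_integer_
  }

  warnings <- character()
  plant <- function(pl, kind, min_snp) {
    info <- list()
    if (is.null(pl)) return(info)
    for (r in seq_len(nrow(pl))) {
      jj <- which(map$chr == pl$chr[r] & map$bp >= pl$start_bp[r] &
                    map$bp <= pl$end_bp[r])
      carriers <- sort(sample.int(n, round(pl$carrier_fraction[r] * n)))
      if (length(jj) < min_snp) {
        msg <- sprintf(
          "planted %s region %d (chr %d) has %d SNPs, below the detector minimum of %d",
          kind, r, pl$chr[r], length(jj), min_snp)
        warnings <<- c(warnings, msg)
        warning(msg)
      }
      if (length(jj) && length(carriers)) {
        if (kind == "ROH") {
          geno[carriers, jj] <<- 2L * h1[carriers, jj]
          # delimit the planted run with two heterozygous flank markers on
          # each side: no window or run satisfying the default one-het cap
          # can cross them, so the homozygous tract is exactly the planted
          # interval
          same_chr <- which(map$chr == pl$chr[r])
          left <- utils::tail(same_chr[same_chr < min(jj)], 2L)
          right <- utils::head(same_chr[same_chr > max(jj)], 2L)
          for (fl in c(left, right)) geno[carriers, fl] <<- 1L
        } else {
          geno[carriers, jj] <<- 1L
        }
      }
      info[[r]] <- list(chr = pl$chr[r], start_bp = pl$start_bp[r],
                        end_bp = pl$end_bp[r], markers = jj,
                        carriers = carriers)
    }
    info
  }
  roh_info <- plant(config$planted_roh, "ROH", 20L)
  rohet_info <- plant(config$planted_rohet, "ROHet", 15L)

  samples <- data.frame(id = sprintf("ewe%04d", seq_len(n)), farm = farm,
                        stringsAsFactors = FALSE)
  ds <- genotype_dataset(geno, map, samples)
  truth <- list(p_ancestral = p_anc, p_farm = p_farm,
                planted_roh = roh_info, planted_rohet = rohet_info,
                warnings = warnings, config = config)
  list(dataset = ds, truth = truth)
}

#' Simulate longitudinal test-day milk records with reaction-norm structure
#'
#' Each animal receives a milk-level value and a reaction-norm slope whose
#' genetic parts are drawn from a multivariate normal with covariance
#' implied by (\code{h2_milk}, \code{h2_resilience},
#' \code{rg_milk_resilience}) and the dataset's own genomic relationship
#' matrix; independent permanent-environment parts fill the remaining
#' phenotypic variance. The population mean curve is the quadratic whose
#' slope equals \code{slope_mean_cold} at 10 degrees C and
#' \code{slope_mean_hot} at 25 degrees C. Record temperatures are i.i.d.
#' Normal(\code{temp_mean}, \code{temp_sd}); test-day yield adds fixed
#' effects of farm, lactation, year and month of lambing and a days-in-milk
#' decline, plus the individual curve at the record's temperature and
#' Gaussian residual noise.
#'
#' @param dataset a [genotype_dataset()] from [simulate_genotypes()].
#' @param truth the matching truth record (updated and returned).
#' @param config the same [sim_config()].
#' @return list: \code{records} (animal, farm, lactation, year_lambing,
#'   month_lambing, dim, date, temperature, milk) and \code{truth} extended
#'   with per-animal breeding values, total level/slope, true slopes at 10
#'   and 25 degrees C, and the true variance components.
#' @export
simulate_phenotypes <- function(dataset, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- n_samples(dataset)
  vl <- config$level_sd^2
  vs <- config$slope_sd^2
  cg <- config$rg_milk_resilience *
    sqrt(config$h2_milk * vl * config$h2_resilience * vs)
  G0 <- matrix(c(config$h2_milk * vl, cg, cg, config$h2_resilience * vs),
               2L, 2L)
  if (min(eigen(G0, symmetric = TRUE, only.values = TRUE)$values) < -1e-12)
    stop("genetic covariance is not positive semi-definite: ",
         "rg_milk_resilience = ", config$rg_milk_resilience,
         " with h2_milk = ", config$h2_milk,
         " and h2_resilience = ", config$h2_resilience)
  G <- suppressWarnings(compute_grm(dataset))$G
  M <- t(chol(G + diag(1e-6, n)))
  C0 <- t(chol(G0 + diag(1e-12, 2L)))
  Bv <- M %*% matrix(stats::rnorm(2L * n), n, 2L) %*% t(C0)
  pe <- cbind(stats::rnorm(n, 0, sqrt(max((1 - config$h2_milk) * vl, 0))),
              stats::rnorm(n, 0, sqrt(max((1 - config$h2_resilience) * vs,
                                          0))))
  level <- Bv[, 1L] + pe[, 1L]
  slope <- Bv[, 2L] + pe[, 2L]  # individual slope deviation at 25 degrees C

  # population mean curve m(T): slope c1 + 2 c2 T hits the configured means
  c2 <- (config$slope_mean_hot - config$slope_mean_cold) / (2 * (25 - 10))
  c1 <- config$slope_mean_cold - 2 * c2 * 10
  tm <- config$temp_mean
  mean_curve <- function(tt) c1 * (tt - tm) + c2 * (tt^2 - tm^2)
  # individual deviation curve: level + b (T - tm) + k (T - tm)^2, with the
  # linear term anchored so the deviation slope at 25 degrees C is `slope`
  curv <- stats::rnorm(n, 0, config$curvature_sd)
  blin <- slope - 2 * curv * (25 - tm)

  farm_eff <- stats::setNames(
    seq(-0.1, 0.1, length.out = config$n_farms),
    paste0("F", seq_len(config$n_farms)))
  nrec <- 1L + stats::rpois(n, max(config$records_mean - 1, 0))
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    k <- nrec[i]
    idx <- seq_len(k)
    lact <- 1L + (idx - 1L) %/% 8L
    within <- (idx - 1L) %% 8L
    dim <- 10L + 28L * within
    year0 <- sample(2003:2016, 1L)
    month0 <- sample(1:12, 1L)
    year_lambing <- year0 + (lact - 1L)
    date <- as.Date(sprintf("%d-%02d-01", year_lambing, month0)) + dim
    tt <- stats::rnorm(k, config$temp_mean, config$temp_sd)
    yield <- config$mu_milk +
      farm_eff[[dataset$samples$farm[i]]] +
      0.05 * (lact - 1L) +
      0.01 * (year_lambing - 2003L) +
      0.05 * sin(2 * pi * month0 / 12) -
      0.003 * dim +
      mean_curve(tt) +
      level[i] + blin[i] * (tt - tm) + curv[i] * (tt - tm)^2 +
      stats::rnorm(k, 0, config$resid_sd)
    recs[[i]] <- data.frame(
      animal = dataset$samples$id[i], farm = dataset$samples$farm[i],
      lactation = lact, year_lambing = year_lambing, month_lambing = month0,
      dim = dim, date = date, temperature = tt, milk = yield,
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL

  truth$animals <- data.frame(
    animal = dataset$samples$id,
    g_level = Bv[, 1L], g_slope = Bv[, 2L],
    level = level, slope = slope, curvature = curv,
    true_slope_T10 = c1 + 2 * c2 * 10 + blin + 2 * curv * (10 - tm),
    true_slope_T25 = c1 + 2 * c2 * 25 + slope,
    stringsAsFactors = FALSE)
  truth$varcomp <- list(
    vg_level = G0[1L, 1L], vg_slope = G0[2L, 2L], cov_g = G0[1L, 2L],
    ve_level = (1 - config$h2_milk) * vl,
    ve_slope = (1 - config$h2_resilience) * vs,
    resid = config$resid_sd^2)
  truth$mean_curve <- c(c1 = c1, c2 = c2)
  list(records = records, truth = truth)
}
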