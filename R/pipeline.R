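#' Assemble the per-animal trait table and fixed-effect design
#'
#' Builds the per-animal analysis table behind the genomic models: resilience
#' slopes at the requested temperatures, lifetime milk yield and productive
#' life, farm, year and month of first lambing, and total number of
#' lactations, merged with the leading principal components.
#'
#' @param records longitudinal records (see [fit_reaction_norms()]).
#' @param slopes per-animal slope table from [slopes_at()].
#' @param lifetime per-animal table from [lifetime_traits()].
#' @param pcs matrix of PC scores with animal row names.
#' @return data.frame keyed by \code{animal}.
#' @export
animal_table <- function(records, slopes, lifetime, pcs) {
  first <- do.call(rbind, lapply(split(records, records$animal), function(r) {
    o <- r[order(as.numeric(r$date)), , drop = FALSE]
    data.frame(animal = o$animal[1L], farm = o$farm[1L],
               year_first = o$year_lambing[1L],
               month_first = o$month_lambing[1L],
               n_lactations = max(o$lactation), stringsAsFactors = FALSE)
  }))
  tab <- merge(first, slopes, by = "animal")
  tab <- merge(tab, lifetime, by = "animal")
  pcs_df <- data.frame(animal = rownames(pcs), pcs,
                       stringsAsFactors = FALSE)
  tab <- merge(tab, pcs_df, by = "animal")
  tab[order(tab$animal), , drop = FALSE]
}

#' Fixed-effect design for one trait (Model 1 covariate set)
#'
#' Farm, year and month of first lambing, total lactations, the first
#' \code{n_pc} principal components, plus the reciprocal
#' longevity/production covariate: productive life for every trait except
#' itself, and lifetime milk for productive life.
#'
#' @param tab an [animal_table()].
#' @param trait response column name.
#' @param n_pc how many PC columns to include.
#' @return a [mixed_model_spec()].
#' @export
trait_spec <- function(tab, trait, n_pc = 3L) {
  covar <- if (trait == "productive_days") "lifetime_milk" else
    "productive_days"
  terms <- c("factor(farm)", "factor(year_first)", "factor(month_first)",
             "n_lactations", covar, paste0("PC", seq_len(n_pc)))
  keep <- vapply(c(farm = "farm", year_first = "year_first",
                   month_first = "month_first"),
                 function(cn) length(unique(tab[[cn]])) > 1L, logical(1L))
  terms <- terms[c(keep, rep(TRUE, length(terms) - 3L))]
  W <- stats::model.matrix(stats::reformulate(terms), tab)
  mixed_model_spec(tab[[trait]], W, ids = tab$animal)
}

write_tsv <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (line in meta) writeLines(paste0("# ", line), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(config[order(names(config))], file = f)
  unname(tools::md5sum(f))
}

#' Read a plain-text key = value configuration file
#'
#' Lines of the form \code{key = value}; blank lines and \code{#} comments
#' are ignored; values are parsed as numbers where possible.
#'
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (l in lines) {
    kv <- strsplit(l, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("malformed config line: ", l)
    key <- trimws(kv[1L])
    val <- trimws(kv[2L])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Run the full characterization and resilience pipeline
#'
#' Sequences QC, diversity, ROH/ROHet detection, F_ROH, islands,
#' reaction-norm fitting, GRM/PCA, univariate and bivariate REML, GEBV,
#' GWAS and regional heritability mapping on one dataset, writing one TSV
#' per stage (each with a provenance header: package version, configuration
#' hash, seed).
#'
#' @param sim a [sim_config()] describing the dataset to simulate, or a list
#'   with elements \code{dataset} (a [genotype_dataset()]) and
#'   \code{records} (longitudinal records) for pre-existing data.
#' @param out_dir output directory (created if missing); NULL skips writing.
#' @param traits trait columns to run the genomic analyses on.
#' @param temps reaction-norm evaluation temperatures.
#' @param rn_order Legendre order of the reaction norm.
#' @param gwas_mode \code{"fast"} or \code{"exact"}.
#' @param rhm_size,rhm_overlap regional-heritability window settings.
#' @param island_quantile quantile for island calling.
#' @param maf_min MAF filter applied before the genomic analyses.
#' @return invisible list with every stage result.
#' @export
run_pipeline <- function(sim, out_dir = NULL,
                         traits = c("slope_T10", "slope_T25",
                                    "lifetime_milk", "productive_days"),
                         temps = c(10, 25), rn_order = 2L,
                         gwas_mode = "fast", rhm_size = 100L,
                         rhm_overlap = 30L, island_quantile = 0.999,
                         maf_min = 0.01) {
  if (inherits(sim, "sim_config")) {
    g <- simulate_genotypes(sim)
    ph <- simulate_phenotypes(g$dataset, g$truth, sim)
    dataset <- g$dataset
    records <- ph$records
    seed <- sim$seed
    cfg_for_hash <- unclass(sim)
  } else {
    dataset <- sim$dataset
    records <- sim$records
    seed <- if (!is.null(sim$seed)) sim$seed else NA_integer_
    cfg_for_hash <- list(external_data = TRUE, seed = seed)
  }
  meta <- c(paste("flockscan version",
                  as.character(utils::packageVersion("flockscan"))),
            paste("config md5", config_hash(cfg_for_hash)),
            paste("seed", seed))
  emit <- function(df, name, extra = character()) {
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      write_tsv(df, file.path(out_dir, paste0(name, ".tsv")),
                c(meta, extra))
    }
  }

  ## genome characterization on the call-rate/autosome-filtered data
  ds_qc <- apply_qc(dataset)
  emit(attr(ds_qc, "qc_report"), "qc_report")
  div <- diversity(ds_qc)
  emit(div$per_snp, "diversity_per_snp")
  emit(div$per_sample, "diversity_per_sample")
  emit(div$summary, "diversity_summary")

  roh <- detect_roh(ds_qc)
  rohet <- detect_rohet(ds_qc)
  emit(roh, "roh")
  emit(rohet, "rohet")
  fr <- froh(roh, ds_qc)
  emit(fr, "froh")
  freq_roh <- snp_run_frequency(roh, ds_qc)
  freq_rohet <- snp_run_frequency(rohet, ds_qc)
  emit(freq_roh, "roh_snp_frequency")
  emit(freq_rohet, "rohet_snp_frequency")
  isl_roh <- suppressWarnings(call_islands(freq_roh, island_quantile))
  isl_rohet <- suppressWarnings(call_islands(freq_rohet, island_quantile))
  emit(isl_roh, "roh_islands",
       paste("threshold", attr(isl_roh, "threshold")))
  emit(isl_rohet, "rohet_islands",
       paste("threshold", attr(isl_rohet, "threshold")))

  ## resilience analyses on the MAF-filtered marker set
  ds_maf <- apply_qc(dataset, maf_min = maf_min)
  rn <- fit_reaction_norms(records, order = rn_order)
  slopes <- slopes_at(rn, temps)
  lifetime <- lifetime_traits(records)
  grm <- compute_grm(ds_maf)
  pca <- pca_grm(grm, k = 3L)
  emit(data.frame(pc = seq_along(pca$proportions),
                  proportion = pca$proportions), "pca_proportions")
  tab <- animal_table(records, slopes, lifetime, pca$scores)
  emit(tab, "animal_traits")

  ## align the genotype data with the animals that have phenotypes
  keep <- match(tab$animal, ds_maf$samples$id)
  ds_an <- subset_dataset(ds_maf, samples = keep)
  grm_an <- compute_grm(ds_an)

  specs <- lapply(traits, function(tr) trait_spec(tab, tr))
  names(specs) <- traits
  uni <- lapply(specs, reml_univariate, g = grm_an)
  vt <- data.frame(trait = traits,
                   vg = vapply(uni, `[[`, 0, "vg"),
                   ve = vapply(uni, `[[`, 0, "ve"),
                   h2 = vapply(uni, `[[`, 0, "h2"),
                   se_h2 = vapply(uni, `[[`, 0, "se_h2"))
  emit(vt, "variance_components")

  rg_tab <- NULL
  if (length(traits) >= 2L) {
    prs <- utils::combn(traits, 2L)
    rg_tab <- data.frame(trait1 = prs[1L, ], trait2 = prs[2L, ],
                         rg = NA_real_, se_rg = NA_real_, p_rg = NA_real_)
    for (k in seq_len(ncol(prs))) {
      bv <- reml_bivariate(specs[[prs[1L, k]]], specs[[prs[2L, k]]], grm_an)
      rg_tab$rg[k] <- bv$rg
      rg_tab$se_rg[k] <- bv$se_rg
      rg_tab$p_rg[k] <- bv$p_rg
    }
    emit(rg_tab, "genetic_correlations")
  }

  gebv_tab <- do.call(rbind, lapply(traits, function(tr) {
    gg <- gebv(specs[[tr]], grm_an, uni[[tr]])
    cbind(trait = tr, gg)
  }))
  emit(gebv_tab, "gebv")

  gwas_res <- lapply(traits, function(tr)
    genomic_control(lmm_gwas(specs[[tr]], grm_an, ds_an, mode = gwas_mode,
                             null_fit = uni[[tr]])))
  names(gwas_res) <- traits
  thr <- bonferroni_thresholds(n_markers(ds_an))
  for (tr in traits)
    emit(gwas_res[[tr]], paste0("gwas_", tr),
         c(paste("lambda", attr(gwas_res[[tr]], "lambda")),
           paste("genomewide_p", thr$genomewide_p),
           paste("suggestive_p", thr$suggestive_p)))

  windows <- make_windows(ds_an, size = rhm_size, overlap = rhm_overlap)
  rhm_thr <- rhm_thresholds(nrow(windows))
  rhm_res <- lapply(traits, function(tr)
    rhm_scan(specs[[tr]], ds_an, windows))
  names(rhm_res) <- traits
  for (tr in traits)
    emit(rhm_res[[tr]], paste0("rhm_", tr),
         c(paste("genomewide_p", rhm_thr$genomewide_p),
           paste("suggestive_p", rhm_thr$suggestive_p)))

  invisible(list(dataset = ds_qc, dataset_maf = ds_an, records = records,
                 diversity = div, roh = roh, rohet = rohet, froh = fr,
                 islands_roh = isl_roh, islands_rohet = isl_rohet,
                 reaction_norm = rn, slopes = slopes, lifetime = lifetime,
                 grm = grm_an, pca = pca, animal_table = tab,
                 univariate = uni, variance_table = vt,
                 genetic_correlations = rg_tab, gebv = gebv_tab,
                 gwas = gwas_res, gwas_thresholds = thr,
                 windows = windows, rhm = rhm_res,
                 rhm_thresholds = rhm_thr))
}
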