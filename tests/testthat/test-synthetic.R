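test_that("identical seeds give bit-identical datasets and phenotypes", {
  cfg <- sim_config(n_individuals = 40, n_snps = 200, n_chromosomes = 2,
                    chromosome_length_bp = 1e7, records_mean = 5, seed = 77)
  a <- simulate_genotypes(cfg)
  b <- simulate_genotypes(cfg)
  expect_identical(a$dataset$geno, b$dataset$geno)
  expect_identical(a$dataset$map, b$dataset$map)
  pa <- simulate_phenotypes(a$dataset, a$truth, cfg)
  pb <- simulate_phenotypes(b$dataset, b$truth, cfg)
  expect_identical(pa$records, pb$records)
})

test_that("planted ROH carriers are homozygous across the region", {
  cfg <- sim_config(n_individuals = 30, n_snps = 400, n_chromosomes = 1,
                    chromosome_length_bp = 2e7, missing_rate = 0.01,
                    seed = 5,
                    planted_roh = data.frame(chr = 1, start_bp = 5e6,
                                             end_bp = 7e6,
                                             carrier_fraction = 1.0))
  g <- simulate_genotypes(cfg)
  jj <- g$truth$planted_roh[[1]]$markers
  expect_gt(length(jj), 0)
  sub <- g$dataset$geno[, jj]
  expect_true(all(!is.na(sub)))
  expect_true(all(sub != 1L))  # at most one heterozygote: here zero
})

test_that("planted ROHet carriers are heterozygous across the region", {
  cfg <- sim_config(n_individuals = 30, n_snps = 400, n_chromosomes = 1,
                    chromosome_length_bp = 2e7, seed = 6,
                    planted_rohet = data.frame(chr = 1, start_bp = 5e6,
                                               end_bp = 7e6,
                                               carrier_fraction = 0.5))
  g <- simulate_genotypes(cfg)
  info <- g$truth$planted_rohet[[1]]
  sub <- g$dataset$geno[info$carriers, info$markers]
  expect_true(all(sub == 1L))
})

test_that("a planted region smaller than the detector minimum warns", {
  cfg <- sim_config(n_individuals = 10, n_snps = 100, n_chromosomes = 1,
                    chromosome_length_bp = 1e8, seed = 7,
                    planted_roh = data.frame(chr = 1, start_bp = 1e6,
                                             end_bp = 2e6,
                                             carrier_fraction = 1))
  expect_warning(g <- simulate_genotypes(cfg), "below the detector minimum")
  expect_gt(length(g$truth$warnings), 0)
})

test_that("sample MAF agrees with the drawn frequencies by direct counting", {
  cfg <- sim_config(n_individuals = 200, n_snps = 300, n_chromosomes = 1,
                    chromosome_length_bp = 2e7, farm_divergence = 0,
                    missing_rate = 0, maf_range = c(0.05, 0.5), seed = 8)
  g <- simulate_genotypes(cfg)
  p_hat <- colSums(g$dataset$geno) / (2 * 200)
  p_true <- g$truth$p_ancestral
  # binomial sampling error: ~4 SD bound per SNP, checked in bulk
  se <- sqrt(p_true * (1 - p_true) / (2 * 200))
  expect_gt(mean(abs(p_hat - p_true) <= 4 * se), 0.99)
  expect_lt(abs(mean(p_hat - p_true)), 0.01)
})

test_that("simulated temperatures and slope means match the configuration", {
  cfg <- sim_config(n_individuals = 500, n_snps = 200, n_chromosomes = 1,
                    chromosome_length_bp = 1e7, records_mean = 20, seed = 9)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g$dataset, g$truth, cfg)
  tt <- ph$records$temperature
  expect_gt(length(tt), 9000)
  # 3-sigma Monte-Carlo bounds at ~10,000 records / 500 animals
  expect_lt(abs(mean(tt) - 15.51), 3 * 8.45 / sqrt(length(tt)))
  expect_lt(abs(sd(tt) - 8.45), 3 * 8.45 / sqrt(2 * length(tt)))
  expect_lt(abs(mean(ph$truth$animals$true_slope_T25) - (-0.006)),
            3 * 0.015 / sqrt(500))
  expect_lt(abs(mean(ph$truth$animals$true_slope_T10) - 0.003),
            3 * 0.016 / sqrt(500))
})

test_that("records regress on the true animal effects with slope one", {
  sim <- shared_sim()
  recs <- sim$records
  tr <- sim$truth$animals
  lv <- tr$level[match(recs$animal, tr$animal)]
  sl <- tr$slope[match(recs$animal, tr$animal)]
  # remove the known mean structure, then regress on the true level
  part <- recs$milk - sl * (recs$temperature - sim$cfg$temp_mean)
  fit <- lm(part ~ lv + factor(recs$farm) + recs$lactation +
              recs$year_lambing + factor(recs$month_lambing) + recs$dim +
              recs$temperature + I(recs$temperature^2))
  co <- summary(fit)$coefficients["lv", ]
  expect_lt(abs(co[1] - 1), 3 * co[2])
})

test_that("zero residual and zero slope give identical yields at fixed
           covariates", {
  cfg <- sim_config(n_individuals = 5, n_snps = 100, n_chromosomes = 1,
                    chromosome_length_bp = 5e6, records_mean = 10,
                    resid_sd = 0, slope_sd = 1e-12, curvature_sd = 0,
                    slope_mean_cold = 0, slope_mean_hot = 0, seed = 10)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g$dataset, g$truth, cfg)
  r1 <- ph$records[ph$records$animal == ph$records$animal[1], ]
  same <- r1[r1$lactation == 1 & r1$dim == r1$dim[1], ]
  # identical covariates => identical milk regardless of temperature
  expect_true(all(abs(same$milk - same$milk[1]) < 1e-9))
})
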