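test_that("constructor validates and sorts the marker map", {
  geno <- matrix(c(0L, 1L, 2L, 1L), 2, 2)
  map <- data.frame(chr = c(1L, 1L), snp = c("b", "a"), bp = c(500, 100))
  samples <- data.frame(id = c("s1", "s2"), farm = "F1")
  ds <- genotype_dataset(geno, map, samples)
  expect_equal(ds$map$snp, c("a", "b"))
  expect_equal(unname(ds$geno[, 1L]), c(2L, 1L))
  expect_error(genotype_dataset(geno, map[1L, ], samples), "rows")
  expect_error(genotype_dataset(matrix(3L, 2, 2), map, samples), "0, 1, 2")
})

test_that("PED/MAP round trip preserves minor-allele-coded data", {
  sim <- shared_sim()
  ds <- recode_minor(sim$dataset)
  prefix <- file.path(tempdir(), "rt")
  write_genotypes(ds, prefix, "ped_map")
  back <- read_genotypes(prefix, "ped_map")
  expect_equal(unname(back$geno), unname(ds$geno))
  expect_equal(back$map$bp, ds$map$bp)
  expect_equal(back$samples$id, ds$samples$id)
})

test_that("hand-written PED with one missing call parses cell-exactly", {
  dir <- tempdir()
  writeLines(c("1\tm1\t0\t100", "1\tm2\t0\t200", "1\tm3\t0\t300",
               "1\tm4\t0\t400"), file.path(dir, "toy.map"))
  writeLines(c(
    "F1 s1 0 0 0 -9 A A A C C C 0 0",
    "F1 s2 0 0 0 -9 A C A A C C A C",
    "F2 s3 0 0 0 -9 C C A C C C A A"),
    file.path(dir, "toy.ped"))
  ds <- read_genotypes(file.path(dir, "toy"), "ped_map")
  expect_equal(sum(is.na(ds$geno)), 1L)
  expect_true(is.na(ds$geno["s1", "m4"]))
  # marker m1: alleles A freq 3/6 = C freq; tie broken to "A" as counted
  expect_equal(unname(ds$geno[, "m1"]), c(2L, 1L, 0L))
  # marker m3 monomorphic C: counted allele is the absent one
  expect_equal(unname(ds$geno[, "m3"]), c(0L, 0L, 0L))
})

test_that("BED/BIM/FAM and PED/MAP encodings agree", {
  sim <- shared_sim()
  ds <- recode_minor(sim$dataset)
  p1 <- file.path(tempdir(), "fmt_ped")
  p2 <- file.path(tempdir(), "fmt_bed")
  write_genotypes(ds, p1, "ped_map")
  write_genotypes(ds, p2, "bed_bim_fam")
  a <- read_genotypes(p1, "ped_map")
  b <- read_genotypes(p2, "bed_bim_fam")
  expect_equal(unname(a$geno), unname(b$geno))
  expect_equal(a$map$bp, b$map$bp)
  expect_error(read_genotypes(file.path(tempdir(), "nope"), "bed_bim_fam"),
               "missing file")
})

test_that("QC removes low-call-rate samples then markers, and is idempotent", {
  set.seed(1)
  geno <- matrix(rbinom(10 * 10, 2, 0.4), 10, 10)
  geno[1, 1:2] <- NA  # sample 1: call rate 8/10
  ds <- make_ds(geno, bp = seq(1e5, 1e6, length.out = 10))
  out <- apply_qc(ds, sample_cr = 0.9, marker_cr = 0.5)
  rep <- attr(out, "qc_report")
  expect_equal(nrow(out$geno), 9L)
  expect_equal(rep$removed[rep$step == "sample_call_rate"], 1L)
  # idempotence
  out2 <- apply_qc(out, sample_cr = 0.9, marker_cr = 0.5)
  expect_equal(out2$geno, out$geno)
  # thresholds of 0 and no MAF filter leave data unchanged (up to recoding)
  same <- apply_qc(recode_minor(ds), sample_cr = 0, marker_cr = 0,
                   autosomes_only = FALSE)
  expect_equal(dim(same$geno), dim(ds$geno))
  # MAF filter removes a monomorphic SNP
  geno2 <- cbind(geno, 0L)
  ds2 <- make_ds(geno2, bp = seq(1e5, 1.1e6, length.out = 11))
  out3 <- apply_qc(ds2, maf_min = 0.01)
  expect_equal(ncol(out3$geno), ncol(geno2) - 1L)
  expect_error(apply_qc(make_ds(matrix(NA_integer_, 2, 2), c(1, 2))),
               "every sample")
})

test_that("diversity matches a direct-counting oracle", {
  set.seed(42)
  geno <- matrix(rbinom(5 * 8, 2, runif(8, 0.2, 0.8)), 5, 8, byrow = TRUE)
  geno[2, 3] <- NA
  ds <- make_ds(geno, bp = seq(1e5, 8e5, length.out = 8))
  d <- diversity(ds)
  # per-SNP oracle by explicit counting
  for (j in seq_len(8)) {
    g <- geno[, j]
    nm <- sum(!is.na(g))
    expect_equal(d$per_snp$ho[j], sum(g == 1, na.rm = TRUE) / nm,
                 tolerance = 1e-12)
    p <- sum(g, na.rm = TRUE) / (2 * nm)
    expect_equal(d$per_snp$he[j], 2 * p * (1 - p), tolerance = 1e-12)
  }
  # per-sample F oracle
  p_all <- colSums(geno, na.rm = TRUE) / (2 * colSums(!is.na(geno)))
  t_all <- 2 * colSums(!is.na(geno))
  for (i in seq_len(5)) {
    obs <- !is.na(geno[i, ])
    o_hom <- sum(geno[i, obs] != 1)
    e_hom <- sum(1 - 2 * p_all[obs] * (1 - p_all[obs]) *
                   t_all[obs] / (t_all[obs] - 1))
    expect_equal(d$per_sample$f[i], (o_hom - e_hom) / (sum(obs) - e_hom),
                 tolerance = 1e-12)
  }
})

test_that("all-heterozygous data gives Ho = 1 and negative F", {
  ds <- make_ds(matrix(1L, 4, 6), bp = seq(1e5, 6e5, length.out = 6))
  d <- diversity(ds)
  expect_true(all(d$per_snp$ho == 1))
  expect_true(all(d$per_snp$he == 0.5))  # p = 0.5 closed form
  expect_true(all(d$per_sample$f < 0))
})

test_that("ld_r2 equals 1 with itself and tracks a direct correlation", {
  set.seed(11)
  x <- rbinom(100, 2, 0.4)
  y <- x
  flip <- 7
  y[flip] <- 2 - y[flip]
  ds <- make_ds(cbind(x, y), bp = c(1e5, 2e5))
  expect_equal(ld_r2(ds, 1, 1), 1.0)
  expect_equal(ld_r2(ds, "m1", "m2"), cor(x, y)^2, tolerance = 1e-12)
  # two independent markers, large n: r2 near zero
  set.seed(12)
  a <- rbinom(10000, 2, 0.3)
  b <- rbinom(10000, 2, 0.45)
  ds2 <- make_ds(cbind(a, b), bp = c(1e5, 2e5))
  expect_lt(ld_r2(ds2, 1, 2), 0.01)
})
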