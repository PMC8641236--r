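test_that("an all-homozygous chromosome yields exactly one spanning ROH", {
  bp <- seq(10000, 310000, length.out = 26)
  ds <- make_ds(matrix(2L, 1, 26), bp = bp)
  p <- run_params("ROH", window_snp = 10)
  runs <- detect_roh(ds, p)
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$start_bp, bp[1])
  expect_equal(runs$end_bp, bp[26])
  expect_equal(runs$n_snp, 26L)
  # fully heterozygous sample: zero runs
  het <- make_ds(matrix(1L, 1, 26), bp = bp)
  expect_equal(nrow(detect_roh(het, p)), 0L)
  # chromosome shorter than the window: warning, no runs
  short <- make_ds(matrix(2L, 1, 5), bp = bp[1:5])
  expect_warning(r0 <- detect_roh(short, run_params("ROH")), "fewer SNPs")
  expect_equal(nrow(r0), 0L)
})

test_that("ROH detection matches the brute-force window-enumeration oracle", {
  p <- run_params("ROH", window_snp = 15, min_snp = 10,
                  min_length_bp = 100000)
  for (seed in 1:12) {
    ds <- random_run_dataset(n_samples = 5, n_snps = 200, seed = seed)
    got <- detect_roh(ds, p)
    want <- oracle_roh(ds, p)
    ord <- function(r) {
      r <- r[order(r$sample, r$chr, r$start_bp), , drop = FALSE]
      rownames(r) <- NULL
      attr(r, "params") <- NULL
      r
    }
    expect_equal(ord(got), ord(want), info = paste("seed", seed))
  }
})

test_that("planted homozygous tract is recovered with matching boundaries", {
  set.seed(5)
  n_snps <- 1000
  geno <- matrix(1L, 1, n_snps)  # heterozygous background
  bp <- cumsum(sample(5000:15000, n_snps, replace = TRUE))
  tract <- 301:330  # 30 SNPs
  geno[1, tract] <- 2L
  ds <- make_ds(geno, bp = bp)
  p <- run_params("ROH", window_snp = 20)
  got <- detect_roh(ds, p)
  want <- oracle_roh(ds, p)
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$start_bp, want$start_bp)
  expect_equal(got$end_bp, want$end_bp)
  expect_equal(nrow(got), 1L)
  expect_gte(got$start_bp[1], bp[tract[1]])
  expect_lte(got$end_bp[1], bp[tract[length(tract)]])
})

test_that("a fully heterozygous chromosome yields one spanning ROHet", {
  bp <- seq(10000, 310000, length.out = 20)
  ds <- make_ds(matrix(1L, 1, 20), bp = bp)
  runs <- detect_rohet(ds, run_params("ROHet"))
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$n_snp, 20L)
  expect_equal(runs$start_bp, bp[1])
  # fully homozygous: none
  hom <- make_ds(matrix(0L, 1, 20), bp = bp)
  expect_equal(nrow(detect_rohet(hom, run_params("ROHet"))), 0L)
})

test_that("planted het tract with interior homozygotes matches the
           exhaustive subinterval oracle", {
  set.seed(6)
  m <- 120
  geno <- matrix(sample(c(0L, 2L), m, replace = TRUE), 1, m)  # hom background
  bp <- cumsum(sample(15000:30000, m, replace = TRUE))
  tract <- 50:67  # 18 SNPs
  geno[1, tract] <- 1L
  geno[1, c(55, 60)] <- 2L  # two interior homozygotes
  ds <- make_ds(geno, bp = bp)
  p <- run_params("ROHet")
  got <- detect_rohet(ds, p)
  want <- oracle_rohet(ds, p)
  expect_equal(got$start_bp, want$start_bp)
  expect_equal(got$end_bp, want$end_bp)
  expect_equal(nrow(got), 1L)
  expect_equal(got$start_bp[1], bp[50])
  expect_equal(got$end_bp[1], bp[67])
})

test_that("ROHet detection matches the oracle on random data", {
  p <- run_params("ROHet", min_snp = 8, min_length_bp = 50000)
  for (seed in 21:30) {
    ds <- random_run_dataset(n_samples = 5, n_snps = 150, seed = seed)
    got <- detect_rohet(ds, p)
    want <- oracle_rohet(ds, p)
    ord <- function(r) {
      r <- r[order(r$sample, r$chr, r$start_bp), , drop = FALSE]
      rownames(r) <- NULL
      attr(r, "params") <- NULL
      r
    }
    expect_equal(ord(got), ord(want), info = paste("seed", seed))
  }
})

test_that("emitted runs always satisfy their own constraints and are
           monotone in the thresholds", {
  p_roh <- run_params("ROH", window_snp = 15, min_snp = 10,
                      min_length_bp = 100000)
  p_het <- run_params("ROHet", min_snp = 8, min_length_bp = 50000)
  for (seed in 41:45) {
    ds <- random_run_dataset(n_samples = 6, n_snps = 200, seed = seed)
    roh <- detect_roh(ds, p_roh)
    het <- detect_rohet(ds, p_het)
    expect_true(validate_runs(roh, ds, p_roh))
    expect_true(validate_runs(het, ds, p_het))
    # raising min_snp / min_length never increases the run count
    p2 <- p_roh; p2$min_snp <- p_roh$min_snp + 5L
    p3 <- p_roh; p3$min_length_bp <- p_roh$min_length_bp * 2
    expect_lte(nrow(detect_roh(ds, p2)), nrow(roh))
    expect_lte(nrow(detect_roh(ds, p3)), nrow(roh))
  }
})

test_that("F_ROH equals covered length over autosome length", {
  bp <- seq(1, 1e6, length.out = 50)
  ds <- make_ds(matrix(2L, 2, 50), bp = bp)
  runs <- detect_roh(ds, run_params("ROH", window_snp = 10))
  fr <- froh(runs, ds)
  expect_equal(fr$froh, c(1, 1))  # single run covering the whole map
  # arithmetic case: 100 Mb + 150 Mb over L_aut = 2500 Mb
  fake_runs <- data.frame(sample = "s1", chr = 1L,
                          start_bp = c(1, 3e8), end_bp = c(1e8, 4.5e8),
                          length_bp = c(1e8, 1.5e8), n_snp = 10L,
                          n_opposite = 0L, n_miss = 0L)
  big <- make_ds(matrix(2L, 1, 2), bp = c(1, 2.5e9))
  fr2 <- froh(fake_runs, big)
  expect_equal(fr2$froh, 0.1)
  # size-class columns never exceed the overall F_ROH
  cls <- as.matrix(fr2[, grep("^froh_", names(fr2))])
  expect_true(all(cls <= fr2$froh + 1e-12))
  # empty run list: all zero
  fr3 <- froh(flockscan:::empty_run_frame(), ds)
  expect_true(all(fr3$froh == 0))
})

test_that("size classes bin left-closed right-open and conserve counts", {
  runs <- data.frame(length_bp = c(1e6, 7e6, 30e6))
  tab <- size_class_table(runs, breaks_bp = c(0, 6e6, 12e6, 24e6, 48e6))
  expect_equal(tab$n, c(1L, 1L, 0L, 1L, 0L))
  expect_equal(sum(tab$n), nrow(runs))
  empty <- size_class_table(data.frame(length_bp = numeric()),
                            breaks_bp = c(0, 6e6, 12e6))
  expect_true(all(empty$n == 0L))
})
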