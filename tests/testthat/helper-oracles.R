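# Independent oracle implementations and fixture builders used across the
# suite. Oracles recompute everything from scratch (no shared code with the
# package internals beyond the data container).

# Small dataset straight from a genotype matrix; positions in bp.
make_ds <- function(geno, bp, chr = rep(1L, length(bp)),
                    farm = rep("F1", nrow(geno))) {
  map <- data.frame(chr = chr, snp = paste0("m", seq_along(bp)), bp = bp,
                    a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  samples <- data.frame(id = paste0("s", seq_len(nrow(geno))), farm = farm,
                        stringsAsFactors = FALSE)
  genotype_dataset(geno, map, samples)
}

# Random single-chromosome dataset exercising het/missing/gap structure.
random_run_dataset <- function(n_samples, n_snps, seed,
                               missing_rate = 0.02) {
  set.seed(seed)
  p <- runif(n_snps, 0.1, 0.9)
  geno <- matrix(rbinom(n_samples * n_snps, 1, rep(p, each = n_samples)) +
                   rbinom(n_samples * n_snps, 1, rep(p, each = n_samples)),
                 n_samples, n_snps)
  geno[runif(n_samples * n_snps) < missing_rate] <- NA_integer_
  bp <- cumsum(sample(c(1e3:5e4, 3e5), n_snps, replace = TRUE))
  make_ds(geno, bp)
}

# Brute-force sliding-window ROH caller: every window and every candidate
# stretch evaluated directly from the definition.
oracle_roh <- function(ds, params) {
  out <- list()
  for (ch in unique(ds$map$chr)) {
    jj <- which(ds$map$chr == ch)
    m <- length(jj)
    w <- params$window_snp
    if (m < w) next
    bp <- ds$map$bp[jj]
    for (i in seq_len(nrow(ds$geno))) {
      g <- ds$geno[i, jj]
      is_het <- function(k) !is.na(g[k]) && g[k] == 1L
      is_mis <- function(k) is.na(g[k])
      is_hom <- function(k) !is.na(g[k]) && g[k] != 1L
      win_hom <- logical(m - w + 1L)
      for (s in seq_len(m - w + 1L)) {
        idx <- s:(s + w - 1L)
        win_hom[s] <- sum(vapply(idx, is_het, TRUE)) <= params$max_opposite &&
          sum(vapply(idx, is_mis, TRUE)) <= params$max_missing
      }
      cand <- logical(m)
      for (k in seq_len(m)) {
        wins <- max(1L, k - w + 1L):min(k, m - w + 1L)
        cand[k] <- mean(win_hom[wins]) >= params$window_hom_prop
      }
      # maximal candidate stretches with gap splits
      k <- 1L
      while (k <= m) {
        if (!cand[k]) { k <- k + 1L; next }
        e <- k
        while (e < m && cand[e + 1L] && bp[e + 1L] - bp[e] <=
                 params$max_gap_bp) e <- e + 1L
        s <- k
        while (s <= e && !is_hom(s)) s <- s + 1L
        ee <- e
        while (ee >= s && !is_hom(ee)) ee <- ee - 1L
        if (s <= ee) {
          n_snp <- ee - s + 1L
          len <- bp[ee] - bp[s] + 1
          n_het <- sum(vapply(s:ee, is_het, TRUE))
          n_mis <- sum(vapply(s:ee, is_mis, TRUE))
          if (n_snp >= params$min_snp && len >= params$min_length_bp &&
              n_het <= params$max_opposite && n_mis <= params$max_missing)
            out[[length(out) + 1L]] <- data.frame(
              sample = ds$samples$id[i], chr = ch, start_bp = bp[s],
              end_bp = bp[ee], length_bp = len, n_snp = n_snp,
              n_opposite = n_het, n_miss = n_mis, stringsAsFactors = FALSE)
        }
        k <- e + 1L
      }
    }
  }
  if (length(out)) do.call(rbind, out) else flockscan:::empty_run_frame()
}

# Exhaustive consecutive-method ROHet caller: for each scan origin the
# maximal feasible extension is found by direct evaluation of every
# subinterval (all constraints recomputed from scratch).
oracle_rohet <- function(ds, params) {
  feasible <- function(g, bp, s, e) {
    idx <- s:e
    if (sum(!is.na(g[idx]) & g[idx] != 1L) > params$max_opposite) return(FALSE)
    if (sum(is.na(g[idx])) > params$max_missing) return(FALSE)
    if (e > s && any(diff(bp[idx]) > params$max_gap_bp)) return(FALSE)
    TRUE
  }
  out <- list()
  for (ch in unique(ds$map$chr)) {
    jj <- which(ds$map$chr == ch)
    m <- length(jj)
    bp <- ds$map$bp[jj]
    for (i in seq_len(nrow(ds$geno))) {
      g <- ds$geno[i, jj]
      s <- 1L
      while (s <= m) {
        if (!feasible(g, bp, s, s)) { s <- s + 1L; next }
        e <- s
        while (e < m && feasible(g, bp, s, e + 1L)) e <- e + 1L
        ts <- s; te <- e
        while (ts <= te && !(!is.na(g[ts]) && g[ts] == 1L)) ts <- ts + 1L
        while (te >= ts && !(!is.na(g[te]) && g[te] == 1L)) te <- te - 1L
        emitted <- FALSE
        if (ts <= te && te - ts + 1L >= params$min_snp &&
            bp[te] - bp[ts] + 1 >= params$min_length_bp) {
          idx <- ts:te
          out[[length(out) + 1L]] <- data.frame(
            sample = ds$samples$id[i], chr = ch, start_bp = bp[ts],
            end_bp = bp[te], length_bp = bp[te] - bp[ts] + 1,
            n_snp = te - ts + 1L,
            n_opposite = sum(!is.na(g[idx]) & g[idx] != 1L),
            n_miss = sum(is.na(g[idx])), stringsAsFactors = FALSE)
          emitted <- TRUE
          s <- te + 1L
        }
        if (!emitted) s <- s + 1L
      }
    }
  }
  if (length(out)) do.call(rbind, out) else flockscan:::empty_run_frame()
}

# Post-hoc validator: every emitted run satisfies its parameter constraints.
validate_runs <- function(runs, ds, params) {
  if (!nrow(runs)) return(TRUE)
  for (k in seq_len(nrow(runs))) {
    i <- match(runs$sample[k], ds$samples$id)
    jj <- which(ds$map$chr == runs$chr[k] & ds$map$bp >= runs$start_bp[k] &
                  ds$map$bp <= runs$end_bp[k])
    g <- ds$geno[i, jj]
    opp <- if (params$kind == "ROH") sum(!is.na(g) & g == 1L) else
      sum(!is.na(g) & g != 1L)
    ok <- length(jj) >= params$min_snp &&
      runs$length_bp[k] >= params$min_length_bp &&
      opp <= params$max_opposite &&
      sum(is.na(g)) <= params$max_missing &&
      all(diff(ds$map$bp[jj]) <= params$max_gap_bp)
    if (!ok) return(FALSE)
  }
  TRUE
}

# Shared mid-sized simulated dataset for expensive modules (built once per
# test run).
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_individuals = 200, n_snps = 800,
                        n_chromosomes = 2, chromosome_length_bp = 4e7,
                        missing_rate = 0.002, records_mean = 10, seed = 314)
      g <- simulate_genotypes(cfg)
      ph <- simulate_phenotypes(g$dataset, g$truth, cfg)
      cache <<- list(cfg = cfg, dataset = g$dataset, truth = ph$truth,
                     records = ph$records)
    }
    cache
  }
})
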