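#' Parameters for run detection
#'
#' Defaults are the standard medium-density array settings: for runs of
#' homozygosity (ROH), a 50-SNP sliding window, a homozygous-window
#' proportion threshold of 0.05, a minimum of 20 SNPs and 250 kb per run, a
#' maximum inter-SNP gap of 250 kb, and at most 1 heterozygous and 1 missing
#' call per run. For heterozygosity-rich regions (ROHet, consecutive
#' method), a minimum of 15 SNPs and 250 kb, the same gap cap, and at most 3
#' homozygous and 2 missing calls.
#'
#' @param kind \code{"ROH"} or \code{"ROHet"}.
#' @param window_snp sliding-window size in SNPs (ROH only).
#' @param window_hom_prop minimum proportion of homozygous overlapping
#'   windows for a SNP to be a run candidate (ROH only).
#' @param min_snp minimum SNPs per run.
#' @param min_length_bp minimum run length in bp.
#' @param max_gap_bp maximum gap between consecutive SNPs inside a run.
#' @param max_missing maximum missing calls per window and per run.
#' @param max_opposite maximum opposite-state calls per window and per run
#'   (heterozygotes for ROH, homozygotes for ROHet).
#' @return a list of class \code{run_params}.
#' @export
run_params <- function(kind = c("ROH", "ROHet"), window_snp = 50L,
                       window_hom_prop = 0.05,
                       min_snp = if (kind == "ROH") 20L else 15L,
                       min_length_bp = 250000, max_gap_bp = 250000,
                       max_missing = if (kind == "ROH") 1L else 2L,
                       max_opposite = if (kind == "ROH") 1L else 3L) {
  kind <- match.arg(kind)
  stopifnot(window_snp >= 1, window_hom_prop > 0, window_hom_prop <= 1,
            min_snp >= 1, min_length_bp > 0, max_gap_bp > 0,
            max_missing >= 0, max_opposite >= 0)
  structure(list(kind = kind, window_snp = as.integer(window_snp),
                 window_hom_prop = window_hom_prop,
                 min_snp = as.integer(min_snp),
                 min_length_bp = min_length_bp, max_gap_bp = max_gap_bp,
                 max_missing = as.integer(max_missing),
                 max_opposite = as.integer(max_opposite)),
            class = "run_params")
}

empty_run_frame <- function() {
  data.frame(sample = character(), chr = integer(), start_bp = numeric(),
             end_bp = numeric(), length_bp = numeric(), n_snp = integer(),
             n_opposite = integer(), n_miss = integer(),
             stringsAsFactors = FALSE)
}

## Trim a candidate stretch [s, e] (chromosome-local indices) so both
## endpoints are in the target state (homozygous for ROH, het for ROHet).
## Returns c(s, e) or NULL if nothing remains.
trim_to_state <- function(s, e, target) {
  while (s <= e && !target[s]) s <- s + 1L
  while (e >= s && !target[e]) e <- e - 1L
  if (s > e) NULL else c(s, e)
}

run_row <- function(id, chr, bp, s, e, opp, mis) {
  data.frame(sample = id, chr = chr, start_bp = bp[s], end_bp = bp[e],
             length_bp = bp[e] - bp[s] + 1, n_snp = e - s + 1L,
             n_opposite = sum(opp[s:e]), n_miss = sum(mis[s:e]),
             stringsAsFactors = FALSE)
}

#' Detect runs of homozygosity by the sliding-window method
#'
#' For each sample and chromosome a window of \code{window_snp} SNPs slides
#' one SNP at a time (windows fully inside the chromosome). A window is
#' homozygous when it contains at most \code{max_opposite} heterozygotes and
#' at most \code{max_missing} missing calls. Each SNP receives the proportion
#' of its overlapping windows that are homozygous; SNPs at or above
#' \code{window_hom_prop} are candidates. Maximal candidate stretches are
#' split at inter-SNP gaps larger than \code{max_gap_bp}, trimmed to
#' homozygous non-missing endpoints, and kept when they satisfy the minimum
#' SNP count and length and the per-run heterozygote/missing caps.
#'
#' @param ds a [genotype_dataset()].
#' @param params a [run_params()] with \code{kind = "ROH"}.
#' @return data.frame of runs (sample, chr, start_bp, end_bp, length_bp,
#'   n_snp, n_opposite, n_miss) with \code{params} attached as an attribute;
#'   \code{n_opposite} counts heterozygotes.
#' @export
detect_roh <- function(ds, params = run_params("ROH")) {
  stopifnot(inherits(params, "run_params"), params$kind == "ROH")
  out <- list()
  chrs <- unique(ds$map$chr)
  short <- character()
  for (ch in chrs) {
    jj <- which(ds$map$chr == ch)
    m <- length(jj)
    if (m < params$window_snp) {
      short <- c(short, as.character(ch))
      next
    }
    bp <- ds$map$bp[jj]
    w <- params$window_snp
    nw <- m - w + 1L
    gap_break <- c(diff(bp) > params$max_gap_bp, FALSE)
    for (i in seq_len(n_samples(ds))) {
      g <- ds$geno[i, jj]
      mis <- is.na(g)
      het <- !mis & g == 1L
      hom <- !mis & g != 1L
      ch_het <- cumsum(het); ch_mis <- cumsum(mis)
      het_in_w <- ch_het[w:m] - c(0L, ch_het)[1:nw]
      mis_in_w <- ch_mis[w:m] - c(0L, ch_mis)[1:nw]
      win_hom <- het_in_w <= params$max_opposite &
        mis_in_w <= params$max_missing
      cw <- c(0L, cumsum(win_hom))
      idx <- seq_len(m)
      lo <- pmax(1L, idx - w + 1L)
      hi <- pmin(idx, nw)
      lo <- pmin(lo, nw)
      n_over <- hi - lo + 1L
      n_hom_over <- cw[hi + 1L] - cw[lo]
      cand <- n_hom_over / n_over >= params$window_hom_prop
      # maximal candidate stretches, split at oversized gaps
      runs_se <- stretch_bounds(cand, gap_break)
      for (se in runs_se) {
        tr <- trim_to_state(se[1L], se[2L], hom)
        if (is.null(tr)) next
        s <- tr[1L]; e <- tr[2L]
        if (e - s + 1L < params$min_snp) next
        if (bp[e] - bp[s] + 1 < params$min_length_bp) next
        if (sum(het[s:e]) > params$max_opposite) next
        if (sum(mis[s:e]) > params$max_missing) next
        out[[length(out) + 1L]] <-
          run_row(ds$samples$id[i], ch, bp, s, e, het, mis)
      }
    }
  }
  if (length(short))
    warning("chromosome(s) with fewer SNPs than window_snp skipped: ",
            paste(short, collapse = ", "))
  res <- if (length(out)) do.call(rbind, out) else empty_run_frame()
  rownames(res) <- NULL
  attr(res, "params") <- params
  res
}

## Maximal stretches of TRUE in `cand`, additionally split after position i
## whenever gap_break[i] is TRUE. Returns list of c(start, end).
stretch_bounds <- function(cand, gap_break) {
  m <- length(cand)
  res <- list()
  s <- NA_integer_
  for (i in seq_len(m)) {
    if (cand[i] && is.na(s)) s <- i
    end_here <- FALSE
    if (!is.na(s)) {
      if (i == m || !cand[i + 1L] || gap_break[i]) end_here <- TRUE
    }
    if (end_here) {
      res[[length(res) + 1L]] <- c(s, i)
      s <- NA_integer_
    }
  }
  res
}

#' Detect heterozygosity-rich regions by the consecutive method
#'
#' Scans each sample's chromosome left to right growing a candidate run; the
#' candidate stops just before the SNP whose inclusion would exceed
#' \code{max_opposite} homozygotes or \code{max_missing} missing calls, or
#' when the gap to the next SNP exceeds \code{max_gap_bp}. The candidate is
#' trimmed to heterozygous endpoints and emitted when it has at least
#' \code{min_snp} SNPs and \code{min_length_bp} bp. After an emitted run the
#' scan resumes at the SNP following the run (greedy, non-overlapping);
#' after a rejected candidate it resumes one SNP to the right of the
#' candidate's origin, so a later-starting passing interval is never missed.
#'
#' @inheritParams detect_roh
#' @param params a [run_params()] with \code{kind = "ROHet"}.
#' @return data.frame of runs as in [detect_roh()]; \code{n_opposite} counts
#'   homozygotes.
#' @export
detect_rohet <- function(ds, params = run_params("ROHet")) {
  stopifnot(inherits(params, "run_params"), params$kind == "ROHet")
  out <- list()
  for (ch in unique(ds$map$chr)) {
    jj <- which(ds$map$chr == ch)
    m <- length(jj)
    bp <- ds$map$bp[jj]
    for (i in seq_len(n_samples(ds))) {
      g <- ds$geno[i, jj]
      mis <- is.na(g)
      het <- !mis & g == 1L
      hom <- !mis & g != 1L
      s <- 1L
      while (s <= m) {
        # grow maximal candidate from s
        e <- s
        n_opp <- as.integer(hom[s]); n_mis <- as.integer(mis[s])
        if (n_opp > params$max_opposite || n_mis > params$max_missing) {
          s <- s + 1L
          next
        }
        while (e < m) {
          if (bp[e + 1L] - bp[e] > params$max_gap_bp) break
          no2 <- n_opp + hom[e + 1L]
          nm2 <- n_mis + mis[e + 1L]
          if (no2 > params$max_opposite || nm2 > params$max_missing) break
          e <- e + 1L
          n_opp <- no2; n_mis <- nm2
        }
        tr <- trim_to_state(s, e, het)
        emitted <- FALSE
        if (!is.null(tr)) {
          ts <- tr[1L]; te <- tr[2L]
          if (te - ts + 1L >= params$min_snp &&
              bp[te] - bp[ts] + 1 >= params$min_length_bp) {
            out[[length(out) + 1L]] <-
              run_row(ds$samples$id[i], ch, bp, ts, te, hom, mis)
            emitted <- TRUE
            s <- te + 1L
          }
        }
        if (!emitted) s <- s + 1L
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty_run_frame()
  rownames(res) <- NULL
  attr(res, "params") <- params
  res
}

#' Genomic inbreeding from runs of homozygosity
#'
#' F_ROH for each individual is the summed length of its ROH divided by the
#' autosome length covered by the marker map,
#' L_aut = sum over chromosomes of (last SNP bp - first SNP bp + 1).
#' Class-restricted versions sum only runs whose length falls in each class.
#'
#' @param runs run data.frame from [detect_roh()].
#' @param ds the [genotype_dataset()] the runs came from.
#' @param classes_mb numeric vector of left edges (Mb) of the length classes;
#'   each class is left-closed, right-open, the last is unbounded. Default
#'   classes: [2,4), [4,8), [8,16), [16,Inf) Mb.
#' @return data.frame with one row per sample: \code{id}, \code{froh}, and
#'   one \code{froh_<class>} column per class; \code{L_aut} attached as an
#'   attribute.
#' @export
froh <- function(runs, ds, classes_mb = c(2, 4, 8, 16)) {
  l_aut <- sum(tapply(ds$map$bp, ds$map$chr, function(x)
    max(x) - min(x) + 1))
  ids <- as.character(ds$samples$id)
  tot <- tapply(runs$length_bp, factor(runs$sample, levels = ids), sum)
  tot[is.na(tot)] <- 0
  res <- data.frame(id = ids, froh = as.numeric(tot) / l_aut,
                    stringsAsFactors = FALSE)
  edges <- c(classes_mb * 1e6, Inf)
  for (k in seq_along(classes_mb)) {
    in_cls <- runs$length_bp >= edges[k] & runs$length_bp < edges[k + 1L]
    cls_tot <- tapply(runs$length_bp[in_cls],
                      factor(runs$sample[in_cls], levels = ids), sum)
    cls_tot[is.na(cls_tot)] <- 0
    lab <- if (is.finite(edges[k + 1L]))
      sprintf("froh_%g_%gMb", classes_mb[k], edges[k + 1L] / 1e6)
    else sprintf("froh_gt%gMb", classes_mb[k])
    res[[lab]] <- as.numeric(cls_tot) / l_aut
  }
  attr(res, "L_aut") <- l_aut
  res
}

#' Count runs per length class
#'
#' @param runs run data.frame.
#' @param breaks_bp increasing numeric vector of bin edges in bp; bins are
#'   left-closed, right-open; a final \code{Inf} edge is appended when the
#'   last edge is finite.
#' @return data.frame with columns \code{class} and \code{n}.
#' @export
size_class_table <- function(runs, breaks_bp) {
  stopifnot(!is.unsorted(breaks_bp, strictly = TRUE))
  if (is.finite(breaks_bp[length(breaks_bp)]))
    breaks_bp <- c(breaks_bp, Inf)
  cls <- cut(runs$length_bp, breaks = breaks_bp, right = FALSE,
             include.lowest = FALSE)
  tab <- table(cls)
  data.frame(class = names(tab), n = as.integer(tab),
             stringsAsFactors = FALSE)
}
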