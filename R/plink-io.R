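#' Read genotypes from PED/MAP or BED/BIM/FAM files
#'
#' Both readers produce the same container: dosages of the counted allele,
#' which is the minor allele observed in the file (lexicographic tie-break;
#' see [recode_minor()]). The BED reader decodes the standard SNP-major
#' 2-bit encoding (magic bytes 0x6C 0x1B, mode 0x01) exactly.
#'
#' @param prefix path prefix; \code{<prefix>.ped/.map} or
#'   \code{<prefix>.bed/.bim/.fam} must exist.
#' @param format \code{"ped_map"} or \code{"bed_bim_fam"}.
#' @return a [genotype_dataset()].
#' @export
read_genotypes <- function(prefix, format = c("ped_map", "bed_bim_fam")) {
  format <- match.arg(format)
  if (format == "ped_map") read_ped_map(prefix) else read_bed_bim_fam(prefix)
}

read_map_file <- function(path) {
  map <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(map) < 4L) stop("map file ", path, " needs 4 columns (chr snp cm bp)")
  data.frame(chr = as.integer(map[[1L]]), snp = as.character(map[[2L]]),
             bp = as.numeric(map[[4L]]), stringsAsFactors = FALSE)
}

read_ped_map <- function(prefix) {
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  for (p in c(ped_path, map_path)) if (!file.exists(p)) stop("missing file: ", p)
  map <- read_map_file(map_path)
  m <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 6L + 2L * m))
    stop("PED file ", ped_path, " has rows with ", nf[nf != 6L + 2L * m][1L],
         " fields but ", map_path, " defines ", m, " markers (need ",
         6L + 2L * m, ")")
  n <- length(fields)
  ped <- matrix(unlist(fields), nrow = n, byrow = TRUE)
  samples <- data.frame(id = ped[, 2L], farm = ped[, 1L],
                        stringsAsFactors = FALSE)
  al1 <- ped[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  al2 <- ped[, 6L + 2L * seq_len(m), drop = FALSE]
  geno <- matrix(NA_integer_, n, m)
  a1 <- a2 <- character(m)
  for (j in seq_len(m)) {
    x1 <- al1[, j]; x2 <- al2[, j]
    miss <- x1 == "0" | x2 == "0"
    obs <- sort(unique(c(x1[!miss], x2[!miss])))
    if (length(obs) > 2L)
      stop("marker ", map$snp[j], " is not biallelic: alleles ",
           paste(obs, collapse = "/"))
    if (length(obs) == 0L) obs <- c("A", "B")
    if (length(obs) == 1L) obs <- c(obs, setdiff(c("A", "B"), obs)[1L])
    a1[j] <- obs[1L]; a2[j] <- obs[2L]
    g <- (x1 == obs[1L]) + (x2 == obs[1L])
    g[miss] <- NA_integer_
    geno[, j] <- g
  }
  map$a1 <- a1; map$a2 <- a2
  recode_minor(genotype_dataset(geno, map, samples))
}

read_bed_bim_fam <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  for (p in paths) if (!file.exists(p)) stop("missing file: ", p)
  bim <- utils::read.table(paths[2L], header = FALSE, stringsAsFactors = FALSE)
  map <- data.frame(chr = as.integer(bim[[1L]]), snp = as.character(bim[[2L]]),
                    bp = as.numeric(bim[[4L]]), a1 = as.character(bim[[5L]]),
                    a2 = as.character(bim[[6L]]), stringsAsFactors = FALSE)
  fam <- utils::read.table(paths[3L], header = FALSE, stringsAsFactors = FALSE)
  samples <- data.frame(id = as.character(fam[[2L]]),
                        farm = as.character(fam[[1L]]), stringsAsFactors = FALSE)
  n <- nrow(fam); m <- nrow(map)
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(paths[1L], "raw", n = 3L + m * bytes_per_snp)
  if (length(raw) < 3L || raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b))
    stop("not a BED file (bad magic bytes): ", paths[1L])
  if (raw[3L] != as.raw(0x01))
    stop("only SNP-major BED files are supported: ", paths[1L])
  if (length(raw) != 3L + m * bytes_per_snp)
    stop("BED file ", paths[1L], " size inconsistent with ", paths[2L],
         " (", m, " markers) and ", paths[3L], " (", n, " samples)")
  body <- as.integer(raw[-(1:3)])
  # 2-bit codes per sample, least-significant pair first:
  # 00 = hom a1, 01 = missing, 10 = het, 11 = hom a2
  codes <- matrix(0L, nrow = 4L * bytes_per_snp, ncol = m)
  b <- matrix(body, nrow = bytes_per_snp, ncol = m)
  for (k in 0:3) {
    codes[seq.int(k + 1L, by = 4L, length.out = bytes_per_snp), ] <-
      b %% 4L
    b <- b %/% 4L
  }
  codes <- codes[seq_len(n), , drop = FALSE]
  lut <- c(2L, NA_integer_, 1L, 0L)  # dosage of a1 per code 0..3
  geno <- matrix(lut[codes + 1L], n, m)
  recode_minor(genotype_dataset(geno, map, samples))
}

#' Write a genotype dataset to PLINK text or binary files
#'
#' @param ds a [genotype_dataset()].
#' @param prefix output path prefix.
#' @param format \code{"ped_map"} or \code{"bed_bim_fam"}.
#' @return \code{prefix}, invisibly.
#' @export
write_genotypes <- function(ds, prefix, format = c("ped_map", "bed_bim_fam")) {
  format <- match.arg(format)
  map <- ds$map
  if (format == "ped_map") {
    utils::write.table(
      data.frame(map$chr, map$snp, 0, format(map$bp, scientific = FALSE,
                                             trim = TRUE)),
      paste0(prefix, ".map"), quote = FALSE, sep = "\t",
      row.names = FALSE, col.names = FALSE)
    n <- n_samples(ds); m <- n_markers(ds)
    a1 <- as.character(map$a1); a2 <- as.character(map$a2)
    out <- matrix("", n, 6L + 2L * m)
    out[, 1L] <- as.character(ds$samples$farm)
    out[, 2L] <- as.character(ds$samples$id)
    out[, 3L] <- "0"; out[, 4L] <- "0"; out[, 5L] <- "0"; out[, 6L] <- "-9"
    for (j in seq_len(m)) {
      g <- ds$geno[, j]
      c1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, a1[j], a2[j]))
      c2 <- ifelse(is.na(g), "0", ifelse(g == 2L, a1[j], a2[j]))
      out[, 6L + 2L * j - 1L] <- c1
      out[, 6L + 2L * j] <- c2
    }
    writeLines(apply(out, 1L, paste, collapse = " "), paste0(prefix, ".ped"))
  } else {
    utils::write.table(
      data.frame(map$chr, map$snp, 0, format(map$bp, scientific = FALSE,
                                             trim = TRUE), map$a1, map$a2),
      paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
      row.names = FALSE, col.names = FALSE)
    utils::write.table(
      data.frame(ds$samples$farm, ds$samples$id, 0, 0, 0, -9),
      paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
      row.names = FALSE, col.names = FALSE)
    n <- n_samples(ds); m <- n_markers(ds)
    bytes_per_snp <- ceiling(n / 4)
    code <- matrix(1L, 4L * bytes_per_snp, m)  # pad with "missing"
    g <- ds$geno
    cd <- matrix(NA_integer_, n, m)
    cd[!is.na(g) & g == 2L] <- 0L
    cd[is.na(g)] <- 1L
    cd[!is.na(g) & g == 1L] <- 2L
    cd[!is.na(g) & g == 0L] <- 3L
    code[seq_len(n), ] <- cd
    w <- matrix(0L, bytes_per_snp, m)
    for (k in 0:3) {
      w <- w + code[seq.int(k + 1L, by = 4L, length.out = bytes_per_snp), ,
                    drop = FALSE] * 4L^k
    }
    con <- file(paste0(prefix, ".bed"), "wb")
    on.exit(close(con))
    writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
    writeBin(as.raw(as.vector(w)), con)
  }
  invisible(prefix)
}
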