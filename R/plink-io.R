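# PLINK 1 binary layout: 3 magic bytes 0x6c 0x1b 0x01, then (variant-major)
# ceil(n_samples/4) bytes per variant, two bits per sample, least-significant
# pair first: 00 = hom A1/A1 (dosage 2), 01 = missing, 10 = het (1),
# 11 = hom A2/A2 (0).

.bed_magic <- as.raw(c(0x6c, 0x1b, 0x01))

# dosage (0/1/2/NA) -> 2-bit code and back
.code_from_dosage <- c(`2` = 0L, `1` = 2L, `0` = 3L)
.dosage_from_code <- c(2L, NA_integer_, 1L, 0L)  # codes 0,1,2,3

#' Read PLINK bed/bim/fam binary genotypes
#'
#' Loads a PLINK 1 binary fileset into a \code{\link{genotype_dataset}}.
#' Genotypes count copies of the first .bim allele (A1). Sample order follows
#' the .fam file; the population label is taken from the .fam family id.
#' Variants are sorted by (chromosome, position) after loading.
#'
#' @param prefix path prefix, or explicit \code{bed}/\code{bim}/\code{fam}
#'   paths.
#' @param bed,bim,fam optional explicit file paths overriding \code{prefix}.
#' @return A \code{genotype_dataset}.
#' @export
read_plink <- function(prefix, bed = NULL, bim = NULL, fam = NULL) {
  if (is.null(bed)) bed <- paste0(prefix, ".bed")
  if (is.null(bim)) bim <- paste0(prefix, ".bim")
  if (is.null(fam)) fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)

  bim_df <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                              col.names = c("chrom", "id", "cm", "pos",
                                            "a1", "a2"))
  fam_df <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE,
                              col.names = c("fid", "iid", "pid", "mid",
                                            "sex", "pheno"))
  n <- nrow(fam_df)
  m <- nrow(bim_df)
  bytes_per_var <- ceiling(n / 4)

  con <- file(bed, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 3)
  if (length(magic) < 3 || magic[1] != .bed_magic[1] ||
      magic[2] != .bed_magic[2])
    stop("not a PLINK .bed file (bad magic bytes): ", bed, call. = FALSE)
  if (magic[3] != .bed_magic[3])
    stop("only SNP-major (variant-major) .bed files are supported: ", bed,
         call. = FALSE)
  payload <- readBin(con, "raw", n = bytes_per_var * m + 1L)
  if (length(payload) != bytes_per_var * m)
    stop(".bed payload size does not match .bim/.fam dimensions (",
         length(payload), " bytes, expected ", bytes_per_var * m, ")",
         call. = FALSE)

  b <- as.integer(payload)
  dim(b) <- c(bytes_per_var, m)
  # expand each byte into its four 2-bit codes, samples within byte LSB first
  g <- matrix(NA_integer_, nrow = n, ncol = m)
  for (k in 0:3) {
    idx <- seq.int(k + 1L, by = 4L, length.out = bytes_per_var)
    rows <- idx[idx <= n]
    if (!length(rows)) next
    codes <- (b[ceiling(rows / 4), , drop = FALSE] %/% (4L^k)) %% 4L
    g[rows, ] <- .dosage_from_code[codes + 1L]
  }

  samples <- data.frame(sample_id = fam_df$iid,
                        population = fam_df$fid,
                        stringsAsFactors = FALSE)
  variants <- bim_df[, c("chrom", "id", "pos", "a1", "a2")]
  genotype_dataset(g, samples, variants)
}

#' Write PLINK bed/bim/fam binary genotypes
#'
#' Inverse of \code{\link{read_plink}}: the population label becomes the .fam
#' family id and genotypes are encoded as allele-1 dosages in SNP-major
#' order. Round-trips the genotype matrix bit-exactly for all legal states.
#'
#' @param dataset a \code{genotype_dataset}.
#' @param prefix output path prefix (writes \code{prefix.bed/.bim/.fam}).
#' @return \code{prefix}, invisibly.
#' @export
write_plink <- function(dataset, prefix) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  g <- dataset$genotypes
  n <- nrow(g)
  m <- ncol(g)
  v <- dataset$variants
  s <- dataset$samples

  utils::write.table(
    data.frame(v$chrom, v$id, 0L, v$pos, v$a1, v$a2),
    paste0(prefix, ".bim"),
    quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(s$population, s$sample_id, 0L, 0L, 0L, -9L),
    paste0(prefix, ".fam"),
    quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)

  codes <- matrix(1L, nrow = 4 * ceiling(n / 4), ncol = m)  # pad = missing
  gc <- g
  gc[] <- ifelse(is.na(g), 1L,
                 ifelse(g == 2L, 0L, ifelse(g == 1L, 2L, 3L)))
  codes[seq_len(n), ] <- gc
  dim(codes) <- c(4L, length(codes) / 4L)
  bytes <- as.raw(codes[1, ] + 4L * codes[2, ] + 16L * codes[3, ] +
                    64L * codes[4, ])
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.bed_magic, con)
  writeBin(bytes, con)
  invisible(prefix)
}

#' Write PLINK ped/map text genotypes
#'
#' @param dataset a \code{genotype_dataset}.
#' @param prefix output path prefix (writes \code{prefix.ped/.map}).
#' @return \code{prefix}, invisibly.
#' @export
write_pedmap <- function(dataset, prefix) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  v <- dataset$variants
  s <- dataset$samples
  g <- dataset$genotypes
  utils::write.table(
    data.frame(v$chrom, v$id, 0L, v$pos),
    paste0(prefix, ".map"),
    quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  n <- nrow(g)
  m <- ncol(g)
  al1 <- matrix("0", n, m)
  al2 <- matrix("0", n, m)
  a1m <- matrix(v$a1, n, m, byrow = TRUE)
  a2m <- matrix(v$a2, n, m, byrow = TRUE)
  keep <- !is.na(g)
  al1[keep] <- ifelse(g[keep] >= 1L, a1m[keep], a2m[keep])
  al2[keep] <- ifelse(g[keep] == 2L, a1m[keep], a2m[keep])
  inter <- matrix("", n, 2 * m)
  inter[, seq(1, 2 * m, 2)] <- al1
  inter[, seq(2, 2 * m, 2)] <- al2
  lines <- apply(cbind(s$population, s$sample_id, "0", "0", "0", "-9", inter),
                 1, paste, collapse = " ")
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(prefix)
}

#' Read PLINK ped/map text genotypes
#'
#' The .ped dialect stores allele symbols, not dosages; genotypes are returned
#' as counts of a designated allele per variant. By default the designated
#' (A1) allele is the lexicographically smaller of the observed alleles; pass
#' \code{a1} to fix the counted allele explicitly (e.g. for round-trips).
#'
#' @param prefix path prefix (reads \code{prefix.ped/.map}).
#' @param a1 optional character vector, one counted allele per variant.
#' @return A \code{genotype_dataset}.
#' @export
read_pedmap <- function(prefix, a1 = NULL) {
  map <- utils::read.table(paste0(prefix, ".map"), header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "id", "cm", "pos"))
  ped <- utils::read.table(paste0(prefix, ".ped"), header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6 + 2 * m)
    stop(".ped has ", ncol(ped) - 6, " allele columns for ", m,
         " .map variants", call. = FALSE)
  n <- nrow(ped)
  al1 <- as.matrix(ped[, 6 + seq(1, 2 * m, 2), drop = FALSE])
  al2 <- as.matrix(ped[, 6 + seq(2, 2 * m, 2), drop = FALSE])
  a1v <- character(m)
  a2v <- character(m)
  g <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    obs <- setdiff(sort(unique(c(al1[, j], al2[, j]))), "0")
    if (length(obs) > 2)
      stop("variant ", map$id[j], " has >2 alleles in .ped", call. = FALSE)
    aj <- if (!is.null(a1)) a1[j] else if (length(obs)) obs[1] else "0"
    bj <- setdiff(obs, aj)
    a1v[j] <- aj
    a2v[j] <- if (length(bj)) bj[1] else aj
    ok <- al1[, j] != "0" & al2[, j] != "0"
    g[ok, j] <- (al1[ok, j] == aj) + (al2[ok, j] == aj)
  }
  samples <- data.frame(sample_id = ped[[2]], population = ped[[1]],
                        stringsAsFactors = FALSE)
  variants <- data.frame(chrom = map$chrom, id = map$id, pos = map$pos,
                         a1 = a1v, a2 = a2v, stringsAsFactors = FALSE)
  genotype_dataset(g, samples, variants)
}
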