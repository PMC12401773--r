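#' Construct a genotype dataset
#'
#' Container for diploid autosomal SNP genotypes: a samples x variants matrix
#' of allele-1 dosages together with sample records (id, population label) and
#' variant records (chromosome, 1-based bp position, alleles). Variants are
#' sorted by (chromosome, position) on construction; positions must be strictly
#' increasing within each chromosome.
#'
#' @param genotypes integer matrix, samples in rows, variants in columns;
#'   entries in \{0, 1, 2, NA\} counting copies of allele 1.
#' @param samples data.frame with columns \code{sample_id} and
#'   \code{population}.
#' @param variants data.frame with columns \code{chrom}, \code{id},
#'   \code{pos} (1-based bp), \code{a1}, \code{a2}.
#' @return An object of class \code{genotype_dataset}.
#' @export
genotype_dataset <- function(genotypes, samples, variants) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  stopifnot(
    all(c("sample_id", "population") %in% names(samples)),
    all(c("chrom", "id", "pos", "a1", "a2") %in% names(variants))
  )
  if (nrow(genotypes) != nrow(samples))
    stop("genotype matrix has ", nrow(genotypes), " rows but ", nrow(samples),
         " sample records", call. = FALSE)
  if (ncol(genotypes) != nrow(variants))
    stop("genotype matrix has ", ncol(genotypes), " columns but ",
         nrow(variants), " variant records", call. = FALSE)
  bad <- !(genotypes %in% c(0L, 1L, 2L) | is.na(genotypes))
  if (any(bad))
    stop("genotypes must be 0, 1, 2 or NA", call. = FALSE)
  chrom_key <- suppressWarnings(as.numeric(variants$chrom))
  ord <- if (anyNA(chrom_key)) order(variants$chrom, variants$pos) else
    order(chrom_key, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  genotypes <- genotypes[, ord, drop = FALSE]
  rownames(variants) <- NULL
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (anyDuplicated(p))
      stop("duplicate positions on chromosome ", ch, call. = FALSE)
  }
  rownames(genotypes) <- samples$sample_id
  colnames(genotypes) <- variants$id
  structure(
    list(genotypes = genotypes, samples = samples, variants = variants),
    class = "genotype_dataset"
  )
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$genotypes), "samples x",
      ncol(x$genotypes), "variants on",
      length(unique(x$variants$chrom)), "chromosome(s)\n")
  pops <- table(x$samples$population)
  cat("populations:", paste(names(pops), pops, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$genotypes)

#' Subset a genotype dataset by samples and/or variants
#'
#' @param dataset a \code{genotype_dataset}.
#' @param samples logical/integer/character index into sample records.
#' @param variants logical/integer index into variant records.
#' @return A \code{genotype_dataset}.
#' @export
subset_dataset <- function(dataset, samples = NULL, variants = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  g <- dataset$genotypes
  s <- dataset$samples
  v <- dataset$variants
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, s$sample_id)
    g <- g[samples, , drop = FALSE]
    s <- s[samples, , drop = FALSE]
  }
  if (!is.null(variants)) {
    g <- g[, variants, drop = FALSE]
    v <- v[variants, , drop = FALSE]
  }
  rownames(s) <- NULL
  genotype_dataset(g, s, v)
}

#' Per-variant allele-1 frequencies over non-missing calls
#'
#' @param dataset a \code{genotype_dataset}.
#' @return Numeric vector of allele-1 frequencies (NaN where no calls).
#' @export
allele_frequencies <- function(dataset) {
  g <- dataset$genotypes
  colSums(g, na.rm = TRUE) / (2 * colSums(!is.na(g)))
}
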