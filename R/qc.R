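#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test of HWE for a biallelic genotype count triple: the
#' p-value is the sum of the probabilities of all heterozygote counts (given
#' the observed allele counts) whose conditional probability does not exceed
#' that of the observed count. This is the standard exact test used by PLINK's
#' --hwe filter (no mid-p adjustment). Monomorphic variants return p = 1.
#'
#' @param n_het observed heterozygote count.
#' @param n_hom1,n_hom2 observed homozygote counts for the two alleles.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_het, n_hom1, n_hom2) {
  stopifnot(n_het >= 0, n_hom1 >= 0, n_hom2 >= 0)
  n <- n_het + n_hom1 + n_hom2
  if (n == 0) return(1)
  n_rare <- 2 * min(n_hom1, n_hom2) + n_het
  if (n_rare == 0 || n_rare == 2 * n) return(1)
  # support: het counts with the parity of n_rare, 0 <= h <= min(n_rare, 2n - n_rare)
  hmax <- min(n_rare, 2 * n - n_rare)
  h <- seq.int(n_rare %% 2, hmax, by = 2)
  # log P(het = h | n, n_rare) up to a constant:
  #   n! / (h! a! b!) * 2^h  with a = (n_rare - h)/2, b = n - h - a
  a <- (n_rare - h) / 2
  b <- n - h - a
  logp <- lgamma(n + 1) - lgamma(h + 1) - lgamma(a + 1) - lgamma(b + 1) +
    h * log(2)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(n_het, h)]
  if (is.na(p_obs))
    stop("heterozygote count ", n_het, " impossible given allele counts",
         call. = FALSE)
  # tolerance guards ties broken by floating-point noise
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

.hwe_pvalues <- function(genotypes) {
  vapply(seq_len(ncol(genotypes)), function(j) {
    gj <- genotypes[, j]
    hwe_exact_test(sum(gj == 1L, na.rm = TRUE),
                   sum(gj == 2L, na.rm = TRUE),
                   sum(gj == 0L, na.rm = TRUE))
  }, numeric(1))
}

#' Apply genotype quality-control filters
#'
#' Three passes in a fixed, recorded order: (1) remove samples with a missing
#' genotype fraction above \code{sample_missing_max}; (2) remove variants with
#' a missing fraction above \code{variant_missing_max} (computed on retained
#' samples); (3) remove variants with an exact HWE test p-value below
#' \code{hwe_p_min}. The operation is idempotent and conserves counts:
#' removed + retained equals the input on both axes.
#'
#' @param dataset a \code{\link{genotype_dataset}}.
#' @param sample_missing_max,variant_missing_max maximum tolerated missing
#'   fraction per sample / per variant (default 0.05 each).
#' @param hwe_p_min exact HWE p-value threshold (default 0.001); variants with
#'   p < \code{hwe_p_min} are removed.
#' @return List with elements \code{dataset} (filtered) and \code{report}
#'   (class \code{qc_report}: removed ids with reasons, thresholds, pass
#'   order).
#' @export
apply_qc <- function(dataset, sample_missing_max = 0.05,
                     variant_missing_max = 0.05, hwe_p_min = 0.001) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  g <- dataset$genotypes
  if (nrow(g) == 0 || ncol(g) == 0)
    stop("empty dataset", call. = FALSE)

  smiss <- rowMeans(is.na(g))
  drop_s <- smiss > sample_missing_max
  if (all(drop_s))
    stop("all samples removed by the missingness filter", call. = FALSE)
  removed_samples <- if (any(drop_s)) data.frame(
    sample_id = dataset$samples$sample_id[drop_s],
    reason = "missingness",
    value = smiss[drop_s],
    stringsAsFactors = FALSE) else data.frame(
      sample_id = character(), reason = character(), value = numeric(),
      stringsAsFactors = FALSE)
  g2 <- g[!drop_s, , drop = FALSE]

  vmiss <- colMeans(is.na(g2))
  drop_miss <- vmiss > variant_missing_max
  keep1 <- which(!drop_miss)
  g3 <- g2[, keep1, drop = FALSE]
  hwe_p <- .hwe_pvalues(g3)
  drop_hwe <- hwe_p < hwe_p_min

  removed_variants <- rbind(
    if (any(drop_miss)) data.frame(
      id = dataset$variants$id[drop_miss], reason = "missingness",
      value = vmiss[drop_miss], stringsAsFactors = FALSE),
    if (any(drop_hwe)) data.frame(
      id = dataset$variants$id[keep1][drop_hwe], reason = "hwe",
      value = hwe_p[drop_hwe], stringsAsFactors = FALSE))
  if (is.null(removed_variants))
    removed_variants <- data.frame(id = character(), reason = character(),
                                   value = numeric(),
                                   stringsAsFactors = FALSE)

  out <- subset_dataset(dataset, samples = which(!drop_s),
                        variants = keep1[!drop_hwe])
  report <- structure(list(
    removed_samples = removed_samples,
    removed_variants = removed_variants,
    thresholds = c(sample_missing_max = sample_missing_max,
                   variant_missing_max = variant_missing_max,
                   hwe_p_min = hwe_p_min),
    pass_order = c("sample_missingness", "variant_missingness", "hwe"),
    n_samples_in = nrow(g), n_variants_in = ncol(g),
    n_samples_out = nrow(out$genotypes),
    n_variants_out = ncol(out$genotypes),
    notes = "relatedness screening by method-of-moments pihat (pairwise_pihat)"
  ), class = "qc_report")
  list(dataset = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", x$n_samples_in, "->", x$n_samples_out, "samples;",
      x$n_variants_in, "->", x$n_variants_out, "variants\n")
  cat("pass order:", paste(x$pass_order, collapse = " -> "), "\n")
  cat("thresholds:",
      paste(names(x$thresholds), x$thresholds, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a QC report as TSV
#'
#' @param report a \code{qc_report}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  rs <- report$removed_samples
  rv <- report$removed_variants
  df <- rbind(
    if (nrow(rs)) data.frame(type = "sample", id = rs$sample_id,
                             reason = rs$reason, value = rs$value),
    if (nrow(rv)) data.frame(type = "variant", id = rv$id,
                             reason = rv$reason, value = rv$value))
  if (is.null(df)) df <- data.frame(type = character(), id = character(),
                                    reason = character(), value = numeric())
  utils::write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Pairwise method-of-moments relatedness (pihat)
#'
#' Estimates the genome-wide proportion of alleles shared identical by
#' descent for every sample pair from identity-by-state counts, inverting the
#' expected IBS distribution given allele frequencies (the PLINK --genome
#' method-of-moments): pihat = P(IBD=1)/2 + P(IBD=2), clamped to [0, 1].
#' Variants with no non-missing calls are excluded with a warning.
#'
#' @param dataset a \code{\link{genotype_dataset}} with at least two samples.
#' @return A symmetric matrix of pihat values with unit diagonal and an
#'   attribute \code{flagged} listing pairs with pihat >= 0.5.
#' @export
pairwise_pihat <- function(dataset) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  g <- dataset$genotypes
  n <- nrow(g)
  if (n < 2) stop("need at least two samples", call. = FALSE)
  called <- colSums(!is.na(g)) > 0
  if (!all(called)) {
    warning(sum(!called), " variant(s) with zero non-missing calls excluded")
    g <- g[, called, drop = FALSE]
  }
  p <- colSums(g, na.rm = TRUE) / (2 * colSums(!is.na(g)))
  q <- 1 - p
  # per-variant expected IBS-class probabilities under IBD state 0/1/2
  e0_ibs0 <- 2 * p^2 * q^2
  e0_ibs1 <- 4 * p^3 * q + 4 * p * q^3
  e0_ibs2 <- p^4 + q^4 + 4 * p^2 * q^2
  e1_ibs1 <- 2 * p^2 * q + 2 * p * q^2
  e1_ibs2 <- p^3 + q^3 + p^2 * q + p * q^2

  pihat <- diag(1, n)
  rownames(pihat) <- colnames(pihat) <- dataset$samples$sample_id
  flagged <- list()
  for (i in seq_len(n - 1)) {
    gi <- g[i, ]
    for (j in seq.int(i + 1, n)) {
      gj <- g[j, ]
      ok <- !is.na(gi) & !is.na(gj)
      d <- abs(gi[ok] - gj[ok])
      ibs0 <- sum(d == 2)
      ibs1 <- sum(d == 1)
      ibs2 <- sum(d == 0)
      s0_0 <- sum(e0_ibs0[ok]); s0_1 <- sum(e0_ibs1[ok])
      s0_2 <- sum(e0_ibs2[ok]); s1_1 <- sum(e1_ibs1[ok])
      s1_2 <- sum(e1_ibs2[ok]); nt <- sum(ok)
      p0 <- if (s0_0 > 0) ibs0 / s0_0 else 0
      p1 <- if (s1_1 > 0) (ibs1 - p0 * s0_1) / s1_1 else 0
      p2 <- (ibs2 - p0 * s0_2 - p1 * s1_2) / nt
      p0 <- min(max(p0, 0), 1); p1 <- min(max(p1, 0), 1)
      p2 <- min(max(p2, 0), 1)
      ph <- min(max(p1 / 2 + p2, 0), 1)
      pihat[i, j] <- pihat[j, i] <- ph
      if (ph >= 0.5)
        flagged[[length(flagged) + 1]] <-
          data.frame(id1 = rownames(pihat)[i], id2 = rownames(pihat)[j],
                     pihat = ph, stringsAsFactors = FALSE)
    }
  }
  attr(pihat, "flagged") <- if (length(flagged)) do.call(rbind, flagged) else
    data.frame(id1 = character(), id2 = character(), pihat = numeric())
  pihat
}
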