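# Six ROH length classes partitioning [0.3 Mb, Inf): half-open upward except
# the closed upper bound of ROH5 at 8 Mb (ROH6 is strictly > 8 Mb).
.category_labels <- c("ROH1", "ROH2", "ROH3", "ROH4", "ROH5", "ROH6")
.category_bounds_mb <- data.frame(
  label = .category_labels,
  lower = c(0.3, 0.5, 1, 2, 4, 8),
  upper = c(0.5, 1, 2, 4, 8, Inf),
  stringsAsFactors = FALSE)

#' ROH length classes
#'
#' @return data.frame of the six length classes with bounds in Mb:
#'   ROH1 [0.3, 0.5), ROH2 [0.5, 1), ROH3 [1, 2), ROH4 [2, 4), ROH5 [4, 8],
#'   ROH6 (8, Inf).
#' @export
roh_length_categories <- function() .category_bounds_mb

#' Classify an ROH length into one of the six classes
#'
#' @param length_bp segment length(s) in bp; must be >= 300,000 (the caller's
#'   minimum).
#' @return Factor with levels ROH1..ROH6.
#' @export
classify_length <- function(length_bp) {
  if (any(length_bp < 3e5))
    stop("lengths below 0.3 Mb cannot be classified (caller minimum)",
         call. = FALSE)
  mb <- length_bp / 1e6
  lab <- ifelse(mb < 0.5, "ROH1",
         ifelse(mb < 1, "ROH2",
         ifelse(mb < 2, "ROH3",
         ifelse(mb < 4, "ROH4",
         ifelse(mb <= 8, "ROH5", "ROH6")))))
  factor(lab, levels = .category_labels)
}

#' Genomic inbreeding coefficient from ROH content
#'
#' F_ROH is the summed length of ROH at or above a length threshold, divided
#' by the autosomal genome length: with the conventional 1.5 Mb threshold it
#' estimates the autozygous fraction of the genome attributable to relatively
#' recent common ancestry. The denominator defaults to 3 Gb (the human
#' autosomal convention); pass the simulated genome length when scoring
#' synthetic data.
#'
#' @param segments data.frame of one sample's segments (needs
#'   \code{length_bp}), or an \code{roh_table} restricted to one sample.
#' @param threshold_mb minimum segment length in Mb (inclusive; default 1.5).
#' @param genome_bp genome length denominator in bp (default 3e9).
#' @return Proportion in [0, 1].
#' @export
compute_f_roh <- function(segments, threshold_mb = 1.5, genome_bp = 3e9) {
  if (nrow(segments) == 0) return(0)
  sum(segments$length_bp[segments$length_bp >= threshold_mb * 1e6]) / genome_bp
}

#' Wright's F_IS from homozygote excess
#'
#' F_IS = (O_hom - E_hom) / (N - E_hom), where O_hom is the observed number of
#' homozygous genotypes of the sample, N its non-missing genotype count, and
#' E_hom the HWE-expected homozygote count summed over the sample's
#' non-missing variants. The per-variant expectation applies the allele-count
#' small-sample correction 1 - 2p(1-p) n/(n-1), n being the allele count used
#' to estimate p (as PLINK --het does); set \code{correct = FALSE} for the
#' textbook 1 - 2p(1-p).
#'
#' @param genotypes dosage vector (0/1/2/NA) for one sample.
#' @param freqs allele-1 frequencies estimated from the full dataset
#'   (\code{\link{allele_frequencies}}).
#' @param allele_counts non-missing allele counts per variant backing
#'   \code{freqs} (2 x non-missing samples); required when
#'   \code{correct = TRUE}.
#' @param correct apply the small-sample correction (default TRUE).
#' @return List with \code{f_is} (NA with a warning when N = E_hom),
#'   \code{o_hom}, \code{e_hom}, \code{n}.
#' @export
compute_f_is <- function(genotypes, freqs, allele_counts = NULL,
                         correct = TRUE) {
  ok <- !is.na(genotypes) & !is.nan(freqs)
  n_obs <- sum(ok)
  o_hom <- sum(genotypes[ok] != 1L)
  h <- 2 * freqs[ok] * (1 - freqs[ok])
  if (correct) {
    if (is.null(allele_counts))
      stop("allele_counts required for the small-sample correction",
           call. = FALSE)
    ac <- allele_counts[ok]
    h <- h * ifelse(ac > 1, ac / (ac - 1), 1)
  }
  e_hom <- sum(1 - h)
  denom <- n_obs - e_hom
  f_is <- if (abs(denom) < 1e-12) {
    warning("degenerate F_IS denominator (N = E_hom); returning NA")
    NA_real_
  } else (o_hom - e_hom) / denom
  list(f_is = f_is, o_hom = o_hom, e_hom = e_hom, n = n_obs)
}

#' Per-individual inbreeding and ROH-class records
#'
#' One row per sample: per-class NROH and SROH (Mb), totals, F_ROH and
#' (when the dataset is supplied) F_IS with its backing counts. Samples with
#' no called ROH get zero counts.
#'
#' @param roh an \code{roh_table}.
#' @param dataset optional \code{\link{genotype_dataset}} used to compute
#'   F_IS; allele frequencies are estimated from it.
#' @param threshold_mb,genome_bp passed to \code{\link{compute_f_roh}}.
#' @return data.frame with columns \code{sample_id}, \code{population},
#'   \code{nroh_ROH1..6}, \code{sroh_ROH1..6}, \code{nroh}, \code{sroh_mb},
#'   \code{nroh_1.5}, \code{sroh_1.5_mb}, \code{f_roh}, and when available
#'   \code{f_is}, \code{o_hom}, \code{e_hom}, \code{n_nonmissing}.
#' @export
inbreeding_records <- function(roh, dataset = NULL, threshold_mb = 1.5,
                               genome_bp = 3e9) {
  samp <- roh_samples(roh)
  cat_f <- if (nrow(roh)) classify_length(roh$length_bp) else
    factor(character(), levels = .category_labels)
  sid <- factor(roh$sample_id, levels = samp$sample_id)
  nroh_c <- table(sid, cat_f)
  sroh_c <- tapply(roh$length_bp / 1e6, list(sid, cat_f), sum, default = 0)
  if (is.null(dim(sroh_c)))
    sroh_c <- matrix(0, nrow(samp), 6,
                     dimnames = list(samp$sample_id, .category_labels))
  long <- roh$length_bp >= threshold_mb * 1e6
  out <- data.frame(
    sample_id = samp$sample_id, population = samp$population,
    stringsAsFactors = FALSE)
  for (k in .category_labels) {
    out[[paste0("nroh_", k)]] <- as.integer(nroh_c[, k])
    out[[paste0("sroh_", k)]] <- as.numeric(sroh_c[, k])
  }
  out$nroh <- as.integer(rowSums(nroh_c))
  out$sroh_mb <- rowSums(sroh_c)
  out$nroh_1.5 <- as.integer(table(factor(roh$sample_id[long],
                                          levels = samp$sample_id)))
  out$sroh_1.5_mb <- as.numeric(
    tapply(roh$length_bp[long] / 1e6,
           factor(roh$sample_id[long], levels = samp$sample_id),
           sum, default = 0))
  out$f_roh <- vapply(samp$sample_id, function(id)
    compute_f_roh(roh[roh$sample_id == id, , drop = FALSE],
                  threshold_mb, genome_bp), numeric(1))
  if (!is.null(dataset)) {
    idx <- match(samp$sample_id, dataset$samples$sample_id)
    if (anyNA(idx))
      stop("samples in the ROH table absent from the dataset", call. = FALSE)
    freqs <- allele_frequencies(dataset)
    ac <- 2 * colSums(!is.na(dataset$genotypes))
    fis <- lapply(idx, function(i)
      compute_f_is(dataset$genotypes[i, ], freqs, ac))
    out$f_is <- vapply(fis, `[[`, numeric(1), "f_is")
    out$o_hom <- vapply(fis, `[[`, numeric(1), "o_hom")
    out$e_hom <- vapply(fis, `[[`, numeric(1), "e_hom")
    out$n_nonmissing <- vapply(fis, `[[`, numeric(1), "n")
  }
  rownames(out) <- NULL
  out
}

#' Derive a per-class population summary from class totals
#'
#' Takes raw per-class totals (carrier count, NROH, SROH in Mb) for one
#' population of \code{n} individuals and derives the usual summary columns:
#' carrier percentage, per-class share of NROH and SROH, per-individual
#' means, mean segment length, plus a TOTAL row.
#'
#' @param categories data.frame with columns \code{category},
#'   \code{carriers}, \code{nroh}, \code{sroh_mb} (one row per class).
#' @param n number of individuals in the population.
#' @param population optional population label attached to the result.
#' @return data.frame with the six class rows plus a TOTAL row and columns
#'   \code{carriers}, \code{carriers_pct}, \code{nroh}, \code{nroh_pct},
#'   \code{nroh_per_ind}, \code{sroh_mb}, \code{sroh_pct},
#'   \code{sroh_per_ind}, \code{mean_length_mb}.
#' @export
summarize_categories <- function(categories, n, population = NA_character_) {
  stopifnot(all(c("category", "carriers", "nroh", "sroh_mb") %in%
                  names(categories)), n >= 1)
  cat_df <- categories[match(.category_labels, categories$category), ]
  cat_df$category <- .category_labels
  cat_df[is.na(cat_df$nroh), c("carriers", "nroh", "sroh_mb")] <- 0
  tot_n <- sum(cat_df$nroh)
  tot_s <- sum(cat_df$sroh_mb)
  out <- data.frame(
    population = population, n = n, category = cat_df$category,
    carriers = cat_df$carriers,
    carriers_pct = 100 * cat_df$carriers / n,
    nroh = cat_df$nroh,
    nroh_pct = if (tot_n > 0) 100 * cat_df$nroh / tot_n else NA_real_,
    nroh_per_ind = cat_df$nroh / n,
    sroh_mb = cat_df$sroh_mb,
    sroh_pct = if (tot_s > 0) 100 * cat_df$sroh_mb / tot_s else NA_real_,
    sroh_per_ind = cat_df$sroh_mb / n,
    mean_length_mb = ifelse(cat_df$nroh > 0, cat_df$sroh_mb / cat_df$nroh,
                            NA_real_),
    stringsAsFactors = FALSE)
  total <- data.frame(
    population = population, n = n, category = "TOTAL",
    carriers = NA_integer_, carriers_pct = NA_real_,
    nroh = tot_n, nroh_pct = if (tot_n > 0) 100 else NA_real_,
    nroh_per_ind = tot_n / n,
    sroh_mb = tot_s, sroh_pct = if (tot_s > 0) 100 else NA_real_,
    sroh_per_ind = tot_s / n,
    mean_length_mb = if (tot_n > 0) tot_s / tot_n else NA_real_,
    stringsAsFactors = FALSE)
  rbind(out, total)
}

#' Population summary of ROH by length class
#'
#' Aggregates an \code{roh_table} for one population into per-class totals
#' (individuals carrying >= 1 segment of the class, NROH, SROH) and derives
#' percentages, per-individual means and mean segment lengths via
#' \code{\link{summarize_categories}}.
#'
#' @param roh an \code{roh_table} whose sample table carries population
#'   labels.
#' @param population population label to summarize.
#' @return data.frame as returned by \code{\link{summarize_categories}}.
#' @export
summarize_population <- function(roh, population) {
  samp <- roh_samples(roh)
  ids <- samp$sample_id[samp$population == population]
  if (!length(ids))
    stop("unknown population label: ", population, call. = FALSE)
  sub <- roh[roh$sample_id %in% ids, , drop = FALSE]
  if (nrow(sub)) {
    cf <- classify_length(sub$length_bp)
    carriers <- vapply(.category_labels, function(k)
      length(unique(sub$sample_id[cf == k])), integer(1))
    nroh <- as.integer(table(cf))
    sroh <- as.numeric(tapply(sub$length_bp / 1e6, cf, sum, default = 0))
  } else {
    carriers <- integer(6); nroh <- integer(6); sroh <- numeric(6)
  }
  summarize_categories(
    data.frame(category = .category_labels, carriers = carriers,
               nroh = nroh, sroh_mb = sroh, stringsAsFactors = FALSE),
    n = length(ids), population = population)
}

#' Per-chromosome ROH counts and mean coverage
#'
#' For segments at or above \code{min_length_mb}: the number of segments per
#' chromosome (pooled over individuals) and the mean over individuals of the
#' percentage of the chromosome covered by their qualifying ROH.
#'
#' @param roh an \code{roh_table}.
#' @param chrom_sizes data.frame with \code{chrom} and \code{size_bp}.
#' @param min_length_mb minimum segment length in Mb (0.3 or 1.5 in typical
#'   use).
#' @return data.frame with \code{chrom}, \code{nroh}, \code{coverage_pct}.
#' @export
chromosome_distribution <- function(roh, chrom_sizes, min_length_mb = 0.3) {
  stopifnot(all(c("chrom", "size_bp") %in% names(chrom_sizes)))
  missing_chr <- setdiff(unique(roh$chrom), chrom_sizes$chrom)
  if (length(missing_chr))
    stop("segments on chromosome(s) absent from the size table: ",
         paste(missing_chr, collapse = ", "), call. = FALSE)
  samp <- roh_samples(roh)
  n_ind <- nrow(samp)
  sub <- roh[roh$length_bp >= min_length_mb * 1e6, , drop = FALSE]
  out <- data.frame(chrom = chrom_sizes$chrom,
                    nroh = 0L, coverage_pct = 0,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    ch <- out$chrom[i]
    s <- sub[sub$chrom == ch, , drop = FALSE]
    out$nroh[i] <- nrow(s)
    if (nrow(s)) {
      per_ind <- tapply(s$length_bp, factor(s$sample_id,
                                            levels = samp$sample_id),
                        sum, default = 0)
      out$coverage_pct[i] <-
        mean(per_ind / chrom_sizes$size_bp[i]) * 100
    }
  }
  out
}

#' Spearman correlation matrix of ROH variables with a clustering order
#'
#' Pairwise Spearman correlations (average ranks for ties) over the
#' per-individual variables NROH by class (6), SROH by class (6) and F_ROH,
#' plus the leaf order from average-linkage hierarchical clustering on the
#' distance 1 - rho.
#'
#' @param records data.frame from \code{\link{inbreeding_records}} (>= 3
#'   rows).
#' @return List with \code{rho} (13 x 13 matrix; NA where a variable has zero
#'   variance) and \code{order} (character vector of variable names in leaf
#'   order).
#' @export
correlation_heatmap_inputs <- function(records) {
  vars <- c(paste0("nroh_", .category_labels),
            paste0("sroh_", .category_labels), "f_roh")
  stopifnot(all(vars %in% names(records)), nrow(records) >= 3)
  x <- as.matrix(records[, vars])
  sdv <- apply(x, 2, stats::sd)
  rho <- suppressWarnings(stats::cor(x, method = "spearman"))
  rho[sdv == 0, ] <- NA
  rho[, sdv == 0] <- NA
  diag(rho) <- 1
  d <- 1 - rho
  d[is.na(d)] <- 1  # zero-variance variables join the tree at maximal distance
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  list(rho = rho, order = vars[hc$order])
}

#' Mixed-model weights of the ROH length classes on F_ROH
#'
#' Fits a linear mixed model of F_ROH on the six per-individual SROH class
#' values with a random intercept per population (REML). Response and
#' predictors are z-scored first, so the fixed-effect coefficients are
#' standardized weights. Falls back to an ordinary fixed-effects model with a
#' warning when the mixed fit is singular or fails.
#'
#' @param records data.frame from \code{\link{inbreeding_records}} with
#'   \code{population}, \code{f_roh} and the \code{sroh_ROH*} columns;
#'   >= 2 populations with >= 3 individuals each for the mixed fit.
#' @return data.frame with \code{category}, \code{coefficient},
#'   \code{p_value}; attribute \code{method} records "lmm" or "lm".
#' @export
lmm_category_weights <- function(records) {
  vars <- paste0("sroh_", .category_labels)
  stopifnot(all(c("population", "f_roh", vars) %in% names(records)))
  z <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else
    v * 0
  df <- data.frame(population = factor(records$population),
                   y = z(records$f_roh))
  for (v in vars) df[[v]] <- z(records[[v]])
  fml <- stats::as.formula(paste("y ~", paste(vars, collapse = " + ")))
  fit <- tryCatch(
    nlme::lme(fml, random = ~ 1 | population, data = df, method = "REML"),
    error = function(e) NULL)
  coefs <- stats::setNames(rep(NA_real_, 6), vars)
  pvals <- coefs
  if (!is.null(fit)) {
    tt <- summary(fit)$tTable
    hit <- intersect(vars, rownames(tt))
    coefs[hit] <- tt[hit, "Value"]
    pvals[hit] <- tt[hit, "p-value"]
    method <- "lmm"
  } else {
    warning("mixed-model fit failed; falling back to a fixed-effects model")
    fit <- stats::lm(fml, data = df)
    sm <- summary(fit)$coefficients
    hit <- intersect(vars, rownames(sm))  # aliased predictors stay NA
    coefs[hit] <- sm[hit, "Estimate"]
    pvals[hit] <- sm[hit, "Pr(>|t|)"]
    method <- "lm"
  }
  res <- data.frame(category = .category_labels,
                    coefficient = unname(coefs), p_value = unname(pvals))
  attr(res, "method") <- method
  res
}
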