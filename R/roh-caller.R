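#' Parameters for sliding-window ROH detection
#'
#' Defaults reproduce the PLINK 1.9 run-of-homozygosity settings commonly used
#' for ~2.4M-SNP array data: a 30-SNP scanning window allowing at most 1
#' heterozygous and 5 missing calls, a SNP counted as homozygous-state when at
#' least 5\% of the windows covering it are homozygous, and segments required
#' to hold >= 30 SNPs, span >= 300 kb, have <= 30 kb per SNP, and contain no
#' inter-SNP gap above 1000 kb. Semantics follow the PLINK 1.9 manual:
#' \code{min_length_kb} is the minimum segment length (--homozyg-kb),
#' \code{max_kb_per_snp} the maximum inverse density (--homozyg-density) and
#' \code{max_gap_kb} the maximum within-segment gap (--homozyg-gap).
#'
#' @param min_snps_segment minimum SNPs per emitted segment (--homozyg-snp).
#' @param min_length_kb minimum segment length in kb (--homozyg-kb).
#' @param max_kb_per_snp maximum kb per SNP within a segment
#'   (--homozyg-density).
#' @param max_gap_kb maximum inter-SNP gap in kb within a segment
#'   (--homozyg-gap).
#' @param window_snps SNPs per scanning window (--homozyg-window-snp).
#' @param window_max_het maximum heterozygous calls per homozygous window
#'   (--homozyg-window-het).
#' @param window_max_missing maximum missing calls per homozygous window
#'   (--homozyg-window-missing).
#' @param window_hit_threshold minimum fraction of covering windows that must
#'   be homozygous for a SNP to be in homozygous state
#'   (--homozyg-window-threshold).
#' @param window_max_kb optional cap on window physical span in kb
#'   (--homozyg-window-kb); \code{NULL} (default) disables it, so windows are
#'   defined by SNP count only.
#' @return An object of class \code{roh_params}.
#' @export
roh_params <- function(min_snps_segment = 30, min_length_kb = 300,
                       max_kb_per_snp = 30, max_gap_kb = 1000,
                       window_snps = 30, window_max_het = 1,
                       window_max_missing = 5, window_hit_threshold = 0.05,
                       window_max_kb = NULL) {
  stopifnot(min_snps_segment >= 1, min_length_kb >= 1, max_kb_per_snp >= 1,
            max_gap_kb >= 1, window_snps >= 1, window_max_het >= 0,
            window_max_missing >= 0,
            window_hit_threshold > 0, window_hit_threshold <= 1)
  structure(list(
    min_snps_segment = min_snps_segment, min_length_kb = min_length_kb,
    max_kb_per_snp = max_kb_per_snp, max_gap_kb = max_gap_kb,
    window_snps = window_snps, window_max_het = window_max_het,
    window_max_missing = window_max_missing,
    window_hit_threshold = window_hit_threshold,
    window_max_kb = window_max_kb), class = "roh_params")
}

# Call ROH on one chromosome of one sample. g: dosages (0/1/2/NA), pos:
# strictly increasing bp. Returns data.frame of segments (possibly 0 rows).
.call_roh_chrom <- function(g, pos, params) {
  L <- length(g)
  W <- params$window_snps
  empty <- data.frame(start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), n_het = integer(),
                      n_missing = integer())
  if (L < W) return(empty)

  het <- as.integer(!is.na(g) & g == 1L)
  mis <- as.integer(is.na(g))
  ch <- c(0L, cumsum(het))
  cm <- c(0L, cumsum(mis))
  starts <- seq_len(L - W + 1)                  # window i covers SNPs i..i+W-1
  win_hom <- (ch[starts + W] - ch[starts]) <= params$window_max_het &
    (cm[starts + W] - cm[starts]) <= params$window_max_missing
  if (!is.null(params$window_max_kb))
    win_hom <- win_hom &
      (pos[starts + W - 1] - pos[starts] + 1) <= params$window_max_kb * 1000

  # SNP j is covered by windows max(1, j-W+1) .. min(j, L-W+1)
  cw <- c(0L, cumsum(as.integer(win_hom)))
  j <- seq_len(L)
  lo <- pmax(1L, j - W + 1L)
  hi <- pmin(j, L - W + 1L)
  n_hom_win <- cw[hi + 1L] - cw[lo]
  n_win <- hi - lo + 1L
  state <- n_hom_win / n_win >= params$window_hit_threshold

  # maximal runs of homozygous-state SNPs, split at oversized gaps
  gap_break <- c(FALSE, diff(pos) > params$max_gap_kb * 1000)
  run_start <- state & (!c(FALSE, state[-L]) | gap_break)
  run_id <- cumsum(run_start)
  run_id[!state] <- 0L
  keep <- run_id > 0L
  if (!any(keep)) return(empty)
  idx <- split(j[keep], run_id[keep])
  segs <- lapply(idx, function(ii) {
    s <- ii[1]; e <- ii[length(ii)]
    data.frame(start_bp = pos[s], end_bp = pos[e],
               n_snps = e - s + 1L,
               n_het = ch[e + 1L] - ch[s],
               n_missing = cm[e + 1L] - cm[s])
  })
  out <- do.call(rbind, segs)
  len <- out$end_bp - out$start_bp + 1
  ok <- out$n_snps >= params$min_snps_segment &
    len >= params$min_length_kb * 1000 &
    len / out$n_snps <= params$max_kb_per_snp * 1000
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call runs of homozygosity for one sample
#'
#' Sliding-window scan, per chromosome: (1) every window of exactly
#' \code{window_snps} consecutive SNPs is classified homozygous iff it holds
#' at most \code{window_max_het} heterozygous and \code{window_max_missing}
#' missing calls; (2) each SNP's hit fraction is the proportion of windows
#' covering it that are homozygous (only full windows are formed, so SNPs near
#' chromosome ends have fewer covering windows); a SNP is in homozygous state
#' iff its hit fraction reaches \code{window_hit_threshold}; (3) maximal runs
#' of homozygous-state SNPs, split where the gap between adjacent SNPs exceeds
#' \code{max_gap_kb}, are candidate segments; (4) candidates pass iff they
#' satisfy the SNP-count, length and density bounds. Segment coordinates are
#' the bp positions of the first and last SNP (1-based inclusive); length is
#' \code{end - start + 1}.
#'
#' @param genotypes integer vector of dosages (0/1/2/NA) for one sample, in
#'   variant order.
#' @param variants data.frame with \code{chrom} and strictly increasing
#'   \code{pos} per chromosome (as in a \code{genotype_dataset}).
#' @param params a \code{\link{roh_params}} object.
#' @return data.frame of segments: \code{chrom}, \code{start_bp},
#'   \code{end_bp}, \code{length_bp}, \code{n_snps}, \code{n_het},
#'   \code{n_missing}, sorted and non-overlapping within chromosome.
#' @export
call_roh_sample <- function(genotypes, variants, params = roh_params()) {
  stopifnot(inherits(params, "roh_params"),
            length(genotypes) == nrow(variants))
  res <- lapply(unique(variants$chrom), function(ch) {
    sel <- variants$chrom == ch
    segs <- .call_roh_chrom(genotypes[sel], variants$pos[sel], params)
    if (nrow(segs)) cbind(chrom = ch, segs) else NULL
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    res <- data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), n_snps = integer(),
                      n_het = integer(), n_missing = integer())
  res$length_bp <- if (nrow(res)) res$end_bp - res$start_bp + 1 else integer()
  res[, c("chrom", "start_bp", "end_bp", "length_bp", "n_snps", "n_het",
          "n_missing")]
}

#' Call runs of homozygosity for every sample in a dataset
#'
#' @param dataset a \code{\link{genotype_dataset}} (QC-passed).
#' @param params a \code{\link{roh_params}} object.
#' @return An \code{roh_table}: data.frame with \code{sample_id} plus the
#'   \code{\link{call_roh_sample}} columns, with the parameters and dataset
#'   dimensions recorded as attributes.
#' @export
call_roh <- function(dataset, params = roh_params()) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  n <- nrow(dataset$genotypes)
  segs <- lapply(seq_len(n), function(i) {
    s <- call_roh_sample(dataset$genotypes[i, ], dataset$variants, params)
    if (nrow(s)) cbind(sample_id = dataset$samples$sample_id[i], s) else NULL
  })
  out <- do.call(rbind, segs)
  if (is.null(out))
    out <- data.frame(sample_id = character(), chrom = character(),
                      start_bp = integer(), end_bp = integer(),
                      length_bp = integer(), n_snps = integer(),
                      n_het = integer(), n_missing = integer())
  rownames(out) <- NULL
  roh_table(out, params = params,
            samples = dataset$samples)
}

#' Construct an ROH table
#'
#' @param segments data.frame of called segments (columns \code{sample_id},
#'   \code{chrom}, \code{start_bp}, \code{end_bp}, \code{length_bp},
#'   \code{n_snps}, \code{n_het}, \code{n_missing}; the last three may be
#'   absent when importing external calls).
#' @param params the \code{\link{roh_params}} used (recorded as provenance).
#' @param samples optional data.frame (\code{sample_id}, \code{population})
#'   covering every sample, including those with zero segments.
#' @return data.frame of class \code{roh_table}.
#' @export
roh_table <- function(segments, params = NULL, samples = NULL) {
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  need <- c("sample_id", "chrom", "start_bp", "end_bp")
  stopifnot(all(need %in% names(segments)))
  if (is.null(segments$length_bp))
    segments$length_bp <- segments$end_bp - segments$start_bp + 1
  attr(segments, "params") <- params
  attr(segments, "samples") <- samples
  class(segments) <- c("roh_table", "data.frame")
  segments
}

#' Samples covered by an ROH table
#'
#' Returns the sample table recorded at call time, or reconstructs one from
#' the segment sample ids (population NA) when absent.
#'
#' @param roh an \code{roh_table}.
#' @return data.frame with \code{sample_id} and \code{population}.
#' @export
roh_samples <- function(roh) {
  s <- attr(roh, "samples")
  if (is.null(s))
    s <- data.frame(sample_id = unique(roh$sample_id),
                    population = NA_character_, stringsAsFactors = FALSE)
  s
}

#' Write an ROH table as a PLINK-style .hom file
#'
#' @param roh an \code{roh_table}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_hom <- function(roh, path) {
  s <- roh_samples(roh)
  fid <- s$population[match(roh$sample_id, s$sample_id)]
  df <- data.frame(
    FID = ifelse(is.na(fid), roh$sample_id, fid), IID = roh$sample_id,
    CHR = roh$chrom, POS1 = roh$start_bp, POS2 = roh$end_bp,
    KB = round(roh$length_bp / 1000, 3), NSNP = roh$n_snps,
    DENSITY = round(roh$length_bp / 1000 / roh$n_snps, 3),
    NHET = roh$n_het, NMISS = roh$n_missing)
  utils::write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Read a .hom file written by \code{\link{write_hom}}
#'
#' @param path .hom path.
#' @param samples optional sample table (\code{sample_id},
#'   \code{population}); defaults to the FID/IID pairs in the file.
#' @return An \code{roh_table}.
#' @export
read_hom <- function(path, samples = NULL) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (is.null(samples))
    samples <- unique(data.frame(sample_id = df$IID, population = df$FID,
                                 stringsAsFactors = FALSE))
  roh_table(data.frame(
    sample_id = df$IID, chrom = df$CHR, start_bp = df$POS1,
    end_bp = df$POS2, n_snps = df$NSNP, n_het = df$NHET,
    n_missing = df$NMISS, stringsAsFactors = FALSE), samples = samples)
}

#' Export ROH segments as a BED track
#'
#' Internal coordinates are 1-based inclusive; BED lines are 0-based
#' half-open, so each segment becomes \code{[start_bp - 1, end_bp)}. The BED
#' name column carries the sample id.
#'
#' @param roh an \code{roh_table}.
#' @param path output BED path.
#' @return \code{path}, invisibly.
#' @export
write_roh_bed <- function(roh, path) {
  df <- data.frame(roh$chrom, roh$start_bp - 1, roh$end_bp, roh$sample_id)
  utils::write.table(df, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
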