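# ROH islands: tile each chromosome with fixed windows (default 100 kb),
# count the distinct individuals whose ROH touch each window, and flag
# windows whose count exceeds binomial expectation at a Bonferroni-corrected
# level; runs of adjacent significant windows merge into islands. Island
# coordinates are 0-based half-open unions of whole windows.

#' Per-window ROH carrier counts for one population
#'
#' Tiles each chromosome with non-overlapping windows of \code{window_bp} and
#' counts, per window, the distinct individuals with at least 1 bp of ROH
#' overlap. Internal segment coordinates (1-based inclusive) are converted to
#' 0-based half-open before intersection.
#'
#' @param roh an \code{roh_table}.
#' @param population population label; segments of other populations are
#'   ignored. Use \code{NULL} to pool every sample in the table.
#' @param chrom_sizes data.frame with \code{chrom}, \code{size_bp}; windows
#'   tile \code{[0, window_bp * ceiling(size_bp / window_bp))}.
#' @param window_bp window size in bp (default 100,000).
#' @return Object of class \code{window_count_track}: data.frame with
#'   \code{chrom}, \code{window} (0-based index), \code{start}, \code{end}
#'   (0-based half-open) and \code{count}; attributes \code{n} (population
#'   size), \code{window_bp}, \code{population}.
#' @export
window_counts <- function(roh, population = NULL, chrom_sizes,
                          window_bp = 1e5) {
  stopifnot(all(c("chrom", "size_bp") %in% names(chrom_sizes)))
  samp <- roh_samples(roh)
  if (!is.null(population)) {
    ids <- samp$sample_id[samp$population %in% population]
    if (!length(ids))
      stop("unknown population label: ",
           paste(population, collapse = ","), call. = FALSE)
  } else ids <- samp$sample_id
  sub <- roh[roh$sample_id %in% ids, , drop = FALSE]

  track <- do.call(rbind, lapply(seq_len(nrow(chrom_sizes)), function(i) {
    ch <- chrom_sizes$chrom[i]
    nw <- ceiling(chrom_sizes$size_bp[i] / window_bp)
    cnt <- integer(nw)
    s <- sub[sub$chrom == ch, , drop = FALSE]
    if (nrow(s)) {
      s0 <- s$start_bp - 1
      e0 <- s$end_bp
      k1 <- pmax(0L, as.integer(s0 %/% window_bp))
      k2 <- pmin(nw - 1L, as.integer((e0 - 1) %/% window_bp))
      pairs <- unique(do.call(rbind, lapply(seq_len(nrow(s)), function(r)
        if (k2[r] >= k1[r])
          cbind(match(s$sample_id[r], ids), k1[r]:k2[r]))))
      if (!is.null(pairs) && nrow(pairs)) {
        tb <- table(pairs[, 2])
        cnt[as.integer(names(tb)) + 1L] <- as.integer(tb)
      }
    }
    data.frame(chrom = ch, window = seq_len(nw) - 1L,
               start = (seq_len(nw) - 1L) * window_bp,
               end = seq_len(nw) * window_bp,
               count = cnt, stringsAsFactors = FALSE)
  }))
  rownames(track) <- NULL
  structure(track, n = length(ids), window_bp = window_bp,
            population = if (is.null(population)) NA_character_ else
              paste(population, collapse = "+"),
            class = c("window_count_track", "data.frame"))
}

#' Bonferroni-corrected per-window significance level
#'
#' @param family_alpha family-wise level (default 0.05).
#' @param n_windows number of windows in the testing family; 2500 reproduces
#'   the conventional 2e-5 threshold.
#' @return \code{family_alpha / n_windows}.
#' @export
bonferroni_alpha <- function(family_alpha = 0.05, n_windows) {
  stopifnot(n_windows >= 1)
  family_alpha / n_windows
}

#' Exact binomial upper-tail probability
#'
#' P(X >= count) for X ~ Binomial(n, p); the one-sided test statistic used
#' for window enrichment.
#'
#' @param count observed carrier count.
#' @param n population size.
#' @param p null per-window carrier proportion.
#' @return Tail probability.
#' @export
binom_tail <- function(count, n, p) {
  stats::pbinom(count - 1, n, p, lower.tail = FALSE)
}

#' Detect ROH islands by binomial window enrichment
#'
#' A window is significant when its exact binomial upper tail
#' P(X >= count | n, null_p) falls below \code{alpha_per_window}; maximal
#' runs of adjacent significant windows on a chromosome merge into one
#' island. When \code{null_p} is omitted it defaults to the realized mean
#' per-window carrier proportion of the track, sum(count) / (n * #windows) —
#' the genome-wide expectation under no local enrichment.
#'
#' @param track a \code{\link{window_counts}} track.
#' @param null_p null carrier proportion per window (in (0, 1)).
#' @param alpha_per_window per-window level, e.g.
#'   \code{\link{bonferroni_alpha}(0.05, nrow(track))}.
#' @return data.frame of islands: \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open, whole windows), \code{length_bp}, \code{n_windows},
#'   \code{min_p}, \code{max_count}, \code{population}. Attach sharing
#'   percentages with \code{\link{attach_island_sharing}}.
#' @export
detect_islands <- function(track, null_p = NULL, alpha_per_window) {
  stopifnot(inherits(track, "window_count_track"))
  n <- attr(track, "n")
  if (n == 0) stop("empty population (n = 0)", call. = FALSE)
  if (is.null(null_p))
    null_p <- sum(track$count) / (n * nrow(track))
  if (!(null_p > 0 && null_p < 1)) {
    # a track with no ROH at all has null_p = 0: nothing can be enriched
    return(.empty_islands(attr(track, "population")))
  }
  pv <- binom_tail(track$count, n, null_p)
  sig <- pv < alpha_per_window
  if (!any(sig)) return(.empty_islands(attr(track, "population")))
  d <- track[sig, , drop = FALSE]
  d$p <- pv[sig]
  new_island <- c(TRUE, d$chrom[-1] != d$chrom[-nrow(d)] |
                    diff(d$window) != 1L)
  iid <- cumsum(new_island)
  isl <- do.call(rbind, lapply(split(d, iid), function(w) {
    data.frame(chrom = w$chrom[1], start = min(w$start), end = max(w$end),
               length_bp = max(w$end) - min(w$start),
               n_windows = nrow(w), min_p = min(w$p),
               max_count = max(w$count),
               population = attr(track, "population"),
               stringsAsFactors = FALSE)
  }))
  rownames(isl) <- NULL
  isl
}

#' Attach sharing percentages to a set of islands
#'
#' @param islands island data.frame from \code{\link{detect_islands}}.
#' @param roh the \code{roh_table} the islands were detected from.
#' @param population population label(s) defining the sharing denominator;
#'   \code{NULL} pools all samples.
#' @param n population size override.
#' @return \code{islands} with a \code{sharing_pct} column.
#' @export
attach_island_sharing <- function(islands, roh, population = NULL, n = NULL) {
  islands$sharing_pct <- vapply(seq_len(nrow(islands)), function(i)
    island_sharing(islands[i, ], roh, population = population, n = n),
    numeric(1))
  islands
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.empty_islands <- function(population) {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             length_bp = numeric(), n_windows = integer(), min_p = numeric(),
             max_count = integer(), population = character(),
             stringsAsFactors = FALSE)
}

#' Percentage of individuals sharing an island
#'
#' 100 x (distinct individuals with >= 1 bp ROH overlap of the island) / n.
#'
#' @param island one-row data.frame with \code{chrom}, \code{start},
#'   \code{end} (0-based half-open).
#' @param roh an \code{roh_table} from the same population set.
#' @param population optional label restricting the table; \code{NULL} uses
#'   every sample.
#' @param n population size; defaults to the number of samples considered.
#' @return Percentage in [0, 100].
#' @export
island_sharing <- function(island, roh, population = NULL, n = NULL) {
  samp <- roh_samples(roh)
  ids <- if (is.null(population)) samp$sample_id else
    samp$sample_id[samp$population %in% population]
  if (is.null(n)) n <- length(ids)
  s <- roh[roh$sample_id %in% ids & roh$chrom == island$chrom, , drop = FALSE]
  hit <- (s$start_bp - 1) < island$end & s$end_bp > island$start
  100 * length(unique(s$sample_id[hit])) / n
}

#' Match islands between two populations by reciprocal overlap
#'
#' Two islands are declared the same when their overlap covers at least
#' \code{min_fraction} of EACH island's length (the reciprocal, symmetric
#' reading of a 75\% length-sharing rule). All overlapping pairs are
#' reported; one-to-many matches are not collapsed.
#'
#' @param islands_a,islands_b island data.frames
#'   (\code{\link{detect_islands}} output).
#' @param min_fraction reciprocal overlap fraction (default 0.75).
#' @return data.frame with one row per overlapping pair: indices
#'   \code{idx_a}, \code{idx_b}, \code{chrom}, \code{overlap_bp},
#'   \code{frac_a}, \code{frac_b}, \code{same_island}.
#' @export
match_islands <- function(islands_a, islands_b, min_fraction = 0.75) {
  out <- list()
  for (i in seq_len(nrow(islands_a))) {
    a <- islands_a[i, ]
    for (j in seq_len(nrow(islands_b))) {
      b <- islands_b[j, ]
      if (a$chrom != b$chrom) next
      ov <- min(a$end, b$end) - max(a$start, b$start)
      if (ov <= 0) next
      fa <- ov / (a$end - a$start)
      fb <- ov / (b$end - b$start)
      out[[length(out) + 1]] <- data.frame(
        idx_a = i, idx_b = j, chrom = a$chrom, overlap_bp = ov,
        frac_a = fa, frac_b = fb,
        same_island = fa >= min_fraction && fb >= min_fraction,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(idx_a = integer(), idx_b = integer(),
                      chrom = character(), overlap_bp = numeric(),
                      frac_a = numeric(), frac_b = numeric(),
                      same_island = logical(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Filter islands by representation or length
#'
#' @param islands island data.frame with \code{sharing_pct} (for mode
#'   \code{high_representation}) or \code{length_bp} (for mode \code{long}).
#' @param mode \code{"high_representation"} keeps sharing >= 90\%;
#'   \code{"long"} keeps length >= 1.5 Mb.
#' @return Subset of \code{islands}.
#' @export
filter_islands <- function(islands,
                           mode = c("high_representation", "long")) {
  mode <- match.arg(mode)
  if (mode == "high_representation") {
    stopifnot(!is.null(islands$sharing_pct))
    islands[islands$sharing_pct >= 90, , drop = FALSE]
  } else {
    islands[islands$length_bp >= 1.5e6, , drop = FALSE]
  }
}

#' Island detection per metapopulation
#'
#' Re-runs the window-count / binomial-detection / sharing pipeline on the
#' pooled samples of each group of populations (metapopulation semantics): a
#' group of one population is identical to the per-population run.
#'
#' @param roh an \code{roh_table} with population labels.
#' @param grouping data.frame with \code{population} and \code{group}
#'   covering every population present in the table.
#' @param chrom_sizes,window_bp,family_alpha,n_windows_bonferroni,null_p see
#'   \code{\link{window_counts}} and \code{\link{detect_islands}};
#'   \code{n_windows_bonferroni = NULL} uses the actual window count.
#' @return Named list of island data.frames, one per group, each with
#'   \code{sharing_pct} attached.
#' @export
metapopulation_islands <- function(roh, grouping, chrom_sizes,
                                   window_bp = 1e5, family_alpha = 0.05,
                                   n_windows_bonferroni = NULL,
                                   null_p = NULL) {
  stopifnot(all(c("population", "group") %in% names(grouping)))
  samp <- roh_samples(roh)
  missing_pop <- setdiff(unique(samp$population), grouping$population)
  if (length(missing_pop))
    stop("population(s) absent from the grouping: ",
         paste(missing_pop, collapse = ", "), call. = FALSE)
  groups <- split(grouping$population, grouping$group)
  out <- lapply(groups, function(pops) {
    tr <- window_counts(roh, population = pops, chrom_sizes, window_bp)
    alpha <- bonferroni_alpha(family_alpha,
                              n_windows_bonferroni %||% nrow(tr))
    isl <- detect_islands(tr, null_p = null_p, alpha_per_window = alpha)
    if (nrow(isl))
      isl$sharing_pct <- vapply(seq_len(nrow(isl)), function(i)
        island_sharing(isl[i, ], roh, population = pops,
                       n = attr(tr, "n")), numeric(1))
    isl
  })
  out
}

#' Summary statistics of a population's islands
#'
#' Number of islands, mean/SD/max length (Mb) and mean/SD/max sharing
#' percentage — the usual per-population island report.
#'
#' @param islands island data.frame with \code{length_bp} and
#'   \code{sharing_pct}.
#' @param n population size.
#' @return One-row data.frame.
#' @export
island_summary <- function(islands, n) {
  data.frame(
    n = n, n_islands = nrow(islands),
    mean_length_mb = if (nrow(islands)) mean(islands$length_bp) / 1e6 else NA,
    sd_length_mb = if (nrow(islands) > 1)
      stats::sd(islands$length_bp / 1e6) else NA,
    max_length_mb = if (nrow(islands)) max(islands$length_bp) / 1e6 else NA,
    mean_sharing_pct = if (nrow(islands)) mean(islands$sharing_pct) else NA,
    sd_sharing_pct = if (nrow(islands) > 1)
      stats::sd(islands$sharing_pct) else NA,
    max_sharing_pct = if (nrow(islands)) max(islands$sharing_pct) else NA)
}

#' Genes overlapping each island
#'
#' Reads a BED or GFF3 annotation (via rtracklayer) and reports, per island,
#' the gene records with >= 1 bp overlap, ordered by position. GFF3 inputs
#' are restricted to records of type "gene" when a type column is present;
#' zero-length abutment at the half-open island end does not count as
#' overlap.
#'
#' @param islands island data.frame (0-based half-open \code{start},
#'   \code{end}).
#' @param annotation path to a BED or GFF3 file.
#' @return List (one element per island row) of data.frames with
#'   \code{gene}, \code{chrom}, \code{start}, \code{end} (1-based inclusive,
#'   as returned by rtracklayer).
#' @export
gene_overlap <- function(islands, annotation) {
  ann <- tryCatch(rtracklayer::import(annotation),
                  error = function(e)
                    stop("failed to parse annotation: ",
                         conditionMessage(e), call. = FALSE))
  md <- S4Vectors::mcols(ann)
  if (!is.null(md$type)) ann <- ann[as.character(md$type) == "gene"]
  md <- S4Vectors::mcols(ann)
  gene_names <- if (!is.null(md$Name)) as.character(md$Name)
    else if (!is.null(md$name)) as.character(md$name)
    else if (!is.null(md$ID)) as.character(md$ID)
    else paste0("feature_", seq_along(ann))
  lapply(seq_len(nrow(islands)), function(i) {
    isl <- GenomicRanges::GRanges(
      islands$chrom[i],
      IRanges::IRanges(start = islands$start[i] + 1, end = islands$end[i]))
    hits <- GenomicRanges::findOverlaps(isl, ann, minoverlap = 1)
    j <- S4Vectors::subjectHits(hits)
    df <- data.frame(
      gene = gene_names[j],
      chrom = as.character(GenomicRanges::seqnames(ann)[j]),
      start = GenomicRanges::start(ann)[j],
      end = GenomicRanges::end(ann)[j],
      stringsAsFactors = FALSE)
    df[order(df$start, df$end), , drop = FALSE]
  })
}

#' Write islands as a BED file
#'
#' @param islands island data.frame (already 0-based half-open).
#' @param path output BED path.
#' @return \code{path}, invisibly.
#' @export
write_islands_bed <- function(islands, path) {
  df <- data.frame(islands$chrom, islands$start, islands$end,
                   islands$population)
  utils::write.table(df, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
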