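#' Published per-class ROH reference summary for six WM populations
#'
#' Transcribed summary statistics of ROH by length class for six western
#' Mediterranean population samples (three southern Iberian: SPEA eastern
#' Andalusians, SPWA western Andalusians, SPOR southern Portuguese; three
#' Moroccan Berber: MAAS Asni, MABO Bouhria, MAFI Figuig), as commonly
#' reported for array-based ROH scans: per class, the number of individuals
#' carrying at least one such segment, the class NROH and SROH (Mb) with
#' their population percentages, per-individual means and mean segment
#' length, plus a TOTAL row per population. Used as an internal-consistency
#' fixture: the derived columns must be reproducible from the raw counts
#' with \code{\link{summarize_categories}}.
#'
#' @return data.frame mirroring the columns of
#'   \code{\link{summarize_categories}} output.
#' @export
wm_reference_summary <- function() {
  path <- system.file("extdata", "wm_roh_class_reference.tsv",
                      package = "rohscape", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Recompute the derived columns of the WM reference summary
#'
#' Runs \code{\link{summarize_categories}} on the raw per-class counts
#' (carriers, NROH, SROH) of every population in
#' \code{\link{wm_reference_summary}} and returns recomputed and printed
#' values side by side for the derived columns.
#'
#' @return List with \code{recomputed} (stacked summaries), \code{printed}
#'   (the transcribed table in the same row order) and
#'   \code{max_abs_difference} over all derived numeric columns.
#' @export
wm_reference_consistency <- function() {
  ref <- wm_reference_summary()
  pops <- unique(ref$population)
  rec <- do.call(rbind, lapply(pops, function(p) {
    sub <- ref[ref$population == p & ref$category != "TOTAL", ]
    summarize_categories(
      sub[, c("category", "carriers", "nroh", "sroh_mb")],
      n = sub$n[1], population = p)
  }))
  rownames(rec) <- NULL
  ord <- order(match(ref$population, pops),
               match(ref$category, c(paste0("ROH", 1:6), "TOTAL")))
  printed <- ref[ord, ]
  rownames(printed) <- NULL
  derived <- c("carriers_pct", "nroh_pct", "nroh_per_ind", "sroh_pct",
               "sroh_per_ind", "mean_length_mb")
  diffs <- abs(as.matrix(rec[, derived]) - as.matrix(printed[, derived]))
  list(recomputed = rec, printed = printed,
       max_abs_difference = max(diffs, na.rm = TRUE))
}
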