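#' Reference regression of SROH on NROH
#'
#' Ordinary least squares of the summed length of long ROH (SROH >= 1.5 Mb,
#' Mb) on their number (NROH >= 1.5 Mb) in a reference (outbred, panmictic)
#' cohort. Individuals lying well above this line carry more long-ROH
#' sequence than their segment count predicts, the signature of recent
#' consanguinity; drift inflates both coordinates jointly.
#'
#' @param records data.frame with \code{nroh_1.5} and \code{sroh_1.5_mb}
#'   (from \code{\link{inbreeding_records}}); >= 3 rows with NROH variance.
#' @return List with \code{slope}, \code{intercept} and the \code{lm} fit.
#' @export
sroh_nroh_reference <- function(records) {
  stopifnot(all(c("nroh_1.5", "sroh_1.5_mb") %in% names(records)))
  if (nrow(records) < 3)
    stop("need at least 3 reference individuals", call. = FALSE)
  if (stats::sd(records$nroh_1.5) == 0)
    stop("reference NROH has zero variance", call. = FALSE)
  fit <- stats::lm(sroh_1.5_mb ~ nroh_1.5, data = records)
  co <- stats::coef(fit)
  list(slope = unname(co[2]), intercept = unname(co[1]), fit = fit)
}

#' Classify the origin of autozygosity from the F_ROH / F_IS plane
#'
#' Position relative to the diagonal (F_IS = F_ROH) and the horizontal
#' (F_IS = 0): points with clearly positive F_IS lying closer to the diagonal
#' than to the zero line indicate systematic (cultural) consanguinity; points
#' on the zero line with appreciable F_ROH indicate panmictic inbreeding from
#' genetic drift; clearly negative F_IS indicates isolation with small
#' effective size. The rules, with tolerance \code{eps}:
#' \itemize{
#'   \item \code{f_is < -eps} -> \code{isolation_low_Ne};
#'   \item \code{|f_is| <= eps} and \code{f_roh > eps} ->
#'     \code{panmictic_drift};
#'   \item \code{f_is > eps} and \code{|f_is - f_roh| <= |f_is|} (closer to
#'     the diagonal than to the zero line) -> \code{systematic_inbreeding};
#'   \item otherwise \code{indeterminate}.
#' }
#' The rule set is total and scale-free: scaling \code{f_roh}, \code{f_is}
#' and \code{eps} by a common positive constant never changes the label.
#'
#' @param f_roh,f_is mean inbreeding coefficients (vectorized).
#' @param eps half-width of the "close to a line" band (default 0.005).
#' @return Character vector of labels.
#' @export
classify_origin <- function(f_roh, f_is, eps = 0.005) {
  stopifnot(is.finite(f_roh), is.finite(f_is), eps > 0)
  ifelse(f_is < -eps, "isolation_low_Ne",
  ifelse(abs(f_is) <= eps & f_roh > eps, "panmictic_drift",
  ifelse(f_is > eps & abs(f_is - f_roh) <= abs(f_is),
         "systematic_inbreeding", "indeterminate")))
}

#' Origin calls per individual and per population
#'
#' Applies \code{\link{classify_origin}} to each individual and to population
#' means, and records each unit's residual from a reference SROH~NROH line
#' when one is supplied.
#'
#' @param records data.frame from \code{\link{inbreeding_records}} including
#'   \code{f_is}.
#' @param reference optional result of \code{\link{sroh_nroh_reference}}.
#' @param eps tolerance passed to \code{\link{classify_origin}}.
#' @return List of two data.frames, \code{individuals} and
#'   \code{populations}, each with \code{unit_id}, \code{f_roh}, \code{f_is},
#'   \code{sroh_1.5_mb}, \code{nroh_1.5}, \code{label} and \code{residual}.
#' @export
origin_calls <- function(records, reference = NULL, eps = 0.005) {
  stopifnot(all(c("f_roh", "f_is", "nroh_1.5", "sroh_1.5_mb") %in%
                  names(records)))
  resid_of <- function(nroh, sroh)
    if (is.null(reference)) rep(0, length(nroh)) else
      sroh - (reference$intercept + reference$slope * nroh)
  ind <- data.frame(
    unit_id = records$sample_id,
    f_roh = records$f_roh, f_is = records$f_is,
    sroh_1.5_mb = records$sroh_1.5_mb, nroh_1.5 = records$nroh_1.5,
    label = classify_origin(records$f_roh, records$f_is, eps),
    residual = resid_of(records$nroh_1.5, records$sroh_1.5_mb),
    stringsAsFactors = FALSE)
  pops <- split(records, records$population)
  pop <- do.call(rbind, lapply(names(pops), function(pn) {
    r <- pops[[pn]]
    data.frame(
      unit_id = pn,
      f_roh = mean(r$f_roh), f_is = mean(r$f_is),
      sroh_1.5_mb = mean(r$sroh_1.5_mb), nroh_1.5 = mean(r$nroh_1.5),
      label = classify_origin(mean(r$f_roh), mean(r$f_is), eps),
      residual = resid_of(mean(r$nroh_1.5), mean(r$sroh_1.5_mb)),
      stringsAsFactors = FALSE)
  }))
  list(individuals = ind, populations = pop)
}
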