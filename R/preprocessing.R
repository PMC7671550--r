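#' Fraction of missing days in a score series
#'
#' @param series Numeric vector of daily scores with `NA` marking missing
#'   days, or a patient-by-day matrix (then a per-patient vector is
#'   returned).
#' @return Fraction(s) in \[0, 1\].
#' @export
missing_fraction <- function(series) {
  if (!is.null(dim(series))) return(rowMeans(is.na(series)))
  if (length(series) == 0L) stop("empty series", call. = FALSE)
  mean(is.na(series))
}

#' Filter a cohort by missingness cut-off and degenerate recording patterns
#'
#' Retains patients whose missing-day fraction does not exceed `cutoff`
#' (inclusive: a patient exactly at the cut-off is kept). Patients whose
#' observed values never vary — including all-zero diaries of patients who
#' recorded no symptoms and no drugs every day — carry no trend information
#' and are excluded when `drop_constant` is `TRUE`. Every exclusion is
#' logged with its reason.
#'
#' @param scores Patient-by-day score matrix (`NA` = missing).
#' @param cutoff Maximum tolerated missing fraction, in (0, 1\];
#'   default 0.375.
#' @param drop_constant Exclude zero-variance recorders; default `TRUE`.
#' @return List of class `cohort_filter` with elements `scores` (retained
#'   rows), `exclusions` (data frame `patient_id`, `reason` in
#'   `{"cutoff", "zero_variance"}`) and `cutoff`.
#' @export
filter_cohort <- function(scores, cutoff = 0.375, drop_constant = TRUE) {
  if (!(cutoff > 0 && cutoff <= 1)) stop("cutoff must be in (0, 1]", call. = FALSE)
  if (is.null(rownames(scores)))
    rownames(scores) <- as.character(seq_len(nrow(scores)))
  frac <- missing_fraction(scores)
  reason <- rep(NA_character_, nrow(scores))
  reason[frac > cutoff] <- "cutoff"
  if (drop_constant) {
    constant <- apply(scores, 1L, function(x) {
      x <- x[!is.na(x)]
      length(x) > 0L && stats::var(x) == 0
    })
    reason[is.na(reason) & constant] <- "zero_variance"
  }
  keep <- is.na(reason)
  if (!any(keep)) stop("no patients retained after filtering", call. = FALSE)
  out <- list(
    scores = scores[keep, , drop = FALSE],
    exclusions = data.frame(patient_id = rownames(scores)[!keep],
                            reason = reason[!keep]),
    cutoff = cutoff
  )
  attr(out$scores, "normalized") <- attr(scores, "normalized")
  class(out) <- "cohort_filter"
  out
}

#' @export
print.cohort_filter <- function(x, ...) {
  cat(sprintf("Cohort filter: %d retained, %d excluded (cutoff %.3f)\n",
              nrow(x$scores), nrow(x$exclusions), x$cutoff))
  if (nrow(x$exclusions))
    print(table(x$exclusions$reason))
  invisible(x)
}

impute_vector <- function(x) {
  obs <- which(!is.na(x))
  if (length(obs) == 0L) stop("cannot impute an all-missing series", call. = FALSE)
  v <- length(x)
  # leading gap: carry the first observed value backwards
  if (obs[1L] > 1L) x[seq_len(obs[1L] - 1L)] <- x[obs[1L]]
  # trailing gap: carry the last observed value forwards
  if (obs[length(obs)] < v) x[(obs[length(obs)] + 1L):v] <- x[obs[length(obs)]]
  # interior gaps: linear interpolation between the flanking observations,
  # y[t'+t''] = y[t'] + (y[t'+w] - y[t']) * t''/w for a gap of length w-1
  for (j in seq_along(obs)[-1L]) {
    t0 <- obs[j - 1L]; t1 <- obs[j]; w <- t1 - t0
    if (w > 1L) {
      tt <- seq_len(w - 1L)
      x[t0 + tt] <- x[t0] + (x[t1] - x[t0]) * tt / w
    }
  }
  x
}

#' Impute missing days in score series
#'
#' Leading missing days take the first observed value, trailing missing
#' days the last observed value, and each interior gap is filled by linear
#' interpolation between its flanking observations. Observed values are
#' never altered and the operation is idempotent.
#'
#' @param scores Numeric vector or patient-by-day matrix with `NA` marking
#'   missing days; every series must contain at least one observation.
#' @return Same shape with no `NA`s.
#' @export
impute_scores <- function(scores) {
  if (is.null(dim(scores))) return(impute_vector(scores))
  out <- t(apply(scores, 1L, impute_vector))
  dimnames(out) <- dimnames(scores)
  attr(out, "normalized") <- attr(scores, "normalized")
  out
}

#' Write the cohort exclusion log as delimited text
#'
#' @param filtered A `cohort_filter` object from [filter_cohort()].
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @return Invisibly, the exclusion data frame.
#' @export
write_exclusion_log <- function(filtered, path, sep = "\t") {
  utils::write.table(filtered$exclusions, path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(filtered$exclusions)
}
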