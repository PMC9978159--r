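#' Per-assessor Z-score normalisation of sensory panel scores
#'
#' Z = (x - mu) / sigma per assessor, with mu and sigma the mean and
#' standard deviation of all scores that assessor gave (within one
#' ripening-time session when a `week` column is present and
#' `by_session = TRUE`). This removes assessor-specific location and scale
#' so panellists with different personal scales become comparable.
#' Assessors (or assessor-sessions) with zero score variance are excluded
#' with a warning.
#'
#' @param scores data.frame with columns `assessor`, `cheese`, `score`
#'   (0-20 scale) and optionally `week`.
#' @param by_session Standardise within assessor x week rather than
#'   pooling an assessor's scores across sessions.
#' @param sd_type "sample" (n-1 denominator, the default) or "population".
#' @return The input rows (minus excluded assessors) with a `z` column;
#'   each retained assessor's Z-scores have mean 0.
#' @export
assessor_zscores <- function(scores, by_session = TRUE,
                             sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  stopifnot(all(c("assessor", "cheese", "score") %in% names(scores)))
  if (any(scores$score < 0 | scores$score > 20))
    stop("scores must lie on the 0-20 scale")
  key <- if (by_session && "week" %in% names(scores)) {
    interaction(scores$assessor, scores$week, drop = TRUE)
  } else factor(scores$assessor)
  out <- scores
  out$z <- NA_real_
  dropped <- character()
  for (k in levels(key)) {
    i <- which(key == k)
    x <- scores$score[i]
    if (length(x) < 2L || length(unique(x)) < 2L) {
      dropped <- c(dropped, k)
      next
    }
    sigma <- stats::sd(x)
    if (sd_type == "population")
      sigma <- sigma * sqrt((length(x) - 1) / length(x))
    out$z[i] <- (x - mean(x)) / sigma
  }
  if (length(dropped) > 0L) {
    warning("excluding assessor(s) with constant scores: ",
            paste(dropped, collapse = ", "))
    out <- out[!is.na(out$z), , drop = FALSE]
  }
  out
}

#' Mean Z-score per cheese
#'
#' Averages the per-assessor Z-scores over all panel members who scored a
#' cheese; the result is the sensory quality criterion. Invariant to
#' assessor-specific affine rescaling of the raw scores (positive scale).
#'
#' @param z Output of [assessor_zscores()].
#' @return data.frame with `cheese` (and `week` if present) and `mean_z`.
#' @export
cheese_zscore <- function(z) {
  stopifnot(all(c("cheese", "z") %in% names(z)))
  if (nrow(z) == 0L) stop("no scores available")
  keys <- intersect(c("cheese", "week"), names(z))
  agg <- stats::aggregate(z$z, by = z[keys], FUN = mean)
  names(agg)[ncol(agg)] <- "mean_z"
  agg[do.call(order, agg[keys]), , drop = FALSE]
}
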