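# Detection-flag filtering and quantile normalization, applied before any
# statistics.

#' Filter features by detection call
#'
#' Keeps features whose fraction of `Present`-or-`Marginal` detection
#' calls reaches `min_fraction` (default: at least 50% of samples, the
#' discovery-cohort rule; `strict = TRUE` turns the comparison into a
#' strict inequality, matching the "> 80%" phrasing used for
#' validation-style cohorts).  When the matrix carries no flags, a
#' fallback intensity floor may be used instead.
#'
#' @param expr An `expr_matrix`.
#' @param min_fraction Detection fraction threshold in \[0, 1\].
#' @param strict Use `>` rather than `>=` when comparing to the threshold.
#' @param intensity_floor Fallback: with no flags, a cell counts as
#'   detected when its log2 intensity exceeds this floor.
#' @return The filtered `expr_matrix`; the sample set is unchanged.
#' @export
filter_detected <- function(expr, min_fraction = 0.5, strict = FALSE,
                            intensity_floor = NULL) {
  v <- .values(expr)
  flags <- if (inherits(expr, "expr_matrix")) expr$flags else NULL
  if (min_fraction < 0 || min_fraction > 1)
    .cfg_stop("min_fraction", "must lie in [0, 1]")
  if (is.null(flags)) {
    if (is.null(intensity_floor))
      .cfg_stop("intensity_floor",
                "matrix has no detection flags and no fallback floor was given")
    det <- v > intensity_floor
  } else {
    det <- flags == "Present" | flags == "Marginal"
  }
  frac <- rowMeans(det)
  keep <- if (strict) frac > min_fraction else frac >= min_fraction
  expression_matrix(v[keep, , drop = FALSE],
                    if (is.null(flags)) NULL else flags[keep, , drop = FALSE])
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample onto the common distribution defined by the
#' across-sample mean of sorted value vectors.  Ties within a sample
#' receive the mean of the quantile values their ranks span, which keeps
#' the transform deterministic and rank-preserving.
#'
#' @param expr An `expr_matrix` or numeric matrix with at least 2 samples.
#' @return An object of the same kind with normalized values.
#' @export
quantile_normalize <- function(expr) {
  v <- .values(expr)
  if (ncol(v) < 2L) stop("quantile normalization needs at least 2 samples")
  if (!all(is.finite(v))) stop("quantile normalization requires finite values")
  m <- rowMeans(apply(v, 2L, sort))
  s0 <- c(0, cumsum(m))
  out <- v
  for (j in seq_len(ncol(v))) {
    rmin <- rank(v[, j], ties.method = "min")
    rmax <- rank(v[, j], ties.method = "max")
    out[, j] <- (s0[rmax + 1L] - s0[rmin]) / (rmax - rmin + 1L)
  }
  if (inherits(expr, "expr_matrix")) expression_matrix(out, expr$flags) else out
}
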