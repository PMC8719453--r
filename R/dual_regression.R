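# normalize matrix rows (or columns) to unit variance (population sd).
# Zero-variance regressors are a rank failure for the regression stages.
.normalize_rows <- function(A, what = "map row") {
  s <- sqrt(rowMeans(sweep(A, 1, rowMeans(A), `-`)^2))
  bad <- which(s < 1e-12)
  if (length(bad)) {
    stop(sprintf("rank deficiency: %s(s) %s have zero variance", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  A / s
}

.check_rank <- function(M, K, what) {
  qrM <- qr(M)
  if (qrM$rank < K) {
    offending <- sort(qrM$pivot[(qrM$rank + 1):K])
    stop(sprintf("rank deficiency: %s span rank %d < %d (offending component(s): %s)",
                 what, qrM$rank, K, paste(offending, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Spatial regression: group maps to subject time courses
#'
#' First stage of dual regression. Each time point's voxel pattern is
#' regressed on the K group spatial maps (rows of `A`, variance-normalized
#' first so coefficient scales are comparable across subjects):
#' `TC = X A' (A A')^{-1}`. No intercept: inputs are assumed demeaned by
#' standardization.
#'
#' @param X_s Subject data, T x V matrix or `bold_series`.
#' @param A K x V group spatial maps (full row rank).
#' @return A `subject_timecourses`: `TC` (T x K), `subject_id`, `source`.
#' @export
spatial_regression <- function(X_s, A) {
  sid <- "s"
  if (inherits(X_s, "bold_series")) {
    sid <- X_s$subject_id
    X_s <- X_s$data
  }
  A <- as.matrix(A)
  if (ncol(X_s) != ncol(A)) stop("X_s and A must share the voxel dimension", call. = FALSE)
  K <- nrow(A)
  An <- .normalize_rows(A, "map row")
  .check_rank(t(An), K, "group map rows")
  TC <- t(solve(tcrossprod(An), An %*% t(X_s)))
  structure(list(subject_id = sid, TC = TC, source = "full-map"),
            class = "subject_timecourses")
}

#' Temporal regression: subject time courses to subject spatial maps
#'
#' Second stage of dual regression. Each voxel's time course is regressed
#' on the K subject-specific component time courses (columns
#' variance-normalized first): `B = (TC' TC)^{-1} TC' X_s`.
#'
#' @param X_s Subject data, T x V matrix or `bold_series`.
#' @param TC T x K time-course matrix or `subject_timecourses`.
#' @return A `subject_maps`: `B` (K x V), `subject_id`.
#' @export
temporal_regression <- function(X_s, TC) {
  sid <- "s"
  if (inherits(X_s, "bold_series")) {
    sid <- X_s$subject_id
    X_s <- X_s$data
  }
  if (inherits(TC, "subject_timecourses")) TC <- TC$TC
  TC <- as.matrix(TC)
  if (nrow(X_s) != nrow(TC)) stop("X_s and TC must share the time dimension", call. = FALSE)
  K <- ncol(TC)
  TCn <- t(.normalize_rows(t(TC), "time course"))
  .check_rank(TCn, K, "time courses")
  B <- solve(crossprod(TCn), crossprod(TCn, X_s))
  structure(list(subject_id = sid, B = B), class = "subject_maps")
}

#' Run both dual-regression stages for a list of subjects
#'
#' @param series List of `bold_series` (standardized internally).
#' @param A K x V group spatial maps.
#' @return List with `timecourses` and `maps`, one element per subject.
#' @export
dual_regression <- function(series, A) {
  series <- lapply(series, standardize_series)
  tcs <- lapply(series, spatial_regression, A = A)
  maps <- Map(function(b, tc) temporal_regression(b, tc), series, tcs)
  list(timecourses = tcs, maps = maps)
}
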