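#' One-sample group t-statistics over subject spatial maps
#'
#' For every (component, voxel) cell, tests the subject-specific map
#' coefficients against zero: `t = mean / (sd / sqrt(n))`, `df = n - 1`.
#' Cells with zero across-subject variance get `t = 0` and are counted in
#' `n_degenerate` (with a warning).
#'
#' @param subject_maps List of `subject_maps` (>= 3 subjects).
#' @return List with `T_stat` (K x V), `df`, `n_degenerate`.
#' @export
group_t_maps <- function(subject_maps) {
  if (length(subject_maps) < 3) stop("need at least 3 subjects for a group t-test", call. = FALSE)
  mats <- lapply(subject_maps, function(m) if (inherits(m, "subject_maps")) m$B else as.matrix(m))
  K <- nrow(mats[[1]]); V <- ncol(mats[[1]])
  n <- length(mats)
  stacked <- matrix(vapply(mats, as.numeric, numeric(K * V)), K * V, n)
  m <- rowMeans(stacked)
  s2 <- (rowSums(stacked^2) - n * m^2) / (n - 1)
  s2[s2 < 0] <- 0
  s <- sqrt(s2)
  tval <- numeric(K * V)
  zero_var <- s < 1e-14
  tval[!zero_var] <- m[!zero_var] / (s[!zero_var] / sqrt(n))
  n_degenerate <- sum(zero_var & abs(m) > 0)
  if (n_degenerate > 0) {
    warning(sprintf("%d cell(s) had zero across-subject variance; t set to 0", n_degenerate))
  }
  list(T_stat = matrix(tval, K, V), df = n - 1L, n_degenerate = n_degenerate)
}

#' Convert t-statistics to z-scores
#'
#' Maps each t value through its cumulative distribution into the standard
#' normal quantile of equal tail probability, using log-scale survival
#' functions on both tails for numerical stability at large |t|. Sign is
#' preserved and the transform is strictly monotone.
#'
#' @param t_stat Numeric vector/matrix of t statistics.
#' @param df Degrees of freedom (>= 1).
#' @return z-scores with the same shape as `t_stat`.
#' @export
t_to_z <- function(t_stat, df) {
  if (df < 1) stop("`df` must be >= 1", call. = FALSE)
  z <- t_stat
  pos <- !is.na(t_stat) & t_stat >= 0
  if (any(pos)) {
    z[pos] <- stats::qnorm(stats::pt(t_stat[pos], df, lower.tail = FALSE, log.p = TRUE),
                           lower.tail = FALSE, log.p = TRUE)
  }
  if (any(!pos)) {
    z[!pos] <- stats::qnorm(stats::pt(t_stat[!pos], df, lower.tail = TRUE, log.p = TRUE),
                            lower.tail = TRUE, log.p = TRUE)
  }
  z
}

#' Multiple-testing control over z-scored significance maps
#'
#' Converts z-scores to two-sided p-values and applies the chosen
#' correction pooled over all K x V tests. Non-surviving cells are zeroed
#' in the thresholding view `Z_thresh`.
#'
#' @param Z K x V z-score matrix.
#' @param df Degrees of freedom of the originating t-test (metadata).
#' @param q Significance level in (0, 1).
#' @param method `"bh-fdr"` (Benjamini-Hochberg, default) or `"bonferroni"`.
#' @return A `significance_maps`: `Z`, `Z_thresh`, `surviving_mask`
#'   (K x V logical), `df`, `q`, `correction`.
#' @export
multiplicity_correct <- function(Z, df, q = 0.05, method = c("bh-fdr", "bonferroni")) {
  method <- match.arg(method)
  if (!(is.numeric(q) && length(q) == 1 && q > 0 && q < 1)) {
    stop("`q` must be a single value in (0, 1)", call. = FALSE)
  }
  Z <- as.matrix(Z)
  p <- 2 * stats::pnorm(abs(Z), lower.tail = FALSE)
  p_adj <- stats::p.adjust(as.numeric(p), method = if (method == "bh-fdr") "BH" else "bonferroni")
  surviving <- matrix(p_adj <= q, nrow(Z), ncol(Z))
  Z_thresh <- Z
  Z_thresh[!surviving] <- 0
  structure(
    list(Z = Z, Z_thresh = Z_thresh, surviving_mask = surviving,
         df = df, q = q, correction = method),
    class = "significance_maps"
  )
}

#' Sweep the global z threshold, counting overlaps and unassigned voxels
#'
#' For each threshold `theta`, a voxel's multiplicity is the number of
#' components with a surviving z-score of at least `theta` there.
#' `n_zeros` counts voxels with multiplicity 0; `n_overlap` is by default
#' the total surplus `sum(max(0, m_v - 1))` (repeated assignments), or the
#' number of multiply-covered voxels with `overlap_count = "voxels"`.
#'
#' @param sig A `significance_maps`.
#' @param t_min,t_max,step Threshold grid (defaults 1.6 to 3.0 by 0.1).
#' @param overlap_count `"surplus"` (default) or `"voxels"`.
#' @return A `threshold_sweep` data structure with per-threshold counts.
#' @export
sweep_threshold <- function(sig, t_min = 1.6, t_max = 3.0, step = 0.1,
                            overlap_count = c("surplus", "voxels")) {
  overlap_count <- match.arg(overlap_count)
  stopifnot(inherits(sig, "significance_maps"))
  if (!(t_min < t_max) || step <= 0) stop("need t_min < t_max and step > 0", call. = FALSE)
  thresholds <- seq(t_min, t_max, by = step)
  Zv <- sig$Z_thresh
  V <- ncol(Zv)
  n_zeros <- integer(length(thresholds))
  n_overlap <- integer(length(thresholds))
  for (i in seq_along(thresholds)) {
    m_v <- colSums(Zv >= thresholds[i] & sig$surviving_mask)
    n_zeros[i] <- sum(m_v == 0)
    n_overlap[i] <- if (overlap_count == "surplus") sum(pmax(0L, m_v - 1L)) else sum(m_v > 1)
  }
  structure(
    list(thresholds = thresholds, n_overlap = n_overlap, n_zeros = n_zeros,
         V = V, overlap_count = overlap_count, chosen = NA_real_,
         policy = NULL),
    class = "threshold_sweep"
  )
}

#' Choose the global threshold from a sweep
#'
#' Default policy minimizes
#' `J(theta) = n_zeros(theta)/V + gamma * n_overlap(theta)/V`
#' with `gamma = 0.1`, so unassigned voxels are weighted more heavily than
#' repeated assignments (preferring to reduce unassigned voxels). Ties go
#' to the smaller threshold. A `manual` value overrides the policy.
#'
#' @param sweep A `threshold_sweep`.
#' @param gamma Relative weight of overlaps (default 0.1).
#' @param manual Optional explicit threshold to use instead.
#' @return The chosen threshold (scalar).
#' @export
choose_threshold <- function(sweep, gamma = 0.1, manual = NULL) {
  stopifnot(inherits(sweep, "threshold_sweep"))
  if (!length(sweep$thresholds)) stop("empty threshold sweep", call. = FALSE)
  if (!is.null(manual)) return(as.numeric(manual))
  J <- sweep$n_zeros / sweep$V + gamma * sweep$n_overlap / sweep$V
  sweep$thresholds[which.min(J)]   # which.min takes the first = smallest theta
}

#' Hard-label voxels from significance maps at a global threshold
#'
#' Each voxel receives the label of the component with the largest
#' surviving z-score at or above `theta`; voxels with no qualifying
#' component get label 0 (unassigned). Exact ties go to the lowest
#' component index.
#'
#' @param sig A `significance_maps`.
#' @param theta Global z threshold.
#' @param geometry Optional `voxel_geometry` to attach.
#' @return A `parcellation`: `labels` (length-V integer, 0 = unassigned),
#'   `K`, `threshold`, `geometry`, `provenance`.
#' @export
assign_labels <- function(sig, theta, geometry = NULL) {
  stopifnot(inherits(sig, "significance_maps"))
  Z <- sig$Z
  qualify <- (Z >= theta) & sig$surviving_mask
  Zq <- Z
  Zq[!qualify] <- -Inf
  labels <- max.col(t(Zq), ties.method = "first")
  labels[colSums(qualify) == 0] <- 0L
  structure(
    list(labels = as.integer(labels), K = nrow(Z), threshold = theta,
         geometry = geometry,
         provenance = list(correction = sig$correction, q = sig$q, df = sig$df,
                           tie_rule = "lowest component index")),
    class = "parcellation"
  )
}

#' Construct a parcellation from a label vector
#'
#' Wraps an existing hard labeling (e.g. an external atlas in the same
#' geometry, or a planted ground truth) so it can be scored with the
#' evaluation metrics.
#'
#' @param labels Integer vector, one label per voxel (0 = unassigned).
#' @param geometry Optional `voxel_geometry`.
#' @param K Number of components; defaults to `max(labels)`.
#' @param threshold Threshold metadata (if any).
#' @return A `parcellation`.
#' @export
as_parcellation <- function(labels, geometry = NULL, K = NULL, threshold = NA_real_) {
  labels <- as.integer(labels)
  if (any(labels < 0)) stop("labels must be non-negative", call. = FALSE)
  if (!is.null(geometry) && length(labels) != n_voxels(geometry)) {
    stop("label vector and geometry disagree on voxel count", call. = FALSE)
  }
  if (is.null(K)) K <- max(labels, 1L)
  structure(
    list(labels = labels, K = as.integer(K), threshold = threshold,
         geometry = geometry, provenance = list(source = "as_parcellation")),
    class = "parcellation"
  )
}

#' @export
print.parcellation <- function(x, ...) {
  tab <- table(factor(x$labels[x$labels > 0], levels = seq_len(x$K)))
  cat(sprintf("<parcellation> %d voxels, K = %d, threshold = %.2f\n",
              length(x$labels), x$K, x$threshold))
  cat(sprintf("  %d assigned (%d nonempty parcels), %d unassigned\n",
              sum(x$labels > 0), sum(tab > 0), sum(x$labels == 0)))
  invisible(x)
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat(sprintf("<threshold_sweep> %d thresholds in [%.2f, %.2f], V = %d (%s overlap count)\n",
              length(x$thresholds), min(x$thresholds), max(x$thresholds), x$V,
              x$overlap_count))
  invisible(x)
}
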