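#' Parcel-masked seed time course by spatial regression
#'
#' The group spatial map of a component is zeroed outside the voxels of
#' its parcel, and the subject's data are regressed on this single masked
#' regressor (variance-normalized), yielding one seed time course for the
#' parcel.
#'
#' @param X_s Subject data, T x V matrix or `bold_series` (standardized
#'   internally).
#' @param group_map_row Length-V spatial map of the component.
#' @param parc A `parcellation`.
#' @param parcel_id Label whose voxels define the mask.
#' @return Length-T numeric seed time course.
#' @export
masked_seed_timecourse <- function(X_s, group_map_row, parc, parcel_id) {
  stopifnot(inherits(parc, "parcellation"))
  if (inherits(X_s, "bold_series")) X_s <- standardize_series(X_s)$data
  w <- as.numeric(group_map_row)
  if (length(w) != ncol(X_s)) stop("map row and data disagree on voxel count", call. = FALSE)
  inside <- parc$labels == parcel_id
  if (!any(inside)) stop(sprintf("parcel %s is empty", parcel_id), call. = FALSE)
  w[!inside] <- 0
  tc <- spatial_regression(X_s, matrix(w, 1))
  as.numeric(tc$TC[, 1])
}

#' Seed-to-target Pearson connectivity map
#'
#' @param tc Length-T seed time course.
#' @param targets T x M matrix of target time courses.
#' @param subject_id,condition,parcel_id Metadata tags.
#' @return A `connectivity_map`: `r` (length-M correlations; constant
#'   target columns give r = 0 with a warning), plus metadata.
#' @export
connectivity_map <- function(tc, targets, subject_id = "s", condition = "synthetic",
                             parcel_id = 1L) {
  targets <- as.matrix(targets)
  if (length(tc) != nrow(targets)) {
    stop("seed time course and targets disagree on the number of time points", call. = FALSE)
  }
  if (ncol(targets) < 1) stop("need at least one target column", call. = FALSE)
  sds <- apply(targets, 2, stats::sd)
  constant <- sds < 1e-14 | stats::sd(tc) < 1e-14
  r <- rep(0, ncol(targets))
  if (any(!constant)) {
    r[!constant] <- as.numeric(stats::cor(tc, targets[, !constant, drop = FALSE]))
  }
  if (any(constant)) warning(sprintf("%d constant column(s); r set to 0", sum(constant)))
  structure(
    list(subject_id = subject_id, condition = condition, parcel_id = parcel_id, r = r),
    class = "connectivity_map"
  )
}

#' Two-condition contrast of connectivity maps
#'
#' Per target, a two-tailed two-sample t-test comparing Fisher
#' z-transformed correlations between conditions, followed by multiplicity
#' correction pooled over targets. A paired mode and a plain-r mode are
#' available.
#'
#' @param maps_A,maps_B Lists of `connectivity_map` (one per subject), or
#'   subject-by-target matrices of correlations.
#' @param q Significance level for the correction.
#' @param method `"bh-fdr"` (default) or `"bonferroni"`.
#' @param transform `"fisher"` (default, atanh before testing) or `"raw"`.
#' @param paired Use a paired t-test (same subjects in both conditions).
#' @return A `condition_contrast`: `t_map`, `df`, `p`, `p_adj`,
#'   `surviving_mask`, `direction` (sign of the mean difference A - B).
#' @export
contrast_conditions <- function(maps_A, maps_B, q = 0.05,
                                method = c("bh-fdr", "bonferroni"),
                                transform = c("fisher", "raw"),
                                paired = FALSE) {
  method <- match.arg(method)
  transform <- match.arg(transform)
  as_mat <- function(maps) {
    if (is.matrix(maps)) return(maps)
    do.call(rbind, lapply(maps, function(m) {
      if (inherits(m, "connectivity_map")) m$r else as.numeric(m)
    }))
  }
  RA <- as_mat(maps_A); RB <- as_mat(maps_B)
  if (ncol(RA) != ncol(RB)) stop("conditions disagree on target count", call. = FALSE)
  n1 <- nrow(RA); n2 <- nrow(RB)
  if (n1 < 3 || n2 < 3) stop("need at least 3 subjects per condition", call. = FALSE)
  if (transform == "fisher") {
    clamp <- function(x) pmin(pmax(x, -1 + 1e-12), 1 - 1e-12)
    RA <- atanh(clamp(RA)); RB <- atanh(clamp(RB))
  }
  if (paired) {
    if (n1 != n2) stop("paired test needs equal subject counts", call. = FALSE)
    Dm <- RA - RB
    m <- colMeans(Dm)
    s <- apply(Dm, 2, stats::sd)
    df <- n1 - 1L
    tval <- ifelse(s < 1e-14, 0, m / (s / sqrt(n1)))
  } else {
    m1 <- colMeans(RA); m2 <- colMeans(RB)
    v1 <- apply(RA, 2, stats::var); v2 <- apply(RB, 2, stats::var)
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    df <- n1 + n2 - 2L
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    tval <- ifelse(se < 1e-14, 0, (m1 - m2) / se)
    m <- m1 - m2
  }
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  p_adj <- stats::p.adjust(p, method = if (method == "bh-fdr") "BH" else "bonferroni")
  structure(
    list(t_map = tval, df = df, p = p, p_adj = p_adj,
         surviving_mask = p_adj <= q, direction = sign(m),
         q = q, correction = method, transform = transform, paired = paired),
    class = "condition_contrast"
  )
}

#' @export
print.condition_contrast <- function(x, ...) {
  cat(sprintf("<condition_contrast> %d targets, df = %d, %d surviving at %s q = %g (%s)\n",
              length(x$t_map), x$df, sum(x$surviving_mask), x$correction, x$q,
              x$transform))
  invisible(x)
}
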