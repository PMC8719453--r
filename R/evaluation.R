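#' PCA functional homogeneity of a parcellation
#'
#' For each subject and each parcel with at least 2 voxels, computes the
#' eigenvalues of the voxel-by-voxel covariance of the parcel's
#' standardized time courses and reports the ratio of the first eigenvalue
#' to their sum -- the fraction of the parcel's temporal variance carried
#' by its first principal component.
#'
#' @param series A `bold_series` or list of them (standardized internally).
#' @param parc A `parcellation`.
#' @param min_size Parcels smaller than this are skipped with a warning.
#' @return A `homogeneity_result`: `table` (data.frame subject, parcel,
#'   size, eigen_ratio), `mean_per_subject`, `mean_overall` (mean over
#'   parcels, then over subjects).
#' @export
homogeneity <- function(series, parc, min_size = 2L) {
  stopifnot(inherits(parc, "parcellation"))
  if (all(parc$labels == 0)) stop("empty parcellation: no assigned voxels", call. = FALSE)
  if (inherits(series, "bold_series")) series <- list(series)
  series <- lapply(series, standardize_series)
  parcels <- sort(unique(parc$labels[parc$labels > 0]))
  small <- parcels[vapply(parcels, function(k) sum(parc$labels == k), integer(1)) < min_size]
  if (length(small)) {
    warning(sprintf("skipping %d parcel(s) with fewer than %d voxels", length(small), min_size))
    parcels <- setdiff(parcels, small)
  }
  if (!length(parcels)) stop("no parcel has enough voxels to evaluate", call. = FALSE)
  rows <- list()
  for (s in seq_along(series)) {
    X <- series[[s]]$data
    for (k in parcels) {
      vox <- which(parc$labels == k)
      d <- svd(X[, vox, drop = FALSE], nu = 0, nv = 0)$d
      ev <- d^2
      rows[[length(rows) + 1L]] <- data.frame(
        subject = series[[s]]$subject_id, parcel = k, size = length(vox),
        eigen_ratio = ev[1] / sum(ev))
    }
  }
  tab <- do.call(rbind, rows)
  per_subj <- tapply(tab$eigen_ratio, tab$subject, mean)
  structure(
    list(table = tab, mean_per_subject = per_subj,
         mean_overall = mean(per_subj)),
    class = "homogeneity_result"
  )
}

#' @export
print.homogeneity_result <- function(x, ...) {
  cat(sprintf("<homogeneity_result> %d (subject, parcel) entries; mean eigen ratio %.4f\n",
              nrow(x$table), x$mean_overall))
  invisible(x)
}

# Average correlation matrix over subjects. Per-subject Pearson correlations
# are averaged entrywise, which equals averaging per-subject bin means
# downstream because pair counts do not vary across subjects. With
# `fisher = TRUE` correlations are atanh-transformed before averaging.
.mean_corr <- function(series, fisher = FALSE) {
  series <- lapply(series, standardize_series)
  V <- ncol(series[[1]]$data)
  acc <- matrix(0, V, V)
  for (b in series) {
    R <- suppressWarnings(stats::cor(b$data))
    if (fisher) R <- atanh(pmin(pmax(R, -1 + 1e-12), 1 - 1e-12))
    acc <- acc + R
  }
  acc / length(series)
}

# lower-triangle pair index (i > j, ordered as dist()/lower.tri())
.pair_index <- function(V) {
  which(lower.tri(matrix(0, V, V)), arr.ind = TRUE)
}

# per-bin within/between sums and counts for one correlation vector
.pair_stats <- function(rvec, dvec, li, lj, bin_edges) {
  nb <- length(bin_edges) - 1L
  bin <- findInterval(dvec, bin_edges, left.open = TRUE)  # (lo, hi] bins
  ok <- li > 0L & lj > 0L & !is.na(rvec) & bin >= 1L & bin <= nb
  within <- li == lj
  idx <- which(ok)
  code <- (bin[idx] - 1L) * 2L + ifelse(within[idx], 1L, 2L)
  cnt <- tabulate(code, nbins = 2L * nb)
  sums <- numeric(2L * nb)
  if (length(idx)) {
    agg <- rowsum(rvec[idx], group = code)
    sums[as.integer(rownames(agg))] <- agg[, 1]
  }
  w_cnt <- cnt[seq(1L, 2L * nb, by = 2L)]
  b_cnt <- cnt[seq(2L, 2L * nb, by = 2L)]
  w_mean <- ifelse(w_cnt > 0, sums[seq(1L, 2L * nb, by = 2L)] / w_cnt, NA_real_)
  b_mean <- ifelse(b_cnt > 0, sums[seq(2L, 2L * nb, by = 2L)] / b_cnt, NA_real_)
  list(within_corr = w_mean, between_corr = b_mean,
       n_within_pairs = w_cnt, n_between_pairs = b_cnt)
}

.dcbc_weights <- function(n_within, n_between, weighting) {
  both <- n_within > 0 & n_between > 0
  if (!any(both)) {
    stop("no spatial bin contains both within- and between-region pairs", call. = FALSE)
  }
  w <- numeric(length(n_within))
  if (weighting == "harmonic") {
    w[both] <- n_within[both] * n_between[both] / (n_within[both] + n_between[both])
  } else {
    w[both] <- 1
  }
  w / sum(w)
}

.dcbc_from_corr <- function(Rbar, labels, coords, bin_edges, weighting) {
  V <- length(labels)
  dvec <- as.numeric(stats::dist(coords))
  pidx <- .pair_index(V)
  rvec <- Rbar[lower.tri(Rbar)]
  st <- .pair_stats(rvec, dvec, labels[pidx[, 1]], labels[pidx[, 2]], bin_edges)
  if (all(st$n_within_pairs + st$n_between_pairs == 0)) {
    stop("no voxel pair qualifies for any spatial bin", call. = FALSE)
  }
  w <- .dcbc_weights(st$n_within_pairs, st$n_between_pairs, weighting)
  diff <- st$within_corr - st$between_corr
  global <- sum(w[w > 0] * diff[w > 0])
  structure(
    c(list(bin_edges = bin_edges), st,
      list(weight = w, global_dcbc = global, weighting = weighting)),
    class = "dcbc_result"
  )
}

#' Distance-binned within/between-region pair correlations (DCBC)
#'
#' Computes the Pearson correlation of every voxel pair, classifies pairs
#' as within-region (same nonzero label) or between-region (different
#' nonzero labels; pairs touching label 0 are excluded), bins them by
#' Euclidean distance into half-open bins `(lo, hi]`, and reports per-bin
#' mean correlations averaged over subjects, together with the global
#' distance-controlled boundary coefficient.
#'
#' @param series A `bold_series` or list of them.
#' @param parc A `parcellation` (its labels are used).
#' @param geometry Voxel geometry; defaults to `parc$geometry`.
#' @param bin_edges Distance bin edges in mm; default `seq(0, 30, 3)`
#'   giving bins (0,3], ..., (27,30]. Pairs beyond the last edge are
#'   ignored.
#' @param weighting `"harmonic"` (default; bin weight proportional to
#'   `n_w * n_b / (n_w + n_b)`) or `"uniform"`. Bins lacking either pair
#'   type get weight 0.
#' @param fisher Average Fisher-z transformed correlations instead of raw
#'   correlations (default off).
#' @return A `dcbc_result`: `bin_edges`, `within_corr`, `between_corr`,
#'   `n_within_pairs`, `n_between_pairs`, `weight`, `global_dcbc`.
#' @export
pairwise_bin_correlations <- function(series, parc, geometry = NULL,
                                      bin_edges = seq(0, 30, by = 3),
                                      weighting = c("harmonic", "uniform"),
                                      fisher = FALSE) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(parc, "parcellation"))
  if (inherits(series, "bold_series")) series <- list(series)
  if (!length(series)) stop("need at least one subject", call. = FALSE)
  if (is.null(geometry)) geometry <- parc$geometry
  if (is.null(geometry)) stop("no geometry available (pass `geometry`)", call. = FALSE)
  Rbar <- .mean_corr(series, fisher = fisher)
  .dcbc_from_corr(Rbar, parc$labels, geometry$coords, bin_edges, weighting)
}

#' Global DCBC from binned pair correlations
#'
#' Weighted sum over distance bins of (within-region minus between-region)
#' mean correlation. Positive values indicate that voxel pairs inside one
#' region are more correlated than equally distant pairs straddling a
#' boundary.
#'
#' @param d A `dcbc_result`.
#' @return Scalar global DCBC.
#' @export
global_dcbc <- function(d) {
  stopifnot(inherits(d, "dcbc_result"))
  both <- d$n_within_pairs > 0 & d$n_between_pairs > 0
  if (!any(both)) stop("undefined result: no bin has both pair types", call. = FALSE)
  sum(d$weight[both] * (d$within_corr[both] - d$between_corr[both]))
}

#' @export
print.dcbc_result <- function(x, ...) {
  nb <- length(x$bin_edges) - 1
  cat(sprintf("<dcbc_result> %d distance bins (%g-%g mm), global DCBC = %.4f (%s weights)\n",
              nb, min(x$bin_edges), max(x$bin_edges), x$global_dcbc, x$weighting))
  invisible(x)
}

#' Face-adjacent region pairs of a parcellation
#'
#' @param parc A `parcellation`.
#' @param geometry Voxel geometry; defaults to `parc$geometry`.
#' @return Data frame with `region_a < region_b` (both nonzero) and
#'   `n_adjacent_voxel_pairs`, one row per boundary: region pairs sharing
#'   at least one face-adjacent (6-connectivity) voxel pair.
#' @export
region_adjacency <- function(parc, geometry = NULL) {
  stopifnot(inherits(parc, "parcellation"))
  if (is.null(geometry)) geometry <- parc$geometry
  adj <- lattice_adjacency(geometry)
  la <- parc$labels[adj[, 1]]
  lb <- parc$labels[adj[, 2]]
  keep <- la > 0 & lb > 0 & la != lb
  if (!any(keep)) {
    return(data.frame(region_a = integer(0), region_b = integer(0),
                      n_adjacent_voxel_pairs = integer(0)))
  }
  a <- pmin(la[keep], lb[keep])
  b <- pmax(la[keep], lb[keep])
  tab <- table(a, b)
  idx <- which(tab > 0, arr.ind = TRUE)
  out <- data.frame(
    region_a = as.integer(rownames(tab))[idx[, 1]],
    region_b = as.integer(colnames(tab))[idx[, 2]],
    n_adjacent_voxel_pairs = as.integer(tab[idx]))
  out[order(out$region_a, out$region_b), , drop = FALSE]
}

#' Local DCBC of one boundary
#'
#' DCBC restricted to the voxels of the two regions flanking one boundary:
#' within-region pairs come from a-a and b-b, between-region pairs from
#' a-b; all other voxels are ignored.
#'
#' @param series A `bold_series` or list of them (ignored if `corr` given).
#' @param parc A `parcellation`.
#' @param region_a,region_b The two (face-adjacent) region labels.
#' @param geometry Voxel geometry; defaults to `parc$geometry`.
#' @param bin_edges,weighting,fisher As in [pairwise_bin_correlations()].
#' @param corr Optional precomputed subject-averaged correlation matrix
#'   (from the full voxel set), e.g. to amortize over many boundaries.
#' @return Scalar local DCBC.
#' @export
local_dcbc <- function(series, parc, region_a, region_b, geometry = NULL,
                       bin_edges = seq(0, 30, by = 3),
                       weighting = c("harmonic", "uniform"),
                       fisher = FALSE, corr = NULL) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(parc, "parcellation"))
  if (is.null(geometry)) geometry <- parc$geometry
  bounds <- region_adjacency(parc, geometry)
  hit <- bounds$region_a == min(region_a, region_b) &
    bounds$region_b == max(region_a, region_b)
  if (!any(hit)) {
    stop(sprintf("regions %d and %d share no face-adjacent voxel pair",
                 region_a, region_b), call. = FALSE)
  }
  if (is.null(corr)) {
    if (inherits(series, "bold_series")) series <- list(series)
    corr <- .mean_corr(series, fisher = fisher)
  }
  keep <- parc$labels %in% c(region_a, region_b)
  res <- .dcbc_from_corr(corr[keep, keep, drop = FALSE], parc$labels[keep],
                         geometry$coords[keep, , drop = FALSE], bin_edges, weighting)
  res$global_dcbc
}

#' Local DCBC for every boundary of a parcellation
#'
#' @inheritParams local_dcbc
#' @return A `boundary_table` data frame: `region_a`, `region_b`,
#'   `n_adjacent_voxel_pairs`, `local_dcbc`.
#' @export
boundary_table <- function(series, parc, geometry = NULL,
                           bin_edges = seq(0, 30, by = 3),
                           weighting = c("harmonic", "uniform"),
                           fisher = FALSE) {
  weighting <- match.arg(weighting)
  if (is.null(geometry)) geometry <- parc$geometry
  bounds <- region_adjacency(parc, geometry)
  if (!nrow(bounds)) stop("parcellation has no boundary between nonzero regions", call. = FALSE)
  if (inherits(series, "bold_series")) series <- list(series)
  corr <- .mean_corr(series, fisher = fisher)
  bounds$local_dcbc <- mapply(function(a, b) {
    tryCatch(local_dcbc(NULL, parc, a, b, geometry, bin_edges, weighting,
                        fisher, corr = corr),
             error = function(e) NA_real_)
  }, bounds$region_a, bounds$region_b)
  class(bounds) <- c("boundary_table", "data.frame")
  bounds
}

#' Negative-boundary audit of a boundary table
#'
#' @param bt A `boundary_table` (any data frame with a `local_dcbc`
#'   column), one row per boundary.
#' @return List with `n_boundaries`, `n_negative`, and `proportion`
#'   (negatives / boundaries, reported to 4 decimals).
#' @export
negative_boundary_report <- function(bt) {
  v <- bt$local_dcbc
  if (is.null(v) || !length(v)) stop("boundary table has no local_dcbc values", call. = FALSE)
  v <- v[!is.na(v)]
  n <- length(v)
  neg <- sum(v < 0)
  list(n_boundaries = n, n_negative = neg, proportion = round(neg / n, 4))
}

#' Permutation null distribution of the global DCBC
#'
#' Recomputes the global DCBC under random permutations of the voxel
#' labels (data and distances fixed), giving the null distribution against
#' which an observed DCBC can be judged.
#'
#' @inheritParams pairwise_bin_correlations
#' @param n_perm Number of label permutations.
#' @param seed RNG seed.
#' @return Numeric vector of `n_perm` null DCBC values.
#' @export
dcbc_permutation_null <- function(series, parc, geometry = NULL,
                                  bin_edges = seq(0, 30, by = 3),
                                  weighting = c("harmonic", "uniform"),
                                  n_perm = 1000L, seed = 1, fisher = FALSE) {
  weighting <- match.arg(weighting)
  if (is.null(geometry)) geometry <- parc$geometry
  if (inherits(series, "bold_series")) series <- list(series)
  Rbar <- .mean_corr(series, fisher = fisher)
  set.seed(seed)
  V <- length(parc$labels)
  vapply(seq_len(n_perm), function(i) {
    lab <- parc$labels[sample.int(V)]
    .dcbc_from_corr(Rbar, lab, geometry$coords, bin_edges, weighting)$global_dcbc
  }, numeric(1))
}
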