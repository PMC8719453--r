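#' Construct a BOLD series object
#'
#' A `bold_series` binds one subject's time-by-voxel data matrix to a
#' voxel geometry and a condition tag.
#'
#' @param data T x V numeric matrix (rows = time points, columns = voxels).
#' @param geometry A `voxel_geometry` with V voxels.
#' @param subject_id Subject tag.
#' @param condition Condition tag (e.g. `"movie"`, `"rest"`, `"synthetic"`).
#' @param standardized Logical; whether columns are zero-mean unit-variance.
#' @return A `bold_series` object.
#' @export
bold_series <- function(data, geometry, subject_id = "s1",
                        condition = "synthetic", standardized = FALSE) {
  data <- as.matrix(data)
  if (!inherits(geometry, "voxel_geometry")) {
    stop("`geometry` must be a voxel_geometry", call. = FALSE)
  }
  if (ncol(data) != n_voxels(geometry)) {
    stop(sprintf("data has %d columns but geometry has %d voxels",
                 ncol(data), n_voxels(geometry)), call. = FALSE)
  }
  if (nrow(data) < 2) stop("a BOLD series needs T >= 2 time points", call. = FALSE)
  structure(
    list(subject_id = subject_id, condition = condition, data = data,
         geometry = geometry, standardized = standardized),
    class = "bold_series"
  )
}

#' @export
print.bold_series <- function(x, ...) {
  cat(sprintf("<bold_series> subject '%s' (%s): %d time points x %d voxels%s\n",
              x$subject_id, x$condition, nrow(x$data), ncol(x$data),
              if (isTRUE(x$standardized)) ", standardized" else ""))
  invisible(x)
}

# Smooth standardized temporal atoms: white Gaussian series passed through a
# moving-average window, then zero-mean unit-variance (population convention).
# Models BOLD-like temporal autocorrelation without committing to an HRF.
.smooth_atoms <- function(n_time, K, window = 5) {
  raw <- matrix(stats::rnorm((n_time + window - 1) * K), n_time + window - 1, K)
  sm <- apply(raw, 2, function(x) {
    y <- as.numeric(stats::filter(x, rep(1 / window, window), sides = 1))
    y[window:(n_time + window - 1)]
  })
  sm <- matrix(sm, n_time, K)
  .standardize_columns(sm)$data
}

# AR(1) noise matrix with unit marginal variance
.ar1_noise <- function(n_time, V, phi) {
  e <- matrix(stats::rnorm(n_time * V), n_time, V)
  if (phi == 0) return(e)
  x <- apply(e, 2, function(col) as.numeric(stats::filter(col, phi, method = "recursive")))
  x * sqrt(1 - phi^2)
}

# Seeded region growing on the lattice: K spatially compact regions produced
# by round-robin multi-source breadth-first search from random seeds.
.grow_regions <- function(geometry, K) {
  V <- n_voxels(geometry)
  if (K > V) stop("cannot partition ", V, " voxels into ", K, " regions", call. = FALSE)
  nb <- .neighbour_list(geometry)
  seeds <- sample.int(V, K)
  labels <- integer(V)
  labels[seeds] <- seq_len(K)
  frontier <- as.list(seeds)
  remaining <- V - K
  while (remaining > 0) {
    progressed <- FALSE
    for (k in seq_len(K)) {
      f <- frontier[[k]]
      if (!length(f)) next
      cand <- unique(unlist(nb[f], use.names = FALSE))
      cand <- cand[labels[cand] == 0L]
      if (length(cand)) {
        labels[cand] <- k
        frontier[[k]] <- cand
        remaining <- remaining - length(cand)
        progressed <- TRUE
      } else {
        frontier[[k]] <- integer(0)
      }
    }
    if (!progressed) break
  }
  labels
}

#' Generate a multi-subject synthetic BOLD dataset with planted structure
#'
#' Each subject's data matrix is `D_s %*% A_s + E_s`: per-subject smooth
#' temporal atoms (`D_s`, independent draws across subjects), shared sparse
#' spatial loadings `A_true` (optionally jittered per subject), and Gaussian
#' noise scaled per voxel to the requested signal-to-noise ratio. Spatial
#' supports are K spatially compact lattice regions from seeded region
#' growing, so boundary metrics downstream are meaningful.
#'
#' @param geometry A `voxel_geometry`.
#' @param K_true Number of planted components (>= 2).
#' @param n_subjects Number of subjects (>= 2).
#' @param n_time Time points per subject (> `K_true`).
#' @param snr Signal-to-noise ratio: per-voxel signal sd / noise sd
#'   (averaged over voxels); `Inf` disables noise.
#' @param overlap_fraction Fraction of voxels whose loading support includes
#'   a second component (in `[0, 0.5)`).
#' @param unassigned_fraction Fraction of voxels carrying no component
#'   (label 0, pure noise; in `[0, 0.5)`).
#' @param jitter Per-subject multiplicative loading jitter sd (default 10%).
#' @param smooth_window Moving-average window (samples) for temporal atoms.
#' @param ar_phi AR(1) coefficient for temporally correlated noise
#'   (0 = white).
#' @param seed Integer RNG seed; identical seeds give identical datasets.
#' @return List with `subjects` (list of `bold_series`) and `truth`
#'   (a `synthetic_truth`: `true_labels`, `true_maps` (K x V), `true_atoms`
#'   (per-subject T x K list), `snr`, `seed`, and the generator parameters).
#' @export
generate_group_dataset <- function(geometry, K_true, n_subjects, n_time, snr,
                                   overlap_fraction = 0, unassigned_fraction = 0,
                                   jitter = 0.1, smooth_window = 5, ar_phi = 0,
                                   seed = 1) {
  stopifnot(inherits(geometry, "voxel_geometry"))
  V <- n_voxels(geometry)
  if (K_true < 2) stop("`K_true` must be >= 2", call. = FALSE)
  if (K_true > V) stop("infeasible partition: K_true > number of voxels", call. = FALSE)
  if (n_subjects < 2) stop("`n_subjects` must be >= 2", call. = FALSE)
  if (n_time <= K_true) stop("`n_time` must exceed `K_true`", call. = FALSE)
  if (!(is.infinite(snr) || snr > 0)) stop("`snr` must be positive", call. = FALSE)
  if (overlap_fraction < 0 || overlap_fraction >= 0.5 ||
      unassigned_fraction < 0 || unassigned_fraction >= 0.5) {
    stop("overlap/unassigned fractions must lie in [0, 0.5)", call. = FALSE)
  }
  set.seed(seed)

  labels <- .grow_regions(geometry, K_true)
  if (unassigned_fraction > 0) {
    drop <- sample.int(V, round(unassigned_fraction * V))
    labels[drop] <- 0L
  }

  A_true <- matrix(0, K_true, V)
  assigned <- which(labels > 0)
  A_true[cbind(labels[assigned], assigned)] <- stats::runif(length(assigned), 0.8, 1.2)
  if (overlap_fraction > 0 && length(assigned)) {
    ov <- sample(assigned, round(overlap_fraction * V))
    second <- vapply(labels[ov], function(k) {
      sample(setdiff(seq_len(K_true), k), 1)
    }, integer(1))
    A_true[cbind(second, ov)] <- stats::runif(length(ov), 0.3, 0.6)
  }

  subjects <- vector("list", n_subjects)
  atoms <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    D_s <- .smooth_atoms(n_time, K_true, smooth_window)
    A_s <- if (jitter > 0) {
      A_true * (1 + jitter * matrix(stats::rnorm(K_true * V), K_true, V))
    } else A_true
    signal <- D_s %*% A_s
    if (is.infinite(snr)) {
      X <- signal
    } else {
      sig_sd <- apply(signal, 2, stats::sd)
      # noise-only voxels get the average signal amplitude as reference
      ref <- if (any(sig_sd > 0)) mean(sig_sd[sig_sd > 0]) else 1
      sig_sd[sig_sd == 0] <- ref
      E <- .ar1_noise(n_time, V, ar_phi)
      X <- signal + sweep(E, 2, sig_sd / snr, `*`)
    }
    atoms[[s]] <- D_s
    subjects[[s]] <- bold_series(X, geometry, subject_id = sprintf("sub%02d", s),
                                 condition = "synthetic")
  }

  truth <- structure(
    list(true_labels = labels, true_atoms = atoms, true_maps = A_true,
         snr = snr, seed = seed, connectivity_plan = NULL,
         params = list(K_true = K_true, n_subjects = n_subjects, n_time = n_time,
                       overlap_fraction = overlap_fraction,
                       unassigned_fraction = unassigned_fraction, jitter = jitter,
                       smooth_window = smooth_window, ar_phi = ar_phi)),
    class = "synthetic_truth"
  )
  list(subjects = subjects, truth = truth)
}
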