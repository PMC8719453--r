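#' Generate a two-condition dataset with planted seed-target connectivity
#'
#' Emulates a seed-based connectivity contrast between two acquisition
#' conditions (movie-like vs rest-like). All voxels of `geometry` form one
#' seed region whose mean time course carries a smooth latent signal; a
#' designated subset of "cortical" target columns correlates with that
#' signal at population value `r_A` in condition A and `r_B` in condition
#' B (targets built as `r*s + sqrt(1-r^2)*e` with independent unit-variance
#' noise), while the remaining targets are independent noise.
#'
#' @param geometry A `voxel_geometry`; its voxels are the seed region.
#' @param n_cortex_targets Number of target time courses (>= 1).
#' @param n_subjects Subjects per condition (same subjects, two sessions).
#' @param n_time Time points per session.
#' @param r_A,r_B Planted population correlations, each in (-1, 1).
#' @param n_planted Number of target columns carrying the planted
#'   correlation (default ~1/5 of targets).
#' @param seed_snr SNR of the latent signal within the seed region voxels.
#' @param smooth_window Moving-average window for the latent signal.
#' @param seed Integer RNG seed.
#' @return List with `condition_A`, `condition_B` (lists of `bold_series`),
#'   `targets_A`, `targets_B` (per-subject lists of T x M target matrices),
#'   and `truth` (planted target set and the connectivity plan).
#' @export
generate_two_condition_dataset <- function(geometry, n_cortex_targets,
                                           n_subjects, n_time, r_A, r_B,
                                           n_planted = max(1L, round(n_cortex_targets / 5)),
                                           seed_snr = 10, smooth_window = 5,
                                           seed = 1) {
  stopifnot(inherits(geometry, "voxel_geometry"))
  if (abs(r_A) >= 1 || abs(r_B) >= 1) {
    stop("planted correlations must satisfy |r| < 1", call. = FALSE)
  }
  if (n_cortex_targets < 1) stop("`n_cortex_targets` must be >= 1", call. = FALSE)
  if (n_planted > n_cortex_targets) {
    stop("`n_planted` cannot exceed `n_cortex_targets`", call. = FALSE)
  }
  set.seed(seed)
  V <- n_voxels(geometry)
  target_set <- seq_len(n_planted)
  loading <- stats::runif(V, 0.8, 1.2)

  make_condition <- function(r, condition) {
    subjects <- vector("list", n_subjects)
    targets <- vector("list", n_subjects)
    for (s in seq_len(n_subjects)) {
      sig <- .smooth_atoms(n_time, 1, smooth_window)[, 1]
      E <- matrix(stats::rnorm(n_time * V), n_time, V)
      X <- outer(sig, loading) + sweep(E, 2, loading / seed_snr, `*`)
      M <- matrix(stats::rnorm(n_time * n_cortex_targets), n_time, n_cortex_targets)
      M[, target_set] <- r * sig + sqrt(1 - r^2) * M[, target_set, drop = FALSE]
      subjects[[s]] <- bold_series(X, geometry, subject_id = sprintf("sub%02d", s),
                                   condition = condition)
      targets[[s]] <- M
    }
    list(subjects = subjects, targets = targets)
  }

  A <- make_condition(r_A, "movie")
  B <- make_condition(r_B, "rest")

  truth <- structure(
    list(true_labels = rep(1L, V), true_atoms = NULL, true_maps = matrix(loading, 1, V),
         snr = seed_snr, seed = seed,
         connectivity_plan = list(list(seed_component = 1L, target_set = target_set,
                                       r_condition_A = r_A, r_condition_B = r_B)),
         params = list(n_cortex_targets = n_cortex_targets, n_planted = n_planted,
                       n_subjects = n_subjects, n_time = n_time,
                       smooth_window = smooth_window)),
    class = "synthetic_truth"
  )
  list(condition_A = A$subjects, condition_B = B$subjects,
       targets_A = A$targets, targets_B = B$targets, truth = truth)
}
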