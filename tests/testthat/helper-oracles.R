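# Independent brute-force oracles used across test files. These stay
# deliberately naive (explicit loops, no shared code with the package
# internals they check).

sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

# exhaustive per-bin within/between pair statistics from raw data
oracle_bin_stats <- function(data_list, labels, coords, bin_edges) {
  V <- length(labels)
  nb <- length(bin_edges) - 1
  Rs <- lapply(data_list, function(X) suppressWarnings(stats::cor(X)))
  Rbar <- Reduce(`+`, Rs) / length(Rs)
  wsum <- wcnt <- bsum <- bcnt <- rep(0, nb)
  for (i in seq_len(V - 1)) {
    for (j in seq(i + 1, V)) {
      if (labels[i] == 0 || labels[j] == 0) next
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      b <- NA
      for (k in seq_len(nb)) if (d > bin_edges[k] && d <= bin_edges[k + 1]) b <- k
      if (is.na(b)) next
      r <- Rbar[i, j]
      if (is.na(r)) next
      if (labels[i] == labels[j]) {
        wsum[b] <- wsum[b] + r; wcnt[b] <- wcnt[b] + 1
      } else {
        bsum[b] <- bsum[b] + r; bcnt[b] <- bcnt[b] + 1
      }
    }
  }
  list(within = ifelse(wcnt > 0, wsum / wcnt, NA_real_),
       between = ifelse(bcnt > 0, bsum / bcnt, NA_real_),
       n_within = wcnt, n_between = bcnt)
}

oracle_global_dcbc <- function(st) {
  both <- st$n_within > 0 & st$n_between > 0
  w <- st$n_within[both] * st$n_between[both] / (st$n_within[both] + st$n_between[both])
  w <- w / sum(w)
  sum(w * (st$within[both] - st$between[both]))
}

# per-threshold recount of overlaps and unassigned voxels by explicit loops
oracle_sweep <- function(Zv, surviving, thresholds) {
  V <- ncol(Zv)
  nz <- nov <- integer(length(thresholds))
  for (t in seq_along(thresholds)) {
    for (v in seq_len(V)) {
      m <- 0
      for (k in seq_len(nrow(Zv))) {
        if (surviving[k, v] && Zv[k, v] >= thresholds[t]) m <- m + 1
      }
      if (m == 0) nz[t] <- nz[t] + 1L
      if (m > 1) nov[t] <- nov[t] + (m - 1L)
    }
  }
  list(n_zeros = nz, n_overlap = nov)
}

# greedy best matching of estimated to true component maps by |correlation|
match_components <- function(est, truth) {
  K <- nrow(truth)
  C <- abs(stats::cor(t(est), t(truth)))
  matched <- numeric(K)
  for (i in seq_len(K)) {
    idx <- which(C == max(C, na.rm = TRUE), arr.ind = TRUE)[1, ]
    matched[idx[2]] <- C[idx[1], idx[2]]
    C[idx[1], ] <- -Inf
    C[, idx[2]] <- -Inf
  }
  matched
}

# small standardized smooth dataset with planted compact regions
make_planted <- function(grid = c(4, 4, 4), K_true = 4, n_subjects = 3,
                         n_time = 80, snr = 5, seed = 1, spacing = 2, ...) {
  geom <- generate_geometry(grid, spacing)
  sim <- generate_group_dataset(geom, K_true = K_true, n_subjects = n_subjects,
                                n_time = n_time, snr = snr, seed = seed, ...)
  list(geom = geom, sim = sim,
       parc = as_parcellation(sim$truth$true_labels, geom, K = K_true))
}
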