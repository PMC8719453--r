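test_that("homogeneity eigen ratio hits its closed forms and bounds", {
  g <- generate_geometry(c(2, 2, 1), 2)
  tcourse <- rnorm(30)
  # all four voxels share one time course: rank-1, ratio 1
  b <- bold_series(matrix(tcourse, 30, 4), g)
  parc <- as_parcellation(rep(1L, 4), g)
  h <- homogeneity(b, parc)
  expect_equal(h$table$eigen_ratio, 1, tolerance = 1e-12)

  # two voxels with orthogonal equal-variance courses: ratio 1/2
  g2 <- generate_geometry(c(2, 1, 1), 2)
  x <- rep(c(1, -1), 15); y <- rep(c(1, 1, -1, -1), length.out = 30)
  b2 <- bold_series(cbind(x, y), g2)
  h2 <- homogeneity(b2, as_parcellation(c(1L, 1L), g2))
  expect_equal(h2$table$eigen_ratio, 0.5, tolerance = 1e-12)

  # dense eigensolver oracle on a random parcel
  set.seed(14)
  g10 <- generate_geometry(c(10, 1, 1), 2)
  X <- matrix(rnorm(40 * 10), 40, 10)
  b10 <- bold_series(X, g10)
  h10 <- homogeneity(b10, as_parcellation(rep(1L, 10), g10))
  Xs <- standardize_series(X)
  ev <- eigen(crossprod(Xs) / 40, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(h10$table$eigen_ratio, ev[1] / sum(ev), tolerance = 1e-10)
  # bound: 1/min(T, n_vox) <= ratio <= 1
  expect_gte(h10$table$eigen_ratio, 1 / 10)
  expect_lte(h10$table$eigen_ratio, 1)

  expect_error(homogeneity(b10, as_parcellation(rep(0L, 10), g10)), "empty")
  expect_warning(homogeneity(b10, as_parcellation(c(2L, rep(1L, 9)), g10)),
                 "fewer than")
})

test_that("identical time courses give zero DCBC with unit correlations", {
  g <- generate_geometry(c(3, 3, 1), 2)
  tc <- rnorm(25)
  b <- bold_series(matrix(tc, 25, 9) + outer(rep(0, 25), 1:9), g)
  parc <- as_parcellation(rep(1:3, each = 3), g)
  d <- pairwise_bin_correlations(b, parc, bin_edges = c(0, 3, 6, 9))
  pop <- d$n_within_pairs > 0 & d$n_between_pairs > 0
  expect_equal(d$within_corr[pop], rep(1, sum(pop)), tolerance = 1e-12)
  expect_equal(d$between_corr[pop], rep(1, sum(pop)), tolerance = 1e-12)
  expect_equal(d$global_dcbc, 0, tolerance = 1e-12)
  expect_equal(global_dcbc(d), d$global_dcbc)
  expect_equal(sum(d$weight), 1, tolerance = 1e-12)
})

test_that("a hand-built 3-voxel line matches exhaustive pair enumeration", {
  g <- generate_geometry(c(3, 1, 1), 3)
  X <- cbind(c(1, 2, 3, 4, 2), c(2, 1, 4, 3, 5), c(5, 3, 1, 2, 4))
  b <- bold_series(X, g)
  labels <- c(1L, 1L, 2L)
  parc <- as_parcellation(labels, g)
  d <- pairwise_bin_correlations(b, parc, bin_edges = c(0, 3, 6))
  # pairs: (1,2) within at 3mm; (2,3) between at 3mm; (1,3) between at 6mm
  expect_equal(d$within_corr[1], cor(X[, 1], X[, 2]), tolerance = 1e-12)
  expect_equal(d$between_corr[1], cor(X[, 2], X[, 3]), tolerance = 1e-12)
  expect_equal(d$between_corr[2], cor(X[, 1], X[, 3]), tolerance = 1e-12)
  expect_equal(d$n_within_pairs, c(1L, 0L))
  expect_equal(d$n_between_pairs, c(1L, 1L))
  # only bin 1 has both pair types -> it takes all the weight
  expect_equal(d$weight, c(1, 0))
  expect_equal(d$global_dcbc, cor(X[, 1], X[, 2]) - cor(X[, 2], X[, 3]),
               tolerance = 1e-12)
})

test_that("bin statistics equal the brute-force oracle on random grids", {
  set.seed(15)
  pl <- make_planted(grid = c(5, 5, 5), K_true = 4, n_subjects = 3,
                     n_time = 50, snr = 2, seed = 15)
  # include unassigned voxels to exercise the label-0 exclusion
  lab <- pl$parc$labels
  lab[sample(125, 10)] <- 0L
  parc <- as_parcellation(lab, pl$geom, K = 4)
  edges <- seq(0, 18, by = 3)
  d <- pairwise_bin_correlations(pl$sim$subjects, parc, bin_edges = edges)
  orc <- oracle_bin_stats(lapply(pl$sim$subjects, function(b) b$data),
                          lab, pl$geom$coords, edges)
  expect_equal(d$within_corr, orc$within, tolerance = 1e-12)
  expect_equal(d$between_corr, orc$between, tolerance = 1e-12)
  expect_equal(d$n_within_pairs, orc$n_within)
  expect_equal(d$n_between_pairs, orc$n_between)
  expect_equal(d$global_dcbc, oracle_global_dcbc(orc), tolerance = 1e-12)
})

test_that("bin statistics are invariant to voxel permutation", {
  set.seed(16)
  pl <- make_planted(grid = c(4, 4, 2), K_true = 3, n_subjects = 2,
                     n_time = 40, snr = 3, seed = 16)
  edges <- seq(0, 12, by = 3)
  d1 <- pairwise_bin_correlations(pl$sim$subjects, pl$parc, bin_edges = edges)
  perm <- sample(32)
  g2 <- pl$geom; g2$coords <- g2$coords[perm, , drop = FALSE]
  series2 <- lapply(pl$sim$subjects, function(b) {
    bold_series(b$data[, perm], g2, b$subject_id)
  })
  parc2 <- as_parcellation(pl$parc$labels[perm], NULL, K = 3)
  d2 <- pairwise_bin_correlations(series2, parc2, geometry = g2, bin_edges = edges)
  expect_equal(d2$within_corr, d1$within_corr, tolerance = 1e-12)
  expect_equal(d2$between_corr, d1$between_corr, tolerance = 1e-12)
  expect_equal(d2$global_dcbc, d1$global_dcbc, tolerance = 1e-12)
})

test_that("region adjacency respects 6-connectivity and label-0 gaps", {
  g <- generate_geometry(c(4, 1, 1), 2)
  adj <- region_adjacency(as_parcellation(c(1L, 1L, 2L, 2L), g))
  expect_equal(nrow(adj), 1)
  expect_equal(adj$region_a, 1L); expect_equal(adj$region_b, 2L)
  expect_equal(adj$n_adjacent_voxel_pairs, 1L)

  # checkerboard of 2 labels: one boundary, many adjacent pairs
  g2 <- generate_geometry(c(4, 4, 1), 2)
  board <- as.integer((arrayInd(1:16, c(4, 4, 1))[, 1] +
                         arrayInd(1:16, c(4, 4, 1))[, 2]) %% 2 + 1)
  adj2 <- region_adjacency(as_parcellation(board, g2))
  expect_equal(nrow(adj2), 1)
  expect_equal(adj2$n_adjacent_voxel_pairs, 24L)

  # an unassigned slab separates the labels: no boundary
  adj3 <- region_adjacency(as_parcellation(c(1L, 0L, 0L, 2L), g))
  expect_equal(nrow(adj3), 0)
})

test_that("local DCBC reduces to global for two regions and rejects non-adjacent pairs", {
  set.seed(17)
  pl <- make_planted(grid = c(4, 4, 2), K_true = 2, n_subjects = 3,
                     n_time = 60, snr = 5, seed = 17)
  edges <- seq(0, 12, by = 3)
  d <- pairwise_bin_correlations(pl$sim$subjects, pl$parc, bin_edges = edges)
  l <- local_dcbc(pl$sim$subjects, pl$parc, 1, 2, bin_edges = edges)
  expect_equal(l, d$global_dcbc, tolerance = 1e-12)
  expect_gt(l, 0)   # planted boundary separates distinct signals
  expect_error(local_dcbc(pl$sim$subjects, pl$parc, 1, 5, bin_edges = edges),
               "no face-adjacent")
})

test_that("boundary table covers adjacency and the negative audit matches arithmetic", {
  set.seed(18)
  pl <- make_planted(grid = c(5, 5, 2), K_true = 4, n_subjects = 3,
                     n_time = 60, snr = 5, seed = 18)
  bt <- boundary_table(pl$sim$subjects, pl$parc, bin_edges = seq(0, 15, 3))
  adj <- region_adjacency(pl$parc)
  expect_equal(nrow(bt), nrow(adj))
  expect_true(all(bt$region_a < bt$region_b))
  rep_ <- negative_boundary_report(bt)
  expect_equal(rep_$n_boundaries, nrow(bt))
  expect_equal(rep_$proportion, round(rep_$n_negative / rep_$n_boundaries, 4))

  fake <- data.frame(local_dcbc = c(rep(-0.01, 14), rep(0.1, 243 - 14)))
  expect_equal(negative_boundary_report(fake)$proportion, 0.0576)
  expect_equal(negative_boundary_report(data.frame(local_dcbc = rep(0.2, 10)))$proportion, 0)
})
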