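make_subject_maps <- function(values) {
  # values: list of K x V matrices
  lapply(seq_along(values), function(i) {
    structure(list(subject_id = paste0("s", i), B = values[[i]]), class = "subject_maps")
  })
}

test_that("group t-maps match hand-computed statistics and guard degeneracy", {
  maps <- make_subject_maps(list(matrix(2, 1, 2), matrix(4, 1, 2), matrix(6, 1, 2)))
  maps[[1]]$B[1, 2] <- 1; maps[[2]]$B[1, 2] <- 1; maps[[3]]$B[1, 2] <- 1
  expect_warning(tm <- group_t_maps(maps), "zero across-subject variance")
  expect_equal(tm$df, 2L)
  expect_equal(tm$T_stat[1, 1], 4 / (2 / sqrt(3)), tolerance = 1e-10)
  expect_equal(tm$T_stat[1, 1], 3.4641, tolerance = 1e-4)
  expect_equal(tm$T_stat[1, 2], 0)   # sd = 0 -> t = 0, counted
  expect_equal(tm$n_degenerate, 1)

  sym <- make_subject_maps(list(matrix(-1, 1, 1), matrix(0, 1, 1), matrix(1, 1, 1)))
  expect_equal(group_t_maps(sym)$T_stat[1, 1], 0)
  expect_error(group_t_maps(sym[1:2]), "at least 3")
})

test_that("t-to-z preserves sign, fixed points, and monotonicity", {
  expect_equal(t_to_z(0, 5), 0)
  expect_equal(t_to_z(1.96, 1000), 1.96, tolerance = 0.02)
  expect_equal(t_to_z(c(-2, 2), 7), c(-1, 1) * t_to_z(2, 7))
  # strictly monotone on random grids, finite at extreme t
  set.seed(3)
  for (df in c(2, 10, 50)) {
    t_sorted <- sort(rnorm(50, sd = 5))
    z <- t_to_z(t_sorted, df)
    expect_true(all(diff(z) > 0))
  }
  expect_true(is.finite(t_to_z(200, 19)))
})

test_that("multiplicity correction reproduces hand BH and Bonferroni decisions", {
  p_target <- c(0.001, 0.02, 0.03, 0.9)
  z <- qnorm(1 - p_target / 2)
  sig <- multiplicity_correct(matrix(z, 1), df = 10, q = 0.05, method = "bh-fdr")
  expect_identical(as.logical(sig$surviving_mask), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(sig$Z_thresh[1, 4], 0)

  bon <- multiplicity_correct(matrix(z, 1), df = 10, q = 0.05, method = "bonferroni")
  expect_identical(as.logical(bon$surviving_mask), p_target <= 0.05 / 4)

  null_z <- matrix(qnorm(1 - 0.5 / 2), 3, 5)
  expect_false(any(multiplicity_correct(null_z, 4, 0.05)$surviving_mask))
  expect_error(multiplicity_correct(matrix(z, 1), 10, q = 1.5), "\\(0, 1\\)")
})

test_that("threshold sweep counts overlaps and unassigned voxels correctly", {
  # one component above threshold everywhere: nothing unassigned, no overlap
  Z <- rbind(rep(5, 6), rep(0, 6))
  sig <- multiplicity_correct(Z, 9, q = 0.5)
  sw <- sweep_threshold(sig, 1.6, 3.0, 0.1)
  expect_true(all(sw$n_zeros == 0))
  expect_true(all(sw$n_overlap == 0))

  # two components at z = 3 at every voxel: full double cover below 3
  Z2 <- matrix(3, 2, 7)
  sig2 <- multiplicity_correct(Z2, 9, q = 0.5)
  sw2 <- sweep_threshold(sig2, 1.6, 3.0, 0.1)
  at2 <- which.min(abs(sw2$thresholds - 2.0))
  expect_equal(sw2$n_overlap[at2], 7)
  expect_equal(sw2$n_zeros[at2], 0)
  sw2v <- sweep_threshold(sig2, 1.6, 3.0, 0.1, overlap_count = "voxels")
  expect_equal(sw2v$n_overlap[at2], 7)   # here surplus == covered voxels
})

test_that("sweep counts equal a brute-force recount and are monotone", {
  set.seed(12)
  for (i in 1:5) {
    Z <- matrix(rnorm(6 * 40, sd = 2), 6, 40)
    sig <- multiplicity_correct(Z, 9, q = 0.4)
    sw <- sweep_threshold(sig, 1.6, 3.0, 0.1)
    oracle <- oracle_sweep(sig$Z_thresh, sig$surviving_mask, sw$thresholds)
    expect_equal(sw$n_zeros, oracle$n_zeros)
    expect_equal(sw$n_overlap, oracle$n_overlap)
    expect_true(all(diff(sw$n_zeros) >= 0))
    expect_true(all(diff(sw$n_overlap) <= 0))
  }
})

test_that("threshold choice minimizes the stated objective", {
  sw <- structure(list(thresholds = seq(1.6, 3.0, 0.1),
                       n_zeros = rep(0L, 15),
                       n_overlap = as.integer(seq(140, 0, by = -10)),
                       V = 100, overlap_count = "surplus"),
                  class = "threshold_sweep")
  # nothing unassigned anywhere: pick the threshold with least overlap
  expect_equal(choose_threshold(sw), 3.0)

  set.seed(13)
  for (i in 1:10) {
    swr <- structure(list(thresholds = seq(1.6, 3.0, 0.1),
                          n_zeros = sort(sample(0:50, 15, TRUE)),
                          n_overlap = sort(sample(0:200, 15, TRUE), decreasing = TRUE),
                          V = 100, overlap_count = "surplus"),
                     class = "threshold_sweep")
    g <- runif(1, 0, 0.5)
    J <- swr$n_zeros / 100 + g * swr$n_overlap / 100
    expect_equal(choose_threshold(swr, gamma = g),
                 swr$thresholds[which.min(J)])
    # gamma = 0 ignores overlaps entirely
    expect_equal(choose_threshold(swr, gamma = 0),
                 swr$thresholds[which.min(swr$n_zeros)])
  }
  expect_equal(choose_threshold(sw, manual = 2.2), 2.2)
})

test_that("hard labeling follows argmax with documented tie-breaking", {
  Z <- cbind(c(1.0, 2.5, 2.4), c(0.5, 1.0, 1.2), c(2.5, 2.5, 0.1))
  sig <- multiplicity_correct(Z, 9, q = 0.99)
  parc <- assign_labels(sig, 2.0)
  expect_equal(parc$labels, c(2L, 0L, 1L))  # argmax; all-below -> 0; tie -> lowest k
  expect_equal(parc$threshold, 2.0)
  expect_equal(parc$K, 3)

  # labels are a pure function of (Z, mask, theta)
  expect_identical(assign_labels(sig, 2.0)$labels, parc$labels)
})
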