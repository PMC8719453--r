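test_that("lattice geometry places voxels at the documented mm positions", {
  g <- generate_geometry(c(1, 1, 2), spacing_mm = 2)
  expect_equal(n_voxels(g), 2)
  expect_equal(as.numeric(dist(g$coords)), 2)

  g3 <- generate_geometry(c(3, 3, 3), spacing_mm = 3)
  expect_equal(n_voxels(g3), 27)
  d <- dist(g3$coords)
  expect_length(d, 351)
  # brute-force max over all pairs
  dm <- as.matrix(d)
  mx <- 0
  for (i in 1:26) for (j in (i + 1):27) mx <- max(mx, dm[i, j])
  expect_equal(max(d), mx)
  expect_equal(mx, 3 * sqrt(12), tolerance = 1e-12)

  gu <- generate_geometry(c(2, 2, 2), spacing_mm = 1)
  du <- sort(unique(round(as.numeric(dist(gu$coords)), 10)))
  expect_equal(du, round(c(1, sqrt(2), sqrt(3)), 10))
  expect_length(as.numeric(dist(gu$coords)), 28)
})

test_that("invalid geometry arguments are rejected", {
  expect_error(generate_geometry(c(0, 1, 1)), "positive")
  expect_error(generate_geometry(c(2, 2)), "three")
  expect_error(generate_geometry(c(2, 2, 2), spacing_mm = -1), "positive")
})

test_that("group generator is deterministic and honors its contracts", {
  geom <- generate_geometry(c(4, 4, 4), 2)
  a <- generate_group_dataset(geom, K_true = 4, n_subjects = 3, n_time = 50,
                              snr = 5, seed = 7)
  b <- generate_group_dataset(geom, K_true = 4, n_subjects = 3, n_time = 50,
                              snr = 5, seed = 7)
  expect_identical(a$subjects[[2]]$data, b$subjects[[2]]$data)
  expect_identical(a$truth$true_labels, b$truth$true_labels)

  # all K labels used, no unassigned voxels when fraction is 0
  expect_setequal(unique(a$truth$true_labels), 1:4)
  expect_true(all(a$truth$true_labels > 0))

  # noiseless data factorizes exactly: rank <= K_true
  nf <- generate_group_dataset(geom, K_true = 4, n_subjects = 2, n_time = 50,
                               snr = Inf, seed = 1)
  expect_lte(qr(nf$subjects[[1]]$data)$rank, 4)

  expect_error(generate_group_dataset(geom, K_true = 100, n_subjects = 2,
                                      n_time = 200, snr = 5), "infeasible")
  expect_error(generate_group_dataset(geom, K_true = 4, n_subjects = 3,
                                      n_time = 50, snr = 5,
                                      unassigned_fraction = 0.6), "0.5")
})

test_that("realized SNR tracks the requested value within 5% for V >= 100", {
  geom <- generate_geometry(c(5, 5, 5), 2)
  out <- generate_group_dataset(geom, K_true = 5, n_subjects = 2, n_time = 200,
                                snr = 5, jitter = 0, seed = 11)
  for (s in 1:2) {
    signal <- out$truth$true_atoms[[s]] %*% out$truth$true_maps
    noise <- out$subjects[[s]]$data - signal
    ratio <- apply(signal, 2, sd) / apply(noise, 2, sd)
    expect_equal(mean(ratio), 5, tolerance = 0.05)
  }
})

test_that("planted labels are spatially compact regions", {
  geom <- generate_geometry(c(6, 6, 6), 2)
  sim <- generate_group_dataset(geom, K_true = 6, n_subjects = 2, n_time = 30,
                                snr = Inf, seed = 5)
  lab <- sim$truth$true_labels
  nb <- cbparcel:::.neighbour_list(geom)
  # every region is connected: BFS from one member reaches all members
  for (k in 1:6) {
    members <- which(lab == k)
    seen <- members[1]; frontier <- members[1]
    while (length(frontier)) {
      nxt <- setdiff(intersect(unlist(nb[frontier]), members), seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    expect_setequal(seen, members)
  }
})

test_that("two-condition generator plants the requested seed-target correlation", {
  geom <- generate_geometry(c(3, 3, 3), 2)
  ds <- generate_two_condition_dataset(geom, n_cortex_targets = 30,
                                       n_subjects = 30, n_time = 500,
                                       r_A = 0.8, r_B = 0, n_planted = 6, seed = 9)
  planted <- ds$truth$connectivity_plan[[1]]$target_set
  r_obs <- sapply(seq_len(30), function(s) {
    seed_tc <- rowMeans(ds$condition_A[[s]]$data)
    mean(cor(seed_tc, ds$targets_A[[s]][, planted]))
  })
  # Fisher-z sampling at T=500 keeps 95% of subjects within 0.8 +/- 0.1
  expect_gte(mean(abs(r_obs - 0.8) <= 0.1), 0.95)

  # non-targets are independent noise: mean |r| below the null bound 2/sqrt(T)
  r_null <- sapply(seq_len(30), function(s) {
    seed_tc <- rowMeans(ds$condition_B[[s]]$data)
    mean(abs(cor(seed_tc, ds$targets_B[[s]][, -planted])))
  })
  expect_lt(mean(r_null), 2 / sqrt(500))

  expect_error(generate_two_condition_dataset(geom, 10, 5, 100, r_A = 1, r_B = 0),
               "\\|r\\| < 1")
})
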