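# Generator contracts: determinism, ground-truth conservation, and agreement
# with closed-form distributional oracles.

test_that("generators are deterministic under a fixed seed", {
  a <- simulate_smlm_field(3, 50, 30, 1, 10, 1000, 2, seed = 42)
  b <- simulate_smlm_field(3, 50, 30, 1, 10, 1000, 2, seed = 42)
  expect_identical(a, b)

  A <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, byrow = TRUE)
  a <- simulate_trajectories(20, 15, c(0.05, 0.5), A, seed = 42)
  b <- simulate_trajectories(20, 15, c(0.05, 0.5), A, seed = 42)
  expect_identical(a, b)

  a <- simulate_two_channel_image(c(64, 64), 100, 5, 5, 0.4, seed = 42)
  b <- simulate_two_channel_image(c(64, 64), 100, 5, 5, 0.4, seed = 42)
  expect_identical(a, b)

  a <- simulate_mea_recording(2, c(1, 2), 5, seed = 42)
  b <- simulate_mea_recording(2, c(1, 2), 5, seed = 42)
  expect_identical(a, b)
})

test_that("smlm field: labels cover all detections and trivial regimes hold", {
  # no background: every detection carries the (single) cluster label
  sim <- simulate_smlm_field(1, 100, 50, 0, 10, 1000, 2, seed = 1)
  expect_equal(length(sim$truth$detection_cluster), nrow(sim$localizations))
  expect_true(all(sim$truth$detection_cluster == 1L))

  # zero localization error, no blinking: detections coincide with emitters
  sim <- simulate_smlm_field(2, 50, 30, 0, 0, 1000, 1, seed = 2)
  em <- sim$truth$emitters
  pos_e <- paste(round(em$x, 9), round(em$y, 9))
  pos_d <- paste(round(sim$localizations$x, 9), round(sim$localizations$y, 9))
  expect_true(all(pos_d %in% pos_e))
  expect_equal(nrow(sim$localizations), nrow(em))  # one detection per emitter

  # coordinates stay inside the field
  sim <- simulate_smlm_field(5, 100, 50, 2, 25, 1000, 3, seed = 3)
  expect_true(all(sim$localizations$x >= 0 & sim$localizations$x <= 10000))
  expect_true(all(sim$localizations$y >= 0 & sim$localizations$y <= 10000))
  expect_true(all(diff(order(sim$localizations$frame)) > 0) ||
                !is.unsorted(sim$localizations$frame))
})

test_that("background-only detection counts follow the Poisson thinning oracle", {
  # field 10x10 um, density d: detections ~ Poisson(100 d) thinned through
  # geometric blinking with mean m => E[count] = 100 * d * m
  d <- 2; m <- 2
  counts <- vapply(1:200, function(s) {
    nrow(simulate_smlm_field(0, 0, 20, d, 10, 1000, m, seed = s)$localizations)
  }, numeric(1))
  expected <- 100 * d * m
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("trajectories: frozen particle, Brownian variance, geometric dwell", {
  # D = 0, no noise: all positions identical within a trajectory
  sim <- simulate_trajectories(5, 10, 0, dt_s = 0.02, seed = 1)
  spread <- dplyr::summarise(dplyr::group_by(sim$trajectories, traj_id),
                             s = max(x_um) - min(x_um) + max(y_um) - min(y_um))
  expect_true(all(spread$s == 0))

  # closed-form per-axis displacement variance 2 D dt
  sim <- simulate_trajectories(100, 1000, 0.1, dt_s = 0.02, seed = 2)
  ds <- displacements(sim$trajectories, 0.02)
  v <- c(ds$steps$dx, ds$steps$dy)
  expected <- 2 * 0.1 * 0.02
  se <- sd(v^2) / sqrt(length(v))
  expect_lt(abs(mean(v^2) - expected), 3 * se)

  # geometric dwell: interior (uncensored) run lengths have mean
  # 1/(1 - A_kk) = 50 frames; long chains keep the censored boundary runs
  # negligible and give >= 1e4 interior runs
  A <- matrix(c(0.98, 0.02, 0.02, 0.98), 2, byrow = TRUE)
  sim <- simulate_trajectories(25, 25000, c(0.01, 1), A, seed = 3)
  full_runs <- unlist(lapply(split(sim$truth$states$state,
                                   sim$truth$states$traj_id), function(s) {
    r <- rle(s)$lengths
    if (length(r) > 2) r[-c(1, length(r))] else numeric(0)
  }))
  expect_gt(length(full_runs), 1e4)
  expect_lt(abs(mean(full_runs) - 50) / 50, 0.05)

  # invalid inputs rejected
  expect_error(simulate_trajectories(5, 5, c(0.1, -1),
                                     matrix(0.5, 2, 2), seed = 1), "non-negative")
  expect_error(simulate_trajectories(5, 5, c(0.1, 1),
                                     matrix(c(0.5, 0.4, 0.4, 0.6), 2), seed = 1),
               "sum to 1")
})

test_that("two-channel images honour overlap geometry and Poisson statistics", {
  # forced overlap: every a centre within 1 px of a b centre
  sim <- simulate_two_channel_image(c(128, 128), 100, 20, 20, 1,
                                    amplitude = 50, seed = 1)
  d <- sapply(seq_len(20), function(i) {
    min(sqrt((sim$truth$centers_b$row - sim$truth$centers_a$row[i])^2 +
               (sim$truth$centers_b$col - sim$truth$centers_a$col[i])^2))
  })
  expect_true(all(d <= 1 + 1e-9))

  # forced disjoint: no a centre within 5 sigma of any b centre
  sim <- simulate_two_channel_image(c(128, 128), 100, 15, 15, 0,
                                    psf_sigma_px = 1.5, seed = 2)
  d <- sapply(seq_len(15), function(i) {
    min(sqrt((sim$truth$centers_b$row - sim$truth$centers_a$row[i])^2 +
               (sim$truth$centers_b$col - sim$truth$centers_a$col[i])^2))
  })
  expect_true(all(d >= 5 * 1.5))

  # amplitude 0: pure Poisson(background) field
  sim <- simulate_two_channel_image(c(128, 128), 100, 10, 10, 0.5,
                                    amplitude = 1e-12, background_rate = 10,
                                    seed = 3)
  for (img in list(sim$channel_a, sim$channel_b)) {
    se <- sd(img) / sqrt(length(img))
    expect_lt(abs(mean(img) - 10), 3 * se)
  }

  expect_error(simulate_two_channel_image(c(64, 64), 100, 5, 5, 0.5,
                                          psf_sigma_px = 0, seed = 1))
})

test_that("mea recording: noise-only sd, Poisson counts, close-spike truth", {
  # rate 0: pure noise with the requested sd (10 min x 10 kHz)
  rec <- simulate_mea_recording(1, 0, 600, seed = 1)
  expect_lt(abs(sd(rec$traces[1, ]) - 1) / 1, 0.02)
  expect_length(rec$spike_times[[1]], 0)

  # Poisson spike count at 1 Hz for 600 s
  counts <- vapply(1:10, function(s) {
    length(simulate_mea_recording(1, 1, 600, seed = s)$spike_times[[1]])
  }, numeric(1))
  expect_true(all(abs(counts - 600) <= 3 * sqrt(600)))

  # colliding spikes: at high rate some true spikes fall closer than the
  # template duration; they superpose linearly and the ground truth keeps
  # every event
  rec <- simulate_mea_recording(1, 200, 5, noise_sd = 1e-6, seed = 2)
  tt <- rec$spike_times[[1]]
  expect_true(!is.unsorted(tt))
  expect_true(any(diff(tt) < 0.0005))
  # superposed peaks exceed a single template's 12 sd peak
  expect_gt(max(abs(rec$traces[1, ])), 12 * 1e-6 * 1.5)

  # template longer than the trace is rejected
  expect_error(simulate_mea_recording(1, 1, 0.001, spike_template = rep(1, 100),
                                      seed = 1), "shorter")
})
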