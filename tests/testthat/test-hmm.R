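# Displacement extraction, variational inference invariants, closed-form
# limits and per-state metrics.

test_that("displacements: differences, drops and gap splitting", {
  traj <- tibble::tibble(traj_id = 1L, frame = 0:2,
                         x_um = c(0, 1, 1), y_um = c(0, 0, 1))
  ds <- displacements(traj)
  expect_equal(ds$steps$dx, c(1, 0))
  expect_equal(ds$steps$dy, c(0, 1))

  # single-position trajectory dropped and counted
  traj <- tibble::tibble(traj_id = c(1L, 2L, 2L), frame = c(0L, 0L, 1L),
                         x_um = c(0, 0, 1), y_um = 0)
  ds <- displacements(traj)
  expect_equal(ds$n_dropped, 1L)
  expect_equal(nrow(ds$steps), 1)

  # frames 0,1,3,4: split into two sequences of one displacement each
  traj <- tibble::tibble(traj_id = 1L, frame = c(0L, 1L, 3L, 4L),
                         x_um = c(0, 1, 5, 6), y_um = 0)
  ds <- displacements(traj)
  expect_equal(length(ds$seq_len), 2)
  expect_equal(ds$seq_len, c(1L, 1L))
  expect_equal(ds$steps$dx, c(1, 1))  # the 4-um jump across the gap is not a step
})

test_that("one-state fit matches the closed-form estimator and handles frozen particles", {
  sim <- simulate_trajectories(50, 400, 0.1, dt_s = 0.02, seed = 21)
  ds <- displacements(sim$trajectories, 0.02)
  f <- fit_hmm(ds, 1, seed = 1)
  mle <- mean(ds$steps$r2) / (4 * 0.02)
  expect_lt(abs(f$D_um2_s - mle) / mle, 0.02)
  expect_true(f$converged)

  # frozen particle with tiny jitter: the posterior pulls D to ~prior mass /
  # n steps, collapsing below 1e-6 um^2/s at 1e5 displacements
  set.seed(62)
  traj <- tibble::tibble(traj_id = rep(1:100, each = 1000),
                         frame = rep(0:999, 100),
                         x_um = rnorm(1e5, 0, 1e-9),
                         y_um = rnorm(1e5, 0, 1e-9))
  ds0 <- displacements(traj, 0.02)
  f0 <- fit_hmm(ds0, 1, seed = 2)
  expect_lt(f0$D_um2_s, 1e-6)
})

test_that("variational updates keep the bound non-decreasing and rows on the simplex", {
  A <- matrix(c(0.96, 0.04, 0.04, 0.96), 2, byrow = TRUE)
  sim <- simulate_trajectories(400, 12, c(0.02, 0.5), A, seed = 31)
  ds <- displacements(sim$trajectories, 0.02)
  for (K in 1:3) {
    f <- fit_hmm(ds, K, n_restarts = 3, seed = K)
    expect_true(all(diff(f$elbo_trace) > -1e-6),
                label = sprintf("monotone ELBO, K = %d", K))
    expect_equal(rowSums(f$A), rep(1, K), tolerance = 1e-9)
    expect_equal(sum(f$pi), 1, tolerance = 1e-9)
    expect_equal(sum(f$occupancy), 1, tolerance = 1e-6)
    expect_true(all(diff(f$D_um2_s) >= 0))   # canonical ordering by D
    expect_true(is.finite(f$evidence))
  }
})

test_that("two-state parameters and metrics are recovered from simulation truth", {
  A <- matrix(c(0.98, 0.02, 0.03, 0.97), 2, byrow = TRUE)
  sim <- simulate_trajectories(1500, 12, c(0.02, 0.6), A, seed = 41)
  ds <- displacements(sim$trajectories, 0.02)
  f <- fit_hmm(ds, 2, n_restarts = 5, seed = 42)
  expect_lt(abs(f$D_um2_s[1] - 0.02) / 0.02, 0.2)
  expect_lt(abs(f$D_um2_s[2] - 0.6) / 0.6, 0.2)
  expect_lt(abs(f$A[1, 1] - 0.98), 0.02)
  expect_lt(abs(f$A[2, 2] - 0.97), 0.02)
  truth_occ <- as.numeric(table(sim$truth$states$state) / nrow(sim$truth$states))
  expect_lt(max(abs(state_metrics(f)$occupancy - truth_occ)), 0.05)
})

test_that("state metrics encode dwell = dt/(1 - A_kk) and stationary occupancy", {
  m <- structure(
    list(K = 2L, D_um2_s = c(0.01, 0.5),
         A = matrix(c(0.98, 0.02, 0.02, 0.98), 2, byrow = TRUE),
         pi = c(0.5, 0.5), occupancy = c(0.5, 0.5), dt_s = 0.020),
    class = "diffusion_hmm")
  sm <- state_metrics(m)
  # A_kk = 0.98 at 20 ms frames: 50-frame dwell = 1000 ms
  expect_equal(sm$dwell_time_ms, c(1000, 1000))
  expect_false(any(sm$dwell_infinite))

  # uniform transitions: stationary occupancy (0.5, 0.5)
  m$A <- matrix(0.5, 2, 2)
  expect_equal(state_metrics(m)$occupancy_stationary, c(0.5, 0.5))

  # absorbing state: infinite dwell, flagged
  m$A <- matrix(c(1, 0, 0.05, 0.95), 2, byrow = TRUE)
  sm <- state_metrics(m)
  expect_true(sm$dwell_infinite[1])
  expect_equal(sm$dwell_time_ms[1], Inf)
})

test_that("model selection validates input and reports one bound per K", {
  sim <- simulate_trajectories(200, 10, 0.1, dt_s = 0.02, seed = 51)
  ds <- displacements(sim$trajectories, 0.02)
  expect_error(select_model(ds, candidate_K = integer(0)), "non-empty")
  expect_error(select_model(ds, candidate_K = c(2, 5)), "non-empty|1:3")
  sel <- select_model(ds, candidate_K = c(1, 2), n_restarts = 3, seed = 52)
  expect_equal(sort(sel$bounds$K), c(1L, 2L))
  expect_s3_class(sel$best, "diffusion_hmm")
  expect_equal(sel$best_K, sel$best$K)
})

test_that("fit_hmm rejects invalid state counts and empty data", {
  sim <- simulate_trajectories(10, 5, 0.1, dt_s = 0.02, seed = 61)
  ds <- displacements(sim$trajectories, 0.02)
  expect_error(fit_hmm(ds, 4), "1, 2 or 3")
  empty <- displacements(tibble::tibble(traj_id = 1L, frame = 0L,
                                        x_um = 0, y_um = 0))
  expect_error(fit_hmm(empty, 1), "no displacements")
})
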