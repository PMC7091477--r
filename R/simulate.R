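# Synthetic data generators. Each returns the simulated measurement in the
# same tabular form the analysis functions consume, together with the ground
# truth used to generate it, so recovery can be scored exactly.

#' Simulate a single-molecule localization field with clusters and blinking
#'
#' Emitters are placed uniformly inside discs of radius `cluster_radius_nm`
#' around uniformly positioned cluster centres, plus a Poisson background of
#' unclustered emitters. Each emitter blinks for a geometric number of
#' consecutive frames (mean `blink_repeat_mean`, support >= 1) starting at a
#' uniform frame, and every detection is jittered by isotropic Gaussian
#' localization error of sd `localization_sigma_nm` (clamped to the field).
#'
#' The number of emitters per cluster is the deterministic
#' `round(detections_per_cluster_mean / blink_repeat_mean)` so that the
#' expected number of detections per cluster equals
#' `detections_per_cluster_mean`; the background emitter count is Poisson with
#' mean `field area (um^2) * background_density_per_um2`.
#'
#' @param n_clusters number of clusters.
#' @param detections_per_cluster_mean expected detections per cluster.
#' @param cluster_radius_nm radius (nm) of the disc emitters occupy.
#' @param background_density_per_um2 background emitter density (emitters/um^2).
#' @param localization_sigma_nm isotropic localization error sd (nm).
#' @param n_frames number of acquisition frames.
#' @param blink_repeat_mean mean number of consecutive-frame detections per
#'   emitter (>= 1); 1 disables blinking.
#' @param field_width_nm,field_height_nm field extent (nm).
#' @param seed integer seed; fixes the whole pseudorandom stream.
#'
#' @return A list with `localizations` (tibble `frame`, `x`, `y` in nm, sorted
#'   by frame, x, y, with attributes `field_width_nm`, `field_height_nm`) and
#'   `truth` (emitter table, per-detection cluster labels aligned with the
#'   rows of `localizations`, -1 = background, and the generator parameters).
#' @export
simulate_smlm_field <- function(n_clusters,
                                detections_per_cluster_mean = 100,
                                cluster_radius_nm = 50,
                                background_density_per_um2 = 0,
                                localization_sigma_nm = 10,
                                n_frames = 20000,
                                blink_repeat_mean = 2,
                                field_width_nm = 10000,
                                field_height_nm = 10000,
                                seed = NULL) {
  check_number(n_clusters, "n_clusters", lower = 0, integerish = TRUE)
  check_number(detections_per_cluster_mean, "detections_per_cluster_mean", lower = 0)
  check_number(cluster_radius_nm, "cluster_radius_nm", lower = 0)
  check_number(background_density_per_um2, "background_density_per_um2", lower = 0)
  check_number(localization_sigma_nm, "localization_sigma_nm", lower = 0)
  check_number(n_frames, "n_frames", lower = 1, integerish = TRUE)
  check_number(blink_repeat_mean, "blink_repeat_mean", lower = 1)
  check_number(field_width_nm, "field_width_nm", lower = 1e-9)
  check_number(field_height_nm, "field_height_nm", lower = 1e-9)
  local_seed_if(seed)

  centers <- tibble(
    cluster = seq_len(n_clusters),
    x = runif(n_clusters, 0, field_width_nm),
    y = runif(n_clusters, 0, field_height_nm)
  )

  emitters_per_cluster <- as.integer(round(detections_per_cluster_mean / blink_repeat_mean))
  if (n_clusters > 0 && emitters_per_cluster > 0) {
    theta <- runif(n_clusters * emitters_per_cluster, 0, 2 * pi)
    rad <- cluster_radius_nm * sqrt(runif(n_clusters * emitters_per_cluster))
    cl <- rep(centers$cluster, each = emitters_per_cluster)
    em_clustered <- tibble(
      cluster = cl,
      x = pmin(pmax(centers$x[cl] + rad * cos(theta), 0), field_width_nm),
      y = pmin(pmax(centers$y[cl] + rad * sin(theta), 0), field_height_nm)
    )
  } else {
    em_clustered <- tibble(cluster = integer(), x = numeric(), y = numeric())
  }

  area_um2 <- (field_width_nm / 1000) * (field_height_nm / 1000)
  n_bg <- rpois(1, area_um2 * background_density_per_um2)
  em_bg <- tibble(
    cluster = rep(-1L, n_bg),
    x = runif(n_bg, 0, field_width_nm),
    y = runif(n_bg, 0, field_height_nm)
  )

  emitters <- dplyr::bind_rows(em_clustered, em_bg)
  emitters$emitter <- seq_len(nrow(emitters))

  if (nrow(emitters) > 0) {
    # geometric (support >= 1) number of consecutive-frame detections
    n_det <- 1L + rgeom(nrow(emitters), prob = 1 / blink_repeat_mean)
    n_det <- pmin(n_det, n_frames)
    start <- floor(runif(nrow(emitters), 0, n_frames - n_det + 1))
    idx <- rep(seq_len(nrow(emitters)), n_det)
    frame <- as.integer(start[idx] + sequence(n_det) - 1)
    det <- tibble(
      frame = frame,
      x = emitters$x[idx] + rnorm(length(idx), 0, localization_sigma_nm),
      y = emitters$y[idx] + rnorm(length(idx), 0, localization_sigma_nm),
      emitter = emitters$emitter[idx],
      cluster = emitters$cluster[idx]
    )
    det$x <- pmin(pmax(det$x, 0), field_width_nm)
    det$y <- pmin(pmax(det$y, 0), field_height_nm)
    det <- arrange(det, .data$frame, .data$x, .data$y)
  } else {
    det <- tibble(frame = integer(), x = numeric(), y = numeric(),
                  emitter = integer(), cluster = integer())
  }

  locs <- det[c("frame", "x", "y")]
  attr(locs, "field_width_nm") <- field_width_nm
  attr(locs, "field_height_nm") <- field_height_nm

  list(
    localizations = locs,
    truth = list(
      emitters = emitters[c("emitter", "x", "y", "cluster")],
      detection_cluster = det$cluster,
      detection_emitter = det$emitter,
      cluster_centers = centers,
      params = list(
        n_clusters = n_clusters,
        detections_per_cluster_mean = detections_per_cluster_mean,
        cluster_radius_nm = cluster_radius_nm,
        background_density_per_um2 = background_density_per_um2,
        localization_sigma_nm = localization_sigma_nm,
        n_frames = n_frames,
        blink_repeat_mean = blink_repeat_mean,
        field_width_nm = field_width_nm,
        field_height_nm = field_height_nm
      )
    )
  )
}

stationary_distribution <- function(A) {
  K <- nrow(A)
  if (K == 1L) return(1)
  # left eigenvector of A with eigenvalue 1
  e <- eigen(t(A))
  i <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, i]))
  v / sum(v)
}

#' Simulate Markov-switching Brownian trajectories
#'
#' Each trajectory carries a hidden state chain initialised from the
#' stationary distribution of the transition matrix `A` (steady-state
#' assumption) and evolved by `A` once per frame. Given the state, the x and
#' y displacement over one frame are independent Gaussian with variance
#' `2 * D_state * dt_s`. Optional localization noise is added to every
#' recorded position.
#'
#' @param n_trajectories number of trajectories.
#' @param n_steps displacements per trajectory (scalar or per-trajectory
#'   vector); trajectories have `n_steps + 1` positions (minimum length 2).
#' @param D_um2_s vector of per-state diffusion coefficients (um^2/s).
#' @param transition_matrix row-stochastic K x K per-frame transition matrix;
#'   defaults to identity for K = 1.
#' @param dt_s frame interval in seconds (default 0.020, i.e. 50 Hz).
#' @param localization_sigma_um static localization error sd (um) added to
#'   each position (default 0).
#' @param field_um trajectories start uniformly in a square of this side (um).
#' @param seed integer seed.
#'
#' @return list with `trajectories` (tibble `traj_id`, `frame`, `x_um`,
#'   `y_um`) and `truth` (per-step state table, `D_um2_s`, `A`, stationary
#'   `pi`, `dt_s`).
#' @export
simulate_trajectories <- function(n_trajectories,
                                  n_steps,
                                  D_um2_s,
                                  transition_matrix = NULL,
                                  dt_s = 0.020,
                                  localization_sigma_um = 0,
                                  field_um = 10,
                                  seed = NULL) {
  check_number(n_trajectories, "n_trajectories", lower = 1, integerish = TRUE)
  if (!is.numeric(D_um2_s) || any(!is.finite(D_um2_s)) || any(D_um2_s < 0)) {
    abort("`D_um2_s` must be a vector of finite non-negative diffusion coefficients.")
  }
  K <- length(D_um2_s)
  if (is.null(transition_matrix)) {
    if (K != 1L) abort("`transition_matrix` is required when more than one state is given.")
    transition_matrix <- matrix(1, 1, 1)
  }
  A <- as.matrix(transition_matrix)
  if (nrow(A) != K || ncol(A) != K) abort("`transition_matrix` must be K x K.")
  if (any(A < 0) || any(abs(rowSums(A) - 1) > 1e-8)) {
    abort("`transition_matrix` rows must be non-negative and sum to 1.")
  }
  check_number(dt_s, "dt_s", lower = 1e-12)
  check_number(localization_sigma_um, "localization_sigma_um", lower = 0)
  lens <- rep_len(as.integer(n_steps), n_trajectories)
  if (any(lens < 1L)) abort("`n_steps` must be >= 1 (trajectories need >= 2 positions).")
  local_seed_if(seed)

  pi0 <- stationary_distribution(A)
  n_total_steps <- sum(lens)

  # hidden chain, vectorised across trajectories step by step
  max_len <- max(lens)
  state <- matrix(NA_integer_, n_trajectories, max_len)
  cumA <- t(apply(A, 1, cumsum))
  state[, 1] <- findInterval(runif(n_trajectories), cumsum(pi0)) + 1L
  if (max_len > 1L) {
    for (t in 2:max_len) {
      act <- lens >= t
      if (!any(act)) break
      u <- runif(sum(act))
      prev <- state[act, t - 1L]
      if (K == 1L) {
        state[act, t] <- 1L
      } else {
        nxt <- integer(length(u))
        for (k in seq_len(K)) {
          sel <- prev == k
          if (any(sel)) nxt[sel] <- findInterval(u[sel], cumA[k, ]) + 1L
        }
        state[act, t] <- nxt
      }
    }
  }

  keep <- !is.na(t(state))
  step_state <- t(state)[keep]                    # column-major: by trajectory
  traj_of_step <- rep(seq_len(n_trajectories), lens)
  step_in_traj <- sequence(lens)

  sd_step <- sqrt(2 * D_um2_s[step_state] * dt_s)
  dx <- rnorm(n_total_steps, 0, sd_step)
  dy <- rnorm(n_total_steps, 0, sd_step)

  x0 <- runif(n_trajectories, 0, field_um)
  y0 <- runif(n_trajectories, 0, field_um)

  # cumulative sums restarted at each trajectory boundary
  csum_by_traj <- function(v) {
    cs <- cumsum(v)
    cs - rep(c(0, head(cs[cumsum(lens)], -1)), lens)
  }
  x_steps <- csum_by_traj(dx)
  y_steps <- csum_by_traj(dy)

  n_pos <- lens + 1L
  traj_id <- rep(seq_len(n_trajectories), n_pos)
  frame <- sequence(n_pos) - 1L
  pos_x <- numeric(sum(n_pos))
  pos_y <- numeric(sum(n_pos))
  first_pos <- cumsum(c(1L, head(n_pos, -1L)))
  pos_x[first_pos] <- x0
  pos_y[first_pos] <- y0
  not_first <- setdiff(seq_len(sum(n_pos)), first_pos)
  pos_x[not_first] <- rep(x0, lens) + x_steps
  pos_y[not_first] <- rep(y0, lens) + y_steps
  if (localization_sigma_um > 0) {
    pos_x <- pos_x + rnorm(length(pos_x), 0, localization_sigma_um)
    pos_y <- pos_y + rnorm(length(pos_y), 0, localization_sigma_um)
  }

  list(
    trajectories = tibble(traj_id = traj_id, frame = frame,
                          x_um = pos_x, y_um = pos_y),
    truth = list(
      states = tibble(traj_id = traj_of_step, step = step_in_traj,
                      state = step_state),
      D_um2_s = D_um2_s, A = A, pi = pi0, dt_s = dt_s,
      localization_sigma_um = localization_sigma_um
    )
  )
}

#' Simulate a two-channel image of Gaussian puncta on Poisson background
#'
#' A controlled fraction of channel-A puncta share centres (within 1 px) with
#' channel-B puncta; the remaining centres are kept at least
#' `min_separation_px` from every centre of the other channel and
#' `within_channel_separation_px` from centres of the same channel, so true
#' overlap is unambiguous. Pixel values are Poisson draws of
#' `background_rate + sum of Gaussian spot profiles`.
#'
#' @param shape image dimensions `c(rows, cols)`.
#' @param pixel_size_nm pixel pitch (nm).
#' @param n_puncta_a,n_puncta_b puncta counts per channel.
#' @param overlap_fraction fraction of A puncta sharing a centre with B.
#' @param psf_sigma_px Gaussian spot sd in pixels.
#' @param amplitude peak spot intensity (photons) above background.
#' @param background_rate Poisson background rate per pixel.
#' @param min_separation_px minimum distance between non-paired centres of
#'   different channels (default `5 * psf_sigma_px`).
#' @param within_channel_separation_px minimum distance between centres of the
#'   same channel (default `4 * psf_sigma_px`).
#' @param seed integer seed.
#'
#' @return list with integer matrices `channel_a`, `channel_b`, `pixel_size_nm`
#'   and `truth` (centre tables in 1-based `(row, col)` pixel coordinates and
#'   the A->B overlap pairing).
#' @export
simulate_two_channel_image <- function(shape = c(256, 256),
                                       pixel_size_nm = 100,
                                       n_puncta_a = 50,
                                       n_puncta_b = 50,
                                       overlap_fraction = 0.5,
                                       psf_sigma_px = 1.5,
                                       amplitude = 50,
                                       background_rate = 10,
                                       min_separation_px = 5 * psf_sigma_px,
                                       within_channel_separation_px = 4 * psf_sigma_px,
                                       seed = NULL) {
  if (length(shape) != 2L || any(shape < 8)) abort("`shape` must be two dims >= 8.")
  check_number(pixel_size_nm, "pixel_size_nm", lower = 1e-9)
  check_number(overlap_fraction, "overlap_fraction", lower = 0, upper = 1)
  check_number(psf_sigma_px, "psf_sigma_px", lower = 1e-9)
  check_number(amplitude, "amplitude", lower = 0)
  check_number(background_rate, "background_rate", lower = 0)
  local_seed_if(seed)

  margin <- 3 * psf_sigma_px + 1
  draw_centers <- function(n, existing_same, existing_other) {
    out <- matrix(numeric(0), 0, 2)
    attempts <- 0L
    while (nrow(out) < n && attempts < 20000L) {
      attempts <- attempts + 1L
      p <- c(runif(1, margin, shape[1] - margin), runif(1, margin, shape[2] - margin))
      all_same <- rbind(existing_same, out)
      ok <- TRUE
      if (nrow(all_same) > 0) {
        ok <- all(sqrt((all_same[, 1] - p[1])^2 + (all_same[, 2] - p[2])^2) >=
                    within_channel_separation_px)
      }
      if (ok && nrow(existing_other) > 0) {
        ok <- all(sqrt((existing_other[, 1] - p[1])^2 + (existing_other[, 2] - p[2])^2) >=
                    min_separation_px)
      }
      if (ok) out <- rbind(out, p)
    }
    if (nrow(out) < n) abort("could not place puncta with the requested separations; lower the density.")
    out
  }

  b_centers <- draw_centers(n_puncta_b, matrix(numeric(0), 0, 2), matrix(numeric(0), 0, 2))

  n_overlap <- as.integer(round(overlap_fraction * n_puncta_a))
  n_overlap <- min(n_overlap, n_puncta_b)
  paired_b <- if (n_overlap > 0) sample.int(n_puncta_b, n_overlap) else integer(0)
  if (n_overlap > 0) {
    ang <- runif(n_overlap, 0, 2 * pi)
    rad <- sqrt(runif(n_overlap))        # uniform in the unit disc: offset <= 1 px
    a_paired <- cbind(b_centers[paired_b, 1] + rad * cos(ang),
                      b_centers[paired_b, 2] + rad * sin(ang))
  } else {
    a_paired <- matrix(numeric(0), 0, 2)
  }
  a_free <- if (n_puncta_a - n_overlap > 0) {
    draw_centers(n_puncta_a - n_overlap, a_paired, b_centers)
  } else matrix(numeric(0), 0, 2)
  a_centers <- rbind(a_paired, a_free)

  render <- function(centers) {
    img <- matrix(background_rate, shape[1], shape[2])
    r <- ceiling(4 * psf_sigma_px)
    for (i in seq_len(nrow(centers))) {
      rows <- max(1, floor(centers[i, 1] - r)):min(shape[1], ceiling(centers[i, 1] + r))
      cols <- max(1, floor(centers[i, 2] - r)):min(shape[2], ceiling(centers[i, 2] + r))
      g <- outer(exp(-(rows - centers[i, 1])^2 / (2 * psf_sigma_px^2)),
                 exp(-(cols - centers[i, 2])^2 / (2 * psf_sigma_px^2)))
      img[rows, cols] <- img[rows, cols] + amplitude * g
    }
    matrix(rpois(length(img), img), shape[1], shape[2])
  }

  pairing <- tibble(
    a_id = seq_len(n_overlap),
    b_id = as.integer(paired_b)
  )
  list(
    channel_a = render(a_centers),
    channel_b = render(b_centers),
    pixel_size_nm = pixel_size_nm,
    truth = list(
      centers_a = tibble(id = seq_len(nrow(a_centers)),
                         row = a_centers[, 1], col = a_centers[, 2]),
      centers_b = tibble(id = seq_len(nrow(b_centers)),
                         row = b_centers[, 1], col = b_centers[, 2]),
      pairing = pairing,
      params = list(overlap_fraction = overlap_fraction, amplitude = amplitude,
                    background_rate = background_rate, psf_sigma_px = psf_sigma_px,
                    pixel_size_nm = pixel_size_nm)
    )
  )
}

#' Default biphasic extracellular spike template
#'
#' Difference of two Gaussian lobes (sharp negative then broader positive),
#' normalised to unit peak absolute amplitude. Duration ~2 ms at 10 kHz.
#'
#' @param sampling_rate_hz sampling rate (Hz).
#' @param duration_ms template duration (ms).
#' @return numeric vector with `max(abs(.)) == 1`.
#' @export
spike_template_biphasic <- function(sampling_rate_hz = 10000, duration_ms = 2) {
  n <- max(5L, round(duration_ms / 1000 * sampling_rate_hz))
  t <- seq_len(n)
  t_neg <- n * 0.3
  t_pos <- n * 0.6
  w <- -exp(-(t - t_neg)^2 / (2 * (n * 0.06)^2)) +
    0.45 * exp(-(t - t_pos)^2 / (2 * (n * 0.12)^2))
  w / max(abs(w))
}

#' Simulate a multielectrode-array recording with known spike times
#'
#' Each channel is white Gaussian noise of sd `noise_sd` plus a biphasic
#' spike template added at homogeneous-Poisson event times (per-channel rates
#' `rates_hz`). The template peak is `spike_amplitude_sd_units * noise_sd`.
#' Spikes closer than the template length simply sum (linear superposition);
#' both events are still recorded in the ground truth.
#'
#' @param n_channels number of electrodes.
#' @param rates_hz per-channel firing rate(s) in Hz (recycled).
#' @param duration_s recording duration (s); default 600 (a 10-min session).
#' @param sampling_rate_hz sampling rate, default 10000.
#' @param spike_template waveform added per spike (unit peak); default
#'   [spike_template_biphasic()].
#' @param spike_amplitude_sd_units spike peak in units of noise sd.
#' @param noise_sd baseline noise sd.
#' @param seed integer seed.
#'
#' @return list with `traces` (n_channels x n_samples matrix), `spike_times`
#'   (list of sorted true spike times in s), `sampling_rate_hz`, `duration_s`,
#'   `noise_sd`.
#' @export
simulate_mea_recording <- function(n_channels = 1,
                                   rates_hz = 1,
                                   duration_s = 600,
                                   sampling_rate_hz = 10000,
                                   spike_template = NULL,
                                   spike_amplitude_sd_units = 12,
                                   noise_sd = 1,
                                   seed = NULL) {
  check_number(n_channels, "n_channels", lower = 1, integerish = TRUE)
  if (any(rates_hz < 0)) abort("`rates_hz` must be non-negative.")
  check_number(duration_s, "duration_s", lower = 1e-9)
  check_number(sampling_rate_hz, "sampling_rate_hz", lower = 1)
  check_number(noise_sd, "noise_sd", lower = 0)
  n_samples <- round(duration_s * sampling_rate_hz)
  if (is.null(spike_template)) {
    spike_template <- spike_template_biphasic(sampling_rate_hz)
  }
  if (length(spike_template) >= n_samples) {
    abort("`spike_template` must be much shorter than the trace.")
  }
  local_seed_if(seed)

  rates <- rep_len(rates_hz, n_channels)
  tmpl <- spike_template * spike_amplitude_sd_units * noise_sd
  traces <- matrix(0, n_channels, n_samples)
  spike_times <- vector("list", n_channels)
  tl <- length(spike_template)
  for (ch in seq_len(n_channels)) {
    x <- rnorm(n_samples, 0, noise_sd)
    n_sp <- rpois(1, rates[ch] * duration_s)
    tt <- sort(runif(n_sp, 0, duration_s - tl / sampling_rate_hz))
    for (t0 in tt) {
      i0 <- floor(t0 * sampling_rate_hz) + 1L
      idx <- i0:(i0 + tl - 1L)
      x[idx] <- x[idx] + tmpl
    }
    traces[ch, ] <- x
    spike_times[[ch]] <- tt
  }
  list(traces = traces, spike_times = spike_times,
       sampling_rate_hz = sampling_rate_hz, duration_s = duration_s,
       noise_sd = noise_sd,
       params = list(rates_hz = rates,
                     spike_amplitude_sd_units = spike_amplitude_sd_units))
}
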