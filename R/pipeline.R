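# Run orchestration: validated configs, per-stage derived seeds, provenance,
# and the rank-sum group comparison used for all pairwise contrasts.

#' Mann-Whitney (Wilcoxon rank-sum) comparison of two groups
#'
#' Two-sided test of whether the two samples come from distributions with the
#' same location. The exact null distribution is used for small samples
#' (`min(n) <= 8`) without ties; otherwise the normal approximation with tie
#' correction and continuity correction.
#'
#' @param values_a,values_b numeric vectors (each n >= 1).
#' @return one-row tibble: `u` (the Mann-Whitney U for group A), `p_value`,
#'   `n_a`, `n_b`, `method`.
#' @export
mann_whitney <- function(values_a, values_b) {
  if (length(values_a) < 1 || length(values_b) < 1) {
    abort("both groups must contain at least one observation.")
  }
  ties <- any(duplicated(c(values_a, values_b)))
  exact <- min(length(values_a), length(values_b)) <= 8 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, alternative = "two.sided",
                       exact = exact, correct = TRUE)
  )
  tibble(
    u = unname(wt$statistic),
    p_value = min(1, wt$p.value),
    n_a = length(values_a),
    n_b = length(values_b),
    method = if (exact) "exact" else "normal approximation (tie-corrected)"
  )
}

# ---------------------------------------------------------------------------
# Pipeline runner

stage_registry <- function() {
  list(
    simulate_smlm = list(
      params = c("n_clusters", "detections_per_cluster_mean", "cluster_radius_nm",
                 "background_density_per_um2", "localization_sigma_nm", "n_frames",
                 "blink_repeat_mean", "field_width_nm", "field_height_nm"),
      validate = function(p) {
        for (nm in intersect(names(p), c("n_clusters", "background_density_per_um2",
                                         "localization_sigma_nm")))
          check_number(p[[nm]], nm, lower = 0)
      }
    ),
    cluster = list(
      params = c("eps_nm", "min_pts", "merge_radius_nm", "max_frame_gap", "merge"),
      validate = function(p) {
        if (!is.null(p$eps_nm)) check_number(p$eps_nm, "eps_nm", lower = 1e-12)
        if (!is.null(p$min_pts)) check_number(p$min_pts, "min_pts", lower = 1, integerish = TRUE)
        if (!is.null(p$merge_radius_nm)) check_number(p$merge_radius_nm, "merge_radius_nm", lower = 0)
      }
    ),
    simulate_spt = list(
      params = c("n_trajectories", "n_steps", "D_um2_s", "transition_matrix",
                 "dt_s", "localization_sigma_um"),
      validate = function(p) {
        if (!is.null(p$dt_s)) check_number(p$dt_s, "dt_s", lower = 1e-12)
        if (!is.null(p$D_um2_s) && any(p$D_um2_s < 0)) abort("`D_um2_s` must be >= 0.")
      }
    ),
    spt_hmm = list(
      params = c("dt_s", "candidate_K", "n_restarts", "prior_D_um2_s",
                 "prior_dwell_frames"),
      validate = function(p) {
        if (!is.null(p$dt_s)) check_number(p$dt_s, "dt_s", lower = 1e-12)
        if (!is.null(p$candidate_K) && !all(p$candidate_K %in% 1:3))
          abort("`candidate_K` must be within 1:3.")
      }
    ),
    simulate_image = list(
      params = c("shape", "pixel_size_nm", "n_puncta_a", "n_puncta_b",
                 "overlap_fraction", "psf_sigma_px", "amplitude", "background_rate"),
      validate = function(p) {
        if (!is.null(p$overlap_fraction))
          check_number(p$overlap_fraction, "overlap_fraction", lower = 0, upper = 1)
        if (!is.null(p$psf_sigma_px)) check_number(p$psf_sigma_px, "psf_sigma_px", lower = 1e-9)
      }
    ),
    segment = list(
      params = c("n_scales", "threshold_k", "min_size_px", "pixel_size_nm", "channel"),
      validate = function(p) {
        if (!is.null(p$threshold_k)) check_number(p$threshold_k, "threshold_k", lower = 0)
      }
    ),
    coloc = list(params = c("mode", "apposition_dist_px"), validate = function(p) NULL),
    endocytosis = list(params = character(0), validate = function(p) NULL),
    simulate_mea = list(
      params = c("n_channels", "rates_hz", "duration_s", "sampling_rate_hz",
                 "spike_amplitude_sd_units", "noise_sd"),
      validate = function(p) {
        if (!is.null(p$rates_hz) && any(p$rates_hz < 0)) abort("`rates_hz` must be >= 0.")
        if (!is.null(p$duration_s)) check_number(p$duration_s, "duration_s", lower = 1e-9)
      }
    ),
    mea = list(
      params = c("highpass_hz", "threshold_sd", "sd_estimator", "dead_time_ms",
                 "analysis_duration_s", "min_rate_hz"),
      validate = function(p) {
        if (!is.null(p$threshold_sd)) check_number(p$threshold_sd, "threshold_sd", lower = 1e-9)
        if (!is.null(p$highpass_hz)) check_number(p$highpass_hz, "highpass_hz", lower = 1e-9)
      }
    ),
    stats = list(params = c("value_column", "group_column"), validate = function(p) NULL)
  )
}

validate_config <- function(config) {
  known_top <- c("seed", "stages")
  unknown <- setdiff(names(config), known_top)
  if (length(unknown)) abort(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  if (is.null(config$stages) || !length(config$stages)) abort("config has no stages.")
  reg <- stage_registry()
  for (i in seq_along(config$stages)) {
    st <- config$stages[[i]]
    if (is.null(st$stage) || !st$stage %in% names(reg)) {
      abort(sprintf("stage %d: unknown stage `%s`.", i, st$stage %||% "<missing>"))
    }
    unknown_keys <- setdiff(names(st), c("stage", "params", "in", "out"))
    if (length(unknown_keys)) {
      abort(sprintf("stage %d (%s): unknown keys: %s", i, st$stage,
                    paste(unknown_keys, collapse = ", ")))
    }
    spec <- reg[[st$stage]]
    bad <- setdiff(names(st$params), spec$params)
    if (length(bad)) {
      abort(sprintf("stage %d (%s): unknown parameters: %s", i, st$stage,
                    paste(bad, collapse = ", ")))
    }
    spec$validate(st$params %||% list())
  }
  invisible(config)
}

#' Run a configured multi-stage analysis
#'
#' Executes the stages of a validated config in order, writing every stage's
#' outputs, a resolved copy of the config, a provenance record (package
#' version, seed, parameters) and a log into `out_dir`. The whole config is
#' validated before any stage runs. Stage `i` uses the derived seed
#' `seed + i` so per-stage randomness is reproducible independently of the
#' other stages. Metric files contain no timestamps, so a rerun with the same
#' config and seed is byte-identical (timestamps go to the log only).
#'
#' Stages: `simulate_smlm`, `cluster`, `simulate_spt`, `spt_hmm`,
#' `simulate_image`, `segment`, `coloc`, `endocytosis`, `simulate_mea`,
#' `mea`, `stats`. Stage inputs are taken from the preceding stage's in-memory
#' result or, where `in` names a file written earlier (or an external CSV),
#' from disk.
#'
#' @param config path to a YAML config or an equivalent named list with
#'   top-level `seed` and `stages`.
#' @param out_dir run directory, created if needed.
#' @return (invisibly) a named list of per-stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  validate_config(config)
  seed <- as.integer(config$seed %||% 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  log_path <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), sprintf(...))
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
  }
  yaml::write_yaml(config, file.path(out_dir, "resolved_config.yaml"))

  results <- list()
  carry <- NULL   # last stage's primary in-memory object
  for (i in seq_along(config$stages)) {
    st <- config$stages[[i]]
    p <- st$params %||% list()
    stage_seed <- seed + i
    log_line("stage %d: %s (seed %d)", i, st$stage, stage_seed)
    res <- tryCatch(
      run_stage(st, p, stage_seed, carry, out_dir),
      error = function(e) abort(sprintf("stage %d (%s) failed: %s",
                                        i, st$stage, conditionMessage(e)))
    )
    carry <- res
    results[[paste0(i, "_", st$stage)]] <- res
  }
  write_metrics_json(
    list(package = "polyquant",
         version = as.character(utils::packageVersion("polyquant")),
         seed = seed,
         stages = lapply(config$stages, function(s) s["stage"])),
    file.path(out_dir, "provenance.json")
  )
  log_line("run complete")
  invisible(results)
}

run_stage <- function(st, p, stage_seed, carry, out_dir) {
  out_of <- function(default) file.path(out_dir, st$out %||% default)
  switch(
    st$stage,
    simulate_smlm = {
      sim <- do.call(simulate_smlm_field, c(p, list(seed = stage_seed)))
      write_localizations(sim$localizations, out_of("localizations.csv"))
      sim
    },
    cluster = {
      locs <- if (!is.null(st[["in"]])) {
        read_localizations(resolve_in(st[["in"]], out_dir))
      } else if (!is.null(carry$localizations)) {
        carry$localizations
      } else abort("no localization input available.")
      if (isTRUE(p$merge %||% TRUE)) {
        locs <- merge_consecutive_detections(
          locs, merge_radius_nm = p$merge_radius_nm %||% 20,
          max_frame_gap = p$max_frame_gap %||% 1)
      }
      cs <- dbscan_cluster(locs, eps_nm = p$eps_nm %||% 20,
                           min_pts = p$min_pts %||% 20)
      readr::write_csv(tidy(cs), out_of("clusters.csv"))
      readr::write_csv(tibble(label = cs$labels), file.path(out_dir, "labels.csv"))
      write_metrics_json(as.list(cluster_metrics(cs)), file.path(out_dir, "cluster_metrics.json"))
      cs
    },
    simulate_spt = {
      p$transition_matrix <- if (!is.null(p$transition_matrix)) {
        matrix(unlist(p$transition_matrix), nrow = length(p$D_um2_s), byrow = TRUE)
      }
      sim <- do.call(simulate_trajectories, c(p, list(seed = stage_seed)))
      write_trajectories(sim$trajectories, out_of("trajectories.csv"))
      sim
    },
    spt_hmm = {
      traj <- if (!is.null(st[["in"]])) {
        read_trajectories(resolve_in(st[["in"]], out_dir))
      } else if (!is.null(carry$trajectories)) {
        carry$trajectories
      } else abort("no trajectory input available.")
      ds <- displacements(traj, dt_s = p$dt_s %||% 0.020)
      priors <- hmm_priors(prior_D_um2_s = p$prior_D_um2_s %||% 0.1,
                           prior_dwell_frames = p$prior_dwell_frames %||% 50)
      sel <- select_model(ds, priors = priors,
                          candidate_K = p$candidate_K %||% 1:3,
                          n_restarts = p$n_restarts %||% 10, seed = stage_seed)
      m <- sel$best
      write_metrics_json(
        list(K = m$K, D_um2_s = m$D_um2_s, A = m$A, pi = m$pi,
             occupancy = m$occupancy, evidence = m$evidence,
             bounds = sel$bounds, metrics = state_metrics(m)),
        out_of("hmm_model.json"))
      sel
    },
    simulate_image = {
      if (!is.null(p$shape)) p$shape <- unlist(p$shape)
      sim <- do.call(simulate_two_channel_image, c(p, list(seed = stage_seed)))
      write_image_tiff(sim$channel_a, file.path(out_dir, "channel_a.tif"))
      write_image_tiff(sim$channel_b, file.path(out_dir, "channel_b.tif"))
      sim
    },
    segment = {
      imgs <- if (!is.null(carry$channel_a)) {
        list(a = carry$channel_a, b = carry$channel_b)
      } else if (!is.null(st[["in"]])) {
        list(a = read_image_tiff(resolve_in(st[["in"]], out_dir)))
      } else abort("no image input available.")
      masks <- lapply(imgs, wavelet_segment,
                      n_scales = p$n_scales %||% 2,
                      threshold_k = p$threshold_k %||% 3.0,
                      min_size_px = p$min_size_px %||% 4,
                      pixel_size_nm = p$pixel_size_nm %||% 100)
      for (nm in names(masks)) {
        readr::write_csv(tidy(masks[[nm]]),
                         file.path(out_dir, sprintf("structures_%s.csv", nm)))
      }
      write_metrics_json(lapply(masks, function(m) as.list(structure_metrics(m))),
                         file.path(out_dir, "structure_metrics.json"))
      masks
    },
    coloc = {
      if (is.null(carry$a) || is.null(carry$b)) abort("coloc needs two segmented channels.")
      cl <- colocalize(carry$a, carry$b, mode = p$mode %||% "overlap",
                       apposition_dist_px = p$apposition_dist_px %||% 2)
      write_metrics_json(list(fraction_a_coloc = cl$fraction_a_coloc,
                              n_a = cl$n_a, n_a_coloc = cl$n_a_coloc,
                              mode = cl$mode),
                         out_of("colocalization.json"))
      # keep the masks flowing so a later endocytosis stage can reuse them
      list(a = carry$a, b = carry$b, coloc = cl)
    },
    endocytosis = {
      if (is.null(carry$a) || is.null(carry$b)) abort("endocytosis needs two segmented channels.")
      res <- classify_endocytosed(carry$a, carry$b)
      write_metrics_json(as.list(res), out_of("endocytosis.json"))
      res
    },
    simulate_mea = {
      sim <- do.call(simulate_mea_recording, c(p, list(seed = stage_seed)))
      write_mea_recording(sim, file.path(out_dir, "recording"))
      sim
    },
    mea = {
      rec <- if (!is.null(st[["in"]])) {
        read_mea_recording(resolve_in(st[["in"]], out_dir))
      } else if (!is.null(carry$traces)) {
        carry
      } else abort("no recording input available.")
      fs <- rec$sampling_rate_hz
      dur <- min(rec$duration_s, p$analysis_duration_s %||% 600)
      times <- lapply(seq_len(nrow(rec$traces)), function(ch) {
        f <- highpass_filter(rec$traces[ch, ], cutoff_hz = p$highpass_hz %||% 300,
                             sampling_rate_hz = fs)
        detect_spikes(f, sampling_rate_hz = fs,
                      threshold_sd = p$threshold_sd %||% 6,
                      sd_estimator = p$sd_estimator %||% "robust",
                      dead_time_ms = p$dead_time_ms %||% 1.0)
      })
      spikes <- tibble(channel = rep(seq_along(times), lengths(times)),
                       t_s = unlist(times) %||% numeric(0))
      readr::write_csv(spikes, out_of("spikes.csv"))
      cr <- channel_rates(spikes, analysis_duration_s = dur,
                          min_rate_hz = p$min_rate_hz %||% 0.1,
                          channels = seq_along(times))
      readr::write_csv(tidy(cr), file.path(out_dir, "rates.csv"))
      write_metrics_json(as.list(glance(cr)), file.path(out_dir, "rate_metrics.json"))
      cr
    },
    stats = {
      if (is.null(st[["in"]])) abort("stats stage needs `in`: a CSV with value/group columns.")
      df <- readr::read_csv(resolve_in(st[["in"]], out_dir), show_col_types = FALSE)
      vc <- p$value_column %||% "value"; gc <- p$group_column %||% "group"
      gs <- split(df[[vc]], df[[gc]])
      if (length(gs) != 2) abort("stats stage expects exactly two groups.")
      res <- mann_whitney(gs[[1]], gs[[2]])
      write_metrics_json(as.list(res), out_of("rank_test.json"))
      res
    },
    abort(sprintf("unimplemented stage `%s`.", st$stage))
  )
}

resolve_in <- function(path, out_dir) {
  if (file.exists(path)) path else {
    candidate <- file.path(out_dir, path)
    if (!file.exists(candidate) && !file.exists(paste0(candidate, ".json"))) {
      abort(sprintf("input `%s` not found.", path))
    }
    candidate
  }
}
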