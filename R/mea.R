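# Multielectrode-array analysis: zero-phase high-pass filtering, +/- threshold
# spike detection in noise-sd units, per-channel firing rates with the 0.1 Hz
# activity cut, and the control-normalised DIV14 -> DIV21 network change.

#' Zero-phase high-pass filter for extracellular traces
#'
#' 4th-order Butterworth high-pass applied forward and backward, so the
#' output is zero-phase and the DC component is removed. The trace is
#' extended at both ends by odd reflection before filtering and cropped
#' afterwards, which confines the filter's startup transient to the
#' discarded padding.
#'
#' @param trace numeric vector.
#' @param cutoff_hz cutoff frequency (Hz), default 300.
#' @param sampling_rate_hz sampling rate (Hz), default 10000.
#' @return filtered numeric vector of the same length.
#' @export
highpass_filter <- function(trace, cutoff_hz = 300, sampling_rate_hz = 10000) {
  check_number(cutoff_hz, "cutoff_hz", lower = 1e-9)
  check_number(sampling_rate_hz, "sampling_rate_hz", lower = 1e-9)
  if (cutoff_hz >= sampling_rate_hz / 2) {
    abort("`cutoff_hz` must be below the Nyquist frequency.")
  }
  bf <- signal::butter(4, cutoff_hz / (sampling_rate_hz / 2), type = "high")
  n <- length(trace)
  if (n < 2) return(rep(0, n))
  npad <- min(n - 1L, max(1000L, 3L * round(sampling_rate_hz / cutoff_hz)))
  left <- 2 * trace[1] - trace[(npad + 1):2]
  right <- 2 * trace[n] - trace[(n - 1):(n - npad)]
  x <- c(left, trace, right)
  y <- .iir_filter(bf$b, bf$a, x)
  y <- rev(.iir_filter(bf$b, bf$a, rev(y)))
  y[(npad + 1):(npad + n)]
}

#' Detect spikes by a +/- threshold in noise-sd units
#'
#' Noise sd is estimated robustly as `median(|x|) / 0.6745` (default) or as
#' the plain standard deviation. Events are runs of `|x| > threshold_sd * sd`;
#' the event time is the sample of peak absolute amplitude within the run,
#' and events closer than `dead_time_ms` after an accepted event are
#' suppressed.
#'
#' @param trace filtered numeric vector (see [highpass_filter()]).
#' @param sampling_rate_hz sampling rate (Hz).
#' @param threshold_sd threshold in sd units (default 6).
#' @param sd_estimator `"robust"` (default) or `"sd"`.
#' @param dead_time_ms refractory suppression window (ms), default 1.
#' @return sorted numeric vector of spike times in seconds (0-based: the
#'   first sample is time 0).
#' @export
detect_spikes <- function(trace, sampling_rate_hz = 10000, threshold_sd = 6,
                          sd_estimator = c("robust", "sd"), dead_time_ms = 1.0) {
  check_number(threshold_sd, "threshold_sd", lower = 1e-9)
  check_number(dead_time_ms, "dead_time_ms", lower = 0)
  sd_estimator <- match.arg(sd_estimator)
  sigma <- switch(sd_estimator,
                  robust = median(abs(trace)) / 0.6745,
                  sd = sd(trace))
  if (!is.finite(sigma) || sigma == 0) return(numeric(0))
  thr <- threshold_sd * sigma
  above <- abs(trace) > thr
  if (!any(above)) return(numeric(0))
  rl <- rle(above)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  runs <- which(rl$values)
  peak <- vapply(runs, function(i) {
    seg <- starts[i]:ends[i]
    seg[which.max(abs(trace[seg]))]
  }, integer(1))
  peak <- sort(peak)
  dead <- dead_time_ms / 1000 * sampling_rate_hz
  keep <- logical(length(peak))
  last <- -Inf
  for (i in seq_along(peak)) {
    if (peak[i] - last >= dead) {
      keep[i] <- TRUE
      last <- peak[i]
    }
  }
  (peak[keep] - 1) / sampling_rate_hz
}

#' Per-channel firing rates and the active-channel network mean
#'
#' Rates are spike counts over the analysis window (default 600 s, a 10-min
#' session). Channels firing below `min_rate_hz` (strict `<`; exactly
#' 0.1 Hz is kept) are flagged inactive/nonspiking and excluded from the
#' network mean.
#'
#' @param spikes tibble with columns `channel`, `t_s`, or a named list of
#'   spike-time vectors.
#' @param analysis_duration_s analysis window (s), default 600.
#' @param min_rate_hz activity cut (Hz), default 0.1.
#' @param channels optional vector of all channel ids (so silent channels
#'   appear with rate 0); defaults to the channels present in `spikes`.
#' @return list of class `channel_rates`: `channels` tibble (`channel`,
#'   `n_spikes`, `rate_hz`, `active`), `network_mean_rate_hz` (NA when no
#'   channel is active), `analysis_duration_s`, `min_rate_hz`.
#' @export
channel_rates <- function(spikes, analysis_duration_s = 600, min_rate_hz = 0.1,
                          channels = NULL) {
  check_number(analysis_duration_s, "analysis_duration_s", lower = 1e-9)
  check_number(min_rate_hz, "min_rate_hz", lower = 0)
  if (is.list(spikes) && !is.data.frame(spikes)) {
    ids <- names(spikes) %||% as.character(seq_along(spikes))
    spikes <- tibble(
      channel = rep(ids, lengths(spikes)),
      t_s = unlist(spikes, use.names = FALSE) %||% numeric(0)
    )
    channels <- channels %||% ids
  }
  spikes <- as_tibble(spikes)
  if (!all(c("channel", "t_s") %in% names(spikes))) {
    abort("`spikes` needs columns `channel` and `t_s`.")
  }
  if (nrow(spikes) && (any(spikes$t_s < 0) || any(spikes$t_s > analysis_duration_s))) {
    abort("spike times must lie within the analysis window.")
  }
  channels <- channels %||% sort(unique(spikes$channel))
  counts <- table(factor(spikes$channel, levels = channels))
  tab <- tibble(
    channel = channels,
    n_spikes = as.integer(counts),
    rate_hz = as.integer(counts) / analysis_duration_s
  )
  tab$active <- tab$rate_hz >= min_rate_hz
  net <- if (any(tab$active)) mean(tab$rate_hz[tab$active]) else NA_real_
  structure(list(channels = tab, network_mean_rate_hz = net,
                 analysis_duration_s = analysis_duration_s,
                 min_rate_hz = min_rate_hz),
            class = "channel_rates")
}

#' @export
print.channel_rates <- function(x, ...) {
  cat(sprintf("<channel_rates> %d channels, %d active, network mean %.3f Hz\n",
              nrow(x$channels), sum(x$channels$active), x$network_mean_rate_hz))
  invisible(x)
}

#' @rdname channel_rates
#' @param x a `channel_rates` object.
#' @param ... unused.
#' @method tidy channel_rates
#' @export
tidy.channel_rates <- function(x, ...) x$channels

#' @rdname channel_rates
#' @method glance channel_rates
#' @export
glance.channel_rates <- function(x, ...) {
  tibble(n_channels = nrow(x$channels), n_active = sum(x$channels$active),
         network_mean_rate_hz = x$network_mean_rate_hz)
}

#' Control-normalised change in network firing rate between two ages
#'
#' For matched recordings of each plate at 14 and 21 days in vitro, the
#' per-plate ratio `r = rate_div21 / rate_div14` is normalised by the mean
#' ratio over control plates, absorbing the inherent developmental increase
#' common to all plates. Plates with zero (or missing) DIV14 rate are
#' excluded and flagged.
#'
#' @param plates tibble with columns `plate`, `rate_div14`, `rate_div21`
#'   (network mean rates in Hz).
#' @param control_plates character/id vector naming the control plates.
#' @return tibble: `plate`, `is_control`, `ratio`, `normalized_change`,
#'   `excluded`.
#' @export
normalized_change <- function(plates, control_plates) {
  plates <- as_tibble(plates)
  if (!all(c("plate", "rate_div14", "rate_div21") %in% names(plates))) {
    abort("`plates` needs columns `plate`, `rate_div14`, `rate_div21`.")
  }
  if (length(control_plates) == 0 || !any(plates$plate %in% control_plates)) {
    abort("at least one control plate is required.")
  }
  out <- mutate(
    plates,
    is_control = .data$plate %in% control_plates,
    excluded = !is.finite(.data$rate_div14) | .data$rate_div14 <= 0 |
      !is.finite(.data$rate_div21),
    ratio = ifelse(.data$excluded, NA_real_, .data$rate_div21 / .data$rate_div14)
  )
  ctrl <- out$ratio[out$is_control & !out$excluded]
  if (length(ctrl) == 0) abort("no usable control plate (zero or missing DIV14 rate).")
  out$normalized_change <- out$ratio / mean(ctrl)
  out[c("plate", "is_control", "ratio", "normalized_change", "excluded")]
}
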