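# Readers and writers for the formats shared across stages: localization and
# trajectory CSV, TIFF images, flat-binary int16 MEA recordings with a JSON
# sidecar, and JSON metric/provenance files.

#' Write / read a localization table as CSV
#'
#' Columns `frame,x_nm,y_nm`; the reader also accepts ThunderSTORM-style
#' headers (`frame`, `x [nm]`, `y [nm]`). Field extent is carried in a JSON
#' comment-free sidecar-less way: as extra columns it is not; pass or recover
#' it via the attributes/arguments.
#'
#' @param locs localization tibble (`frame`, `x`, `y` in nm).
#' @param path CSV path.
#' @return `write_localizations()` returns `path` invisibly;
#'   `read_localizations()` returns the tibble with field-extent attributes.
#' @export
write_localizations <- function(locs, path) {
  locs <- as_localizations(locs)
  readr::write_csv(tibble(frame = locs$frame, x_nm = locs$x, y_nm = locs$y), path)
  invisible(path)
}

#' @rdname write_localizations
#' @param field_width_nm,field_height_nm optional known field extent (nm);
#'   defaults to the coordinate bounding box.
#' @export
read_localizations <- function(path, field_width_nm = NULL, field_height_nm = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  locs <- as_localizations(df)
  locs <- locs[c("frame", "x", "y")]
  attr(locs, "field_width_nm") <- field_width_nm %||%
    (if (nrow(locs)) max(locs$x) else 0)
  attr(locs, "field_height_nm") <- field_height_nm %||%
    (if (nrow(locs)) max(locs$y) else 0)
  locs
}

#' Write / read a trajectory table as CSV
#'
#' Columns `traj_id,frame,x_um,y_um`.
#'
#' @param traj trajectory tibble.
#' @param path CSV path.
#' @export
write_trajectories <- function(traj, path) {
  traj <- as_tibble(traj)
  stopifnot(all(c("traj_id", "frame", "x_um", "y_um") %in% names(traj)))
  readr::write_csv(traj[c("traj_id", "frame", "x_um", "y_um")], path)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write / read an image as TIFF
#'
#' Integer images (synthetic camera counts) are written as 16-bit TIFF;
#' real-valued images (rendered super-resolution fields) as 32-bit float.
#'
#' @param image numeric matrix.
#' @param path TIFF path.
#' @param bits 16 (integer counts, values 0..65535) or 32 (float).
#' @export
write_image_tiff <- function(image, path, bits = if (all(image == round(image))) 16 else 32) {
  stopifnot(is.matrix(image))
  if (bits == 16) {
    if (any(image < 0) || any(image > 65535)) abort("16-bit image values must be in 0..65535.")
    tiff::writeTIFF(image / 65535, path, bits.per.sample = 16)
  } else {
    tiff::writeTIFF(image, path, bits.per.sample = 32)
  }
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path, info = TRUE)
  bps <- attr(img, "bits.per.sample")
  out <- if (isTRUE(bps == 16)) round(unclass(img) * 65535) else unclass(img)
  out <- matrix(as.numeric(out), nrow(img), ncol(img))
  out
}

#' Write / read a multichannel MEA recording (flat binary int16 + JSON header)
#'
#' Traces are quantised to int16 with a stored scale (`volts_per_lsb`, here
#' arbitrary units per LSB) and written sample-major per channel
#' (channel 1 samples, channel 2 samples, ...). The JSON sidecar records
#' `n_channels`, `n_samples`, `sampling_rate_hz`, `scale` and optional true
#' spike times.
#'
#' @param rec a recording as from [simulate_mea_recording()] (elements
#'   `traces`, `sampling_rate_hz`; optional `spike_times`).
#' @param path_prefix path without extension; writes `.bin` and `.json`.
#' @export
write_mea_recording <- function(rec, path_prefix) {
  traces <- rec$traces
  stopifnot(is.matrix(traces))
  scale <- max(abs(traces), 1e-12) / 32000
  q <- as.integer(round(t(traces) / scale))   # channel-major blocks
  con <- file(paste0(path_prefix, ".bin"), "wb")
  on.exit(close(con))
  writeBin(q, con, size = 2L, endian = "little")
  header <- list(
    n_channels = nrow(traces),
    n_samples = ncol(traces),
    sampling_rate_hz = rec$sampling_rate_hz,
    scale = scale
  )
  if (!is.null(rec$spike_times)) header$spike_times <- rec$spike_times
  jsonlite::write_json(header, paste0(path_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path_prefix)
}

#' @rdname write_mea_recording
#' @export
read_mea_recording <- function(path_prefix) {
  header <- jsonlite::read_json(paste0(path_prefix, ".json"), simplifyVector = TRUE)
  n <- header$n_channels * header$n_samples
  con <- file(paste0(path_prefix, ".bin"), "rb")
  on.exit(close(con))
  q <- readBin(con, "integer", n = n, size = 2L, signed = TRUE, endian = "little")
  traces <- t(matrix(q * header$scale, header$n_samples, header$n_channels))
  out <- list(traces = traces, sampling_rate_hz = header$sampling_rate_hz,
              duration_s = header$n_samples / header$sampling_rate_hz)
  if (!is.null(header$spike_times)) {
    st <- header$spike_times
    if (!is.list(st)) st <- list(st)
    out$spike_times <- lapply(st, as.numeric)
  }
  out
}

#' Write an R object as pretty JSON (metrics, ground truth, provenance)
#'
#' @param x list / tibble.
#' @param path output path.
#' @export
write_metrics_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
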