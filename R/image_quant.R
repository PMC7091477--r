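# Wavelet-based puncta segmentation and the derived intensity, density,
# colocalization and endocytosis readouts. Images are plain numeric matrices
# in R's native 1-based (row, col) convention, origin top-left.

# separable 1-D convolution with the B3-spline kernel dilated by `step`
# (a-trous: zeros inserted between taps), mirror boundary
conv_b3_atrous <- function(img, step) {
  w <- c(1, 4, 6, 4, 1) / 16
  offsets <- c(-2L, -1L, 0L, 1L, 2L) * step
  reflect <- function(i, n) {
    i <- ifelse(i < 1L, 2L - i, i)
    ifelse(i > n, 2L * n - i, i)
  }
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (j in seq_along(offsets)) {           # rows
    out <- out + w[j] * img[reflect(seq_len(nr) + offsets[j], nr), , drop = FALSE]
  }
  out2 <- matrix(0, nr, nc)
  for (j in seq_along(offsets)) {           # columns
    out2 <- out2 + w[j] * out[, reflect(seq_len(nc) + offsets[j], nc), drop = FALSE]
  }
  out2
}

#' Undecimated a-trous wavelet planes of an image
#'
#' Successive smoothings with the B3-spline kernel dilated by powers of two;
#' plane `j` is the difference between smoothing levels `j - 1` and `j` and
#' carries structure at spatial scale ~`2^j` pixels.
#'
#' @param image numeric matrix.
#' @param n_scales number of planes.
#' @return list of wavelet-plane matrices, plus the final smooth as
#'   attribute `residual`.
#' @export
atrous_planes <- function(image, n_scales = 2) {
  check_number(n_scales, "n_scales", lower = 1, integerish = TRUE)
  if (!is.matrix(image) || !is.numeric(image)) abort("`image` must be a numeric matrix.")
  planes <- vector("list", n_scales)
  c_prev <- image
  for (j in seq_len(n_scales)) {
    c_j <- conv_b3_atrous(c_prev, 2L^(j - 1L))
    planes[[j]] <- c_prev - c_j
    c_prev <- c_j
  }
  attr(planes, "residual") <- c_prev
  planes
}

label_components_8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  labels <- matrix(0L, nr, nc)
  if (length(fg) == 0) return(labels)
  in_fg <- integer(nr * nc)
  in_fg[fg] <- seq_along(fg)
  r <- ((fg - 1L) %% nr) + 1L
  cc <- ((fg - 1L) %/% nr) + 1L
  edges <- integer(0)
  # half the 8-neighbourhood: E, SE, S, SW (column-major index offsets)
  for (off in list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))) {
    rr <- r + off[1]; ccn <- cc + off[2]
    ok <- rr >= 1L & rr <= nr & ccn >= 1L & ccn <= nc
    nb <- (ccn[ok] - 1L) * nr + rr[ok]
    has <- in_fg[nb] > 0L
    if (any(has)) {
      edges <- c(edges, rbind(in_fg[fg[ok]][has], in_fg[nb][has]))
    }
  }
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_along(fg)]
  # relabel 1..n by first (column-major) pixel occurrence, deterministic
  comp <- match(comp, unique(comp))
  labels[fg] <- comp
  labels
}

#' Segment fluorescent puncta by a-trous wavelet thresholding
#'
#' The detection plane is wavelet scale `n_scales` of the undecimated
#' B3-spline a-trous transform. Pixels where the plane exceeds
#' `threshold_k` times a robust noise sd (median absolute deviation of the
#' plane / 0.6745) form the mask; 8-connected components smaller than
#' `min_size_px` are discarded. Per-structure intensities are summed from the
#' original image, i.e. the mask is background-free but intensities are not
#' background-subtracted.
#'
#' @param image numeric matrix (fluorescence counts).
#' @param n_scales detection scale (default 2, structure ~4 px).
#' @param threshold_k threshold in robust noise-sd units (default 3).
#' @param min_size_px minimum structure size in pixels (default 4).
#' @param pixel_size_nm pixel pitch (nm), used for areas and densities.
#' @return object of class `structure_mask`: `labels` (integer matrix, 0 =
#'   background, structures numbered from 1), `structures` tibble (`id`,
#'   `n_px`, `area_um2`, `total_intensity`, `centroid_row`, `centroid_col`),
#'   `pixel_size_nm`, and the detection parameters.
#' @export
wavelet_segment <- function(image, n_scales = 2, threshold_k = 3.0,
                            min_size_px = 4, pixel_size_nm = 100) {
  if (!is.matrix(image) || !is.numeric(image)) abort("`image` must be a numeric matrix.")
  if (any(!is.finite(image))) abort("`image` must be finite.")
  check_number(threshold_k, "threshold_k", lower = 0)
  check_number(min_size_px, "min_size_px", lower = 1, integerish = TRUE)
  check_number(pixel_size_nm, "pixel_size_nm", lower = 1e-9)

  planes <- atrous_planes(image, n_scales)
  plane <- planes[[n_scales]]
  noise_sd <- mad(plane, center = median(plane))
  mask <- plane > threshold_k * noise_sd
  labels <- label_components_8(mask)

  sizes <- tabulate(labels)
  keep <- which(sizes >= min_size_px)
  relabel <- integer(length(sizes))
  relabel[keep] <- seq_along(keep)
  labels[labels > 0L] <- relabel[labels[labels > 0L]]

  n_str <- length(keep)
  if (n_str > 0) {
    px <- which(labels > 0L)
    lab <- labels[px]
    rowi <- ((px - 1L) %% nrow(image)) + 1L
    coli <- ((px - 1L) %/% nrow(image)) + 1L
    n_px <- tabulate(lab, n_str)
    structures <- tibble(
      id = seq_len(n_str),
      n_px = n_px,
      area_um2 = n_px * (pixel_size_nm / 1000)^2,
      total_intensity = as.numeric(tapply(image[px], lab, sum)),
      centroid_row = as.numeric(tapply(rowi, lab, mean)),
      centroid_col = as.numeric(tapply(coli, lab, mean))
    )
  } else {
    structures <- tibble(id = integer(), n_px = integer(), area_um2 = numeric(),
                         total_intensity = numeric(), centroid_row = numeric(),
                         centroid_col = numeric())
  }
  structure(
    list(labels = labels, structures = structures,
         pixel_size_nm = pixel_size_nm,
         params = list(n_scales = n_scales, threshold_k = threshold_k,
                       min_size_px = min_size_px, noise_sd = noise_sd)),
    class = "structure_mask"
  )
}

#' Build a structure mask from an existing binary segmentation
#'
#' For workflows where thresholding has already been done elsewhere (or for
#' constructed test masks): labels the 8-connected components of a logical
#' matrix and computes the same per-structure records as [wavelet_segment()].
#'
#' @param binary logical matrix (TRUE = foreground).
#' @param image optional original image for per-structure intensities;
#'   defaults to unit intensity per pixel.
#' @param pixel_size_nm pixel pitch (nm).
#' @param min_size_px minimum structure size in pixels (default 1).
#' @return a `structure_mask` object.
#' @export
as_structure_mask <- function(binary, image = NULL, pixel_size_nm = 100,
                              min_size_px = 1) {
  if (!is.matrix(binary) || !is.logical(binary)) {
    abort("`binary` must be a logical matrix.")
  }
  img <- image %||% matrix(1, nrow(binary), ncol(binary))
  if (!all(dim(img) == dim(binary))) abort("`image` must match `binary` in shape.")
  check_number(min_size_px, "min_size_px", lower = 1, integerish = TRUE)
  labels <- label_components_8(binary)
  sizes <- tabulate(labels)
  keep <- which(sizes >= min_size_px)
  relabel <- integer(length(sizes))
  relabel[keep] <- seq_along(keep)
  labels[labels > 0L] <- relabel[labels[labels > 0L]]
  n_str <- length(keep)
  if (n_str > 0) {
    px <- which(labels > 0L)
    lab <- labels[px]
    rowi <- ((px - 1L) %% nrow(binary)) + 1L
    coli <- ((px - 1L) %/% nrow(binary)) + 1L
    n_px <- tabulate(lab, n_str)
    structures <- tibble(
      id = seq_len(n_str), n_px = n_px,
      area_um2 = n_px * (pixel_size_nm / 1000)^2,
      total_intensity = as.numeric(tapply(img[px], lab, sum)),
      centroid_row = as.numeric(tapply(rowi, lab, mean)),
      centroid_col = as.numeric(tapply(coli, lab, mean))
    )
  } else {
    structures <- tibble(id = integer(), n_px = integer(), area_um2 = numeric(),
                         total_intensity = numeric(), centroid_row = numeric(),
                         centroid_col = numeric())
  }
  structure(
    list(labels = labels, structures = structures,
         pixel_size_nm = pixel_size_nm,
         params = list(n_scales = NA_integer_, threshold_k = NA_real_,
                       min_size_px = min_size_px, noise_sd = NA_real_)),
    class = "structure_mask"
  )
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> %d structures on a %d x %d field (k = %g, scale %d)\n",
              nrow(x$structures), nrow(x$labels), ncol(x$labels),
              x$params$threshold_k, x$params$n_scales))
  invisible(x)
}

#' @rdname wavelet_segment
#' @param x a `structure_mask`.
#' @param ... unused.
#' @method tidy structure_mask
#' @export
tidy.structure_mask <- function(x, ...) x$structures

#' @rdname wavelet_segment
#' @method glance structure_mask
#' @export
glance.structure_mask <- function(x, ...) structure_metrics(x)

#' Per-image structure metrics
#'
#' Field-level summaries of a segmentation: mean total fluorescence intensity
#' per cluster, cluster density per square micrometre, the summed intensity of
#' all structures, and the percentage of field area occupied by structures.
#'
#' @param mask a `structure_mask` from [wavelet_segment()].
#' @return one-row tibble: `n_structures`, `mean_intensity_per_cluster`,
#'   `clusters_per_um2`, `summed_intensity`, `percent_area`.
#' @export
structure_metrics <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  field_um2 <- length(mask$labels) * (mask$pixel_size_nm / 1000)^2
  s <- mask$structures
  tibble(
    n_structures = nrow(s),
    mean_intensity_per_cluster = if (nrow(s)) mean(s$total_intensity) else 0,
    clusters_per_um2 = nrow(s) / field_um2,
    summed_intensity = sum(s$total_intensity),
    percent_area = 100 * sum(mask$labels > 0L) / length(mask$labels)
  )
}

#' Colocalization between two segmented channels
#'
#' An A structure is colocalized when it shares at least one pixel with any B
#' structure (`mode = "overlap"`); in `mode = "apposition"` structures whose
#' centroids lie within `apposition_dist_px` of a B centroid also count.
#'
#' @param mask_a,mask_b `structure_mask` objects on the same pixel grid.
#' @param mode `"overlap"` (default) or `"apposition"`.
#' @param apposition_dist_px centroid distance (px) counted as apposed.
#' @return list of class `coloc_result`: `fraction_a_coloc`, `n_a`,
#'   `n_a_coloc`, `pairing` tibble (`a_id`, `b_id`, pixel-overlap pairs),
#'   `mode`.
#' @export
colocalize <- function(mask_a, mask_b, mode = c("overlap", "apposition"),
                       apposition_dist_px = 2) {
  stopifnot(inherits(mask_a, "structure_mask"), inherits(mask_b, "structure_mask"))
  mode <- match.arg(mode)
  if (!all(dim(mask_a$labels) == dim(mask_b$labels))) {
    abort("masks must have identical dimensions.")
  }
  la <- mask_a$labels; lb <- mask_b$labels
  both <- la > 0L & lb > 0L
  pairing <- if (any(both)) {
    dplyr::distinct(tibble(a_id = la[both], b_id = lb[both]))
  } else {
    tibble(a_id = integer(), b_id = integer())
  }
  coloc_ids <- unique(pairing$a_id)
  if (mode == "apposition" && nrow(mask_a$structures) && nrow(mask_b$structures)) {
    ca <- mask_a$structures; cb <- mask_b$structures
    d <- sqrt(outer(ca$centroid_row, cb$centroid_row, "-")^2 +
                outer(ca$centroid_col, cb$centroid_col, "-")^2)
    coloc_ids <- union(coloc_ids, ca$id[apply(d <= apposition_dist_px, 1, any)])
  }
  n_a <- nrow(mask_a$structures)
  structure(
    list(fraction_a_coloc = if (n_a > 0) length(coloc_ids) / n_a else NA_real_,
         n_a = n_a, n_a_coloc = length(coloc_ids),
         pairing = pairing, mode = mode),
    class = "coloc_result"
  )
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %d / %d A structures colocalized (%.3f, mode %s)\n",
              x$n_a_coloc, x$n_a, x$fraction_a_coloc, x$mode))
  invisible(x)
}

#' Classify green puncta as surface-bound or endocytosed
#'
#' In the surface-labelling assay, structures present in the green (total
#' fibril) channel that overlap a red (surface-restricted streptavidin)
#' structure are at the cell surface; green-only structures are
#' internalized (endocytosed).
#'
#' @param mask_green,mask_red `structure_mask` objects on the same grid.
#' @return tibble: `n_total_green`, `n_surface`, `n_internal`,
#'   `fraction_internal` (NA with zero green structures).
#' @export
classify_endocytosed <- function(mask_green, mask_red) {
  cl <- colocalize(mask_green, mask_red, mode = "overlap")
  n_total <- cl$n_a
  n_surface <- cl$n_a_coloc
  tibble(
    n_total_green = n_total,
    n_surface = n_surface,
    n_internal = n_total - n_surface,
    fraction_internal = if (n_total > 0) (n_total - n_surface) / n_total else NA_real_
  )
}
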