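# Single-molecule localization analysis: blink correction, density-based
# clustering at the 20 nm / 20 detections threshold, cluster metrics and
# Gaussian rendering.

as_localizations <- function(locs) {
  locs <- as_tibble(locs)
  # ThunderSTORM-style aliases
  nm <- names(locs)
  nm[nm %in% c("x [nm]", "x_nm")] <- "x"
  nm[nm %in% c("y [nm]", "y_nm")] <- "y"
  names(locs) <- nm
  if (!all(c("frame", "x", "y") %in% names(locs))) {
    abort("localization table needs columns `frame`, `x`, `y` (nm).")
  }
  if (nrow(locs) > 0 && (any(!is.finite(locs$x)) || any(!is.finite(locs$y)))) {
    abort("localization coordinates must be finite.")
  }
  locs
}

field_area_um2_of <- function(locs, field_width_nm = NULL, field_height_nm = NULL) {
  w <- field_width_nm %||% attr(locs, "field_width_nm")
  h <- field_height_nm %||% attr(locs, "field_height_nm")
  if (is.null(w) || is.null(h)) {
    if (nrow(locs) == 0) return(0)
    w <- diff(range(locs$x))
    h <- diff(range(locs$y))
  }
  (w / 1000) * (h / 1000)
}

#' Merge repeated detections of one emitter in consecutive frames
#'
#' A blinking fluorophore that stays on across frames produces a chain of
#' detections at nearly the same position in consecutive frames. Chains whose
#' successive members are within `merge_radius_nm` of the running chain
#' centroid and within `max_frame_gap` frames of the previous member are
#' collapsed to a single localization at the chain centroid, carrying the
#' first frame of the chain. Two detections in the same frame are never
#' merged (they are simultaneous, hence distinct emitters).
#'
#' The chaining pass is repeated until a fixed point (dense fields can leave
#' freshly merged chain centroids that are themselves chainable), which makes
#' the operation idempotent.
#'
#' @param locs localization tibble (`frame`, `x`, `y` in nm).
#' @param merge_radius_nm maximum distance (nm) from the running centroid.
#' @param max_frame_gap maximum frame difference between successive chain
#'   members; 1 (default) merges strictly consecutive frames only.
#' @return localization tibble of the same shape, `nrow(out) <= nrow(locs)`,
#'   sorted by (frame, x, y); field-extent attributes are preserved.
#' @export
merge_consecutive_detections <- function(locs, merge_radius_nm = 20, max_frame_gap = 1) {
  check_number(merge_radius_nm, "merge_radius_nm", lower = 0)
  check_number(max_frame_gap, "max_frame_gap", lower = 0, integerish = TRUE)
  repeat {
    out <- merge_pass(locs, merge_radius_nm, max_frame_gap)
    if (nrow(out) == nrow(as_tibble(locs))) return(out)
    locs <- out
  }
}

merge_pass <- function(locs, merge_radius_nm, max_frame_gap) {
  atts <- attributes(locs)[c("field_width_nm", "field_height_nm")]
  locs <- as_localizations(locs)
  if (nrow(locs) <= 1) {
    out <- arrange(locs, .data$frame, .data$x, .data$y)
    attr(out, "field_width_nm") <- atts$field_width_nm
    attr(out, "field_height_nm") <- atts$field_height_nm
    return(out)
  }
  locs <- arrange(locs, .data$frame, .data$x, .data$y)

  # active chains: running centroid, member count, first/last frame
  cap <- 256L
  ch_x <- ch_y <- numeric(cap); ch_n <- integer(cap)
  ch_first <- ch_last <- integer(cap)
  n_active <- 0L
  out_x <- out_y <- numeric(0); out_f <- integer(0)

  flush_chains <- function(keep) {
    done <- seq_len(n_active)[!keep[seq_len(n_active)]]
    if (length(done)) {
      out_x <<- c(out_x, ch_x[done]); out_y <<- c(out_y, ch_y[done])
      out_f <<- c(out_f, ch_first[done])
    }
    live <- seq_len(n_active)[keep[seq_len(n_active)]]
    ch_x[seq_along(live)] <<- ch_x[live]; ch_y[seq_along(live)] <<- ch_y[live]
    ch_n[seq_along(live)] <<- ch_n[live]
    ch_first[seq_along(live)] <<- ch_first[live]; ch_last[seq_along(live)] <<- ch_last[live]
    n_active <<- length(live)
  }

  frames <- unique(locs$frame)
  idx_by_frame <- split(seq_len(nrow(locs)), locs$frame)
  for (f in frames) {
    if (n_active > 0) {
      keep <- logical(cap)
      keep[seq_len(n_active)] <- (f - ch_last[seq_len(n_active)]) <= max_frame_gap
      flush_chains(keep)
    }
    rows <- idx_by_frame[[as.character(f)]]
    extended <- logical(n_active)   # a chain absorbs at most one detection per frame
    for (i in rows) {
      x <- locs$x[i]; y <- locs$y[i]
      best <- 0L; best_d <- Inf
      if (n_active > 0) {
        jj <- seq_len(n_active)
        elig <- !extended[jj] & ch_last[jj] < f
        if (any(elig)) {
          jj <- jj[elig]
          d <- sqrt((ch_x[jj] - x)^2 + (ch_y[jj] - y)^2)
          m <- which.min(d)
          if (d[m] <= merge_radius_nm) { best <- jj[m]; best_d <- d[m] }
        }
      }
      if (best > 0L) {
        n1 <- ch_n[best] + 1L
        ch_x[best] <- ch_x[best] + (x - ch_x[best]) / n1
        ch_y[best] <- ch_y[best] + (y - ch_y[best]) / n1
        ch_n[best] <- n1
        ch_last[best] <- as.integer(f)
        extended[best] <- TRUE
      } else {
        n_active <- n_active + 1L
        if (n_active > cap) {
          cap <- cap * 2L
          length(ch_x) <- cap; length(ch_y) <- cap; length(ch_n) <- cap
          length(ch_first) <- cap; length(ch_last) <- cap
        }
        ch_x[n_active] <- x; ch_y[n_active] <- y; ch_n[n_active] <- 1L
        ch_first[n_active] <- as.integer(f); ch_last[n_active] <- as.integer(f)
        extended <- c(extended, TRUE)
      }
    }
  }
  if (n_active > 0) flush_chains(rep(FALSE, cap))

  out <- tibble(frame = out_f, x = out_x, y = out_y)
  out <- arrange(out, .data$frame, .data$x, .data$y)
  attr(out, "field_width_nm") <- atts$field_width_nm
  attr(out, "field_height_nm") <- atts$field_height_nm
  out
}

# grid-indexed fixed-radius neighbour search; returns, for each point,
# the indices within `eps` (including the point itself)
grid_neighbours <- function(x, y, eps) {
  n <- length(x)
  cx <- floor(x / eps); cy <- floor(y / eps)
  key <- paste(cx, cy)
  cell_of <- split(seq_len(n), key)
  neigh <- vector("list", n)
  for (cell in names(cell_of)) {
    pts <- cell_of[[cell]]
    cc <- as.numeric(strsplit(cell, " ", fixed = TRUE)[[1]])
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      k <- paste(cc[1] + dx, cc[2] + dy)
      cand <- c(cand, cell_of[[k]])
    }
    dx2 <- outer(x[pts], x[cand], "-")^2
    dy2 <- outer(y[pts], y[cand], "-")^2
    within <- dx2 + dy2 <= eps^2
    for (i in seq_along(pts)) neigh[[pts[i]]] <- cand[within[i, ]]
  }
  neigh
}

hull_area_nm2 <- function(x, y) {
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3) return(list(area = 0, degenerate = TRUE))
  h <- grDevices::chull(pts)
  hx <- pts[h, 1]; hy <- pts[h, 2]
  area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  list(area = area, degenerate = area == 0)
}

#' Density-based (DBSCAN) clustering of localizations
#'
#' Standard DBSCAN on the Euclidean plane: a localization is a core point if
#' at least `min_pts` localizations (counting itself) lie within `eps_nm`;
#' clusters are the density-connected components of core points, border
#' points join the lowest-id reachable cluster, everything else is noise.
#' Points are scanned in (frame, x, y) order, making labels deterministic and
#' independent of input row order. Defaults are the 20 detections within
#' 20 nm density threshold used for fibrillar alpha-synuclein nanocluster
#' analysis.
#'
#' @param locs localization tibble (`frame`, `x`, `y` in nm).
#' @param eps_nm neighbourhood radius (nm).
#' @param min_pts minimum detections within `eps_nm`, self included.
#' @param field_width_nm,field_height_nm optional field extent (nm) for the
#'   density denominator; defaults to the table's attributes, then to the
#'   bounding box.
#' @return an object of class `smlm_clusters`: per-localization `labels`
#'   (-1 = noise, clusters numbered from 1 in scan order), a per-cluster
#'   tibble (`cluster`, `n_detections`, `centroid_x_nm`, `centroid_y_nm`,
#'   `area_nm2`, `degenerate`), the (sorted) localization table, and
#'   `field_area_um2`. Use [tidy()] / [glance()] / [cluster_metrics()].
#' @export
dbscan_cluster <- function(locs, eps_nm = 20, min_pts = 20,
                           field_width_nm = NULL, field_height_nm = NULL) {
  check_number(eps_nm, "eps_nm", lower = 1e-12)
  check_number(min_pts, "min_pts", lower = 1, integerish = TRUE)
  area <- field_area_um2_of(locs, field_width_nm, field_height_nm)
  locs <- as_localizations(locs)
  locs <- arrange(locs, .data$frame, .data$x, .data$y)
  n <- nrow(locs)

  if (n == 0) {
    return(new_smlm_clusters(locs, integer(0), empty_cluster_table(), area,
                             eps_nm, min_pts))
  }

  neigh <- grid_neighbours(locs$x, locs$y, eps_nm)
  n_neigh <- lengths(neigh)
  core <- n_neigh >= min_pts

  labels <- rep(-1L, n)
  cluster_id <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != -1L) next
    cluster_id <- cluster_id + 1L
    labels[i] <- cluster_id
    frontier <- i
    while (length(frontier)) {
      nb <- unique(unlist(neigh[frontier], use.names = FALSE))
      nb_core_new <- nb[core[nb] & labels[nb] == -1L]
      labels[nb_core_new] <- cluster_id
      frontier <- nb_core_new
    }
  }
  # border points: lowest-id cluster among core neighbours
  border <- which(!core)
  for (i in border) {
    cn <- neigh[[i]]
    cl <- labels[cn[core[cn]]]
    if (length(cl)) labels[i] <- min(cl)
  }

  if (cluster_id > 0) {
    clusters <- purrr::map_dfr(seq_len(cluster_id), function(k) {
      m <- labels == k
      hull <- hull_area_nm2(locs$x[m], locs$y[m])
      tibble(cluster = k, n_detections = sum(m),
             centroid_x_nm = mean(locs$x[m]), centroid_y_nm = mean(locs$y[m]),
             area_nm2 = hull$area, degenerate = hull$degenerate)
    })
  } else {
    clusters <- empty_cluster_table()
  }
  new_smlm_clusters(locs, labels, clusters, area, eps_nm, min_pts)
}

empty_cluster_table <- function() {
  tibble(cluster = integer(), n_detections = integer(),
         centroid_x_nm = numeric(), centroid_y_nm = numeric(),
         area_nm2 = numeric(), degenerate = logical())
}

new_smlm_clusters <- function(locs, labels, clusters, field_area_um2,
                              eps_nm, min_pts) {
  structure(
    list(localizations = locs, labels = as.integer(labels), clusters = clusters,
         field_area_um2 = field_area_um2, eps_nm = eps_nm, min_pts = min_pts),
    class = "smlm_clusters"
  )
}

#' @export
print.smlm_clusters <- function(x, ...) {
  cat(sprintf("<smlm_clusters> %d localizations, %d clusters, %d noise (eps %g nm, minPts %d)\n",
              length(x$labels), nrow(x$clusters), sum(x$labels == -1L),
              x$eps_nm, x$min_pts))
  invisible(x)
}

#' @rdname dbscan_cluster
#' @param x an `smlm_clusters` object.
#' @param ... unused.
#' @method tidy smlm_clusters
#' @export
tidy.smlm_clusters <- function(x, ...) x$clusters

#' @rdname dbscan_cluster
#' @method glance smlm_clusters
#' @export
glance.smlm_clusters <- function(x, ...) cluster_metrics(x)

#' Field-level cluster metrics
#'
#' The per-field readouts reported for fibrillar polymorph nanoclusters:
#' detection density over the field, the fraction of detections falling in
#' clusters, and summaries of per-cluster area (convex hull; collinear
#' degenerate clusters have area 0 and are flagged).
#'
#' @param cs an `smlm_clusters` object from [dbscan_cluster()].
#' @return one-row tibble: `n_localizations`, `n_clusters`,
#'   `detections_per_um2`, `fraction_in_clusters`, `mean_cluster_area_nm2`,
#'   `median_cluster_area_nm2`.
#' @export
cluster_metrics <- function(cs) {
  stopifnot(inherits(cs, "smlm_clusters"))
  if (cs$field_area_um2 <= 0) abort("field area must be positive.")
  n <- length(cs$labels)
  n_cl <- sum(cs$labels != -1L)
  tibble(
    n_localizations = n,
    n_clusters = nrow(cs$clusters),
    detections_per_um2 = n / cs$field_area_um2,
    fraction_in_clusters = if (n > 0) n_cl / n else 0,
    mean_cluster_area_nm2 = if (nrow(cs$clusters)) mean(cs$clusters$area_nm2) else NA_real_,
    median_cluster_area_nm2 = if (nrow(cs$clusters)) median(cs$clusters$area_nm2) else NA_real_
  )
}

#' Render a localization table as a super-resolution image
#'
#' Each localization contributes a unit-mass isotropic Gaussian kernel of sd
#' `kernel_sigma_nm`, evaluated at pixel centres of a `pixel_size_nm` grid
#' (the 10 nm pointing-accuracy rendering convention). Kernels are normalised
#' before placement, so total image mass equals the number of localizations
#' up to truncation at the field edges.
#'
#' @param locs localization tibble (`frame`, `x`, `y` in nm).
#' @param pixel_size_nm rendering pixel size (nm), default 10.
#' @param kernel_sigma_nm Gaussian kernel sd (nm), default 10.
#' @param field_width_nm,field_height_nm field extent (nm); defaults to the
#'   table's attributes, then to the coordinate maxima.
#' @return numeric matrix (rows = y, cols = x) with attributes
#'   `pixel_size_nm`, `kernel_sigma_nm`.
#' @export
render_storm <- function(locs, pixel_size_nm = 10, kernel_sigma_nm = 10,
                         field_width_nm = NULL, field_height_nm = NULL) {
  check_number(pixel_size_nm, "pixel_size_nm", lower = 1e-12)
  check_number(kernel_sigma_nm, "kernel_sigma_nm", lower = 1e-12)
  locs <- as_localizations(locs)
  w <- field_width_nm %||% attr(locs, "field_width_nm") %||%
    (if (nrow(locs)) max(locs$x) else pixel_size_nm)
  h <- field_height_nm %||% attr(locs, "field_height_nm") %||%
    (if (nrow(locs)) max(locs$y) else pixel_size_nm)
  nc <- max(1L, ceiling(w / pixel_size_nm))
  nr <- max(1L, ceiling(h / pixel_size_nm))
  img <- matrix(0, nr, nc)
  if (nrow(locs) == 0) {
    attr(img, "pixel_size_nm") <- pixel_size_nm
    attr(img, "kernel_sigma_nm") <- kernel_sigma_nm
    return(img)
  }
  r <- ceiling(4 * kernel_sigma_nm / pixel_size_nm)
  px_centers <- function(idx) (idx - 0.5) * pixel_size_nm
  for (i in seq_len(nrow(locs))) {
    cx <- locs$x[i] / pixel_size_nm + 0.5   # fractional pixel index
    cy <- locs$y[i] / pixel_size_nm + 0.5
    cols <- max(1L, floor(cx - r)):min(nc, ceiling(cx + r))
    rows <- max(1L, floor(cy - r)):min(nr, ceiling(cy + r))
    gx <- exp(-(px_centers(cols) - locs$x[i])^2 / (2 * kernel_sigma_nm^2))
    gy <- exp(-(px_centers(rows) - locs$y[i])^2 / (2 * kernel_sigma_nm^2))
    # normalise over the full (untruncated) kernel support so mass is unit
    full_cols <- (floor(cx - r)):(ceiling(cx + r))
    full_rows <- (floor(cy - r)):(ceiling(cy + r))
    gx_full <- exp(-((full_cols - 0.5) * pixel_size_nm - locs$x[i])^2 / (2 * kernel_sigma_nm^2))
    gy_full <- exp(-((full_rows - 0.5) * pixel_size_nm - locs$y[i])^2 / (2 * kernel_sigma_nm^2))
    stamp <- outer(gy, gx) / (sum(gy_full) * sum(gx_full))
    img[rows, cols] <- img[rows, cols] + stamp
  }
  attr(img, "pixel_size_nm") <- pixel_size_nm
  attr(img, "kernel_sigma_nm") <- kernel_sigma_nm
  img
}
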