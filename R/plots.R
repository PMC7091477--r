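# ggplot2 views of the result objects. These are diagnostic renders, not
# figure reproductions.

#' @rdname dbscan_cluster
#' @param object an `smlm_clusters` object.
#' @method autoplot smlm_clusters
#' @export
autoplot.smlm_clusters <- function(object, ...) {
  df <- object$localizations
  df$cluster <- factor(ifelse(object$labels == -1L, "noise", object$labels),
                       levels = c(sort(unique(object$labels[object$labels != -1L])), "noise"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, colour = .data$cluster)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.7) +
    ggplot2::scale_colour_discrete(na.value = "grey70") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)",
                  title = sprintf("%d clusters (eps %g nm, minPts %d)",
                                  nrow(object$clusters), object$eps_nm, object$min_pts))
}

#' @rdname fit_hmm
#' @param object a `diffusion_hmm` object.
#' @method autoplot diffusion_hmm
#' @export
autoplot.diffusion_hmm <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$state), y = .data$occupancy,
                                   fill = .data$D_um2_s)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_viridis_c(name = expression(D ~ (mu * m^2 / s)),
                                  trans = "log10") +
    ggplot2::labs(x = "diffusive state (slow to fast)", y = "occupancy",
                  title = sprintf("K = %d, ELBO = %.1f", object$K, object$evidence))
}

#' @rdname select_model
#' @param object an `hmm_selection` object.
#' @method autoplot hmm_selection
#' @export
autoplot.hmm_selection <- function(object, ...) {
  ggplot2::ggplot(object$bounds, ggplot2::aes(x = factor(.data$K), y = .data$evidence)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_line(ggplot2::aes(group = 1)) +
    ggplot2::labs(x = "number of diffusive states K", y = "evidence lower bound (nats)",
                  title = sprintf("maximal evidence selects K = %d", object$best_K))
}

#' @rdname wavelet_segment
#' @param object a `structure_mask` object.
#' @method autoplot structure_mask
#' @export
autoplot.structure_mask <- function(object, ...) {
  lab <- object$labels
  df <- tibble(
    row = rep(seq_len(nrow(lab)), ncol(lab)),
    col = rep(seq_len(ncol(lab)), each = nrow(lab)),
    structure = as.vector(lab) > 0L
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$structure)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "black", `TRUE` = "white")) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%d structures", nrow(object$structures)))
}

#' Raster plot of spike trains
#'
#' @param spikes tibble with `channel`, `t_s` (as written by the `mea` stage).
#' @return a ggplot object.
#' @export
plot_spike_raster <- function(spikes) {
  spikes <- as_tibble(spikes)
  ggplot2::ggplot(spikes, ggplot2::aes(x = .data$t_s, y = factor(.data$channel))) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::labs(x = "time (s)", y = "electrode")
}
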