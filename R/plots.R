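#' Plot one slice of a volume
#'
#' Heat-map of an axial (default), coronal or sagittal slice, in world-mm
#' coordinates with the grid center as origin.
#'
#' @param vol Volume to plot.
#' @param slice Slice index along `axis`; defaults to the middle slice.
#' @param axis 1 (sagittal), 2 (coronal) or 3 (axial).
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_slice <- function(vol, slice = NULL, axis = 3, title = NULL) {
  stopifnot(is_volume(vol), axis %in% 1:3)
  d <- dim(vol)
  if (is.null(slice)) slice <- ceiling(d[axis] / 2)
  sl <- switch(axis,
               unclass(vol)[slice, , ],
               unclass(vol)[, slice, ],
               unclass(vol)[, , slice])
  vox <- voxel_mm(vol)
  dd <- dim(sl)
  ctr <- (dd + 1) / 2
  df <- tidyr::expand_grid(i = seq_len(dd[1]), j = seq_len(dd[2]))
  df$value <- sl[cbind(df$i, df$j)]
  df$x <- (df$i - ctr[1]) * vox
  df$y <- (df$j - ctr[2]) * vox
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(title = title, x = "mm", y = "mm", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.wmap <- function(object, slice = NULL, axis = 3, ...) {
  p <- plot_slice(object$w, slice = slice, axis = axis,
                  title = sprintf("W-score map%s (age %.0f)",
                                  if (is.null(object$subject_id)) "" else
                                    paste0(" ", object$subject_id),
                                  object$age))
  suppressMessages(
    p + ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                      high = "#2166ac", midpoint = 0,
                                      na.value = "grey90"))
}

#' @export
autoplot.wscore_frequency <- function(object, slice = NULL, axis = 3, ...) {
  plot_slice(object$fraction, slice = slice, axis = axis,
             title = sprintf("Suprathreshold fraction (n = %d)", object$n))
}

#' @export
autoplot.cluster_fwe <- function(object, slice = NULL, axis = 3, ...) {
  plot_slice(object$tmap, slice = slice, axis = axis,
             title = sprintf("t-map (df = %d, height t > %.2f)",
                             object$df, object$critical_t))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.cluster_fwe <- function(x, ...) {
  flatten_cluster_table(x$table)
}

#' @export
glance.cluster_fwe <- function(x, ...) {
  tibble::tibble(
    df = x$df, critical_t = x$critical_t, height_p = x$height_p,
    cluster_p = x$cluster_p, extent = x$extent,
    connectivity = x$connectivity, n_perm = x$n_perm, seed = x$seed,
    n_clusters = nrow(x$table),
    n_significant = sum(x$table$significant)
  )
}
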