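#' Build the analysis mask
#'
#' The mask is `mean_gm_prob > threshold` (strict: a voxel exactly at the
#' threshold is excluded) minus the named excluded atlas regions. The
#' occipital lobe is excluded by default, reflecting comparative analyses in
#' which differing ambient (visual) conditions at tracer injection make
#' occipital uptake uninterpretable.
#'
#' @param mean_gm_prob Pooled (all-subject) mean GM probability volume.
#' @param template A `template_set` supplying the atlas and label names.
#' @param threshold Absolute GM threshold (default 0.1).
#' @param excluded_labels Character vector of atlas region names to remove.
#' @return An `analysis_mask`: logical volume plus provenance fields.
#' @export
make_analysis_mask <- function(mean_gm_prob, template, threshold = 0.1,
                               excluded_labels = "occipital") {
  stopifnot(is_volume(mean_gm_prob), inherits(template, "template_set"))
  assert_same_grid(mean_gm_prob, template$gm_prob)
  m <- unclass(mean_gm_prob) > threshold
  if (length(excluded_labels)) {
    m <- m & !unclass(region_mask(template, excluded_labels))
  }
  if (!any(m)) {
    stop(sprintf("analysis mask is empty at threshold %g", threshold),
         call. = FALSE)
  }
  structure(list(
    mask = like_volume(m, mean_gm_prob),
    threshold = threshold,
    excluded_labels = excluded_labels,
    n_voxels = sum(m)
  ), class = "analysis_mask")
}

#' @export
print.analysis_mask <- function(x, ...) {
  cat(sprintf("<analysis_mask> %d voxels (GM > %g, excluding %s)\n",
              x$n_voxels, x$threshold,
              if (length(x$excluded_labels)) {
                paste(x$excluded_labels, collapse = ", ")
              } else "nothing"))
  invisible(x)
}

as_mask_array <- function(mask) {
  if (inherits(mask, "analysis_mask")) unclass(mask$mask) else unclass(mask)
}

#' Proportional intensity normalization
#'
#' Divides the image by its mean over the analysis mask, so the in-mask mean
#' of the output is exactly 1. Undefined (`NA`) voxels are ignored in the mean
#' and stay undefined. Idempotent, and invariant to global rescaling of the
#' input.
#'
#' @param vol Volume to normalize.
#' @param mask An [make_analysis_mask()] result (or logical volume).
#' @return Normalized volume.
#' @export
proportional_normalize <- function(vol, mask) {
  stopifnot(is_volume(vol))
  m <- as_mask_array(mask)
  v <- unclass(vol)[m]
  mu <- mean(v[is.finite(v)])
  if (!is.finite(mu) || mu <= 0) {
    stop("mean activity within the mask is not positive; cannot normalize",
         call. = FALSE)
  }
  like_volume(unclass(vol) / mu, vol)
}

#' Reference-region (SUVR) scaling
#'
#' Divides the image by its mean uptake over named atlas reference regions
#' (cerebellar structures by default).
#'
#' @param vol Volume to scale.
#' @param template A `template_set`.
#' @param reference_labels Atlas region names of the reference.
#' @return SUVR volume.
#' @export
suvr <- function(vol, template, reference_labels = "cerebellum") {
  stopifnot(is_volume(vol), inherits(template, "template_set"))
  ref <- unclass(region_mask(template, reference_labels))
  v <- unclass(vol)[ref]
  v <- v[is.finite(v)]
  if (!length(v)) stop("reference region is empty", call. = FALSE)
  mu <- mean(v)
  if (!is.finite(mu) || mu <= 0) {
    stop("reference-region mean is not positive", call. = FALSE)
  }
  like_volume(unclass(vol) / mu, vol)
}

#' Gaussian smoothing, optionally masked
#'
#' Unmasked, this is [gaussian_blur()] except that `NA` voxels are handled by
#' normalized convolution (they contribute nothing and stay `NA`). With a
#' mask, smoothing is confined to the mask by normalized convolution: values
#' outside the mask never leak in, constants are preserved inside, and
#' everything outside the mask is `NA`.
#'
#' @param vol Volume to smooth.
#' @param fwhm_mm Kernel FWHM in mm (default 8); 0 is the identity.
#' @param mask Optional [make_analysis_mask()] result or logical volume.
#' @return Smoothed volume.
#' @export
smooth_volume <- function(vol, fwhm_mm = 8, mask = NULL) {
  stopifnot(is_volume(vol))
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm < 0) {
    stop("`fwhm_mm` must be a single non-negative number", call. = FALSE)
  }
  x <- unclass(vol)
  support <- is.finite(x)
  if (!is.null(mask)) support <- support & as_mask_array(mask)
  if (fwhm_mm == 0) {
    out <- array(NA_real_, dim(vol))
    out[support] <- x[support]
    return(like_volume(out, vol))
  }
  if (is.null(mask) && all(support)) {
    return(gaussian_blur(vol, fwhm_mm))
  }
  num <- x
  num[!support] <- 0
  num <- unclass(gaussian_blur(like_volume(num, vol), fwhm_mm))
  den <- unclass(gaussian_blur(like_volume(support * 1, vol), fwhm_mm))
  out <- array(NA_real_, dim(vol))
  out[support] <- num[support] / den[support]
  like_volume(out, vol)
}
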