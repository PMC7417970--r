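#' Scanner point-spread-function model
#'
#' An isotropic Gaussian PSF described by its full width at half maximum.
#' `fwhm_mm = 0` is the identity kernel.
#'
#' @param fwhm_mm FWHM in mm, `>= 0`. The default 5.5 mm mimics the effective
#'   resolution of a modern time-of-flight PET reconstruction.
#' @return A `psf_model` object.
#' @export
psf_model <- function(fwhm_mm = 5.5) {
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm < 0) {
    stop("`fwhm_mm` must be a single non-negative number", call. = FALSE)
  }
  structure(list(fwhm_mm = fwhm_mm), class = "psf_model")
}

#' @export
print.psf_model <- function(x, ...) {
  cat(sprintf("<psf_model> isotropic Gaussian, FWHM %g mm (sigma %.4g mm)\n",
              x$fwhm_mm, fwhm_to_sigma(x$fwhm_mm)))
  invisible(x)
}

psf_blur <- function(vol, psf) gaussian_blur(vol, psf$fwhm_mm)

#' Estimate white-matter activity by regression
#'
#' Regresses the observed PET image on the PSF-blurred WM probability map over
#' voxels with high WM probability, through the origin. The slope is the
#' apparent pure-WM activity used for the WM spill-in term of the
#' Mueller-Gartner correction.
#'
#' @param pet Observed uptake volume.
#' @param wm_prob WM probability volume on the same grid.
#' @param psf A [psf_model()].
#' @param wm_threshold Voxels with `wm_prob > wm_threshold` enter the
#'   regression (default 0.95).
#' @return Scalar WM activity (a.u.).
#' @export
estimate_wm_activity <- function(pet, wm_prob, psf = psf_model(),
                                 wm_threshold = 0.95) {
  stopifnot(is_volume(pet), is_volume(wm_prob), inherits(psf, "psf_model"))
  assert_same_grid(pet, wm_prob)
  sel <- which(unclass(wm_prob) > wm_threshold & is.finite(unclass(pet)))
  if (!length(sel)) {
    stop(sprintf("no voxel has WM probability > %g; cannot estimate WM activity",
                 wm_threshold), call. = FALSE)
  }
  bwm <- unclass(psf_blur(wm_prob, psf))[sel]
  y <- unclass(pet)[sel]
  sum(y * bwm) / sum(bwm^2)
}

#' Mueller-Gartner partial-volume correction
#'
#' Corrects GM voxels for WM spill-in and GM spill-out:
#' `(pet - wm_activity * blur(wm_prob)) / blur(gm_prob)` wherever
#' `gm_prob >= gm_threshold` and the blurred GM probability is above `eps`.
#' All other voxels are undefined (`NA`), never zero; voxels inside the GM
#' threshold whose blurred GM probability is degenerate are also `NA` and are
#' counted in the correction report.
#'
#' @param pet Observed uptake volume.
#' @param gm_prob,wm_prob Tissue probability volumes on the same grid.
#' @param wm_activity Scalar WM activity, normally from
#'   [estimate_wm_activity()].
#' @param psf A [psf_model()].
#' @param gm_threshold GM probability below which a voxel is left undefined
#'   (default 0.3).
#' @param eps Smallest admissible blurred GM probability in the denominator.
#' @return Corrected volume with attributes `wm_activity`, `gm_threshold` and
#'   `n_degenerate`; see [pvc_report()].
#' @export
muller_gartner <- function(pet, gm_prob, wm_prob, wm_activity,
                           psf = psf_model(), gm_threshold = 0.3,
                           eps = 1e-3) {
  stopifnot(is_volume(pet), is_volume(gm_prob), is_volume(wm_prob),
            is.numeric(wm_activity), length(wm_activity) == 1L)
  if (gm_threshold <= 0 || gm_threshold >= 1) {
    stop("`gm_threshold` must be in (0, 1)", call. = FALSE)
  }
  assert_same_grid(pet, gm_prob)
  assert_same_grid(pet, wm_prob)
  bgm <- unclass(psf_blur(gm_prob, psf))
  bwm <- unclass(psf_blur(wm_prob, psf))
  inside <- unclass(gm_prob) >= gm_threshold
  degenerate <- inside & bgm <= eps
  keep <- inside & !degenerate
  out <- array(NA_real_, dim(pet))
  out[keep] <- (unclass(pet)[keep] - wm_activity * bwm[keep]) / bgm[keep]
  res <- like_volume(out, pet)
  attr(res, "wm_activity") <- wm_activity
  attr(res, "gm_threshold") <- gm_threshold
  attr(res, "n_degenerate") <- sum(degenerate)
  res
}

#' Report on a Mueller-Gartner correction
#'
#' @param vol A [muller_gartner()] output.
#' @return One-row tibble with the WM activity used, the GM threshold, the
#'   number of defined voxels and the number of degenerate (excluded) voxels.
#' @export
pvc_report <- function(vol) {
  stopifnot(is_volume(vol), !is.null(attr(vol, "wm_activity")))
  tibble::tibble(
    wm_activity = attr(vol, "wm_activity"),
    gm_threshold = attr(vol, "gm_threshold"),
    n_defined = sum(is.finite(vol)),
    n_degenerate = attr(vol, "n_degenerate")
  )
}

#' Region-based (geometric transfer matrix) partial-volume correction
#'
#' Solves the GTM linear system for true regional means: entry (r, s) of the
#' transfer matrix is the mean over region r of the PSF-blurred indicator of
#' region s, and the right-hand side is the observed regional mean of the PET
#' image. With `fwhm = 0` the matrix is the identity and corrected means equal
#' raw means. When tissue probability maps are supplied, a WM background
#' compartment (`wm_prob >= 0.5` outside the atlas) absorbs spill from
#' unlabelled tissue.
#'
#' @param pet Observed uptake volume.
#' @param atlas Integer-label volume (0 = unlabelled).
#' @param psf A [psf_model()].
#' @param gm_prob,wm_prob Optional tissue probability volumes enabling the WM
#'   background compartment.
#' @param labels Optional tibble `label`/`name` for naming the output rows.
#' @param max_condition Condition-number ceiling; a worse-conditioned transfer
#'   matrix is an error.
#' @return Tibble with `region`, `label`, `n_voxels`, `observed_mean`,
#'   `corrected_mean` (background row dropped).
#' @export
region_based_correct <- function(pet, atlas, psf = psf_model(),
                                 gm_prob = NULL, wm_prob = NULL,
                                 labels = NULL, max_condition = 1e8) {
  stopifnot(is_volume(pet), is_volume(atlas))
  assert_same_grid(pet, atlas)
  lab <- as.integer(unclass(atlas))
  ids <- sort(unique(lab[lab > 0L]))
  if (!length(ids)) stop("atlas contains no labelled region", call. = FALSE)

  masks <- lapply(ids, function(l) lab == l)
  names(masks) <- as.character(ids)
  if (!is.null(wm_prob)) {
    assert_same_grid(pet, wm_prob)
    bg <- lab == 0L & unclass(wm_prob) >= 0.5
    if (any(bg)) masks <- c(masks, list(background = bg))
  }
  m <- length(masks)
  blurred <- lapply(masks, function(mk) {
    unclass(psf_blur(like_volume(mk * 1, pet), psf))
  })
  idx <- lapply(masks, which)
  W <- matrix(0, m, m)
  for (r in seq_len(m)) {
    for (s in seq_len(m)) {
      W[r, s] <- mean(blurred[[s]][idx[[r]]])
    }
  }
  kap <- kappa(W, exact = TRUE)
  if (!is.finite(kap) || kap > max_condition) {
    stop(sprintf("geometric transfer matrix is ill-conditioned (condition number %.3g)",
                 kap), call. = FALSE)
  }
  o <- vapply(idx, function(i) mean(unclass(pet)[i]), numeric(1))
  t_hat <- solve(W, o)

  keep <- seq_along(ids)
  out <- tibble::tibble(
    label = ids,
    n_voxels = vapply(idx[keep], length, integer(1)),
    observed_mean = unname(o[keep]),
    corrected_mean = unname(t_hat[keep])
  )
  if (!is.null(labels)) {
    out$region <- labels$name[match(out$label, labels$label)]
  } else {
    out$region <- as.character(out$label)
  }
  attr(out, "condition_number") <- kap
  dplyr::relocate(out, "region")
}
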