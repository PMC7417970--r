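#' Create a volume
#'
#' A volume is a plain 3-D numeric array carrying its isotropic voxel size (mm)
#' and a shared-space identifier. All image-valued operations in the package
#' consume and produce volumes; voxels whose value is undefined (for example
#' outside the support of a partial-volume correction) are `NA`, never zero.
#'
#' @param data 3-D numeric or logical array.
#' @param voxel_mm Positive scalar, isotropic voxel edge length in mm.
#' @param space Character identifier of the analysis space; volumes may only be
#'   combined when dimensions, voxel size and space all agree.
#' @return An object of class `volume`.
#' @export
new_volume <- function(data, voxel_mm = 3, space = "phantom") {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-D array", call. = FALSE)
  }
  if (!is.numeric(voxel_mm) || length(voxel_mm) != 1L || !is.finite(voxel_mm) ||
      voxel_mm <= 0) {
    stop("`voxel_mm` must be a positive scalar", call. = FALSE)
  }
  structure(data,
            voxel_mm = as.numeric(voxel_mm),
            space = as.character(space),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<volume> %d x %d x %d voxels @ %g mm, space '%s'\n",
              d[1], d[2], d[3], attr(x, "voxel_mm"), attr(x, "space")))
  v <- x[is.finite(x)]
  if (length(v)) {
    cat(sprintf("  range [%.4g, %.4g], %d NA voxels\n",
                min(v), max(v), sum(!is.finite(x))))
  }
  invisible(x)
}

#' @rdname new_volume
#' @param x Object to test or query.
#' @export
is_volume <- function(x) inherits(x, "volume")

#' @rdname new_volume
#' @export
voxel_mm <- function(x) attr(x, "voxel_mm")

#' Rebuild a volume from raw data on the grid of an existing one
#'
#' @param data Array or vector recyclable to the template's dimensions.
#' @param template Volume supplying grid dimensions, voxel size and space.
#' @return A volume on the template grid.
#' @export
like_volume <- function(data, template) {
  new_volume(array(data, dim(template)),
             voxel_mm = attr(template, "voxel_mm"),
             space = attr(template, "space"))
}

#' @noRd
assert_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b)) ||
      !isTRUE(all.equal(attr(a, "voxel_mm"), attr(b, "voxel_mm"))) ||
      !identical(attr(a, "space"), attr(b, "space"))) {
    stop(sprintf("%s are not on the same grid (dims/voxel size/space differ)",
                 what), call. = FALSE)
  }
  invisible(TRUE)
}

#' Convert a Gaussian FWHM to its standard deviation
#'
#' @param fwhm Full width at half maximum (any length unit).
#' @return Standard deviation in the same unit, `fwhm / (2 sqrt(2 ln 2))`.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# 1-D convolution matrix with whole-sample reflection at the edges
blur_matrix <- function(d, sigma_vox) {
  if (sigma_vox <= 0) return(diag(d))
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  w <- stats::dnorm(seq(-r, r), sd = sigma_vox)
  w <- w / sum(w)
  K <- matrix(0, d, d)
  for (i in seq_len(d)) {
    for (k in seq(-r, r)) {
      j <- i + k
      while (j < 1L || j > d) {
        if (j < 1L) j <- 1L - j
        if (j > d) j <- 2L * d + 1L - j
      }
      K[i, j] <- K[i, j] + w[k + r + 1L]
    }
  }
  K
}

apply_along_axis <- function(x, K, axis) {
  d <- dim(x)
  if (axis == 1L) {
    array(K %*% matrix(x, d[1]), d)
  } else if (axis == 2L) {
    xp <- aperm(x, c(2L, 1L, 3L))
    yp <- array(K %*% matrix(xp, d[2]), d[c(2L, 1L, 3L)])
    aperm(yp, c(2L, 1L, 3L))
  } else {
    xp <- aperm(x, c(3L, 1L, 2L))
    yp <- array(K %*% matrix(xp, d[3]), d[c(3L, 1L, 2L)])
    aperm(yp, c(2L, 3L, 1L))
  }
}

#' Isotropic Gaussian blur of a volume
#'
#' Separable Gaussian convolution with whole-sample reflection at the grid
#' boundaries (so a constant image stays constant). `fwhm_mm = 0` is the
#' identity. `NA` voxels propagate; use [smooth_volume()] for normalized
#' (NA-aware, masked) smoothing.
#'
#' @param vol A [new_volume()] object.
#' @param fwhm_mm Full width at half maximum of the kernel, mm, `>= 0`.
#' @return Blurred volume on the same grid.
#' @export
gaussian_blur <- function(vol, fwhm_mm) {
  stopifnot(is_volume(vol))
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm < 0) {
    stop("`fwhm_mm` must be a single non-negative number", call. = FALSE)
  }
  if (fwhm_mm == 0) return(vol)
  sigma <- fwhm_to_sigma(fwhm_mm) / attr(vol, "voxel_mm")
  x <- unclass(vol)
  attributes(x) <- list(dim = dim(vol))
  d <- dim(x)
  for (ax in 1:3) {
    x <- apply_along_axis(x, blur_matrix(d[ax], sigma), ax)
  }
  like_volume(x, vol)
}

#' Read / write volumes as NIfTI-1
#'
#' Thin wrappers around \pkg{RNifti} that carry the voxel size on the NIfTI
#' `pixdim` field.
#'
#' @param vol Volume to write.
#' @param path File path (`.nii` or `.nii.gz`).
#' @param space Space identifier to attach on read.
#' @return `write_volume()` returns `path` invisibly; `read_volume()` returns a
#'   volume.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_volume(vol))
  x <- unclass(vol)
  attributes(x) <- list(dim = dim(vol))
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- rep(attr(vol, "voxel_mm"), 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, space = "phantom") {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected a 3-D NIfTI image", call. = FALSE)
  new_volume(array(as.numeric(img), d),
             voxel_mm = RNifti::pixdim(img)[1],
             space = space)
}
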