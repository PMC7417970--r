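#' Fit the control-based normative model
#'
#' Per-voxel ordinary least squares of intensity on age over the control
#' group: intercept, age slope and residual SD maps. The residual SD uses the
#' model degrees of freedom, `n - 2`.
#'
#' @param control_images List of control volumes.
#' @param control_ages Ages (years) in image order; must vary.
#' @param mask An [make_analysis_mask()] result or logical volume.
#' @param allow_zero_sd Keep voxels whose residual SD is exactly zero (useful
#'   only for noise-free synthetic data); by default a zero in-mask residual
#'   SD is an error, so W-scores can never divide by zero.
#' @return A `normative_model` with `intercept`, `slope`, `resid_sd` volumes,
#'   `n_controls`, and the mask.
#' @export
fit_normative <- function(control_images, control_ages, mask,
                          allow_zero_sd = FALSE) {
  n <- length(control_images)
  if (n < 3L) stop("at least 3 controls are required", call. = FALSE)
  if (length(control_ages) != n) {
    stop("one age per control image is required", call. = FALSE)
  }
  if (stats::var(control_ages) == 0) {
    stop("control ages are constant; the age slope is not identifiable",
         call. = FALSE)
  }
  mask_arr <- as_mask_array(mask)
  idx <- which(mask_arr)
  Y <- stack_images(control_images, mask_arr)
  X <- cbind(1, control_ages)
  XtXinv <- solve(crossprod(X))
  B <- XtXinv %*% crossprod(X, Y)
  resid <- Y - X %*% B
  sdv <- sqrt(colSums(resid^2) / (n - 2))
  # zero up to numerical noise, relative to the data scale
  scale <- mean(abs(Y[is.finite(Y)]))
  bad <- is.finite(sdv) & sdv <= 1e-8 * max(scale, .Machine$double.eps)
  if (any(bad) && !allow_zero_sd) {
    stop(sprintf("%d in-mask voxel(s) have zero residual SD; refusing to fit a degenerate normative model",
                 sum(bad)), call. = FALSE)
  }
  ref <- control_images[[1]]
  tovol <- function(v) {
    a <- array(NA_real_, dim(ref))
    a[idx] <- v
    like_volume(a, ref)
  }
  structure(list(
    intercept = tovol(B[1, ]),
    slope = tovol(B[2, ]),
    resid_sd = tovol(sdv),
    n_controls = n,
    age_range = range(control_ages),
    mask = mask
  ), class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf("<normative_model> %d controls (ages %.1f-%.1f), %d voxels\n",
              x$n_controls, x$age_range[1], x$age_range[2],
              sum(is.finite(x$resid_sd))))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.normative_model <- function(x, ...) {
  maps <- list(intercept = x$intercept, age_slope = x$slope,
               resid_sd = x$resid_sd)
  purrr::map_dfr(names(maps), function(nm) {
    v <- unclass(maps[[nm]])
    v <- v[is.finite(v)]
    tibble::tibble(term = nm, mean = mean(v), sd = stats::sd(v),
                   min = min(v), max = max(v))
  })
}

#' @export
glance.normative_model <- function(x, ...) {
  sdv <- unclass(x$resid_sd)
  tibble::tibble(
    n_controls = x$n_controls,
    n_voxels = sum(is.finite(sdv)),
    age_min = x$age_range[1], age_max = x$age_range[2],
    median_resid_sd = stats::median(sdv[is.finite(sdv)])
  )
}

#' Per-subject W-score map
#'
#' `W = (raw - (intercept + slope * age)) / resid_sd`, voxelwise in the model
#' mask: a covariate-adjusted z-score quantifying how far a subject's uptake
#' deviates from the value expected for their age in the control group.
#'
#' @param subject_image Volume on the model grid.
#' @param age Subject age (years).
#' @param model A [fit_normative()] model.
#' @param subject_id Optional identifier carried on the result.
#' @return A `wmap`: `w` volume plus `age` and `subject_id`.
#' @export
wmap <- function(subject_image, age, model, subject_id = NULL) {
  stopifnot(inherits(model, "normative_model"), is_volume(subject_image))
  assert_same_grid(subject_image, model$intercept, "subject image and model")
  expected <- unclass(model$intercept) + unclass(model$slope) * age
  w <- (unclass(subject_image) - expected) / unclass(model$resid_sd)
  structure(list(
    w = like_volume(w, subject_image),
    age = age,
    subject_id = subject_id
  ), class = "wmap")
}

#' @export
print.wmap <- function(x, ...) {
  v <- unclass(x$w)
  v <- v[is.finite(v)]
  cat(sprintf("<wmap>%s age %.1f, W range [%.2f, %.2f]\n",
              if (is.null(x$subject_id)) "" else paste0(" ", x$subject_id),
              x$age, min(v), max(v)))
  invisible(x)
}

w_volume <- function(w) if (inherits(w, "wmap")) w$w else w

#' Binarize a W-score map
#'
#' Hypometabolic maps flag `W <= -threshold`; hypermetabolic maps flag
#' `W >= +threshold`. Both boundaries are inclusive.
#'
#' @param w A [wmap()] or W volume.
#' @param direction `"hypo"` or `"hyper"`.
#' @param threshold Positive abnormality threshold (default 1.96, the two-sided
#'   2.5th percentile of the standard normal).
#' @return Logical volume (`NA` voxels are not flagged).
#' @export
binarize_w <- function(w, direction = c("hypo", "hyper"), threshold = 1.96) {
  direction <- match.arg(direction)
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("`threshold` must be positive", call. = FALSE)
  }
  v <- unclass(w_volume(w))
  flag <- if (direction == "hypo") v <= -threshold else v >= threshold
  flag[!is.finite(v)] <- FALSE
  like_volume(flag, w_volume(w))
}

#' W-score frequency map
#'
#' Voxelwise count and fraction of subjects whose binarized W-map flags the
#' voxel, summarizing how consistently an abnormality recurs across a cohort.
#'
#' @param binary_maps Non-empty list of logical volumes on one grid.
#' @return A `wscore_frequency`: `counts` and `fraction` volumes, `n`,
#'   `max_fraction`, and `max_location` (voxel index triple of the first
#'   maximum).
#' @export
frequency_map <- function(binary_maps) {
  if (!length(binary_maps)) stop("need at least one map", call. = FALSE)
  ref <- binary_maps[[1]]
  acc <- array(0L, dim(ref))
  for (b in binary_maps) {
    assert_same_grid(ref, b)
    acc <- acc + (unclass(b) %in% TRUE)
  }
  n <- length(binary_maps)
  frac <- acc / n
  imax <- which.max(frac)
  structure(list(
    counts = like_volume(acc, ref),
    fraction = like_volume(frac, ref),
    n = n,
    max_fraction = frac[imax],
    max_location = arrayInd(imax, dim(ref))[1, ]
  ), class = "wscore_frequency")
}

#' @export
print.wscore_frequency <- function(x, ...) {
  cat(sprintf("<wscore_frequency> %d subjects, max fraction %.3f (%.0f%%) at voxel (%s)\n",
              x$n, x$max_fraction, 100 * x$max_fraction,
              paste(x$max_location, collapse = ", ")))
  invisible(x)
}

#' Mean W-score map
#'
#' @param wmaps Non-empty list of [wmap()]s or W volumes on one grid.
#' @return Volume of voxelwise arithmetic means.
#' @export
mean_wmap <- function(wmaps) {
  if (!length(wmaps)) stop("need at least one W-map", call. = FALSE)
  vols <- lapply(wmaps, w_volume)
  ref <- vols[[1]]
  acc <- array(0, dim(ref))
  for (v in vols) {
    assert_same_grid(ref, v)
    acc <- acc + unclass(v)
  }
  like_volume(acc / length(vols), ref)
}

#' Central standard-normal probability mass
#'
#' Mass of the standard normal on `[-z, +z]`; `central_mass(1.96)` is 0.95 to
#' four decimals, which motivates the conventional W-score abnormality
#' threshold.
#'
#' @param z Non-negative scalar.
#' @return Probability in `[0, 1)`.
#' @export
central_mass <- function(z) {
  if (!is.numeric(z) || length(z) != 1L || is.na(z) || z < 0) {
    stop("`z` must be a single non-negative number", call. = FALSE)
  }
  stats::pnorm(z) - stats::pnorm(-z)
}

#' Per-subject suprathreshold voxel counts by atlas region
#'
#' @param binary_maps Named list of logical volumes (one per subject).
#' @param template A `template_set`.
#' @param mask Optional analysis mask restricting the counts.
#' @return Tibble `subject_id`, `region`, `n_voxels`, `n_suprathreshold`,
#'   `any_suprathreshold`.
#' @export
region_supra_counts <- function(binary_maps, template, mask = NULL) {
  lab <- unclass(template$atlas)
  keep <- if (is.null(mask)) rep(TRUE, length(lab)) else as_mask_array(mask)
  purrr::map_dfr(names(binary_maps), function(id) {
    b <- unclass(binary_maps[[id]]) & keep
    purrr::map_dfr(seq_len(nrow(template$labels)), function(i) {
      l <- template$labels$label[i]
      sel <- lab == l & keep
      tibble::tibble(
        subject_id = id,
        region = template$labels$name[i],
        n_voxels = sum(sel),
        n_suprathreshold = sum(b[sel])
      )
    })
  }) |>
    dplyr::mutate(any_suprathreshold = .data$n_suprathreshold > 0L)
}
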