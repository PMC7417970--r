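#' Build a group-comparison design matrix
#'
#' Columns are an intercept, a carrier indicator, and optional mean-centered
#' age and total-intracranial-volume nuisance covariates. The contrast tests
#' the group difference one-sidedly: `direction = "hypo"` targets lower values
#' in carriers (control minus carrier), `"hyper"` the reverse.
#'
#' @param group Factor (or character) with levels `control` and `carrier`, one
#'   entry per subject in image order.
#' @param age,tiv Optional numeric nuisance covariates.
#' @param direction `"hypo"` or `"hyper"`.
#' @return A `design_matrix`: list with matrix `X`, numeric `contrast` and the
#'   group factor.
#' @export
make_design <- function(group, age = NULL, tiv = NULL,
                        direction = c("hypo", "hyper")) {
  direction <- match.arg(direction)
  group <- factor(as.character(group), levels = c("control", "carrier"))
  if (anyNA(group)) {
    stop("`group` must only contain 'control' and 'carrier'", call. = FALSE)
  }
  X <- cbind(intercept = 1, carrier = as.numeric(group == "carrier"))
  if (!is.null(age)) X <- cbind(X, age = age - mean(age))
  if (!is.null(tiv)) X <- cbind(X, tiv = tiv - mean(tiv))
  contrast <- stats::setNames(numeric(ncol(X)), colnames(X))
  contrast["carrier"] <- if (direction == "hypo") -1 else 1
  structure(list(X = X, contrast = contrast, group = group,
                 direction = direction),
            class = "design_matrix")
}

# stack masked voxels into a subjects x voxels matrix
stack_images <- function(images, mask_arr) {
  idx <- which(mask_arr)
  t(vapply(images, function(im) unclass(im)[idx], numeric(length(idx))))
}

validate_design <- function(design, n) {
  stopifnot(is.list(design), !is.null(design$X), !is.null(design$contrast))
  X <- design$X
  cvec <- design$contrast
  if (nrow(X) != n) stop("one image per design row is required", call. = FALSE)
  if (length(cvec) != ncol(X)) {
    stop("contrast length must equal the number of design columns",
         call. = FALSE)
  }
  if (all(cvec == 0)) stop("contrast must not be all zeros", call. = FALSE)
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient", call. = FALSE)
  }
  if (n <= ncol(X) + 1L) {
    stop("need more subjects than design columns + 1", call. = FALSE)
  }
  invisible(TRUE)
}

# precompute the pieces of the mass-univariate t statistic
t_engine <- function(X, cvec) {
  XtXinv <- solve(crossprod(X))
  A <- XtXinv %*% t(X)
  Rf <- diag(nrow(X)) - X %*% A
  list(cA = drop(crossprod(cvec, A)),
       cfac = drop(crossprod(cvec, XtXinv %*% cvec)),
       Rf = Rf,
       df = nrow(X) - ncol(X))
}

engine_t <- function(eng, Y) {
  num <- drop(eng$cA %*% Y)
  s2 <- colSums((eng$Rf %*% Y)^2) / eng$df
  tt <- num / sqrt(eng$cfac * s2)
  tt[!is.finite(tt)] <- NA_real_
  tt
}

#' Mass-univariate GLM over an analysis mask
#'
#' Ordinary least squares per voxel; the returned t statistic is
#' `contrast' beta / SE` with `df = n - rank(X)`. Voxels with a missing value
#' in any subject are left `NA`.
#'
#' @param images List of volumes, one per design row.
#' @param design A [make_design()] result (or list with `X` and `contrast`).
#' @param mask An [make_analysis_mask()] result or logical volume.
#' @return A `voxel_glm`: t-map and effect-size (`contrast' beta`) volumes,
#'   degrees of freedom, and the design.
#' @export
fit_glm <- function(images, design, mask) {
  n <- length(images)
  validate_design(design, n)
  mask_arr <- as_mask_array(mask)
  Y <- stack_images(images, mask_arr)
  ok <- colSums(!is.finite(Y)) == 0L
  eng <- t_engine(design$X, design$contrast)
  tvals <- rep(NA_real_, ncol(Y))
  evals <- rep(NA_real_, ncol(Y))
  if (any(ok)) {
    Yok <- Y[, ok, drop = FALSE]
    tvals[ok] <- engine_t(eng, Yok)
    beta_c <- drop(eng$cA %*% Yok)
    evals[ok] <- beta_c
  }
  ref <- images[[1]]
  tmap <- array(NA_real_, dim(ref))
  emap <- array(NA_real_, dim(ref))
  idx <- which(mask_arr)
  tmap[idx] <- tvals
  emap[idx] <- evals
  structure(list(
    tmap = like_volume(tmap, ref),
    effect = like_volume(emap, ref),
    df = eng$df, design = design, n = n,
    mask = mask
  ), class = "voxel_glm")
}

#' @export
print.voxel_glm <- function(x, ...) {
  cat(sprintf("<voxel_glm> n = %d, df = %d, %d voxels fit\n",
              x$n, x$df, sum(is.finite(x$tmap))))
  invisible(x)
}

#' Threshold a t-map at an uncorrected one-sided height
#'
#' Retains voxels whose t exceeds the upper-tail Student-t quantile at `p`.
#'
#' @param tmap t-statistic volume.
#' @param df Degrees of freedom (`>= 1`).
#' @param p One-sided height probability, in `(0, 0.5]` (default 0.001).
#' @return Logical volume with attribute `critical_t`.
#' @export
height_threshold <- function(tmap, df, p = 0.001) {
  stopifnot(is_volume(tmap), df >= 1)
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 0.5) {
    stop("`p` must be in (0, 0.5]", call. = FALSE)
  }
  crit <- stats::qt(1 - p, df)
  out <- like_volume(is.finite(unclass(tmap)) & unclass(tmap) > crit, tmap)
  attr(out, "critical_t") <- crit
  out
}

conn_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
  s <- rowSums(abs(g))
  switch(as.character(connectivity),
         "6" = g[s == 1L, , drop = FALSE],
         "18" = g[s <= 2L, , drop = FALSE],
         "26" = g,
         stop("`connectivity` must be 6, 18 or 26", call. = FALSE))
}

# connected components of a logical 3-D array; returns list of member index
# vectors (unsorted order of discovery)
components3d <- function(b, offs) {
  d <- dim(b)
  idx <- which(b)
  comps <- list()
  if (!length(idx)) return(comps)
  unvisited <- b
  for (start in idx) {
    if (!unvisited[start]) next
    unvisited[start] <- FALSE
    frontier <- start
    members <- start
    while (length(frontier)) {
      fc <- arrayInd(frontier, d)
      nb <- integer(0)
      for (k in seq_len(nrow(offs))) {
        n1 <- fc[, 1] + offs[k, 1]
        n2 <- fc[, 2] + offs[k, 2]
        n3 <- fc[, 3] + offs[k, 3]
        ok <- n1 >= 1L & n1 <= d[1] & n2 >= 1L & n2 <= d[2] &
          n3 >= 1L & n3 <= d[3]
        if (!any(ok)) next
        lin <- n1[ok] + (n2[ok] - 1L) * d[1] + (n3[ok] - 1L) * d[1] * d[2]
        lin <- lin[unvisited[lin]]
        if (length(lin)) {
          unvisited[lin] <- FALSE
          nb <- c(nb, lin)
        }
      }
      frontier <- unique(nb)
      members <- c(members, frontier)
    }
    comps[[length(comps) + 1L]] <- members
  }
  comps
}

#' Connected suprathreshold clusters
#'
#' Connected components of a binary volume under 18-connectivity
#' (faces + edges; 6 and 26 also available), dropping components smaller than
#' the extent threshold.
#'
#' @param binary Logical volume (e.g. from [height_threshold()]).
#' @param connectivity 6, 18 or 26.
#' @param extent Minimum voxel count for a cluster to be kept (default 150).
#' @return Tibble `cluster_id`, `size`, `voxels` (list of linear indices),
#'   ordered by decreasing size, with attribute `label_map` (integer volume,
#'   0 outside clusters).
#' @export
clusterize <- function(binary, connectivity = 18, extent = 150) {
  stopifnot(is_volume(binary) || is.array(binary))
  b <- as_mask_array(binary)
  b[is.na(b)] <- FALSE
  comps <- components3d(b, conn_offsets(connectivity))
  comps <- comps[order(-vapply(comps, length, integer(1)))]
  comps <- comps[vapply(comps, length, integer(1)) >= extent]
  lab <- array(0L, dim(b))
  for (i in seq_along(comps)) lab[comps[[i]]] <- i
  out <- tibble::tibble(
    cluster_id = seq_along(comps),
    size = vapply(comps, length, integer(1)),
    voxels = comps
  )
  attr(out, "label_map") <- if (is_volume(binary)) {
    like_volume(lab, binary)
  } else {
    lab
  }
  out
}

max_component_size <- function(b, offs) {
  comps <- components3d(b, offs)
  if (!length(comps)) 0L else max(vapply(comps, length, integer(1)))
}

#' Percent group difference within a voxel set
#'
#' `100 * (control mean - carrier mean) / control mean`, where the group
#' means are voxelwise subject averages, then averaged over the voxels of the
#' cluster at which both group means are defined.
#'
#' @param images List of volumes, one per subject.
#' @param groups Factor with levels `control`/`carrier` in image order.
#' @param voxels Integer vector of linear voxel indices (a `voxels` entry of a
#'   [clusterize()] table).
#' @return Percent difference (positive = lower in carriers).
#' @export
percent_difference <- function(images, groups, voxels) {
  if (!length(voxels)) stop("cluster is empty", call. = FALSE)
  groups <- factor(as.character(groups), levels = c("control", "carrier"))
  M <- vapply(images, function(im) unclass(im)[voxels],
              numeric(length(voxels)))
  M <- matrix(M, nrow = length(voxels))
  mc <- rowMeans(M[, groups == "control", drop = FALSE])
  mk <- rowMeans(M[, groups == "carrier", drop = FALSE])
  ok <- is.finite(mc) & is.finite(mk)
  if (!any(ok)) stop("no defined voxel in cluster for both groups", call. = FALSE)
  cm <- mean(mc[ok])
  if (!is.finite(cm) || cm == 0) {
    stop("control mean over cluster is zero; percent difference undefined",
         call. = FALSE)
  }
  100 * (cm - mean(mk[ok])) / cm
}

#' Cluster-level familywise-error inference by permutation
#'
#' Fits the GLM, forms suprathreshold clusters at the one-sided height
#' threshold, and assigns each cluster a familywise-error-corrected p value
#' from the permutation distribution of the maximal suprathreshold cluster
#' size. Nuisance covariates are handled by Freedman-Lane residualization:
#' reduced-model residuals are row-permuted, the reduced fit is added back,
#' and the full-model t statistic is recomputed. Corrected p uses add-one
#' smoothing: `(1 + #\{perm max >= observed size\}) / (1 + n_perm)`.
#'
#' @param images List of volumes (the smoothed, normalized analysis images).
#' @param design A [make_design()] result.
#' @param mask An [make_analysis_mask()] result or logical volume.
#' @param n_perm Number of permutations (>= 500 recommended; fewer warns).
#' @param seed Mandatory integer seed for the permutation stream.
#' @param height_p One-sided height threshold probability (default 0.001).
#' @param cluster_p Cluster-level corrected threshold (default 0.05).
#' @param extent Minimum cluster extent in voxels (default 150).
#' @param connectivity Cluster connectivity (default 18).
#' @param pd_images Optional list of volumes on which the per-cluster percent
#'   difference is measured (defaults to `images`); pass the normalized,
#'   unsmoothed images to report effect sizes free of smoothing dilution.
#' @return A `cluster_fwe` object whose `table` is a tibble with `cluster_id`,
#'   `size`, `peak_t`, `peak_ijk`, `peak_mm`, `p_fwe`, `pct_diff`,
#'   `significant`.
#' @export
cluster_fwe <- function(images, design, mask, n_perm = 500, seed = NULL,
                        height_p = 0.001, cluster_p = 0.05, extent = 150,
                        connectivity = 18, pd_images = NULL) {
  if (is.null(seed)) {
    stop("a permutation `seed` is mandatory for reproducible inference",
         call. = FALSE)
  }
  if (n_perm < 500) {
    warning("n_perm < 500 gives a coarse corrected-p resolution")
  }
  n <- length(images)
  validate_design(design, n)
  groups <- design$group
  if (!is.null(groups) && any(table(groups) < 3L)) {
    stop("each group needs at least 3 subjects for permutation inference",
         call. = FALSE)
  }
  mask_arr <- as_mask_array(mask)
  idx <- which(mask_arr)
  Y <- stack_images(images, mask_arr)
  ok <- colSums(!is.finite(Y)) == 0L
  Yok <- Y[, ok, drop = FALSE]
  okidx <- idx[ok]
  eng <- t_engine(design$X, design$contrast)
  crit <- stats::qt(1 - height_p, eng$df)
  offs <- conn_offsets(connectivity)
  d <- dim(images[[1]])

  binarize <- function(tvals) {
    b <- array(FALSE, d)
    b[okidx] <- is.finite(tvals) & tvals > crit
    b
  }

  t_obs <- engine_t(eng, Yok)
  obs_tab <- clusterize(like_volume(binarize(t_obs), images[[1]]),
                        connectivity = connectivity, extent = extent)

  # Freedman-Lane: permute reduced-model residuals, add back the reduced fit
  nuis <- which(design$contrast == 0)
  if (length(nuis)) {
    Z <- design$X[, nuis, drop = FALSE]
    Hz <- Z %*% solve(crossprod(Z)) %*% t(Z)
    E <- Yok - Hz %*% Yok
    Yfit <- Hz %*% Yok
  } else {
    E <- Yok
    Yfit <- matrix(0, nrow(Yok), ncol(Yok))
  }
  perm_max <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(b) {
      pm <- sample.int(n)
      tt <- engine_t(eng, E[pm, , drop = FALSE] + Yfit)
      max_component_size(binarize(tt), offs)
    }, integer(1))
  })

  tmap <- array(NA_real_, d)
  tmap[okidx] <- t_obs
  tmap <- like_volume(tmap, images[[1]])

  tab <- obs_tab
  if (nrow(tab)) {
    tab$peak_t <- vapply(tab$voxels, function(v) max(tmap[v]), numeric(1))
    peak_idx <- vapply(tab$voxels, function(v) v[which.max(tmap[v])],
                       numeric(1))
    pk <- arrayInd(as.integer(peak_idx), d)
    ctr <- (d + 1) / 2
    tab$peak_ijk <- lapply(seq_len(nrow(pk)), function(i) pk[i, ])
    tab$peak_mm <- lapply(seq_len(nrow(pk)), function(i) {
      (pk[i, ] - ctr) * voxel_mm(images[[1]])
    })
    tab$p_fwe <- vapply(tab$size, function(s) {
      (1 + sum(perm_max >= s)) / (1 + n_perm)
    }, numeric(1))
    tab$pct_diff <- if (!is.null(groups)) {
      vapply(tab$voxels, function(v) {
        percent_difference(pd_images %||% images, groups, v)
      }, numeric(1))
    } else {
      NA_real_
    }
    tab$significant <- tab$p_fwe < cluster_p
  } else {
    tab$peak_t <- numeric(0)
    tab$peak_ijk <- list()
    tab$peak_mm <- list()
    tab$p_fwe <- numeric(0)
    tab$pct_diff <- numeric(0)
    tab$significant <- logical(0)
  }

  structure(list(
    table = tab, tmap = tmap, df = eng$df, critical_t = crit,
    height_p = height_p, cluster_p = cluster_p, extent = extent,
    connectivity = connectivity, n_perm = n_perm, seed = as.integer(seed),
    perm_max = perm_max,
    label_map = attr(obs_tab, "label_map")
  ), class = "cluster_fwe")
}

#' @export
print.cluster_fwe <- function(x, ...) {
  cat(sprintf("<cluster_fwe> df = %d, height t > %.3f, extent >= %d, %d permutations\n",
              x$df, x$critical_t, x$extent, x$n_perm))
  if (nrow(x$table)) {
    print(dplyr::select(x$table, "cluster_id", "size", "peak_t", "p_fwe",
                        "pct_diff", "significant"))
  } else {
    cat("  no suprathreshold cluster\n")
  }
  invisible(x)
}

#' Group-by-age slope interaction map
#'
#' GLM with group, age and their interaction; the t-map tests whether the
#' age slope differs between carriers and controls.
#'
#' @param images List of volumes.
#' @param ages Numeric ages in image order.
#' @param groups Factor `control`/`carrier` in image order.
#' @param mask Analysis mask.
#' @return A `voxel_glm` for the interaction contrast.
#' @export
slope_interaction_test <- function(images, ages, groups, mask) {
  groups <- factor(as.character(groups), levels = c("control", "carrier"))
  if (stats::var(ages) == 0) {
    stop("ages are degenerate (no variance)", call. = FALSE)
  }
  spans <- tapply(ages, groups, function(a) diff(range(a)))
  if (any(spans < 10)) {
    warning("age span below 10 years in at least one group; the slope contrast is weakly identified")
  }
  g <- as.numeric(groups == "carrier")
  ac <- ages - mean(ages)
  X <- cbind(intercept = 1, carrier = g, age = ac, carrier_age = g * ac)
  design <- list(X = X,
                 contrast = c(intercept = 0, carrier = 0, age = 0,
                              carrier_age = 1),
                 group = groups)
  fit_glm(images, design, mask)
}
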