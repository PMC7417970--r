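#' Specify a synthetic phantom world
#'
#' Collects every generative assumption of the synthetic study: grid geometry,
#' the linear-in-age uptake model, acquisition blur and noise, the regional
#' lesion and atrophy effects carried by mutation carriers, and the clinical
#' covariate distributions (CSF neurofilaments, cognitive subdomain scores,
#' upper-motor-neuron signs). Defaults encode a presymptomatic-carrier study:
#' 25 controls vs 17 carriers aged 30-65, 5.5 mm scanner resolution, deep-GM
#' hypometabolism of -25%, peri-Rolandic hypermetabolism of +6%, -20% regional
#' GM atrophy, and NfL exceeding the 1227 pg/mL diagnostic cutoff in ~19% of
#' carriers.
#'
#' @param grid_dims Integer vector of 3 grid dimensions (each >= 8).
#' @param voxel_mm Isotropic voxel size, mm.
#' @param n_controls,n_carriers Group sizes; `n_controls >= 3`,
#'   `n_carriers >= 0`.
#' @param age_range Two ages (years), strictly increasing.
#' @param baseline_intercept,age_slope Uptake model: noise-free GM activity at
#'   age 0 (a.u.) and its change per year (negative for age-related decline).
#' @param noise_sd SD of i.i.d. Gaussian voxel noise added to uptake (a.u.).
#' @param wm_uptake_fraction WM activity as a fraction of the GM age line
#'   (FDG grey:white ratio of ~4:1 gives 0.25).
#' @param acquisition_fwhm_mm Scanner point-spread FWHM applied to the
#'   noise-free uptake, mm.
#' @param mri_fwhm_mm Effective resolution of the GM-volume maps, mm.
#' @param gm_noise_sd SD of voxel noise on GM-volume maps.
#' @param lesion_defs Data frame `region`/`effect`: multiplicative metabolic
#'   effects (fractions in (-1, 1); negative = hypometabolism) applied to
#'   carrier uptake within named atlas regions.
#' @param atrophy_defs Data frame `region`/`effect`: analogous multiplicative
#'   effects on carrier GM-volume maps.
#' @param tiv_mean,tiv_sd Total intracranial volume distribution, mm^3.
#' @param sex_female_p Named probabilities of female sex per group.
#' @param nf_params Lognormal parameters for NfL and pNfH; carriers draw NfL
#'   from a mixture with an elevated component hit with probability
#'   `elevated_fraction`.
#' @param ecas_params Normative `mean`/`sd` per cognitive subdomain plus the
#'   fraction of carriers with a deficit and its depth in SD units.
#' @param umn_p Named probabilities of upper-motor-neuron signs per group.
#' @param seed Integer seed; the whole phantom world is deterministic given it.
#' @return A `phantom_spec` object (validated list).
#' @export
phantom_spec <- function(grid_dims = c(48L, 56L, 48L),
                         voxel_mm = 3,
                         n_controls = 25L,
                         n_carriers = 17L,
                         age_range = c(30, 65),
                         baseline_intercept = 100,
                         age_slope = -0.4,
                         noise_sd = 6,
                         wm_uptake_fraction = 0.25,
                         acquisition_fwhm_mm = 5.5,
                         mri_fwhm_mm = 4,
                         gm_noise_sd = 0.02,
                         lesion_defs = default_lesions(),
                         atrophy_defs = default_atrophy(),
                         tiv_mean = 1.45e6,
                         tiv_sd = 1.2e5,
                         sex_female_p = c(control = 12 / 25, carrier = 12 / 17),
                         nf_params = default_nf_params(),
                         ecas_params = default_ecas_params(),
                         umn_p = c(control = 0.04, carrier = 0.59),
                         seed = 1L) {
  grid_dims <- as.integer(grid_dims)
  if (length(grid_dims) != 3L || any(is.na(grid_dims)) || any(grid_dims < 8L)) {
    stop("`grid_dims` must be 3 integers, each >= 8 (degenerate grid)",
         call. = FALSE)
  }
  stopifnot(voxel_mm > 0, acquisition_fwhm_mm >= 0, mri_fwhm_mm >= 0,
            noise_sd >= 0, gm_noise_sd >= 0)
  n_controls <- as.integer(n_controls)
  n_carriers <- as.integer(n_carriers)
  if (is.na(n_controls) || n_controls < 3L) {
    stop("`n_controls` must be >= 3", call. = FALSE)
  }
  if (is.na(n_carriers) || n_carriers < 0L) {
    stop("`n_carriers` must be >= 0", call. = FALSE)
  }
  if (length(age_range) != 2L || diff(age_range) <= 0) {
    stop("`age_range` must be two increasing ages", call. = FALSE)
  }
  lesion_defs <- tibble::as_tibble(lesion_defs)
  atrophy_defs <- tibble::as_tibble(atrophy_defs)
  for (df in list(lesion_defs, atrophy_defs)) {
    if (nrow(df) && (!all(c("region", "effect") %in% names(df)) ||
                     any(abs(df$effect) >= 1))) {
      stop("lesion/atrophy effects need `region` and `effect` in (-1, 1)",
           call. = FALSE)
    }
  }
  structure(list(
    grid_dims = grid_dims, voxel_mm = voxel_mm,
    n_controls = n_controls, n_carriers = n_carriers,
    age_range = as.numeric(age_range),
    baseline_intercept = baseline_intercept, age_slope = age_slope,
    noise_sd = noise_sd, wm_uptake_fraction = wm_uptake_fraction,
    acquisition_fwhm_mm = acquisition_fwhm_mm, mri_fwhm_mm = mri_fwhm_mm,
    gm_noise_sd = gm_noise_sd,
    lesion_defs = lesion_defs, atrophy_defs = atrophy_defs,
    tiv_mean = tiv_mean, tiv_sd = tiv_sd,
    sex_female_p = sex_female_p,
    nf_params = nf_params, ecas_params = ecas_params, umn_p = umn_p,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_lesions <- function() {
  tibble::tibble(
    region = c("thalamus_l", "thalamus_r", "insula_l", "insula_r",
               "peri_rolandic_l", "peri_rolandic_r"),
    effect = c(-0.25, -0.25, -0.25, -0.25, 0.06, 0.06)
  )
}

#' @rdname phantom_spec
#' @export
default_atrophy <- function() {
  tibble::tibble(
    region = c("thalamus_l", "thalamus_r", "insula_l", "insula_r"),
    effect = -0.20
  )
}

#' @rdname phantom_spec
#' @export
default_nf_params <- function() {
  list(
    nfl = list(meanlog = log(650), sdlog = 0.35,
               elevated_fraction = 0.19,
               elevated_meanlog = log(1500), elevated_sdlog = 0.08),
    pnfh = list(meanlog = log(195), sdlog = 0.35)
  )
}

#' @rdname phantom_spec
#' @export
default_ecas_params <- function() {
  list(
    norms = tibble::tibble(
      subdomain = c("language", "fluency", "executive", "memory",
                    "visuospatial"),
      mean = c(27, 18, 38, 17, 11.5),
      sd = c(1.2, 2, 4, 2.5, 0.6)
    ),
    affected_fraction = 0.29,
    affected_shift_sd = 2.2
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %dx%dx%d @ %g mm, %d controls vs %d carriers, ages %g-%g\n",
              x$grid_dims[1], x$grid_dims[2], x$grid_dims[3], x$voxel_mm,
              x$n_controls, x$n_carriers, x$age_range[1], x$age_range[2]))
  cat(sprintf("  uptake %g %+g/yr, noise sd %g, PSF %g mm, seed %d\n",
              x$baseline_intercept, x$age_slope, x$noise_sd,
              x$acquisition_fwhm_mm, x$seed))
  if (nrow(x$lesion_defs)) {
    cat("  lesions:", paste(sprintf("%s %+.0f%%", x$lesion_defs$region,
                                    100 * x$lesion_defs$effect),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

phantom_label_names <- c(
  "frontal_l", "frontal_r", "temporal_l", "temporal_r",
  "parietal_l", "parietal_r", "peri_rolandic_l", "peri_rolandic_r",
  "occipital", "insula_l", "insula_r", "thalamus_l", "thalamus_r",
  "cerebellum"
)

#' Build the synthetic template set
#'
#' Constructs, deterministically from `spec$seed`, the tissue probability maps
#' (GM, WM, CSF), an integer atlas of 14 named parcels (bilateral frontal,
#' temporal, parietal and peri-Rolandic cortex, midline occipital cortex,
#' insulae and thalami as deep-GM islands embedded in WM, and the cerebellum)
#' and a reference intracranial volume. Anatomy is idealized: an ellipsoidal
#' cerebrum with a cortical GM shell over a WM core, ventricular and
#' peripheral CSF, and a separate cerebellar ellipsoid. Cortical parcels are
#' nearest-prototype sectors of the shell; prototype positions are jittered by
#' the seed so different worlds differ.
#'
#' @param spec A [phantom_spec()].
#' @return A `template_set`: `gm_prob`, `wm_prob`, `csf_prob`, `atlas`
#'   volumes, a `labels` tibble, and `tiv_reference` (mm^3).
#' @export
build_template <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_dims
  vox <- spec$voxel_mm
  withr::with_seed(spec$seed, {
    ctr <- (d + 1) / 2
    ax <- 0.42 * d
    X <- (slice.index(array(0, d), 1) - ctr[1]) / ax[1]
    Y <- (slice.index(array(0, d), 2) - ctr[2]) / ax[2]
    Z <- (slice.index(array(0, d), 3) - ctr[3]) / ax[3]
    r <- sqrt(X^2 + Y^2 + Z^2)

    ell <- function(cen, semi) {
      sqrt(((X - cen[1]) / semi[1])^2 + ((Y - cen[2]) / semi[2])^2 +
             ((Z - cen[3]) / semi[3])^2) <= 1
    }
    brain <- r <= 1
    cereb <- ell(c(0, -0.62, -0.60), c(0.45, 0.30, 0.28))
    cerebral <- brain & !cereb
    vent <- ell(c(0, 0.05, 0.05), c(0.10, 0.22, 0.12)) & cerebral
    wm_core <- cerebral & r <= 0.78 & !vent
    cortex <- cerebral & r > 0.78

    thal_l <- ell(c(-0.22, -0.05, 0.02), c(0.17, 0.17, 0.18)) & wm_core
    thal_r <- ell(c(0.22, -0.05, 0.02), c(0.17, 0.17, 0.18)) & wm_core
    ins_l <- ell(c(-0.56, 0.10, 0.05), c(0.11, 0.21, 0.19)) & wm_core
    ins_r <- ell(c(0.56, 0.10, 0.05), c(0.11, 0.21, 0.19)) & wm_core
    islands <- thal_l | thal_r | ins_l | ins_r

    cb_r <- sqrt(((X - 0) / 0.45)^2 + ((Y + 0.62) / 0.30)^2 +
                   ((Z + 0.60) / 0.28)^2)
    cb_gm <- cereb & cb_r > 0.55
    cb_wm <- cereb & cb_r <= 0.55

    gm_bin <- cortex | islands | cb_gm
    wm_bin <- (wm_core & !islands) | cb_wm
    csf_bin <- vent | (r > 1 & r <= 1.07 & !cereb)

    # cortical parcels: nearest prototype in normalized coordinates
    proto <- rbind(
      frontal_l = c(-0.40, 0.72, 0.20), frontal_r = c(0.40, 0.72, 0.20),
      temporal_l = c(-0.80, 0.05, -0.35), temporal_r = c(0.80, 0.05, -0.35),
      parietal_l = c(-0.40, -0.55, 0.55), parietal_r = c(0.40, -0.55, 0.55),
      peri_rolandic_l = c(-0.45, 0.15, 0.80),
      peri_rolandic_r = c(0.45, 0.15, 0.80),
      occipital = c(0, -0.88, 0.10)
    )
    proto <- proto + matrix(stats::runif(length(proto), -0.03, 0.03),
                            nrow(proto), 3)
    atlas <- array(0L, d)
    cidx <- which(cortex)
    dist2 <- sapply(seq_len(nrow(proto)), function(k) {
      (X[cidx] - proto[k, 1])^2 + (Y[cidx] - proto[k, 2])^2 +
        (Z[cidx] - proto[k, 3])^2
    })
    atlas[cidx] <- max.col(-dist2)
    atlas[ins_l] <- 10L
    atlas[ins_r] <- 11L
    atlas[thal_l] <- 12L
    atlas[thal_r] <- 13L
    atlas[cereb] <- 14L

    soften <- function(bin) {
      gaussian_blur(new_volume(bin * 1, vox, "phantom"), 4)
    }
    gm_p <- soften(gm_bin)
    wm_p <- soften(wm_bin)
    csf_p <- soften(csf_bin)
    tot <- unclass(gm_p) + unclass(wm_p) + unclass(csf_p)
    over <- tot > 1
    gm_p[over] <- gm_p[over] / tot[over]
    wm_p[over] <- wm_p[over] / tot[over]
    csf_p[over] <- csf_p[over] / tot[over]

    structure(list(
      gm_prob = gm_p, wm_prob = wm_p, csf_prob = csf_p,
      atlas = new_volume(atlas, vox, "phantom"),
      labels = tibble::tibble(label = seq_along(phantom_label_names),
                              name = phantom_label_names),
      tiv_reference = sum(brain | cereb) * vox^3,
      grid = list(dims = d, voxel_mm = vox, space = "phantom"),
      seed = spec$seed
    ), class = "template_set")
  })
}

#' @export
print.template_set <- function(x, ...) {
  d <- x$grid$dims
  cat(sprintf("<template_set> %dx%dx%d @ %g mm, %d atlas regions, TIV ref %.3g mm^3\n",
              d[1], d[2], d[3], x$grid$voxel_mm, nrow(x$labels),
              x$tiv_reference))
  invisible(x)
}

#' Logical mask of named atlas regions
#'
#' @param template A `template_set`.
#' @param regions Character vector of atlas region names.
#' @return Logical volume, TRUE inside the union of the named regions.
#' @export
region_mask <- function(template, regions) {
  stopifnot(inherits(template, "template_set"))
  ids <- template$labels$label[template$labels$name %in% regions]
  missing <- setdiff(regions, template$labels$name)
  if (length(missing)) {
    stop("unknown atlas region(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  like_volume(unclass(template$atlas) %in% ids, template$atlas)
}

#' Simulate a phantom cohort
#'
#' Draws controls and carriers from the generative model of the spec. The
#' noise-free uptake of a subject of age `a` is
#' `(intercept + slope * a) * (gm_prob + wm_uptake_fraction * wm_prob)`;
#' carriers additionally have each lesioned region multiplied by
#' `1 + effect`. That image is blurred by the acquisition PSF, then i.i.d.
#' Gaussian voxel noise is added (blur before noise: the noise models
#' post-reconstruction variability). GM-volume maps are
#' `(tiv / tiv_reference) * gm_prob` with carrier atrophy effects applied the
#' same way, blurred at `mri_fwhm_mm` and noised. Clinical covariates (sex,
#' TIV, NfL, pNfH, cognitive subdomain scores, UMN signs) are drawn per the
#' spec distributions. Fully deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @param template The matching [build_template()] output.
#' @return A `phantom_cohort`: `participants` tibble, named lists `uptake` and
#'   `gm_volume` of volumes, plus the template and spec.
#' @export
simulate_cohort <- function(spec, template) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(template, "template_set"))
  if (!identical(spec$grid_dims, template$grid$dims) ||
      !isTRUE(all.equal(spec$voxel_mm, template$grid$voxel_mm))) {
    stop("template grid does not match spec", call. = FALSE)
  }
  n <- spec$n_controls + spec$n_carriers
  if (n == 0L) stop("cohort must contain at least one subject", call. = FALSE)
  group <- factor(rep(c("control", "carrier"),
                      c(spec$n_controls, spec$n_carriers)),
                  levels = c("control", "carrier"))
  ids <- sprintf("S%03d", seq_len(n))

  gm <- unclass(template$gm_prob)
  wm <- unclass(template$wm_prob)
  lesion_masks <- lapply(seq_len(nrow(spec$lesion_defs)), function(i) {
    which(region_mask(template, spec$lesion_defs$region[i]))
  })
  atrophy_masks <- lapply(seq_len(nrow(spec$atrophy_defs)), function(i) {
    which(region_mask(template, spec$atrophy_defs$region[i]))
  })

  withr::with_seed(spec$seed + 1L, {
    age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
    sex <- ifelse(stats::runif(n) < spec$sex_female_p[as.character(group)],
                  "F", "M")
    tiv <- stats::rnorm(n, spec$tiv_mean, spec$tiv_sd)

    uptake <- vector("list", n)
    gm_volume <- vector("list", n)
    for (i in seq_len(n)) {
      glevel <- spec$baseline_intercept + spec$age_slope * age[i]
      base <- glevel * gm + spec$wm_uptake_fraction * glevel * wm
      if (group[i] == "carrier") {
        for (k in seq_along(lesion_masks)) {
          base[lesion_masks[[k]]] <-
            base[lesion_masks[[k]]] * (1 + spec$lesion_defs$effect[k])
        }
      }
      img <- gaussian_blur(new_volume(base, spec$voxel_mm, "phantom"),
                           spec$acquisition_fwhm_mm)
      if (spec$noise_sd > 0) {
        img <- like_volume(unclass(img) +
                             stats::rnorm(length(img), 0, spec$noise_sd), img)
      }
      uptake[[i]] <- img

      gvol <- (tiv[i] / template$tiv_reference) * gm
      if (group[i] == "carrier") {
        for (k in seq_along(atrophy_masks)) {
          gvol[atrophy_masks[[k]]] <-
            gvol[atrophy_masks[[k]]] * (1 + spec$atrophy_defs$effect[k])
        }
      }
      gimg <- gaussian_blur(new_volume(gvol, spec$voxel_mm, "phantom"),
                            spec$mri_fwhm_mm)
      if (spec$gm_noise_sd > 0) {
        gimg <- like_volume(unclass(gimg) +
                              stats::rnorm(length(gimg), 0, spec$gm_noise_sd),
                            gimg)
      }
      gm_volume[[i]] <- gimg
    }
    names(uptake) <- ids
    names(gm_volume) <- ids

    nfp <- spec$nf_params
    elevated <- group == "carrier" &
      stats::runif(n) < nfp$nfl$elevated_fraction
    nfl <- ifelse(elevated,
                  stats::rlnorm(n, nfp$nfl$elevated_meanlog,
                                nfp$nfl$elevated_sdlog),
                  stats::rlnorm(n, nfp$nfl$meanlog, nfp$nfl$sdlog))
    pnfh <- stats::rlnorm(n, nfp$pnfh$meanlog, nfp$pnfh$sdlog)

    ep <- spec$ecas_params
    affected <- group == "carrier" & stats::runif(n) < ep$affected_fraction
    ecas <- sapply(seq_len(nrow(ep$norms)), function(k) {
      s <- stats::rnorm(n, ep$norms$mean[k], ep$norms$sd[k])
      if (ep$norms$subdomain[k] %in% c("executive", "fluency")) {
        s <- s - affected * ep$affected_shift_sd * ep$norms$sd[k]
      }
      s
    })
    colnames(ecas) <- paste0("ecas_", ep$norms$subdomain)

    umn_sign <- stats::runif(n) < spec$umn_p[as.character(group)]

    participants <- tibble::tibble(
      subject_id = ids, group = group, age = age, sex = sex, tiv = tiv,
      nfl = nfl, pnfh = pnfh
    )
    participants <- dplyr::bind_cols(participants,
                                     tibble::as_tibble(ecas))
    participants$umn_sign <- unname(umn_sign)

    structure(list(participants = participants, uptake = uptake,
                   gm_volume = gm_volume, template = template, spec = spec),
              class = "phantom_cohort")
  })
}

#' @export
print.phantom_cohort <- function(x, ...) {
  tab <- table(x$participants$group)
  cat(sprintf("<phantom_cohort> %d controls, %d carriers on %s grid\n",
              tab[["control"]], tab[["carrier"]],
              paste(x$template$grid$dims, collapse = "x")))
  invisible(x)
}

#' Write a phantom cohort to disk
#'
#' Writes one NIfTI per subject per modality (`<id>_uptake.nii.gz`,
#' `<id>_gm.nii.gz`), the tissue/atlas template volumes, a `participants.tsv`
#' and a JSON sidecar echoing the generating spec.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$uptake)) {
    write_volume(cohort$uptake[[id]], file.path(dir, paste0(id, "_uptake.nii.gz")))
    write_volume(cohort$gm_volume[[id]], file.path(dir, paste0(id, "_gm.nii.gz")))
  }
  tpl <- cohort$template
  write_volume(tpl$gm_prob, file.path(dir, "template_gm_prob.nii.gz"))
  write_volume(tpl$wm_prob, file.path(dir, "template_wm_prob.nii.gz"))
  write_volume(tpl$csf_prob, file.path(dir, "template_csf_prob.nii.gz"))
  write_volume(tpl$atlas, file.path(dir, "template_atlas.nii.gz"))
  utils::write.table(cohort$participants, file.path(dir, "participants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  spec_json <- cohort$spec
  class(spec_json) <- NULL
  jsonlite::write_json(spec_json, file.path(dir, "phantom_spec.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
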