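#' Configure an end-to-end phantom analysis run
#'
#' Gathers every threshold and seed of the pipeline in one validated object.
#' All thresholds must be present (a `NULL` is a validation error before any
#' computation), and the permutation seed is explicit.
#'
#' @param spec A [phantom_spec()] describing the cohort to simulate.
#' @param perm_seed Integer seed for permutation inference (mandatory).
#' @param out_dir Output directory, or `NULL` to return results in memory
#'   only.
#' @param n_perm Permutations for cluster-level FWE control.
#' @param height_p,cluster_p,extent,connectivity Cluster inference settings.
#' @param mask_threshold Absolute GM threshold of the analysis mask.
#' @param excluded_labels Atlas regions excluded from all analyses.
#' @param reference_labels SUVR reference regions.
#' @param smooth_fwhm_mm Smoothing kernel FWHM, mm.
#' @param w_threshold W-score abnormality threshold.
#' @param wm_threshold,gm_threshold Tissue thresholds of the partial-volume
#'   correction.
#' @param psf_fwhm_mm PSF FWHM assumed by the correction; defaults to the
#'   spec's acquisition FWHM.
#' @param cutoffs A [cutoff_config()].
#' @param run_vbm,run_voi,run_wscore Stage switches.
#' @return A validated `run_config`.
#' @export
run_config <- function(spec = phantom_spec(), perm_seed = NULL,
                       out_dir = NULL, n_perm = 500,
                       height_p = 0.001, cluster_p = 0.05, extent = 150,
                       connectivity = 18, mask_threshold = 0.1,
                       excluded_labels = "occipital",
                       reference_labels = "cerebellum",
                       smooth_fwhm_mm = 8, w_threshold = 1.96,
                       wm_threshold = 0.95, gm_threshold = 0.3,
                       psf_fwhm_mm = spec$acquisition_fwhm_mm,
                       cutoffs = cutoff_config(),
                       run_vbm = TRUE, run_voi = TRUE, run_wscore = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(perm_seed)) {
    stop("`perm_seed` must be given explicitly", call. = FALSE)
  }
  needed <- list(n_perm = n_perm, height_p = height_p, cluster_p = cluster_p,
                 extent = extent, connectivity = connectivity,
                 mask_threshold = mask_threshold,
                 smooth_fwhm_mm = smooth_fwhm_mm, w_threshold = w_threshold,
                 wm_threshold = wm_threshold, gm_threshold = gm_threshold,
                 psf_fwhm_mm = psf_fwhm_mm)
  for (nm in names(needed)) {
    v <- needed[[nm]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || is.na(v)) {
      stop(sprintf("configuration value `%s` is missing or not a number", nm),
           call. = FALSE)
    }
  }
  stopifnot(inherits(cutoffs, "cutoff_config"))
  structure(c(list(spec = spec, perm_seed = as.integer(perm_seed),
                   out_dir = out_dir, cutoffs = cutoffs,
                   excluded_labels = excluded_labels,
                   reference_labels = reference_labels,
                   run_vbm = isTRUE(run_vbm), run_voi = isTRUE(run_voi),
                   run_wscore = isTRUE(run_wscore)),
              needed),
            class = "run_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

flatten_cluster_table <- function(tab) {
  if (!nrow(tab)) {
    return(tibble::tibble(cluster_id = integer(0), size = integer(0),
                          peak_t = numeric(0), peak_x_mm = numeric(0),
                          peak_y_mm = numeric(0), peak_z_mm = numeric(0),
                          p_fwe = numeric(0), pct_diff = numeric(0),
                          significant = logical(0)))
  }
  mm <- do.call(rbind, tab$peak_mm)
  tibble::tibble(cluster_id = tab$cluster_id, size = tab$size,
                 peak_t = tab$peak_t,
                 peak_x_mm = mm[, 1], peak_y_mm = mm[, 2],
                 peak_z_mm = mm[, 3],
                 p_fwe = tab$p_fwe, pct_diff = tab$pct_diff,
                 significant = tab$significant)
}

#' Run the full phantom analysis pipeline
#'
#' Simulates the cohort, applies Mueller-Gartner partial-volume correction,
#' builds the analysis mask, normalizes and smooths, then runs the group
#' cluster-FWE analyses (tracer hypo- and hypermetabolism; optionally GM
#' volume with TIV as an extra nuisance), the control-based W-score stage
#' with frequency maps, the GTM-corrected volume-of-interest analysis with
#' Benjamini-Hochberg correction, and the clinical summary. Deterministic
#' given the spec seed and `perm_seed`; when `out_dir` is set, writes TSV
#' tables, NIfTI maps, a JSON provenance sidecar and a markdown report.
#'
#' @param config A [run_config()].
#' @param verbose Print stage progress.
#' @return A `pipeline_result` list; see the vignette for a tour.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  spec <- config$spec
  psf <- psf_model(config$psf_fwhm_mm)

  say("stage simulate: %d + %d subjects on %s grid",
      spec$n_controls, spec$n_carriers,
      paste(spec$grid_dims, collapse = "x"))
  template <- run_stage("simulate", build_template(spec))
  cohort <- run_stage("simulate", simulate_cohort(spec, template))
  part <- cohort$participants
  group <- part$group

  say("stage pvc: Mueller-Gartner at %g mm PSF", psf$fwhm_mm)
  pvc_imgs <- run_stage("pvc", {
    lapply(stats::setNames(nm = part$subject_id), function(id) {
      wa <- estimate_wm_activity(cohort$uptake[[id]], template$wm_prob, psf,
                                 wm_threshold = config$wm_threshold)
      muller_gartner(cohort$uptake[[id]], template$gm_prob, template$wm_prob,
                     wa, psf, gm_threshold = config$gm_threshold)
    })
  })
  pvc_tab <- dplyr::mutate(
    purrr::map_dfr(pvc_imgs, pvc_report),
    subject_id = part$subject_id, .before = 1)

  say("stage preprocess: mask, proportional normalization, %g mm smoothing",
      config$smooth_fwhm_mm)
  prep <- run_stage("preprocess", {
    mean_gm <- like_volume(
      Reduce(`+`, lapply(cohort$gm_volume, unclass)) / nrow(part),
      template$gm_prob)
    mask <- make_analysis_mask(mean_gm, template, config$mask_threshold,
                               config$excluded_labels)
    normalized <- lapply(pvc_imgs, proportional_normalize, mask = mask)
    smoothed <- lapply(normalized, smooth_volume,
                       fwhm_mm = config$smooth_fwhm_mm, mask = mask)
    list(mask = mask, normalized = normalized, smoothed = smoothed)
  })
  mask <- prep$mask

  say("stage glm: cluster-FWE, %d permutations", config$n_perm)
  glm_res <- run_stage("glm", {
    hypo <- cluster_fwe(prep$smoothed,
                        make_design(group, part$age, direction = "hypo"),
                        mask, n_perm = config$n_perm,
                        seed = config$perm_seed,
                        height_p = config$height_p,
                        cluster_p = config$cluster_p,
                        extent = config$extent,
                        connectivity = config$connectivity,
                        pd_images = prep$normalized)
    hyper <- cluster_fwe(prep$smoothed,
                         make_design(group, part$age, direction = "hyper"),
                         mask, n_perm = config$n_perm,
                         seed = config$perm_seed + 1L,
                         height_p = config$height_p,
                         cluster_p = config$cluster_p,
                         extent = config$extent,
                         connectivity = config$connectivity,
                         pd_images = prep$normalized)
    list(hypo = hypo, hyper = hyper)
  })

  vbm_res <- NULL
  if (config$run_vbm) {
    say("stage vbm: GM-volume comparison with TIV nuisance")
    vbm_res <- run_stage("vbm", {
      gm_smoothed <- lapply(cohort$gm_volume, smooth_volume,
                            fwhm_mm = config$smooth_fwhm_mm, mask = mask)
      cluster_fwe(gm_smoothed,
                  make_design(group, part$age, part$tiv, direction = "hypo"),
                  mask, n_perm = config$n_perm,
                  seed = config$perm_seed + 2L,
                  height_p = config$height_p, cluster_p = config$cluster_p,
                  extent = config$extent,
                  connectivity = config$connectivity,
                  pd_images = cohort$gm_volume)
    })
  }

  wscore_res <- NULL
  if (config$run_wscore && any(group == "carrier")) {
    say("stage wscore: normative fit on %d controls", sum(group == "control"))
    wscore_res <- run_stage("wscore", {
      ctrl <- part$subject_id[group == "control"]
      carr <- part$subject_id[group == "carrier"]
      model <- fit_normative(prep$smoothed[ctrl],
                             part$age[match(ctrl, part$subject_id)], mask)
      wmaps <- lapply(stats::setNames(nm = carr), function(id) {
        wmap(prep$smoothed[[id]], part$age[match(id, part$subject_id)],
             model, subject_id = id)
      })
      hypo_bin <- lapply(wmaps, binarize_w, direction = "hypo",
                         threshold = config$w_threshold)
      hyper_bin <- lapply(wmaps, binarize_w, direction = "hyper",
                          threshold = config$w_threshold)
      list(model = model, wmaps = wmaps,
           freq_hypo = frequency_map(hypo_bin),
           freq_hyper = frequency_map(hyper_bin),
           mean_w = mean_wmap(wmaps),
           region_counts = region_supra_counts(hypo_bin, template, mask))
    })
  }

  voi_res <- NULL
  if (config$run_voi) {
    say("stage voi: GTM regional correction and group tests")
    voi_res <- run_stage("voi", {
      tab <- purrr::map_dfr(part$subject_id, function(id) {
        rc <- region_based_correct(cohort$uptake[[id]], template$atlas, psf,
                                   gm_prob = template$gm_prob,
                                   wm_prob = template$wm_prob,
                                   labels = template$labels)
        dplyr::mutate(
          dplyr::select(rc, "region", "label", "n_voxels",
                        mean = "corrected_mean"),
          subject_id = id, .before = 1)
      })
      cmp <- group_compare_regions(tab, part, side = "less")
      bh <- benjamini_hochberg(cmp$p_value, q = 0.05)
      cmp$p_adjusted <- bh$p_adjusted
      cmp$rejected <- bh$rejected
      list(table = tab, comparison = cmp)
    })
  }

  say("stage clinical: cohort summary and cutoff classification")
  clinical_res <- run_stage("clinical", {
    carr <- part[part$group == "carrier", ]
    nf <- if (nrow(carr)) {
      dplyr::mutate(flag_nf(carr$nfl, carr$pnfh, config$cutoffs),
                    subject_id = carr$subject_id, .before = 1)
    } else NULL
    norms <- spec$ecas_params$norms
    ecas_cols <- paste0("ecas_", norms$subdomain)
    ecas <- if (nrow(carr) && all(ecas_cols %in% names(part))) {
      purrr::map_dfr(seq_len(nrow(carr)), function(i) {
        sc <- stats::setNames(as.numeric(carr[i, ecas_cols]),
                              norms$subdomain)
        dplyr::mutate(classify_ecas(sc, norms, config$cutoffs),
                      subject_id = carr$subject_id[i], .before = 1)
      })
    } else NULL
    list(summary = cohort_summary(part, config$cutoffs),
         nf_flags = nf, ecas_flags = ecas)
  })

  result <- structure(list(
    config = config, template = template, cohort = cohort,
    pvc_report = pvc_tab, mask = mask,
    normalized = prep$normalized, smoothed = prep$smoothed,
    glm = glm_res, vbm = vbm_res, wscore = wscore_res, voi = voi_res,
    clinical = clinical_res
  ), class = "pipeline_result")

  if (!is.null(config$out_dir)) {
    say("writing outputs to %s", config$out_dir)
    run_stage("write", write_pipeline_outputs(result, config$out_dir))
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  clusters (hypometabolism): %d significant of %d\n",
              sum(x$glm$hypo$table$significant), nrow(x$glm$hypo$table)))
  cat(sprintf("  clusters (hypermetabolism): %d significant of %d\n",
              sum(x$glm$hyper$table$significant), nrow(x$glm$hyper$table)))
  if (!is.null(x$wscore)) {
    cat(sprintf("  W-score hypo frequency max: %.0f%%\n",
                100 * x$wscore$freq_hypo$max_fraction))
  }
  invisible(x)
}

write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(result$cohort$participants, "participants.tsv")
  wt(result$pvc_report, "pvc_report.tsv")
  wt(flatten_cluster_table(result$glm$hypo$table), "clusters_hypo.tsv")
  wt(flatten_cluster_table(result$glm$hyper$table), "clusters_hyper.tsv")
  write_volume(result$glm$hypo$tmap, file.path(dir, "tmap_hypo.nii.gz"))
  write_volume(result$glm$hyper$tmap, file.path(dir, "tmap_hyper.nii.gz"))
  if (!is.null(result$vbm)) {
    wt(flatten_cluster_table(result$vbm$table), "clusters_vbm.tsv")
    write_volume(result$vbm$tmap, file.path(dir, "tmap_vbm.nii.gz"))
  }
  if (!is.null(result$wscore)) {
    write_volume(result$wscore$freq_hypo$fraction,
                 file.path(dir, "wscore_freq_hypo.nii.gz"))
    write_volume(result$wscore$freq_hypo$counts,
                 file.path(dir, "wscore_counts_hypo.nii.gz"))
    write_volume(result$wscore$freq_hyper$fraction,
                 file.path(dir, "wscore_freq_hyper.nii.gz"))
    write_volume(result$wscore$mean_w, file.path(dir, "wscore_mean.nii.gz"))
    wt(result$wscore$region_counts, "wscore_region_counts.tsv")
  }
  if (!is.null(result$voi)) {
    wt(result$voi$table, "voi_means.tsv")
    wt(result$voi$comparison, "voi_comparison.tsv")
  }
  wt(result$clinical$summary, "clinical_summary.tsv")
  if (!is.null(result$clinical$nf_flags)) {
    wt(result$clinical$nf_flags, "nf_flags.tsv")
  }

  prov <- list(
    package = "petnorm",
    version = as.character(utils::packageVersion("petnorm")),
    spec_seed = cfg$spec$seed, perm_seed = cfg$perm_seed,
    n_perm = cfg$n_perm, height_p = cfg$height_p, cluster_p = cfg$cluster_p,
    extent = cfg$extent, connectivity = cfg$connectivity,
    mask_threshold = cfg$mask_threshold,
    excluded_labels = cfg$excluded_labels,
    smooth_fwhm_mm = cfg$smooth_fwhm_mm, w_threshold = cfg$w_threshold,
    wm_threshold = cfg$wm_threshold, gm_threshold = cfg$gm_threshold,
    psf_fwhm_mm = cfg$psf_fwhm_mm,
    nfl_cutoff = cfg$cutoffs$nfl_cutoff,
    pnfh_cutoff = cfg$cutoffs$pnfh_cutoff
  )
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)

  rep <- c(
    "# Phantom pipeline report", "",
    sprintf("- cohort: %d controls vs %d carriers, ages %g-%g",
            cfg$spec$n_controls, cfg$spec$n_carriers,
            cfg$spec$age_range[1], cfg$spec$age_range[2]),
    sprintf("- analysis mask: %d voxels (GM > %g, excluding %s)",
            result$mask$n_voxels, cfg$mask_threshold,
            paste(cfg$excluded_labels, collapse = ", ")),
    sprintf("- inference: height p < %g, cluster FWE p < %g, extent >= %d voxels, %d permutations (seed %d)",
            cfg$height_p, cfg$cluster_p, cfg$extent, cfg$n_perm,
            cfg$perm_seed),
    sprintf("- hypometabolism: %d significant cluster(s)",
            sum(result$glm$hypo$table$significant)),
    sprintf("- hypermetabolism: %d significant cluster(s)",
            sum(result$glm$hyper$table$significant))
  )
  if (!is.null(result$wscore)) {
    rep <- c(rep, sprintf(
      "- W-score (threshold %g): max hypo frequency %.0f%%, max hyper frequency %.0f%%",
      cfg$w_threshold, 100 * result$wscore$freq_hypo$max_fraction,
      100 * result$wscore$freq_hyper$max_fraction))
  }
  if (!is.null(result$voi)) {
    rep <- c(rep, sprintf("- VOI analysis: %d region(s) significant after Benjamini-Hochberg",
                          sum(result$voi$comparison$rejected)))
  }
  writeLines(rep, file.path(dir, "report.md"))
  invisible(dir)
}
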