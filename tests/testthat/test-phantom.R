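test_that("template construction is deterministic and anatomically coherent", {
  spec <- phantom_spec(grid_dims = c(24, 28, 24), seed = 11L)
  t1 <- build_template(spec)
  t2 <- build_template(spec)
  expect_identical(unclass(t1$gm_prob), unclass(t2$gm_prob))
  expect_identical(unclass(t1$atlas), unclass(t2$atlas))

  # probability partition
  tot <- unclass(t1$gm_prob) + unclass(t1$wm_prob) + unclass(t1$csf_prob)
  expect_lte(max(tot), 1 + 1e-12)
  expect_gte(min(unclass(t1$gm_prob)), 0)

  # at least 10 named regions, occipital and cerebellum present
  present <- sort(unique(as.integer(unclass(t1$atlas))))
  present <- present[present > 0]
  expect_gte(length(present), 10)
  expect_true(all(c("occipital", "cerebellum") %in%
                    t1$labels$name[t1$labels$label %in% present]))

  # every labelled voxel lies on brain tissue
  lab_vox <- unclass(t1$atlas) > 0
  expect_true(all((unclass(t1$gm_prob) + unclass(t1$wm_prob))[lab_vox] > 0))

  expect_error(phantom_spec(grid_dims = c(4, 20, 20)), "degenerate")
})

test_that("noise-free unblurred uptake follows the generative GM age line", {
  spec <- phantom_spec(grid_dims = c(20, 24, 20), noise_sd = 0,
                       acquisition_fwhm_mm = 0, wm_uptake_fraction = 0,
                       gm_noise_sd = 0, n_controls = 3, n_carriers = 0,
                       lesion_defs = tibble::tibble(),
                       atrophy_defs = tibble::tibble(), seed = 3L)
  tpl <- build_template(spec)
  co <- simulate_cohort(spec, tpl)
  a <- co$participants$age[1]
  expected <- (spec$baseline_intercept + spec$age_slope * a) *
    unclass(tpl$gm_prob)
  expect_equal(unclass(co$uptake[[1]]), expected, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("carrier lesions scale regional means by exactly 1 + effect when noise-free", {
  spec <- phantom_spec(grid_dims = c(24, 28, 24), noise_sd = 0,
                       acquisition_fwhm_mm = 0, gm_noise_sd = 0,
                       mri_fwhm_mm = 0, age_slope = 0, n_controls = 3,
                       n_carriers = 3, seed = 5L)
  tpl <- build_template(spec)
  co <- simulate_cohort(spec, tpl)
  g <- co$participants$group
  for (i in seq_len(nrow(spec$lesion_defs))) {
    rg <- spec$lesion_defs$region[i]
    eff <- spec$lesion_defs$effect[i]
    idx <- which(unclass(region_mask(tpl, rg)))
    ctrl <- mean(sapply(co$uptake[g == "control"], function(v) mean(v[idx])))
    carr <- mean(sapply(co$uptake[g == "carrier"], function(v) mean(v[idx])))
    expect_equal(carr / ctrl, 1 + eff, tolerance = 1e-10)
  }
  # atrophy applies analogously on GM-volume maps (TIV scaling cancels in
  # the ratio only approximately; compare per-subject against the template)
  for (i in seq_len(nrow(spec$atrophy_defs))) {
    rg <- spec$atrophy_defs$region[i]
    eff <- spec$atrophy_defs$effect[i]
    idx <- which(unclass(region_mask(tpl, rg)))
    carr_id <- co$participants$subject_id[g == "carrier"][1]
    tiv <- co$participants$tiv[co$participants$subject_id == carr_id]
    expected <- (tiv / tpl$tiv_reference) * (1 + eff) *
      mean(unclass(tpl$gm_prob)[idx])
    expect_equal(mean(co$gm_volume[[carr_id]][idx]), expected,
                 tolerance = 1e-10)
  }
})

test_that("regional contrast survives acquisition blur in the region core", {
  spec <- phantom_spec(noise_sd = 0, acquisition_fwhm_mm = 5.5,
                       gm_noise_sd = 0, age_slope = 0, n_controls = 3,
                       n_carriers = 3, seed = 6L)
  tpl <- build_template(spec)
  co <- simulate_cohort(spec, tpl)
  g <- co$participants$group
  # core = voxels whose blurred region indicator stays near 1, i.e. voxels
  # the 5.5 mm kernel cannot mix with tissue outside the region
  rm_ <- region_mask(tpl, "thalamus_l")
  interior <- unclass(gaussian_blur(like_volume(unclass(rm_) * 1, rm_), 5.5))
  idx <- which(unclass(rm_) & interior > 0.99)
  expect_gt(length(idx), 5)
  ctrl <- mean(sapply(co$uptake[g == "control"], function(v) mean(v[idx])))
  carr <- mean(sapply(co$uptake[g == "carrier"], function(v) mean(v[idx])))
  expect_equal(carr / ctrl, 0.75, tolerance = 0.02)
})

test_that("cohorts are reproducible and voxel noise matches the configured SD", {
  spec <- phantom_spec(grid_dims = c(16, 20, 16), n_controls = 100,
                       n_carriers = 100, noise_sd = 6,
                       lesion_defs = tibble::tibble(),
                       atrophy_defs = tibble::tibble(), seed = 9L)
  tpl <- build_template(spec)
  co1 <- simulate_cohort(spec, tpl)
  co2 <- simulate_cohort(spec, tpl)
  expect_identical(co1$participants, co2$participants)
  expect_identical(unclass(co1$uptake[[5]]), unclass(co2$uptake[[5]]))

  # noise-free twin shares the RNG stream up to the noise draws
  spec0 <- spec
  spec0$noise_sd <- 0
  co0 <- simulate_cohort(spec0, tpl)
  expect_identical(co0$participants$age, co1$participants$age)
  resid <- unlist(lapply(seq_len(200), function(i) {
    unclass(co1$uptake[[i]]) - unclass(co0$uptake[[i]])
  }))
  expect_equal(sd(resid), 6, tolerance = 0.05 * 6)
})

test_that("NfL exceeds its cutoff in the configured carrier minority", {
  spec <- phantom_spec(grid_dims = c(16, 20, 16), n_controls = 100,
                       n_carriers = 400,
                       lesion_defs = tibble::tibble(),
                       atrophy_defs = tibble::tibble(), seed = 21L)
  tpl <- build_template(spec)
  co <- simulate_cohort(spec, tpl)
  p <- co$participants
  carr_elev <- mean(p$nfl[p$group == "carrier"] > 1227)
  ctrl_elev <- mean(p$nfl[p$group == "control"] > 1227)
  expect_equal(carr_elev, spec$nf_params$nfl$elevated_fraction,
               tolerance = 0.07)
  expect_lt(ctrl_elev, 0.1)
  expect_true(all(p$nfl > 0) && all(p$pnfh > 0))
  # cognitive deficits in a minority of carriers only
  norms <- spec$ecas_params$norms
  exec_thr <- norms$mean[norms$subdomain == "executive"] -
    1.6449 * norms$sd[norms$subdomain == "executive"]
  frac_abn <- mean(p$ecas_executive[p$group == "carrier"] < exec_thr)
  expect_gt(frac_abn, 0.05)
  expect_lt(frac_abn, 0.5)
})

test_that("cohorts round-trip to disk as NIfTI + TSV + JSON", {
  world <- small_world(c(16, 20, 16), seed = 13L, n_controls = 3,
                       n_carriers = 2)
  co <- simulate_cohort(world$spec, world$template)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "participants.tsv")))
  expect_true(file.exists(file.path(dir, "phantom_spec.json")))
  back <- read_volume(file.path(dir, "S001_uptake.nii.gz"))
  expect_equal(unclass(back), unclass(co$uptake[["S001"]]),
               ignore_attr = TRUE, tolerance = 1e-6)
  tsv <- utils::read.delim(file.path(dir, "participants.tsv"))
  expect_equal(nrow(tsv), 5)
  expect_error(simulate_cohort(world$spec, build_template(
    phantom_spec(grid_dims = c(20, 20, 20)))), "grid")
})
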