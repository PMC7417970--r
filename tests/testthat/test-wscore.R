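test_that("the normative fit matches a per-voxel lm() oracle to 1e-8", {
  set.seed(20)
  d <- c(7, 8, 7)
  gen <- linear_age_images(20, d, intercept = 100, slope = -0.5, sd = 2)
  mask <- new_volume(array(TRUE, d), 3)
  model <- fit_normative(gen$images, gen$ages, mask)
  vox <- sample(prod(d), 50)
  for (v in vox) {
    y <- sapply(gen$images, function(im) im[v])
    lmfit <- lm(y ~ gen$ages)
    expect_equal(model$intercept[v], unname(coef(lmfit)[1]), tolerance = 1e-8)
    expect_equal(model$slope[v], unname(coef(lmfit)[2]), tolerance = 1e-8)
    expect_equal(model$resid_sd[v], summary(lmfit)$sigma, tolerance = 1e-8)
  }
})

test_that("noise-free phantoms are interpolated exactly; degenerate fits are refused", {
  d <- c(6, 6, 6)
  ages <- c(40, 50, 60, 70)
  gen <- linear_age_images(4, d, intercept = 100, slope = -0.5, sd = 0,
                           ages = ages)
  mask <- new_volume(array(TRUE, d), 3)
  # zero residual SD is an error unless explicitly allowed
  expect_error(fit_normative(gen$images, ages, mask), "zero residual SD")
  model <- fit_normative(gen$images, ages, mask, allow_zero_sd = TRUE)
  expect_equal(unclass(model$intercept)[1], 100, tolerance = 1e-10)
  expect_equal(unclass(model$slope)[1], -0.5, tolerance = 1e-10)
  expect_error(fit_normative(gen$images[1:2], ages[1:2], mask), "3 controls")
  expect_error(fit_normative(gen$images, rep(50, 4), mask), "constant")
})

test_that("generative parameters are recovered from a large control group", {
  set.seed(21)
  d <- c(8, 8, 8)
  gen <- linear_age_images(200, d, intercept = 100, slope = -0.5, sd = 2)
  mask <- new_volume(array(TRUE, d), 3)
  model <- fit_normative(gen$images, gen$ages, mask)
  expect_equal(mean(unclass(model$slope)), -0.5, tolerance = 0.05)
  expect_equal(mean(unclass(model$resid_sd)), 2, tolerance = 0.05 * 2)
  gl <- glance(model)
  expect_equal(gl$n_controls, 200)
  expect_equal(gl$n_voxels, prod(d))
  expect_equal(nrow(tidy(model)), 3)
})

test_that("W-scores are the covariate-adjusted z-scores of the formula", {
  d <- c(5, 5, 5)
  mkv <- function(x) new_volume(array(x, d), 3)
  model <- structure(list(intercept = mkv(100), slope = mkv(-0.5),
                          resid_sd = mkv(2), n_controls = 10,
                          age_range = c(30, 65),
                          mask = new_volume(array(TRUE, d), 3)),
                     class = "normative_model")
  # raw equals prediction -> W = 0
  w0 <- wmap(mkv(100 - 0.5 * 50), age = 50, model)
  expect_true(all(abs(unclass(w0$w)) < 1e-12))
  # intercept 100, slope -0.5, SD 2, age 50, raw 71 -> (71 - 75)/2 = -2
  w <- wmap(mkv(71), age = 50, model)
  expect_equal(w$w[1, 1, 1], -2, tolerance = 1e-12)
  expect_error(wmap(new_volume(array(71, c(4, 4, 4)), 3), 50, model), "grid")
})

test_that("binarization thresholds are inclusive on the correct side", {
  d <- c(3, 3, 3)
  w <- new_volume(array(c(-1.96, -1.95, 1.96, 1.95, 0,
                          rep(NA_real_, 22)), d), 3)
  hypo <- binarize_w(w, "hypo")
  hyper <- binarize_w(w, "hyper")
  expect_true(hypo[1])       # -1.96 flagged (boundary included)
  expect_false(hypo[2])      # -1.95 not flagged
  expect_true(hyper[3])      # +1.96 flagged
  expect_false(hyper[4])
  expect_false(hypo[6])      # NA voxels are never flagged
  expect_error(binarize_w(w, "hypo", threshold = -1), "positive")
})

test_that("frequency and mean maps aggregate subjects voxelwise", {
  d <- c(4, 4, 4)
  mkb <- function(flagged) {
    b <- array(FALSE, d)
    if (flagged) b[1, 1, 1] <- TRUE
    new_volume(b, 3)
  }
  maps <- lapply(c(rep(TRUE, 14), rep(FALSE, 3)), mkb)
  fr <- frequency_map(maps)
  expect_equal(fr$counts[1, 1, 1], 14)
  expect_equal(fr$fraction[1, 1, 1], 14 / 17, tolerance = 1e-12)
  expect_equal(round(100 * fr$max_fraction), 82)
  expect_equal(fr$max_location, c(1, 1, 1))
  all_on <- frequency_map(lapply(1:17, function(i) mkb(TRUE)))
  expect_equal(all_on$fraction[1, 1, 1], 1)
  none <- frequency_map(lapply(1:3, function(i) mkb(FALSE)))
  expect_true(all(unclass(none$fraction) == 0))
  expect_error(frequency_map(list()), "at least one")

  mkw <- function(x) new_volume(array(x, d), 3)
  expect_true(all(unclass(mean_wmap(list(mkw(2), mkw(-2)))) == 0))
  expect_equal(mean_wmap(list(mkw(1), mkw(2), mkw(3)))[1, 1, 1], 2)
  expect_equal(unclass(mean_wmap(list(mkw(1.5)))), unclass(mkw(1.5)))
})

test_that("central normal mass reproduces the conventional thresholds", {
  expect_equal(round(central_mass(1.96), 4), 0.95)
  expect_equal(central_mass(0), 0)
  expect_equal(round(central_mass(2.5758), 4), 0.99)
  expect_error(central_mass(-1), "non-negative")
})

test_that("null subjects exceed |W| >= 1.96 at the nominal 2.5% per side", {
  set.seed(22)
  d <- c(13, 13, 13)          # 2197 voxels x 200 subjects > 1e5 draws
  mask <- new_volume(array(TRUE, d), 3)
  gen <- linear_age_images(500, d, intercept = 100, slope = -0.5, sd = 2)
  model <- fit_normative(gen$images, gen$ages, mask)
  nulls <- linear_age_images(200, d, intercept = 100, slope = -0.5, sd = 2)
  rates <- sapply(seq_len(200), function(i) {
    w <- wmap(nulls$images[[i]], nulls$ages[i], model)
    c(mean(unclass(w$w) <= -1.96), mean(unclass(w$w) >= 1.96))
  })
  expect_equal(mean(rates[1, ]), 0.025, tolerance = 0.003 / 0.025)
  expect_equal(mean(rates[2, ]), 0.025, tolerance = 0.003 / 0.025)
})

test_that("W-maps are invariant to a common rescaling of all images", {
  set.seed(23)
  d <- c(6, 6, 6)
  mask <- new_volume(array(TRUE, d), 3)
  gen <- linear_age_images(30, d, intercept = 100, slope = -0.5, sd = 2)
  subj <- new_volume(array(95 + rnorm(prod(d)), d), 3)
  m1 <- fit_normative(gen$images, gen$ages, mask)
  w1 <- wmap(subj, 48, m1)
  sc <- 3.7
  m2 <- fit_normative(lapply(gen$images, function(v) {
    like_volume(unclass(v) * sc, v)
  }), gen$ages, mask)
  w2 <- wmap(like_volume(unclass(subj) * sc, subj), 48, m2)
  expect_equal(unclass(w1$w), unclass(w2$w), tolerance = 1e-10)
})

test_that("suprathreshold voxels are countable by atlas region", {
  world <- small_world()
  tpl <- world$template
  b <- like_volume(array(FALSE, dim(tpl$gm_prob)), tpl$gm_prob)
  thal <- which(unclass(region_mask(tpl, "thalamus_l")))
  b[thal[1:5]] <- TRUE
  counts <- region_supra_counts(list(S1 = b), tpl)
  row <- counts[counts$region == "thalamus_l", ]
  expect_equal(row$n_suprathreshold, 5L)
  expect_true(row$any_suprathreshold)
  expect_equal(sum(counts$n_suprathreshold), 5L)
})
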